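grid_with_missing <- function(rows, cols, n_missing, seed = 1) {
  set.seed(seed)
  m <- matrix(100 + rnorm(rows * cols, 0, 5), rows, cols)
  if (n_missing > 0) m[sample(length(m), n_missing)] <- NA
  m
}

test_that("qc flags plates by overall and per-line missingness", {
  # 80/1536 = 5.21% > 5%
  qc <- qc_flag(toy_plate(grid_with_missing(32, 48, 80)))
  expect_true(qc$flagged)
  expect_equal(qc$reasons, "too_many_missing")

  expect_false(qc_flag(toy_plate(grid_with_missing(32, 48, 0)))$flagged)

  # one full row missing: 48/1536 = 3.1% does not trip the overall rule
  m <- grid_with_missing(32, 48, 0)
  m[7, ] <- NA
  qc <- qc_flag(toy_plate(m))
  expect_true(qc$flagged)
  expect_equal(qc$reasons, "row_or_col_missing")
})

test_that("known-empty spots are excluded from qc denominators", {
  m <- grid_with_missing(8, 12, 0)
  lay <- expand.grid(row = 1:8, col = 1:12)
  lay$gene <- sprintf("g%03d", seq_len(nrow(lay)))
  lay$known_empty <- FALSE
  # 6 known-empty spots with no size reported must not count as missing
  empty_idx <- c(1, 10, 20, 30, 40, 50)
  lay$gene[empty_idx] <- NA; lay$known_empty[empty_idx] <- TRUE
  m[cbind(lay$row[empty_idx], lay$col[empty_idx])] <- NA
  expect_false(qc_flag(toy_plate(m, layout = lay))$flagged)
  # an all-empty plate cannot be assessed
  lay$known_empty[] <- TRUE; lay$gene[] <- NA
  expect_error(qc_flag(toy_plate(m, layout = lay)), "no non-empty")
})

test_that("surface correction flattens trends inside the quadratic span", {
  flat <- toy_plate(matrix(100, 8, 12))
  expect_equal(surface_correct(flat)$size, matrix(100, 8, 12))

  r <- matrix(seq_len(8), 8, 12)
  lin <- toy_plate(10 * r)
  out <- surface_correct(lin)
  expect_equal(out$size, matrix(mean(10 * r), 8, 12), tolerance = 1e-10)
  expect_equal(out$stage, "surface")

  cc <- matrix(seq_len(12), 8, 12, byrow = TRUE)
  bowl <- toy_plate((r - 4.5)^2 + (cc - 6.5)^2)
  expect_equal(surface_correct(bowl)$size,
               matrix(mean(bowl$size), 8, 12), tolerance = 1e-10)
})

test_that("surface fit matches a normal-equations least-squares oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(200 + rnorm(96, 0, 20), 8, 12)
    m[sample(96, 5)] <- NA
    out <- surface_correct(toy_plate(m))$size
    # independent oracle: explicit normal equations on the same basis
    obs <- which(!is.na(m), arr.ind = TRUE)
    y <- m[obs]
    r <- obs[, 1] - mean(obs[, 1]); cc <- obs[, 2] - mean(obs[, 2])
    X <- cbind(1, r, cc, r^2, cc^2, r * cc)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expected <- y - as.vector(X %*% beta) + mean(y)
    expect_equal(out[obs], expected, tolerance = 1e-8)
    # missing positions preserved, plate mean preserved
    expect_identical(is.na(out), is.na(m))
    expect_equal(mean(out, na.rm = TRUE), mean(m, na.rm = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("surface correction enforces its preconditions", {
  small <- toy_plate(matrix(c(rep(NA, 86), rnorm(10, 100)), 8, 12))
  expect_error(surface_correct(small), ">= 12 non-missing")
  done <- surface_correct(toy_plate(matrix(100, 8, 12)))
  expect_error(surface_correct(done), "expects a raw plate")
})

test_that("border correction maps the outer-ring median onto the inner median", {
  m <- matrix(100, 10, 10)
  ring <- chemgenomics:::outer_ring_mask(10, 10)
  m[ring] <- 200
  p <- toy_plate(m, stage = "surface")
  out <- border_correct(p)
  expect_equal(out$size[ring], rep(100, sum(ring)))
  expect_equal(out$size[!ring], m[!ring])  # inner untouched
  expect_equal(out$stage, "border")

  # equal medians: unchanged
  p2 <- toy_plate(matrix(100, 10, 10), stage = "surface")
  expect_equal(border_correct(p2)$size, p2$size)
})

test_that("border correction ignores missing values, matching a dense-subset oracle", {
  set.seed(7)
  m <- matrix(rlnorm(100, log(100), 0.2), 10, 10)
  ring <- chemgenomics:::outer_ring_mask(10, 10)
  m[sample(which(ring), 8)] <- NA
  m[sample(which(!ring), 3)] <- NA
  out <- border_correct(toy_plate(m, stage = "surface"))$size
  ratio <- median(m[!ring], na.rm = TRUE) / median(m[ring], na.rm = TRUE)
  expect_equal(out[ring], m[ring] * ratio)
  expect_error(border_correct(toy_plate(matrix(1, 4, 4), stage = "surface")),
               "at least 5x5")
})

test_that("relative fitness is the ratio of strain to reference medians", {
  mk <- function(val, strain, rep = 1L) {
    plate_grid(matrix(val, 8, 12), plate_id = paste0(strain, rep),
               strain = strain, condition = "c1", replicate = rep,
               batch = 1L, stage = "border")
  }
  fr <- relative_fitness(list(mk(80, "y55")), list(mk(100, "ref")))
  expect_equal(fr$phi, 0.8)
  expect_s3_class(fr, "fitness_record")

  same <- list(mk(100, "ref", 1L), mk(110, "ref", 2L))
  fr2 <- relative_fitness(same, same)
  expect_equal(fr2$phi, c(1, 1))

  # batch mismatch is a contract violation
  other <- mk(100, "ref")
  other$batch <- 2L
  expect_error(relative_fitness(list(mk(80, "y55")), list(other)),
               "same batch")
  zero <- mk(0, "ref")
  expect_error(relative_fitness(list(mk(80, "y55")), list(zero)),
               "reference median")
})

test_that("a condition-effect difference is recovered by phi", {
  lay <- gen_layout(100, 0, c(8, 24), n_empty = 1, seed = 3)
  ce <- c(c1 = 1)
  mkplates <- function(strain, cond_eff) {
    tr <- ground_truth(lay$genes, "c1", strains = strain,
                       condition_effect = c(c1 = cond_eff),
                       noise_sd = 0.1, surface_sd = 0.02,
                       border_factor = 1.2, seed = 21)
    lapply(gen_plates(lay, tr, "c1", n_replicates = 4, strain = strain),
           normalize_plate)
  }
  fr <- relative_fitness(mkplates("slow", 0.5), mkplates("ref", 1))
  expect_equal(mean(fr$phi), 0.5, tolerance = 0.08)
})
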