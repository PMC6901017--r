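test_that("quantile normalization matches hand-computed order statistics", {
  S <- cbind(c1 = c(1, 2, 3), c2 = c(10, 20, 30))
  rownames(S) <- paste0("g", 1:3)
  out <- quantile_normalize(toy_scores(S, normalized = FALSE))
  expect_true(out$normalized)
  expect_equal(unname(out$S[, "c1"]), c(5.5, 11, 16.5))
  expect_equal(unname(out$S[, "c2"]), c(5.5, 11, 16.5))
})

test_that("quantile normalization fixes identical distributions and equalizes columns", {
  set.seed(3)
  vals <- rnorm(50)
  S <- cbind(c1 = vals, c2 = sample(vals), c3 = sample(vals))
  rownames(S) <- sprintf("g%02d", 1:50)
  out <- quantile_normalize(toy_scores(S, normalized = FALSE))
  expect_equal(out$S, S)  # already identical distributions: a fixed point

  # definitional postcondition: all columns share one sorted vector
  S2 <- matrix(rnorm(200), 50, 4,
               dimnames = list(sprintf("g%02d", 1:50), paste0("c", 1:4)))
  out2 <- quantile_normalize(toy_scores(S2, normalized = FALSE))
  sorted <- apply(out2$S, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2])
  expect_equal(sorted[, 1], sorted[, 4])

  # missing values stay missing and are excluded from the ranks
  S3 <- S2; S3[sample(200, 12)] <- NA
  out3 <- quantile_normalize(toy_scores(S3, normalized = FALSE))
  expect_identical(is.na(out3$S), is.na(S3))

  one <- toy_scores(S2[, 1, drop = FALSE], normalized = FALSE)
  expect_warning(res <- quantile_normalize(one), "single condition")
  expect_equal(res$S, one$S)
  expect_error(quantile_normalize(out2), "already")
})

test_that("null genes score near zero and planted sensitivity is direction-specific", {
  fx <- screen_fixture()
  st <- fx$st
  planted <- rbind(st$planted_specific, st$planted_shared,
                   st$planted_background)
  kmat <- outer(rownames(fx$sm_a$S), colnames(fx$sm_a$S), paste)
  null_s <- fx$sm_a$S[!(kmat %in% pair_key(planted))]
  expect_gt(mean(abs(null_s) < 2, na.rm = TRUE), 0.95)

  spec_s <- fx$sm_a$S[kmat %in% pair_key(st$planted_specific)]
  # conditionally essential deletions (multiplier 0.25) score strongly negative
  expect_gt(mean(spec_s < -2, na.rm = TRUE), 0.9)
  expect_lt(median(spec_s, na.rm = TRUE), -4)
})

test_that("scoring is deterministic and respects replicate minima", {
  lay <- gen_layout(40, 0, c(8, 12), n_empty = 2, seed = 12)
  tr <- ground_truth(lay$genes, c("c1", "c2"), strains = "s1", seed = 12)
  plates <- lapply(gen_plates(lay, tr, c("c1", "c2"), n_replicates = 4),
                   normalize_plate)
  a <- compute_sscores(plates, lay)
  b <- compute_sscores(plates, lay)
  expect_identical(a$S, b$S)
  expect_true(all(a$n_rep[!is.na(a$S)] >= 3))

  # a condition with < 3 replicates is dropped with a warning
  keep <- vapply(plates, function(p) p$condition == "c1" | p$replicate <= 2,
                 logical(1))
  expect_warning(cut <- compute_sscores(plates[keep], lay), "dropped")
  expect_equal(colnames(cut$S), "c1")
})

test_that("duplicate positions pool by default and split on request", {
  fx <- screen_fixture()
  st <- fx$st
  dup <- st$layout$duplicate_genes
  pooled <- fx$sm_a
  expect_true(all(dup %in% rownames(pooled$S)))
  expect_false(any(grepl("::", rownames(pooled$S))))
  # pooled duplicates carry roughly twice the measurements
  expect_gt(mean(pooled$n_rep[dup, ]), 1.8 * mean(pooled$n_rep[setdiff(rownames(pooled$S), dup), ]))

  split <- score_simulated_strain(st, "strainA", split_duplicates = TRUE)
  expect_true(all(paste0(dup, "::1") %in% rownames(split$S)))
  expect_true(all(paste0(dup, "::2") %in% rownames(split$S)))
})

test_that("phenotype calls follow the one-tailed normal survival convention", {
  fx <- screen_fixture()
  calls <- fx$calls_a
  expect_equal(calls$p, pnorm(abs(calls$z), lower.tail = FALSE))
  expect_true(all(calls$call[calls$q < 0.05 & calls$z < 0] == "sensitive"))
  expect_true(all(calls$call[calls$q < 0.05 & calls$z > 0] == "resistant"))
  expect_true(all(calls$call[calls$q >= 0.05] == "none"))
  # z = 0 maps to p = 0.5
  closest <- which.min(abs(calls$z))
  expect_equal(calls$p[closest], pnorm(abs(calls$z[closest]), lower.tail = FALSE))
  expect_lt(abs(pnorm(0, lower.tail = FALSE) - 0.5), 1e-12)

  # monotone in the FDR level
  n_calls <- vapply(c(0.01, 0.05, 0.10, 0.25),
                    function(f) sum(call_phenotypes(fx$sm_a, fdr = f)$call != "none"),
                    numeric(1))
  expect_true(all(diff(n_calls) >= 0))
})

test_that("an all-null screen makes almost no phenotype calls", {
  st <- simulate_screen(n_genes = 300, n_conditions = 8,
                        strains = c("ref", "strainA"),
                        specific_frac = 0, shared_frac = 0,
                        background_frac = 0, grid_shape = c(16L, 24L),
                        seed = 77)
  sm <- score_simulated_strain(st, "strainA")
  calls <- call_phenotypes(sm)
  expect_lt(mean(calls$call != "none"), 0.05)
})
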