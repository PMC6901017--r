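rand_scores <- function(n_genes, n_cond, seed, strain = "s",
                        gen = function(n) rnorm(n)) {
  set.seed(seed)
  S <- matrix(gen(n_genes * n_cond), n_genes, n_cond,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cond))))
  toy_scores(S, strain = strain)
}

test_that("identical batches give a degenerate null at the sd floor", {
  a <- rand_scores(100, 5, seed = 1)
  nm <- build_null(a, a, n_slices = 10, min_obs = 20)
  expect_equal(nm$mu_sub, rep(0, nm$n_slices))
  expect_equal(nm$sigma_sub, rep(1e-6, nm$n_slices))
  expect_true(all(diff(nm$center) >= 0))
  expect_true(all(nm$n_obs >= nm$min_obs))
})

test_that("independent standard-normal batches match the closed-form mean of |S1-S2|", {
  a <- rand_scores(1000, 10, seed = 11)
  b <- rand_scores(1000, 10, seed = 12)
  nm <- build_null(a, b)
  pooled <- sum(nm$mu_sub * nm$n_obs) / sum(nm$n_obs)
  # E|X| for X ~ N(0, 2) is 2/sqrt(pi); 3 standard errors at n = 10,000
  se <- sqrt(2 - 4 / pi) / sqrt(10000)
  expect_lt(abs(pooled - 2 / sqrt(pi)), 3 * se)
})

test_that("slice spread tracks planted heteroscedasticity", {
  set.seed(42)
  n <- 20000
  mu <- rnorm(n, 0, 2)
  mk <- function(seed) {
    set.seed(seed)
    S <- matrix(mu + rnorm(n, 0, 0.2 + 0.4 * abs(mu)), 2000, 10,
                dimnames = list(sprintf("g%04d", 1:2000), sprintf("c%02d", 1:10)))
    toy_scores(S)
  }
  nm <- build_null(mk(1), mk(2))
  # more extreme N_sum (lower center) must carry larger sigma overall
  expect_lt(cor(nm$center, nm$sigma_sub, method = "spearman"), -0.8)
})

test_that("slice count adapts to small inputs and refuses hopeless ones", {
  a <- rand_scores(30, 10, seed = 3)
  b <- rand_scores(30, 10, seed = 4)
  expect_warning(nm <- build_null(a, b), "reducing slices")
  expect_true(all(nm$n_obs >= nm$min_obs))
  tiny <- rand_scores(5, 5, seed = 5)
  tiny2 <- rand_scores(5, 5, seed = 6)
  expect_error(build_null(tiny, tiny2), "at least")
})

test_that("difference p-values behave at the identity and in the far tail", {
  a <- rand_scores(200, 10, seed = 21)
  b <- rand_scores(200, 10, seed = 22)
  nm <- build_null(a, b)
  d_self <- diff_pvalues(a, a, nm)
  expect_true(all(d_self$n_sub == 0))
  expect_true(all(d_self$p_diff > 0.5))
  expect_equal(sum(d_self$q_diff < 0.01), 0)

  # inject one pair far beyond any slice: must be called
  b2 <- b
  b2$S["g0001", "c01"] <- a$S["g0001", "c01"] + 30
  d <- diff_pvalues(a, b2, nm)
  hit <- d[d$gene == "g0001" & d$condition == "c01", ]
  expect_lt(hit$q_diff, 0.01)
  expect_error(diff_pvalues(a, b, structure(list(center = numeric(0)),
                                            class = "diff_null")),
               "empty null")
})

test_that("null-vs-null comparisons stay under the nominal error rate", {
  a <- rand_scores(1000, 10, seed = 31)
  b <- rand_scores(1000, 10, seed = 32)
  nm <- build_null(a, b)
  d <- diff_pvalues(rand_scores(1000, 10, seed = 33),
                    rand_scores(1000, 10, seed = 34), nm)
  expect_lt(mean(d$q_diff < 0.01), 0.05)
})

test_that("comparison classes follow the shared/exclusive/incoherent rules", {
  mk_calls <- function(strain, calls) {
    data.frame(gene = sprintf("g%d", seq_along(calls)), condition = "c1",
               strain = strain, s = 0, z = 0, p = 1, q = 1, call = calls,
               stringsAsFactors = FALSE)
  }
  d <- data.frame(
    gene = sprintf("g%d", 1:6), condition = "c1",
    strain_a = "A", strain_b = "B", s_a = 0, s_b = 0, n_sum = 0, n_sub = 0,
    p_diff = c(0.5, 0.001, 0.001, 0.001, 0.001, 0.5),
    q_diff = c(0.5, 0.001, 0.001, 0.001, 0.001, 0.5),
    class = "not_considered", stringsAsFactors = FALSE)
  class(d) <- c("diff_calls", "data.frame")
  ca <- mk_calls("A", c("sensitive", "sensitive", "sensitive", "none",
                        "sensitive", "none"))
  cb <- mk_calls("B", c("sensitive", "none", "sensitive", "none",
                        "resistant", "none"))
  out <- classify_comparisons(d, ca, cb, alpha = 0.01)
  expect_equal(out$class,
               c("shared", "exclusive_a", "incoherent", "incoherent",
                 "sign_reversal", "not_considered"))
  # incoherent entries are masked to q = 1 and can never count as exclusive
  expect_equal(out$q_diff[out$class == "incoherent"], c(1, 1))
  # the classes partition every compared pair
  expect_true(all(out$class %in% c("shared", "exclusive_a", "exclusive_b",
                                   "sign_reversal", "incoherent",
                                   "not_considered")))
})

test_that("shared fractions count conserved phenotypes per focal strain", {
  mk <- function(classes, sa = "A", sb = "B") {
    d <- data.frame(gene = sprintf("g%d", seq_along(classes)),
                    condition = "c1", strain_a = sa, strain_b = sb,
                    s_a = 0, s_b = 0, n_sum = 0, n_sub = 0, p_diff = 1,
                    q_diff = 1, class = classes, stringsAsFactors = FALSE)
    class(d) <- c("diff_calls", "data.frame")
    d
  }
  sf <- shared_fractions(list(mk(c("shared", "shared", "shared",
                                   "exclusive_a"))), c("A", "B"), k = 2)
  expect_equal(sf$fraction[sf$strain == "A"], 0.75)
  expect_equal(sf$fraction[sf$strain == "B"], 1)  # no exclusive_b

  all_shared <- list(mk(rep("shared", 5)), mk(rep("shared", 5), "A", "C"),
                     mk(rep("shared", 5), "B", "C"))
  sf3 <- shared_fractions(all_shared, c("A", "B", "C"), k = 3)
  expect_equal(sf3$fraction, rep(1, 3))
  expect_error(shared_fractions(all_shared, c("A", "B", "C"), k = 4),
               "between 2")
})

test_that("exclusiveness ranks genes by their changing-phenotype propensity", {
  d <- data.frame(
    gene = c("g1", "g1", "g1", "g1", "g2", "g2", "g3"),
    condition = paste0("c", 1:7), strain_a = "A", strain_b = "B",
    s_a = 0, s_b = 0, n_sum = 0, n_sub = 0, p_diff = 1, q_diff = 1,
    class = c("exclusive_a", "exclusive_b", "shared", "shared",
              "shared", "shared", "not_considered"),
    stringsAsFactors = FALSE)
  class(d) <- c("diff_calls", "data.frame")
  ex <- exclusiveness(list(d))
  g1 <- ex[ex$gene == "g1", ]
  expect_equal(g1$E, 0.5)
  expect_true(g1$high_exclusiveness)
  g2 <- ex[ex$gene == "g2", ]
  expect_equal(g2$E, 0)
  expect_false(g2$high_exclusiveness)
  g3 <- ex[ex$gene == "g3", ]
  expect_true(is.na(g3$E))
  expect_equal(ex$gene[1], "g1")  # ranked by E
})

test_that("condition summaries join phi and surface variable genes", {
  d <- data.frame(
    gene = c("g1", "g2", "g3"), condition = c("c1", "c1", "c2"),
    strain_a = "A", strain_b = "B", s_a = 0, s_b = 0, n_sum = 0, n_sub = 0,
    p_diff = c(1e-6, 0.5, 0.2), q_diff = c(5e-5, 0.5, 0.2),
    class = c("exclusive_a", "shared", "not_considered"),
    stringsAsFactors = FALSE)
  class(d) <- c("diff_calls", "data.frame")
  fit <- data.frame(strain = c("A", "A", "B", "B"),
                    condition = c("c1", "c2", "c1", "c2"),
                    replicate = 1L, phi = c(0.8, 0.9, 1, 1))
  cs <- condition_summary(list(d), fit)
  expect_equal(cs$variable_genes,
               data.frame(condition = "c1", gene = "g1"))
  a_c1 <- cs$summary[cs$summary$strain == "A" & cs$summary$condition == "c1", ]
  expect_equal(a_c1$n_exclusive, 1)
  # the lower-fitness strain carries the exclusive phenotypes
  expect_lt(cs$correlation, 0)

  # with no exclusive phenotypes anywhere the correlation is undefined
  d0 <- d; d0$class <- "shared"
  cs0 <- condition_summary(list(d0), fit)
  expect_true(is.na(cs0$correlation))
})
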