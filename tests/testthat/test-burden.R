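test_that("SIFT neutrality transform is calibrated and monotone increasing", {
  # closed form at SIFT = 1: 1 / (1 + exp(-4.104...)) ~ 0.9838
  expect_equal(pneutral_sift(1), 1 / (1 + exp(-(1.312 * log(1 + 1.598e-5) + 4.104))))
  expect_equal(pneutral_sift(1), 0.9838, tolerance = 1e-4)
  expect_lt(pneutral_sift(0), 1e-4)  # fully deleterious -> near zero
  grid <- seq(0, 1, length.out = 100)
  expect_true(all(diff(pneutral_sift(grid)) > 0))
  expect_true(all(pneutral_sift(grid) > 0 & pneutral_sift(grid) < 1))
  # the literal sign reading is exposed and reverses the direction
  expect_true(all(diff(pneutral_sift(grid, literal_sign = TRUE)) < 0))
  expect_error(pneutral_sift(1.2), "\\[0, 1\\]")
})

test_that("FoldX neutrality transform is calibrated and monotone decreasing", {
  expect_equal(pneutral_foldx(0), 1 / (1 + exp(-0.074)))
  expect_equal(pneutral_foldx(0), 0.5185, tolerance = 1e-4)
  grid <- seq(-10, 30, length.out = 100)
  expect_true(all(diff(pneutral_foldx(grid)) < 0))
  expect_lt(pneutral_foldx(50), 1e-4)  # strongly destabilizing -> ~0
  expect_true(all(diff(pneutral_foldx(grid, literal_sign = TRUE)) > 0))
  expect_error(pneutral_foldx(NA), "finite")
})

test_that("nonsense neutrality follows the last-5%-of-protein rule", {
  expect_equal(pneutral_nonsense(0.96), 0.99)
  expect_equal(pneutral_nonsense(0.50), 0.01)
  expect_equal(pneutral_nonsense(0.95), 0.01)  # boundary: strictly greater
  expect_equal(pneutral_nonsense(c(0.951, 1)), c(0.99, 0.99))
  expect_error(pneutral_nonsense(0), "\\(0, 1\\]")
  expect_error(pneutral_nonsense(1.01), "\\(0, 1\\]")
})

mk_var <- function(kind, sift = NA, foldx = NA, rel_pos = NA) {
  data.frame(strain = "s1", gene = "gX", kind = kind, sift = sift,
             foldx = foldx, rel_pos = rel_pos, stringsAsFactors = FALSE)
}

test_that("gene disruption combines variant neutralities as 1 - product", {
  # absent gene: fixed 0.99 whatever else is present, digitized 1
  rec <- gene_disruption(rbind(mk_var("absence"), mk_var("missense", sift = 1)))
  expect_equal(rec$p_af, 0.99)
  expect_equal(rec$digitized, 1L)

  # empty variant list
  rec0 <- gene_disruption(mk_var("missense")[0, ], gene = "gX", strain = "s1")
  expect_equal(rec0$p_af, 0)
  expect_equal(rec0$digitized, 0L)

  # two scored variants: p_af = 1 - product of their neutralities
  v <- rbind(mk_var("missense", sift = 0.8), mk_var("nonsense", rel_pos = 0.3))
  rec2 <- gene_disruption(v)
  expect_equal(rec2$p_neutral_list, c(pneutral_sift(0.8), 0.01))
  expect_equal(rec2$p_af, 1 - pneutral_sift(0.8) * 0.01)

  # unscored missense falls back to the supplied neutrality
  rec3 <- gene_disruption(mk_var("missense"), fallback_pneutral = 0.4)
  expect_equal(rec3$p_af, 0.6)
  rec4 <- gene_disruption(rbind(mk_var("missense"), mk_var("missense")),
                          fallback_pneutral = 0.9)
  expect_equal(rec4$p_af, 1 - 0.81)
})

test_that("SIFT takes priority over FoldX and p_af grows with variant count", {
  both <- mk_var("missense", sift = 0.3, foldx = 5)
  sift_only <- mk_var("missense", sift = 0.3)
  expect_identical(gene_disruption(both)$p_af, gene_disruption(sift_only)$p_af)

  # adding variants can only raise 1 - prod
  set.seed(4)
  v <- do.call(rbind, lapply(runif(8), function(s) mk_var("missense", sift = s)))
  pafs <- vapply(seq_len(nrow(v)),
                 function(k) gene_disruption(v[seq_len(k), , drop = FALSE])$p_af,
                 numeric(1))
  expect_true(all(diff(pafs) >= 0))
})

test_that("digitization thresholds strictly at 0.9", {
  expect_equal(digitize_paf(c(0.95, 0.9, 0.91, 0, 0.99)), c(1L, 0L, 1L, 0L, 1L))
  expect_error(digitize_paf(1.5), "\\[0, 1\\]")
})

test_that("panel-wide disruption table flags absent genes and respects the fallback", {
  panel <- gen_variant_panel(n_strains = 40, n_genes = 15, causal_gene = "g0003",
                             effect_size = 1, absence_rate = 0.05, seed = 2)
  recs <- panel_variant_records(panel)
  tab <- disruption_table(recs)
  absent <- which(panel$presence == 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(absent))) {
    row <- tab[tab$gene == rownames(panel$presence)[absent[i, 1]] &
                 tab$strain == colnames(panel$presence)[absent[i, 2]], ]
    expect_equal(row$p_af, 0.99)
    expect_equal(row$digitized, 1L)
  }
  expect_true(all(tab$p_af >= 0 & tab$p_af <= 1))
})

test_that("MAF filter keeps common variants (at least 5%)", {
  n <- 100
  mk_row <- function(k) c(rep(1L, k), rep(0L, n - k))
  g <- rbind(maf04 = mk_row(4), maf05 = mk_row(5), maf50 = mk_row(50),
             mono = mk_row(0), fixed = mk_row(100))
  colnames(g) <- sprintf("s%03d", 1:n)
  out <- maf_filter(g)
  expect_equal(rownames(out), c("maf05", "maf50"))
  strict <- maf_filter(g, strict = TRUE)
  expect_equal(rownames(strict), "maf50")
  expect_error(maf_filter(g + 2L), "biallelic")
})

test_that("feature encoding stacks typed blocks over a shared strain universe", {
  strains <- sprintf("s%02d", 1:20)
  snps <- matrix(rbinom(200, 1, 0.3), 10, 20,
                 dimnames = list(sprintf("v%02d", 1:10), strains))
  burden <- matrix(rbinom(60, 1, 0.1), 3, 20,
                   dimnames = list(sprintf("g%02d", 1:3), strains))
  enc <- encode_features(snps, burden = burden)
  expect_equal(dim(enc$matrix), c(13, 20))
  expect_equal(sort(unique(enc$features$type)), c("burden", "snp"))
  expect_true(all(enc$matrix[enc$features$type == "burden", ] %in% 0:1))

  bad <- burden[, rev(strains)]
  expect_error(encode_features(snps, burden = bad), "mismatch")
  expect_error(encode_features(snps, burden = burden + 5L), "0/1")
})
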