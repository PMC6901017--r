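#' S-score correlation between two replicate batches
#'
#' Pearson correlation over the gene x condition pairs scored in both
#' matrices, the screen's technical/biological reproducibility measure.
#'
#' @param scores_b1,scores_b2 `score_matrix` objects.
#' @return list with `r` (`NA` with fewer than 3 shared pairs) and `n`.
#' @export
batch_correlation <- function(scores_b1, scores_b2) {
  pairs <- paired_scores(scores_b1, scores_b2)
  if (nrow(pairs) < 3L) return(list(r = NA_real_, n = nrow(pairs)))
  list(r = stats::cor(pairs$s1, pairs$s2), n = nrow(pairs))
}

#' S-score correlation between duplicate library positions
#'
#' For genes pinned at two positions and scored with
#' `compute_sscores(..., split_duplicates = TRUE)` (gene ids suffixed
#' `::1` / `::2`), the Pearson correlation between the two positions'
#' S-score vectors across genes and conditions — the biological
#' reproducibility of the screen within a single pass.
#'
#' @param sm a `score_matrix` scored with split duplicates.
#' @return list with `r`, `n` (pairs) and `n_genes` (duplicated genes).
#' @export
duplicate_correlation <- function(sm) {
  stopifnot(inherits(sm, "score_matrix"))
  g1 <- grep("::1$", rownames(sm$S), value = TRUE)
  if (!length(g1)) {
    abort_input("no duplicate positions found; score with split_duplicates = TRUE")
  }
  base <- sub("::1$", "", g1)
  g2 <- paste0(base, "::2")
  keep <- g2 %in% rownames(sm$S)
  g1 <- g1[keep]; g2 <- g2[keep]; base <- base[keep]
  if (!length(g1)) abort_input("duplicate positions never co-occur in the matrix")
  a <- as.vector(sm$S[g1, , drop = FALSE])
  b <- as.vector(sm$S[g2, , drop = FALSE])
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) return(list(r = NA_real_, n = sum(ok), n_genes = length(base)))
  list(r = stats::cor(a[ok], b[ok]), n = sum(ok), n_genes = length(base))
}

#' False-positive rate of phenotype-change calling
#'
#' Runs the differential machinery between two replicate-derived score
#' matrices of the same strain — where no true change exists — and reports
#' the proportion of gene x condition pairs called significantly different
#' (`q_diff < q_threshold`) over all comparisons: an empirical estimate of
#' the change-calling error rate.
#'
#' @param scores_rep_a,scores_rep_b replicate `score_matrix` objects.
#' @param null a `diff_null` (ideally built from an independent replicate
#'   pair).
#' @param q_threshold corrected-P threshold (default 0.01).
#' @return list with `rate` (`NA` on an empty universe), `n_significant`
#'   and `n_total`.
#' @export
error_rate <- function(scores_rep_a, scores_rep_b, null, q_threshold = 0.01) {
  d <- diff_pvalues(scores_rep_a, scores_rep_b, null)
  if (!nrow(d)) return(list(rate = NA_real_, n_significant = 0L, n_total = 0L))
  n_sig <- sum(d$q_diff < q_threshold)
  list(rate = n_sig / nrow(d), n_significant = n_sig, n_total = nrow(d))
}

#' Cross-strain similarity of per-gene S-score profiles
#'
#' For every gene present in all strains, the mean pairwise Pearson
#' correlation of its condition profile across strains (how conserved the
#' gene's chemical-genomic signature is), compared with a background of
#' random gene pairs correlated across random strain pairs. Genes are
#' stratified by the average number of conditions in which they show a
#' significant phenotype, since genes with no phenotype carry no signal to
#' correlate.
#'
#' @param matrices named list of `score_matrix` objects, one per strain
#'   (at least 2).
#' @param calls optional list of `phenotype_calls` parallel to `matrices`,
#'   used for the stratification; without it all genes land in one stratum.
#' @param q_threshold phenotype significance threshold for the
#'   stratification (default 0.01).
#' @param n_background number of random gene pairs (default 1000).
#' @param seed RNG seed for the background sampling.
#' @return list with `gene_correlations` (`gene`, `r`, `n_phenotypes`,
#'   `stratum`), `background` (numeric vector of background correlations)
#'   and `strata` (per-stratum mean gene and background correlation).
#' @export
profile_similarity <- function(matrices, calls = NULL, q_threshold = 0.01,
                               n_background = 1000L, seed = 1L) {
  if (length(matrices) < 2L) abort_input("need score matrices for at least 2 strains")
  genes <- Reduce(intersect, lapply(matrices, function(m) rownames(m$S)))
  conds <- Reduce(intersect, lapply(matrices, function(m) colnames(m$S)))
  if (length(genes) < 2L || length(conds) < 3L) {
    abort_input("too few shared genes/conditions across strains")
  }
  S <- lapply(matrices, function(m) m$S[genes, conds, drop = FALSE])
  strain_pairs <- utils::combn(length(S), 2, simplify = FALSE)

  mean_pair_cor <- function(g1, g2) {
    vals <- vapply(strain_pairs, function(sp) {
      x <- S[[sp[1]]][g1, ]; y <- S[[sp[2]]][g2, ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(x[ok], y[ok])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }

  gene_r <- vapply(genes, function(g) mean_pair_cor(g, g), numeric(1))

  n_pheno <- rep(0, length(genes))
  if (!is.null(calls)) {
    per_strain <- vapply(calls, function(cl) {
      cnt <- tapply(cl$q < q_threshold, cl$gene, sum)
      out <- cnt[genes]; out[is.na(out)] <- 0
      as.numeric(out)
    }, numeric(length(genes)))
    n_pheno <- rowMeans(per_strain)
  }
  stratum <- cut(n_pheno, breaks = c(-Inf, 0.5, 2.5, 5.5, Inf),
                 labels = c("0", "1-2", "3-5", "6+"))

  set.seed(derive_seed(seed, "profile_background"))
  bg <- vapply(seq_len(n_background), function(i) {
    gp <- sample(genes, 2L)
    mean_pair_cor(gp[1], gp[2])
  }, numeric(1))

  gc <- data.frame(gene = genes, r = gene_r, n_phenotypes = n_pheno,
                   stratum = stratum, stringsAsFactors = FALSE)
  strata <- stats::aggregate(r ~ stratum, data = gc,
                             FUN = function(x) mean(x, na.rm = TRUE))
  strata$background_mean <- mean(bg, na.rm = TRUE)
  list(gene_correlations = gc, background = bg, strata = strata)
}

# ROC AUC by the rank (Mann-Whitney) statistic; ties count one half
rank_auc <- function(pos, neg) {
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# area under the precision-recall curve by descending-score step
# integration
pr_auc <- function(pos, neg) {
  scores <- c(pos, neg)
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  ok <- is.finite(scores)
  scores <- scores[ok]; labels <- labels[ok]
  if (!sum(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  tp <- cumsum(labels)
  precision <- tp / seq_along(labels)
  recall <- tp / sum(labels)
  sum(precision[labels == 1L]) / sum(labels)
}

#' Benchmark a score matrix against known functional relationships
#'
#' Scores every candidate gene pair by the Pearson correlation of the two
#' genes' S-score profiles and asks how well that ranking recovers a set of
#' known co-functional pairs (same complex or pathway). Genes without any
#' significant phenotype are excluded first when calls are supplied — a
#' profile that never deviates carries no usable signal. Each of
#' `n_negative_sets` random gene-pair sets of the same size as the positive
#' set (excluding positives and self-pairs) serves as true negatives;
#' ROC and precision-recall AUCs are reported as the mean and mean absolute
#' deviation across the negative sets.
#'
#' @param sm a `score_matrix`.
#' @param positive_pairs data frame with columns `gene1`, `gene2`. Pairs
#'   with genes missing from the matrix are dropped with a warning; an
#'   empty positive set is an error.
#' @param calls optional `phenotype_calls` used to restrict to genes with
#'   at least one phenotype at `q < q_threshold`.
#' @param q_threshold phenotype threshold for the restriction (default
#'   0.01).
#' @param n_negative_sets number of random negative sets (default 10).
#' @param seed RNG seed; fixes the negative sets.
#' @return list with `roc_auc`, `roc_auc_mad`, `pr_auc`, `pr_auc_mad`,
#'   `n_positive`, `n_genes` and per-set vectors `roc_aucs`, `pr_aucs`.
#' @export
benchmark_functional <- function(sm, positive_pairs, calls = NULL,
                                 q_threshold = 0.01, n_negative_sets = 10L,
                                 seed = 1L) {
  stopifnot(inherits(sm, "score_matrix"))
  genes <- rownames(sm$S)
  if (!is.null(calls)) {
    with_pheno <- unique(calls$gene[calls$q < q_threshold])
    genes <- intersect(genes, with_pheno)
  }
  if (length(genes) < 4L) abort_input("fewer than 4 usable genes for benchmarking")
  keep <- positive_pairs$gene1 %in% genes & positive_pairs$gene2 %in% genes
  if (!all(keep)) {
    warning(sprintf("%d positive pair(s) dropped (gene absent or no phenotype)",
                    sum(!keep)))
  }
  pp <- positive_pairs[keep, , drop = FALSE]
  if (!nrow(pp)) abort_input("no usable positive pairs")

  C <- stats::cor(t(sm$S[genes, , drop = FALSE]), use = "pairwise.complete.obs")
  pair_score <- function(g1, g2) C[cbind(g1, g2)]
  pos_scores <- pair_score(pp$gene1, pp$gene2)

  canon <- function(g1, g2) paste(pmin(g1, g2), pmax(g1, g2), sep = "\r")
  pos_keys <- canon(pp$gene1, pp$gene2)

  set.seed(derive_seed(seed, "benchmark_negatives"))
  roc_aucs <- numeric(n_negative_sets)
  pr_aucs <- numeric(n_negative_sets)
  for (i in seq_len(n_negative_sets)) {
    neg <- matrix(character(0), 0, 2)
    guard <- 0L
    while (nrow(neg) < nrow(pp) && guard < 50L) {
      need <- nrow(pp) - nrow(neg)
      g1 <- sample(genes, 2L * need + 10L, replace = TRUE)
      g2 <- sample(genes, 2L * need + 10L, replace = TRUE)
      ok <- g1 != g2 & !(canon(g1, g2) %in% pos_keys)
      cand <- unique(cbind(g1[ok], g2[ok]))
      neg <- rbind(neg, cand)[seq_len(min(nrow(neg) + nrow(cand), nrow(pp))), ,
                              drop = FALSE]
      guard <- guard + 1L
    }
    neg_scores <- pair_score(neg[, 1], neg[, 2])
    roc_aucs[i] <- rank_auc(pos_scores, neg_scores)
    pr_aucs[i] <- pr_auc(pos_scores, neg_scores)
  }
  list(roc_auc = mean(roc_aucs), roc_auc_mad = mean(abs(roc_aucs - mean(roc_aucs))),
       pr_auc = mean(pr_aucs), pr_auc_mad = mean(abs(pr_aucs - mean(pr_aucs))),
       n_positive = nrow(pp), n_genes = length(genes),
       roc_aucs = roc_aucs, pr_aucs = pr_aucs)
}
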