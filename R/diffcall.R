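#' Sliding-window empirical null for S-score differences
#'
#' Builds the null model for "no change in phenotype between two screens"
#' from two replicate batches of the same strain. For every gene x condition
#' pair present in both batches it computes
#'
#'   N_sum = -|S1 + S2|   and   N_sub = |S1 - S2|
#'
#' Because S-score variance grows with |S|, the pairs are sorted by N_sum
#' and divided into `n_slices` contiguous equal-count slices (merged until
#' every slice holds at least `min_obs` observations); each slice records
#' the mean N_sum (its center), the mean and the standard deviation of
#' N_sub. Downstream, a difference observed at a given N_sum is judged
#' against the normal distribution interpolated from these slices.
#'
#' @param scores_b1,scores_b2 `score_matrix` objects from the two replicate
#'   batches; pairs missing in either are dropped.
#' @param n_slices target number of slices (default 100).
#' @param min_obs minimum observations per slice (default 20). With fewer
#'   than `n_slices * min_obs` pairs the slice count is reduced with a
#'   warning; fewer than `2 * min_obs` pairs is an error.
#' @param sd_floor lower bound on the per-slice standard deviation, guarding
#'   the degenerate identical-batch case.
#' @return an object of class `diff_null` with per-slice vectors `center`,
#'   `mu_sub`, `sigma_sub`, `n_obs`.
#' @export
build_null <- function(scores_b1, scores_b2, n_slices = 100L, min_obs = 20L,
                       sd_floor = 1e-6) {
  pairs <- paired_scores(scores_b1, scores_b2)
  n <- nrow(pairs)
  if (n < 2L * min_obs) {
    abort_input("need at least %d shared gene-condition pairs to build a null, got %d",
                2L * min_obs, n)
  }
  if (n < n_slices * min_obs) {
    n_slices_new <- max(2L, n %/% min_obs)
    warning(sprintf("only %d pairs: reducing slices from %d to %d",
                    n, n_slices, n_slices_new))
    n_slices <- n_slices_new
  }
  n_sum <- -abs(pairs$s1 + pairs$s2)
  n_sub <- abs(pairs$s1 - pairs$s2)
  ord <- order(n_sum)
  n_sum <- n_sum[ord]; n_sub <- n_sub[ord]
  slice <- ceiling(seq_len(n) / (n / n_slices))
  center <- as.numeric(tapply(n_sum, slice, mean))
  mu_sub <- as.numeric(tapply(n_sub, slice, mean))
  sigma_sub <- pmax(as.numeric(tapply(n_sub, slice, stats::sd)), sd_floor)
  sigma_sub[is.na(sigma_sub)] <- sd_floor
  n_obs <- as.integer(tapply(n_sub, slice, length))
  structure(list(center = center, mu_sub = mu_sub, sigma_sub = sigma_sub,
                 n_obs = n_obs, n_slices = length(center),
                 min_obs = as.integer(min_obs), sd_floor = sd_floor),
            class = "diff_null")
}

#' @export
print.diff_null <- function(x, ...) {
  cat(sprintf("<diff_null> %d slices over N_sum [%.2f, %.2f]; pooled mean N_sub %.3f\n",
              x$n_slices, min(x$center), max(x$center),
              sum(x$mu_sub * x$n_obs) / sum(x$n_obs)))
  invisible(x)
}

# align two score matrices on their shared gene x condition pairs
paired_scores <- function(a, b) {
  stopifnot(inherits(a, "score_matrix"), inherits(b, "score_matrix"))
  genes <- intersect(rownames(a$S), rownames(b$S))
  conds <- intersect(colnames(a$S), colnames(b$S))
  if (!length(genes) || !length(conds)) {
    abort_input("score matrices share no gene-condition universe")
  }
  s1 <- a$S[genes, conds, drop = FALSE]
  s2 <- b$S[genes, conds, drop = FALSE]
  ok <- !is.na(s1) & !is.na(s2)
  idx <- which(ok, arr.ind = TRUE)
  data.frame(gene = genes[idx[, 1]], condition = conds[idx[, 2]],
             s1 = s1[ok], s2 = s2[ok], stringsAsFactors = FALSE)
}

#' P-values for S-score differences between two strains
#'
#' For every shared gene x condition pair, computes N_sum and N_sub for the
#' strain pair, linearly interpolates the null's slice mean and standard
#' deviation at the observed N_sum (clamping beyond the terminal slices),
#' takes the upper-tail survival probability of Normal(mu, sigma) at N_sub,
#' and Benjamini-Hochberg-corrects across all pairs of the comparison.
#'
#' @param scores_a,scores_b `score_matrix` objects for the two strains.
#' @param null a `diff_null` built by [build_null()].
#' @return data frame of class `diff_calls`: `gene`, `condition`,
#'   `strain_a`, `strain_b`, `s_a`, `s_b`, `n_sum`, `n_sub`, `p_diff`,
#'   `q_diff`, `class` (initialized `"not_considered"`; see
#'   [classify_comparisons()]).
#' @export
diff_pvalues <- function(scores_a, scores_b, null) {
  if (!inherits(null, "diff_null")) abort_input("`null` must be a diff_null")
  if (!length(null$center)) abort_input("empty null model")
  pairs <- paired_scores(scores_a, scores_b)
  pairs$n_sum <- -abs(pairs$s1 + pairs$s2)
  pairs$n_sub <- abs(pairs$s1 - pairs$s2)
  mu <- stats::approx(null$center, null$mu_sub, xout = pairs$n_sum,
                      rule = 2, ties = mean)$y
  sigma <- stats::approx(null$center, null$sigma_sub, xout = pairs$n_sum,
                         rule = 2, ties = mean)$y
  p <- stats::pnorm(pairs$n_sub, mean = mu, sd = sigma, lower.tail = FALSE)
  out <- data.frame(
    gene = pairs$gene, condition = pairs$condition,
    strain_a = scores_a$strain, strain_b = scores_b$strain,
    s_a = pairs$s1, s_b = pairs$s2,
    n_sum = pairs$n_sum, n_sub = pairs$n_sub,
    p_diff = p, q_diff = stats::p.adjust(p, method = "BH"),
    class = "not_considered", stringsAsFactors = FALSE)
  class(out) <- c("diff_calls", "data.frame")
  out
}

#' Classify strain-pair phenotype comparisons
#'
#' Combines difference q-values with each strain's phenotype calls into the
#' comparison classes:
#'
#' * `incoherent` — the difference is nominally significant
#'   (`q_diff < alpha`) but both strains have a significant phenotype in the
#'   same direction, or neither strain has one; such contradictions are
#'   masked by forcing `q_diff` to 1.
#' * `shared` — both strains have a significant phenotype and the
#'   difference is not significant (`q_diff >= alpha`).
#' * `exclusive_a` / `exclusive_b` — exactly one strain has a significant
#'   phenotype and the difference is significant.
#' * `sign_reversal` — both strains significant with opposite directions
#'   and a significant difference.
#' * `not_considered` — everything else.
#'
#' @param diffs a `diff_calls` data frame from [diff_pvalues()].
#' @param calls_a,calls_b `phenotype_calls` for the two strains.
#' @param alpha corrected-P threshold on the difference (default 0.01).
#' @return the `diff_calls` data frame with `class` filled in and `q_diff`
#'   forced to 1 on incoherent entries.
#' @export
classify_comparisons <- function(diffs, calls_a, calls_b, alpha = 0.01) {
  stopifnot(inherits(diffs, "diff_calls"))
  key <- function(d) paste(d$gene, d$condition, sep = "\r")
  ka <- stats::setNames(calls_a$call, key(calls_a))
  kb <- stats::setNames(calls_b$call, key(calls_b))
  ca <- ka[key(diffs)]; cb <- kb[key(diffs)]
  if (any(is.na(ca)) || any(is.na(cb))) {
    abort_input("phenotype calls do not cover the compared gene-condition universe")
  }
  sig_a <- ca != "none"; sig_b <- cb != "none"
  same_dir <- sig_a & sig_b & ca == cb
  opp_dir <- sig_a & sig_b & ca != cb
  sig_diff <- diffs$q_diff < alpha

  cls <- rep("not_considered", nrow(diffs))
  incoherent <- sig_diff & (same_dir | (!sig_a & !sig_b))
  cls[incoherent] <- "incoherent"
  cls[!incoherent & sig_a & sig_b & !sig_diff] <- "shared"
  cls[!incoherent & sig_a & !sig_b & sig_diff] <- "exclusive_a"
  cls[!incoherent & !sig_a & sig_b & sig_diff] <- "exclusive_b"
  cls[!incoherent & opp_dir & sig_diff] <- "sign_reversal"
  diffs$class <- cls
  diffs$q_diff[incoherent] <- 1
  attr(diffs, "alpha") <- alpha
  diffs
}

# exclusivity class from the focal strain's point of view
focal_exclusive <- function(d, strain) {
  ifelse(d$strain_a == strain, "exclusive_a",
         ifelse(d$strain_b == strain, "exclusive_b", NA_character_))
}

#' Fraction of deletion phenotypes conserved across strains
#'
#' For each focal strain, among the comparisons classified `shared` or
#' exclusive-to-the-focal-strain: the pairwise fraction is
#' `shared / (shared + exclusive_focal)` against each other strain; the
#' k-way fraction requires the phenotype to be shared with every other
#' strain of the subset. Reports the mean and standard deviation across the
#' other strains (k = 2) or across k-subsets (k = 3, 4), mirroring how
#' multi-strain conservation is usually displayed with error bars.
#'
#' @param classified named list of classified `diff_calls`, one per
#'   unordered strain pair (all pairs among `strains` must be present).
#' @param strains strain identifiers.
#' @param k comparison order: 2 (pairwise), 3 or 4.
#' @return data frame: `strain`, `k`, `fraction`, `sd`, `n_subsets`.
#' @export
shared_fractions <- function(classified, strains, k = 2L) {
  k <- as.integer(k)
  if (k < 2L || k > length(strains)) {
    abort_input("k must be between 2 and the number of strains (%d)", length(strains))
  }
  pair_of <- function(s, t) {
    for (d in classified) {
      if (setequal(c(d$strain_a[1], d$strain_b[1]), c(s, t))) return(d)
    }
    abort_input("missing pairwise comparison %s vs %s", s, t)
  }
  res <- lapply(strains, function(s) {
    others <- setdiff(strains, s)
    subsets <- utils::combn(others, k - 1L, simplify = FALSE)
    fracs <- vapply(subsets, function(sub) {
      # per comparison: keep entries where the focal strain's phenotype is
      # under consideration (shared or exclusive to focal)
      status <- NULL
      for (t in sub) {
        d <- pair_of(s, t)
        excl <- focal_exclusive(d, s)
        keep <- d$class == "shared" | d$class == excl
        st <- stats::setNames(d$class[keep] == "shared",
                              paste(d$gene[keep], d$condition[keep], sep = "\r"))
        status <- if (is.null(status)) st else {
          shared_keys <- intersect(names(status), names(st))
          stats::setNames(status[shared_keys] & st[shared_keys], shared_keys)
        }
      }
      if (!length(status)) return(NA_real_)
      mean(status)
    }, numeric(1))
    data.frame(strain = s, k = k, fraction = mean(fracs, na.rm = TRUE),
               sd = stats::sd(fracs), n_subsets = length(fracs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-gene exclusiveness of deletion phenotypes
#'
#' Across all pairwise strain comparisons, each gene's propensity to change
#' its conditional-essentiality profile:
#'
#'   E = P_exclusive / (P_exclusive + P_shared)
#'
#' where `P_exclusive` counts its phenotypes that vary significantly
#' between strains (classes `exclusive_a`, `exclusive_b`, `sign_reversal`)
#' and `P_shared` those present in both strains without significant change
#' (class `shared`). A gene with E > 0 is flagged high-exclusiveness.
#' Entries masked as incoherent (q forced to 1) never count as exclusive.
#'
#' @param classified list of classified `diff_calls` (all pairwise
#'   comparisons).
#' @return data frame of class `exclusiveness_record`: `gene`,
#'   `p_exclusive`, `p_shared`, `E` (`NA` when both counts are 0),
#'   `high_exclusiveness`, ordered by decreasing E.
#' @export
exclusiveness <- function(classified) {
  all_d <- do.call(rbind, lapply(classified, as.data.frame))
  excl <- all_d$class %in% c("exclusive_a", "exclusive_b", "sign_reversal")
  shar <- all_d$class == "shared"
  genes <- sort(unique(all_d$gene))
  p_ex <- as.integer(tapply(excl, factor(all_d$gene, genes), sum))
  p_sh <- as.integer(tapply(shar, factor(all_d$gene, genes), sum))
  E <- ifelse(p_ex + p_sh > 0, p_ex / (p_ex + p_sh), NA_real_)
  out <- data.frame(gene = genes, p_exclusive = p_ex, p_shared = p_sh,
                    E = E, high_exclusiveness = !is.na(E) & E > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$E, out$gene, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("exclusiveness_record", "data.frame")
  out
}

#' Per-condition summary of exclusive phenotypes and fitness
#'
#' For each condition and strain, counts exclusive phenotypes (averaged over
#' that strain's pairwise comparisons), joins the strain's relative fitness
#' phi in that condition, and reports the Pearson correlation between phi
#' and the exclusive-phenotype count across condition x strain records —
#' asking whether generally sicker strains accumulate more
#' condition-specific gene requirements. Also lists "variable genes" per
#' condition: genes whose difference reaches `q_diff < variable_q` in at
#' least one comparison.
#'
#' @param classified list of classified `diff_calls`.
#' @param fitness `fitness_record` rows (phi per strain, condition,
#'   replicate); averaged over replicates.
#' @param variable_q corrected-P cutoff for the variable-gene list
#'   (default 1e-4).
#' @return list with `summary` (condition, strain, n_exclusive, phi),
#'   `correlation` (Pearson r, `NA` when undefined) and `variable_genes`
#'   (condition, gene).
#' @export
condition_summary <- function(classified, fitness, variable_q = 1e-4) {
  all_d <- do.call(rbind, lapply(classified, as.data.frame))
  strains <- sort(unique(c(all_d$strain_a, all_d$strain_b)))
  conds <- sort(unique(all_d$condition))
  if (!nrow(fitness) || !any(fitness$condition %in% conds)) {
    abort_input("fitness records share no condition with the comparisons")
  }
  recs <- list()
  for (s in strains) {
    inv <- Filter(function(d) s %in% c(d$strain_a[1], d$strain_b[1]), classified)
    for (cc in conds) {
      n_ex <- vapply(inv, function(d) {
        sum(d$condition == cc & d$class == focal_exclusive(d, s))
      }, numeric(1))
      recs[[length(recs) + 1L]] <- data.frame(
        condition = cc, strain = s, n_exclusive = mean(n_ex),
        stringsAsFactors = FALSE)
    }
  }
  summ <- do.call(rbind, recs)
  phi_tab <- stats::aggregate(phi ~ strain + condition, data = fitness, FUN = mean)
  summ <- merge(summ, phi_tab, by = c("strain", "condition"), all.x = TRUE)

  ok <- stats::complete.cases(summ[, c("phi", "n_exclusive")])
  r <- if (sum(ok) >= 3L && stats::sd(summ$n_exclusive[ok]) > 0 &&
           stats::sd(summ$phi[ok]) > 0) {
    stats::cor(summ$phi[ok], summ$n_exclusive[ok])
  } else NA_real_

  var_hits <- all_d[all_d$q_diff < variable_q, c("condition", "gene")]
  var_genes <- unique(var_hits)
  var_genes <- var_genes[order(var_genes$condition, var_genes$gene), , drop = FALSE]
  rownames(var_genes) <- NULL
  list(summary = summ, correlation = r, variable_genes = var_genes)
}
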