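#' S-score matrix container
#'
#' Genes x conditions matrix of S-scores for one strain, with a parallel
#' matrix of replicate counts. Built by [compute_sscores()]; conditions are
#' quantile-normalized by [quantile_normalize()] before phenotype calling.
#'
#' @param S numeric genes x conditions matrix (dimnames required).
#' @param n_rep integer matrix of the same shape: number of colony
#'   measurements behind each score.
#' @param strain strain identifier.
#' @param normalized has quantile normalization been applied?
#' @return an object of class `score_matrix`.
#' @export
score_matrix <- function(S, n_rep, strain, normalized = FALSE) {
  if (!is.matrix(S) || is.null(rownames(S)) || is.null(colnames(S))) {
    abort_input("S must be a matrix with gene rownames and condition colnames")
  }
  if (!identical(dim(S), dim(n_rep))) abort_input("S and n_rep shapes differ")
  if (any(n_rep[!is.na(S)] < 3L)) {
    abort_input("every non-missing S-score needs at least 3 replicate measurements")
  }
  structure(list(S = S, n_rep = n_rep, strain = as.character(strain),
                 genes = rownames(S), conditions = colnames(S),
                 normalized = isTRUE(normalized)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> strain %s: %d genes x %d conditions (%s), %d missing\n",
              x$strain, nrow(x$S), ncol(x$S),
              if (x$normalized) "quantile-normalized" else "raw",
              sum(is.na(x$S))))
  invisible(x)
}

#' Compute S-scores from normalized plates
#'
#' Turns border-corrected replicate plates of one strain into a moderated
#' t-like S-score per (gene, condition): how far the mutant's mean colony
#' size in a condition deviates from its typical size across conditions,
#' in units of the pooled standard error. Negative scores mean the deletion
#' grows worse than expected in that condition (sensitivity), positive
#' scores better (resistance).
#'
#' Procedure: sizes below `min_size` pixels are floored to `min_size`
#' (keeping strongly sick colonies informative); plates are scaled to a
#' common median so plate-level throughput differences cancel; conditions
#' with fewer than `min_replicates` replicates are dropped. For gene g in
#' condition c the experimental mean `m_E`, variance `v_E` and count `n_E`
#' are taken over all its colonies in that condition's replicate plates.
#' The control side uses the gene's behaviour across the whole screen:
#' `m_C` = median of its per-condition means, `v_C` = variance of those
#' means, `n_C` = number of conditions. Both variances are moderated by
#' flooring them at the median variance among genes in the same decile of
#' mean colony size, which stabilizes scores for low-variance flukes. Then
#'
#'   S = (m_E - m_C) / sqrt(v'_E / n_E + v'_C / n_C)
#'
#' Genes pinned at two library positions are pooled as extra replicates by
#' default; `split_duplicates = TRUE` scores the two positions separately
#' (gene ids suffixed `::1`, `::2`), which the duplicate-reproducibility
#' analysis needs.
#'
#' @param plates list of `plate_grid`s for one strain, QC-passed and at
#'   stage `"border"`.
#' @param layout the `library_layout` mapping positions to genes.
#' @param min_size minimum colony size in pixels (default 5).
#' @param min_replicates minimum replicates per retained condition
#'   (default 3).
#' @param split_duplicates score duplicate positions separately?
#' @return a `score_matrix` (not yet quantile-normalized). Gene x condition
#'   cells with fewer than 3 measurements are `NA`.
#' @export
compute_sscores <- function(plates, layout, min_size = 5,
                            min_replicates = 3L, split_duplicates = FALSE) {
  if (is_plate_grid(plates)) plates <- list(plates)
  if (!length(plates)) abort_input("no plates supplied")
  if (!all(vapply(plates, is_plate_grid, logical(1)))) {
    abort_input("`plates` must be plate_grid objects")
  }
  stages <- vapply(plates, function(p) p$stage, character(1))
  if (!all(stages == "border")) {
    abort_input("all plates must be border-corrected before scoring")
  }
  strain <- unique(vapply(plates, function(p) p$strain, character(1)))
  if (length(strain) != 1L) abort_input("plates must belong to a single strain")

  # duplicate-position labels: per gene, occurrences ordered by
  # (plate, row, col) get stable suffixes ::1, ::2
  pos <- layout$positions[!is.na(layout$positions$gene), , drop = FALSE]
  pos <- pos[order(pos$gene, pos$plate, pos$row, pos$col), ]
  occ <- stats::ave(seq_len(nrow(pos)), pos$gene, FUN = seq_along)
  pos$label <- if (split_duplicates) {
    ifelse(pos$gene %in% layout$duplicate_genes,
           paste0(pos$gene, "::", occ), pos$gene)
  } else pos$gene
  key <- paste(pos$plate, pos$row, pos$col, sep = "\r")
  label_of <- stats::setNames(pos$label, key)

  # long table of colony measurements
  recs <- lapply(plates, function(p) {
    lay <- p$layout
    if (is.null(lay)) abort_input("plate %s carries no layout", p$plate_id)
    filled <- lay[!is.na(lay$gene), , drop = FALSE]
    sz <- p$size[cbind(filled$row, filled$col)]
    plate_no <- if ("plate" %in% names(filled)) filled$plate else 1L
    data.table::data.table(
      gene = label_of[paste(plate_no, filled$row, filled$col, sep = "\r")],
      condition = p$condition, replicate = p$replicate, size = sz,
      plate = p$plate_id)
  })
  dt <- data.table::rbindlist(recs)
  if (any(is.na(dt$gene))) {
    warning("some positions map to no layout gene; skipped")
    dt <- dt[!is.na(gene)]
  }
  dt <- dt[!is.na(size)]
  if (!nrow(dt)) abort_input("no colony measurements available")

  # floor tiny colonies, then equalize plate medians
  size <- NULL; plate <- NULL; condition <- NULL; gene <- NULL
  med <- NULL; v_e <- NULL; v_c <- NULL; m_e <- NULL; m_c <- NULL # NSE notes
  dt[, size := pmax(size, min_size)]
  plate_med <- dt[, list(med = stats::median(size)), by = plate]
  ref_med <- stats::median(plate_med$med)
  dt <- merge(dt, plate_med, by = "plate")
  dt[, size := size * ref_med / med]

  # drop conditions with too few replicates
  cond_reps <- dt[, list(n = length(unique(replicate))), by = condition]
  keep <- cond_reps$condition[cond_reps$n >= min_replicates]
  if (!length(keep)) abort_input("no condition reaches %d replicates", min_replicates)
  dropped <- setdiff(cond_reps$condition, keep)
  if (length(dropped)) {
    warning(sprintf("conditions dropped (< %d replicates): %s",
                    min_replicates, paste(dropped, collapse = ", ")))
  }
  dt <- dt[condition %in% keep]

  # experimental side: per gene x condition
  exper <- dt[, list(m_e = mean(size), v_e = stats::var(size), n_e = .N),
              by = list(gene, condition)]
  # control side: typical behaviour of the gene across conditions
  ctrl <- exper[, list(m_c = stats::median(m_e), v_c = stats::var(m_e),
                       n_c = .N), by = gene]

  # variance moderation: floor at the median variance within the same
  # decile of mean size
  exper[, v_e := floor_variance(v_e, m_e)]
  ctrl[, v_c := floor_variance(v_c, m_c)]

  tab <- merge(exper, ctrl, by = "gene")
  tab$S <- (tab$m_e - tab$m_c) / sqrt(tab$v_e / tab$n_e + tab$v_c / tab$n_c)
  tab$S[tab$n_e < 3L | tab$n_c < 2L] <- NA_real_

  genes <- sort(unique(tab$gene)); conds <- sort(keep)
  S <- matrix(NA_real_, length(genes), length(conds),
              dimnames = list(genes, conds))
  n_rep <- matrix(0L, length(genes), length(conds),
                  dimnames = list(genes, conds))
  S[cbind(tab$gene, tab$condition)] <- tab$S
  n_rep[cbind(tab$gene, tab$condition)] <- tab$n_e
  score_matrix(S, n_rep, strain = strain, normalized = FALSE)
}

# floor variances at the median variance of entries in the same decile of
# mean size; NA variances (single measurement) become the decile median
floor_variance <- function(v, m, n_bins = 10L) {
  br <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1L),
                               na.rm = TRUE))
  bin <- if (length(br) > 2L) {
    cut(m, breaks = br, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, length(m))
  med <- stats::ave(v, bin, FUN = function(x) stats::median(x, na.rm = TRUE))
  med[is.na(med)] <- stats::median(v, na.rm = TRUE)
  out <- pmax(v, med)
  out[is.na(v)] <- med[is.na(v)]
  out
}

#' Quantile-normalize an S-score matrix across conditions
#'
#' Classic column-wise quantile normalization: each condition's sorted
#' scores are replaced by the across-condition mean of the order statistics,
#' so after normalization every condition shares one score distribution.
#' Ties are averaged; missing values stay missing and are excluded from the
#' ranks. Delegates to limma's reference implementation.
#'
#' @param sm a `score_matrix` not yet normalized.
#' @return the normalized `score_matrix`. A single-condition matrix is
#'   returned unchanged with a warning.
#' @export
quantile_normalize <- function(sm) {
  stopifnot(inherits(sm, "score_matrix"))
  if (sm$normalized) abort_input("matrix is already quantile-normalized")
  if (ncol(sm$S) < 2L) {
    warning("single condition: quantile normalization is the identity")
    sm$normalized <- TRUE
    return(sm)
  }
  Sn <- limma::normalizeQuantiles(sm$S, ties = TRUE)
  dimnames(Sn) <- dimnames(sm$S)
  sm$S <- Sn
  sm$normalized <- TRUE
  sm
}

#' Call significant growth phenotypes from normalized S-scores
#'
#' Within each condition the bulk of the S-scores follows a normal
#' distribution; each condition's location and scale are fitted and the
#' scores standardized to z-scores, the one-tailed P-value is the
#' upper-tail survival probability of |z| under the standard normal
#' (direction carried separately by the sign), and Benjamini-Hochberg
#' correction is applied across all gene x condition pairs of the strain.
#' A pair is called `sensitive` (loss-of-function, z < 0) or `resistant`
#' (gain-of-function, z > 0) when its q-value falls below `fdr`, else
#' `none`.
#'
#' By default location and scale are fitted robustly (median and
#' MAD), so the fit describes the null bulk of the condition rather than
#' being dragged by the real phenotypes in its tails; `robust = FALSE`
#' uses the plain mean and standard deviation.
#'
#' @param sm a quantile-normalized `score_matrix`.
#' @param fdr false discovery rate for calling (default 0.05).
#' @param robust fit location/scale as median/MAD (default) instead of
#'   mean/sd.
#' @return data frame of class `phenotype_calls`: `gene`, `condition`,
#'   `strain`, `s`, `z`, `p`, `q`, `call`. Conditions with zero score
#'   spread are skipped with a warning.
#' @export
call_phenotypes <- function(sm, fdr = 0.05, robust = TRUE) {
  stopifnot(inherits(sm, "score_matrix"))
  if (!sm$normalized) abort_input("call_phenotypes expects a quantile-normalized matrix")
  out <- list()
  for (cond in colnames(sm$S)) {
    s <- sm$S[, cond]
    ok <- !is.na(s)
    if (sum(ok) < 3L) next
    if (robust) {
      mu <- stats::median(s[ok]); sdv <- stats::mad(s[ok])
    } else {
      mu <- mean(s[ok]); sdv <- stats::sd(s[ok])
    }
    if (!is.finite(sdv) || sdv == 0) {
      warning(sprintf("condition %s skipped: zero score spread", cond))
      next
    }
    z <- (s - mu) / sdv
    out[[cond]] <- data.frame(
      gene = rownames(sm$S), condition = cond, strain = sm$strain,
      s = s, z = z, p = stats::pnorm(abs(z), lower.tail = FALSE),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(out)) abort_input("no condition could be scored")
  calls <- do.call(rbind, out)
  calls <- calls[!is.na(calls$s), , drop = FALSE]
  calls$q <- stats::p.adjust(calls$p, method = "BH")
  calls$call <- ifelse(calls$q < fdr,
                       ifelse(calls$z < 0, "sensitive", "resistant"),
                       "none")
  rownames(calls) <- NULL
  class(calls) <- c("phenotype_calls", "data.frame")
  attr(calls, "fdr") <- fdr
  calls
}
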