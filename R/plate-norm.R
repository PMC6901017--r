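#' Quality-control flagging of a raw plate
#'
#' Flags poor-quality plates before normalization. Two rules, both computed
#' over the layout positions that are not known-empty: `too_many_missing`
#' when more than 5% of colonies have no reported size (poor overall
#' quality), and `row_or_col_missing` when more than 90% of any whole row or
#' column is missing (potential grid misalignment). Known-empty spots never
#' count as missing.
#'
#' @param plate a `plate_grid` at stage `"raw"`.
#' @param max_missing_frac overall missing-fraction threshold (default 0.05).
#' @param line_missing_frac per-row/column missing-fraction threshold
#'   (default 0.9).
#' @return a list of class `qc_status`: `plate_id`, `flagged`, `reasons`
#'   (character subset of `"too_many_missing"`, `"row_or_col_missing"`),
#'   `missing_frac`.
#' @export
qc_flag <- function(plate, max_missing_frac = 0.05, line_missing_frac = 0.9) {
  stopifnot(is_plate_grid(plate))
  if (plate$stage != "raw") abort_input("qc_flag expects a raw plate")
  considered <- layout_mask(plate) & !empty_mask(plate)
  if (!any(considered)) {
    abort_input("plate %s has no non-empty layout positions", plate$plate_id)
  }
  miss <- is.na(plate$size) & considered
  frac <- sum(miss) / sum(considered)
  reasons <- character(0)
  if (frac > max_missing_frac) reasons <- c(reasons, "too_many_missing")

  row_frac <- rowSums(miss) / pmax(rowSums(considered), 1L)
  col_frac <- colSums(miss) / pmax(colSums(considered), 1L)
  row_frac[rowSums(considered) == 0] <- 0
  col_frac[colSums(considered) == 0] <- 0
  if (any(row_frac > line_missing_frac) || any(col_frac > line_missing_frac)) {
    reasons <- c(reasons, "row_or_col_missing")
  }
  structure(list(plate_id = plate$plate_id, flagged = length(reasons) > 0,
                 reasons = reasons, missing_frac = frac),
            class = "qc_status")
}

#' @export
print.qc_status <- function(x, ...) {
  cat(sprintf("<qc_status> %s: %s%s (%.2f%% missing)\n", x$plate_id,
              if (x$flagged) "FLAGGED" else "pass",
              if (x$flagged) paste0(" [", paste(x$reasons, collapse = ", "), "]") else "",
              100 * x$missing_frac))
  invisible(x)
}

# degree-2 polynomial design on centered row/column indices:
# {1, r, c, r^2, c^2, r*c}
surface_design <- function(r, c_) {
  r <- r - mean(r); c_ <- c_ - mean(c_)
  cbind(1, r, c_, r^2, c_^2, r * c_)
}

#' Surface correction of a colony plate
#'
#' Removes smooth spatial artifacts (uneven nutrient distribution, pinning
#' pressure gradients) by fitting ordinary least squares of colony size on
#' the second-degree polynomial expansion of the row and column indices —
#' terms 1, r, c, r^2, c^2, r*c — solved through the QR factorization of
#' the expanded design. The corrected size is
#' `raw - fitted + mean(raw over non-missing colonies)`, so the plate mean
#' is preserved while the fitted spatial trend is flattened out. Missing
#' colonies stay missing.
#'
#' @param plate a `plate_grid` at stage `"raw"` with at least 12 non-missing
#'   colonies (degrees of freedom for the 6-term fit).
#' @return the corrected `plate_grid` at stage `"surface"`. If the design is
#'   rank-deficient after dropping missing positions the fit degenerates to
#'   the constant (the plate is returned unchanged) with a warning.
#' @export
surface_correct <- function(plate) {
  stopifnot(is_plate_grid(plate))
  if (plate$stage != "raw") abort_input("surface_correct expects a raw plate")
  obs <- which(!is.na(plate$size), arr.ind = TRUE)
  if (nrow(obs) < 12L) {
    abort_input("surface fit needs >= 12 non-missing colonies, plate %s has %d",
                plate$plate_id, nrow(obs))
  }
  y <- plate$size[obs]
  X <- surface_design(obs[, "row"], obs[, "col"])
  fit <- stats::lm.fit(X, y)  # QR with pivoting
  if (fit$rank < ncol(X)) {
    warning(sprintf("plate %s: rank-deficient surface design (rank %d); constant fit used",
                    plate$plate_id, fit$rank))
    plate$stage <- "surface"
    return(plate)
  }
  corrected <- y - fit$fitted.values + mean(y)
  out <- plate
  out$size[obs] <- corrected
  out$stage <- "surface"
  out
}

#' Border correction of a colony plate
#'
#' Colonies on the plate edge grow larger because they compete for fewer
#' nutrients. The outer region — the two outermost rows and two outermost
#' columns — is rescaled so its median matches the inner-plate median:
#' `S_outer * median(S_inner) / median(S_outer)`. Inner colonies are left
#' untouched; medians are taken over non-missing colonies only.
#'
#' @param plate a `plate_grid` at stage `"surface"`, at least 5 x 5 so the
#'   inner region is non-empty.
#' @return the corrected `plate_grid` at stage `"border"`. If the outer
#'   median is zero or the outer ring is all-missing the correction is
#'   skipped with a warning (stage still advances).
#' @export
border_correct <- function(plate) {
  stopifnot(is_plate_grid(plate))
  if (plate$stage != "surface") abort_input("border_correct expects a surface-corrected plate")
  rows <- nrow(plate$size); cols <- ncol(plate$size)
  if (rows < 5L || cols < 5L) {
    abort_input("border correction needs a grid of at least 5x5 (got %dx%d)", rows, cols)
  }
  ring <- outer_ring_mask(rows, cols)
  outer_vals <- plate$size[ring]
  inner_vals <- plate$size[!ring]
  med_outer <- stats::median(outer_vals, na.rm = TRUE)
  med_inner <- stats::median(inner_vals, na.rm = TRUE)
  out <- plate
  if (!is.finite(med_outer) || med_outer == 0 || !is.finite(med_inner)) {
    warning(sprintf("plate %s: border correction skipped (degenerate outer/inner median)",
                    plate$plate_id))
  } else {
    out$size[ring] <- plate$size[ring] * med_inner / med_outer
  }
  out$stage <- "border"
  out
}

#' Normalize a raw plate (surface then border correction)
#'
#' Convenience wrapper running [surface_correct()] then [border_correct()].
#'
#' @param plate a raw `plate_grid`.
#' @return the plate at stage `"border"`.
#' @export
normalize_plate <- function(plate) border_correct(surface_correct(plate))

#' Relative wild-type fitness of a strain against a reference
#'
#' Computes phi, the ratio of a strain's median normalized colony size to
#' the reference strain's, per condition and replicate. Both plate sets must
#' be fully normalized (stage `"border"`), share the condition, and come
#' from the same experimental batch — plates screened at different times are
#' refused so the ratio is robust to changes in experimental conditions.
#'
#' @param strain_plates,reference_plates lists of `plate_grid` objects at
#'   stage `"border"` for one condition.
#' @return data frame of class `fitness_record` with columns `strain`,
#'   `condition`, `replicate`, `phi`. The reference's median is matched by
#'   replicate when that replicate exists in the reference set, otherwise
#'   pooled over the reference plates.
#' @export
relative_fitness <- function(strain_plates, reference_plates) {
  if (is_plate_grid(strain_plates)) strain_plates <- list(strain_plates)
  if (is_plate_grid(reference_plates)) reference_plates <- list(reference_plates)
  all_p <- c(strain_plates, reference_plates)
  if (!all(vapply(all_p, is_plate_grid, logical(1)))) {
    abort_input("inputs must be plate_grid objects")
  }
  if (!all(vapply(all_p, function(p) p$stage, character(1)) == "border")) {
    abort_input("relative fitness is computed on border-corrected plates")
  }
  conds <- unique(vapply(all_p, function(p) p$condition, character(1)))
  if (length(conds) != 1L) {
    abort_input("all plates must share one condition (got: %s)",
                paste(conds, collapse = ", "))
  }
  batches <- unique(vapply(all_p, function(p) p$batch, integer(1)))
  if (length(batches) != 1L) {
    abort_input("strain and reference plates must come from the same batch (got batches: %s)",
                paste(batches, collapse = ", "))
  }
  strain <- unique(vapply(strain_plates, function(p) p$strain, character(1)))
  if (length(strain) != 1L) abort_input("strain plates must belong to one strain")

  ref_sizes_by_rep <- split(
    unlist(lapply(reference_plates, function(p) as.vector(p$size))),
    rep(vapply(reference_plates, function(p) p$replicate, integer(1)),
        vapply(reference_plates, function(p) length(p$size), integer(1))))
  ref_pooled <- unlist(lapply(reference_plates, function(p) as.vector(p$size)))

  reps <- sort(unique(vapply(strain_plates, function(p) p$replicate, integer(1))))
  phi <- vapply(reps, function(r) {
    sv <- unlist(lapply(strain_plates[vapply(strain_plates, function(p) p$replicate, integer(1)) == r],
                        function(p) as.vector(p$size)))
    rv <- ref_sizes_by_rep[[as.character(r)]] %||% ref_pooled
    ref_med <- stats::median(rv, na.rm = TRUE)
    if (!is.finite(ref_med) || ref_med == 0) {
      abort_input("reference median is zero or undefined; relative fitness undefined")
    }
    stats::median(sv, na.rm = TRUE) / ref_med
  }, numeric(1))

  out <- data.frame(strain = strain, condition = conds, replicate = reps,
                    phi = phi, stringsAsFactors = FALSE)
  class(out) <- c("fitness_record", "data.frame")
  out
}
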