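#' Simulate colony-size plates for a KO library screen
#'
#' Generates raw `plate_grid`s for one strain under the multiplicative
#' fitness model held by a [ground_truth()]: colony size at position (r, c)
#' carrying gene g in condition c is
#' `base * gene_effect(g) * condition_effect(c) * interaction(strain, g, c)`
#' times the plate's spatial surface factor, the border factor (outer two
#' rows/columns) and lognormal replicate noise, rounded to whole pixels.
#' Known-empty and unused positions emit `NA`.
#'
#' Each (condition, batch, replicate, plate) combination yields one grid;
#' screens of this kind collect four biological replicates per condition,
#' so `n_replicates` defaults to 4. Output is deterministic given the
#' truth's seed and the metadata of each plate, independent of generation
#' order.
#'
#' @param layout a `library_layout`.
#' @param truth a `ground_truth` covering the layout's genes and the
#'   requested conditions.
#' @param conditions condition identifiers to screen.
#' @param n_replicates biological replicates per condition (>= 3, the
#'   minimum the scoring stage accepts).
#' @param n_batches number of experimental batches; each batch repeats the
#'   full replicate set.
#' @param strain strain screened; defaults to the layout's strain.
#' @return list of `plate_grid` objects at stage `"raw"`.
#' @export
gen_plates <- function(layout, truth, conditions, n_replicates = 4L,
                       n_batches = 1L, strain = layout$strain) {
  if (!inherits(layout, "library_layout")) abort_input("`layout` must be a library_layout")
  if (!inherits(truth, "ground_truth")) abort_input("`truth` must be a ground_truth")
  n_replicates <- as.integer(n_replicates); n_batches <- as.integer(n_batches)
  if (n_replicates < 3L) {
    abort_input("n_replicates must be >= 3 (the scoring stage drops conditions with fewer)")
  }
  missing_genes <- setdiff(layout$genes, names(truth$gene_effect))
  if (length(missing_genes)) {
    abort_input("truth lacks gene effects for: %s",
                paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  missing_conds <- setdiff(conditions, names(truth$condition_effect))
  if (length(missing_conds)) {
    abort_input("truth lacks condition effects for: %s",
                paste(missing_conds, collapse = ", "))
  }

  rows <- layout$grid[["rows"]]; cols <- layout$grid[["cols"]]
  imap <- interaction_map(truth, strain)
  border_m <- border_factor_matrix(truth, rows, cols)

  plates <- list()
  for (p in seq_len(layout$n_plates)) {
    lay <- plate_layout(layout, p)
    filled <- lay[!is.na(lay$gene), , drop = FALSE]
    idx <- cbind(filled$row, filled$col)
    surf <- surface_factor(truth, strain, p, rows, cols)
    ge <- truth$gene_effect[filled$gene]
    for (cond in conditions) {
      ce <- truth$condition_effect[[cond]]
      ia <- imap[paste(filled$gene, cond, sep = "\r")]
      ia[is.na(ia)] <- 1
      mu <- truth$base_size * ge * ce * ia
      for (b in seq_len(n_batches)) {
        for (r in seq_len(n_replicates)) {
          size <- matrix(NA_real_, rows, cols)
          noise <- if (truth$noise_sd > 0) {
            set.seed(derive_seed(truth$seed, "noise", strain, cond, b, r, p))
            exp(stats::rnorm(nrow(filled), 0, truth$noise_sd))
          } else rep(1, nrow(filled))
          size[idx] <- round(mu * surf[idx] * border_m[idx] * noise)
          plates[[length(plates) + 1L]] <- plate_grid(
            size,
            plate_id = sprintf("%s_%s_b%d_r%d_p%d", strain, cond, b, r, p),
            strain = strain, condition = cond, replicate = r, batch = b,
            layout = lay)
        }
      }
    }
  }
  plates
}
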