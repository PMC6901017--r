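#' Generate a KO-library plate layout
#'
#' Builds a randomized library layout: gene deletions assigned to positions
#' on one or more rows x cols plates (default 32 x 48, the 1,536-colony
#' format), with a configurable number of genes pinned at exactly two
#' positions (duplicates, used for biological reproducibility estimates) and
#' intentionally empty spots that downstream quality control relies on.
#'
#' `n_genes` singleton genes occupy one position each and `n_duplicates`
#' additional genes occupy two positions each, so the layout carries
#' `n_genes + n_duplicates` distinct genes over
#' `n_genes + 2 * n_duplicates + n_empty` positions. Positions left over
#' are unused (no strain pinned, not flagged as known-empty).
#'
#' @param n_genes number of singleton genes.
#' @param n_duplicates number of genes placed at exactly two positions.
#' @param grid_shape integer vector `c(rows, cols)`; default `c(32, 48)`.
#' @param n_empty number of known-empty spots (at least one per plate).
#' @param n_plates number of plates.
#' @param strain strain identifier attached to the layout.
#' @param seed integer seed; the same seed yields an identical layout.
#' @return an object of class `library_layout` with elements `strain`,
#'   `grid` (rows, cols), `n_plates`, `positions` (data frame: `plate`,
#'   `row`, `col`, `gene`, `known_empty`), `genes`, `duplicate_genes`.
#' @export
gen_layout <- function(n_genes, n_duplicates = 0L, grid_shape = c(32L, 48L),
                       n_empty = 1L, n_plates = 1L, strain = "strain1",
                       seed = 1L) {
  n_genes <- as.integer(n_genes); n_duplicates <- as.integer(n_duplicates)
  n_empty <- as.integer(n_empty); n_plates <- as.integer(n_plates)
  if (n_genes < 1L || n_duplicates < 0L || n_empty < 0L || n_plates < 1L) {
    abort_input("counts must be positive (n_genes >= 1, others >= 0)")
  }
  rows <- as.integer(grid_shape[1]); cols <- as.integer(grid_shape[2])
  capacity <- rows * cols * n_plates
  required <- n_genes + 2L * n_duplicates + n_empty
  if (required > capacity) {
    abort_input(
      "layout needs %d positions (%d singleton + 2x%d duplicate + %d empty) but only %d are available on %d %dx%d plate(s)",
      required, n_genes, n_duplicates, n_empty, capacity, n_plates, rows, cols)
  }
  if (n_empty < n_plates) {
    abort_input("need at least one known-empty spot per plate (%d plates, %d empty)",
                n_plates, n_empty)
  }

  genes <- sprintf("g%04d", seq_len(n_genes + n_duplicates))
  dup_genes <- if (n_duplicates > 0L) genes[seq_len(n_duplicates)] else character(0)
  # pinned labels: duplicated genes twice, singletons once
  labels <- c(rep(dup_genes, each = 2L), setdiff(genes, dup_genes))

  set.seed(derive_seed(seed, "layout", n_genes, n_duplicates, rows, cols,
                       n_empty, n_plates))
  all_pos <- data.frame(
    plate = rep(seq_len(n_plates), each = rows * cols),
    row = rep(rep(seq_len(rows), times = cols), times = n_plates),
    col = rep(rep(seq_len(cols), each = rows), times = n_plates)
  )
  # guarantee one empty spot per plate, the rest anywhere
  ord <- sample.int(nrow(all_pos))
  all_pos <- all_pos[ord, ]
  first_per_plate <- !duplicated(all_pos$plate)
  empty_idx <- which(first_per_plate)[seq_len(n_plates)]
  remaining <- setdiff(seq_len(nrow(all_pos)), empty_idx)
  extra_empty <- remaining[seq_len(n_empty - n_plates)]
  empty_idx <- c(empty_idx, extra_empty)
  gene_idx <- setdiff(seq_len(nrow(all_pos)), empty_idx)[seq_along(labels)]

  positions <- all_pos
  positions$gene <- NA_character_
  positions$gene[gene_idx] <- labels
  positions$known_empty <- FALSE
  positions$known_empty[empty_idx] <- TRUE
  # drop unused positions not part of the pinned library
  positions <- positions[!is.na(positions$gene) | positions$known_empty, ]
  positions <- positions[order(positions$plate, positions$row, positions$col), ]
  rownames(positions) <- NULL

  structure(
    list(strain = strain, grid = c(rows = rows, cols = cols),
         n_plates = n_plates, positions = positions,
         genes = genes, duplicate_genes = dup_genes, seed = seed),
    class = "library_layout"
  )
}

#' @export
print.library_layout <- function(x, ...) {
  cat(sprintf("<library_layout> strain %s: %d genes (%d duplicated), %d plate(s) of %d x %d, %d known-empty spots\n",
              x$strain, length(x$genes), length(x$duplicate_genes),
              x$n_plates, x$grid["rows"], x$grid["cols"],
              sum(x$positions$known_empty)))
  invisible(x)
}

# layout rows for one plate, as expected by plate_grid()
plate_layout <- function(layout, plate) {
  sub <- layout$positions[layout$positions$plate == plate,
                          c("plate", "row", "col", "gene", "known_empty")]
  rownames(sub) <- NULL
  sub
}
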