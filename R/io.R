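#' Write a plate grid as a gitter-style .dat table
#'
#' One row per layout position with columns `row`, `col`, `size` and
#' `flag` (`E` for known-empty spots, `M` for missing colony sizes, empty
#' otherwise), tab-separated with `#`-prefixed header comments. Plate
#' metadata (plate id, strain, condition, replicate, batch, stage, grid
#' shape) goes to a YAML sidecar `<path>.yaml`.
#'
#' @param plate a `plate_grid`.
#' @param path output `.dat` path.
#' @return `path`, invisibly.
#' @export
write_gitter <- function(plate, path) {
  stopifnot(is_plate_grid(plate))
  lay <- plate$layout
  if (is.null(lay)) {
    lay <- expand.grid(row = seq_len(nrow(plate$size)),
                       col = seq_len(ncol(plate$size)))
    lay$gene <- NA_character_; lay$known_empty <- FALSE
  }
  sz <- plate$size[cbind(lay$row, lay$col)]
  flag <- ifelse(lay$known_empty, "E", ifelse(is.na(sz), "M", ""))
  tab <- data.frame(row = lay$row, col = lay$col,
                    size = ifelse(is.na(sz), "NA", format(sz, trim = TRUE)),
                    flag = flag, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gitter-style colony size table",
               sprintf("# plate_id: %s", plate$plate_id)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(
    list(plate_id = plate$plate_id, strain = plate$strain,
         condition = plate$condition, replicate = plate$replicate,
         batch = plate$batch, stage = plate$stage,
         rows = nrow(plate$size), cols = ncol(plate$size)),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read a gitter-style .dat plate back into a `plate_grid`
#'
#' Counterpart of [write_gitter()]; expects the YAML metadata sidecar next
#' to the `.dat` file.
#'
#' @param path `.dat` path written by [write_gitter()].
#' @return a `plate_grid`.
#' @export
read_gitter <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c("integer", "integer", "character",
                                          "character"))
  size <- matrix(NA_real_, meta$rows, meta$cols)
  vals <- suppressWarnings(as.numeric(tab$size))
  size[cbind(tab$row, tab$col)] <- vals
  layout <- data.frame(row = tab$row, col = tab$col,
                       gene = NA_character_,
                       known_empty = tab$flag == "E",
                       stringsAsFactors = FALSE)
  plate_grid(size, plate_id = meta$plate_id, strain = meta$strain,
             condition = meta$condition, replicate = meta$replicate,
             batch = meta$batch, stage = meta$stage, layout = layout)
}

#' Write an S-score matrix as TSV
#'
#' Genes x conditions, with a `gene` first column.
#'
#' @param sm a `score_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(sm, path) {
  stopifnot(inherits(sm, "score_matrix"))
  df <- data.frame(gene = rownames(sm$S), sm$S, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write phenotype or difference calls as long-format TSV
#'
#' @param calls a data frame (`phenotype_calls` or `diff_calls`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene coordinates from a BED file
#'
#' BED is 0-based half-open on disk; coordinates are converted to the
#' 1-based inclusive convention used internally.
#'
#' @param path BED path (columns chrom, start, end, name).
#' @return data frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `gene`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) abort_input("BED file needs at least 4 columns")
  data.frame(chrom = tab[[1]], start = tab[[2]] + 1L, end = tab[[3]],
             gene = tab[[4]], stringsAsFactors = FALSE)
}

#' Write gene coordinates as BED
#'
#' Converts from the internal 1-based inclusive convention to BED's
#' 0-based half-open intervals.
#'
#' @param genes data frame with `chrom`, `start`, `end`, `gene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  tab <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
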