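#' Colony-size plate grid
#'
#' A `plate_grid` holds one plate's colony sizes on a rows x columns grid
#' together with screen metadata (strain, condition, replicate, batch) and a
#' link to the library layout describing which gene deletion sits at each
#' position. Sizes are non-negative pixel counts; positions where no colony
#' size could be measured (or that are known-empty in the layout) are `NA`.
#'
#' The `stage` field tracks normalization: plates start `"raw"`, move to
#' `"surface"` after [surface_correct()] and to `"border"` after
#' [border_correct()]; stage transitions are enforced by those functions.
#'
#' @param size numeric matrix (rows x cols) of colony sizes in pixels;
#'   `NA` marks missing colonies. Negative values are rejected.
#' @param plate_id plate identifier.
#' @param strain,condition,replicate,batch screen metadata.
#' @param stage one of `"raw"`, `"surface"`, `"border"`.
#' @param layout optional data frame with columns `row`, `col`, `gene`
#'   (`NA` for positions carrying no strain) and `known_empty` (logical,
#'   positions left intentionally empty when the library was pinned).
#' @return an object of class `plate_grid`.
#' @export
plate_grid <- function(size, plate_id, strain, condition,
                       replicate = 1L, batch = 1L, stage = "raw",
                       layout = NULL) {
  if (!is.matrix(size) || !is.numeric(size)) {
    abort_input("`size` must be a numeric matrix")
  }
  if (any(size < 0, na.rm = TRUE)) {
    abort_input("colony sizes must be non-negative pixel counts")
  }
  stage <- match.arg(stage, c("raw", "surface", "border"))
  if (!is.null(layout)) {
    need <- c("row", "col", "gene", "known_empty")
    if (!all(need %in% names(layout))) {
      abort_input("plate layout needs columns: %s", paste(need, collapse = ", "))
    }
    if (any(layout$row > nrow(size)) || any(layout$col > ncol(size))) {
      abort_input("layout positions fall outside the %dx%d grid",
                  nrow(size), ncol(size))
    }
  }
  structure(
    list(size = size, plate_id = as.character(plate_id),
         strain = as.character(strain), condition = as.character(condition),
         replicate = as.integer(replicate), batch = as.integer(batch),
         stage = stage, layout = layout),
    class = "plate_grid"
  )
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf(
    "<plate_grid> %s | strain %s | condition %s | rep %d | batch %d | stage %s\n",
    x$plate_id, x$strain, x$condition, x$replicate, x$batch, x$stage))
  cat(sprintf("  %d x %d grid, %d missing colonies\n",
              nrow(x$size), ncol(x$size), sum(is.na(x$size))))
  invisible(x)
}

is_plate_grid <- function(x) inherits(x, "plate_grid")

# positions that belong to the pinned library (gene or known-empty);
# when no layout is attached every grid position counts as a layout position
layout_mask <- function(plate) {
  m <- matrix(FALSE, nrow(plate$size), ncol(plate$size))
  if (is.null(plate$layout)) {
    m[] <- TRUE
  } else {
    lay <- plate$layout
    m[cbind(lay$row, lay$col)] <- TRUE
  }
  m
}

# logical matrix of known-empty spots
empty_mask <- function(plate) {
  m <- matrix(FALSE, nrow(plate$size), ncol(plate$size))
  if (!is.null(plate$layout)) {
    lay <- plate$layout[plate$layout$known_empty, , drop = FALSE]
    if (nrow(lay)) m[cbind(lay$row, lay$col)] <- TRUE
  }
  m
}
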