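#' Ground truth for synthetic screens
#'
#' Encodes the multiplicative fitness model the screen analysis assumes: the
#' expected colony size of deletion mutant g in condition c for strain s is
#'
#'   base_size * gene_effect(g) * condition_effect(c) * interaction(s, g, c)
#'
#' modulated per plate by a smooth spatial surface factor, a border factor on
#' the two outermost rows/columns, and lognormal replicate noise.
#' `interaction == 1` means the deletion behaves as expected from its marginal
#' fitness (no chemical-genetic interaction); interactions different from 1
#' are "planted" phenotypes whose recovery downstream can be scored.
#'
#' @param genes,conditions,strains identifiers covered by the truth.
#' @param gene_effect named positive vector per gene; by default drawn
#'   lognormal with `gene_effect_sd` on the log scale.
#' @param condition_effect named positive vector per condition; defaults
#'   lognormal with `condition_effect_sd`.
#' @param interactions data frame with columns `strain`, `gene`,
#'   `condition`, `multiplier` (positive) for the planted set; all other
#'   triples have multiplier 1.
#' @param base_size expected colony size in pixels for a neutral gene in a
#'   neutral condition.
#' @param surface_sd standard deviation of the per-plate quadratic surface
#'   coefficients (log scale, on row/column indices rescaled to \[-1, 1\]);
#'   0 gives a flat surface.
#' @param border_factor multiplicative size factor for colonies in the two
#'   outermost rows and columns (1 = no border effect).
#' @param noise_sd lognormal replicate noise, log scale.
#' @param gene_effect_sd,condition_effect_sd log-scale spread of the default
#'   marginal effects.
#' @param seed integer seed controlling every random draw derived from this
#'   truth (effects, surfaces, replicate noise).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(genes, conditions, strains,
                         gene_effect = NULL, condition_effect = NULL,
                         interactions = NULL,
                         base_size = 300, surface_sd = 0.05,
                         border_factor = 1.2, noise_sd = 0.2,
                         gene_effect_sd = 0.15, condition_effect_sd = 0.1,
                         seed = 1L) {
  check_number(base_size, "base_size"); check_number(noise_sd, "noise_sd")
  check_number(border_factor, "border_factor")
  if (base_size <= 0 || border_factor <= 0 || noise_sd < 0 || surface_sd < 0) {
    abort_input("base_size and border_factor must be > 0; sds must be >= 0")
  }
  if (is.null(gene_effect)) {
    set.seed(derive_seed(seed, "gene_effect"))
    gene_effect <- stats::setNames(exp(stats::rnorm(length(genes), 0, gene_effect_sd)), genes)
  }
  if (is.null(condition_effect)) {
    set.seed(derive_seed(seed, "condition_effect"))
    condition_effect <- stats::setNames(
      exp(stats::rnorm(length(conditions), 0, condition_effect_sd)), conditions)
  }
  if (!all(genes %in% names(gene_effect))) {
    abort_input("gene_effect must cover every gene")
  }
  if (!all(conditions %in% names(condition_effect))) {
    abort_input("condition_effect must cover every condition")
  }
  if (any(gene_effect <= 0) || any(condition_effect <= 0)) {
    abort_input("all effect multipliers must be positive")
  }
  if (is.null(interactions)) {
    interactions <- data.frame(strain = character(0), gene = character(0),
                               condition = character(0), multiplier = numeric(0))
  }
  if (nrow(interactions)) {
    need <- c("strain", "gene", "condition", "multiplier")
    if (!all(need %in% names(interactions))) {
      abort_input("interactions needs columns: %s", paste(need, collapse = ", "))
    }
    if (any(interactions$multiplier <= 0)) {
      abort_input("interaction multipliers must be positive")
    }
    bad <- !(interactions$gene %in% genes) | !(interactions$condition %in% conditions)
    if (any(bad)) abort_input("interactions reference unknown genes/conditions")
  }
  structure(
    list(genes = genes, conditions = conditions, strains = strains,
         gene_effect = gene_effect, condition_effect = condition_effect,
         interactions = interactions, base_size = base_size,
         surface_sd = surface_sd, border_factor = border_factor,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d genes x %d conditions x %d strains, %d planted interactions\n",
              length(x$genes), length(x$conditions), length(x$strains),
              nrow(x$interactions)))
  cat(sprintf("  base %g px, noise_sd %g, border_factor %g, surface_sd %g, seed %d\n",
              x$base_size, x$noise_sd, x$border_factor, x$surface_sd, x$seed))
  invisible(x)
}

# interaction multiplier lookup for one strain; returns named vector over
# (gene, condition) keys "gene\rcondition"
interaction_map <- function(truth, strain) {
  it <- truth$interactions[truth$interactions$strain == strain, , drop = FALSE]
  if (!nrow(it)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(it$multiplier, paste(it$gene, it$condition, sep = "\r"))
}

# per-plate smooth surface factor (matrix rows x cols); quadratic in the
# rescaled row/column indices, exponentiated so it is positive
surface_factor <- function(truth, strain, plate, rows, cols) {
  if (truth$surface_sd == 0) return(matrix(1, rows, cols))
  set.seed(derive_seed(truth$seed, "surface", strain, plate))
  b <- stats::rnorm(5, 0, truth$surface_sd)
  r <- if (rows > 1) 2 * (seq_len(rows) - 1) / (rows - 1) - 1 else rep(0, rows)
  c_ <- if (cols > 1) 2 * (seq_len(cols) - 1) / (cols - 1) - 1 else rep(0, cols)
  R <- matrix(r, rows, cols); C <- matrix(c_, rows, cols, byrow = TRUE)
  exp(b[1] * R + b[2] * C + b[3] * R^2 + b[4] * C^2 + b[5] * R * C)
}

# border factor matrix: truth$border_factor on the two outermost rows and
# columns, 1 elsewhere
border_factor_matrix <- function(truth, rows, cols) {
  m <- matrix(1, rows, cols)
  m[outer_ring_mask(rows, cols)] <- truth$border_factor
  m
}

# logical mask of the outer two rows and columns
outer_ring_mask <- function(rows, cols) {
  m <- matrix(FALSE, rows, cols)
  depth <- 2L
  m[seq_len(min(depth, rows)), ] <- TRUE
  m[seq(max(1L, rows - depth + 1L), rows), ] <- TRUE
  m[, seq_len(min(depth, cols))] <- TRUE
  m[, seq(max(1L, cols - depth + 1L), cols)] <- TRUE
  m
}
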