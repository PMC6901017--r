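#' Simulate a multi-strain chemical-genomic screen with known ground truth
#'
#' Assembles the complete study design the downstream modules are tested
#' against: a library layout, a ground truth with three layers of planted
#' chemical-genetic interactions, and the bookkeeping needed to score
#' recovery afterwards.
#'
#' The interaction layers emulate the structure of real deletion screens:
#'
#' * a background of weak interactions (`background_frac` of all
#'   gene x condition pairs, log-normal multipliers with spread
#'   `background_sd`) present identically in every strain, giving the
#'   S-score distribution its heavy-ish tails and the continuum of effect
#'   sizes that the sliding-window null's variance-vs-magnitude trend is
#'   built from;
#' * strong conserved interactions (`shared_frac` of pairs, multiplier
#'   `effect_multiplier`) present in every strain — phenotypes expected to
#'   be called in each background and classified as shared;
#' * strong strain-specific interactions (`specific_frac` of pairs,
#'   multiplier `effect_multiplier`) present only in the focal strain —
#'   the differential-phenotype signal whose recovery is the pipeline's
#'   main job.
#'
#' The planted conservation fraction for the focal strain is therefore
#' `shared_frac / (shared_frac + specific_frac)`.
#'
#' @param n_genes genes in the library.
#' @param n_conditions screened conditions.
#' @param strains strain identifiers; the first is the reference (used for
#'   the batch-replicate null), the second the focal strain carrying the
#'   strain-specific layer.
#' @param specific_frac fraction of gene x condition pairs with a planted
#'   focal-strain-specific interaction (default 0.05).
#' @param shared_frac fraction with a strong interaction conserved in all
#'   strains (default 0.05).
#' @param background_frac fraction with a weak conserved interaction
#'   (default 0.15).
#' @param effect_multiplier fitness multiplier of the strong layers
#'   (default 0.25, i.e. |log2| = 2, conditionally essential).
#' @param background_sd log-scale spread of the weak layer (default 0.4).
#' @param n_duplicates genes pinned at two library positions (see
#'   [gen_layout()]); duplicated genes are drawn from the same gene pool,
#'   so `n_genes` counts singletons only.
#' @param grid_shape,n_empty,noise_sd,... forwarded to [gen_layout()] and
#'   [ground_truth()].
#' @param seed master seed.
#' @return list of class `screen_truth`: `layout`, `truth`, `conditions`,
#'   `strains`, `planted_specific` and `planted_shared` (data frames of
#'   gene, condition), `conservation_frac`.
#' @export
simulate_screen <- function(n_genes = 1000L, n_conditions = 12L,
                            strains = c("ref", "strainA", "strainB"),
                            specific_frac = 0.05, shared_frac = 0.05,
                            background_frac = 0.15,
                            effect_multiplier = 0.25, background_sd = 0.4,
                            grid_shape = c(32L, 48L), n_empty = 8L,
                            n_duplicates = 0L, noise_sd = 0.2, seed = 1L, ...) {
  if (length(strains) < 2L) abort_input("need a reference and at least one focal strain")
  capacity <- prod(grid_shape)
  n_plates <- ceiling((n_genes + 2L * n_duplicates + n_empty) / capacity)
  n_empty <- max(n_empty, n_plates)
  layout <- gen_layout(n_genes, n_duplicates = n_duplicates,
                       grid_shape = grid_shape,
                       n_empty = n_empty, n_plates = n_plates, seed = seed)
  conds <- sprintf("cond%02d", seq_len(n_conditions))

  set.seed(derive_seed(seed, "planted"))
  pairs <- expand.grid(gene = layout$genes, condition = conds,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  n_pairs <- nrow(pairs)
  n_spec <- round(specific_frac * n_pairs)
  n_shar <- round(shared_frac * n_pairs)
  n_bg <- round(background_frac * n_pairs)
  pick <- sample(n_pairs, n_spec + n_shar + n_bg)
  spec <- pairs[pick[seq_len(n_spec)], , drop = FALSE]
  shar <- pairs[pick[n_spec + seq_len(n_shar)], , drop = FALSE]
  bg <- pairs[pick[n_spec + n_shar + seq_len(n_bg)], , drop = FALSE]
  bg_mult <- exp(stats::rnorm(n_bg, 0, background_sd))

  focal <- strains[2]
  layer <- function(strain, pairs, multiplier) {
    if (!nrow(pairs)) return(NULL)
    data.frame(strain = strain, gene = pairs$gene,
               condition = pairs$condition, multiplier = multiplier,
               stringsAsFactors = FALSE)
  }
  ints <- do.call(rbind, c(
    list(layer(focal, spec, effect_multiplier)),
    lapply(strains, function(s) layer(s, shar, effect_multiplier)),
    lapply(strains, function(s) layer(s, bg, bg_mult))))
  if (is.null(ints)) ints <- NULL else rownames(ints) <- NULL

  truth <- ground_truth(layout$genes, conds, strains = strains,
                        interactions = ints, noise_sd = noise_sd,
                        seed = seed, ...)
  structure(
    list(layout = layout, truth = truth, conditions = conds,
         strains = strains, planted_specific = spec, planted_shared = shar,
         planted_background = bg,
         conservation_frac = if (n_spec + n_shar > 0) n_shar / (n_spec + n_shar) else NA_real_),
    class = "screen_truth")
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf("<screen_truth> %d genes x %d conditions, strains: %s\n",
              length(x$layout$genes), length(x$conditions),
              paste(x$strains, collapse = ", ")))
  cat(sprintf("  planted: %d specific (focal %s), %d shared, %d weak background; conservation %.2f\n",
              nrow(x$planted_specific), x$strains[2], nrow(x$planted_shared),
              nrow(x$planted_background), x$conservation_frac))
  invisible(x)
}

#' Simulate, normalize and score one strain of a screen
#'
#' Convenience wrapper: generates plates for `strain` under a
#' `screen_truth`, runs surface and border correction, computes S-scores
#' and quantile-normalizes them. A `seed_offset` shifts the replicate-noise
#' stream, giving independent experimental batches of the same underlying
#' truth.
#'
#' @param st a `screen_truth` from [simulate_screen()].
#' @param strain strain to screen.
#' @param n_replicates replicates per condition (default 4).
#' @param batch batch label stamped on the plates.
#' @param seed_offset added to the truth seed for the noise stream.
#' @param split_duplicates forwarded to [compute_sscores()].
#' @return a quantile-normalized `score_matrix`.
#' @export
score_simulated_strain <- function(st, strain, n_replicates = 4L, batch = 1L,
                                   seed_offset = 0L, split_duplicates = FALSE) {
  stopifnot(inherits(st, "screen_truth"))
  truth <- st$truth
  truth$seed <- truth$seed + as.integer(seed_offset)
  plates <- gen_plates(st$layout, truth, st$conditions,
                       n_replicates = n_replicates, n_batches = 1L,
                       strain = strain)
  plates <- lapply(plates, function(p) { p$batch <- as.integer(batch); p })
  plates <- lapply(plates, normalize_plate)
  quantile_normalize(compute_sscores(plates, st$layout,
                                     split_duplicates = split_duplicates))
}
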