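#' Probability that a missense variant is neutral, from its SIFT score
#'
#' Logistic calibration of SIFT scores to the probability that the variant
#' leaves gene function intact, with constants fitted elsewhere on variants
#' of known impact:
#'
#'   P_neutral = 1 / (1 + exp(-z)),  z = 1.312 * ln(SIFT + 1.598e-5) + 4.104
#'
#' Tolerated variants (SIFT near 1) map to high neutrality (about 0.984 at
#' SIFT = 1), deleterious ones (SIFT near 0) to low. The printed form of
#' the calibration leaves the exponent's sign typographically ambiguous;
#' the default resolves it by the biological monotonicity requirement
#' (P_neutral increasing in SIFT). `literal_sign = TRUE` flips the sign to
#' the literal alternative reading.
#'
#' @param sift SIFT score(s) in \[0, 1\].
#' @param literal_sign use the opposite (decreasing) sign reading.
#' @return P_neutral in (0, 1), vectorized.
#' @export
pneutral_sift <- function(sift, literal_sign = FALSE) {
  if (any(!is.finite(sift)) || any(sift < 0 | sift > 1)) {
    abort_input("SIFT scores must lie in [0, 1]")
  }
  s <- if (literal_sign) -1 else 1
  stats::plogis(s * 1.312 * log(sift + 1.598e-5) + 4.104)
}

#' Probability that a missense variant is neutral, from its FoldX ddG
#'
#' Logistic calibration of FoldX stability predictions (ddG, kcal/mol):
#'
#'   P_neutral = 1 / (1 + exp(-z)),  z = -0.218 * ddG + 0.074
#'
#' Destabilizing variants (large positive ddG) get low neutrality; at
#' ddG = 0, P_neutral is about 0.519. As with [pneutral_sift()], the
#' default sign is fixed by monotonicity (P_neutral decreasing in ddG) and
#' `literal_sign = TRUE` gives the alternative reading.
#'
#' @param ddg FoldX ddG value(s) in kcal/mol.
#' @param literal_sign use the opposite (increasing) sign reading.
#' @return P_neutral in (0, 1), vectorized.
#' @export
pneutral_foldx <- function(ddg, literal_sign = FALSE) {
  if (any(!is.finite(ddg))) abort_input("FoldX ddG must be finite")
  s <- if (literal_sign) 1 else -1
  stats::plogis(s * 0.218 * ddg + 0.074)
}

#' Probability that a nonsense variant is neutral, from its position
#'
#' Premature stops near the end of the protein usually spare function:
#' P_neutral is 0.99 when the variant falls in the last 5% of the protein
#' sequence (relative position strictly greater than 0.95) and 0.01
#' otherwise.
#'
#' @param rel_pos relative position(s) in the protein, in (0, 1].
#' @return 0.99 or 0.01, vectorized.
#' @export
pneutral_nonsense <- function(rel_pos) {
  if (any(!is.finite(rel_pos)) || any(rel_pos <= 0 | rel_pos > 1)) {
    abort_input("relative positions must lie in (0, 1]")
  }
  ifelse(rel_pos > 0.95, 0.99, 0.01)
}

#' Gene disruption score P(AF) for one gene in one strain
#'
#' Combines a gene's variants into the probability that its function is
#' affected:
#'
#'   P(AF) = 1 - prod_i P_neutral(i)
#'
#' over its k missense and nonsense variants. Per missense variant, the
#' SIFT calibration is used when a SIFT score is available (SIFT takes
#' priority over FoldX), else the FoldX calibration, else
#' `fallback_pneutral` — conventionally the highest P_neutral observed
#' across the scored dataset (see [max_observed_pneutral()]). Nonsense
#' variants use the positional rule. A gene recorded as absent gets
#' P(AF) = 0.99 outright. The digitized score is 1 when P(AF) > 0.9.
#'
#' @param variants data frame of one gene/strain's variants with columns
#'   `kind` (`"missense"`, `"nonsense"`, `"absence"`; other kinds ignored),
#'   `sift`, `foldx`, `rel_pos` (`NA` when not applicable). Zero rows give
#'   P(AF) = 0.
#' @param fallback_pneutral P_neutral for missense variants with neither
#'   predictor.
#' @param gene,strain identifiers carried through to the record.
#' @param literal_sign passed to the logistic calibrations.
#' @return a list of class `disruption_record`: `strain`, `gene`,
#'   `p_neutral_list`, `p_af`, `digitized`.
#' @export
gene_disruption <- function(variants, fallback_pneutral = 0.99,
                            gene = NULL, strain = NULL,
                            literal_sign = FALSE) {
  if (is.null(gene)) gene <- if (nrow(variants)) variants$gene[1] else NA_character_
  if (is.null(strain)) strain <- if (nrow(variants) && "strain" %in% names(variants))
    variants$strain[1] else NA_character_
  if (nrow(variants)) {
    if ("gene" %in% names(variants) && length(unique(variants$gene)) > 1L) {
      abort_input("all variants must belong to one gene")
    }
    if ("strain" %in% names(variants) && length(unique(variants$strain)) > 1L) {
      abort_input("all variants must belong to one strain")
    }
  }
  make_record <- function(p_neutral, p_af) {
    structure(list(strain = strain, gene = gene,
                   p_neutral_list = p_neutral, p_af = p_af,
                   digitized = digitize_paf(p_af)),
              class = "disruption_record")
  }
  if (!nrow(variants)) return(make_record(numeric(0), 0))
  if (any(variants$kind == "absence")) {
    return(make_record(numeric(0), 0.99))
  }
  pn <- numeric(0)
  for (i in seq_len(nrow(variants))) {
    k <- variants$kind[i]
    if (k == "missense") {
      pn <- c(pn, if (!is.na(variants$sift[i])) {
        pneutral_sift(variants$sift[i], literal_sign)
      } else if (!is.na(variants$foldx[i])) {
        pneutral_foldx(variants$foldx[i], literal_sign)
      } else fallback_pneutral)
    } else if (k == "nonsense") {
      pn <- c(pn, pneutral_nonsense(variants$rel_pos[i]))
    }
  }
  make_record(pn, 1 - prod(pn))
}

#' Digitize a gene disruption score
#'
#' @param p_af P(AF) value(s) in \[0, 1\].
#' @return 1 when P(AF) > 0.9, else 0.
#' @export
digitize_paf <- function(p_af) {
  if (any(p_af < 0 | p_af > 1, na.rm = TRUE)) abort_input("P(AF) must lie in [0, 1]")
  as.integer(p_af > 0.9)
}

#' @export
print.disruption_record <- function(x, ...) {
  cat(sprintf("<disruption_record> %s / %s: P(AF) = %.4g (%d variants), digitized %d\n",
              x$strain, x$gene, x$p_af, length(x$p_neutral_list), x$digitized))
  invisible(x)
}

#' Highest observed P_neutral across scored missense variants
#'
#' The conventional fallback for missense variants lacking both SIFT and
#' FoldX predictions: the dataset-wide maximum P_neutral among variants
#' that could be scored.
#'
#' @param variants data frame with `kind`, `sift`, `foldx` columns.
#' @param literal_sign passed to the calibrations.
#' @return a single probability; 0.99 when nothing is scorable.
#' @export
max_observed_pneutral <- function(variants, literal_sign = FALSE) {
  mis <- variants[variants$kind == "missense", , drop = FALSE]
  vals <- c(
    if (any(!is.na(mis$sift))) pneutral_sift(mis$sift[!is.na(mis$sift)], literal_sign),
    if (any(is.na(mis$sift) & !is.na(mis$foldx))) {
      pneutral_foldx(mis$foldx[is.na(mis$sift) & !is.na(mis$foldx)], literal_sign)
    })
  if (!length(vals)) 0.99 else max(vals)
}

#' Gene disruption scores for a whole strain panel
#'
#' Applies [gene_disruption()] to every (strain, gene) with variant or
#' absence evidence, using the dataset-wide maximum observed P_neutral as
#' the fallback for unscorable missense variants.
#'
#' @param records long variant table as produced by
#'   [panel_variant_records()]: `strain`, `gene`, `kind`, `sift`, `foldx`,
#'   `rel_pos`.
#' @param literal_sign passed to the calibrations.
#' @return data frame: `strain`, `gene`, `p_af`, `digitized`.
#' @export
disruption_table <- function(records, literal_sign = FALSE) {
  fallback <- max_observed_pneutral(records, literal_sign)
  sp <- split(records, paste(records$strain, records$gene, sep = "\r"))
  rows <- lapply(sp, function(v) {
    rec <- gene_disruption(v, fallback_pneutral = fallback,
                           literal_sign = literal_sign)
    data.frame(strain = rec$strain, gene = rec$gene, p_af = rec$p_af,
               digitized = rec$digitized, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strain, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minor-allele-frequency filter for biallelic variants
#'
#' Retains common variants: minor allele frequency at least `maf_min`
#' (default 5%) among non-missing calls. Monomorphic variants drop out
#' silently (their MAF is 0).
#'
#' @param genotypes variants x strains matrix with 0/1 calls (`NA`
#'   allowed).
#' @param maf_min threshold (default 0.05).
#' @param strict require MAF strictly greater than `maf_min` instead of at
#'   least.
#' @return the filtered genotype matrix.
#' @export
maf_filter <- function(genotypes, maf_min = 0.05, strict = FALSE) {
  if (!is.matrix(genotypes)) abort_input("`genotypes` must be a matrix")
  bad <- !(genotypes %in% c(0L, 1L, NA))
  if (any(bad)) abort_input("genotypes must be biallelic 0/1 calls")
  f <- rowMeans(genotypes, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  keep <- if (strict) maf > maf_min else maf >= maf_min
  keep[is.na(keep)] <- FALSE
  genotypes[keep, , drop = FALSE]
}

#' Unified feature matrix for association
#'
#' Stacks common-variant genotypes, copy-number counts, gene
#' presence/absence patterns and digitized gene-disruption scores into one
#' features x strains matrix, each row labeled by its feature type, ready
#' for an external association engine.
#'
#' @param snps variants x strains 0/1 matrix (after [maf_filter()]).
#' @param cnv genes x strains integer copy-number matrix (optional).
#' @param presence genes x strains 0/1 presence matrix (optional).
#' @param burden genes x strains 0/1 digitized disruption matrix
#'   (optional).
#' @return list with `matrix` (features x strains) and `features` (data
#'   frame: `feature`, `type`, `source`).
#' @export
encode_features <- function(snps, cnv = NULL, presence = NULL, burden = NULL) {
  blocks <- list(snp = snps, cnv = cnv, pav = presence, burden = burden)
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) abort_input("no feature blocks supplied")
  strains <- colnames(blocks[[1]])
  for (nm in names(blocks)) {
    if (!identical(colnames(blocks[[nm]]), strains)) {
      abort_input("strain universe mismatch in block '%s'", nm)
    }
  }
  if (!is.null(burden) && !all(burden %in% c(0L, 1L, NA))) {
    abort_input("digitized burden values must be 0/1")
  }
  mats <- lapply(names(blocks), function(nm) {
    m <- blocks[[nm]]
    rownames(m) <- paste(nm, rownames(m), sep = ":")
    m
  })
  full <- do.call(rbind, mats)
  info <- data.frame(
    feature = rownames(full),
    type = rep(names(blocks), vapply(blocks, nrow, integer(1))),
    source = unlist(lapply(blocks, rownames), use.names = FALSE),
    stringsAsFactors = FALSE)
  list(matrix = full, features = info)
}
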