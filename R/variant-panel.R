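#' Simulate a natural-isolate variant panel with a known causal gene
#'
#' Generates, for a panel of strains, the inputs the loss-of-function burden
#' and association-overlap stages consume: a per-strain variant table
#' (missense records with SIFT scores and FoldX ddG values, nonsense records
#' with relative protein positions, gene absence flags), a biallelic
#' variant x strain genotype matrix, gene presence/absence and copy-number
#' tables, gene coordinates on a synthetic chromosome, a quantitative
#' phenotype driven additively by the causal gene's damaging variants, and a
#' per-variant association table. Association P-values come from a Welch
#' two-group location test per variant on the synthetic phenotype — simple
#' plumbing standing in for a mixed-model association scan, which this
#' package consumes but does not compute.
#'
#' @param n_strains number of strains (>= 2); defaults to a panel of 925,
#'   the size of large published yeast isolate collections.
#' @param n_genes number of genes.
#' @param causal_gene gene whose damaging-variant burden drives the
#'   phenotype; must be among the `n_genes` genes.
#' @param effect_size additive phenotype shift per unit of causal burden;
#'   0 yields a null panel with uniform association P-values.
#' @param mean_variants_per_gene Poisson mean of segregating coding variants
#'   per gene.
#' @param absence_rate per-strain probability that a non-causal gene is
#'   absent; the causal gene is absent at twice this rate.
#' @param seed integer seed; the same seed yields identical tables.
#' @return a list of class `variant_panel` with elements `strains`,
#'   `variants` (site table: `variant_id`, `gene`, `kind`, `chrom`,
#'   `position`, `sift`, `foldx`, `rel_pos`, `af`), `genotypes`
#'   (variants x strains 0/1 matrix), `presence` and `cnv`
#'   (genes x strains), `genes` (coordinate table: `chrom`, `start`, `end`,
#'   `gene`, 1-based inclusive), `phenotype` (named numeric per strain),
#'   `assoc` (per-variant `chrom`, `position`, `condition`, `p`) and
#'   `causal_gene`.
#' @export
gen_variant_panel <- function(n_strains = 925L, n_genes = 100L,
                              causal_gene = "g0001", effect_size = 1,
                              mean_variants_per_gene = 1.5,
                              absence_rate = 0.01, seed = 1L) {
  n_strains <- as.integer(n_strains); n_genes <- as.integer(n_genes)
  if (n_strains < 2L) abort_input("need at least 2 strains, got %d", n_strains)
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (!causal_gene %in% genes) {
    abort_input("causal gene %s not among the %d simulated genes", causal_gene, n_genes)
  }
  strains <- sprintf("s%04d", seq_len(n_strains))

  # gene bodies: 1.5 kb genes every 4 kb on one synthetic chromosome
  gene_start <- 1L + (seq_len(n_genes) - 1L) * 4000L
  genes_bed <- data.frame(chrom = "chrS", start = gene_start,
                          end = gene_start + 1499L, gene = genes,
                          stringsAsFactors = FALSE)

  set.seed(derive_seed(seed, "panel", n_strains, n_genes))
  n_var <- stats::rpois(n_genes, mean_variants_per_gene) + 1L
  gene_of <- rep(genes, n_var)
  total <- sum(n_var)
  kind <- sample(c("missense", "nonsense", "snp"), total, replace = TRUE,
                 prob = c(0.55, 0.15, 0.30))
  rel_in_gene <- stats::runif(total)
  position <- gene_start[match(gene_of, genes)] +
    as.integer(floor(rel_in_gene * 1500))

  sift <- ifelse(kind == "missense", stats::runif(total), NA_real_)
  # a fifth of missense sites lack a SIFT prediction, falling back to FoldX
  drop_sift <- kind == "missense" & stats::runif(total) < 0.20
  sift[drop_sift] <- NA_real_
  foldx <- ifelse(kind == "missense", stats::rnorm(total, 1.5, 2.0), NA_real_)
  # a few missense sites have neither predictor
  drop_both <- kind == "missense" & stats::runif(total) < 0.10
  sift[drop_both] <- NA_real_; foldx[drop_both] <- NA_real_
  rel_pos <- ifelse(kind == "nonsense", rel_in_gene, NA_real_)
  rel_pos[kind == "nonsense" & rel_pos == 0] <- 1e-3

  # site frequency spectrum skewed toward rare alleles
  freq <- stats::rbeta(total, 0.8, 3)
  genotypes <- matrix(stats::rbinom(total * n_strains, 1L,
                                    rep(freq, n_strains)),
                      nrow = total, ncol = n_strains,
                      dimnames = list(sprintf("v%05d", seq_len(total)), strains))
  af <- rowMeans(genotypes)

  variants <- data.frame(
    variant_id = rownames(genotypes), gene = gene_of, kind = kind,
    chrom = "chrS", position = position, sift = sift, foldx = foldx,
    rel_pos = rel_pos, af = af, stringsAsFactors = FALSE)

  presence <- matrix(1L, n_genes, n_strains, dimnames = list(genes, strains))
  p_abs <- rep(absence_rate, n_genes)
  p_abs[genes == causal_gene] <- 2 * absence_rate
  presence[stats::runif(n_genes * n_strains) < rep(p_abs, n_strains)] <- 0L
  cnv <- matrix(1L + stats::rbinom(n_genes * n_strains, 1L, 0.02),
                n_genes, n_strains, dimnames = list(genes, strains))

  # causal burden: carrying any damaging (missense/nonsense) causal-gene
  # variant, or lacking the gene entirely
  damaging <- variants$gene == causal_gene & variants$kind %in% c("missense", "nonsense")
  carrier <- if (any(damaging)) {
    as.integer(colSums(genotypes[damaging, , drop = FALSE]) > 0)
  } else rep(0L, n_strains)
  burden <- pmax(carrier, 1L - presence[causal_gene, ])
  phenotype <- stats::setNames(
    effect_size * burden + stats::rnorm(n_strains, 0, 1), strains)

  assoc <- data.frame(
    variant_id = variants$variant_id, chrom = variants$chrom,
    position = variants$position, condition = "growth",
    p = vapply(seq_len(total), function(i) {
      g <- genotypes[i, ]
      if (sum(g == 1L) < 2L || sum(g == 0L) < 2L) return(1)
      stats::t.test(phenotype[g == 1L], phenotype[g == 0L])$p.value
    }, numeric(1)),
    stringsAsFactors = FALSE)

  structure(
    list(strains = strains, variants = variants, genotypes = genotypes,
         presence = presence, cnv = cnv, genes = genes_bed,
         phenotype = phenotype, assoc = assoc, causal_gene = causal_gene,
         effect_size = effect_size, seed = as.integer(seed)),
    class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("<variant_panel> %d strains, %d genes, %d variants; causal gene %s (effect %g)\n",
              length(x$strains), nrow(x$presence), nrow(x$variants),
              x$causal_gene, x$effect_size))
  invisible(x)
}

#' Per-strain variant records for burden scoring
#'
#' Expands a `variant_panel` into the long table [gene_disruption()]
#' consumes: one row per (strain, gene, variant) for carried missense and
#' nonsense variants, plus one `absence` row per missing gene.
#'
#' @param panel a `variant_panel`.
#' @return data frame with columns `strain`, `gene`, `kind`, `sift`,
#'   `foldx`, `rel_pos`.
#' @export
panel_variant_records <- function(panel) {
  stopifnot(inherits(panel, "variant_panel"))
  coding <- panel$variants$kind %in% c("missense", "nonsense")
  gt <- panel$genotypes[coding, , drop = FALSE]
  vv <- panel$variants[coding, , drop = FALSE]
  hit <- which(gt == 1L, arr.ind = TRUE)
  rec <- data.frame(
    strain = colnames(gt)[hit[, 2]], gene = vv$gene[hit[, 1]],
    kind = vv$kind[hit[, 1]], sift = vv$sift[hit[, 1]],
    foldx = vv$foldx[hit[, 1]], rel_pos = vv$rel_pos[hit[, 1]],
    stringsAsFactors = FALSE)
  absent <- which(panel$presence == 0L, arr.ind = TRUE)
  if (nrow(absent)) {
    rec <- rbind(rec, data.frame(
      strain = colnames(panel$presence)[absent[, 2]],
      gene = rownames(panel$presence)[absent[, 1]],
      kind = "absence", sift = NA_real_, foldx = NA_real_,
      rel_pos = NA_real_, stringsAsFactors = FALSE))
  }
  rec[order(rec$strain, rec$gene), , drop = FALSE]
}
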