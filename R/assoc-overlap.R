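#' Overlap association hits with KO deletion phenotypes
#'
#' Intersects significant association variants with genes whose deletion
#' shows a phenotype in the same condition. A variant overlaps a gene when
#' its position falls within a `window_bp`-wide window centred on the gene
#' midpoint (default 3 kbp total width) or, optionally, anywhere inside the
#' gene body — so long genes are never excluded. An overlap record is
#' emitted when the gene has a significant KO phenotype (`call != "none"`)
#' in the hit's condition in at least one strain; the supporting strains
#' are reported.
#'
#' @param hits association table: `chrom`, `position` (1-based bp),
#'   `condition`, `p` (plus any id columns). Only rows with
#'   `p < p_threshold` are considered hits.
#' @param genes gene coordinates: `chrom`, `start`, `end` (1-based
#'   inclusive), `gene`.
#' @param ko_calls `phenotype_calls` rows (any number of strains).
#' @param window_bp total window width centred on the gene midpoint
#'   (default 3000).
#' @param p_threshold association significance threshold (default 1e-6).
#' @param include_gene_body also count variants inside the gene body but
#'   outside the window (default TRUE).
#' @return data frame: `chrom`, `position`, `condition`, `p`, `gene`,
#'   `n_strains`, `strains` (comma-separated). Hits on chromosomes absent
#'   from `genes` are skipped with a warning.
#' @export
window_overlap <- function(hits, genes, ko_calls, window_bp = 3000,
                           p_threshold = 1e-6, include_gene_body = TRUE) {
  need <- c("chrom", "position", "condition", "p")
  if (!all(need %in% names(hits))) {
    abort_input("hits need columns: %s", paste(need, collapse = ", "))
  }
  sig <- hits[hits$p < p_threshold, , drop = FALSE]
  if (!nrow(sig)) return(empty_overlap())
  unknown <- !(sig$chrom %in% genes$chrom)
  if (any(unknown)) {
    warning(sprintf("%d hit(s) on chromosomes without gene annotation skipped",
                    sum(unknown)))
    sig <- sig[!unknown, , drop = FALSE]
  }
  if (!nrow(sig)) return(empty_overlap())

  pheno <- ko_calls[ko_calls$call != "none", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(sig))) {
    g <- hit_genes(sig$position[i], sig$chrom[i], genes, window_bp,
                   include_gene_body)
    if (!length(g)) next
    for (gene in g) {
      sup <- pheno$strain[pheno$gene == gene & pheno$condition == sig$condition[i]]
      sup <- unique(sup)
      if (!length(sup)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = sig$chrom[i], position = sig$position[i],
        condition = sig$condition[i], p = sig$p[i], gene = gene,
        n_strains = length(sup), strains = paste(sort(sup), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_overlap())
  do.call(rbind, out)
}

empty_overlap <- function() {
  data.frame(chrom = character(0), position = numeric(0),
             condition = character(0), p = numeric(0), gene = character(0),
             n_strains = integer(0), strains = character(0),
             stringsAsFactors = FALSE)
}

# genes whose window (and optionally body) covers the position
hit_genes <- function(position, chrom, genes, window_bp, include_gene_body) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  mid <- (g$start + g$end) / 2
  in_window <- abs(position - mid) <= window_bp / 2
  in_body <- include_gene_body & position >= g$start & position <= g$end
  g$gene[in_window | in_body]
}

#' Enrichment of KO phenotypes among association-hit genes
#'
#' Cross-classifies the gene universe by "linked to an association hit"
#' (within the window of any significant variant, phenotype or not) and
#' "has a significant KO phenotype in any strain/condition", then applies
#' the two-sided Fisher exact test to the 2x2 table.
#'
#' @param hits,genes,ko_calls,window_bp,p_threshold,include_gene_body as in
#'   [window_overlap()].
#' @param universe gene identifiers defining the universe; defaults to all
#'   genes in `genes`.
#' @return list of class `enrichment_result`: `table` (2x2), `odds_ratio`
#'   (conditional MLE; `Inf` for perfectly nested sets), `p`, `computed`.
#'   When a margin is empty the test is not computed (`computed = FALSE`,
#'   `p` and `odds_ratio` `NA`) rather than an error.
#' @export
enrichment_test <- function(hits, genes, ko_calls, universe = genes$gene,
                            window_bp = 3000, p_threshold = 1e-6,
                            include_gene_body = TRUE) {
  sig <- hits[hits$p < p_threshold & hits$chrom %in% genes$chrom, , drop = FALSE]
  linked <- character(0)
  for (i in seq_len(nrow(sig))) {
    linked <- c(linked, hit_genes(sig$position[i], sig$chrom[i], genes,
                                  window_bp, include_gene_body))
  }
  linked <- unique(linked)
  pheno_genes <- unique(ko_calls$gene[ko_calls$call != "none"])
  is_linked <- universe %in% linked
  has_pheno <- universe %in% pheno_genes
  tab <- table(factor(is_linked, c(TRUE, FALSE), c("linked", "not_linked")),
               factor(has_pheno, c(TRUE, FALSE), c("phenotype", "no_phenotype")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(table = tab, odds_ratio = NA_real_, p = NA_real_,
                          computed = FALSE),
                     class = "enrichment_result"))
  }
  ft <- stats::fisher.test(tab)
  structure(list(table = tab, odds_ratio = unname(ft$estimate),
                 p = ft$p.value, computed = TRUE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (!x$computed) {
    cat("<enrichment_result> not computed (empty margin)\n")
  } else {
    cat(sprintf("<enrichment_result> odds ratio %.3g, Fisher exact p = %.3g\n",
                x$odds_ratio, x$p))
  }
  print(x$table)
  invisible(x)
}

#' Fisher's exact test on a plain 2x2 table
#'
#' Thin wrapper used by the enrichment report when the table is already
#' built; two-sided.
#'
#' @param tab 2x2 matrix of counts.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}
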