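# eSNP gene-set enrichment: flag genes whose eQTL SNPs carry a significant
# disease association, build the target-vs-universe 2x2 table, Fisher exact.

#' Flag genes with a significantly disease-associated eSNP
#'
#' A gene is flagged when at least one SNP that is an eQTL for it has
#' association `p < threshold`.  Genes with no eQTL SNP are unflagged.
#'
#' @param genes character vector of gene symbols to evaluate.
#' @param eqtl data frame mapping snp -> gene.
#' @param results association/meta results with columns snp, p.
#' @param threshold significance threshold (the block-based Bonferroni
#'   level of the main analysis).
#' @return character vector: the flagged subset of `genes`.
#' @export
flag_genes <- function(genes, eqtl, results, threshold) {
  p <- results$p[match(eqtl$snp, results$snp)]
  hot <- unique(eqtl$gene[!is.na(p) & p < threshold])
  intersect(genes, hot)
}

#' Build the target-vs-background contingency table
#'
#' The background universe is the union of the pathway gene sets with the
#' target genes excluded (disjoint 2x2); `overlap_mode = "inclusive"` keeps
#' target genes in the background instead.
#'
#' @param targets character vector of target gene symbols.
#' @param universe character vector (or GMT list) of background gene
#'   symbols.
#' @param flagged character vector of flagged genes (any superset).
#' @param overlap_mode "disjoint" (default) or "inclusive".
#' @return object of class `contingency_table`: list(a, b, c, d) with
#'   a = flagged targets, b = unflagged targets, c = flagged background,
#'   d = unflagged background.
#' @export
build_table <- function(targets, universe, flagged,
                        overlap_mode = c("disjoint", "inclusive")) {
  overlap_mode <- match.arg(overlap_mode)
  if (is.list(universe)) universe <- unique(unlist(universe))
  universe <- unique(universe)
  targets <- unique(targets)
  background <- if (overlap_mode == "disjoint") setdiff(universe, targets)
                else universe
  if (!length(background)) stop("empty background universe", call. = FALSE)
  a <- sum(targets %in% flagged)
  c_ <- sum(background %in% flagged)
  structure(list(a = a, b = length(targets) - a,
                 c = c_, d = length(background) - c_,
                 overlap_mode = overlap_mode),
            class = "contingency_table")
}

#' One-sided Fisher exact test for enrichment
#'
#' Upper-tail hypergeometric probability `P(X >= a)` with population
#' `N = a+b+c+d`, `K = a+c` flagged genes and `n = a+b` draws (the target
#' set); alternative: target rate greater than background rate.  The odds
#' ratio is `ad/bc` (infinite when `bc = 0`).
#'
#' @param table a `contingency_table`, or numeric `c(a, b, c, d)`.
#' @return object of class `enrichment_result`: list(table, odds_ratio, p).
#' @export
fisher_one_sided <- function(table) {
  tt <- if (inherits(table, "contingency_table")) table
        else as.list(setNames(as.numeric(table), c("a", "b", "c", "d")))
  a <- tt$a; b <- tt$b; cc <- tt$c; d <- tt$d
  if (any(c(a, b, cc, d) < 0)) stop("negative cell count", call. = FALSE)
  p <- phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  structure(list(table = tt, odds_ratio = or, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("eSNP enrichment: ", x$table$a, "/", x$table$a + x$table$b,
      " target genes vs ", x$table$c, "/", x$table$c + x$table$d,
      " background genes flagged\n  one-sided Fisher exact p = ",
      format(x$p, digits = 3), ", OR = ", format(x$odds_ratio, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' End-to-end enrichment test
#'
#' Flags target and background genes from the eQTL table and association
#' results, builds the 2x2 table against the pathway universe and applies
#' the one-sided Fisher exact test.
#'
#' @param targets target gene symbols.
#' @param gmt pathway gene sets (named list, e.g. from [read_gmt()]).
#' @param eqtl snp -> gene eQTL table.
#' @param results association/meta results (snp, p).
#' @param threshold significance threshold for the eSNP flag.
#' @param overlap_mode passed to [build_table()].
#' @return an `enrichment_result` with `flagged_targets` attached.
#' @export
enrichment_test <- function(targets, gmt, eqtl, results, threshold,
                            overlap_mode = "disjoint") {
  universe <- unique(unlist(gmt))
  all_genes <- unique(c(targets, universe))
  flagged <- flag_genes(all_genes, eqtl, results, threshold)
  tab <- build_table(targets, universe, flagged, overlap_mode = overlap_mode)
  res <- fisher_one_sided(tab)
  res$flagged_targets <- intersect(targets, flagged)
  res
}
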