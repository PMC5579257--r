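#' Map a drug-gene interaction table onto gene coordinates
#'
#' Intersects the genes named in an interaction table with a gene BED and
#' returns one record per distinct mappable gene.  Genes listed in the
#' interaction table but absent from the BED are returned in `unmapped`,
#' never silently dropped.
#'
#' @param interactions data frame (or TSV path) with columns `drug`, `gene`,
#'   `interaction`.
#' @param genes data frame (or BED path) of gene coordinates as returned by
#'   [read_bed()]; duplicate symbols are an error.
#' @return list with `genes` (data frame symbol, chrom, start, end) and
#'   `unmapped` (character vector of symbols without coordinates).
#' @export
load_targets <- function(interactions, genes) {
  if (is.character(interactions)) interactions <- read_tsv(interactions)
  if (is.character(genes)) genes <- read_bed(genes)
  need <- c("drug", "gene", "interaction")
  miss <- setdiff(need, names(interactions))
  if (length(miss))
    stop("interaction table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(genes$symbol))
    stop("duplicate gene symbol(s) in coordinate table: ",
         paste(unique(genes$symbol[duplicated(genes$symbol)]), collapse = ", "),
         call. = FALSE)
  want <- unique(interactions$gene)
  want <- want[nzchar(want)]
  hit <- genes[match(intersect(want, genes$symbol), genes$symbol), , drop = FALSE]
  unmapped <- setdiff(want, genes$symbol)
  if (nrow(hit) == 0L)
    stop("no interaction gene has coordinates", call. = FALSE)
  rownames(hit) <- NULL
  list(genes = hit[, c("symbol", "chrom", "start", "end")], unmapped = unmapped)
}

#' Build flanked test windows around target genes
#'
#' One window per gene: `[max(0, start - flank), end + flank)`, 0-based
#' half-open.  Windows may overlap; no merging is performed.
#'
#' @param genes data frame with columns symbol, chrom, start, end.
#' @param flank flank in bp added on each side (default 100 kb, i.e. a
#'   200-kb span added around the gene body).
#' @return data frame of regions (symbol, chrom, start, end, flank).
#' @export
build_windows <- function(genes, flank = 100000L) {
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  stopifnot(all(genes$start < genes$end))
  data.frame(symbol = genes$symbol, chrom = norm_chrom(genes$chrom),
             start = pmax(0, genes$start - flank),
             end = genes$end + flank,
             flank = flank, stringsAsFactors = FALSE)
}

#' Assign SNPs to regions
#'
#' A SNP belongs to every region whose half-open window `[start, end)`
#' contains its position; overlapping windows duplicate membership.
#'
#' @param regions data frame from [build_windows()].
#' @param snp_table data frame with columns id, chrom, pos.
#' @return the regions with a `members` list-column (character SNP ids) and
#'   an `n_snps` count; the distinct member total is in
#'   `attr(, "n_distinct")`.
#' @export
assign_snps <- function(regions, snp_table) {
  rc <- norm_chrom(regions$chrom)
  sc <- norm_chrom(snp_table$chrom)
  if (nrow(snp_table) > 0) {
    bad <- setdiff(unique(rc), unique(sc))
    if (length(bad))
      stop("chromosome name(s) in regions absent from SNP table: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  members <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- sc == rc[i] & snp_table$pos >= regions$start[i] &
      snp_table$pos < regions$end[i]
    snp_table$id[sel][order(snp_table$pos[sel])]
  })
  regions$members <- members
  regions$n_snps <- vapply(members, length, 1L)
  attr(regions, "n_distinct") <- length(unique(unlist(members)))
  regions
}
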