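# File formats: TSV, BED, GMT, VCF, summary statistics.  Chromosome-name
# normalization and the 1-based VCF -> 0-based internal conversion are
# centralized here; no other module touches raw files.

#' Read / write a plain TSV with header
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             quote = "", comment.char = "")
}

#' @rdname read_tsv
#' @param x data frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene BED file
#'
#' BED 0-based half-open, at least 4 columns (chrom, start, end, name).
#' Malformed lines raise a parse error naming the line number.
#'
#' @param path BED file path.
#' @return data frame: chrom, start, end, symbol.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  out <- vector("list", sum(keep))
  k <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L)
      stop("malformed BED line ", i, ": expected >= 4 fields, got ",
           length(f), call. = FALSE)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start >= end)
      stop("malformed BED line ", i, ": bad interval [", f[2], ", ", f[3],
           ")", call. = FALSE)
    k <- k + 1L
    out[[k]] <- data.frame(chrom = f[1], start = start, end = end,
                           symbol = f[4], stringsAsFactors = FALSE)
  }
  do.call(rbind, out[seq_len(k)])
}

#' @rdname read_bed
#' @param genes data frame with chrom, start, end, symbol.
#' @export
write_bed <- function(genes, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", genes$chrom, genes$start, genes$end,
                     genes$symbol), path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' @rdname read_gmt
#' @param gmt named list of gene sets.
#' @export
write_gmt <- function(gmt, path) {
  writeLines(vapply(names(gmt), function(n)
    paste(c(n, "synthetic", gmt[[n]]), collapse = "\t"), ""), path)
  invisible(path)
}

.sumstats_cols <- c("study", "snp", "chr", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "p", "n", "flag")

#' Read per-study association summary statistics
#'
#' The TSV dialect written by [write_summary_stats()]: mandatory columns
#' snp, effect_allele, other_allele, beta, se; optional study, chr, pos,
#' eaf, p, n, flag.  Alleles are upper-cased, chromosome names normalized,
#' and rows violating `se > 0` are rejected with their line numbers.
#'
#' @param path TSV path.
#' @return typed data frame; rejected rows in `attr(, "rejected")`.
#' @export
read_summary_stats <- function(path) {
  d <- read_tsv(path)
  mand <- c("snp", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(mand, names(d))
  if (length(miss))
    stop("summary statistics file lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d$effect_allele <- toupper(d$effect_allele)
  d$other_allele <- toupper(d$other_allele)
  if ("chr" %in% names(d)) d$chr <- norm_chrom(d$chr)
  for (num in intersect(c("pos", "eaf", "beta", "se", "p", "n"), names(d)))
    d[[num]] <- as.numeric(d[[num]])
  bad <- !is.finite(d$se) | d$se <= 0 | !is.finite(d$beta)
  if ("flag" %in% names(d)) bad <- bad & d$flag == "ok"
  rejected <- which(bad)
  if (length(rejected)) {
    message("rejected ", length(rejected), " row(s) with invalid se/beta ",
            "(data lines ", paste(rejected + 1L, collapse = ", "), ")")
    d <- d[!bad, , drop = FALSE]
  }
  rownames(d) <- NULL
  attr(d, "rejected") <- rejected
  d
}

#' @rdname read_summary_stats
#' @param x summary-statistics data frame.
#' @export
write_summary_stats <- function(x, path) {
  write_tsv(x[, intersect(.sumstats_cols, names(x)), drop = FALSE], path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Keeps biallelic SNVs only (others skipped and counted); "0/1", "1/0",
#' "0|1", "1|0" all map to dose 1 and "./." to missing.  When every record
#' is phased the phased haplotype matrix is returned too (panel mode).
#'
#' @param path VCF path (plain text).
#' @return list with `snps` (id, chrom, pos, ref, alt), `G` (n x M dose
#'   matrix), `H` (2n x M haplotype matrix or NULL), `phased`,
#'   `n_skipped`.
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(v)[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  snps <- data.frame(id = ids, chrom = norm_chrom(fix$CHROM),
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  clean <- gsub("\\|", "/", gt)
  if (any(!is.na(clean) & !clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")))
    stop("unsupported genotype encoding (mixed ploidy?)", call. = FALSE)
  dose <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), ids))
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)
  dose[] <- t(matrix(map[clean], nrow = nrow(gt)))
  phased <- nrow(gt) > 0 && all(grepl("|", gt[!is.na(gt)], fixed = TRUE))
  H <- NULL
  if (phased) {
    a1 <- substr(gt, 1, 1) == "1"
    a2 <- substr(gt, 3, 3) == "1"
    H <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt),
                dimnames = list(NULL, ids))
    H[seq(1, 2 * ncol(gt), by = 2), ] <- t(a1) * 1L
    H[seq(2, 2 * ncol(gt), by = 2), ] <- t(a2) * 1L
  }
  list(snps = snps, G = dose, H = H, phased = phased, n_skipped = n_skipped)
}

.vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write a phased haplotype panel to VCF
#'
#' Pairs consecutive haplotype rows into diploid samples with "|"-separated
#' phased genotypes.
#'
#' @param panel a `haplotype_panel`.
#' @param path output path.
#' @export
write_panel_vcf <- function(panel, path) {
  H <- panel$H
  if (nrow(H) %% 2L != 0L) stop("odd haplotype count", call. = FALSE)
  n <- nrow(H) %/% 2L
  samples <- sprintf("HAP%04d", seq_len(n))
  a1 <- H[seq(1, nrow(H), 2), , drop = FALSE]
  a2 <- H[seq(2, nrow(H), 2), , drop = FALSE]
  gtm <- matrix(paste0(a1, "|", a2), nrow = n)
  s <- panel$snps
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                   s$chrom, s$pos, s$id, s$ref, s$alt,
                   apply(gtm, 2, paste, collapse = "\t"))
  writeLines(c(.vcf_header(samples), lines), path)
  invisible(path)
}

#' Write a cohort's unphased genotypes to VCF (+ phenotype TSV)
#'
#' @param cohort a `study_cohort`.
#' @param snps SNP table (id, chrom, pos, ref, alt), typically
#'   `panel$snps`.
#' @param vcf_path,pheno_path output paths; the phenotype TSV (id, status,
#'   sex, age) is only written when `pheno_path` is given.
#' @export
write_cohort_vcf <- function(cohort, snps, vcf_path, pheno_path = NULL) {
  G <- cohort$G
  stopifnot(all(colnames(G) %in% snps$id))
  s <- snps[match(colnames(G), snps$id), ]
  code <- c("0/0", "0/1", "1/1")
  gtm <- matrix("./.", nrow = nrow(G), ncol = ncol(G))
  ok <- !is.na(G)
  gtm[ok] <- code[G[ok] + 1L]
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                   s$chrom, s$pos, s$id, s$ref, s$alt,
                   apply(gtm, 2, paste, collapse = "\t"))
  writeLines(c(.vcf_header(cohort$pheno$id), lines), vcf_path)
  if (!is.null(pheno_path)) write_tsv(cohort$pheno, pheno_path)
  invisible(vcf_path)
}
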