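#' Detect haplotype blocks from pairwise LD classifications
#'
#' Gabriel-style interval rule: a candidate block is a contiguous run of
#' SNPs `[i, j]` with span at most `params$max_span` whose outermost pair is
#' strong LD and in which at least `params$informative_fraction` of the
#' informative pairs (strong or recombination) are strong.  Candidates are
#' accepted greedily by decreasing SNP count (ties: leftmost first); an
#' accepted block removes its SNPs from further consideration.  SNPs in no
#' accepted block are singletons.
#'
#' @param snps data frame with columns id, pos (ascending) and optionally
#'   chrom.
#' @param cls classification matrix from [classify_window()].
#' @param params a [block_params()].
#' @return data frame of blocks: chrom, first, last (SNP indices), start,
#'   end (bp), n_snps, span, snps (list-column of ids); zero rows when no
#'   block is found.
#' @export
find_blocks <- function(snps, cls, params = block_params()) {
  m <- nrow(snps)
  stopifnot(nrow(cls) == m, ncol(cls) == m)
  if (is.unsorted(snps$pos)) stop("SNPs must be position-sorted", call. = FALSE)
  chrom <- if ("chrom" %in% names(snps)) snps$chrom[1] else NA_character_
  empty <- data.frame(chrom = character(), first = integer(), last = integer(),
                      start = integer(), end = integer(), n_snps = integer(),
                      span = integer(), stringsAsFactors = FALSE)
  empty$snps <- list()
  if (m < 2) return(empty)

  # 2-D prefix sums of the strong / informative pair indicators let the
  # within-interval fraction be read off in O(1) per candidate
  S <- (!is.na(cls) & cls == "strong_LD") * 1L
  I <- (!is.na(cls) & cls != "uninformative") * 1L
  S[lower.tri(S, diag = TRUE)] <- 0L
  I[lower.tri(I, diag = TRUE)] <- 0L
  PS <- apply(apply(S, 2, cumsum), 1, cumsum)  # PS[j, i] = sum S[1:i, 1:j]
  PI <- apply(apply(I, 2, cumsum), 1, cumsum)
  subsum <- function(P, i, j) {
    # sum over rows i..j, cols i..j of the (upper-triangular) indicator
    P[j, j] - (if (i > 1) P[j, i - 1] + P[i - 1, j] - P[i - 1, i - 1] else 0)
  }

  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (snps$pos[j] - snps$pos[i] > params$max_span) break
      if (is.na(cls[i, j]) || cls[i, j] != "strong_LD") next
      ni <- subsum(PI, i, j)
      ns <- subsum(PS, i, j)
      if (ni > 0 && ns / ni >= params$informative_fraction)
        cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  if (!length(cand)) return(empty)
  cm <- do.call(rbind, cand)
  ord <- order(-(cm[, 2] - cm[, 1]), cm[, 1])
  cm <- cm[ord, , drop = FALSE]
  used <- logical(m)
  keep <- logical(nrow(cm))
  for (k in seq_len(nrow(cm))) {
    rng <- seq(cm[k, 1], cm[k, 2])
    if (!any(used[rng])) { keep[k] <- TRUE; used[rng] <- TRUE }
  }
  acc <- cm[keep, , drop = FALSE]
  acc <- acc[order(acc[, 1]), , drop = FALSE]
  out <- data.frame(chrom = chrom, first = acc[, 1], last = acc[, 2],
                    start = snps$pos[acc[, 1]], end = snps$pos[acc[, 2]],
                    n_snps = acc[, 2] - acc[, 1] + 1L,
                    span = snps$pos[acc[, 2]] - snps$pos[acc[, 1]],
                    stringsAsFactors = FALSE)
  out$snps <- lapply(seq_len(nrow(acc)),
                     function(k) snps$id[seq(acc[k, 1], acc[k, 2])])
  out
}

#' Detect blocks over a set of region SNPs on a panel
#'
#' Convenience wrapper: restricts the panel to the given SNP ids (position
#' order, per chromosome), classifies pairs and runs [find_blocks()] per
#' contiguous region window.
#'
#' @param panel a `haplotype_panel`.
#' @param snp_ids distinct SNP ids to consider (default: all panel SNPs).
#' @param params a [block_params()].
#' @return block data frame as from [find_blocks()], concatenated over
#'   chromosomes.
#' @export
detect_blocks <- function(panel, snp_ids = NULL, params = block_params()) {
  snps <- panel$snps
  if (!is.null(snp_ids)) snps <- snps[snps$id %in% snp_ids, , drop = FALSE]
  res <- list()
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    H <- panel$H[, s$id, drop = FALSE]
    cls <- classify_window(H = H, pos = s$pos, params = params)
    res[[ch]] <- find_blocks(s, cls, params)
  }
  do.call(rbind, res)
}

#' Effective number of tests and Bonferroni threshold from a block count
#'
#' The number of haplotype blocks stands in for the number of independent
#' tests: `threshold = alpha_family / meff` with `meff` = block count by
#' default, optionally block count plus singleton SNPs.  With
#' `floor_pow10 = TRUE` the threshold is rounded down to the nearest power
#' of ten (e.g. 0.05 / 3131 = 1.6e-5 floors to 1e-5).
#'
#' @param blocks block data frame from [find_blocks()], or an integer block
#'   count.
#' @param M total number of SNPs tested.
#' @param alpha_family family-wise error rate (default 0.05).
#' @param floor_pow10 round the threshold down to a power of ten.
#' @param include_singletons count SNPs outside all blocks as extra
#'   independent tests.
#' @return object of class `eff_tests`: list(M, n_blocks, n_singletons,
#'   meff, alpha_family, threshold, floor_pow10, include_singletons).
#' @export
effective_tests <- function(blocks, M, alpha_family = 0.05,
                            floor_pow10 = FALSE, include_singletons = FALSE) {
  if (is.data.frame(blocks)) {
    n_blocks <- nrow(blocks)
    in_blocks <- sum(blocks$n_snps)
  } else {
    n_blocks <- as.integer(blocks)
    in_blocks <- NA_integer_
  }
  if (M < n_blocks) stop("M must be >= number of blocks", call. = FALSE)
  n_singletons <- if (is.na(in_blocks)) NA_integer_ else M - in_blocks
  meff <- n_blocks + if (include_singletons) {
    if (is.na(n_singletons))
      stop("singleton count unknown; pass the block data frame", call. = FALSE)
    n_singletons
  } else 0L
  if (meff == 0) stop("no tests: meff is zero", call. = FALSE)
  threshold <- alpha_family / meff
  if (floor_pow10) threshold <- 10^floor(log10(threshold))
  structure(list(M = M, n_blocks = n_blocks, n_singletons = n_singletons,
                 meff = meff, alpha_family = alpha_family,
                 threshold = threshold, floor_pow10 = floor_pow10,
                 include_singletons = include_singletons),
            class = "eff_tests")
}

#' @export
print.eff_tests <- function(x, ...) {
  cat("eff_tests: M =", x$M, "SNPs,", x$n_blocks, "blocks,",
      x$n_singletons, "singletons; meff =", x$meff,
      "-> threshold", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Spectral effective number of tests (Nyholt)
#'
#' `Meff = 1 + (M - 1) (1 - Var(lambda) / M)` where `lambda` are the
#' eigenvalues of the SNP correlation matrix and the variance uses
#' denominator `M - 1`; clipped to `[1, M]`.  Serves as the spectral
#' comparator to the block-count correction.
#'
#' @param R symmetric correlation matrix with unit diagonal, M >= 2.
#' @return effective number of independent tests (real).
#' @export
meff_nyholt <- function(R) {
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop("correlation matrix must be symmetric", call. = FALSE)
  M <- nrow(R)
  stopifnot(M >= 2)
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  meff <- 1 + (M - 1) * (1 - var(lambda) / M)
  min(max(meff, 1), M)
}
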