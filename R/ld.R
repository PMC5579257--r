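# Two-locus LD: haplotype counting (phased), EM frequency estimation
# (unphased), D'/r2 arithmetic and the grid-likelihood confidence bounds on
# |D'| that drive Gabriel-style pair classification.

#' Two-locus haplotype counts from phased haplotypes
#'
#' @param h_i,h_j 0/1 vectors over the same haplotypes (1 = alt allele).
#' @return named count vector (AB, Ab, aB, ab); "A"/"B" denote alt alleles.
#' @export
hap_counts <- function(h_i, h_j) {
  stopifnot(length(h_i) == length(h_j))
  c(AB = sum(h_i == 1 & h_j == 1), Ab = sum(h_i == 1 & h_j == 0),
    aB = sum(h_i == 0 & h_j == 1), ab = sum(h_i == 0 & h_j == 0))
}

#' D, D' and r-squared from two-locus haplotype frequencies
#'
#' `D = pAB - pA pB`; `D' = |D| / Dmax` with
#' `Dmax = min(pA(1-pB), (1-pA)pB)` for `D >= 0` and
#' `min(pA pB, (1-pA)(1-pB))` otherwise;
#' `r2 = D^2 / (pA(1-pA) pB(1-pB))`.
#'
#' @param freqs frequencies or counts in order (AB, Ab, aB, ab).
#' @return list with pA, pB, D, Dprime, r2.
#' @export
ld_stats <- function(freqs) {
  if (any(freqs < 0)) stop("negative frequency", call. = FALSE)
  f <- freqs / sum(freqs)
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("LD undefined: monomorphic locus", call. = FALSE)
  D <- f[1] - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(pA = unname(pA), pB = unname(pB), D = unname(D),
       Dprime = unname(if (Dmax == 0) 0 else abs(D) / Dmax),
       r2 = unname(D^2 / (pA * (1 - pA) * pB * (1 - pB))))
}

#' EM estimate of two-locus haplotype frequencies from unphased doses
#'
#' Starts at linkage equilibrium and iterates the classical E/M updates,
#' splitting double heterozygotes between the cis (AB/ab) and trans (Ab/aB)
#' phase in proportion to their current likelihood.  Converges when the
#' largest frequency change is below `tol` or after `max_iter` iterations.
#'
#' @param g_i,g_j integer dose vectors (0/1/2, NA = missing).
#' @param tol convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return named frequency vector (AB, Ab, aB, ab) summing to 1.
#' @export
two_locus_em <- function(g_i, g_j, tol = 1e-10, max_iter = 1000L) {
  stopifnot(length(g_i) == length(g_j))
  ok <- !is.na(g_i) & !is.na(g_j)
  if (!any(ok)) stop("all genotypes missing", call. = FALSE)
  g_i <- g_i[ok]; g_j <- g_j[ok]
  # monomorphic = one ALLELE fixed; all-heterozygous input is polymorphic
  if (all(g_i == 0L) || all(g_i == 2L) || all(g_j == 0L) || all(g_j == 2L))
    stop("LD undefined: monomorphic locus", call. = FALSE)
  n2 <- 2 * length(g_i)
  tab <- table(factor(g_i, 0:2), factor(g_j, 0:2))
  # unambiguous haplotype contributions of each genotype combination
  fixed <- c(
    AB = 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"],
    Ab = 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"],
    aB = 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"],
    ab = 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"])
  ndh <- tab["1", "1"]
  pA <- mean(g_i) / 2; pB <- mean(g_j) / 2
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  for (it in seq_len(max_iter)) {
    cis <- p["AB"] * p["ab"]; trans <- p["Ab"] * p["aB"]
    w <- if (cis + trans == 0) 0.5 else cis / (cis + trans)
    new <- (fixed + ndh * c(w, 1 - w, 1 - w, w)) / n2
    if (max(abs(new - p)) < tol) { p <- new; break }
    p <- new
  }
  names(p) <- c("AB", "Ab", "aB", "ab")
  p
}

#' Likelihood-based confidence bounds on |D'|
#'
#' Evaluates the multinomial likelihood of the observed two-locus haplotype
#' counts on a grid of |D'| in \[0, 1\] (allele frequencies fixed at their
#' observed values, D carrying the observed sign), normalizes it over the
#' grid, and returns `CL` = the largest grid value with at most 5% cumulative
#' mass strictly below it and `CU` = the smallest grid value with at least
#' 95% cumulative mass at or below it.
#'
#' @param counts haplotype counts (AB, Ab, aB, ab), positive total.
#' @param params a [block_params()].
#' @return numeric vector `c(CL, CU)`.
#' @export
dprime_ci <- function(counts, params = block_params()) {
  n <- sum(counts)
  if (n <= 0) stop("empty haplotype counts", call. = FALSE)
  f <- counts / n
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("LD undefined: monomorphic locus", call. = FALSE)
  D_obs <- f[1] - pA * pB
  Dmax <- if (D_obs >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  d <- seq(0, 1, by = params$dprime_grid_step)
  Dd <- (if (D_obs >= 0) 1 else -1) * d * Dmax
  pAB <- pmax(pA * pB + Dd, 1e-12)
  pAb <- pmax(pA * (1 - pB) - Dd, 1e-12)
  paB <- pmax((1 - pA) * pB - Dd, 1e-12)
  pab <- pmax((1 - pA) * (1 - pB) + Dd, 1e-12)
  ll <- counts[1] * log(pAB) + counts[2] * log(pAb) +
    counts[3] * log(paB) + counts[4] * log(pab)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cum <- cumsum(w)
  below <- c(0, cum[-length(cum)])           # mass strictly below each point
  CL <- d[max(which(below <= 0.05))]
  CU <- d[min(which(cum >= 0.95 - 1e-12))]
  c(CL = unname(CL), CU = unname(CU))
}

#' Parameters of the D'-confidence-interval block rule
#'
#' Defaults follow the Gabriel/Haploview convention that PLINK's `--blocks`
#' command adopts: a pair is in strong LD when the one-sided 90% bounds on
#' |D'| satisfy `CL >= 0.70` and `CU >= 0.98`, shows historical
#' recombination when `CU < 0.90`, and is otherwise uninformative; a
#' candidate block requires at least `informative_fraction` of its
#' informative pairs strong and spans at most `max_span` bp.
#'
#' @param strong_ci_low,strong_ci_high strong-LD bounds on (CL, CU).
#' @param recomb_ci_high recombination upper bound on CU.
#' @param informative_fraction minimum strong fraction among informative
#'   pairs inside a block.
#' @param pair_maf_min pairs with either MAF below this are uninformative.
#' @param max_span maximum block span in bp.
#' @param dprime_grid_step grid resolution of the |D'| likelihood.
#' @return object of class `block_params`.
#' @export
block_params <- function(strong_ci_low = 0.70, strong_ci_high = 0.98,
                         recomb_ci_high = 0.90, informative_fraction = 0.95,
                         pair_maf_min = 0.05, max_span = 200000L,
                         dprime_grid_step = 0.001) {
  stopifnot(strong_ci_low > 0, strong_ci_low < strong_ci_high,
            strong_ci_high <= 1, recomb_ci_high < strong_ci_high,
            informative_fraction > 0, informative_fraction <= 1)
  structure(as.list(environment()), class = "block_params")
}

#' Classify one SNP pair from its |D'| confidence bounds
#'
#' @param ci numeric `c(CL, CU)` from [dprime_ci()].
#' @param maf_i,maf_j minor-allele frequencies of the two SNPs.
#' @param params a [block_params()].
#' @return "strong_LD", "recombination" or "uninformative".
#' @export
classify_pair <- function(ci, maf_i, maf_j, params = block_params()) {
  if (maf_i < params$pair_maf_min || maf_j < params$pair_maf_min)
    return("uninformative")
  if (ci[1] >= params$strong_ci_low && ci[2] >= params$strong_ci_high)
    "strong_LD"
  else if (ci[2] < params$recomb_ci_high) "recombination"
  else "uninformative"
}

#' Pairwise LD classification matrix for a window of SNPs
#'
#' Computes, for every pair within `params$max_span`, the haplotype counts
#' (directly from phase when `H` is a phased haplotype matrix, by [two_locus_em()]
#' when `G` holds unphased doses), the |D'| confidence bounds, and the
#' Gabriel classification.
#'
#' @param H phased 0/1 haplotype matrix (columns = SNPs), or `NULL`.
#' @param G unphased dose matrix (columns = SNPs), used when `H` is `NULL`.
#' @param pos SNP positions (bp), ascending.
#' @param params a [block_params()].
#' @return m x m character matrix ("strong_LD"/"recombination"/
#'   "uninformative"/NA beyond max_span), upper and lower triangles filled
#'   symmetrically.
#' @export
classify_window <- function(H = NULL, G = NULL, pos, params = block_params()) {
  X <- if (!is.null(H)) H else G
  m <- ncol(X)
  stopifnot(length(pos) == m, !is.unsorted(pos))
  af <- if (!is.null(H)) colMeans(H) else colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  cls <- matrix(NA_character_, m, m)
  if (m < 2) return(cls)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (pos[j] - pos[i] > params$max_span) break
      if (maf[i] < params$pair_maf_min || maf[j] < params$pair_maf_min) {
        cls[i, j] <- cls[j, i] <- "uninformative"
        next
      }
      counts <- if (!is.null(H)) hap_counts(H[, i], H[, j])
      else {
        n <- sum(!is.na(G[, i]) & !is.na(G[, j]))
        round(two_locus_em(G[, i], G[, j]) * 2 * n)
      }
      cl <- if (sum(counts) == 0 || any(is.na(counts))) "uninformative"
      else classify_pair(dprime_ci(counts, params), maf[i], maf[j], params)
      cls[i, j] <- cls[j, i] <- cl
    }
  }
  cls
}

#' Pairwise r-squared of one SNP against a set of SNPs
#'
#' @param panel a `haplotype_panel`.
#' @param snp_id reference SNP id.
#' @return named numeric vector of r2 against every panel SNP on the same
#'   chromosome (1 for the SNP itself).
#' @export
panel_r2 <- function(panel, snp_id) {
  k <- match(snp_id, panel$snps$id)
  if (is.na(k)) stop("SNP not in panel: ", snp_id, call. = FALSE)
  same <- which(norm_chrom(panel$snps$chrom) ==
                  norm_chrom(panel$snps$chrom[k]))
  h0 <- panel$H[, k]
  r <- suppressWarnings(as.vector(stats::cor(panel$H[, same, drop = FALSE], h0)))
  r2 <- r^2
  r2[is.na(r2)] <- 0
  r2[same == k] <- 1
  setNames(r2, panel$snps$id[same])
}
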