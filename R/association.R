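#' Additive-model logistic association for one SNP
#'
#' Maximum-likelihood fit of `logit P(case) = b0 + beta g + bs sex + ba age`
#' by iteratively reweighted least squares (convergence tolerance 1e-10,
#' at most 25 iterations).  Individuals with missing genotype or covariates
#' are excluded for that SNP.  A monomorphic genotype after exclusions is
#' flagged `"monomorphic"`; non-convergence or `|beta| > 15` (separation)
#' is flagged `"unstable"` — such records carry no usable estimate and are
#' excluded from meta-analysis downstream.
#'
#' @param g integer dose vector (0/1/2, NA = missing).
#' @param status binary phenotype (1 = case).
#' @param sex,age covariates.
#' @return one-row data frame: eaf (effect-allele frequency in controls),
#'   beta, se, z, p, n, flag.
#' @export
fit_logistic_additive <- function(g, status, sex, age) {
  keep <- !is.na(g) & !is.na(status) & !is.na(sex) & !is.na(age)
  g <- g[keep]; status <- status[keep]; sex <- sex[keep]; age <- age[keep]
  n <- length(g)
  out <- data.frame(eaf = NA_real_, beta = NA_real_, se = NA_real_,
                    z = NA_real_, p = NA_real_, n = n, flag = "ok",
                    stringsAsFactors = FALSE)
  if (n == 0L || length(unique(status)) < 2L) {
    out$flag <- "monomorphic"; return(out)
  }
  if (length(unique(g)) == 1L) { out$flag <- "monomorphic"; return(out) }
  out$eaf <- if (any(status == 0)) mean(g[status == 0]) / 2 else mean(g) / 2
  X <- cbind(1, g, sex, age)
  fit <- suppressWarnings(
    glm.fit(X, status, family = binomial(),
            control = list(epsilon = 1e-10, maxit = 25)))
  beta <- fit$coefficients[2]
  if (!fit$converged || !is.finite(beta) || abs(beta) > 15) {
    out$flag <- "unstable"; return(out)
  }
  W <- fit$weights
  cov <- tryCatch(solve(crossprod(X * sqrt(W))), error = function(e) NULL)
  if (is.null(cov) || cov[2, 2] <= 0) { out$flag <- "unstable"; return(out) }
  out$beta <- unname(beta)
  out$se <- sqrt(cov[2, 2])
  out$z <- out$beta / out$se
  out$p <- 2 * pnorm(-abs(out$z))
  out
}

#' Scan all region SNPs in one study cohort
#'
#' Fits [fit_logistic_additive()] once per distinct member SNP (regions
#' sharing a SNP do not duplicate the fit).  The effect allele is the alt
#' allele of the input and is recorded explicitly.
#'
#' @param cohort a `study_cohort`.
#' @param regions regions with `members` from [assign_snps()], or `NULL` to
#'   scan every SNP in the cohort.
#' @param snp_table SNP annotation (id, chrom, pos, ref, alt); defaults to
#'   the columns of `cohort$G` with no positions.
#' @return summary-statistics data frame: study, snp, chr, pos,
#'   effect_allele, other_allele, eaf, beta, se, z, p, n, flag.
#' @export
scan_regions <- function(cohort, regions = NULL, snp_table = NULL) {
  ids <- if (is.null(regions)) colnames(cohort$G)
         else unique(unlist(regions$members))
  ids <- intersect(ids, colnames(cohort$G))
  if (!length(ids))
    return(data.frame(study = character(), snp = character(),
                      chr = character(), pos = integer(),
                      effect_allele = character(), other_allele = character(),
                      eaf = numeric(), beta = numeric(), se = numeric(),
                      z = numeric(), p = numeric(), n = integer(),
                      flag = character(), stringsAsFactors = FALSE))
  ph <- cohort$pheno
  rows <- lapply(ids, function(s)
    fit_logistic_additive(cohort$G[, s], ph$status, ph$sex, ph$age))
  res <- do.call(rbind, rows)
  ann <- if (!is.null(snp_table)) snp_table[match(ids, snp_table$id), ] else NULL
  data.frame(study = cohort$study, snp = ids,
             chr = if (!is.null(ann)) norm_chrom(ann$chrom) else NA_character_,
             pos = if (!is.null(ann)) ann$pos else NA_integer_,
             effect_allele = if (!is.null(ann)) ann$alt else "B",
             other_allele = if (!is.null(ann)) ann$ref else "A",
             res, stringsAsFactors = FALSE, row.names = NULL)
}

#' Genomic-control lambda
#'
#' Median Wald chi-square over the median of the null chi-square(1)
#' distribution (0.455).  Reported for diagnostics only; no correction is
#' applied anywhere in the pipeline.
#'
#' @param z vector of Wald statistics (NAs dropped).
#' @return lambda estimate.
#' @export
lambda_gc <- function(z) {
  z <- z[is.finite(z)]
  stats::median(z^2) / stats::qchisq(0.5, df = 1)
}
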