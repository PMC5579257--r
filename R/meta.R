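# Inverse-variance meta-analysis: allele alignment, fixed effects,
# Cochran's Q with the DerSimonian-Laird between-study variance, the
# p_het < 0.01 model gate, and stage combination with sample-size totals.

#' Align study effects to a common allele orientation
#'
#' Orients every record of each SNP to the first study's effect allele:
#' matching records pass through, swapped records get `beta` negated and
#' `eaf` complemented, records matching neither orientation are dropped (and
#' reported), and strand-ambiguous pairs (A/T, C/G) are dropped when
#' `drop_ambiguous` is set.
#'
#' @param effects data frame with columns study, snp, effect_allele,
#'   other_allele, beta, se and optionally eaf.
#' @param drop_ambiguous drop A/T and C/G SNP records entirely.
#' @return the aligned data frame; dropped records are in
#'   `attr(, "dropped")`.
#' @export
align_alleles <- function(effects, drop_ambiguous = FALSE) {
  ea <- toupper(effects$effect_allele); oa <- toupper(effects$other_allele)
  ambiguous <- (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
  drop <- logical(nrow(effects))
  if (drop_ambiguous) drop <- drop | ambiguous
  ref_ea <- ref_oa <- character(nrow(effects))
  for (s in unique(effects$snp)) {
    idx <- which(effects$snp == s & !drop)
    if (!length(idx)) next
    ref_ea[idx] <- ea[idx[1]]; ref_oa[idx] <- oa[idx[1]]
  }
  same <- ea == ref_ea & oa == ref_oa
  swap <- ea == ref_oa & oa == ref_ea & !same
  mismatch <- !drop & !same & !swap
  drop <- drop | mismatch
  out <- effects
  out$beta[swap] <- -out$beta[swap]
  if ("eaf" %in% names(out)) out$eaf[swap] <- 1 - out$eaf[swap]
  out$effect_allele[swap] <- ref_ea[swap]
  out$other_allele[swap] <- ref_oa[swap]
  dropped <- out[drop, , drop = FALSE]
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Inverse-variance fixed-effects combination
#'
#' `beta_FE = sum(w beta) / sum(w)`, `se_FE = sum(w)^(-1/2)` with
#' `w = 1/se^2`; two-sided normal p.
#'
#' @param beta,se per-study estimates and standard errors (k >= 1).
#' @return list(beta, se, z, p, k).
#' @export
fixed_effects <- function(beta, se) {
  k <- length(beta)
  if (k == 0L) stop("no studies to combine", call. = FALSE)
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  z <- b / s
  list(beta = b, se = s, z = z, p = 2 * pnorm(-abs(z)), k = k)
}

#' Cochran's Q, DerSimonian-Laird tau-squared and the random-effects model
#'
#' `Q = sum w (beta - beta_FE)^2` against chi-square(k-1);
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1 / (se^2 + tau2)`.  With a single study heterogeneity is
#' undefined: tau2 = 0 and the fixed model is returned.
#'
#' @param beta,se per-study estimates and standard errors.
#' @return list(Q, df, p_het, tau2, beta_re, se_re).
#' @export
heterogeneity <- function(beta, se) {
  k <- length(beta)
  fe <- fixed_effects(beta, se)
  if (k < 2L)
    return(list(Q = 0, df = 0L, p_het = NA_real_, tau2 = 0,
                beta_re = fe$beta, se_re = fe$se))
  w <- 1 / se^2
  Q <- sum(w * (beta - fe$beta)^2)
  df <- k - 1L
  p_het <- pchisq(Q, df, lower.tail = FALSE)
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(Q = Q, df = df, p_het = p_het, tau2 = tau2,
       beta_re = sum(ws * beta) / sum(ws), se_re = sqrt(1 / sum(ws)))
}

#' Per-SNP multi-study meta-analysis with heterogeneity gating
#'
#' Aligns alleles, combines each SNP's usable study records (flag "ok" when
#' a `flag` column is present) by inverse variance, computes Cochran's Q and
#' the DerSimonian-Laird random-effects model, and selects the model:
#' random effects when `p_het < het_threshold`, fixed otherwise.  Both
#' models are always emitted so the gate is auditable.
#'
#' @param effects per-study summary statistics (columns study, snp,
#'   effect_allele, other_allele, beta, se; optional eaf, p, flag, chr, pos).
#' @param het_threshold heterogeneity gate (default 0.01).
#' @param drop_ambiguous passed to [align_alleles()].
#' @return data frame, one row per SNP: snp, effect_allele, other_allele,
#'   k, beta_fe, se_fe, p_fe, Q, df, p_het, tau2, beta_re, se_re, p_re,
#'   model_used, beta, se, or_combined, p.
#' @export
meta_analyze <- function(effects, het_threshold = 0.01,
                         drop_ambiguous = FALSE) {
  if ("flag" %in% names(effects))
    effects <- effects[effects$flag == "ok", , drop = FALSE]
  effects <- effects[is.finite(effects$beta) & is.finite(effects$se) &
                       effects$se > 0, , drop = FALSE]
  aligned <- align_alleles(effects, drop_ambiguous = drop_ambiguous)
  rows <- lapply(split(aligned, aligned$snp), function(d) {
    fe <- fixed_effects(d$beta, d$se)
    het <- heterogeneity(d$beta, d$se)
    use_re <- !is.na(het$p_het) && het$p_het < het_threshold
    b <- if (use_re) het$beta_re else fe$beta
    s <- if (use_re) het$se_re else fe$se
    data.frame(snp = d$snp[1],
               chr = if ("chr" %in% names(d)) d$chr[1] else NA_character_,
               pos = if ("pos" %in% names(d)) d$pos[1] else NA_integer_,
               effect_allele = d$effect_allele[1],
               other_allele = d$other_allele[1],
               eaf = if ("eaf" %in% names(d)) mean(d$eaf) else NA_real_,
               k = fe$k, beta_fe = fe$beta, se_fe = fe$se, p_fe = fe$p,
               Q = het$Q, df = het$df, p_het = het$p_het, tau2 = het$tau2,
               beta_re = het$beta_re, se_re = het$se_re,
               p_re = 2 * pnorm(-abs(het$beta_re / het$se_re)),
               model_used = if (use_re) "random" else "fixed",
               beta = b, se = s, or_combined = exp(b),
               p = 2 * pnorm(-abs(b / s)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$snp), , drop = FALSE]
}

#' Combine analysis stages with sample-size bookkeeping
#'
#' The discovery stage (possibly multi-study) is meta-analyzed with the
#' per-SNP heterogeneity gate; additional stages (e.g. a de novo
#' replication) are then combined with the discovery estimates by a
#' fixed-effects model — the across-stage combination is always fixed.
#' Study labels must be unique across stages (non-overlapping samples).
#'
#' @param stages list of stages, each a list with `label`, `n_cases`,
#'   `n_controls` and `effects` (per-study summary statistics).
#' @param het_threshold heterogeneity gate within each stage.
#' @param drop_ambiguous passed to [align_alleles()].
#' @return list with `meta` (per-SNP data frame: stage-gated columns from
#'   the discovery stage plus beta_combined, se_combined, p_combined over
#'   all stages), `total_cases`, `total_controls`.
#' @export
combine_stages <- function(stages, het_threshold = 0.01,
                           drop_ambiguous = FALSE) {
  labels <- unlist(lapply(stages, function(s)
    unique(s$effects$study) %||% s$label))
  if (anyDuplicated(labels))
    stop("duplicate study label(s) across stages: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  per_stage <- lapply(stages, function(s)
    meta_analyze(s$effects, het_threshold = het_threshold,
                 drop_ambiguous = drop_ambiguous))
  disc <- per_stage[[1]]
  if (length(stages) > 1L) {
    stacked <- do.call(rbind, lapply(seq_along(per_stage), function(i) {
      d <- per_stage[[i]]
      data.frame(study = sprintf("stage%d", i), snp = d$snp,
                 effect_allele = d$effect_allele,
                 other_allele = d$other_allele,
                 beta = d$beta, se = d$se, stringsAsFactors = FALSE)
    }))
    aligned <- align_alleles(stacked, drop_ambiguous = FALSE)
    comb <- lapply(split(aligned, aligned$snp), function(d) {
      fe <- fixed_effects(d$beta, d$se)
      data.frame(snp = d$snp[1], beta_combined = fe$beta,
                 se_combined = fe$se, p_combined = fe$p,
                 k_stages = fe$k, stringsAsFactors = FALSE)
    })
    comb <- do.call(rbind, comb)
    disc <- merge(disc, comb, by = "snp", all.x = TRUE, sort = TRUE)
  } else {
    disc$beta_combined <- disc$beta
    disc$se_combined <- disc$se
    disc$p_combined <- disc$p
    disc$k_stages <- 1L
  }
  list(meta = disc,
       total_cases = sum(vapply(stages, function(s) s$n_cases, 1)),
       total_controls = sum(vapply(stages, function(s) s$n_controls, 1)))
}
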