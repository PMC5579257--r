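# Significance screening of meta-analyzed regions, risk-allele orientation,
# LD-proxy expansion and annotation-table joins.

#' Screen meta-analysis results for significant region leads
#'
#' Per region, if any member SNP passes the significance threshold the
#' minimum-p SNP becomes the lead (ties broken by smaller position); regions
#' with no passing SNP emit nothing.  Overlapping regions sharing a lead
#' each report it, with a `shared_lead` flag.  A `gw_significant` boolean
#' marks leads that also pass the conventional genome-wide level.
#'
#' @param meta per-SNP meta-analysis data frame (needs snp, pos, beta, se,
#'   eaf, effect_allele, other_allele, p and, if present, p_combined).
#' @param regions regions with `members` from [assign_snps()].
#' @param threshold per-test significance threshold (from
#'   [effective_tests()]).
#' @param gw_threshold secondary genome-wide significance level.
#' @return data frame of unoriented hits: gene, snp, pos, effect_allele,
#'   other_allele, eaf, beta, se, p, p_combined, shared_lead,
#'   gw_significant.
#' @export
screen_hits <- function(meta, regions, threshold, gw_threshold = 5e-8) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    d <- meta[meta$snp %in% regions$members[[i]] & is.finite(meta$p), ,
              drop = FALSE]
    d <- d[d$p < threshold, , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(d$p, d$pos), , drop = FALSE]
    lead <- d[1, ]
    pc <- if ("p_combined" %in% names(lead)) lead$p_combined else lead$p
    rows[[length(rows) + 1L]] <- data.frame(
      gene = regions$symbol[i], snp = lead$snp, pos = lead$pos,
      effect_allele = lead$effect_allele, other_allele = lead$other_allele,
      eaf = lead$eaf, beta = lead$beta, se = lead$se, p = lead$p,
      p_combined = pc, gw_significant = min(lead$p, pc) < gw_threshold,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(gene = character(), snp = character(), pos = integer(),
                      effect_allele = character(), other_allele = character(),
                      eaf = numeric(), beta = numeric(), se = numeric(),
                      p = numeric(), p_combined = numeric(),
                      gw_significant = logical(), shared_lead = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$shared_lead <- out$snp %in% out$snp[duplicated(out$snp)]
  rownames(out) <- NULL
  out
}

#' Orient hits to the risk allele
#'
#' The risk allele is the allele more frequent in cases: if `beta < 0` the
#' effect and other alleles are swapped, `beta` is negated and the
#' frequency complemented, so `OR = exp(beta) >= 1` for every hit.  A hit
#' with `beta` exactly 0 keeps its orientation and is flagged.
#'
#' @param hits data frame from [screen_hits()].
#' @return hits with columns risk_allele, nonrisk_allele, risk_freq, OR and
#'   `orientation_arbitrary`.
#' @export
orient_risk_allele <- function(hits) {
  flip <- !is.na(hits$beta) & hits$beta < 0
  hits$risk_allele <- ifelse(flip, hits$other_allele, hits$effect_allele)
  hits$nonrisk_allele <- ifelse(flip, hits$effect_allele, hits$other_allele)
  hits$risk_freq <- ifelse(flip, 1 - hits$eaf, hits$eaf)
  hits$beta <- abs(hits$beta)
  hits$OR <- exp(hits$beta)
  hits$orientation_arbitrary <- !is.na(hits$beta) & hits$beta == 0
  hits
}

#' LD proxies of a lead SNP on a reference panel
#'
#' All panel SNPs on the lead's chromosome with `r2 > r2_threshold`
#' (strict); the lead itself is always included (r2 = 1).
#'
#' @param lead_snp SNP id, must exist in the panel.
#' @param panel a `haplotype_panel`.
#' @param r2_threshold proxy threshold (default 0.8).
#' @return character vector of proxy SNP ids (lead first).
#' @export
ld_proxies <- function(lead_snp, panel, r2_threshold = 0.8) {
  r2 <- panel_r2(panel, lead_snp)
  prox <- names(r2)[r2 > r2_threshold]
  unique(c(lead_snp, prox))
}

#' Join eQTL, regulatory and trait annotations onto hits
#'
#' Expands each lead to its proxy set on the panel, then joins the three
#' annotation tables over `{lead} U proxies`.  Trait records are kept only
#' when flagged disease-related AND `p < trait_p_max`.  eQTL direction is
#' reported relative to the risk allele (flipped when the table's effect
#' allele is the non-risk allele).
#'
#' @param hits oriented hits from [orient_risk_allele()].
#' @param panel a `haplotype_panel` for proxy computation.
#' @param eqtl data frame (snp, gene, tissue, direction, optional
#'   effect_allele).
#' @param regulatory data frame (snp, element), or `NULL`.
#' @param traits data frame (snp, trait, p, cad_related), or `NULL`.
#' @param proxy_r2 proxy threshold (default 0.8).
#' @param trait_p_max trait-association p cutoff (default 1e-3).
#' @return list of per-hit annotation records: for each hit, list(gene,
#'   snp, proxies, eqtl, regulatory, traits).
#' @export
annotate_hits <- function(hits, panel, eqtl, regulatory = NULL, traits = NULL,
                          proxy_r2 = 0.8, trait_p_max = 1e-3) {
  if (!all(c("snp", "gene") %in% names(eqtl)))
    stop("eQTL table must have columns snp, gene", call. = FALSE)
  if (!is.null(traits) && !all(c("snp", "trait", "p", "cad_related")
                               %in% names(traits)))
    stop("trait table must have columns snp, trait, p, cad_related",
         call. = FALSE)
  if (!is.null(regulatory) && !all(c("snp", "element") %in% names(regulatory)))
    stop("regulatory table must have columns snp, element", call. = FALSE)
  lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    prox <- ld_proxies(h$snp, panel, proxy_r2)
    eq <- eqtl[eqtl$snp %in% prox, , drop = FALSE]
    if (nrow(eq) && "effect_allele" %in% names(eq) &&
        "direction" %in% names(eq)) {
      flipme <- eq$snp == h$snp & toupper(eq$effect_allele) ==
        toupper(h$nonrisk_allele)
      swap <- c(increased = "decreased", decreased = "increased")
      eq$direction[flipme] <- ifelse(eq$direction[flipme] %in% names(swap),
                                     swap[eq$direction[flipme]],
                                     eq$direction[flipme])
    }
    tr <- if (is.null(traits)) NULL
    else traits[traits$snp %in% prox & traits$cad_related &
                  traits$p < trait_p_max, , drop = FALSE]
    rg <- if (is.null(regulatory)) NULL
    else regulatory[regulatory$snp %in% prox, , drop = FALSE]
    list(gene = h$gene, snp = h$snp, proxies = prox, eqtl = eq,
         regulatory = rg, traits = tr)
  })
}
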