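# One-command pipeline driver: regions -> blocks/threshold -> per-study
# association -> meta-analysis -> screening/annotation -> enrichment.

#' Run the full screening pipeline from files
#'
#' Executes every stage on file inputs and writes all artifacts plus a run
#' manifest (seed, parameter values and per-stage record counts) to the
#' output directory.  `config` may be a YAML path or an equivalent list
#' with elements: `interactions`, `genes_bed`, `panel_vcf`, `studies`
#' (list of `list(label, vcf, pheno, n_cases, n_controls)` and/or
#' `list(label, sumstats, n_cases, n_controls)`), `gmt`, `eqtl`, `traits`,
#' `regulatory` (optional), `out_dir`, and optional parameters `flank`,
#' `alpha_family`, `het_threshold`, `proxy_r2`, `trait_p_max`,
#' `floor_pow10`, `include_singletons`, `drop_ambiguous`, `seed`.
#'
#' @param config YAML path or config list.
#' @return invisibly, a list with regions, blocks, efftests, meta, hits,
#'   annotations, enrichment and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("interactions", "genes_bed", "panel_vcf", "gmt", "eqtl"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("missing input file for '", f, "'", call. = FALSE)
  out_dir <- config$out_dir %||% stop("out_dir required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flank <- config$flank %||% 100000L
  alpha <- config$alpha_family %||% 0.05
  seed <- config$seed %||% 1L
  set.seed(seed)

  # regions
  targets <- load_targets(config$interactions, config$genes_bed)
  regions <- build_windows(targets$genes, flank = flank)
  panel_in <- read_genotypes(config$panel_vcf)
  if (!panel_in$phased)
    stop("panel VCF must be fully phased", call. = FALSE)
  panel <- structure(list(snps = panel_in$snps, H = panel_in$H),
                     class = "haplotype_panel")
  regions <- assign_snps(regions, panel$snps)
  write_tsv(data.frame(regions[, c("symbol", "chrom", "start", "end",
                                   "n_snps")]),
            file.path(out_dir, "regions.tsv"))

  # blocks and threshold
  member_ids <- unique(unlist(regions$members))
  bp <- do.call(block_params, config$block_params %||% list())
  blocks <- detect_blocks(panel, member_ids, params = bp)
  eff <- effective_tests(blocks, M = length(member_ids),
                         alpha_family = alpha,
                         floor_pow10 = isTRUE(config$floor_pow10),
                         include_singletons = isTRUE(config$include_singletons))
  bl_out <- blocks[, c("chrom", "start", "end", "n_snps")]
  bl_out$snps <- vapply(blocks$snps, paste, "", collapse = ",")
  write_tsv(bl_out, file.path(out_dir, "blocks.tsv"))
  jsonlite::write_json(unclass(eff), file.path(out_dir, "efftests.json"),
                       auto_unbox = TRUE, digits = NA)

  # per-study association (or externally supplied summary statistics)
  effects <- list()
  for (st in config$studies) {
    if (!is.null(st$sumstats)) {
      ss <- read_summary_stats(st$sumstats)
      if (!"study" %in% names(ss)) ss$study <- st$label
    } else {
      geno <- read_genotypes(st$vcf)
      ph <- read_tsv(st$pheno)
      ord <- match(rownames(geno$G), ph$id)
      ph <- ph[ord, ]
      cohort <- structure(list(study = st$label, G = geno$G, pheno = ph),
                          class = "study_cohort")
      ss <- scan_regions(cohort, regions, snp_table = geno$snps)
      write_summary_stats(ss, file.path(out_dir,
                                        paste0("assoc_", st$label, ".tsv")))
    }
    effects[[st$label]] <- ss
  }
  stage1 <- do.call(rbind, lapply(effects, function(d)
    d[, intersect(.sumstats_cols, names(d)), drop = FALSE]))
  n_cases <- sum(vapply(config$studies, function(s) s$n_cases %||% NA_real_, 1))
  n_controls <- sum(vapply(config$studies,
                           function(s) s$n_controls %||% NA_real_, 1))
  stages <- list(list(label = "discovery", n_cases = n_cases,
                      n_controls = n_controls, effects = stage1))
  comb <- combine_stages(stages,
                         het_threshold = config$het_threshold %||% 0.01,
                         drop_ambiguous = isTRUE(config$drop_ambiguous))
  meta <- comb$meta
  write_tsv(meta, file.path(out_dir, "meta.tsv"))

  # screening, annotation
  hits <- screen_hits(meta, regions, eff$threshold)
  hits <- orient_risk_allele(hits)
  eqtl <- read_tsv(config$eqtl)
  traits <- if (!is.null(config$traits)) read_tsv(config$traits) else NULL
  regulatory <- if (!is.null(config$regulatory)) read_tsv(config$regulatory)
                else NULL
  ann <- annotate_hits(hits, panel, eqtl, regulatory, traits,
                       proxy_r2 = config$proxy_r2 %||% 0.8,
                       trait_p_max = config$trait_p_max %||% 1e-3)
  write_tsv(hits[, setdiff(names(hits), "members")],
            file.path(out_dir, "hits.tsv"))
  jsonlite::write_json(ann, file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  # enrichment
  gmt <- read_gmt(config$gmt)
  enr <- enrichment_test(targets$genes$symbol, gmt, eqtl, meta,
                         threshold = config$enrichment_threshold %||%
                           eff$threshold)
  jsonlite::write_json(list(table = unclass(enr$table),
                            odds_ratio = enr$odds_ratio,
                            p = enr$p, flagged_targets = enr$flagged_targets),
                       file.path(out_dir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("targetgwas")),
    seed = seed,
    parameters = list(flank = flank, alpha_family = alpha,
                      het_threshold = config$het_threshold %||% 0.01,
                      proxy_r2 = config$proxy_r2 %||% 0.8,
                      trait_p_max = config$trait_p_max %||% 1e-3,
                      floor_pow10 = isTRUE(config$floor_pow10),
                      include_singletons = isTRUE(config$include_singletons),
                      drop_ambiguous = isTRUE(config$drop_ambiguous)),
    counts = list(genes_mapped = nrow(targets$genes),
                  genes_unmapped = length(targets$unmapped),
                  regions = nrow(regions),
                  snps_in_regions = length(member_ids),
                  blocks = eff$n_blocks, singletons = eff$n_singletons,
                  threshold = eff$threshold,
                  studies = length(config$studies),
                  total_cases = comb$total_cases,
                  total_controls = comb$total_controls,
                  hits = nrow(hits),
                  flagged_targets = length(enr$flagged_targets)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(regions = regions, blocks = blocks, efftests = eff,
                 meta = meta, hits = hits, annotations = ann,
                 enrichment = enr, manifest = manifest))
}

#' Run the pipeline in memory on synthetic data
#'
#' Simulates the panel, the cohorts and the annotation fixtures from one
#' [sim_config()], then runs region construction, block-based threshold
#' derivation, per-study association, meta-analysis, screening and
#' enrichment without touching disk.  Used for power/calibration studies
#' and end-to-end validation against the planted truth.
#'
#' @param config a [sim_config()], typically after [plant_effects()].
#' @param flank region flank in bp (default 20 kb, sized to the synthetic
#'   chromosome).
#' @param alpha_family family-wise alpha (default 0.05).
#' @param het_threshold heterogeneity gate (default 0.01).
#' @param block_parameters a [block_params()].
#' @return list: panel, fixtures, regions, blocks, efftests, meta, hits,
#'   enrichment, truth (manifest), recovered / false_genes (planted truth
#'   vs hit genes).
#' @export
run_synthetic_pipeline <- function(config, flank = 20000L,
                                   alpha_family = 0.05,
                                   het_threshold = 0.01,
                                   block_parameters = block_params()) {
  panel <- simulate_panel(config)
  fix <- make_annotation_fixtures(panel, config)
  targets <- load_targets(fix$interactions, fix$genes)
  regions <- build_windows(targets$genes, flank = flank)
  regions <- assign_snps(regions, panel$snps)
  member_ids <- unique(unlist(regions$members))

  blocks <- detect_blocks(panel, member_ids, params = block_parameters)
  eff <- effective_tests(blocks, M = length(member_ids),
                         alpha_family = alpha_family)

  effects <- do.call(rbind, lapply(seq_len(config$n_studies), function(k) {
    cohort <- simulate_cohort(panel, config, k)
    scan_regions(cohort, regions, snp_table = panel$snps)
  }))
  comb <- combine_stages(
    list(list(label = "discovery",
              n_cases = config$n_studies * config$cases_per_study,
              n_controls = config$n_studies * config$controls_per_study,
              effects = effects)),
    het_threshold = het_threshold)
  meta <- comb$meta

  hits <- screen_hits(meta, regions, eff$threshold)
  hits <- orient_risk_allele(hits)
  enr <- enrichment_test(targets$genes$symbol, fix$gmt, fix$eqtl, meta,
                         threshold = eff$threshold)
  truth <- fix$manifest$effect_genes
  list(panel = panel, fixtures = fix, regions = regions, blocks = blocks,
       efftests = eff, effects = effects, meta = meta, hits = hits,
       enrichment = enr, truth = truth,
       recovered = intersect(truth, hits$gene),
       false_genes = setdiff(hits$gene, truth))
}
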