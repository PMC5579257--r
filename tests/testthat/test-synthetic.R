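test_that("generators are deterministic in the seed", {
  cfg <- sim_config(seed = 5, n_blocks = 6, n_panel_haplotypes = 200,
                    n_target_genes = 2, n_background_genes = 20,
                    gene_min_separation_bp = 20000)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  c1 <- simulate_cohort(p1, cfg, 1)
  c2 <- simulate_cohort(p1, cfg, 1)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(p1, cfg, 2)
  expect_false(identical(c1$G, c3$G))
  f1 <- make_annotation_fixtures(p1, cfg)
  f2 <- make_annotation_fixtures(p1, cfg)
  expect_identical(f1, f2)
})

test_that("panel respects its invariants", {
  cfg <- sim_config(seed = 2, n_blocks = 12, maf_min = 0.1,
                    n_panel_haplotypes = 500)
  panel <- simulate_panel(cfg)
  expect_true(all(panel$H %in% 0:1))
  expect_true(all(diff(panel$snps$pos) > 0))
  af <- panel_afs(panel)
  expect_true(all(pmin(af, 1 - af) >= 0.1))
  expect_error(sim_config(founders_per_block = 1), "founders_per_block")
})

test_that("a two-founder block is in perfect internal LD", {
  cfg <- sim_config(seed = 3, n_blocks = 1, snps_per_block = c(4, 4),
                    founders_per_block = 2, n_panel_haplotypes = 400)
  panel <- simulate_panel(cfg)
  r2 <- cor(panel$H)^2
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("independent founder draws give near-zero cross-block LD", {
  cfg <- sim_config(seed = 4, n_blocks = 2, snps_per_block = c(5, 5),
                    founders_per_block = 2, n_panel_haplotypes = 2000)
  panel <- simulate_panel(cfg)
  r2 <- cor(panel$H)^2
  cross <- r2[panel$snps$block == 1, panel$snps$block == 2]
  expect_lt(mean(cross), 0.05)
})

test_that("population genotypes are in Hardy-Weinberg proportions", {
  cfg <- sim_config(seed = 6, n_blocks = 100, snps_per_block = c(5, 5),
                    n_panel_haplotypes = 1000)
  panel <- simulate_panel(cfg)
  set.seed(60)
  G <- simulate_genotypes(panel, 2000)
  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    obs <- tabulate(G[, j] + 1L, 3L)
    p <- mean(G[, j]) / 2
    exp <- nrow(G) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    suppressWarnings(stats::chisq.test(obs, p = exp / sum(exp))$p.value)
  }, 1)
  expect_gte(mean(hwe_p > 0.001), 0.99)
})

test_that("null cohorts show no case-control allele frequency shift", {
  cfg <- sim_config(seed = 7, n_blocks = 10, snps_per_block = c(5, 5),
                    cases_per_study = 1000, controls_per_study = 1000)
  panel <- simulate_panel(cfg)
  cohort <- simulate_cohort(panel, cfg, 1)
  case <- cohort$pheno$status == 1
  f_case <- colMeans(cohort$G[case, ]) / 2
  f_ctrl <- colMeans(cohort$G[!case, ]) / 2
  p_hat <- (f_case + f_ctrl) / 2
  se <- sqrt(p_hat * (1 - p_hat) * (1 / (2 * sum(case)) + 1 / (2 * sum(!case))))
  z <- abs(f_case - f_ctrl) / se
  expect_gte(mean(z < 3), 0.98)
  expect_true(all(z < 4.5))
})

test_that("a planted effect shifts case allele frequency and is recoverable", {
  H <- matrix(0L, 2000, 1)
  H[sample.int(2000, 600), 1] <- 1L          # MAF 0.3
  panel <- make_panel(H)
  cfg <- sim_config(seed = 8, cases_per_study = 1000,
                    controls_per_study = 1000)
  cfg$planted_effects <- data.frame(snp = panel$snps$id, beta = log(1.5))
  cohort <- simulate_cohort(panel, cfg, 1)
  case <- cohort$pheno$status == 1
  expect_gt(mean(cohort$G[case, 1]), mean(cohort$G[!case, 1]))
  fit <- fit_logistic_additive(cohort$G[, 1], cohort$pheno$status,
                               cohort$pheno$sex, cohort$pheno$age)
  expect_lt(abs(fit$beta - log(1.5)), 3 * fit$se)
})

test_that("between-study sd induces detectable effect heterogeneity", {
  H <- matrix(0L, 2000, 1)
  H[sample.int(2000, 600), 1] <- 1L
  panel <- make_panel(H)
  cfg <- sim_config(seed = 10, n_studies = 8, between_study_sd = 0.3,
                    cases_per_study = 500, controls_per_study = 500)
  cfg$planted_effects <- data.frame(snp = panel$snps$id, beta = 0.2)
  fits <- do.call(rbind, lapply(1:8, function(k) {
    co <- simulate_cohort(panel, cfg, k)
    fit_logistic_additive(co$G[, 1], co$pheno$status, co$pheno$sex,
                          co$pheno$age)
  }))
  expect_gt(sd(fits$beta), mean(fits$se))
})

test_that("planted SNPs must exist in the panel", {
  cfg <- sim_config(seed = 1, n_blocks = 2, n_panel_haplotypes = 100)
  panel <- simulate_panel(cfg)
  cfg$planted_effects <- data.frame(snp = "rs-not-there", beta = 1)
  expect_error(simulate_cohort(panel, cfg, 1), "absent from panel")
})

test_that("annotation fixtures have referential integrity and exact universe", {
  cfg <- sim_config(seed = 12, n_target_genes = 5, n_background_genes = 80)
  panel <- simulate_panel(cfg)
  cfg <- plant_effects(panel, cfg, n_effects = 2, beta = 0.25)
  fix <- make_annotation_fixtures(panel, cfg)
  # every interaction gene has coordinates
  expect_true(all(fix$interactions$gene %in% fix$genes$symbol))
  # effect genes cover the planted SNPs
  expect_length(fix$manifest$effect_genes, 2L)
  ge <- fix$genes[match(fix$manifest$effect_genes, fix$genes$symbol), ]
  pos <- panel$snps$pos[match(cfg$planted_effects$snp, panel$snps$id)]
  expect_true(all(pos >= ge$start & pos < ge$end))
  # planted SNPs are eQTLs of their genes (flaggable downstream)
  key <- paste(fix$manifest$planted$snp, fix$manifest$effect_genes)
  expect_true(all(key %in% paste(fix$eqtl$snp, fix$eqtl$gene)))

  # GMT universe size is exactly the background gene count
  cfg2 <- sim_config(seed = 13, n_target_genes = 43,
                     n_background_genes = 7076,
                     gene_min_separation_bp = 10000)
  panel2 <- simulate_panel(cfg2)
  fix2 <- make_annotation_fixtures(panel2, cfg2)
  expect_equal(length(unique(unlist(fix2$gmt))), 7076L)

  # zero planted effects: manifest lists no effect genes
  cfg0 <- sim_config(seed = 14, n_target_genes = 4, n_background_genes = 20)
  fix0 <- make_annotation_fixtures(simulate_panel(cfg0), cfg0)
  expect_length(fix0$manifest$effect_genes, 0L)
})

test_that("null association p-values are uniform", {
  cfg <- sim_config(seed = 15, n_blocks = 500, snps_per_block = c(1, 1),
                    n_panel_haplotypes = 600, cases_per_study = 500,
                    controls_per_study = 500)
  panel <- simulate_panel(cfg)
  cohort <- simulate_cohort(panel, cfg, 1)
  res <- scan_regions(cohort, snp_table = panel$snps)
  p <- res$p[res$flag == "ok"]
  expect_gte(length(p), 500 * 0.99)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})
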