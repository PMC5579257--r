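mk_effects <- function(beta, se, snp = "rs1", ea = "A", oa = "G",
                       study = NULL) {
  k <- length(beta)
  data.frame(study = study %||% sprintf("s%d", seq_len(k)), snp = snp,
             effect_allele = ea, other_allele = oa, eaf = 0.3,
             beta = beta, se = se, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("allele alignment flips, drops and passes through correctly", {
  e <- mk_effects(c(0.1, -0.05), c(0.1, 0.1))
  e$effect_allele <- c("A", "G"); e$other_allele <- c("G", "A")
  a <- align_alleles(e)
  expect_equal(a$beta, c(0.1, 0.05))
  expect_equal(a$eaf, c(0.3, 0.7))
  expect_equal(a$effect_allele, c("A", "A"))

  # mismatching allele pair is dropped and reported
  e2 <- mk_effects(c(0.1, 0.2), c(0.1, 0.1))
  e2$effect_allele <- c("A", "C"); e2$other_allele <- c("G", "T")
  a2 <- align_alleles(e2)
  expect_equal(nrow(a2), 1L)
  expect_equal(nrow(attr(a2, "dropped")), 1L)

  # aligned input is the identity
  e3 <- mk_effects(c(0.1, 0.2), c(0.1, 0.1))
  a3 <- align_alleles(e3)
  expect_equal(a3$beta, e3$beta)

  # strand-ambiguous pairs dropped only when asked
  e4 <- mk_effects(0.1, 0.1, ea = "A", oa = "T")
  expect_equal(nrow(align_alleles(e4)), 1L)
  expect_equal(nrow(align_alleles(e4, drop_ambiguous = TRUE)), 0L)
})

test_that("fixed-effects combination matches hand arithmetic", {
  one <- fixed_effects(0.07, 0.02)
  expect_equal(one$beta, 0.07)
  expect_equal(one$se, 0.02)

  fe <- fixed_effects(c(0.10, 0.00), c(0.10, 0.10))
  expect_equal(fe$beta, 0.05, tolerance = 1e-12)
  expect_equal(fe$se, 1 / sqrt(200), tolerance = 1e-9)
  expect_equal(fe$p, 0.4795, tolerance = 1e-4)

  k <- 4
  feq <- fixed_effects(rep(0.2, k), rep(0.05, k))
  expect_equal(feq$beta, 0.2)
  expect_equal(feq$se, 0.05 / sqrt(k))
  expect_error(fixed_effects(numeric(0), numeric(0)), "no studies")
})

test_that("Cochran's Q and DerSimonian-Laird match hand arithmetic", {
  hom <- heterogeneity(c(0.1, 0.1, 0.1), c(0.05, 0.05, 0.05))
  expect_equal(hom$Q, 0)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$beta_re, 0.1)

  h1 <- heterogeneity(c(0.10, 0.00), c(0.10, 0.10))
  expect_equal(h1$Q, 0.5, tolerance = 1e-12)
  expect_equal(h1$df, 1L)
  expect_equal(h1$p_het, 0.4795, tolerance = 1e-4)
  expect_equal(h1$tau2, 0)

  h2 <- heterogeneity(c(0.5, 0.0), c(0.1, 0.1))
  expect_equal(h2$Q, 12.5, tolerance = 1e-9)
  expect_equal(h2$p_het, 4.07e-4, tolerance = 1e-2)
  expect_equal(h2$tau2, 0.115, tolerance = 1e-9)
  expect_equal(h2$se_re, 0.25, tolerance = 1e-9)
})

test_that("meta-analysis agrees with an independent reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    beta <- rnorm(k, 0.1, 0.2)
    se <- runif(k, 0.05, 0.2)
    fe <- fixed_effects(beta, se)
    het <- heterogeneity(beta, se)
    rma_fe <- metafor::rma(yi = beta, sei = se, method = "FE")
    rma_dl <- metafor::rma(yi = beta, sei = se, method = "DL")
    expect_equal(fe$beta, as.numeric(rma_fe$beta), tolerance = 1e-8)
    expect_equal(fe$se, rma_fe$se, tolerance = 1e-8)
    expect_equal(het$Q, rma_dl$QE, tolerance = 1e-8)
    expect_equal(het$tau2, rma_dl$tau2, tolerance = 1e-8)
    expect_equal(het$beta_re, as.numeric(rma_dl$beta), tolerance = 1e-8)
    expect_equal(het$se_re, rma_dl$se, tolerance = 1e-8)
  }
})

test_that("heterogeneity gate picks the random-effects model", {
  e_hom <- mk_effects(c(0.1, 0.12, 0.09), c(0.05, 0.05, 0.05))
  m1 <- meta_analyze(e_hom)
  expect_equal(m1$model_used, "fixed")
  expect_equal(m1$beta, m1$beta_fe)

  e_het <- mk_effects(c(0.6, -0.4, 0.5), c(0.05, 0.05, 0.05))
  m2 <- meta_analyze(e_het)
  expect_lt(m2$p_het, 0.01)
  expect_equal(m2$model_used, "random")
  expect_equal(m2$beta, m2$beta_re)
  expect_gte(m2$se_re, m2$se_fe)
})

test_that("random-effects se never beats fixed-effects se", {
  set.seed(22)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    beta <- rnorm(k, 0, 0.5); se <- runif(k, 0.02, 0.3)
    expect_gte(heterogeneity(beta, se)$se_re + 1e-12,
               fixed_effects(beta, se)$se)
  }
})

test_that("combination is invariant to study order", {
  e <- mk_effects(c(0.1, 0.3, -0.2, 0.05), c(0.1, 0.2, 0.15, 0.08))
  m1 <- meta_analyze(e)
  m2 <- meta_analyze(e[c(3, 1, 4, 2), ])
  expect_equal(m1$beta, m2$beta, tolerance = 1e-12)
  expect_equal(m1$Q, m2$Q, tolerance = 1e-12)
})

test_that("DerSimonian-Laird tau2 recovery has small relative bias", {
  set.seed(23)
  k <- 10; tau <- 0.15; se <- rep(0.1, k)
  tau2_hat <- replicate(500, {
    beta <- rnorm(k, 0.2, sqrt(se^2 + tau^2))
    heterogeneity(beta, se)$tau2
  })
  expect_lt(abs(mean(tau2_hat) - tau^2) / tau^2, 0.25)
})

test_that("homogeneous summary effects trip the gate at its nominal rate", {
  set.seed(24)
  k <- 4
  p_het <- replicate(2000, {
    se <- rep(0.1, k)
    heterogeneity(rnorm(k, 0.05, se), se)$p_het
  })
  frac <- mean(p_het < 0.01)
  expect_lt(abs(frac - 0.01), 0.0075)
})

test_that("stage combination books sample sizes and rejects overlap", {
  st1 <- list(label = "discovery", n_cases = 84813, n_controls = 202543,
              effects = mk_effects(c(0.05, 0.06), c(0.01, 0.012),
                                   study = c("meta1", "meta2")))
  st2 <- list(label = "denovo", n_cases = 2496, n_controls = 1505,
              effects = mk_effects(0.08, 0.03, study = "genotyping"))
  res <- combine_stages(list(st1, st2))
  expect_equal(res$total_cases, 87309)
  expect_equal(res$total_controls, 204048)
  expect_true(all(c("p_combined", "beta_combined") %in% names(res$meta)))
  # across-stage combination is fixed-effects on the stage estimates
  stage1 <- meta_analyze(st1$effects)
  manual <- fixed_effects(c(stage1$beta, 0.08), c(stage1$se, 0.03))
  expect_equal(res$meta$beta_combined, manual$beta, tolerance = 1e-10)
  expect_equal(res$meta$p_combined, manual$p, tolerance = 1e-10)

  # single stage: combined columns equal the stage columns
  solo <- combine_stages(list(st1))
  expect_equal(solo$meta$p_combined, solo$meta$p)

  st_dup <- list(label = "denovo2", n_cases = 1, n_controls = 1,
                 effects = mk_effects(0.02, 0.05, study = "meta1"))
  expect_error(combine_stages(list(st1, st_dup)), "duplicate")
})
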