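mk_meta <- function(snp, pos, p, beta = 0.1, eaf = 0.3) {
  data.frame(snp = snp, pos = pos, effect_allele = "A", other_allele = "G",
             eaf = eaf, beta = beta, se = 0.02, p = p, p_combined = p,
             stringsAsFactors = FALSE)
}
mk_region <- function(symbol, members) {
  r <- data.frame(symbol = symbol, chrom = "1", start = 0L, end = 1L,
                  flank = 0L, stringsAsFactors = FALSE)
  r$members <- list(members)
  r
}

test_that("screening picks the minimum-p lead under a strict threshold", {
  meta <- mk_meta(c("a", "b", "c"), c(100, 200, 300), c(7.99e-8, 1e-6, 0.2))
  reg <- mk_region("GENE1", c("a", "b", "c"))
  hits <- screen_hits(meta, reg, threshold = 1e-5)
  expect_equal(hits$snp, "a")
  expect_equal(hits$gene, "GENE1")
  expect_false(hits$gw_significant)   # 7.99e-8 misses the 5e-8 level
  gw <- screen_hits(mk_meta("a", 100, 2.98e-8), mk_region("G", "a"), 1e-5)
  expect_true(gw$gw_significant)

  # boundary: min p above threshold emits nothing
  none <- screen_hits(mk_meta("a", 100, 2e-5), mk_region("G", "a"), 1e-5)
  expect_equal(nrow(none), 0L)

  # tie on p: smaller position wins
  tie <- mk_meta(c("x", "y"), c(500, 50), c(1e-7, 1e-7))
  expect_equal(screen_hits(tie, mk_region("G", c("x", "y")), 1e-5)$snp, "y")
})

test_that("screening is deterministic under permuted input", {
  set.seed(31)
  meta <- mk_meta(sprintf("s%d", 1:20), seq(100, 2000, by = 100),
                  10^runif(20, -9, -1))
  reg <- rbind(mk_region("G1", sprintf("s%d", 1:10)),
               mk_region("G2", sprintf("s%d", 11:20)))
  h1 <- screen_hits(meta, reg, 1e-4)
  h2 <- screen_hits(meta[sample.int(20), ], reg[2:1, ], 1e-4)
  expect_equal(h1[order(h1$gene), ], h2[order(h2$gene), ],
               ignore_attr = TRUE)
})

test_that("a lead shared by overlapping regions is reported per gene, flagged", {
  meta <- mk_meta("shared", 100, 1e-8)
  reg <- rbind(mk_region("G1", "shared"), mk_region("G2", "shared"))
  hits <- screen_hits(meta, reg, 1e-5)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$shared_lead))
})

test_that("risk-allele orientation makes every OR at least one", {
  h <- mk_meta("a", 1, 1e-6, beta = -0.05, eaf = 0.85)
  h$gene <- "G"; h$gw_significant <- FALSE; h$shared_lead <- FALSE
  o <- orient_risk_allele(h)
  expect_equal(o$risk_allele, "G")
  expect_equal(o$risk_freq, 0.15, tolerance = 1e-12)
  expect_equal(o$OR, exp(0.05), tolerance = 1e-12)

  h2 <- mk_meta("b", 1, 1e-6, beta = 0.0488, eaf = 0.6)
  h2$effect_allele <- "T"; h2$gene <- "G"
  o2 <- orient_risk_allele(h2)
  expect_equal(o2$risk_allele, "T")
  expect_equal(round(o2$OR, 2), 1.05)

  hz <- mk_meta("c", 1, 1e-6, beta = 0)
  hz$gene <- "G"
  expect_true(orient_risk_allele(hz)$orientation_arbitrary)
})

test_that("bundled lead-SNP table parses and re-emits unchanged", {
  path <- system.file("extdata", "coxib_lead_snps.tsv", package = "targetgwas")
  tab <- read_tsv(path)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$OR, c(1.05, 1.06, 1.04, 1.05))
  mmp9 <- tab[tab$gene == "MMP9", ]
  expect_equal(mmp9$risk_allele, "A")
  expect_equal(mmp9$risk_freq, 0.15)
  expect_equal(mmp9$OR, 1.06)
  tmp <- tempfile(fileext = ".tsv")
  write_tsv(tab, tmp)
  expect_equal(read_tsv(tmp), tab)
})

test_that("LD proxies use strict r2 and fail on unknown leads", {
  set.seed(32)
  base <- rbinom(400, 1, 0.5)
  flip <- function(x, k) { i <- sample(length(x), k); x[i] <- 1L - x[i]; x }
  H <- cbind(base, base, flip(base, 30), rbinom(400, 1, 0.5))
  panel <- make_panel(H)
  r2 <- panel_r2(panel, "snp00001")
  prox <- ld_proxies("snp00001", panel, 0.8)
  expect_true("snp00002" %in% prox)                 # perfect duplicate
  expect_false("snp00004" %in% prox)                # independent SNP
  expect_equal(setdiff(prox, "snp00001"),
               names(r2)[r2 > 0.8 & names(r2) != "snp00001"])
  expect_error(ld_proxies("nope", panel), "nope")
})

test_that("annotation joins honor the proxy set and the trait filter", {
  set.seed(33)
  base <- rbinom(400, 1, 0.5)
  H <- cbind(base, base, rbinom(400, 1, 0.5))
  panel <- make_panel(H)
  hit <- data.frame(gene = "G", snp = "snp00001", pos = 1000,
                    effect_allele = "A", other_allele = "G", eaf = 0.4,
                    beta = 0.1, se = 0.02, p = 1e-7, p_combined = 1e-7,
                    gw_significant = FALSE, shared_lead = FALSE,
                    risk_allele = "A", nonrisk_allele = "G", risk_freq = 0.4,
                    OR = exp(0.1), orientation_arbitrary = FALSE,
                    stringsAsFactors = FALSE)
  eqtl <- data.frame(snp = c("snp00002", "snp00003"), gene = "G",
                     tissue = "blood", direction = "decreased",
                     effect_allele = "A", stringsAsFactors = FALSE)
  traits <- data.frame(snp = c("snp00001", "snp00001", "snp00002"),
                       trait = c("sbp", "ldl", "bmi"),
                       p = c(5e-4, 5e-3, 1e-6),
                       cad_related = c(TRUE, TRUE, FALSE),
                       stringsAsFactors = FALSE)
  reg <- data.frame(snp = "snp00001", element = "Promoter",
                    stringsAsFactors = FALSE)
  ann <- annotate_hits(hit, panel, eqtl, reg, traits)[[1]]
  expect_true("snp00002" %in% ann$proxies)
  # eQTL keyed to the proxy, not the lead, still attaches
  expect_equal(ann$eqtl$snp, "snp00002")
  # trait records: disease-related below 1e-3 only
  expect_equal(ann$traits$trait, "sbp")
  expect_equal(ann$regulatory$element, "Promoter")

  bad_traits <- traits[, c("snp", "p")]
  expect_error(annotate_hits(hit, panel, eqtl, NULL, bad_traits), "trait")
})

test_that("eQTL direction is reported relative to the risk allele", {
  base <- rbinom(200, 1, 0.5)
  panel <- make_panel(cbind(base))
  hit <- data.frame(gene = "G", snp = "snp00001", pos = 1000,
                    effect_allele = "A", other_allele = "G", eaf = 0.6,
                    beta = 0.1, se = 0.02, p = 1e-7, p_combined = 1e-7,
                    gw_significant = FALSE, shared_lead = FALSE,
                    risk_allele = "A", nonrisk_allele = "G", risk_freq = 0.6,
                    OR = exp(0.1), orientation_arbitrary = FALSE,
                    stringsAsFactors = FALSE)
  eqtl <- data.frame(snp = "snp00001", gene = "G", tissue = "blood",
                     direction = "decreased", effect_allele = "G",
                     stringsAsFactors = FALSE)
  ann <- annotate_hits(hit, panel, eqtl)[[1]]
  expect_equal(ann$eqtl$direction, "increased")  # flipped to risk allele
})
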