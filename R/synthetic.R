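#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator: the founder-mosaic
#' haplotype panel (blocky LD, linkage equilibrium between blocks), the
#' multi-study case-control cohorts with planted per-allele log-odds effects,
#' and the annotation fixtures (genes, drug-gene interactions, pathways,
#' eQTL/trait tables).
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param n_blocks number of haplotype blocks on the simulated chromosome.
#' @param snps_per_block integer range (length 2) of SNPs per block.
#' @param founders_per_block number of distinct founder haplotypes per block
#'   (>= 2); 2 gives perfect within-block LD.
#' @param n_panel_haplotypes number of phased panel haplotypes (2N).
#' @param intra_block_spacing bp between adjacent SNPs inside a block.
#' @param inter_block_gap bp between adjacent blocks.
#' @param maf_min minimum realized panel minor-allele frequency, in (0, 0.5].
#' @param n_studies number of case-control studies K.
#' @param cases_per_study,controls_per_study per-study sample sizes.
#' @param planted_effects data frame with columns `snp`, `beta` (per-allele
#'   log-odds); empty for a null simulation.
#' @param between_study_sd sd of the Normal perturbation added to each
#'   planted beta per study (between-study heterogeneity).
#' @param baseline_prevalence disease probability at covariate means with no
#'   genetic effect.
#' @param beta_sex,beta_age covariate log-odds (age enters as (age-50)/10).
#' @param missing_rate uniform genotype missingness rate in cohorts.
#' @param n_target_genes,n_background_genes gene counts for the fixtures.
#' @param fraction_target_genes_with_effect fraction of target genes placed
#'   over a planted SNP (only meaningful when effects are planted).
#' @param gene_span_bp gene body width used when placing genes.
#' @param gene_min_separation_bp minimum distance between target gene centers.
#' @param n_pathways number of gene sets written to the pathway GMT.
#' @param n_chromosome_bp chromosome length; `NULL` sizes it to fit the panel
#'   and all gene bodies.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_blocks = 48L,
                       snps_per_block = c(3L, 6L),
                       founders_per_block = 2L,
                       n_panel_haplotypes = 1000L,
                       intra_block_spacing = 1000L,
                       inter_block_gap = 8000L,
                       maf_min = 0.05,
                       n_studies = 4L,
                       cases_per_study = 1000L,
                       controls_per_study = 1000L,
                       planted_effects = data.frame(snp = character(),
                                                    beta = numeric()),
                       between_study_sd = 0,
                       baseline_prevalence = 0.3,
                       beta_sex = 0.25,
                       beta_age = 0.3,
                       missing_rate = 0,
                       n_target_genes = 10L,
                       n_background_genes = 200L,
                       fraction_target_genes_with_effect = 0.3,
                       gene_span_bp = 4000L,
                       gene_min_separation_bp = 50000L,
                       n_pathways = 20L,
                       n_chromosome_bp = NULL) {
  cfg <- as.list(environment())
  stopifnot(length(snps_per_block) == 2L, snps_per_block[1] >= 1L,
            snps_per_block[2] >= snps_per_block[1])
  if (founders_per_block < 2)
    stop("founders_per_block must be >= 2 (no polymorphism possible otherwise)",
         call. = FALSE)
  if (maf_min <= 0 || maf_min > 0.5)
    stop("maf_min must lie in (0, 0.5]", call. = FALSE)
  pos <- c("n_blocks", "n_panel_haplotypes", "n_studies", "cases_per_study",
           "controls_per_study", "intra_block_spacing", "inter_block_gap")
  for (f in pos) if (cfg[[f]] < 1) stop(f, " must be positive", call. = FALSE)
  if (between_study_sd < 0) stop("between_study_sd must be >= 0", call. = FALSE)
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline_prevalence must lie in (0, 1)", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (!is.data.frame(planted_effects) ||
      !all(c("snp", "beta") %in% names(planted_effects)))
    stop("planted_effects must be a data frame with columns snp, beta",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_blocks, " blocks x ", x$snps_per_block[1], "-",
      x$snps_per_block[2], " SNPs, ", x$founders_per_block, " founders, 2N = ",
      x$n_panel_haplotypes, "\n", x$n_studies, " studies (",
      x$cases_per_study, "/", x$controls_per_study, "), ",
      nrow(x$planted_effects), " planted effects, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# non-strand-ambiguous allele pairs only, so nothing is lost to the
# ambiguity filter during allele alignment
.allele_pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                        ncol = 2, byrow = TRUE)

#' Simulate a phased reference haplotype panel with blocky LD
#'
#' Founder-mosaic model: each block carries `founders_per_block` founder
#' haplotypes with frequencies drawn from a uniform simplex; every panel
#' haplotype copies one founder per block, independently across blocks.
#' Within-block LD is therefore strong (perfect for 2 founders) while
#' between-block loci are in linkage equilibrium.  Founder allele patterns
#' are redrawn until every SNP's realized panel MAF reaches `maf_min`.
#'
#' @param config a [sim_config()].
#' @return an object of class `haplotype_panel`: list with `snps` (data frame
#'   id, chrom, pos, ref, alt, block) and `H` (2N x M 0/1 matrix, 1 = alt).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nb <- config$n_blocks
  nf <- config$founders_per_block
  nh <- config$n_panel_haplotypes
  n_snps_block <- if (config$snps_per_block[1] == config$snps_per_block[2])
    rep(config$snps_per_block[1], nb)
  else
    sample(seq(config$snps_per_block[1], config$snps_per_block[2]),
           nb, replace = TRUE)
  M <- sum(n_snps_block)

  H <- matrix(0L, nrow = nh, ncol = M)
  block <- integer(M)
  pos <- integer(M)
  col <- 1L
  cursor <- 10000L
  for (b in seq_len(nb)) {
    m <- n_snps_block[b]
    # founder frequencies: uniform simplex (Dirichlet(1,...,1)) shifted so
    # every founder keeps frequency >= maf_min and the MAF floor is reachable
    if (nf * config$maf_min >= 1)
      stop("founders_per_block * maf_min must be < 1", call. = FALSE)
    w <- -log(runif(nf))
    w <- config$maf_min + (1 - nf * config$maf_min) * w / sum(w)
    # realized founder shares bound the achievable MAF: resample until every
    # founder is common enough that some allele pattern can clear the floor
    for (try in seq_len(1000L)) {
      fidx <- sample.int(nf, nh, replace = TRUE, prob = w)
      if (min(tabulate(fidx, nf)) / nh >= config$maf_min) break
      if (try == 1000L)
        stop("panel too small to realize MAF >= ", config$maf_min,
             call. = FALSE)
    }
    for (s in seq_len(m)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        pat <- rbinom(nf, 1L, 0.5)
        if (all(pat == pat[1])) next
        colv <- pat[fidx]
        af <- mean(colv)
        if (min(af, 1 - af) >= config$maf_min) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not realize MAF >= ", config$maf_min,
             " for block ", b, "; lower maf_min or enlarge the panel",
             call. = FALSE)
      H[, col] <- colv
      block[col] <- b
      pos[col] <- cursor
      cursor <- cursor + config$intra_block_spacing
      col <- col + 1L
    }
    cursor <- cursor + config$inter_block_gap
  }
  pair <- .allele_pairs[sample.int(nrow(.allele_pairs), M, replace = TRUE), ,
                        drop = FALSE]
  snps <- data.frame(id = sprintf("snp%05d", seq_len(M)),
                     chrom = "1", pos = pos,
                     ref = pair[, 1], alt = pair[, 2],
                     block = block, stringsAsFactors = FALSE)
  colnames(H) <- snps$id
  structure(list(snps = snps, H = H), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel: ", nrow(x$H), " haplotypes x ", ncol(x$H), " SNPs, ",
      length(unique(x$snps$block)), " truth blocks\n", sep = "")
  invisible(x)
}

#' Panel alternate-allele frequencies
#' @param panel a `haplotype_panel`.
#' @return named numeric vector of alt-allele frequencies.
#' @export
panel_afs <- function(panel) colMeans(panel$H)

#' Draw unphased genotypes from a panel under random mating
#'
#' Each individual is the sum of two haplotypes drawn independently (with
#' replacement) from the panel, so genotypes are in Hardy-Weinberg
#' proportions at the panel allele frequencies.
#'
#' @param panel a `haplotype_panel`.
#' @param n number of individuals.
#' @return n x M integer dose matrix (0/1/2).
#' @export
simulate_genotypes <- function(panel, n) {
  nh <- nrow(panel$H)
  i1 <- sample.int(nh, n, replace = TRUE)
  i2 <- sample.int(nh, n, replace = TRUE)
  panel$H[i1, , drop = FALSE] + panel$H[i2, , drop = FALSE]
}

#' Pick SNPs to carry planted effects
#'
#' Chooses `n_effects` panel SNPs with MAF >= `maf_planted`, one per block,
#' from blocks separated by at least `config$gene_min_separation_bp`, and
#' returns the config with `planted_effects` filled in.
#'
#' @param panel a `haplotype_panel`.
#' @param config a [sim_config()].
#' @param n_effects number of SNPs to plant.
#' @param beta per-allele log-odds assigned to every planted SNP (recycled).
#' @param maf_planted minimum panel MAF of a planted SNP.
#' @return the updated `sim_config`.
#' @export
plant_effects <- function(panel, config, n_effects, beta, maf_planted = 0.2) {
  af <- panel_afs(panel)
  maf <- pmin(af, 1 - af)
  eligible <- panel$snps[maf >= maf_planted, ]
  if (nrow(eligible) == 0L) stop("no SNP reaches maf_planted", call. = FALSE)
  set.seed(config$seed + 7L)
  chosen <- character(0)
  last_pos <- -Inf
  used_blocks <- integer(0)
  ord <- eligible[sample.int(nrow(eligible)), ]
  ord <- ord[order(ord$pos), ]
  # greedy sweep keeps planted loci in distinct, well-separated blocks
  for (i in seq_len(nrow(ord))) {
    if (length(chosen) == n_effects) break
    if (ord$block[i] %in% used_blocks) next
    if (ord$pos[i] - last_pos < config$gene_min_separation_bp) next
    chosen <- c(chosen, ord$id[i])
    used_blocks <- c(used_blocks, ord$block[i])
    last_pos <- ord$pos[i]
  }
  if (length(chosen) < n_effects)
    stop("could not place ", n_effects, " separated planted SNPs; ",
         "enlarge the panel or reduce gene_min_separation_bp", call. = FALSE)
  config$planted_effects <- data.frame(snp = chosen,
                                       beta = rep_len(beta, n_effects),
                                       stringsAsFactors = FALSE)
  config
}

#' Simulate one case-control study cohort
#'
#' Individuals are drawn from the panel population (random mating), disease
#' status follows a logistic liability
#' `logit P(case) = b0 + sum_j beta_j(study) g_j + beta_sex sex +
#' beta_age (age-50)/10`, with `beta_j(study) = beta_j + N(0, between_study_sd)`
#' and `b0` solving `baseline_prevalence` at covariate means.  Sampling by
#' rejection continues until the case and control quotas are filled, so the
#' covariate-disease relationships of the population model are preserved.
#' Age is Normal(60, 8) truncated to \[30, 90\]; sex is Bernoulli(0.5).
#'
#' @param panel a `haplotype_panel`.
#' @param config a [sim_config()]; planted SNP ids must exist in the panel.
#' @param study_index 1-based study number (seeds the per-study stream and
#'   the per-study effect perturbation).
#' @return object of class `study_cohort`: list with `study`, `G` (n x M dose
#'   matrix, NA = missing), `pheno` (data frame id, status, sex, age) and
#'   `truth` (realized per-study betas).
#' @export
simulate_cohort <- function(panel, config, study_index = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(config, "sim_config"))
  pe <- config$planted_effects
  if (nrow(pe) > 0 && !all(pe$snp %in% panel$snps$id))
    stop("planted SNP(s) absent from panel: ",
         paste(setdiff(pe$snp, panel$snps$id), collapse = ", "), call. = FALSE)
  set.seed(config$seed + 1000L * study_index)
  beta_study <- if (nrow(pe)) pe$beta + rnorm(nrow(pe), 0, config$between_study_sd)
                else numeric(0)

  af <- panel_afs(panel)
  mean_g <- if (nrow(pe)) 2 * af[pe$snp] else numeric(0)
  # intercept anchors prevalence at covariate/genotype means
  b0 <- qlogis(config$baseline_prevalence) -
    config$beta_sex * 0.5 - config$beta_age * 1 -
    sum(beta_study * mean_g)

  n_cases <- config$cases_per_study
  n_controls <- config$controls_per_study
  need <- n_cases + n_controls
  Gc <- NULL; sexc <- agec <- statusc <- NULL
  got_cases <- 0L; got_controls <- 0L
  batch <- max(2000L, ceiling(1.5 * need))
  for (iter in seq_len(200L)) {
    G <- simulate_genotypes(panel, batch)
    sex <- rbinom(batch, 1L, 0.5)
    age <- pmin(pmax(rnorm(batch, 60, 8), 30), 90)
    eta <- b0 + config$beta_sex * sex + config$beta_age * (age - 50) / 10
    if (nrow(pe))
      eta <- eta + as.vector(G[, pe$snp, drop = FALSE] %*% beta_study)
    status <- rbinom(batch, 1L, plogis(eta))
    keep_case <- which(status == 1L)[seq_len(min(sum(status == 1L),
                                                 n_cases - got_cases))]
    keep_ctrl <- which(status == 0L)[seq_len(min(sum(status == 0L),
                                                 n_controls - got_controls))]
    keep <- c(keep_case, keep_ctrl)
    if (length(keep)) {
      Gc <- rbind(Gc, G[keep, , drop = FALSE])
      sexc <- c(sexc, sex[keep]); agec <- c(agec, age[keep])
      statusc <- c(statusc, status[keep])
      got_cases <- got_cases + length(keep_case)
      got_controls <- got_controls + length(keep_ctrl)
    }
    if (got_cases >= n_cases && got_controls >= n_controls) break
  }
  if (got_cases < n_cases || got_controls < n_controls)
    stop("case/control quota unreachable after 200 batches (",
         got_cases, "/", n_cases, " cases, ", got_controls, "/", n_controls,
         " controls); check baseline_prevalence", call. = FALSE)
  ord <- order(-statusc)
  Gc <- Gc[ord, , drop = FALSE]
  storage.mode(Gc) <- "integer"
  if (config$missing_rate > 0) {
    miss <- runif(length(Gc)) < config$missing_rate
    Gc[miss] <- NA_integer_
  }
  pheno <- data.frame(id = sprintf("st%d_ind%05d", study_index,
                                   seq_len(nrow(Gc))),
                      status = statusc[ord], sex = sexc[ord],
                      age = round(agec[ord], 1), stringsAsFactors = FALSE)
  rownames(Gc) <- pheno$id
  structure(list(study = sprintf("study%d", study_index), G = Gc,
                 pheno = pheno,
                 truth = data.frame(snp = if (nrow(pe)) pe$snp else character(0),
                                    beta = beta_study,
                                    stringsAsFactors = FALSE)),
            class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  cat("study_cohort ", x$study, ": ", sum(x$pheno$status == 1), " cases / ",
      sum(x$pheno$status == 0), " controls x ", ncol(x$G), " SNPs\n", sep = "")
  invisible(x)
}

#' Generate annotation fixtures with known ground truth
#'
#' Places target and background gene bodies on the simulated chromosome and
#' writes the side tables the pipeline consumes: a drug-gene interaction
#' table, a gene BED, a pathway GMT over the background universe, an eQTL
#' table (every target gene gets its local SNPs as eQTLs, so a planted
#' association is discoverable as an eSNP signal), a trait-association table
#' with disease-related records at the planted SNPs, a regulatory-element
#' table, and a ground-truth manifest naming the genes that harbor planted
#' effects.  Target genes carrying an effect are centered on their planted
#' SNP; the rest are centered on unplanted blocks at least
#' `gene_min_separation_bp` apart.
#'
#' @param panel a `haplotype_panel`.
#' @param config a [sim_config()].
#' @param dir optional directory; when given, all fixtures are written there
#'   (BED, TSV, GMT, JSON) and paths are returned in the bundle.
#' @return list with `genes` (BED-style data frame), `interactions`, `gmt`
#'   (named list of gene sets), `eqtl`, `traits`, `regulatory`, `manifest`,
#'   and `paths` when `dir` is given.
#' @export
make_annotation_fixtures <- function(panel, config, dir = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(config, "sim_config"))
  set.seed(config$seed + 17L)
  snps <- panel$snps
  pe <- config$planted_effects
  nt <- config$n_target_genes
  if (nrow(pe) > nt)
    stop("more planted effects than target genes", call. = FALSE)
  half <- config$gene_span_bp %/% 2

  centers <- numeric(0)
  planted_gene <- character(0)
  if (nrow(pe)) {
    centers <- snps$pos[match(pe$snp, snps$id)]
    planted_gene <- sprintf("TG%02d", seq_len(nrow(pe)))
  }
  planted_blocks <- if (nrow(pe)) snps$block[match(pe$snp, snps$id)] else integer(0)
  free_blocks <- setdiff(unique(snps$block), planted_blocks)
  block_center <- vapply(free_blocks, function(b)
    mean(range(snps$pos[snps$block == b])), numeric(1))
  # deterministic left-to-right sweep: first center far enough from every
  # already-placed gene (planted genes are placed first and kept fixed)
  for (ctr in sort(block_center)) {
    if (length(centers) == nt) break
    if (!length(centers) ||
        all(abs(ctr - centers) >= config$gene_min_separation_bp))
      centers <- c(centers, ctr)
  }
  if (length(centers) < nt)
    stop("gene placement failed: cannot fit ", nt, " separated target genes; ",
         "reduce gene_min_separation_bp or n_target_genes", call. = FALSE)
  tsym <- sprintf("TG%02d", seq_len(nt))
  tstart <- pmax(0, round(centers) - half)
  genes_t <- data.frame(chrom = "1", start = tstart,
                        end = tstart + config$gene_span_bp,
                        symbol = tsym, stringsAsFactors = FALSE)

  nbg <- config$n_background_genes
  bg_start <- max(snps$pos) + config$inter_block_gap +
    (seq_len(nbg) - 1L) * (config$gene_span_bp + 1000L)
  genes_b <- data.frame(chrom = "1", start = bg_start,
                        end = bg_start + config$gene_span_bp,
                        symbol = sprintf("BG%04d", seq_len(nbg)),
                        stringsAsFactors = FALSE)
  genes <- rbind(genes_t, genes_b)
  if (!is.null(config$n_chromosome_bp) &&
      max(genes$end) > config$n_chromosome_bp)
    stop("gene bodies do not fit on the simulated chromosome", call. = FALSE)

  drugs <- c("celecoxib", "etoricoxib", "lumiracoxib", "parecoxib",
             "rofecoxib", "valdecoxib")
  interactions <- data.frame(
    drug = drugs[1L + (seq_len(nt) - 1L) %% length(drugs)],
    gene = tsym,
    interaction = sample(c("inhibition", "decreased expression",
                           "increased expression"), nt, replace = TRUE),
    source = "synthetic", stringsAsFactors = FALSE)

  # pathway GMT over the background universe; every background gene in >= 1 set
  memb <- sample.int(config$n_pathways, nbg, replace = TRUE)
  gmt <- lapply(seq_len(config$n_pathways), function(p) genes_b$symbol[memb == p])
  extra <- sample.int(config$n_pathways, nbg, replace = TRUE)
  for (p in seq_len(config$n_pathways))
    gmt[[p]] <- unique(c(gmt[[p]], genes_b$symbol[extra == p]))
  gmt <- gmt[vapply(gmt, length, 1L) > 0]
  names(gmt) <- sprintf("PATHWAY_%03d", seq_along(gmt))

  # eQTLs: target genes get every SNP inside the gene body (planted SNP
  # included by construction); background genes get one random panel SNP
  eq_t <- do.call(rbind, lapply(seq_len(nt), function(i) {
    inside <- snps$id[snps$pos >= genes_t$start[i] & snps$pos < genes_t$end[i]]
    if (!length(inside)) inside <- snps$id[which.min(abs(snps$pos - centers[i]))]
    data.frame(snp = inside, gene = tsym[i], stringsAsFactors = FALSE)
  }))
  eq_b <- data.frame(snp = sample(snps$id, nbg, replace = TRUE),
                     gene = genes_b$symbol, stringsAsFactors = FALSE)
  eqtl <- rbind(eq_t, eq_b)
  eqtl$tissue <- sample(c("monocyte", "macrophage", "whole blood"),
                        nrow(eqtl), replace = TRUE)
  eqtl$direction <- sample(c("increased", "decreased"), nrow(eqtl),
                           replace = TRUE)
  eqtl$effect_allele <- snps$alt[match(eqtl$snp, snps$id)]

  traits <- if (nrow(pe)) {
    data.frame(snp = pe$snp,
               trait = "systolic blood pressure",
               p = 10^runif(nrow(pe), -6, -4),
               cad_related = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(snp = character(), trait = character(), p = numeric(),
               cad_related = logical(), stringsAsFactors = FALSE)
  }
  decoys <- data.frame(snp = sample(snps$id, 5),
                       trait = c("height", "hair color", "height",
                                 "platelet count", "height"),
                       p = c(5e-3, 0.2, 2e-6, 0.04, 1e-5),
                       cad_related = c(TRUE, FALSE, FALSE, TRUE, FALSE),
                       stringsAsFactors = FALSE)
  traits <- rbind(traits, decoys)

  regulatory <- data.frame(
    snp = unique(c(if (nrow(pe)) pe$snp else character(0),
                   sample(snps$id, 10))),
    stringsAsFactors = FALSE)
  regulatory$element <- sample(c("Promoter", "Enhancer", "Promoter/Enhancer"),
                               nrow(regulatory), replace = TRUE)

  effect_genes <- if (nrow(pe)) planted_gene else character(0)
  manifest <- list(target_genes = tsym,
                   background_genes = genes_b$symbol,
                   planted = pe,
                   effect_genes = effect_genes)
  out <- list(genes = genes, interactions = interactions, gmt = gmt,
              eqtl = eqtl, traits = traits, regulatory = regulatory,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genes_bed = file.path(dir, "genes.bed"),
      interactions = file.path(dir, "interactions.tsv"),
      gmt = file.path(dir, "pathways.gmt"),
      eqtl = file.path(dir, "eqtl.tsv"),
      traits = file.path(dir, "traits.tsv"),
      regulatory = file.path(dir, "regulatory.tsv"),
      manifest = file.path(dir, "truth_manifest.json"))
    write_bed(genes, paths$genes_bed)
    write_tsv(interactions, paths$interactions)
    write_gmt(gmt, paths$gmt)
    write_tsv(eqtl, paths$eqtl)
    write_tsv(traits, paths$traits)
    write_tsv(regulatory, paths$regulatory)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}
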