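# Shared fixtures and independent oracle implementations used across the
# suite.  The oracles are deliberately naive (direct enumeration / textbook
# Newton steps) and share no code with the package internals they check.

# construct a haplotype_panel directly from a 0/1 matrix
make_panel <- function(H, pos = NULL, chrom = "1", block = NULL,
                       ref = "A", alt = "G") {
  M <- ncol(H)
  if (is.null(pos)) pos <- seq_len(M) * 1000L
  if (is.null(block)) block <- seq_len(M)
  snps <- data.frame(id = sprintf("snp%05d", seq_len(M)), chrom = chrom,
                     pos = as.integer(pos), ref = rep_len(ref, M),
                     alt = rep_len(alt, M), block = rep_len(block, M),
                     stringsAsFactors = FALSE)
  colnames(H) <- snps$id
  structure(list(snps = snps, H = H), class = "haplotype_panel")
}

# brute-force Gabriel interval rule: enumerate every interval, apply the
# outermost-pair / informative-fraction conditions by direct double loops,
# then greedy acceptance by SNP count (ties leftmost)
naive_find_blocks <- function(pos, cls, params) {
  m <- length(pos)
  cand <- list()
  for (i in seq_len(max(m - 1, 0))) for (j in seq_len(m)[-seq_len(i)]) {
    if (pos[j] - pos[i] > params$max_span) next
    if (is.na(cls[i, j]) || cls[i, j] != "strong_LD") next
    ns <- ni <- 0L
    for (k in i:(j - 1)) for (l in (k + 1):j) {
      cl <- cls[k, l]
      if (is.na(cl) || cl == "uninformative") next
      ni <- ni + 1L
      if (cl == "strong_LD") ns <- ns + 1L
    }
    if (ni > 0 && ns / ni >= params$informative_fraction)
      cand[[length(cand) + 1L]] <- c(i, j)
  }
  if (!length(cand)) return(matrix(integer(0), ncol = 2))
  cm <- do.call(rbind, cand)
  cm <- cm[order(-(cm[, 2] - cm[, 1]), cm[, 1]), , drop = FALSE]
  used <- logical(m)
  out <- list()
  for (r in seq_len(nrow(cm))) {
    rng <- seq(cm[r, 1], cm[r, 2])
    if (!any(used[rng])) { out[[length(out) + 1L]] <- cm[r, ]; used[rng] <- TRUE }
  }
  cm <- do.call(rbind, out)
  cm[order(cm[, 1]), , drop = FALSE]
}

# textbook Newton-Raphson logistic regression
naive_irls <- function(X, y, iter = 50) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(iter)) {
    p <- plogis(as.vector(X %*% beta))
    W <- p * (1 - p)
    H <- crossprod(X, X * W)
    step <- solve(H, crossprod(X, y - p))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < 1e-12) break
  }
  p <- plogis(as.vector(X %*% beta))
  se <- sqrt(diag(solve(crossprod(X, X * p * (1 - p)))))
  list(beta = beta, se = se)
}

# upper-tail hypergeometric p by full enumeration of the support
naive_fisher_enum <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  support <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  sum(probs[support >= a])
}

# random pair-classification matrix for block-detector property tests
random_classification <- function(m, p_strong = 0.5, p_recomb = 0.3) {
  cls <- matrix(NA_character_, m, m)
  labs <- c("strong_LD", "recombination", "uninformative")
  pr <- c(p_strong, p_recomb, 1 - p_strong - p_recomb)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    cls[i, j] <- cls[j, i] <- sample(labs, 1, prob = pr)
  }
  cls
}
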