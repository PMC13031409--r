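# Independent oracles used across the suite. Each re-derives the target
# quantity by a different route than the implementation (ANOVA mean squares,
# exhaustive enumeration, permutation), so agreement is evidence, not
# tautology.

# --- Weir-Cockerham theta via hierarchical ANOVA mean squares --------------
# Observations are per-gamete allele indicators; variance components are
# recovered from the population / individual / gamete mean squares.
oracle_wc_theta <- function(g1, g2) {
  y1 <- geno_alleles(g1[!is.na(g1)])
  y2 <- geno_alleles(g2[!is.na(g2)])
  A <- sort(unique(c(as.vector(y1), as.vector(y2))))[1]
  y <- list(y1 == A, y2 == A)
  n <- vapply(y, nrow, integer(1)); N <- sum(n); r <- 2
  ybar_i <- lapply(y, rowMeans)
  ybar_pop <- vapply(y, mean, numeric(1))
  ybar <- sum(n * ybar_pop) / N
  SSG <- sum(vapply(1:2, function(i) sum((y[[i]] - ybar_i[[i]])^2),
                    numeric(1)))
  SSI <- sum(vapply(1:2, function(i)
    2 * sum((ybar_i[[i]] - ybar_pop[i])^2), numeric(1)))
  SSP <- sum(2 * n * (ybar_pop - ybar)^2)
  MSG <- SSG / N
  MSI <- SSI / (N - r)
  MSP <- SSP / (r - 1)
  nc <- (N - sum(n^2) / N) / (r - 1)
  sig_g <- MSG
  sig_i <- (MSI - MSG) / 2
  sig_p <- (MSP - MSI) / (2 * nc)
  sig_p / (sig_p + sig_i + sig_g)
}

# --- hybrid class log-likelihood by gene-pair-origin enumeration -----------
oracle_class_lik <- function(g, p_a, p_b, phi_row) {
  al <- strsplit(g, "/", fixed = TRUE)[[1]]
  f <- function(p, a) if (a %in% names(p)) unname(p[[a]]) else 0
  pair_p <- function(p1, p2) {
    i <- al[1]; j <- al[2]
    if (i == j) f(p1, i) * f(p2, i)
    else f(p1, i) * f(p2, j) + f(p1, j) * f(p2, i)
  }
  phi_row[1] * pair_p(p_a, p_a) + phi_row[2] * pair_p(p_a, p_b) +
    phi_row[3] * pair_p(p_b, p_b)
}

oracle_classify <- function(g_vec, freqs, model) {
  classes <- rownames(model$phi)
  ll <- vapply(classes, function(cl) {
    s <- log(model$prior[cl])
    for (li in seq_along(g_vec)) {
      if (is.na(g_vec[li])) next
      f <- freqs$freq[[li]]
      s <- s + log(oracle_class_lik(g_vec[li], f[[freqs$pops[1]]],
                                    f[[freqs$pops[2]]],
                                    model$phi[cl, ]))
    }
    s
  }, numeric(1))
  w <- exp(ll - max(ll))
  w / sum(w)
}

# --- parentage LOD by exhaustive enumeration over true genotypes -----------
oracle_lod_locus <- function(g_o, g_m, g_f, p, e) {
  codes <- c("1/1", "1/2", "2/2")
  io <- match(g_o, codes); im <- match(g_m, codes); jf <- match(g_f, codes)
  hw <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  gam <- c(1, 0.5, 0)
  trans <- function(o, m, f) {
    pm <- gam[m]; pf <- gam[f]
    c(pm * pf, pm * (1 - pf) + (1 - pm) * pf, (1 - pm) * (1 - pf))[o]
  }
  E <- function(obs, true) (1 - e) * (obs == true) + e * hw[obs]
  L1 <- 0; L2 <- 0
  for (tm in 1:3) for (tf in 1:3) for (to in 1:3) {
    w <- hw[tm] * hw[tf] * E(im, tm) * E(jf, tf) * E(io, to)
    L1 <- L1 + w * trans(to, tm, tf)
    L2 <- L2 + w * hw[to]
  }
  log(L1 / L2)
}

oracle_lod <- function(g_off, g_mother, g_father, p1, e) {
  tot <- 0
  for (li in seq_along(g_off)) {
    if (is.na(g_off[li]) || is.na(g_mother[li]) || is.na(g_father[li]))
      next
    tot <- tot + oracle_lod_locus(g_off[li], g_mother[li], g_father[li],
                                  p1[li], e)
  }
  tot
}

# --- critical Delta by exhaustive threshold scan ---------------------------
oracle_critical_delta <- function(delta, correct, conf) {
  keep <- !is.na(delta)
  delta <- delta[keep]; correct <- correct[keep]
  for (d in sort(unique(c(0, delta)))) {
    sel <- delta >= d
    if (any(sel) && mean(correct[sel]) >= conf) return(d)
  }
  Inf
}

# --- heterozygote-excess p by permutation of alleles into pairs ------------
oracle_hwe_excess_p <- function(n_het, n_a1, n, reps = 20000) {
  alleles <- c(rep(1L, n_a1), rep(2L, 2 * n - n_a1))
  hets <- replicate(reps, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  mean(hets >= n_het)
}

# --- small random genotype matrices ----------------------------------------
random_gm <- function(n_per_pop = 6, n_loci = 4, miss = 0.1,
                      pops = c("A", "B")) {
  n <- 2 * n_per_pop
  calls <- matrix(NA_character_, n, n_loci,
                  dimnames = list(paste0("s", seq_len(n)),
                                  paste0("L", seq_len(n_loci))))
  for (li in seq_len(n_loci)) {
    p <- stats::runif(1, 0.1, 0.9)
    a1 <- stats::rbinom(n, 1, p); a2 <- stats::rbinom(n, 1, p)
    g <- geno_code(2L - a1, 2L - a2)
    g[stats::runif(n) < miss] <- NA
    calls[, li] <- g
  }
  geno_matrix(calls, rep(pops, each = n_per_pop))
}

write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("ctg1", "101", "snp1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("ctg2", "55", ".", "C", "T", ".", "PASS", ".", "GT",
          "0/1", "./.", "0/0", sep = "\t")), path)
  path
}
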