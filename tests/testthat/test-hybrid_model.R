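# exhaustive two-generation pedigree enumeration of gene-pair origin
# proportions: track P(gamete copy has A-origin) through each cross
enumerate_phi <- function() {
  # a gamete from a parent whose two copies have A-origin probs (q1, q2)
  # carries A with prob (q1 + q2) / 2; copies are independent across the
  # two gametes forming an individual
  indiv <- list(PureA = c(1, 1), PureB = c(0, 0))
  cross <- function(p1, p2) c(mean(p1), mean(p2))
  indiv$F1 <- cross(indiv$PureA, indiv$PureB)
  indiv$F2 <- cross(indiv$F1, indiv$F1)
  indiv$BxA <- cross(indiv$F1, indiv$PureA)
  indiv$BxB <- cross(indiv$F1, indiv$PureB)
  t(vapply(indiv, function(q) {
    c(AA = q[1] * q[2],
      AB = q[1] * (1 - q[2]) + (1 - q[1]) * q[2],
      BB = (1 - q[1]) * (1 - q[2]))
  }, numeric(3)))
}

test_that("the six-class phi table equals pedigree enumeration", {
  model <- hybrid_classes()
  phi_oracle <- enumerate_phi()
  expect_equal(model$phi[rownames(phi_oracle), ], phi_oracle,
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(model$phi) - 1) < 1e-12))
  expect_equal(unname(model$phi["F2", ]), c(0.25, 0.5, 0.25))
  expect_equal(unname(model$phi["BxA", ]), c(0.5, 0.5, 0))
})

test_that("expected genotype probabilities normalise and hit fixed cases", {
  pa <- c(`1` = 1); pb <- c(`2` = 1)
  f1 <- expected_genotype_probs(c(0, 1, 0), pa, pb)
  expect_equal(unname(f1["1/2"]), 1)
  f2 <- expected_genotype_probs(c(0.25, 0.5, 0.25), pa, pb)
  expect_equal(unname(f2[c("1/1", "1/2", "2/2")]), c(0.25, 0.5, 0.25))
  set.seed(51)
  for (i in 1:20) {
    p <- stats::runif(1, 0.05, 0.95); q <- stats::runif(1, 0.05, 0.95)
    phi <- hybrid_classes()$phi[sample(6, 1), ]
    pr <- expected_genotype_probs(phi, c(`1` = p, `2` = 1 - p),
                                  c(`1` = q, `2` = 1 - q))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
  expect_error(expected_genotype_probs(c(1, 0, 0), c(`1` = 0.5),
                                       c(`1` = 1)), "sum to 1")
})

test_that("class simulation respects pedigree constraints at fixed loci", {
  fixed <- bf_biallelic(rep(1, 20), rep(0, 20))
  f1 <- simulate_class(fixed, "F1", 10, seed = 52)
  expect_true(all(f1$calls == "1/2"))
  bxa <- simulate_class(fixed, "BxA", 50, seed = 53)
  expect_false(any(bxa$calls == "2/2"))   # no route to two B alleles
  f2 <- simulate_class(bf_biallelic(1, 0), "F2", 10000, seed = 54)
  props <- c(mean(f2$calls == "1/1"), mean(f2$calls == "1/2"),
             mean(f2$calls == "2/2"))
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * se))
  expect_error(simulate_class(bf_biallelic(numeric(0), numeric(0)),
                              "F1", 5), "empty")
})

test_that("the plug-in classifier equals brute-force mixture likelihood", {
  set.seed(55)
  model <- hybrid_classes()
  for (nl in 1:3) {
    freqs <- bf_biallelic(stats::runif(nl, 0.1, 0.9),
                          stats::runif(nl, 0.1, 0.9))
    gm <- simulate_class(freqs, "F2", 4, seed = 55 + nl)
    got <- classify_hybrids(gm, freqs, model, eps = 0)
    for (si in seq_len(4)) {
      oracle <- oracle_classify(gm$calls[si, ], freqs, model)
      expect_equal(unlist(got[si, rownames(model$phi)]),
                   oracle[rownames(model$phi)], tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
    expect_true(all(abs(rowSums(got[, rownames(model$phi)]) - 1) < 1e-9))
  }
})

test_that("diagnostic panels give near-certain posteriors analytically", {
  fixed <- bf_biallelic(rep(1, 100), rep(0, 100), n = 1e6)
  all_het <- geno_matrix(matrix("1/2", 1, 100,
                                dimnames = list("h", fixed$loci)))
  post <- classify_hybrids(all_het, fixed)
  expect_gt(post$F1[1], 0.999)
  all_a <- geno_matrix(matrix("1/1", 1, 100,
                              dimnames = list("a", fixed$loci)))
  post_a <- classify_hybrids(all_a, fixed)
  expect_gt(post_a$PureA[1], 0.999)
})

test_that("samples with no called loci are unclassified, not uniform", {
  freqs <- bf_biallelic(c(0.9, 0.8), c(0.1, 0.2))
  gm <- geno_matrix(matrix(NA_character_, 1, 2,
                           dimnames = list("void", freqs$loci)))
  post <- classify_hybrids(gm, freqs)
  expect_identical(post$assigned_class, "unclassified")
  expect_true(is.na(post$max_posterior))
})

test_that("population-label swap maps classes symmetrically", {
  set.seed(56)
  freqs <- bf_biallelic(stats::runif(30, 0.6, 0.95),
                        stats::runif(30, 0.05, 0.4))
  gm <- simulate_class(freqs, "BxA", 10, seed = 57)
  post <- classify_hybrids(gm, freqs)
  post_sw <- classify_hybrids(gm, bf_swap(freqs))
  expect_equal(post$PureA, post_sw$PureB, tolerance = 1e-9)
  expect_equal(post$BxA, post_sw$BxB, tolerance = 1e-9)
  expect_equal(post$F1, post_sw$F1, tolerance = 1e-9)
  expect_equal(post$F2, post_sw$F2, tolerance = 1e-9)
})

test_that("power is monotone in threshold and backcrosses are hardest", {
  # strong panel: everything correct at threshold 0.5
  strong <- make_species_panel(60, 0, seed = 58, s_min_diff = 0.8)$freqs
  pw <- hybrid_power(strong, n_per_class = 10, replicates = 2, seed = 59)
  expect_true(all(pw$mean_accuracy[pw$threshold == 0.5] == 1))
  # monotone: accuracy at threshold 1.0 never exceeds accuracy at 0.5
  for (cl in unique(pw$class)) {
    acc <- pw$mean_accuracy[pw$class == cl]
    expect_lte(acc[length(acc)], acc[1])
  }
  # moderately informative panel: backcross accuracy below pure-class
  # accuracy (backcrosses are the hardest categories)
  weak <- bf_biallelic(rep(0.7, 30), rep(0.3, 30))
  pww <- hybrid_power(weak, n_per_class = 30, replicates = 2, seed = 60)
  at5 <- function(cl) pww$mean_accuracy[pww$class == cl &
                                          pww$threshold == 0.5]
  expect_lt(mean(c(at5("BxA"), at5("BxB"))),
            mean(c(at5("PureA"), at5("PureB"))))
})

test_that("accuracy declines with missing data and matches power at m=0", {
  freqs <- make_species_panel(40, 0, seed = 61)$freqs
  am <- accuracy_vs_missing(freqs, m_grid = c(0, 0.5, 0.9),
                            threshold = 0.9, n_per_class = 10, seed = 62)
  mean_acc <- tapply(am$accuracy, am$missing_rate, mean)
  expect_gte(mean_acc[["0"]] + 0.1, mean_acc[["0.9"]])
  expect_true(all(am$accuracy[am$missing_rate == 0] == 1))
})

test_that("anchored curation keeps confident baseline members", {
  pan <- make_species_panel(60, 0, seed = 63)
  pa <- simulate_class(pan$freqs, "PureA", 20, seed = 64, prefix = "pa")
  pb <- simulate_class(pan$freqs, "PureB", 20, seed = 65, prefix = "pb")
  hyb <- simulate_class(pan$freqs, "F1", 3, seed = 66, prefix = "f1")
  calls <- rbind(pa$calls, pb$calls, hyb$calls)
  gm <- geno_matrix(calls, c(rep("A", 20), rep("B", 20), rep("A", 3)))
  z <- stats::setNames(c(rep("PureA", 20), rep("PureB", 20)),
                       c(rownames(pa$calls), rownames(pb$calls)))
  cur <- curate_baseline(gm, z, min_posterior = 0.99)
  expect_true(all(rownames(pa$calls) %in% cur$kept))
  expect_true(all(rownames(pb$calls) %in% cur$kept))
  expect_false(any(rownames(hyb$calls) %in% cur$kept))
})
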