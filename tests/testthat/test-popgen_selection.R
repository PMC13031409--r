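make_two_pop <- function(g1, g2) {
  calls <- matrix(c(g1, g2), ncol = 1,
                  dimnames = list(paste0("s", seq_len(length(g1) + length(g2))),
                                  "L1"))
  geno_matrix(calls, rep(c("A", "B"), c(length(g1), length(g2))))
}

test_that("theta is 1 at a fixed difference and <= 0 for identical pops", {
  gm <- make_two_pop(rep("1/1", 10), rep("2/2", 10))
  expect_equal(unname(weir_cockerham_theta(gm)), 1)
  same <- c("1/1", "1/1", "1/2", "2/2", "1/2")
  gm2 <- make_two_pop(same, same)
  expect_lte(unname(weir_cockerham_theta(gm2)), 0)
})

test_that("theta matches the variance-components oracle on a worked table", {
  gm <- make_two_pop(c("1/1", "1/1", "1/2"), c("2/2", "2/2", "1/2"))
  expect_equal(unname(weir_cockerham_theta(gm)),
               oracle_wc_theta(c("1/1", "1/1", "1/2"),
                               c("2/2", "2/2", "1/2")),
               tolerance = 1e-12)
})

test_that("theta and pi agree with brute-force oracles on random tables", {
  set.seed(99)
  for (i in 1:100) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    p <- stats::runif(1, 0.15, 0.85)
    g1 <- geno_code(2L - stats::rbinom(n1, 1, p), 2L - stats::rbinom(n1, 1, p))
    g2 <- geno_code(2L - stats::rbinom(n2, 1, p + stats::runif(1, -0.1, 0.1)),
                    2L - stats::rbinom(n2, 1, p))
    gm <- geno_matrix(matrix(c(g1, g2), ncol = 1,
                             dimnames = list(NULL, "L1")),
                      rep(c("A", "B"), c(n1, n2)))
    th <- unname(weir_cockerham_theta(gm))
    or <- oracle_wc_theta(g1, g2)
    if (is.na(th)) { expect_true(is.na(or) || is.nan(or)); next }
    expect_equal(th, or, tolerance = 1e-12)
    # pi oracle: average pairwise difference over all called allele pairs
    al <- as.vector(geno_alleles(c(g1, g2)))
    diffs <- outer(al, al, "!=")
    pi_oracle <- sum(diffs) / (length(al) * (length(al) - 1))
    expect_equal(unname(site_pi(gm)), pi_oracle, tolerance = 1e-12)
  }
})

test_that("pi evaluates the unbiased pairwise-difference formula", {
  gm5 <- geno_matrix(matrix(rep("1/2", 5), ncol = 1,
                            dimnames = list(NULL, "L1")))
  expect_equal(unname(site_pi(gm5)), 50 / 90, tolerance = 1e-12)
  gm91 <- geno_matrix(matrix(c(rep("1/1", 4), "1/2"), ncol = 1,
                             dimnames = list(NULL, "L1")))
  expect_equal(unname(site_pi(gm91)), 0.2, tolerance = 1e-12)
  mono <- geno_matrix(matrix(rep("1/1", 6), ncol = 1,
                             dimnames = list(NULL, "L1")))
  expect_equal(unname(site_pi(mono)), 0)
})

test_that("monomorphic loci give undefined (not zero) theta", {
  gm <- make_two_pop(rep("1/1", 5), rep("1/1", 5))
  expect_true(is.na(weir_cockerham_theta(gm)))
  expect_error(weir_cockerham_theta(geno_matrix(
    matrix("1/1", 2, 1), c("A", "B", "C")[1:2])), NA)
})

test_that("one SNP per contig keeps the criterion maximiser", {
  stats <- data.frame(locus_id = c("a", "b", "c", "d"),
                      theta = c(0.1, 0.9, 0.4, 0.2),
                      pi = c(0.3, 0.1, 0.2, 0.4))
  records <- data.frame(locus_id = c("a", "b", "c", "d"),
                        contig = c("c1", "c1", "c1", "c2"),
                        position = c(10, 20, 30, 5))
  kept <- one_snp_per_contig(stats, records, "theta")
  expect_setequal(kept$locus_id, c("b", "d"))
  # singleton contigs pass through unchanged
  solo <- records; solo$contig <- paste0("c", 1:4)
  expect_identical(one_snp_per_contig(stats, solo, "theta")$locus_id,
                   stats$locus_id)
  # criterion ties resolve to the lowest position, deterministically
  tie <- stats; tie$theta <- 0.5
  expect_identical(one_snp_per_contig(tie, records, "theta")$locus_id,
                   c("a", "d"))
})

test_that("linkage thinning drops close pairs with rank priority", {
  stats <- data.frame(locus_id = c("top", "near", "far", "othergroup",
                                   "unmapped"))
  records <- data.frame(
    locus_id = stats$locus_id,
    linkage_group = c("lg1", "lg1", "lg1", "lg2", NA),
    cm_position = c(100, 140, 160, 100, NA))
  kept <- thin_by_linkage(stats, records, min_cm = 50)
  expect_setequal(kept$locus_id, c("top", "far", "othergroup", "unmapped"))
  # 60 cM apart: both kept
  records$cm_position[2] <- 160.0001  # just outside via 'far' spacing check
  kept2 <- thin_by_linkage(stats[1:2, , drop = FALSE], records[1:2, ],
                           min_cm = 50)
  expect_equal(nrow(kept2), 2)
  expect_error(thin_by_linkage(stats, records, min_cm = -1), "negative")
  # monotonicity: wider exclusion never retains more loci
  set.seed(4)
  big <- data.frame(locus_id = paste0("L", 1:40))
  recs <- data.frame(locus_id = big$locus_id,
                     linkage_group = sample(c("lg1", "lg2"), 40, TRUE),
                     cm_position = stats::runif(40, 0, 300))
  counts <- vapply(c(10, 30, 50, 80), function(cm)
    nrow(thin_by_linkage(big, recs, cm)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("panel selection applies the flank rule and top-N ranking", {
  set.seed(6)
  n <- 700
  stats <- data.frame(locus_id = sprintf("L%03d", 1:n),
                      theta = stats::runif(n), pi = stats::runif(n, 0, 0.5))
  records <- data.frame(locus_id = stats$locus_id, contig = stats$locus_id,
                        position = 1,
                        flank_left = strrep("A", 40),
                        flank_right = strrep("C", 40))
  records$flank_left[5] <- strrep("A", 14)   # short flank: rejected
  sel <- select_panels(stats, records, n_s = 303, n_p = 291)
  expect_length(sel$s_loci, 303)
  expect_length(sel$p_loci, 291)
  expect_identical(unname(sel$rejected[stats$locus_id[5]]), "flank")
  expect_false(stats$locus_id[5] %in% c(sel$s_loci, sel$p_loci))
  # S-loci really are the top theta among eligible, in rank order
  elig <- stats[-5, ]
  expect_identical(sel$s_loci,
                   elig$locus_id[order(-elig$theta,
                                       elig$locus_id)][1:303])
  # idempotent and permutation-invariant under the tie rule
  sel2 <- select_panels(stats[sample(n), ], records)
  expect_identical(sel2$s_loci, sel$s_loci)
  expect_identical(sel2$p_loci, sel$p_loci)
  # equal criterion everywhere: deterministic id order
  flat <- stats; flat$theta <- 0.5
  self <- select_panels(flat, records, n_s = 10, n_p = 5)
  expect_identical(self$s_loci, sort(elig$locus_id)[1:10])
  # shortfall reported, not silently truncated
  small <- select_panels(stats[1:50, ], records[1:50, ],
                         n_s = 303, n_p = 291)
  expect_true(all(c("s", "p") %in% names(small$shortfall)))
})
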