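test_that("concordance scoring covers the five comparison outcomes", {
  expect_identical(concordance_score("1/1", "1/1"), 2L)
  expect_identical(concordance_score(NA, "1/1"), 1L)
  expect_identical(concordance_score("1/1", NA), 0L)
  expect_identical(concordance_score(NA_character_, NA_character_), -1L)
  expect_identical(concordance_score("1/1", "1/2"), -2L)
})

test_that("score classes partition every locus across samples", {
  set.seed(41)
  ref <- random_gm(10, 8, miss = 0.2)
  new <- random_gm(10, 8, miss = 0.2)
  sc <- concordance_matrix(ref, new)
  fc <- filter_concordant(sc)
  expect_true(all(rowSums(fc$histogram) == nrow(sc)))
})

test_that("concordance filter keeps loci with fewer than five discordances", {
  ref_calls <- matrix("1/1", 85, 3,
                      dimnames = list(paste0("s", 1:85), c("ok", "edge",
                                                           "bad")))
  new_calls <- ref_calls
  new_calls[1:4, "edge"] <- "1/2"   # 4 discordant: kept
  new_calls[1:5, "bad"] <- "1/2"    # 5 discordant: dropped
  sc <- concordance_matrix(geno_matrix(ref_calls), geno_matrix(new_calls))
  fc <- filter_concordant(sc, max_discordant = 4)
  expect_setequal(fc$retained, c("ok", "edge"))
})

test_that("non-informative loci (monomorphic or empty) are dropped", {
  calls <- cbind(mono = rep("1/1", 10),
                 onehet = c("1/2", rep("1/1", 9)),
                 empty = rep(NA_character_, 10))
  rownames(calls) <- paste0("s", 1:10)
  expect_identical(filter_noninformative(geno_matrix(calls)), "onehet")
})

test_that("exact heterozygote-excess p-values match a permutation oracle", {
  set.seed(42)
  cases <- list(c(n_het = 5, n_a1 = 5, n = 5),
                c(n_het = 3, n_a1 = 6, n = 8),
                c(n_het = 8, n_a1 = 10, n = 10),
                c(n_het = 2, n_a1 = 9, n = 12))
  for (cs in cases) {
    exact <- hwe_excess_het_p(cs["n_het"], cs["n_a1"], cs["n"])
    perm <- oracle_hwe_excess_p(cs["n_het"], cs["n_a1"], cs["n"])
    expect_lt(abs(exact - perm), 0.02)
  }
})

test_that("excess-het and missingness filters drop the right loci", {
  all_het <- matrix("1/2", 50, 1, dimnames = list(paste0("s", 1:50), "dup"))
  hw_ok <- matrix(c(rep("1/1", 13), rep("1/2", 24), rep("2/2", 13)), 50, 1,
                  dimnames = list(paste0("s", 1:50), "fine"))
  missing30 <- matrix(c(rep("1/1", 9), rep("1/2", 18), rep("2/2", 8),
                        rep(NA_character_, 15)), 50, 1,
                      dimnames = list(paste0("s", 1:50), "patchy"))
  gm <- geno_matrix(cbind(all_het, hw_ok, missing30))
  res <- hwe_excess_het_filter(gm)
  expect_identical(unname(res$removed["dup"]), "excess_het")
  expect_identical(unname(res$removed["patchy"]), "missingness")
  expect_true("fine" %in% res$retained)
  expect_lt(res$p_values["dup"], 1e-10)
  # monomorphic loci pass through (test undefined)
  mono <- geno_matrix(matrix("1/1", 20, 1,
                             dimnames = list(paste0("s", 1:20), "mono")))
  expect_identical(hwe_excess_het_filter(mono)$retained, "mono")
})

test_that("modal imputation completes the matrix without touching calls", {
  calls <- cbind(L1 = c("1/1", "1/1", "1/1", "1/2", NA, NA),
                 L2 = c("1/2", "1/2", NA, "2/2", "2/2", NA))
  rownames(calls) <- paste0("s", 1:6)
  gm <- geno_matrix(calls, rep("A", 6))
  imp <- impute_most_frequent(gm)
  expect_false(anyNA(imp$calls))
  expect_identical(imp$calls[5:6, "L1"], c(s5 = "1/1", s6 = "1/1"))
  # modal tie at L2 (2 x "1/2", 2 x "2/2"): smallest allele pair wins
  expect_identical(unname(imp$calls[6, "L2"]), "1/2")
  called <- !is.na(calls)
  expect_identical(imp$calls[called], calls[called])
  # complete input passes through unchanged
  expect_identical(impute_most_frequent(imp)$calls, imp$calls)
  # imputation is per-population and fails loudly with nothing to copy
  gm2 <- geno_matrix(calls, c(rep("A", 5), "B"))
  expect_error(impute_most_frequent(gm2), "population B")
})

test_that("imputation preserves called-genotype allele frequencies", {
  set.seed(43)
  gm <- random_gm(15, 10, miss = 0.3)
  freq_called <- function(calls) {
    apply(calls, 2, function(g) {
      al <- geno_alleles(g[!is.na(g)])
      mean(al == 1)
    })
  }
  before <- freq_called(gm$calls)
  imp <- impute_most_frequent(gm)
  # recompute over the originally-called cells only: untouched
  masked <- imp$calls
  masked[is.na(gm$calls)] <- NA
  expect_identical(freq_called(masked), before)
})

test_that("missingness profile decomposes the overall rate", {
  set.seed(44)
  gm <- random_gm(10, 6, miss = 0.25)
  prof <- missingness_profile(gm)
  expect_equal(mean(prof$per_sample), prof$overall)
  expect_equal(mean(prof$per_locus), prof$overall)
  complete <- impute_most_frequent(gm)
  expect_true(all(missingness_profile(complete)$per_locus == 0))
  gm$calls[3, ] <- NA
  expect_equal(unname(missingness_profile(gm)$per_sample[3]), 1)
})

test_that("the sequential QC pipeline logs every removal with a reason", {
  set.seed(45)
  n <- 40
  ref_calls <- matrix(sample(c("1/1", "1/2", "2/2"), n * 6, TRUE,
                             prob = c(.3, .4, .3)), n, 6,
                      dimnames = list(paste0("s", 1:n), paste0("L", 1:6)))
  ref_calls[, "L3"] <- "1/1"     # concordant with the non-informative L3
  new_calls <- ref_calls
  new_calls[1:6, "L2"] <- ifelse(ref_calls[1:6, "L2"] == "1/1", "2/2",
                                 "1/1")              # discordant locus
  new_calls[, "L3"] <- "1/1"                          # non-informative
  new_calls[, "L4"] <- c(rep("1/2", 36), "1/1", "1/1",
                         "2/2", "2/2")                # strong excess het
  new_calls[1:20, "L5"] <- NA                         # 50% missing
  res <- qc_pipeline(geno_matrix(new_calls), geno_matrix(ref_calls),
                     max_discordant = 4)
  expect_false(any(c("L2", "L3", "L4", "L5") %in% res$retained))
  expect_true("L1" %in% res$retained)
  expect_setequal(
    res$log$filter[match(c("L2", "L3", "L4", "L5"), res$log$locus_id)],
    c("concordance", "informative", "hwe_missingness", "hwe_missingness"))
})
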