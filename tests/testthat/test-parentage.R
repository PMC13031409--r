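test_that("Mendelian transmission probabilities are exact", {
  expect_equal(transmission_prob("1/1", "1/1", "1/1"), 1)
  expect_equal(transmission_prob("1/2", "1/1", "2/2"), 1)
  expect_equal(transmission_prob("1/1", "1/2", "1/2"), 0.25)
  expect_equal(transmission_prob("1/2", "1/2", "1/2"), 0.5)
  expect_equal(transmission_prob("2/2", "1/2", "1/2"), 0.25)
  expect_equal(transmission_prob("2/2", "1/1", "1/2"), 0)
})

test_that("LOD equals exhaustive-enumeration oracle on small cases", {
  set.seed(71)
  for (i in 1:25) {
    nl <- sample(1:2, 1)
    p <- stats::runif(nl, 0.2, 0.8)
    e <- sample(c(0.01, 0.02, 0.1), 1)
    g <- function() sample(c("1/1", "1/2", "2/2"), nl, TRUE)
    go <- g(); gm <- g(); gf <- g()
    expect_lt(abs(lod_pair(go, gm, gf, p, e) -
                    oracle_lod(go, gm, gf, p, e)), 1e-12)
  }
})

test_that("zero genotyping error makes incompatibilities hard exclusions", {
  # offspring carries an allele absent from both candidates
  expect_identical(lod_pair("1/2", "1/1", "1/1", 0.5, e = 0), -Inf)
  expect_identical(lod_pair("2/2", "1/1", "1/2", 0.5, e = 0), -Inf)
  # true parents with informative loci: positive LOD
  expect_gt(lod_pair(c("1/2", "1/1"), c("1/1", "1/1"), c("2/2", "1/1"),
                     c(0.5, 0.9), e = 0), 0)
  # with e > 0 every configuration stays finite
  expect_true(is.finite(lod_pair("1/2", "1/1", "1/1", 0.5, e = 0.02)))
  # untyped everywhere: undefined
  expect_true(is.na(lod_pair(NA_character_, "1/1", "1/1", 0.5, 0.02)))
})

test_that("pair ranking computes Delta from the top two LODs", {
  set.seed(72)
  nl <- 20
  p <- stats::runif(nl, 0.3, 0.7)
  mothers <- matrix(sample(c("1/1", "1/2", "2/2"), 3 * nl, TRUE), 3, nl)
  fathers <- matrix(sample(c("1/1", "1/2", "2/2"), 4 * nl, TRUE), 4, nl)
  off <- mothers[2, ]  # arbitrary genotypes; ranking is what is tested
  res <- rank_and_delta(off, mothers, fathers, p, e = 0.02)
  lods <- outer(1:3, 1:4, Vectorize(function(m, f)
    lod_pair(off, mothers[m, ], fathers[f, ], p, 0.02)))
  srt <- sort(lods, decreasing = TRUE)
  expect_equal(res$best$lod, srt[1], tolerance = 1e-9)
  expect_equal(res$delta, srt[1] - srt[2], tolerance = 1e-9)
  expect_gte(res$delta, 0)
  # adding a weak candidate cannot increase Delta
  fathers2 <- rbind(fathers, sample(c("1/1", "1/2", "2/2"), nl, TRUE))
  res2 <- rank_and_delta(off, mothers, fathers2, p, e = 0.02)
  expect_lte(res2$delta, res$delta + 1e-9)
  # a single candidate pair: Delta equals its LOD by convention
  solo <- rank_and_delta(off, mothers[1, , drop = FALSE],
                         fathers[1, , drop = FALSE], p, e = 0.02)
  expect_equal(solo$delta, solo$best$lod)
})

test_that("critical Delta matches the brute-force threshold scan", {
  set.seed(73)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    rec <- data.frame(delta = round(stats::rexp(n, 0.5), 2),
                      correct = stats::runif(n) < 0.7)
    for (conf in c(0.8, 0.95)) {
      expect_identical(critical_delta(rec, conf),
                       oracle_critical_delta(rec$delta, rec$correct, conf))
    }
  }
  all_right <- data.frame(delta = c(1, 2, 3), correct = TRUE)
  expect_identical(critical_delta(all_right, 0.8), 0)
  expect_identical(critical_delta(all_right, 0.95), 0)
})

test_that("strict critical Delta is never below the relaxed one", {
  set.seed(74)
  p1 <- stats::runif(30, 0.3, 0.7)
  sim <- simulate_assignment(p1, parentage_sim_config(
    n_offspring = 150, n_males = 15, n_females = 15, prop_typed = 0.8,
    error_rate = 0.02, seed = 75))
  s <- sim$summary
  expect_gte(s$critical_delta[s$confidence == 0.95],
             s$critical_delta[s$confidence == 0.80])
  # identical seed, identical records
  sim2 <- simulate_assignment(p1, parentage_sim_config(
    n_offspring = 150, n_males = 15, n_females = 15, prop_typed = 0.8,
    error_rate = 0.02, seed = 75))
  expect_identical(sim$records, sim2$records)
})

test_that("correct-assignment rate is bounded by the sampling proportion", {
  set.seed(76)
  p1 <- stats::runif(40, 0.3, 0.7)
  sim <- simulate_assignment(p1, parentage_sim_config(
    n_offspring = 200, n_males = 10, n_females = 10, prop_sampled = 0.5,
    prop_typed = 1, error_rate = 0, seed = 77))
  rate <- mean(sim$records$correct)
  expect_lte(rate, 0.5 + 3 * sqrt(0.25 / 200))
  expect_false(any(sim$records$correct & !sim$records$sampled))
})

test_that("a fully typed error-free high-He panel assigns perfectly", {
  set.seed(78)
  p1 <- stats::runif(112, 0.35, 0.65)
  sim <- simulate_assignment(p1, parentage_sim_config(
    n_offspring = 200, n_males = 30, n_females = 30, prop_sampled = 1,
    prop_typed = 1, error_rate = 0, seed = 79))
  expect_equal(mean(sim$records$correct), 1)
})

test_that("assignment rate rises with typed loci; Delta falls", {
  set.seed(80)
  p1 <- stats::runif(60, 0.35, 0.65)
  cfg <- parentage_sim_config(n_offspring = 120, n_males = 12,
                              n_females = 12, error_rate = 0.02,
                              seed = 81)
  grid <- sensitivity_grid(p1, typed_grid = c(0.3, 0.9),
                           min_typed_grid = 0.25, cfg = cfg)
  strict <- grid[grid$confidence == 0.95, ]
  expect_lte(strict$assignment_rate[strict$prop_typed == 0.3],
             strict$assignment_rate[strict$prop_typed == 0.9] + 0.1)
  expect_gte(strict$critical_delta[strict$prop_typed == 0.3] + 1e-9,
             strict$critical_delta[strict$prop_typed == 0.9])
})
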