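# Biallelic genotype coding used internally by the parentage machinery:
# 1 = "1/1", 2 = "1/2", 3 = "2/2", 4 = missing.
GENO_CODES <- c("1/1", "1/2", "2/2")

geno_to_idx <- function(g) {
  idx <- match(g, GENO_CODES)
  idx[is.na(idx)] <- 4L
  if (is.matrix(g)) dim(idx) <- dim(g)
  idx
}

hw_probs <- function(p) c(p^2, 2 * p * (1 - p), (1 - p)^2)

#' Mendelian transmission probability
#'
#' Probability of an offspring genotype given both parental genotypes at
#' one biallelic locus under exact Mendelian segregation.
#'
#' @param g_off,g_mother,g_father Genotype codes (`"1/1"`, `"1/2"`,
#'   `"2/2"`).
#' @return Transmission probability.
#' @export
transmission_prob <- function(g_off, g_mother, g_father) {
  T <- mendel_array()
  T[geno_to_idx(g_off), geno_to_idx(g_mother), geno_to_idx(g_father)]
}

# 3 x 3 x 3 array T[o, m, f]; gamete P(allele1 | genotype) = (1, 1/2, 0)
mendel_array <- function() {
  gam <- c(1, 0.5, 0)
  T <- array(0, c(3, 3, 3))
  for (m in 1:3) for (f in 1:3) {
    pm <- gam[m]; pf <- gam[f]
    T[1, m, f] <- pm * pf
    T[2, m, f] <- pm * (1 - pf) + (1 - pm) * pf
    T[3, m, f] <- (1 - pm) * (1 - pf)
  }
  T
}

# single-parent transmission: one allele from the known parent, the other
# drawn from population frequency p; T1[o, parent]
single_parent_array <- function(p) {
  gam <- c(1, 0.5, 0)
  T1 <- matrix(0, 3, 3)
  for (f in 1:3) {
    pf <- gam[f]
    T1[1, f] <- pf * p
    T1[2, f] <- pf * (1 - p) + (1 - pf) * p
    T1[3, f] <- (1 - pf) * (1 - p)
  }
  T1
}

# per-locus LOD contribution table L[o, m, f] (4^3 with missing = 0
# contribution), under the whole-genotype replacement error model:
# each observed genotype is, independently with probability e, a random
# Hardy-Weinberg genotype.  Marginalising the three error indicators:
#   L1/(HW(m) HW(f)) = (1-e)^3 T(o|m,f)
#                    + (1-e)^2 e [T1(o|m) + T1(o|f)]
#                    + (e^3 + 3 e^2 (1-e) + (1-e)^2 e) HW(o)
# and LOD contribution = ln of that over HW(o).
lod_locus_table <- function(p, e) {
  hw <- hw_probs(p)
  T <- mendel_array()
  T1 <- single_parent_array(p)
  L <- array(0, c(4, 4, 4))
  w_hw <- e^3 + 3 * e^2 * (1 - e) + (1 - e)^2 * e
  for (o in 1:3) for (m in 1:3) for (f in 1:3) {
    num <- (1 - e)^3 * T[o, m, f] +
      (1 - e)^2 * e * (T1[o, m] + T1[o, f]) +
      w_hw * hw[o]
    L[o, m, f] <- log(num / hw[o])
  }
  L  # any index 4 (missing) leaves the initialised 0 contribution
}

#' Parent-pair LOD score
#'
#' Natural-log likelihood ratio of "the candidate pair are the parents"
#' against "the offspring is an unrelated population member", summed over
#' loci typed in all three individuals. The genotyping-error model replaces
#' each observed genotype, independently with probability `e`, by a random
#' Hardy-Weinberg genotype; `e > 0` keeps every LOD finite, while `e = 0`
#' makes Mendelian incompatibilities hard exclusions (LOD `-Inf`).
#'
#' @param g_off,g_mother,g_father Genotype-code vectors over the same loci.
#' @param p1 Allele-1 frequency per locus (population baseline).
#' @param e Genotyping-error rate (default 0.02).
#' @return The LOD score; `NA` when no locus is typed in all three.
#' @export
lod_pair <- function(g_off, g_mother, g_father, p1, e = 0.02) {
  stopifnot(length(g_off) == length(g_mother),
            length(g_off) == length(g_father),
            length(g_off) == length(p1))
  o <- geno_to_idx(g_off); m <- geno_to_idx(g_mother)
  f <- geno_to_idx(g_father)
  shared <- o != 4L & m != 4L & f != 4L
  if (!any(shared)) return(NA_real_)
  tot <- 0
  for (li in which(shared)) {
    L <- lod_locus_table(p1[li], e)
    tot <- tot + L[o[li], m[li], f[li]]
  }
  tot
}

#' Rank candidate parent pairs and compute the Delta statistic
#'
#' Scores every mother x father pair for one offspring, and returns the
#' best and second-best pairs with `delta` = difference of their LOD
#' scores. With a single candidate pair, `delta` equals its LOD
#' (convention, so assignment remains defined).
#'
#' @param g_off Offspring genotype-code vector.
#' @param mothers,fathers Genotype matrices (candidates x loci).
#' @param p1 Allele-1 frequency per locus.
#' @param e Genotyping-error rate.
#' @return List: `best` (mother, father indices, lod), `second`, `delta`.
#' @export
rank_and_delta <- function(g_off, mothers, fathers, p1, e = 0.02) {
  lods <- precompute_lod_tables(p1, e)
  o <- geno_to_idx(g_off)
  lodmat <- pair_lod_matrix(o, geno_to_idx(mothers), geno_to_idx(fathers),
                            lods)
  top2_delta(lodmat)
}

# list of 4x4 matrices per locus: L[[l]][m, f] given observed offspring o;
# here stored as full 4x4x4 arrays, sliced later
precompute_lod_tables <- function(p1, e) {
  lapply(p1, lod_locus_table, e = e)
}

# LOD of every mother x father pair, vectorised over the candidate grid
pair_lod_matrix <- function(o_idx, m_idx, f_idx, lods) {
  nm <- nrow(m_idx); nf <- nrow(f_idx)
  acc <- matrix(0, nm, nf)
  for (li in seq_along(lods)) {
    if (o_idx[li] == 4L) next
    M <- lods[[li]][o_idx[li], , ]      # 4 x 4 (mother x father)
    acc <- acc + M[m_idx[, li], f_idx[, li]]
  }
  acc
}

top2_delta <- function(lodmat) {
  best_i <- which.max(lodmat)
  best <- lodmat[best_i]
  bm <- (best_i - 1) %% nrow(lodmat) + 1
  bf <- (best_i - 1) %/% nrow(lodmat) + 1
  if (length(lodmat) == 1) {
    return(list(best = list(mother = bm, father = bf, lod = best),
                second = NULL, delta = best))
  }
  second <- max(lodmat[-best_i])
  list(best = list(mother = bm, father = bf, lod = best),
       second = list(lod = second), delta = best - second)
}

#' Configuration for a parentage-assignment simulation
#'
#' @param n_offspring Simulated offspring (default 10000).
#' @param n_males,n_females Candidate pool sizes (default 100 each).
#' @param prop_sampled Proportion of offspring whose true parent pair is
#'   present in the candidate pool (default 1).
#' @param prop_typed Per-locus typing probability for offspring (default
#'   0.9).
#' @param error_rate Genotyping-error rate (default 0.02).
#' @param min_typed_frac Offspring typed at fewer than this fraction of
#'   loci are dropped (default 0.5).
#' @param confidences Relaxed and strict confidence levels (default 0.80,
#'   0.95).
#' @param seed Integer seed.
#' @return A `parentage_sim_config` list.
#' @export
parentage_sim_config <- function(n_offspring = 10000, n_males = 100,
                                 n_females = 100, prop_sampled = 1,
                                 prop_typed = 0.9, error_rate = 0.02,
                                 min_typed_frac = 0.5,
                                 confidences = c(0.80, 0.95), seed = 1) {
  stopifnot(prop_sampled > 0, prop_sampled <= 1,
            prop_typed > 0, prop_typed <= 1,
            error_rate >= 0, error_rate < 1,
            n_males >= 1, n_females >= 1)
  structure(list(n_offspring = as.integer(n_offspring),
                 n_males = as.integer(n_males),
                 n_females = as.integer(n_females),
                 prop_sampled = prop_sampled, prop_typed = prop_typed,
                 error_rate = error_rate,
                 min_typed_frac = min_typed_frac,
                 confidences = confidences, seed = as.integer(seed)),
            class = "parentage_sim_config")
}

#' Simulate offspring and score parentage assignment
#'
#' Draws candidate mothers and fathers from Hardy-Weinberg genotype
#' frequencies, creates each offspring by Mendelian transmission from a
#' random true pair, masks offspring genotypes as untyped with probability
#' `1 - prop_typed`, corrupts each typed genotype with probability
#' `error_rate` (random Hardy-Weinberg replacement — the same error model
#' the LOD assumes), drops offspring typed at fewer than `min_typed_frac`
#' of loci, removes the true parents from the candidate pool with
#' probability `1 - prop_sampled`, and ranks all pairs by LOD.
#'
#' Candidate parents are treated as fully typed (broodstock-quality
#' genotypes); offspring typing is the sensitivity axis.
#'
#' @param p1 Allele-1 frequency per locus (the panel).
#' @param cfg A [parentage_sim_config()].
#' @return List of class `parentage_sim`: `records` (one row per
#'   offspring: lod_best, lod_second, delta, correct, sampled, dropped)
#'   and `summary` (assignment rate and critical Delta per confidence).
#' @export
simulate_assignment <- function(p1, cfg = parentage_sim_config()) {
  stopifnot(inherits(cfg, "parentage_sim_config"))
  set.seed(cfg$seed)
  nl <- length(p1)
  draw_pool <- function(n) {
    g <- matrix(0L, n, nl)
    for (li in seq_len(nl))
      g[, li] <- sample.int(3, n, replace = TRUE, prob = hw_probs(p1[li]))
    g
  }
  males <- draw_pool(cfg$n_males)
  females <- draw_pool(cfg$n_females)
  gam <- c(1, 0.5, 0)
  lods <- precompute_lod_tables(p1, cfg$error_rate)
  n_off <- cfg$n_offspring
  true_m <- sample.int(cfg$n_females, n_off, replace = TRUE)
  true_f <- sample.int(cfg$n_males, n_off, replace = TRUE)
  sampled <- stats::runif(n_off) <= cfg$prop_sampled
  rec <- data.frame(offspring = seq_len(n_off), lod_best = NA_real_,
                    lod_second = NA_real_, delta = NA_real_,
                    correct = FALSE, sampled = sampled, dropped = FALSE)
  for (i in seq_len(n_off)) {
    pm <- gam[females[true_m[i], ]]; pf <- gam[males[true_f[i], ]]
    a1 <- stats::rbinom(nl, 1, pm); a2 <- stats::rbinom(nl, 1, pf)
    o <- 3L - a1 - a2                     # 2 allele-1 copies -> code 1
    typed <- stats::runif(nl) <= cfg$prop_typed
    err <- typed & stats::runif(nl) < cfg$error_rate
    for (li in which(err))
      o[li] <- sample.int(3, 1, prob = hw_probs(p1[li]))
    o[!typed] <- 4L
    if (mean(typed) < cfg$min_typed_frac) {
      rec$dropped[i] <- TRUE
      next
    }
    lodmat <- pair_lod_matrix(o, females, males, lods)
    if (!sampled[i]) {
      lodmat[true_m[i], ] <- -Inf
      lodmat[, true_f[i]] <- -Inf
    }
    td <- top2_delta(lodmat)
    rec$lod_best[i] <- td$best$lod
    rec$lod_second[i] <- if (is.null(td$second)) NA_real_ else td$second$lod
    rec$delta[i] <- td$delta
    rec$correct[i] <- sampled[i] && td$best$mother == true_m[i] &&
      td$best$father == true_f[i]
  }
  summary <- do.call(rbind, lapply(cfg$confidences, function(conf) {
    dstar <- critical_delta(rec, conf)
    assigned <- !rec$dropped & !is.na(rec$delta) & rec$delta >= dstar
    data.frame(confidence = conf, critical_delta = dstar,
               assignment_rate = mean(rec$correct & assigned),
               n_offspring = n_off)
  }))
  structure(list(records = rec, summary = summary, config = cfg),
            class = "parentage_sim")
}

#' @export
print.parentage_sim <- function(x, ...) {
  cat(sprintf("parentage_sim: %d offspring, %d x %d candidates\n",
              x$config$n_offspring, x$config$n_females, x$config$n_males))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Critical Delta at a confidence level
#'
#' The smallest threshold `d` such that, among scored offspring with
#' `delta >= d`, the fraction whose best pair is the true pair reaches the
#' confidence level; 0 when the unthresholded fraction already does.
#' Returns `Inf` when no threshold achieves the confidence.
#'
#' @param records Records frame from [simulate_assignment()] (columns
#'   `delta`, `correct`; dropped/unscored rows are ignored).
#' @param confidence Target confidence (e.g. 0.80 or 0.95).
#' @return The critical Delta.
#' @export
critical_delta <- function(records, confidence) {
  ok <- !is.na(records$delta)
  d <- records$delta[ok]; corr <- records$correct[ok]
  if (!length(d)) return(Inf)
  if (mean(corr) >= confidence) return(0)
  # scan candidate thresholds in increasing order; fraction correct among
  # delta >= d is monotone in the scanned prefix removals
  ord <- order(d)
  d_sorted <- d[ord]; c_sorted <- corr[ord]
  n <- length(d)
  # suffix sums: correct among indices i..n
  suf_correct <- rev(cumsum(rev(c_sorted)))
  suf_n <- n - seq_len(n) + 1
  frac <- suf_correct / suf_n
  # a threshold must include whole tie groups: only the first index of
  # each distinct delta value is a valid cut point
  valid <- c(TRUE, diff(d_sorted) > 0)
  hit <- which(frac >= confidence & valid)
  if (!length(hit)) return(Inf)
  d_sorted[hit[1]]
}

#' Sensitivity grids over typing, minimum-typed and sampling proportions
#'
#' Re-runs [simulate_assignment()] across grids of the proportion of typed
#' loci, the minimum-typed-loci threshold and the proportion of sampled
#' parents, for one panel, and tabulates assignment rate and critical
#' Delta per grid point and confidence.
#'
#' @param p1 Allele-1 frequency per locus.
#' @param typed_grid Values of `prop_typed` (default 0.5-0.9).
#' @param min_typed_grid Values of `min_typed_frac` (default 0.5).
#' @param sampled_grid Values of `prop_sampled` (default 1).
#' @param cfg Base [parentage_sim_config()] (its typed/min-typed/sampled
#'   fields are overridden by the grids; the seed is advanced
#'   deterministically per grid point).
#' @return Data frame: one row per grid point per confidence.
#' @export
sensitivity_grid <- function(p1, typed_grid = seq(0.5, 0.9, by = 0.1),
                             min_typed_grid = 0.5, sampled_grid = 1,
                             cfg = parentage_sim_config()) {
  rows <- list(); k <- 0L
  for (t in typed_grid) for (mt in min_typed_grid) for (s in sampled_grid) {
    k <- k + 1L
    cfg_i <- cfg
    cfg_i$prop_typed <- t; cfg_i$min_typed_frac <- mt
    cfg_i$prop_sampled <- s
    cfg_i$seed <- cfg$seed + k
    sim <- simulate_assignment(p1, cfg_i)
    sm <- sim$summary
    sm$prop_typed <- t; sm$min_typed_frac <- mt; sm$prop_sampled <- s
    rows[[k]] <- sm
  }
  do.call(rbind, rows)
}
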