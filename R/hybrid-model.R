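#' Gene-pair origin proportions of the six two-generation hybrid classes
#'
#' Each class is characterised by the proportions of loci at which an
#' individual carries two A-origin gene copies, one of each, or two
#' B-origin copies: phi = (phi_AA, phi_AB, phi_BB). The six classes of the
#' two-generation model are the two pure parentals, F1, F2 and the two
#' first-generation backcrosses; their phi rows follow from enumerating
#' gamete origins over two generations of crossing.
#'
#' @param prior Per-class prior probabilities (default uniform).
#' @return A list of class `hybrid_model`: `phi` (6 x 3 matrix) and
#'   `prior`.
#' @export
hybrid_classes <- function(prior = NULL) {
  phi <- rbind(PureA = c(1, 0, 0),
               PureB = c(0, 0, 1),
               F1    = c(0, 1, 0),
               F2    = c(0.25, 0.5, 0.25),
               BxA   = c(0.5, 0.5, 0),
               BxB   = c(0, 0.5, 0.5))
  colnames(phi) <- c("AA", "AB", "BB")
  if (is.null(prior)) prior <- rep(1 / 6, 6)
  stopifnot(length(prior) == 6, abs(sum(prior) - 1) < 1e-9)
  names(prior) <- rownames(phi)
  structure(list(phi = phi, prior = prior), class = "hybrid_model")
}

#' Expected genotype probabilities under a hybrid class
#'
#' Given parental allele-frequency vectors p_A and p_B at one locus and a
#' class's gene-pair origin proportions, the probability of each unordered
#' genotype is
#' `P(i,i) = phi_AA p_Ai^2 + phi_AB p_Ai p_Bi + phi_BB p_Bi^2` and
#' `P(i,j) = phi_AA 2 p_Ai p_Aj + phi_AB (p_Ai p_Bj + p_Aj p_Bi) +
#'  phi_BB 2 p_Bi p_Bj` for i != j.
#'
#' @param phi_row Length-3 vector `(phi_AA, phi_AB, phi_BB)` (a row of
#'   `hybrid_classes()$phi`).
#' @param p_a,p_b Named allele-frequency vectors for the two parental
#'   populations (must sum to 1).
#' @return Named probability vector over genotype codes `"i/j"`, summing
#'   to 1.
#' @export
expected_genotype_probs <- function(phi_row, p_a, p_b) {
  if (abs(sum(p_a) - 1) > 1e-6 || abs(sum(p_b) - 1) > 1e-6)
    stop("allele frequencies must sum to 1")
  alleles <- sort(unique(as.integer(c(names(p_a), names(p_b)))))
  pa <- stats::setNames(rep(0, length(alleles)), alleles)
  pb <- pa
  pa[names(p_a)] <- p_a; pb[names(p_b)] <- p_b
  out <- numeric(0)
  for (ii in seq_along(alleles)) {
    for (jj in ii:length(alleles)) {
      i <- as.character(alleles[ii]); j <- as.character(alleles[jj])
      p <- if (ii == jj)
        phi_row[1] * pa[i]^2 + phi_row[2] * pa[i] * pb[i] +
          phi_row[3] * pb[i]^2
      else
        phi_row[1] * 2 * pa[i] * pa[j] +
          phi_row[2] * (pa[i] * pb[j] + pa[j] * pb[i]) +
          phi_row[3] * 2 * pb[i] * pb[j]
      out[paste0(alleles[ii], "/", alleles[jj])] <- unname(p)
    }
  }
  out
}

#' Simulate individuals of one hybrid class by gamete drawing
#'
#' Pedigree-faithful simulation: pure parentals draw both gametes from
#' their population's allele frequencies; an F1 draws one gamete from each;
#' an F2 is the offspring of two independently simulated F1 parents; a
#' backcross is the offspring of an F1 and a pure parent, with Mendelian
#' segregation at each (unlinked) locus.
#'
#' @param freqs A [baseline_freqs()] object.
#' @param class One of `"PureA", "PureB", "F1", "F2", "BxA", "BxB"`.
#' @param n Number of individuals (default 30).
#' @param seed Integer seed.
#' @param prefix Sample-id prefix.
#' @return A [geno_matrix()] of `n` simulated individuals.
#' @export
simulate_class <- function(freqs, class, n = 30, seed = 1,
                           prefix = class) {
  stopifnot(inherits(freqs, "baseline_freqs"), n >= 1)
  if (!length(freqs$loci)) stop("empty panel")
  class <- match.arg(class, c("PureA", "PureB", "F1", "F2", "BxA", "BxB"))
  set.seed(seed)
  nl <- length(freqs$loci)
  draw_gamete_pop <- function(pop) {
    vapply(freqs$freq, function(f) {
      v <- f[[pop]]
      as.integer(sample(names(v), 1, prob = v))
    }, integer(1))
  }
  pure <- function(pop) cbind(draw_gamete_pop(pop), draw_gamete_pop(pop))
  f1 <- function() cbind(draw_gamete_pop(freqs$pops[1]),
                         draw_gamete_pop(freqs$pops[2]))
  gamete_from <- function(parent)   # Mendelian segregation, unlinked loci
    parent[cbind(seq_len(nl), sample(1:2, nl, replace = TRUE))]
  draw_one <- function() {
    switch(class,
           PureA = pure(freqs$pops[1]),
           PureB = pure(freqs$pops[2]),
           F1 = f1(),
           F2 = cbind(gamete_from(f1()), gamete_from(f1())),
           BxA = cbind(gamete_from(f1()), gamete_from(pure(freqs$pops[1]))),
           BxB = cbind(gamete_from(f1()), gamete_from(pure(freqs$pops[2]))))
  }
  calls <- matrix(NA_character_, n, nl,
                  dimnames = list(paste0(prefix, "_", seq_len(n)),
                                  freqs$loci))
  for (i in seq_len(n)) {
    g <- draw_one()
    calls[i, ] <- geno_code(g[, 1], g[, 2])
  }
  geno_matrix(calls)
}

# smoothed per-locus allele frequencies: eps = 1/(2n+2) pseudo-count per
# allele unless overridden
smoothed_freqs <- function(freqs, eps = NULL) {
  lapply(seq_along(freqs$loci), function(li) {
    f <- freqs$freq[[li]]
    lapply(stats::setNames(freqs$pops, freqs$pops), function(p) {
      v <- f[[p]]
      n2 <- 2 * freqs$n[li, p]
      e <- if (is.null(eps)) 1 / (n2 + 2) else eps
      (v * n2 + e) / (n2 + e * length(v))
    })
  })
}

#' Classify samples into the six hybrid classes (plug-in likelihood)
#'
#' Per sample, the log-likelihood of each class is the sum over called
#' loci of the log expected genotype probability given the baseline
#' parental allele frequencies; the posterior is prior x likelihood,
#' normalised. This is a plug-in approximation of the full Bayesian
#' classifier: parental allele frequencies are fixed from the curated
#' baseline rather than estimated jointly with class membership, which is
#' deterministic given the baseline and auditable by enumeration.
#' Frequencies are smoothed with a pseudo-count (default `1/(2n+2)` per
#' allele) so unseen alleles never yield -Inf log-likelihoods.
#'
#' @param gm A [geno_matrix()] of samples to classify.
#' @param freqs A [baseline_freqs()] object covering the panel loci.
#' @param model A `hybrid_classes()` model.
#' @param min_loci Minimum called loci to classify (default 1); samples
#'   below it get `NA` posteriors and `assigned_class = "unclassified"`.
#' @param eps Smoothing pseudo-count override.
#' @return Data frame of class `hybrid_posteriors`: one row per sample
#'   with the six posterior columns, `n_loci_used`, `assigned_class`,
#'   `max_posterior`.
#' @export
classify_hybrids <- function(gm, freqs, model = hybrid_classes(),
                             min_loci = 1, eps = NULL) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(freqs, "baseline_freqs"))
  loci <- gm_loci(gm)
  missing_loci <- setdiff(loci, freqs$loci)
  if (length(missing_loci))
    stop("loci absent from baseline: ",
         paste(utils::head(missing_loci, 5), collapse = ", "))
  sf <- smoothed_freqs(freqs, eps)
  names(sf) <- freqs$loci
  classes <- rownames(model$phi)
  # per-locus log-probability lookup tables: genotype code -> 6 classes
  tabs <- lapply(loci, function(l) {
    f <- sf[[l]]
    probs <- vapply(classes, function(cl)
      expected_genotype_probs(model$phi[cl, ], f[[freqs$pops[1]]],
                              f[[freqs$pops[2]]]),
      numeric(length(expected_genotype_probs(model$phi[1, ],
                                             f[[freqs$pops[1]]],
                                             f[[freqs$pops[2]]]))))
    log(probs)   # genotypes x classes
  })
  names(tabs) <- loci
  ns <- nrow(gm$calls)
  post <- matrix(NA_real_, ns, 6, dimnames = list(gm_samples(gm), classes))
  n_used <- integer(ns)
  for (si in seq_len(ns)) {
    ll <- rep(log(model$prior), 1)
    used <- 0L
    for (li in seq_along(loci)) {
      g <- gm$calls[si, li]
      if (is.na(g)) next
      tab <- tabs[[li]]
      if (!g %in% rownames(tab)) next  # allele unseen in baseline: skip
      ll <- ll + tab[g, ]
      used <- used + 1L
    }
    n_used[si] <- used
    if (used >= min_loci) {
      m <- max(ll)
      w <- exp(ll - m)
      post[si, ] <- w / sum(w)
    }
  }
  assigned <- ifelse(n_used >= min_loci,
                     classes[max.col(replace(post, is.na(post), -1))],
                     "unclassified")
  out <- data.frame(sample_id = gm_samples(gm), post,
                    n_loci_used = n_used, assigned_class = assigned,
                    max_posterior = apply(post, 1, function(x)
                      if (anyNA(x)) NA_real_ else max(x)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("hybrid_posteriors", "data.frame")
  out
}

#' Hybrid-classification power analysis
#'
#' For each replicate, simulates `n_per_class` individuals of every class,
#' classifies them against the baseline, and tabulates per class and
#' posterior threshold the proportion of individuals whose posterior for
#' their true class reaches the threshold (classification power). Mean and
#' SD are reported across replicates.
#'
#' @param freqs A [baseline_freqs()] object.
#' @param model A `hybrid_classes()` model.
#' @param n_per_class Individuals per class per replicate (default 30).
#' @param thresholds Posterior thresholds (default 0.5 to 1 by 0.05).
#' @param replicates Number of replicates (default 3).
#' @param seed Integer seed.
#' @return Data frame: `class, threshold, mean_accuracy, sd_accuracy`.
#' @export
hybrid_power <- function(freqs, model = hybrid_classes(), n_per_class = 30,
                         thresholds = seq(0.5, 1, by = 0.05),
                         replicates = 3, seed = 1) {
  classes <- rownames(model$phi)
  acc <- array(NA_real_, c(length(classes), length(thresholds), replicates),
               dimnames = list(classes, NULL, NULL))
  for (r in seq_len(replicates)) {
    for (ci in seq_along(classes)) {
      gm <- simulate_class(freqs, classes[ci], n_per_class,
                           seed = seed + 1000 * r + ci)
      post <- classify_hybrids(gm, freqs, model)
      p_true <- post[[classes[ci]]]
      acc[ci, , r] <- vapply(thresholds, function(th)
        mean(p_true >= th), numeric(1))
    }
  }
  out <- expand.grid(class = classes, threshold = thresholds,
                     stringsAsFactors = FALSE)
  out$mean_accuracy <- mapply(function(cl, th)
    mean(acc[cl, which(thresholds == th), ]), out$class, out$threshold)
  out$sd_accuracy <- mapply(function(cl, th)
    stats::sd(acc[cl, which(thresholds == th), ]), out$class, out$threshold)
  out
}

#' Classification accuracy under increasing missing data
#'
#' Simulates all classes, injects missing data at each rate of the grid,
#' reclassifies, and scores the proportion of individuals whose posterior
#' for the true class exceeds `threshold`.
#'
#' @param freqs A [baseline_freqs()] object.
#' @param model A `hybrid_classes()` model.
#' @param m_grid Missingness rates (default 0 to 0.9 by 0.1).
#' @param threshold Posterior threshold (default 0.9).
#' @param n_per_class Individuals per class (default 30).
#' @param seed Integer seed.
#' @return Data frame: `class, missing_rate, accuracy`.
#' @export
accuracy_vs_missing <- function(freqs, model = hybrid_classes(),
                                m_grid = seq(0, 0.9, by = 0.1),
                                threshold = 0.9, n_per_class = 30,
                                seed = 1) {
  classes <- rownames(model$phi)
  sims <- lapply(seq_along(classes), function(ci)
    simulate_class(freqs, classes[ci], n_per_class, seed = seed + ci))
  rows <- list()
  for (m in m_grid) {
    for (ci in seq_along(classes)) {
      gm <- inject_missing(sims[[ci]], m, seed = seed + 100 + round(1000 * m))
      post <- classify_hybrids(gm, freqs, model, min_loci = 1)
      p_true <- post[[classes[ci]]]
      ok <- !is.na(p_true) & p_true > threshold
      rows[[length(rows) + 1]] <- data.frame(
        class = classes[ci], missing_rate = m, accuracy = mean(ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Curate a baseline by anchored classification
#'
#' Computes baseline frequencies only from the designated (anchored)
#' individuals, classifies every sample, and excludes samples whose
#' posterior for their designated class falls below the threshold —
#' the z-anchored curation step that precedes simulation.
#'
#' @param gm A [geno_matrix()] with population labels.
#' @param designations Named vector mapping (a subset of) sample ids to
#'   `"PureA"`/`"PureB"`.
#' @param min_posterior Exclusion threshold (default 0.99).
#' @param model A `hybrid_classes()` model.
#' @return List: `kept`, `excluded` sample ids and the `posteriors` frame.
#' @export
curate_baseline <- function(gm, designations, min_posterior = 0.99,
                            model = hybrid_classes()) {
  anchors <- names(designations)
  if (!length(anchors)) stop("no designated individuals")
  pops <- gm$populations
  anchor_gm <- gm[gm_samples(gm) %in% anchors, ]
  # frequencies computed only from designated individuals, by designation
  anchor_pops <- ifelse(designations[gm_samples(anchor_gm)] == "PureA",
                        "A", "B")
  anchor_gm$populations <- stats::setNames(anchor_pops,
                                           gm_samples(anchor_gm))
  freqs <- baseline_frequencies(anchor_gm, c("A", "B"))
  post <- classify_hybrids(gm, freqs, model)
  target <- designations[post$sample_id]
  # undesignated samples are held to the pure class of their population;
  # the population -> pure-class mapping is voted by the anchors
  if (anyNA(target)) {
    if (is.null(pops)) stop("population labels required for undesignated samples")
    vote <- tapply(designations[anchors], pops[anchors],
                   function(d) names(sort(table(d), decreasing = TRUE))[1])
    target[is.na(target)] <- vote[pops[post$sample_id[is.na(target)]]]
  }
  p_target <- mapply(function(i, cl)
    if (cl %in% rownames(model$phi)) post[i, cl] else NA_real_,
    seq_len(nrow(post)), target)
  keep <- !is.na(p_target) & p_target >= min_posterior
  list(kept = post$sample_id[keep], excluded = post$sample_id[!keep],
       posteriors = post)
}
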