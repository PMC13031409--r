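#' Five-level genotype concordance score
#'
#' Per-cell comparison of a reference genotype set (e.g. ddRAD-derived)
#' against a new genotype set (e.g. amplicon-derived) at shared samples and
#' loci: 2 = identical calls, 1 = only the reference missing, 0 = only the
#' new call missing, -1 = both missing, -2 = both called but different.
#'
#' @param g_ref,g_new Genotype codes (vectors/matrices of `"a/b"` or `NA`).
#' @return Integer scores with the shape of the input.
#' @export
concordance_score <- function(g_ref, g_new) {
  ref_na <- is.na(g_ref); new_na <- is.na(g_new)
  score <- ifelse(ref_na & new_na, -1L,
           ifelse(ref_na & !new_na, 1L,
           ifelse(!ref_na & new_na, 0L,
           ifelse(g_ref == g_new, 2L, -2L))))
  if (is.matrix(g_ref)) score <- matrix(score, nrow(g_ref),
                                        dimnames = dimnames(g_ref))
  score
}

#' Concordance score matrix between two genotype matrices
#'
#' @param gm_ref,gm_new Two [geno_matrix()] objects; scored over shared
#'   samples and shared loci.
#' @param allele_map Optional named list mapping locus id to a two-element
#'   integer vector that recodes the new matrix's alleles (reconciles
#'   ref/alt flips between datasets) before scoring.
#' @return Integer matrix (shared samples x shared loci) of scores.
#' @export
concordance_matrix <- function(gm_ref, gm_new, allele_map = NULL) {
  samples <- intersect(gm_samples(gm_ref), gm_samples(gm_new))
  loci <- intersect(gm_loci(gm_ref), gm_loci(gm_new))
  if (!length(samples) || !length(loci))
    stop("no shared samples/loci to score")
  ref <- gm_ref$calls[samples, loci, drop = FALSE]
  new <- gm_new$calls[samples, loci, drop = FALSE]
  if (!is.null(allele_map)) {
    for (l in intersect(names(allele_map), loci)) {
      map <- allele_map[[l]]
      al <- geno_alleles(new[, l])
      new[, l] <- geno_code(map[al[, 1]], map[al[, 2]])
    }
  }
  concordance_score(ref, new)
}

#' Filter loci on concordance
#'
#' Keeps loci whose count of discordant cells (score -2) is at most
#' `max_discordant` (i.e. "fewer than `max_discordant + 1`").
#'
#' @param scores Score matrix from [concordance_matrix()].
#' @param max_discordant Maximum tolerated discordant genotypes per locus
#'   (default 4, i.e. fewer than five).
#' @return List: `retained` locus ids, `histogram` (loci x score classes
#'   count table).
#' @export
filter_concordant <- function(scores, max_discordant = 4) {
  classes <- c(-2, -1, 0, 1, 2)
  hist <- t(apply(scores, 2, function(col)
    vapply(classes, function(k) sum(col == k), integer(1))))
  colnames(hist) <- as.character(classes)
  stopifnot(all(rowSums(hist) == nrow(scores)))  # partition property
  retained <- colnames(scores)[hist[, "-2"] <= max_discordant]
  list(retained = retained, histogram = hist)
}

#' Drop non-informative loci
#'
#' Removes loci with no genotype variation across all called samples, or
#' with zero calls.
#'
#' @param gm A [geno_matrix()].
#' @return Character vector of retained locus ids.
#' @export
filter_noninformative <- function(gm) {
  keep <- apply(gm$calls, 2, function(g) {
    g <- g[!is.na(g)]
    length(unique(g)) >= 2
  })
  gm_loci(gm)[keep]
}

#' One-sided exact test for heterozygote excess
#'
#' Exact conditional (Levene) distribution of the heterozygote count given
#' the allele counts, with p = P(het >= observed) under Hardy-Weinberg.
#'
#' @param n_het Observed heterozygote count.
#' @param n_a1 Count of allele 1 (over called genotypes).
#' @param n Number of called genotypes.
#' @return One-sided p-value; `NA` for monomorphic data.
#' @export
hwe_excess_het_p <- function(n_het, n_a1, n) {
  n_a2 <- 2 * n - n_a1
  if (n_a1 == 0 || n_a2 == 0) return(NA_real_)
  rare <- min(n_a1, n_a2)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_a1 - h) / 2; nbb <- (n_a2 - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) +
      lgamma(n_a1 + 1) + lgamma(n_a2 + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  sum(p[hets >= n_het])
}

#' Filter loci on heterozygote excess and missingness
#'
#' One-sided exact Hardy-Weinberg test for heterozygote excess per locus
#' within the test population (excess heterozygosity is the signature of
#' collapsed duplicated loci); loci with p below `alpha` are dropped, as
#' are loci whose missingness across all samples exceeds `max_missing`.
#' Monomorphic loci pass through (the test is undefined there).
#'
#' @param gm A [geno_matrix()].
#' @param population Population in which to test (default: all samples).
#' @param alpha Significance level (default 0.05).
#' @param max_missing Missingness ceiling (default 0.2).
#' @param min_called Minimum called genotypes for the test (default 10).
#' @return List: `retained`, `removed` (named reason vector), `p_values`.
#' @export
hwe_excess_het_filter <- function(gm, population = NULL, alpha = 0.05,
                                  max_missing = 0.2, min_called = 10) {
  calls <- if (is.null(population)) gm$calls else
    gm$calls[gm$populations == population, , drop = FALSE]
  miss <- colMeans(is.na(gm$calls))
  pvals <- apply(calls, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g) < min_called) return(NA_real_)
    al <- geno_alleles(g)
    alleles <- sort(unique(as.vector(al)))
    if (length(alleles) < 2) return(NA_real_)
    if (length(alleles) > 2) return(NA_real_)  # test is biallelic
    n_het <- sum(al[, 1] != al[, 2])
    hwe_excess_het_p(n_het, sum(al == alleles[1]), nrow(al))
  })
  removed <- character(0)
  removed[gm_loci(gm)[!is.na(pvals) & pvals < alpha]] <- "excess_het"
  high_miss <- gm_loci(gm)[miss > max_missing]
  removed[setdiff(high_miss, names(removed))] <- "missingness"
  list(retained = setdiff(gm_loci(gm), names(removed)),
       removed = removed, p_values = pvals)
}

#' Impute missing genotypes with the population-modal genotype
#'
#' Each missing cell is replaced by the most frequently observed genotype
#' at that locus within the sample's reference population; called cells
#' are never altered. Modal ties resolve to the lexicographically smallest
#' allele pair. Intended for simulation inputs only, not empirical
#' inference.
#'
#' @param gm A [geno_matrix()] with population labels.
#' @return A completed [geno_matrix()] with zero missing cells.
#' @export
impute_most_frequent <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(gm$populations)) stop("population labels required")
  calls <- gm$calls
  for (p in unique(gm$populations)) {
    rows <- gm$populations == p
    for (li in seq_len(ncol(calls))) {
      col <- calls[rows, li]
      if (!anyNA(col)) next
      g <- col[!is.na(col)]
      if (!length(g))
        stop("no called genotypes to impute from at locus ",
             gm_loci(gm)[li], " in population ", p)
      tb <- table(g)
      top <- sort(names(tb)[tb == max(tb)])[1]
      col[is.na(col)] <- top
      calls[rows, li] <- col
    }
  }
  geno_matrix(calls, gm$populations)
}

#' Missingness profile of a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @return List: `per_sample`, `per_locus` (named missing proportions) and
#'   `overall`.
#' @export
missingness_profile <- function(gm) {
  na <- is.na(gm$calls)
  list(per_sample = rowMeans(na), per_locus = colMeans(na),
       overall = mean(na))
}

#' Sequential panel-optimisation filter pipeline
#'
#' Applies the locus filters in the order the optimisation rounds use them
#' — concordance, informativeness, primer agreement, Hardy-Weinberg excess
#' heterozygosity / missingness — and logs every removal with its filter
#' and reason so the panel accounting can be audited.
#'
#' @param gm_new New-method genotype matrix (the panel under optimisation).
#' @param gm_ref Reference genotype matrix for concordance (optional).
#' @param metrics Per-locus metrics from [primer_metrics()] (optional).
#' @param max_discordant Concordance tolerance (default 4).
#' @param min_agreement Minimum primer agreement rate (default 0.5).
#' @param hwe_population,alpha,max_missing Passed to
#'   [hwe_excess_het_filter()].
#' @return List: `retained` locus ids and `log` (data frame `filter,
#'   locus_id, reason`).
#' @export
qc_pipeline <- function(gm_new, gm_ref = NULL, metrics = NULL,
                        max_discordant = 4, min_agreement = 0.5,
                        hwe_population = NULL, alpha = 0.05,
                        max_missing = 0.2) {
  log <- data.frame(filter = character(0), locus_id = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  note <- function(filter, loci, reason) {
    if (length(loci))
      log <<- rbind(log, data.frame(filter = filter, locus_id = loci,
                                    reason = reason,
                                    stringsAsFactors = FALSE))
  }
  retained <- gm_loci(gm_new)
  if (!is.null(gm_ref)) {
    sc <- concordance_matrix(gm_ref, gm_new)
    fc <- filter_concordant(sc, max_discordant)
    dropped <- setdiff(intersect(retained, colnames(sc)), fc$retained)
    note("concordance", dropped, "discordant>max")
    retained <- setdiff(retained, dropped)
  }
  keep_inf <- filter_noninformative(gm_new[, retained])
  note("informative", setdiff(retained, keep_inf), "no_variation_or_all_missing")
  retained <- keep_inf
  if (!is.null(metrics)) {
    low <- metrics$locus_id[!is.na(metrics$agreement_rate) &
                              metrics$agreement_rate < min_agreement]
    low <- intersect(retained, low)
    note("primer_agreement", low, "agreement<min")
    retained <- setdiff(retained, low)
  }
  hw <- hwe_excess_het_filter(gm_new[, retained], hwe_population,
                              alpha, max_missing)
  note("hwe_missingness", names(hw$removed), unname(hw$removed))
  retained <- setdiff(retained, names(hw$removed))
  list(retained = retained, log = log)
}
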