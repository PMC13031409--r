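#' Per-locus allele frequencies for two parental populations
#'
#' The baseline object every downstream model consumes: for each locus and
#' each of the two parental populations, a named allele-frequency vector and
#' the number of called genotypes it was estimated from. Built either from a
#' curated [geno_matrix()] (see [baseline_frequencies()]) or synthetically
#' (see [simulate_baseline_pair()], [make_species_panel()]).
#'
#' @param freq List (one element per locus) of two-element lists (one per
#'   population) of named numeric allele-frequency vectors summing to 1.
#' @param n Matrix (loci x 2) of called-genotype counts behind each estimate.
#' @param pops Character vector of the two population labels, in order.
#' @param modal Optional list (per locus) of per-population modal genotype
#'   codes (used by imputation).
#' @return An object of class `baseline_freqs`.
#' @export
baseline_freqs <- function(freq, n, pops, modal = NULL) {
  stopifnot(length(pops) == 2, length(freq) == nrow(n))
  loci <- names(freq)
  if (is.null(loci)) {
    if (length(freq)) stop("freq must be a named list (locus ids)")
    loci <- character(0)
  }
  for (l in loci) {
    for (p in pops) {
      f <- freq[[l]][[p]]
      if (is.null(f) || abs(sum(f) - 1) > 1e-9)
        stop("frequencies at locus ", l, " / population ", p,
             " do not sum to 1")
    }
  }
  rownames(n) <- loci
  colnames(n) <- pops
  structure(list(freq = freq, n = n, pops = pops, modal = modal,
                 loci = loci),
            class = "baseline_freqs")
}

#' @export
print.baseline_freqs <- function(x, ...) {
  cat(sprintf("baseline_freqs: %d loci, populations %s vs %s\n",
              length(x$loci), x$pops[1], x$pops[2]))
  invisible(x)
}

#' Build a biallelic baseline from allele-1 frequency vectors
#'
#' Convenience constructor for the common SNP case: alleles are coded 1 and
#' 2 and only the allele-1 frequency in each population is supplied.
#'
#' @param p_a,p_b Numeric vectors of allele-1 frequencies in populations A
#'   and B.
#' @param loci Locus ids (default `L1..Ln`).
#' @param pops The two population labels.
#' @param n Called-genotype count assumed behind each estimate (scalar or
#'   loci x 2 matrix); controls the default smoothing strength in the
#'   classifier.
#' @return A [baseline_freqs()] object.
#' @export
bf_biallelic <- function(p_a, p_b, loci = NULL,
                         pops = c("A", "B"), n = 200) {
  stopifnot(length(p_a) == length(p_b))
  p_a <- unname(p_a); p_b <- unname(p_b)
  if (is.null(loci)) loci <- if (length(p_a))
    paste0("L", seq_along(p_a)) else character(0)
  freq <- lapply(seq_along(p_a), function(i) {
    stats::setNames(list(c(`1` = p_a[i], `2` = 1 - p_a[i]),
                         c(`1` = p_b[i], `2` = 1 - p_b[i])), pops)
  })
  names(freq) <- loci
  if (is.matrix(n)) nn <- n else nn <- matrix(n, length(loci), 2)
  baseline_freqs(freq, nn, pops)
}

#' Allele-1 frequency vector of a biallelic baseline
#'
#' @param bf A [baseline_freqs()] object with alleles coded 1/2.
#' @param pop Population label.
#' @return Named numeric vector of allele-1 frequencies per locus.
#' @export
bf_p1 <- function(bf, pop) {
  vapply(bf$freq, function(f) {
    v <- f[[pop]]
    if ("1" %in% names(v)) unname(v["1"]) else 0
  }, numeric(1))
}

#' Estimate baseline frequencies from called genotypes
#'
#' Allele frequencies, called-genotype counts and the modal (most frequent)
#' genotype are computed per locus within each of two populations, from
#' called genotypes only.
#'
#' @param gm A [geno_matrix()] with population labels.
#' @param pops The two population labels to use (default: the two observed).
#' @return A [baseline_freqs()] object (with modal genotypes filled in).
#' @export
baseline_frequencies <- function(gm, pops = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(gm$populations)) stop("genotype matrix has no population labels")
  if (is.null(pops)) pops <- unique(gm$populations)
  if (length(pops) != 2) stop("exactly two populations required, got ",
                              length(pops))
  loci <- gm_loci(gm)
  freq <- vector("list", length(loci)); names(freq) <- loci
  nmat <- matrix(0L, length(loci), 2)
  modal <- vector("list", length(loci)); names(modal) <- loci
  for (li in seq_along(loci)) {
    per_pop <- list(); per_modal <- character(2)
    for (pi in 1:2) {
      g <- gm$calls[gm$populations == pops[pi], loci[li]]
      g <- g[!is.na(g)]
      nmat[li, pi] <- length(g)
      if (length(g)) {
        al <- as.vector(geno_alleles(g))
        tb <- table(al)
        per_pop[[pops[pi]]] <- stats::setNames(as.numeric(tb) / sum(tb),
                                               names(tb))
        gtb <- sort(table(g), decreasing = TRUE)
        top <- names(gtb)[gtb == max(gtb)]
        per_modal[pi] <- sort(top)[1]    # deterministic tie-break
      } else {
        per_pop[[pops[pi]]] <- stats::setNames(numeric(0), character(0))
        per_modal[pi] <- NA_character_
      }
    }
    freq[[li]] <- per_pop
    modal[[li]] <- stats::setNames(per_modal, pops)
  }
  # zero-call loci cannot carry a frequency map summing to 1; reject early
  zero <- nmat == 0
  if (any(zero)) {
    bad <- loci[rowSums(zero) > 0]
    stop("no called genotypes at locus/population: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  baseline_freqs(freq, nmat, pops, modal)
}

#' Swap the two populations of a baseline
#'
#' @param bf A [baseline_freqs()] object.
#' @return The same baseline with population A and B exchanged.
#' @export
bf_swap <- function(bf) {
  freq <- lapply(bf$freq, function(f) stats::setNames(rev(f), rev(names(f))))
  baseline_freqs(freq, bf$n[, 2:1, drop = FALSE], rev(bf$pops),
                 if (!is.null(bf$modal)) lapply(bf$modal, rev) else NULL)
}
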