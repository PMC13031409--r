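#' Per-locus Weir-Cockerham theta (FST) between two populations
#'
#' The two-population per-site variance-components estimator
#' theta = a / (a + b + c), with a (among populations), b (among individuals
#' within populations) and c (within individuals) computed from observed
#' allele frequencies and heterozygote frequencies. Matches the per-site
#' convention of the standard VCF tooling: negative estimates are retained
#' unclipped, and loci that are monomorphic across both populations (or
#' with fewer than two called genotypes in either population) are returned
#' as `NA` rather than 0.
#'
#' @param gm A [geno_matrix()] with population labels.
#' @param pops The two population labels to compare.
#' @return Named numeric vector of per-locus theta.
#' @export
weir_cockerham_theta <- function(gm, pops = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(gm$populations)) stop("population labels required")
  if (is.null(pops)) pops <- unique(gm$populations)
  if (length(pops) != 2) stop("exactly two populations required")
  out <- stats::setNames(rep(NA_real_, ncol(gm$calls)), gm_loci(gm))
  g1 <- gm$calls[gm$populations == pops[1], , drop = FALSE]
  g2 <- gm$calls[gm$populations == pops[2], , drop = FALSE]
  for (li in seq_len(ncol(gm$calls))) {
    out[li] <- wc_theta_site(g1[, li], g2[, li])
  }
  out
}

# closed-form a/b/c components for one biallelic site, two populations
wc_theta_site <- function(gpop1, gpop2) {
  comp <- wc_components_site(gpop1, gpop2)
  if (is.null(comp)) return(NA_real_)
  with(comp, {
    denom <- a + b + cc
    if (denom == 0) return(NA_real_)
    a / denom
  })
}

wc_components_site <- function(gpop1, gpop2) {
  al1 <- geno_alleles(gpop1[!is.na(gpop1)])
  al2 <- geno_alleles(gpop2[!is.na(gpop2)])
  n1 <- nrow(al1); n2 <- nrow(al2)
  if (is.null(n1) || is.null(n2) || n1 < 2 || n2 < 2) return(NULL)
  alleles <- sort(unique(c(as.vector(al1), as.vector(al2))))
  if (length(alleles) < 2) return(NULL)   # monomorphic across both pops
  if (length(alleles) > 2)
    stop("weir_cockerham_theta expects biallelic loci")
  A <- alleles[1]
  p1 <- mean(al1 == A); p2 <- mean(al2 == A)
  h1 <- mean(al1[, 1] != al1[, 2]); h2 <- mean(al2[, 1] != al2[, 2])
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, cc = cc)
}

#' Per-locus nucleotide diversity within one population
#'
#' Unbiased pairwise-difference estimator over called alleles:
#' pi = sum over allele pairs i<j of 2 n_i n_j / (n (n - 1)). For a
#' biallelic SNP this is the unbiased expected heterozygosity.
#'
#' @param gm A [geno_matrix()].
#' @param pop Population label (default: all samples).
#' @return Named numeric vector of per-locus pi; `NA` where fewer than two
#'   alleles were called.
#' @export
site_pi <- function(gm, pop = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  calls <- if (is.null(pop)) gm$calls else {
    if (is.null(gm$populations)) stop("population labels required")
    gm$calls[gm$populations == pop, , drop = FALSE]
  }
  apply(calls, 2, function(g) {
    al <- as.vector(geno_alleles(g[!is.na(g)]))
    n <- length(al)
    if (n < 2) return(NA_real_)
    counts <- table(al)
    (n^2 - sum(counts^2)) / (n * (n - 1))
  })
}

#' Per-locus summary statistics for marker selection
#'
#' @param gm A [geno_matrix()] with two population labels.
#' @param pops The two populations for theta.
#' @param focal_pop Population in which pi (and MAF) are computed; defaults
#'   to the first of `pops`.
#' @return Data frame: `locus_id, theta, pi, maf, call_rate`.
#' @export
locus_stats <- function(gm, pops = NULL, focal_pop = NULL) {
  if (is.null(pops)) pops <- unique(gm$populations)
  if (is.null(focal_pop)) focal_pop <- pops[1]
  theta <- weir_cockerham_theta(gm, pops)
  pi <- site_pi(gm, focal_pop)
  focal <- gm$calls[gm$populations == focal_pop, , drop = FALSE]
  maf <- apply(focal, 2, function(g) {
    al <- as.vector(geno_alleles(g[!is.na(g)]))
    if (!length(al)) return(NA_real_)
    f <- table(al) / length(al)
    if (length(f) < 2) 0 else min(f)
  })
  call_rate <- colMeans(!is.na(gm$calls))
  data.frame(locus_id = gm_loci(gm), theta = unname(theta),
             pi = unname(pi), maf = unname(maf),
             call_rate = unname(call_rate), stringsAsFactors = FALSE)
}

#' Retain one SNP per contig
#'
#' Keeps, within each contig, the locus maximising the stated selection
#' criterion; ties are broken by lowest position (deterministic).
#'
#' @param stats Data frame with `locus_id` and the criterion column.
#' @param records Locus-record data frame (`locus_id, contig, position`).
#' @param criterion Column of `stats` to maximise (`"theta"` or `"pi"`).
#' @return The retained subset of `stats`, in input order.
#' @export
one_snp_per_contig <- function(stats, records, criterion = c("theta", "pi")) {
  criterion <- match.arg(criterion)
  m <- merge(stats, records[, c("locus_id", "contig", "position")],
             by = "locus_id", sort = FALSE)
  keep <- unlist(lapply(split(m, m$contig), function(d) {
    crit <- d[[criterion]]
    crit[is.na(crit)] <- -Inf
    best <- which(crit == max(crit))
    if (length(best) > 1) best <- best[which.min(d$position[best])]
    d$locus_id[best]
  }), use.names = FALSE)
  stats[stats$locus_id %in% keep, , drop = FALSE]
}

#' Thin loci by linkage-map distance
#'
#' Greedy scan in descending rank order (the order of `stats`, assumed
#' ranked best-first): a candidate is dropped when it lies within `min_cm`
#' centimorgans of an already-retained locus on the same linkage group.
#' Loci without map anchoring pass through untouched.
#'
#' @param stats Ranked data frame with `locus_id` (best first).
#' @param records Locus records with `linkage_group`, `cm_position`.
#' @param min_cm Exclusion radius in centimorgans; a candidate at exactly
#'   `min_cm` is kept (strict `<` exclusion).
#' @return The retained subset of `stats`, in input (rank) order.
#' @export
thin_by_linkage <- function(stats, records, min_cm = 50) {
  if (min_cm < 0) stop("negative cm distance")
  idx <- match(stats$locus_id, records$locus_id)
  lg <- if ("linkage_group" %in% names(records))
    records$linkage_group[idx] else rep(NA_character_, nrow(stats))
  cm <- if ("cm_position" %in% names(records))
    records$cm_position[idx] else rep(NA_real_, nrow(stats))
  kept_lg <- character(0); kept_cm <- numeric(0)
  keep <- logical(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    if (is.na(lg[i]) || is.na(cm[i])) { keep[i] <- TRUE; next }
    same <- kept_lg == lg[i]
    if (any(same) && any(abs(kept_cm[same] - cm[i]) < min_cm)) next
    keep[i] <- TRUE
    kept_lg <- c(kept_lg, lg[i]); kept_cm <- c(kept_cm, cm[i])
  }
  stats[keep, , drop = FALSE]
}

#' Select the S-loci and P-loci panels
#'
#' Ranks eligible loci and takes the top `n_s` by theta (species panel) and
#' the top `n_p` by pi (parentage panel). Loci whose left or right flank is
#' shorter than `min_flank` bases are rejected with reason `"flank"`. Ties
#' are broken by locus id, so selection is deterministic and
#' permutation-invariant. The two panels are selected independently;
#' overlap is permitted and reported.
#'
#' @param stats Data frame from [locus_stats()].
#' @param records Locus records with flanks.
#' @param n_s,n_p Panel sizes requested.
#' @param min_flank Minimum flank length (bp) on both sides.
#' @return A list of class `panel_selection`: `s_loci`, `p_loci` (ordered
#'   ids), `rejected` (named reason vector), `overlap`, and `shortfall`
#'   (named vector when fewer eligible loci than requested).
#' @export
select_panels <- function(stats, records, n_s = 303, n_p = 291,
                          min_flank = 15) {
  idx <- match(stats$locus_id, records$locus_id)
  if (anyNA(idx)) stop("stats contain loci absent from records")
  fl <- nchar(records$flank_left[idx])
  fr <- nchar(records$flank_right[idx])
  rejected <- stats::setNames(
    rep("flank", sum(fl < min_flank | fr < min_flank)),
    stats$locus_id[fl < min_flank | fr < min_flank])
  elig <- stats[fl >= min_flank & fr >= min_flank, , drop = FALSE]
  top_by <- function(col, n) {
    d <- elig[!is.na(elig[[col]]), , drop = FALSE]
    d <- d[order(-d[[col]], d$locus_id), , drop = FALSE]
    utils::head(d$locus_id, n)
  }
  s_loci <- top_by("theta", n_s)
  p_loci <- top_by("pi", n_p)
  shortfall <- c(s = n_s - length(s_loci), p = n_p - length(p_loci))
  out <- list(s_loci = s_loci, p_loci = p_loci, rejected = rejected,
              overlap = intersect(s_loci, p_loci),
              shortfall = shortfall[shortfall > 0])
  class(out) <- "panel_selection"
  out
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf("panel_selection: %d S-loci, %d P-loci (%d overlap), %d rejected\n",
              length(x$s_loci), length(x$p_loci), length(x$overlap),
              length(x$rejected)))
  if (length(x$shortfall))
    cat("shortfall:", paste(names(x$shortfall), x$shortfall,
                            collapse = ", "), "\n")
  invisible(x)
}

#' Write a panel selection to TSV
#'
#' @param sel A `panel_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_selection <- function(sel, path) {
  df <- rbind(
    data.frame(locus_id = sel$s_loci, panel = "S",
               rank = seq_along(sel$s_loci), stringsAsFactors = FALSE),
    data.frame(locus_id = sel$p_loci, panel = "P",
               rank = seq_along(sel$p_loci), stringsAsFactors = FALSE),
    if (length(sel$rejected))
      data.frame(locus_id = names(sel$rejected),
                 panel = paste0("rejected:", unname(sel$rejected)),
                 rank = NA_integer_, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
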