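#' Count on-target reads per locus for one sample
#'
#' Exact-string matching against the probe table: a forward read is
#' assigned to the first panel locus (in table order) whose forward primer
#' is a prefix of the read; an allele probe is counted when the probe
#' sequence occurs within the first `probe_window` bases of that read; a
#' read pair is "pair matched" when the mate read starts with the locus's
#' reverse primer. Reads matching no panel primer are counted as
#' off-target.
#'
#' @param r1_path,r2_path Paired FASTQ files for one sample (`r2_path` may
#'   be `NULL` for single-end counting; pair matching is then 0).
#' @param probes Validated probe table.
#' @param probe_window Probe search window from the read start (bp).
#' @return Data frame, one row per panel locus: `locus_id, n_fwd_primer,
#'   n_probe1, n_probe2, n_pair_matched`, with attributes `n_reads` and
#'   `n_off_target`.
#' @export
count_locus_reads <- function(r1_path, r2_path = NULL, probes,
                              probe_window = 75) {
  probes <- validate_probes(probes)
  r1 <- read_fastq_seqs(r1_path)
  r2 <- if (!is.null(r2_path)) read_fastq_seqs(r2_path) else NULL
  if (!is.null(r2) && length(r2) != length(r1))
    stop("R1/R2 read counts differ")
  nl <- nrow(probes)
  n_fwd <- n_p1 <- n_p2 <- n_pair <- integer(nl)
  off_target <- 0L
  if (length(r1)) {
    # locus assignment: first (table-order) forward primer that prefixes
    # the read; duplicate prefixes are rejected by validate_probes
    assigned <- rep(NA_integer_, length(r1))
    for (li in seq_len(nl)) {
      hit <- is.na(assigned) &
        startsWith(r1, probes$fwd_primer[li])
      assigned[hit] <- li
    }
    off_target <- sum(is.na(assigned))
    win <- substr(r1, 1, probe_window)
    for (li in seq_len(nl)) {
      idx <- which(assigned == li)
      if (!length(idx)) next
      n_fwd[li] <- length(idx)
      p1 <- grepl(probes$probe_allele1[li], win[idx], fixed = TRUE)
      p2 <- grepl(probes$probe_allele2[li], win[idx], fixed = TRUE)
      # a read matching both probes (degenerate probe pair) counts once,
      # for allele 1 by convention
      n_p1[li] <- sum(p1)
      n_p2[li] <- sum(p2 & !p1)
      if (!is.null(r2))
        n_pair[li] <- sum(startsWith(r2[idx], probes$rev_primer[li]))
    }
  }
  out <- data.frame(locus_id = probes$locus_id, n_fwd_primer = n_fwd,
                    n_probe1 = n_p1, n_probe2 = n_p2,
                    n_pair_matched = n_pair, stringsAsFactors = FALSE)
  attr(out, "n_reads") <- length(r1)
  attr(out, "n_off_target") <- off_target
  out
}

read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Ratio-based genotype calling from allele read counts
#'
#' The amplicon calling rule: with allele-count ratio `r = n1 / n2`
#' (`r = Inf` when `n2 = 0`), a cell is missing below the minimum depth;
#' `r >= hom_hi` calls homozygous allele 1, `r <= hom_lo` homozygous
#' allele 2, `het_lo <= r <= het_hi` heterozygous; ratios in the gaps
#' (the ambiguous zones) stay missing.
#'
#' @param n1,n2 Allele read counts (vectors or samples x loci matrices).
#' @param min_depth Minimum total depth to call (default 10).
#' @param hom_hi,hom_lo,het_lo,het_hi Ratio windows (defaults 10, 0.1,
#'   0.2, 5).
#' @return Genotype codes `"1/1"`, `"1/2"`, `"2/2"` or `NA`, with the
#'   shape of the input.
#' @export
call_genotype <- function(n1, n2, min_depth = 10,
                          hom_hi = 10, hom_lo = 0.1,
                          het_lo = 0.2, het_hi = 5) {
  stopifnot(all(n1 >= 0, na.rm = TRUE), all(n2 >= 0, na.rm = TRUE))
  depth <- n1 + n2
  r <- ifelse(n2 == 0, Inf, n1 / n2)
  call <- rep(NA_character_, length(r))
  call[r >= hom_hi] <- "1/1"
  call[r <= hom_lo] <- "2/2"
  call[r >= het_lo & r <= het_hi] <- "1/2"
  call[depth < min_depth] <- NA_character_
  if (is.matrix(n1)) call <- matrix(call, nrow(n1), dimnames = dimnames(n1))
  call
}

#' Call a genotype matrix from count matrices
#'
#' @param counts List with `n1`, `n2` matrices (samples x loci), e.g. from
#'   [simulate_read_counts()].
#' @param populations Optional population labels.
#' @param ... Passed to [call_genotype()].
#' @return A [geno_matrix()]; calling thresholds are recorded in the
#'   `calling_params` attribute.
#' @export
call_genotypes <- function(counts, populations = NULL, ...) {
  calls <- call_genotype(counts$n1, counts$n2, ...)
  gm <- geno_matrix(calls, populations)
  attr(gm, "calling_params") <- list(...)
  gm
}

#' Per-locus primer performance metrics
#'
#' @param counts_list List of per-sample count data frames from
#'   [count_locus_reads()].
#' @return Data frame per locus: `on_target_pct` (share of all reads
#'   carrying this locus's forward primer) and `agreement_rate`
#'   (pair-matched over probe-matched reads); `NA` where undefined.
#' @export
primer_metrics <- function(counts_list) {
  stopifnot(length(counts_list) >= 1)
  total_reads <- sum(vapply(counts_list, function(x)
    attr(x, "n_reads"), numeric(1)))
  agg <- Reduce(function(a, b) {
    a[, -1] <- a[, -1] + b[, -1]; a
  }, counts_list)
  if (total_reads == 0)
    warning("zero total reads: on-target percentages undefined")
  probe_total <- agg$n_probe1 + agg$n_probe2
  data.frame(locus_id = agg$locus_id,
             on_target_pct = if (total_reads == 0) NA_real_ else
               agg$n_fwd_primer / total_reads,
             agreement_rate = ifelse(probe_total == 0, NA_real_,
                                     agg$n_pair_matched / probe_total),
             stringsAsFactors = FALSE)
}

#' Flag loci with aberrant allele-ratio patterns
#'
#' Disomic loci concentrate allele ratios near 0, 1 and infinity; loci with
#' duplicated (tetrasomic) copies pile up in the ambiguous zones between
#' the homozygote and heterozygote windows (e.g. 1:3 ratios). A locus is
#' flagged when more than `max_ambig_frac` of its depth-passing samples
#' fall in the ambiguous ratio zones. This formalises what is otherwise a
#' visual screen of ratio scatter; the threshold is a package choice and is
#' fully configurable.
#'
#' @param n1,n2 Count matrices (samples x loci).
#' @param min_depth Depth floor, as in [call_genotype()].
#' @param min_called Minimum depth-passing samples for a locus to be
#'   assessable.
#' @param max_ambig_frac Flagging threshold (default 0.1).
#' @param hom_hi,hom_lo,het_lo,het_hi Ratio windows, as in
#'   [call_genotype()].
#' @return Data frame per locus: `n_pass`, `frac_ambiguous`, `flagged`.
#' @export
flag_ratio_anomalies <- function(n1, n2, min_depth = 10, min_called = 20,
                                 max_ambig_frac = 0.1,
                                 hom_hi = 10, hom_lo = 0.1,
                                 het_lo = 0.2, het_hi = 5) {
  depth <- n1 + n2
  r <- ifelse(n2 == 0, Inf, n1 / n2)
  pass <- depth >= min_depth
  ambig <- pass & ((r > hom_lo & r < het_lo) | (r > het_hi & r < hom_hi))
  n_pass <- colSums(pass)
  frac <- ifelse(n_pass > 0, colSums(ambig) / n_pass, NA_real_)
  data.frame(locus_id = colnames(n1), n_pass = n_pass,
             frac_ambiguous = frac,
             flagged = n_pass >= min_called & !is.na(frac) &
               frac > max_ambig_frac,
             row.names = NULL, stringsAsFactors = FALSE)
}
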