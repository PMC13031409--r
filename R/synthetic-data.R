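#' Specification for a synthetic two-population baseline
#'
#' Parameters of the Balding-Nichols divergence model used to emulate a pair
#' of partially diverged populations: an ancestral allele frequency is drawn
#' per locus, then each population's frequency is drawn from a Beta law with
#' that mean and scale set by the drift parameter `F` (larger `F` = more
#' divergence). Genotypes are then drawn in Hardy-Weinberg proportions
#' within each population.
#'
#' @param n_loci Number of biallelic loci.
#' @param n_samples_per_pop Samples per population.
#' @param F Drift/divergence parameter in (0, 1).
#' @param ancestral_range Range of the uniform ancestral-frequency law.
#' @param seed Integer seed (mandatory: every generator is reproducible).
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(n_loci, n_samples_per_pop = 50, F = 0.1,
                          ancestral_range = c(0.05, 0.95), seed = 1) {
  stopifnot(n_loci >= 1, F > 0, F < 1, n_samples_per_pop >= 1,
            length(ancestral_range) == 2)
  structure(list(n_loci = as.integer(n_loci),
                 n_samples_per_pop = as.integer(n_samples_per_pop),
                 F = F, ancestral_range = ancestral_range,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

#' Simulate a diverged two-population baseline
#'
#' @param spec A [baseline_spec()].
#' @param pops The two population labels.
#' @return A list with `freqs` (a [baseline_freqs()] built from the *true*
#'   simulated frequencies) and `gm` (a [geno_matrix()] of Hardy-Weinberg
#'   genotypes drawn from them).
#' @export
simulate_baseline_pair <- function(spec, pops = c("A", "B")) {
  stopifnot(inherits(spec, "baseline_spec"))
  set.seed(spec$seed)
  anc <- stats::runif(spec$n_loci, spec$ancestral_range[1],
                      spec$ancestral_range[2])
  scale <- (1 - spec$F) / spec$F
  p_a <- stats::rbeta(spec$n_loci, anc * scale, (1 - anc) * scale)
  p_b <- stats::rbeta(spec$n_loci, anc * scale, (1 - anc) * scale)
  # keep frequencies off the exact boundary so HW draws stay well-defined
  eps <- 1e-6
  p_a <- pmin(pmax(p_a, eps), 1 - eps)
  p_b <- pmin(pmax(p_b, eps), 1 - eps)
  loci <- paste0("L", seq_len(spec$n_loci))
  freqs <- bf_biallelic(p_a, p_b, loci, pops,
                        n = 2 * spec$n_samples_per_pop)
  n <- spec$n_samples_per_pop
  draw_pop <- function(p, prefix) {
    a1 <- matrix(stats::rbinom(n * length(p), 1, rep(p, each = n)) ,
                 n, length(p))
    a2 <- matrix(stats::rbinom(n * length(p), 1, rep(p, each = n)),
                 n, length(p))
    # allele 1 with prob p, allele 2 otherwise
    calls <- geno_code(2L - a1, 2L - a2)
    matrix(calls, n, length(p),
           dimnames = list(paste0(prefix, seq_len(n)), loci))
  }
  calls <- rbind(draw_pop(p_a, paste0(pops[1], "_")),
                 draw_pop(p_b, paste0(pops[2], "_")))
  gm <- geno_matrix(calls, rep(pops, each = n))
  list(freqs = freqs, gm = gm,
       ancestral = stats::setNames(anc, loci))
}

#' Construct a synthetic S-like / P-like marker panel
#'
#' Builds baseline frequencies with the two signatures the panel design
#' targets: species-diagnostic loci (S-like) with a large between-population
#' frequency contrast, and parentage loci (P-like) with high expected
#' heterozygosity within population A.
#'
#' @param n_s_like,n_p_like Panel sizes.
#' @param seed Integer seed.
#' @param s_min_diff Guaranteed minimum `|p_A - p_B|` for S-like loci
#'   (default 0.8, the near-diagnostic tail the selection pipeline keeps;
#'   any value >= 0.5 marks a locus as species-informative).
#' @param p_min_het Guaranteed minimum expected heterozygosity `2p(1-p)` in
#'   population A for P-like loci.
#' @param pops Population labels.
#' @param n Nominal genotype count per population behind the frequencies.
#' @return A list with `freqs` (a [baseline_freqs()] over the whole panel)
#'   and `panel` (list with `s_loci`, `p_loci` id vectors).
#' @export
make_species_panel <- function(n_s_like, n_p_like, seed = 1,
                               s_min_diff = 0.8, p_min_het = 0.4,
                               pops = c("A", "B"), n = 200) {
  stopifnot(n_s_like >= 0, n_p_like >= 0, s_min_diff > 0, s_min_diff <= 1,
            p_min_het >= 0, p_min_het <= 0.5)
  set.seed(seed)
  # S-like: draw the contrast first, centre the pair, jitter within bounds
  d <- stats::runif(n_s_like, s_min_diff, min(0.98, s_min_diff + 0.15))
  centre <- stats::runif(n_s_like, d / 2 + 0.005, 1 - d / 2 - 0.005)
  s_pa <- centre + d / 2
  s_pb <- centre - d / 2
  # P-like: common within A (het >= p_min_het), similar in B
  lo <- 0.5 - sqrt(max(0, 0.25 - p_min_het / 2))
  p_pa <- stats::runif(n_p_like, lo + 0.01, 1 - lo - 0.01)
  p_pb <- pmin(pmax(p_pa + stats::rnorm(n_p_like, 0, 0.08), 0.02), 0.98)
  s_ids <- if (n_s_like) paste0("S", seq_len(n_s_like)) else character(0)
  p_ids <- if (n_p_like) paste0("P", seq_len(n_p_like)) else character(0)
  freqs <- bf_biallelic(c(s_pa, p_pa), c(s_pb, p_pb),
                        c(s_ids, p_ids), pops, n = n)
  list(freqs = freqs, panel = list(s_loci = s_ids, p_loci = p_ids))
}

#' Specification for amplicon read-count simulation
#'
#' @param mean_depth Mean per-(sample, locus) sequencing depth.
#' @param depth_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed; amplicon pools are strongly overdispersed).
#' @param per_read_allele_error Probability that a single read reports the
#'   wrong allele.
#' @param seed Integer seed.
#' @return A `read_sim_spec` list.
#' @export
read_sim_spec <- function(mean_depth = 100, depth_dispersion = 5,
                          per_read_allele_error = 0.01, seed = 1) {
  stopifnot(mean_depth >= 0, depth_dispersion > 0,
            per_read_allele_error >= 0, per_read_allele_error < 0.5)
  structure(list(mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 per_read_allele_error = per_read_allele_error,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate per-locus allele read counts (and optionally FASTQ files)
#'
#' Depth per (sample, locus) is negative binomial; for heterozygotes the
#' allele-1 read count is Binomial(depth, 1/2) before error; each read then
#' flips allele with the per-read error probability. With `fastq_dir` set,
#' paired 75-bp FASTQ files (R1 carrying forward primer + probe, R2 carrying
#' the reverse primer) are written per sample, one read pair per counted
#' read.
#'
#' @param gm A biallelic [geno_matrix()] of true genotypes.
#' @param probes Probe table covering every locus of `gm`.
#' @param spec A [read_sim_spec()].
#' @param fastq_dir Optional directory for FASTQ output.
#' @return A list of matrices `n1`, `n2` (allele read counts, samples x
#'   loci) plus `fastq` (named list of R1/R2 paths per sample, or NULL).
#' @export
simulate_read_counts <- function(gm, probes, spec, fastq_dir = NULL) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(spec, "read_sim_spec"))
  miss <- setdiff(gm_loci(gm), probes$locus_id)
  if (length(miss))
    stop("no probe record for locus: ", paste(miss, collapse = ", "))
  probes <- probes[match(gm_loci(gm), probes$locus_id), ]
  set.seed(spec$seed)
  ns <- nrow(gm$calls); nl <- ncol(gm$calls)
  depth <- matrix(if (spec$mean_depth == 0) 0L else
    stats::rnbinom(ns * nl, size = spec$depth_dispersion,
                   mu = spec$mean_depth), ns, nl)
  al <- geno_alleles(as.vector(gm$calls))
  dose1 <- matrix((al[, 1] == 1L) + (al[, 2] == 1L), ns, nl)  # copies of allele 1
  p1_true <- dose1 / 2
  p1_true[is.na(p1_true)] <- 0          # missing genotype: treat as no signal
  depth[is.na(dose1)] <- 0L
  e <- spec$per_read_allele_error
  p1_obs <- p1_true * (1 - e) + (1 - p1_true) * e
  n1 <- matrix(stats::rbinom(ns * nl, as.vector(depth), as.vector(p1_obs)),
               ns, nl)
  n2 <- depth - n1
  storage.mode(n1) <- storage.mode(n2) <- "integer"
  dimnames(n1) <- dimnames(n2) <- dimnames(gm$calls)
  fastq <- NULL
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)
    fastq <- write_sim_fastq(n1, n2, probes, fastq_dir)
  }
  list(n1 = n1, n2 = n2, fastq = fastq)
}

# emit 75-bp paired reads: R1 = fwd_primer + probe + pad, R2 = rev_primer + pad
write_sim_fastq <- function(n1, n2, probes, dir, read_len = 75) {
  pad <- function(s) {
    s <- substr(s, 1, read_len)
    paste0(s, strrep("A", read_len - nchar(s)))
  }
  out <- list()
  for (si in seq_len(nrow(n1))) {
    s <- rownames(n1)[si]
    r1 <- character(0); r2 <- character(0)
    for (li in seq_len(ncol(n1))) {
      k1 <- n1[si, li]; k2 <- n2[si, li]
      if (k1 + k2 == 0) next
      fwd <- probes$fwd_primer[li]; rev <- probes$rev_primer[li]
      r1 <- c(r1, rep(pad(paste0(fwd, probes$probe_allele1[li])), k1),
              rep(pad(paste0(fwd, probes$probe_allele2[li])), k2))
      r2 <- c(r2, rep(pad(rev), k1 + k2))
    }
    ids <- sprintf("%s_read%06d", s, seq_along(r1))
    p1 <- file.path(dir, paste0(s, "_R1.fastq"))
    p2 <- file.path(dir, paste0(s, "_R2.fastq"))
    write_fastq(ids, r1, p1)
    write_fastq(ids, r2, p2)
    out[[s]] <- c(R1 = p1, R2 = p2)
  }
  out
}

write_fastq <- function(ids, seqs, path) {
  if (!length(seqs)) { file.create(path); return(invisible(path)) }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  invisible(path)
}

#' Build a synthetic probe table for a set of loci
#'
#' Deterministic (seeded) primer/probe sequences for simulated panels: each
#' locus gets a unique forward/reverse primer pair and a probe pair
#' differing at a single (SNP) position.
#'
#' @param loci Locus ids.
#' @param seed Integer seed.
#' @param probe_len Probe length (nt).
#' @return A probe-record data.frame accepted by [validate_probes()].
#' @export
make_probe_table <- function(loci, seed = 1, probe_len = 14) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                collapse = "")
  rows <- lapply(seq_along(loci), function(i) {
    fwd <- rand_seq(20); rev <- rand_seq(20)
    core <- rand_seq(probe_len)
    pos <- sample(probe_len, 1)
    ref <- substr(core, pos, pos)
    alt <- sample(setdiff(bases, ref), 1)
    p2 <- core
    substr(p2, pos, pos) <- alt
    data.frame(locus_id = loci[i], fwd_primer = fwd, rev_primer = rev,
               probe_allele1 = core, probe_allele2 = p2,
               expected_amplicon_length = sample(80:150, 1),
               stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, rows)
  validate_probes(probes)
}

#' Set called genotypes to missing at random
#'
#' Each called cell is independently set to missing with probability `rate`
#' (already-missing cells are left untouched).
#'
#' @param gm A [geno_matrix()].
#' @param rate Missingness probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [geno_matrix()].
#' @export
inject_missing <- function(gm, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(gm)
  set.seed(seed)
  calls <- gm$calls
  hit <- matrix(stats::runif(length(calls)) < rate, nrow(calls), ncol(calls))
  calls[hit] <- NA
  geno_matrix(calls, gm$populations)
}
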