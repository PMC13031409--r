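# Unified nearest-neighbour parameters (SantaLucia 1998):
# dH kcal/mol, dS cal/(mol K) per dinucleotide stack, 5'->3'.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation per terminal base pair
NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
R_GAS <- 1.987  # cal/(mol K)

nn_sums <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  st <- paste0(b[-length(b)], b[-1])
  list(dh = sum(NN_DH[st]) + NN_INIT_DH[b[1]] + NN_INIT_DH[b[length(b)]],
       ds = sum(NN_DS[st]) + NN_INIT_DS[b[1]] + NN_INIT_DS[b[length(b)]],
       n_stack = length(st))
}

check_acgt <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    stop("sequence must be a non-empty string")
  if (!grepl("^[ACGT]+$", seq))
    stop("sequence must contain only A, C, G, T: ", seq)
  invisible(seq)
}

#' Nearest-neighbour melting temperature of a primer
#'
#' Duplex melting temperature of the sequence against its perfect
#' complement, using the unified NN stack and initiation parameters, an
#' entropic monovalent-salt correction of `0.368 * (L - 1) * ln[Na+]`
#' applied to dS, and `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15` for a
#' non-self-complementary duplex at total strand concentration `CT`.
#'
#' @param seq Primer sequence, 5'->3', ACGT only (adapter tags excluded).
#' @param na_mM Monovalent salt concentration (mM).
#' @param conc_nM Total oligo concentration (nM).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(seq, na_mM = 50, conc_nM = 250) {
  check_acgt(seq)
  if (nchar(seq) < 2) stop("sequence too short for NN model")
  s <- nn_sums(seq)
  ds <- s$ds + 0.368 * s$n_stack * log(na_mM / 1000)
  ct <- conc_nM * 1e-9
  1000 * s$dh / (ds + R_GAS * log(ct / 4)) - 273.15
}

# Tm of a short perfectly matched duplex segment (bimolecular, same salt
# model as melting_temp); segments of length < 2 cannot form a stack.
duplex_segment_tm <- function(seq, na_mM = 50, conc_nM = 250) {
  if (nchar(seq) < 2) return(-Inf)
  melting_temp(seq, na_mM, conc_nM)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# best (max) duplex Tm over all gap-free alignments of `short` against
# `long`: maximal runs where short matches revcomp(long) windows.
best_duplex_tm <- function(short, long, na_mM = 50, conc_nM = 250) {
  targets <- unique(c(revcomp(long), long))
  best <- -Inf
  a <- strsplit(short, "")[[1]]
  for (tg in targets) {
    b <- strsplit(tg, "")[[1]]
    la <- length(a); lb <- length(b)
    for (off in (-la + 1):(lb - 1)) {
      i <- max(1, 1 - off); j <- i + off
      run <- 0L; run_start <- i
      while (i <= la && j <= lb) {
        if (a[i] == b[j]) {
          if (run == 0L) run_start <- i
          run <- run + 1L
        } else if (run > 1L) {
          seg <- paste(a[run_start:(run_start + run - 1L)], collapse = "")
          best <- max(best, duplex_segment_tm(seg, na_mM, conc_nM))
          run <- 0L
        } else run <- 0L
        i <- i + 1L; j <- j + 1L
      }
      if (run > 1L) {
        seg <- paste(a[run_start:(run_start + run - 1L)], collapse = "")
        best <- max(best, duplex_segment_tm(seg, na_mM, conc_nM))
      }
    }
  }
  best
}

#' Cross-dimer screen against an accepted primer pool
#'
#' Takes the candidate's 3'-terminal 10 bases and computes the best
#' complementary gap-free duplex against every accepted primer (both
#' orientations). The candidate is rejected when any duplex melting
#' temperature exceeds `max_tm`.
#'
#' @param candidate Candidate primer sequence (5'->3').
#' @param pool Character vector of accepted primer sequences.
#' @param max_tm Rejection threshold (deg C) for the tail duplex Tm.
#' @param na_mM,conc_nM Thermodynamic conditions.
#' @return A list: `reject` (logical), `partner` (offending pool primer or
#'   `NA`), `tm` (best duplex Tm found).
#' @export
cross_dimer_reject <- function(candidate, pool, max_tm = 15,
                               na_mM = 50, conc_nM = 250) {
  check_acgt(candidate)
  tail10 <- substr(candidate, max(1, nchar(candidate) - 9), nchar(candidate))
  best <- -Inf; partner <- NA_character_
  for (p in pool) {
    tm <- best_duplex_tm(tail10, p, na_mM, conc_nM)
    if (tm > best) { best <- tm; partner <- p }
  }
  list(reject = is.finite(best) && best > max_tm,
       partner = if (is.finite(best) && best > max_tm) partner else NA_character_,
       tm = best)
}

#' Hairpin screen
#'
#' Enumerates stem-loop structures with stem length >= `stem_min` and loop
#' length `loop_range` nucleotides, and computes the unimolecular melting
#' temperature of each stem (`Tm = 1000 dH / dS`, with the salt correction
#' and a fixed loop-entropy penalty; no bimolecular concentration term).
#' The sequence is rejected when the best stem melts above `max_tm`.
#'
#' @param seq Primer sequence (5'->3').
#' @param max_tm Rejection threshold (deg C).
#' @param stem_min Minimum stem length (bp).
#' @param loop_range Allowed loop lengths (nt).
#' @param na_mM Monovalent salt (mM).
#' @param loop_ds Loop entropy penalty, cal/(mol K) (negative).
#' @return A list: `reject` (logical), `tm` (best stem Tm, `-Inf` if no stem).
#' @export
hairpin_reject <- function(seq, max_tm = 50, stem_min = 3, loop_range = 3:8,
                           na_mM = 50, loop_ds = -10.5) {
  check_acgt(seq)
  b <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  best <- -Inf
  # enumeration: stem halves s[i..i+k-1] and s[j..j+k-1],
  # loop = j - (i + k), pairing requires s[i + m] complementary to
  # s[j + k - 1 - m] for all m (antiparallel)
  for (i in seq_len(n)) {
    for (k in stem_min:floor((n - i + 1) / 2)) {
      if (k < stem_min) next
      for (loop in loop_range) {
        j <- i + k + loop
        if (j + k - 1L > n) next
        ok <- all(b[i:(i + k - 1L)] ==
                    comp[b[(j + k - 1L):j]])
        if (ok) {
          stem <- paste(b[i:(i + k - 1L)], collapse = "")
          s <- nn_sums(stem)
          ds <- s$ds + 0.368 * s$n_stack * log(na_mM / 1000) + loop_ds
          tm <- 1000 * s$dh / ds - 273.15
          best <- max(best, tm)
        }
      }
    }
  }
  list(reject = is.finite(best) && best > max_tm, tm = best)
}

#' Default primer-screening constraints
#'
#' The multiplex screening rules: primer Tm window 58-64 deg C (adapter
#' tags excluded), amplicon length 80-150 bp, target SNP within the first
#' 75 bases of the amplicon, at most 40 candidates per flank, cross-dimer
#' tail Tm <= 15 deg C, hairpin Tm <= 50 deg C.
#'
#' @param ... Overrides for any constraint.
#' @return Named list of constraints.
#' @export
primer_constraints <- function(...) {
  out <- list(tm_min = 58, tm_max = 64, amp_min = 80, amp_max = 150,
              snp_max_offset = 75, max_per_side = 40,
              primer_len = 18:30, cross_dimer_tm = 15, hairpin_tm = 50,
              na_mM = 50, conc_nM = 250)
  over <- list(...)
  out[names(over)] <- over
  out
}

#' Enumerate candidate primer pairs for one locus
#'
#' Left primers are substrings of the left flank; right primers are reverse
#' complements of right-flank windows. Per side, up to `max_per_side`
#' candidates inside the Tm window are kept (3' ends closest to the SNP
#' first, deterministic). Pairs must give an amplicon inside the length
#' window with the SNP within the first `snp_max_offset` bases.
#'
#' @param record One locus record (row with `locus_id, flank_left,
#'   flank_right`).
#' @param constraints From [primer_constraints()].
#' @return Data frame of candidate pairs (possibly 0 rows): `locus_id,
#'   fwd_seq, rev_seq, tm_fwd, tm_rev, amplicon_length, snp_offset`, with a
#'   `reasons` attribute tabulating exclusions.
#' @export
enumerate_candidates <- function(record, constraints = primer_constraints()) {
  cst <- constraints
  fl <- toupper(record$flank_left); fr <- toupper(record$flank_right)
  reasons <- c(tm_window = 0L, amplicon_len = 0L, snp_position = 0L)
  side_cands <- function(flank, left) {
    n <- nchar(flank)
    out <- list()
    # anchor the primer 3' end at decreasing distance from the SNP
    ends <- if (left) seq(n, max(1, n - 14), by = -1) else
      seq(1, min(n, 15), by = 1)
    for (e in ends) {
      for (L in cst$primer_len) {
        if (left) {
          i <- e - L + 1
          if (i < 1) next
          s <- substr(flank, i, e)
        } else {
          j <- e + L - 1
          if (j > n) next
          s <- revcomp(substr(flank, e, j))
        }
        if (!grepl("^[ACGT]+$", s)) next
        tm <- melting_temp(s, cst$na_mM, cst$conc_nM)
        if (tm < cst$tm_min || tm > cst$tm_max) {
          reasons["tm_window"] <<- reasons["tm_window"] + 1L
          next
        }
        # dist = bases between primer 3' end and the SNP (left side) or
        # primer start offset in the right flank (right side)
        out[[length(out) + 1]] <-
          list(seq = s, tm = tm,
               pos = if (left) n - e else e)  # 0 = flush against SNP
        if (length(out) >= cst$max_per_side) return(out)
      }
      if (length(out) >= cst$max_per_side) break
    }
    out
  }
  lefts <- side_cands(fl, TRUE)
  rights <- side_cands(fr, FALSE)
  rows <- list()
  n_fl <- nchar(fl)
  for (lc in lefts) {
    for (rc in rights) {
      # left primer starts at n_fl - lc$pos - len + 1; SNP at n_fl + 1
      snp_offset <- lc$pos + nchar(lc$seq) + 1L
      amp_len <- snp_offset + rc$pos + nchar(rc$seq)
      if (amp_len < cst$amp_min || amp_len > cst$amp_max) {
        reasons["amplicon_len"] <- reasons["amplicon_len"] + 1L
        next
      }
      if (snp_offset > cst$snp_max_offset) {
        reasons["snp_position"] <- reasons["snp_position"] + 1L
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        locus_id = record$locus_id, fwd_seq = lc$seq, rev_seq = rc$seq,
        tm_fwd = lc$tm, tm_rev = rc$tm, amplicon_length = amp_len,
        snp_offset = snp_offset, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), fwd_seq = character(0),
               rev_seq = character(0), tm_fwd = numeric(0),
               tm_rev = numeric(0), amplicon_length = integer(0),
               snp_offset = integer(0), stringsAsFactors = FALSE)
  attr(out, "reasons") <- reasons
  out
}

#' Assemble a multiplex primer pool by sequential greedy acceptance
#'
#' Loci are visited in the given priority order; for each, candidate pairs
#' are tried in order and the first pair whose two primers pass the hairpin
#' screen and the cross-dimer screen against the currently accepted pool is
#' taken. Loci with no passing pair are rejected with the last failing
#' reason. Deterministic for a fixed input order.
#'
#' @param candidates Named list (by locus id, in priority order) of
#'   candidate-pair data frames from [enumerate_candidates()].
#' @param constraints From [primer_constraints()].
#' @return A list of class `pool_decision`: `accepted` (data frame of
#'   accepted pairs) and `rejected` (named reason vector).
#' @export
assemble_pool <- function(candidates, constraints = primer_constraints()) {
  cst <- constraints
  accepted <- list(); pool_seqs <- character(0)
  rejected <- character(0)
  for (locus in names(candidates)) {
    cand <- candidates[[locus]]
    reason <- if (nrow(cand) == 0) "no_candidates" else NA_character_
    taken <- FALSE
    for (i in seq_len(nrow(cand))) {
      pair_ok <- TRUE
      for (s in c(cand$fwd_seq[i], cand$rev_seq[i])) {
        hp <- hairpin_reject(s, cst$hairpin_tm, na_mM = cst$na_mM)
        if (hp$reject) { reason <- "hairpin"; pair_ok <- FALSE; break }
        cd <- cross_dimer_reject(s, pool_seqs, cst$cross_dimer_tm,
                                 cst$na_mM, cst$conc_nM)
        if (cd$reject) {
          reason <- paste0("cross_dimer(", cd$partner, ")")
          pair_ok <- FALSE; break
        }
      }
      # primers of one pair must also not dimerise with each other
      if (pair_ok) {
        cd <- cross_dimer_reject(cand$rev_seq[i], cand$fwd_seq[i],
                                 cst$cross_dimer_tm, cst$na_mM, cst$conc_nM)
        if (cd$reject) { reason <- paste0("cross_dimer(", cd$partner, ")")
                         pair_ok <- FALSE }
      }
      if (pair_ok) {
        accepted[[locus]] <- cand[i, , drop = FALSE]
        pool_seqs <- c(pool_seqs, cand$fwd_seq[i], cand$rev_seq[i])
        taken <- TRUE
        break
      }
    }
    if (!taken) rejected[locus] <- reason
  }
  out <- list(accepted = if (length(accepted)) do.call(rbind, accepted) else
    NULL, rejected = rejected)
  class(out) <- "pool_decision"
  out
}

#' @export
print.pool_decision <- function(x, ...) {
  cat(sprintf("pool_decision: %d loci accepted, %d rejected\n",
              if (is.null(x$accepted)) 0 else nrow(x$accepted),
              length(x$rejected)))
  invisible(x)
}

#' Re-audit an assembled pool
#'
#' Confirms that every accepted pair still satisfies the single-primer
#' filters and that the final pool is pairwise cross-dimer clean
#' (order-independent check).
#'
#' @param decision A `pool_decision`.
#' @param constraints From [primer_constraints()].
#' @return TRUE invisibly; stops with a message on any violation.
#' @export
audit_pool <- function(decision, constraints = primer_constraints()) {
  cst <- constraints
  acc <- decision$accepted
  if (is.null(acc) || !nrow(acc)) return(invisible(TRUE))
  for (i in seq_len(nrow(acc))) {
    stopifnot(acc$tm_fwd[i] >= cst$tm_min, acc$tm_fwd[i] <= cst$tm_max,
              acc$tm_rev[i] >= cst$tm_min, acc$tm_rev[i] <= cst$tm_max,
              acc$amplicon_length[i] >= cst$amp_min,
              acc$amplicon_length[i] <= cst$amp_max,
              acc$snp_offset[i] <= cst$snp_max_offset)
  }
  seqs <- c(acc$fwd_seq, acc$rev_seq)
  for (i in seq_along(seqs)) {
    others <- seqs[-i]
    cd <- cross_dimer_reject(seqs[i], others, cst$cross_dimer_tm,
                             cst$na_mM, cst$conc_nM)
    if (cd$reject)
      stop("pool audit failed: ", seqs[i], " dimerises with ", cd$partner)
  }
  invisible(TRUE)
}
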