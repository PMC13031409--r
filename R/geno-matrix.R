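#' Diploid genotype matrix
#'
#' The shared genotype container used throughout the package. Genotypes are
#' stored as a character matrix (samples in rows, loci in columns) of
#' unordered allele pairs encoded `"a/b"` with integer allele codes and
#' `a <= b` (so `"1/2"` and `"2/1"` are the same call). Missing genotypes are
#' `NA`. An optional population label per sample carries species/management
#' unit identity; labels are opaque strings.
#'
#' @param calls Character matrix of `"a/b"` codes (or `NA`), with rownames
#'   (sample ids) and colnames (locus ids).
#' @param populations Optional character vector of population labels, either
#'   named by sample id or in row order.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, populations = NULL) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("`calls` must be a character matrix")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  ok <- is.na(calls) | grepl("^[0-9]+/[0-9]+$", calls)
  if (!all(ok))
    stop("malformed genotype code(s): ",
         paste(utils::head(unique(calls[!ok]), 5), collapse = ", "))
  calls[!is.na(calls)] <- normalize_geno(calls[!is.na(calls)])
  if (!is.null(populations)) {
    if (is.null(names(populations))) {
      if (length(populations) != nrow(calls))
        stop("`populations` length must equal the number of samples")
      names(populations) <- rownames(calls)
    }
    missing_pop <- setdiff(rownames(calls), names(populations))
    if (length(missing_pop))
      stop("no population label for sample(s): ",
           paste(utils::head(missing_pop, 5), collapse = ", "))
    populations <- populations[rownames(calls)]
  }
  structure(list(calls = calls, populations = populations),
            class = "geno_matrix")
}

# sort the two allele codes of each "a/b" string numerically
normalize_geno <- function(g) {
  parts <- strsplit(g, "/", fixed = TRUE)
  vapply(parts, function(p) {
    a <- sort(as.integer(p))
    paste0(a[1], "/", a[2])
  }, character(1))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d loci\n",
              nrow(x$calls), ncol(x$calls)))
  if (!is.null(x$populations)) {
    tb <- table(x$populations)
    cat("populations:",
        paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  }
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param i,j Sample and locus indices (any form a matrix accepts).
#' @param ... Unused.
#' @return A `geno_matrix` restricted to the selected samples/loci.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  calls <- x$calls[i, j, drop = FALSE]
  pops <- if (!is.null(x$populations)) x$populations[rownames(calls)] else NULL
  geno_matrix(calls, pops)
}

#' @rdname geno_matrix
#' @param gm A `geno_matrix`.
#' @export
gm_samples <- function(gm) rownames(gm$calls)

#' @rdname geno_matrix
#' @export
gm_loci <- function(gm) colnames(gm$calls)

#' @rdname geno_matrix
#' @export
gm_pops <- function(gm) gm$populations

#' Split genotype codes into allele pairs
#'
#' @param g Character vector of `"a/b"` codes (may contain `NA`).
#' @return Integer matrix with two columns (allele 1, allele 2); `NA` rows for
#'   missing calls.
#' @export
geno_alleles <- function(g) {
  out <- matrix(NA_integer_, length(g), 2)
  ok <- !is.na(g)
  if (any(ok)) {
    parts <- strsplit(g[ok], "/", fixed = TRUE)
    out[ok, ] <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  }
  out
}

#' Compose genotype codes from two allele vectors
#'
#' @param a1,a2 Integer allele codes; `NA` in either yields a missing call.
#' @return Character vector of normalized `"a/b"` codes.
#' @export
geno_code <- function(a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  out <- paste0(lo, "/", hi)
  out[is.na(lo) | is.na(hi)] <- NA_character_
  out
}

# allele codes observed at each locus (sorted unique integers)
gm_allele_sets <- function(gm) {
  apply(gm$calls, 2, function(col) {
    al <- geno_alleles(col)
    sort(unique(as.integer(al[!is.na(al)])))
  }, simplify = FALSE)
}
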