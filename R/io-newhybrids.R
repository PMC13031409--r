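#' Write a NewHybrids individual-data file
#'
#' Emits the NewHybrids "Lumped" individual-data format: a `NumIndivs` /
#' `NumLoci` / `Digits` / `Format Lumped` header, a `LocusNames` row, then
#' one row per individual with its index, an optional `z` designation
#' (known-group anchoring), and one lumped genotype code per locus
#' (`"0"` = missing). Allele codes above 9 widen the digit field to 2; codes
#' above 99 are rejected.
#'
#' @param gm A [geno_matrix()].
#' @param z_map Optional named vector mapping sample ids to z designations
#'   (e.g. `c(S1 = "z0", S2 = "z1")`); samples absent from the map get no
#'   flag.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newhybrids <- function(gm, z_map = NULL, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (nrow(gm$calls) == 0) stop("empty genotype matrix")
  if (!is.null(z_map)) {
    bad <- setdiff(names(z_map), gm_samples(gm))
    if (length(bad))
      stop("z_map names not in sample ids: ", paste(bad, collapse = ", "))
  }
  al <- geno_alleles(as.vector(gm$calls))
  maxa <- max(al, na.rm = TRUE)
  if (maxa > 99) stop("format error: allele codes above 99 not representable")
  d <- if (maxa > 9) 2L else 1L
  fmt <- function(a) sprintf(paste0("%0", d, "d"), a)
  lump <- function(g) {
    a <- geno_alleles(g)
    out <- paste0(fmt(a[, 1]), fmt(a[, 2]))
    out[is.na(a[, 1])] <- "0"
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("NumIndivs", nrow(gm$calls)),
               paste("NumLoci", ncol(gm$calls)),
               paste("Digits", d),
               "Format Lumped",
               paste("LocusNames", paste(gm_loci(gm), collapse = " "))), con)
  for (i in seq_len(nrow(gm$calls))) {
    s <- gm_samples(gm)[i]
    z <- if (!is.null(z_map) && s %in% names(z_map)) z_map[[s]] else NULL
    writeLines(paste(c(i, z, lump(gm$calls[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' Read a NewHybrids individual-data file written by [write_newhybrids()]
#'
#' Round-trip reader for the Lumped dialect this package writes. Sample ids
#' are `ind<row index>`; z designations are returned as an attribute.
#'
#' @param path Input path.
#' @return A [geno_matrix()] with attribute `z_map`.
#' @export
read_newhybrids <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), lines, value = TRUE)[1]
    if (is.na(ln)) stop("parse error: missing ", key, " header")
    sub(paste0("^", key, "\\s+"), "", ln)
  }
  n_ind <- as.integer(hdr("NumIndivs"))
  n_loc <- as.integer(hdr("NumLoci"))
  d <- as.integer(hdr("Digits"))
  loci <- strsplit(hdr("LocusNames"), "\\s+")[[1]]
  if (length(loci) != n_loc) stop("parse error: LocusNames count mismatch")
  data_lines <- lines[grep("^[0-9]+\\s", lines)]
  data_lines <- data_lines[seq_len(n_ind)]
  calls <- matrix(NA_character_, n_ind, n_loc,
                  dimnames = list(paste0("ind", seq_len(n_ind)), loci))
  z_map <- character(0)
  for (i in seq_len(n_ind)) {
    tok <- strsplit(data_lines[i], "\\s+")[[1]][-1]
    if (length(tok) && grepl("^z", tok[1])) {
      z_map[paste0("ind", i)] <- tok[1]
      tok <- tok[-1]
    }
    if (length(tok) != n_loc)
      stop("parse error: row ", i, " has ", length(tok), " genotypes")
    keep <- tok != "0"
    a1 <- as.integer(substr(tok[keep], 1, d))
    a2 <- as.integer(substr(tok[keep], d + 1, 2 * d))
    calls[i, keep] <- geno_code(a1, a2)
  }
  gm <- geno_matrix(calls)
  attr(gm, "z_map") <- z_map
  gm
}
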