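#' Read and validate a probe/primer table
#'
#' The probe table describes one assay per panel locus: forward and reverse
#' primers and the two allele-discriminating probe sequences searched for in
#' the forward read. Expected columns: `locus_id, fwd_primer, rev_primer,
#' probe_allele1, probe_allele2, expected_amplicon_length`.
#'
#' Validation enforces the panel design contract: unique locus ids, probes
#' that differ at one or more positions, and expected amplicon lengths in
#' the 80-150 bp window the multiplex chemistry targets.
#'
#' @param path Delimited file (tab or comma) with a header row.
#' @return A data.frame of probe records.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE)
  need <- c("locus_id", "fwd_primer", "rev_primer",
            "probe_allele1", "probe_allele2", "expected_amplicon_length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("probe table missing column(s): ", paste(miss, collapse = ", "))
  validate_probes(df)
}

#' @rdname read_probe_table
#' @param probes A probe-record data.frame.
#' @export
validate_probes <- function(probes) {
  dup <- unique(probes$locus_id[duplicated(probes$locus_id)])
  if (length(dup))
    stop("duplicate locus_id in probe table: ", paste(dup, collapse = ", "))
  same <- probes$probe_allele1 == probes$probe_allele2
  if (any(same))
    stop("probe alleles identical at locus: ",
         paste(probes$locus_id[same], collapse = ", "))
  len <- probes$expected_amplicon_length
  bad <- is.na(len) | len < 80 | len > 150
  if (any(bad))
    stop("expected_amplicon_length outside 80-150 bp at locus: ",
         paste(probes$locus_id[bad], collapse = ", "))
  dup_primer <- unique(probes$fwd_primer[duplicated(probes$fwd_primer)])
  if (length(dup_primer))
    stop("duplicate forward primer shared by loci: ",
         paste(dup_primer, collapse = ", "))
  probes
}

#' Write a probe table
#'
#' @param probes Probe-record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a plain-text `key: value` configuration file
#'
#' Lines are `key: value`; blank lines and `#` comments are ignored. Values
#' that parse as numbers are returned numeric; comma-separated values become
#' vectors.
#'
#' @param path Config path.
#' @return Named list of parameters.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln)) stop("config parse error at line: ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
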