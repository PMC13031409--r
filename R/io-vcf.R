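#' Read genotypes from a VCF file
#'
#' Extracts the GT field of a VCF 4.x file (via \pkg{vcfR}) and maps it onto
#' the package's allele coding: REF allele = 1, first ALT allele = 2, and so
#' on; `./.` (or half-missing) genotypes become missing. Phasing is ignored
#' (all genotypes are treated as unordered). Locus ids are taken from the ID
#' column when present, otherwise `contig_pos`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param pop_file Optional two-column sidecar file (sample, population; no
#'   header, whitespace- or comma-delimited) supplying population labels.
#' @return A [geno_matrix()].
#' @export
read_vcf_genotypes <- function(path, pop_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  # gt is loci x samples; entries like "0/1", "0|1", ".", "./."
  conv <- function(x) {
    x[x %in% c(".", "./.", ".|.")] <- NA
    al <- strsplit(gsub("|", "/", x, fixed = TRUE), "/", fixed = TRUE)
    vapply(al, function(p) {
      if (length(p) != 2 || anyNA(p) || any(p == ".")) return(NA_character_)
      geno_code(as.integer(p[1]) + 1L, as.integer(p[2]) + 1L)
    }, character(1))
  }
  calls <- t(apply(gt, 2, conv))
  # single-sample VCFs collapse dimensions; rebuild explicitly
  calls <- matrix(calls, nrow = ncol(gt),
                  dimnames = list(colnames(gt), ids))
  pops <- NULL
  if (!is.null(pop_file)) {
    pf <- utils::read.table(pop_file, header = FALSE,
                            stringsAsFactors = FALSE)
    pops <- stats::setNames(as.character(pf[[2]]), pf[[1]])
  }
  geno_matrix(calls, pops)
}

#' Read locus metadata from a delimited file
#'
#' Locus records carry the information the marker-selection and primer
#' modules need: contig, 1-based position, flanking sequences around the
#' target SNP, and optional linkage-map anchoring. Expected columns:
#' `locus_id, contig, position, flank_left, flank_right` and optionally
#' `linkage_group, cm_position`.
#'
#' @param path Input path (tab- or comma-delimited, with header).
#' @return A data.frame of locus records.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE)
  need <- c("locus_id", "contig", "position", "flank_left", "flank_right")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("locus table missing column(s): ", paste(miss, collapse = ", "))
  validate_locus_records(df)
  df
}

validate_locus_records <- function(df) {
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus_id: ",
         paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "))
  iupac <- "^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]*$"
  bad <- !grepl(iupac, df$flank_left) | !grepl(iupac, df$flank_right)
  if (any(bad))
    stop("non-IUPAC flank sequence at locus: ",
         paste(df$locus_id[bad], collapse = ", "))
  has_lg <- "linkage_group" %in% names(df)
  has_cm <- "cm_position" %in% names(df)
  if (has_lg != has_cm)
    stop("linkage_group and cm_position must be given together")
  if (has_cm) {
    one <- !is.na(df$linkage_group) & is.na(df$cm_position) |
      is.na(df$linkage_group) & !is.na(df$cm_position)
    if (any(one))
      stop("cm_position must be present iff linkage_group is, locus: ",
           paste(df$locus_id[one], collapse = ", "))
    if (any(df$cm_position < 0, na.rm = TRUE))
      stop("negative cm_position")
  }
  invisible(df)
}
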