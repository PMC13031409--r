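#' Read a Genepop file
#'
#' Parses the classic Genepop text format: a title line, one locus name per
#' line (or a single comma-separated line), then `POP` blocks of
#' `sample , code code ...` rows. Both 2- and 3-digit allele codes are
#' supported and auto-detected from the code width; all-zero codes
#' (`"0000"`/`"000000"`) are missing. Population labels are `Pop1`, `Pop2`,
#' ... in block order unless `pop_names` is given.
#'
#' @param path Path to the Genepop file.
#' @param pop_names Optional character vector naming the POP blocks in order.
#' @return A [geno_matrix()] with populations set from the POP blocks.
#' @export
read_genepop <- function(path, pop_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3) stop("parse error in ", path, ": too few lines")
  body <- lines[-1]                      # drop title
  pop_idx <- grep("^pop$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("parse error in ", path, ": no POP line")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  n_pops <- length(pop_idx)
  if (!is.null(pop_names) && length(pop_names) != n_pops)
    stop("pop_names length (", length(pop_names),
         ") != number of POP blocks (", n_pops, ")")
  pops_lab <- if (is.null(pop_names)) paste0("Pop", seq_len(n_pops)) else pop_names

  bounds <- c(pop_idx, length(body) + 1)
  rows <- list(); row_pops <- character(0)
  for (b in seq_len(n_pops)) {
    block <- body[seq(bounds[b] + 1, bounds[b + 1] - 1)]
    block <- block[!grepl("^pop$", block, ignore.case = TRUE)]
    for (ln in block) {
      sp <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(sp) < 2)
        stop("parse error in ", path, " at line: ", ln)
      id <- trimws(sp[1])
      codes <- strsplit(trimws(paste(sp[-1], collapse = " ")), "[ \t]+")[[1]]
      if (length(codes) != length(loci))
        stop("dimension error in ", path, ": sample ", id, " has ",
             length(codes), " genotypes for ", length(loci), " loci")
      rows[[id]] <- codes
      row_pops <- c(row_pops, pops_lab[b])
    }
  }
  codes <- do.call(rbind, rows)
  width <- unique(as.vector(nchar(codes)))
  if (length(width) != 1 || !(width %in% c(4L, 6L)))
    stop("parse error in ", path, ": inconsistent allele-code width")
  d <- width / 2L
  a1 <- as.integer(substr(codes, 1L, d))
  a2 <- as.integer(substr(codes, d + 1L, width))
  a1[a1 == 0L] <- NA; a2[a2 == 0L] <- NA
  g <- geno_code(a1, a2)
  calls <- matrix(g, nrow = nrow(codes),
                  dimnames = list(rownames(codes), loci))
  names(row_pops) <- rownames(codes)
  geno_matrix(calls, row_pops)
}

#' Write a Genepop file
#'
#' @param gm A [geno_matrix()]; samples are grouped into POP blocks by their
#'   population label (one block if no labels).
#' @param path Output path.
#' @param digits Allele-code width per allele (2 or 3).
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path, digits = 3, title = "gtpanel export") {
  stopifnot(inherits(gm, "geno_matrix"), digits %in% c(2, 3))
  al <- geno_alleles(as.vector(gm$calls))
  if (any(al >= 10^digits, na.rm = TRUE))
    stop("allele code too wide for ", digits, "-digit Genepop")
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    sprintf(paste0("%0", digits, "d"), a)
  }
  codes <- matrix(paste0(fmt(al[, 1]), fmt(al[, 2])),
                  nrow = nrow(gm$calls), dimnames = dimnames(gm$calls))
  pops <- gm$populations
  if (is.null(pops)) pops <- stats::setNames(rep("Pop1", nrow(codes)),
                                             rownames(codes))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(codes), con)
  for (p in unique(pops)) {
    writeLines("POP", con)
    for (s in names(pops)[pops == p])
      writeLines(paste0(s, " ,  ", paste(codes[s, ], collapse = " ")), con)
  }
  invisible(path)
}

#' Read a delimited genotype table
#'
#' Tab- or comma-delimited table with a `sample` column, an optional
#' `population` column, and one column per locus holding `"a/b"` codes
#' (empty, `"NA"`, `"./."` or `"0/0"` = missing).
#'
#' @param path Input path.
#' @return A [geno_matrix()].
#' @export
read_geno_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% names(df))
    stop("parse error in ", path, ": no 'sample' column")
  pops <- NULL
  if ("population" %in% names(df))
    pops <- stats::setNames(as.character(df$population), df$sample)
  locus_cols <- setdiff(names(df), c("sample", "population"))
  calls <- as.matrix(df[, locus_cols, drop = FALSE])
  rownames(calls) <- df$sample
  calls[calls %in% c("", "NA", "./.", "0/0")] <- NA
  storage.mode(calls) <- "character"
  geno_matrix(calls, pops)
}

#' Write a delimited genotype table
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_geno_table <- function(gm, path, sep = "\t") {
  df <- data.frame(sample = gm_samples(gm), stringsAsFactors = FALSE)
  if (!is.null(gm$populations)) df$population <- unname(gm$populations)
  df <- cbind(df, as.data.frame(gm$calls, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read genotypes in any supported format
#'
#' Dispatcher over the three genotype input formats the pipeline accepts.
#'
#' @param path Input path.
#' @param format One of `"genepop"`, `"vcf"`, `"table"`.
#' @param ... Passed to the format-specific reader.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("genepop", "vcf", "table"), ...) {
  format <- match.arg(format)
  switch(format,
         genepop = read_genepop(path, ...),
         vcf     = read_vcf_genotypes(path, ...),
         table   = read_geno_table(path))
}
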