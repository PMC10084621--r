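#' Read and validate a phenotype/design table
#'
#' Expects a comma-separated, UTF-8 file with a header row containing at least
#' the design columns `individual_id`, `pond_id`, `latitude`, `temperature`,
#' `predator`, `maternal_line` and, when traits were measured, `mass` (mg),
#' `head_width` (mm), `wing_pad` (mm) and `dev_time` (days, integer).  The
#' derived growth rates `grm` (mass/dev_time) and `grh` (head_width/dev_time)
#' are optional but must both be present or both absent.
#'
#' Categorical values are normalized case-insensitively: `latitude` to
#' `high`/`central`, `predator` to `absent`/`present` (the synonyms `0`/`1`
#' are accepted), `temperature` to the numeric levels 20 and 24.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of class `phenotype_table`, one row per individual.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_phenotype_table(df)
}

#' Validate a data.frame as a phenotype table
#'
#' @param df a data.frame with the columns described in [read_phenotypes()].
#' @return the validated, normalized `phenotype_table`.
#' @export
as_phenotype_table <- function(df) {
  for (col in .design_cols)
    if (!col %in% names(df)) stopf("missing required column '%s'", col)
  has_traits <- any(.trait_cols %in% names(df))
  if (has_traits)
    for (col in .trait_cols)
      if (!col %in% names(df)) stopf("missing required column '%s'", col)

  df$individual_id <- as.character(df$individual_id)
  if (anyDuplicated(df$individual_id))
    stopf("duplicate individual_id: %s",
          df$individual_id[anyDuplicated(df$individual_id)])
  df$pond_id <- as.character(df$pond_id)
  df$maternal_line <- as.character(df$maternal_line)
  df$latitude <- .norm_category(df$latitude, .latitude_map, "latitude")
  df$predator <- .norm_category(df$predator, .predator_map, "predator")
  df$temperature <- .norm_category(df$temperature, .temperature_map,
                                   "temperature")

  if (has_traits) {
    for (col in c("mass", "head_width", "wing_pad")) {
      v <- as.numeric(df[[col]])
      bad <- which(!is.finite(v) | v <= 0)
      if (length(bad))
        stopf("non-positive or missing %s at row %d", col, bad[1])
      df[[col]] <- v
    }
    dt <- as.numeric(df$dev_time)
    bad <- which(!is.finite(dt) | dt <= 0 | dt != round(dt))
    if (length(bad))
      stopf("dev_time must be a positive integer; offending row %d (value %s)",
            bad[1], df$dev_time[bad[1]])
    df$dev_time <- as.integer(dt)
  }

  n_derived <- sum(.derived_cols %in% names(df))
  if (n_derived == 1L)
    stopf("derived columns grm and grh must be both present or both absent")
  if (n_derived == 2L) {
    for (col in .derived_cols) {
      v <- as.numeric(df[[col]])
      bad <- which(!is.finite(v) | v < 0)
      if (length(bad)) stopf("negative or missing %s at row %d", col, bad[1])
      df[[col]] <- v
    }
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype table to CSV
#'
#' Inverse of [read_phenotypes()]; a write/read round trip is identity.
#'
#' @param pheno a `phenotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a featureCounts-style gene-level count matrix
#'
#' Parses the tab-separated layout written by gene-level read counters:
#' optional comment lines starting with `#`, then a header
#' `Geneid  Chr  Start  End  Strand  Length` followed by one column per
#' sample.  Multi-part `Chr` entries (`"1;1;1"`) are reduced to their first
#' chromosome label.
#'
#' @param path path to the TSV file.
#' @return a `counts_matrix`: an integer matrix (genes x samples) with
#'   `rownames` the gene ids, plus attributes `chrom` (chromosome label per
#'   gene) and `length` (gene length, if present).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stopf("counts file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")
  if (!"Geneid" %in% names(df)) stopf("missing 'Geneid' column in %s", path)
  if (!"Chr" %in% names(df)) stopf("missing 'Chr' column in %s", path)
  sample_cols <- setdiff(names(df), meta)
  if (!length(sample_cols)) stopf("no sample columns found in %s", path)
  counts <- as.matrix(df[sample_cols])
  storage.mode(counts) <- "double"
  rownames(counts) <- as.character(df$Geneid)
  chrom <- vapply(strsplit(as.character(df$Chr), ";", fixed = TRUE),
                  `[`, character(1), 1L)
  len <- if ("Length" %in% names(df)) as.numeric(df$Length) else NULL
  as_counts_matrix(counts, chrom = chrom, length = len)
}

#' Validate a counts matrix
#'
#' @param counts numeric matrix, genes x samples, with gene ids as rownames.
#' @param chrom chromosome label per gene (optional).
#' @param length gene length per gene (optional).
#' @return a validated `counts_matrix`.
#' @export
as_counts_matrix <- function(counts, chrom = NULL, length = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate Geneid: %s", rownames(counts)[anyDuplicated(rownames(counts))])
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)))
    stopf("duplicate sample id: %s",
          colnames(counts)[anyDuplicated(colnames(counts))])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stopf("count at gene '%s', sample %d is negative, missing or fractional (%s)",
          rownames(counts)[i[1]], i[2], counts[bad[1]])
  }
  storage.mode(counts) <- "integer"
  if (!is.null(chrom)) {
    stopifnot(length(chrom) == nrow(counts))
    attr(counts, "chrom") <- as.character(chrom)
  }
  if (!is.null(length)) attr(counts, "length") <- length
  class(counts) <- c("counts_matrix", class(counts))
  counts
}

#' Drop genes on excluded chromosomes
#'
#' Removes every gene whose chromosome label is in `drop`, e.g. the sex
#' chromosome when samples were not sexed.  Unknown labels are a no-op; gene
#' order is otherwise preserved.  Which label denotes the sex chromosome
#' depends on the reference annotation, so there is deliberately no default.
#'
#' @param counts a `counts_matrix` with a `chrom` attribute.
#' @param drop character vector of chromosome labels to exclude.
#' @return the filtered `counts_matrix`.
#' @export
exclude_chromosomes <- function(counts, drop) {
  chrom <- attr(counts, "chrom")
  if (is.null(chrom)) stopf("counts matrix has no chromosome labels")
  drop <- as.character(drop)
  keep <- !(chrom %in% drop)
  out <- counts[keep, , drop = FALSE]
  attr(out, "chrom") <- chrom[keep]
  len <- attr(counts, "length")
  if (!is.null(len)) attr(out, "length") <- len[keep]
  class(out) <- class(counts)
  out
}

#' Write a counts matrix in featureCounts layout
#'
#' @param counts a `counts_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  chrom <- attr(counts, "chrom") %||% rep("NA", nrow(counts))
  len <- attr(counts, "length") %||% rep(1000L, nrow(counts))
  df <- data.frame(Geneid = rownames(counts), Chr = chrom,
                   Start = 1L, End = as.integer(len), Strand = "+",
                   Length = as.integer(len), check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(counts)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Program:featureCounts", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
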