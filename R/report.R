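#' Write the candidate mutation report
#'
#' Emits the final report as TSV, one row per candidate mutation:
#' region name, position, gene, location label (consequence and CpG-island
#' relation), alternate-allele read support and total depth, site quality,
#' between-line allele frequency difference, and the PC/EC/PE substitution
#' scores. Scores are rendered to two decimals; substitution scores absent
#' for non-coding candidates are rendered `N/A`.
#'
#' @param records Data frame with columns `region`, `snp_bp`, `gene`,
#'   `snp_location`, `alt_reads`, `depth`, `qual`, `afd`, `pc`, `ec`, `pe`
#'   (as produced by [rank_candidates()]). May be empty.
#' @param path Output path.
#' @export
write_candidates <- function(records, path) {
  cols <- c("region", "snp_bp", "gene", "snp_location", "alt_reads",
            "depth", "qual", "afd", "pc", "ec", "pe")
  if (nrow(records) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop(sprintf("candidate records lack column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  fmt2 <- function(x) ifelse(is.na(x), "N/A", sprintf("%.2f", x))
  out <- data.frame(
    region = records$region,
    snp_bp = format(records$snp_bp, scientific = FALSE, trim = TRUE),
    gene = records$gene,
    snp_location = records$snp_location,
    alt_reads = records$alt_reads,
    depth = records$depth,
    qual = ifelse(is.na(records$qual), "N/A",
                  format(records$qual, trim = TRUE)),
    afd = fmt2(records$afd),
    pc = fmt2(records$pc),
    ec = fmt2(records$ec),
    pe = fmt2(records$pe),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate mutation report
#'
#' Inverse of [write_candidates()]; `N/A` entries become `NA`.
#'
#' @param path Path to a candidate report TSV.
#' @return Data frame of candidate records.
#' @export
read_candidates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", "N/A"))
  num_cols <- intersect(c("snp_bp", "alt_reads", "depth", "qual",
                          "afd", "pc", "ec", "pe"), names(df))
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  df
}
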