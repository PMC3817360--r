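#' Construct a value track
#'
#' A per-chromosome series of (position, value) points with values on
#' \[0, 1\] (or `NA` for missing). Used for the divergence, chip-AFD,
#' normalized QTL and combined-score tracks.
#'
#' @param chrom Single chromosome identifier.
#' @param pos_bp Strictly increasing 1-based positions.
#' @param value Values in \[0, 1\], `NA` allowed.
#' @return A `data.frame` of class `value_track` with columns `chrom`,
#'   `pos_bp`, `value`.
#' @export
value_track <- function(chrom, pos_bp, value) {
  chrom <- as.character(chrom)
  if (length(unique(chrom)) > 1L) {
    stop("a value track covers a single chromosome", call. = FALSE)
  }
  pos_bp <- as.numeric(pos_bp)
  value <- as.numeric(value)
  if (length(pos_bp) != length(value)) stop("pos_bp and value lengths differ", call. = FALSE)
  if (is.unsorted(pos_bp, strictly = TRUE)) {
    if (anyDuplicated(pos_bp)) {
      stop("duplicate positions in value track", call. = FALSE)
    }
    stop("value track positions must be strictly increasing", call. = FALSE)
  }
  ok <- is.na(value) | (value >= 0 & value <= 1)
  if (!all(ok)) stop("track values must lie in [0, 1] or be NA", call. = FALSE)
  df <- data.frame(chrom = rep_len(chrom, length(pos_bp)),
                   pos_bp = pos_bp, value = value, stringsAsFactors = FALSE)
  class(df) <- c("value_track", "data.frame")
  df
}

#' Write a value track as TSV
#'
#' @param track A `value_track`.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  df <- as.data.frame(track)
  df$value <- ifelse(is.na(df$value), "NA", format(df$value, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a value track from TSV
#'
#' @param path Path to a TSV with columns `chrom`, `pos_bp`, `value`.
#' @return A `value_track`.
#' @export
read_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  value_track(df$chrom, df$pos_bp, suppressWarnings(as.numeric(df$value)))
}

#' Construct a QTL support curve
#'
#' The statistical support profile of a QTL scan across a region (the
#' per-marker test statistic from the intercross analysis), together with
#' the significance threshold of that scan. The curve is an input to the
#' pipeline, not recomputed by it.
#'
#' @param pos_bp Strictly increasing positions.
#' @param score Finite support scores (arbitrary scale; normalized later).
#' @param sig_threshold Significance level on the same scale as `score`.
#' @param chrom Chromosome identifier.
#' @return An object of class `support_curve`.
#' @export
support_curve <- function(pos_bp, score, sig_threshold, chrom = NA_character_) {
  pos_bp <- as.numeric(pos_bp)
  score <- as.numeric(score)
  if (!length(pos_bp)) stop("support curve is empty", call. = FALSE)
  if (is.unsorted(pos_bp, strictly = TRUE)) {
    stop("support curve positions must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(score))) stop("support scores must be finite", call. = FALSE)
  structure(list(points = data.frame(pos_bp = pos_bp, score = score),
                 sig_threshold = as.numeric(sig_threshold),
                 chrom = as.character(chrom)),
            class = "support_curve")
}

#' @export
print.support_curve <- function(x, ...) {
  cat(sprintf("support_curve: %d points on %s, score range [%.3g, %.3g], sig_threshold %.3g\n",
              nrow(x$points), x$chrom, min(x$points$score),
              max(x$points$score), x$sig_threshold))
  invisible(x)
}

#' Write a support curve as TSV
#'
#' The significance threshold and chromosome are stored in header comments
#' so the file round-trips.
#'
#' @param curve A `support_curve`.
#' @param path Output path.
#' @export
write_support_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("## sig_threshold=%s", format(curve$sig_threshold, digits = 15)),
               sprintf("## chrom=%s", curve$chrom)), con)
  utils::write.table(curve$points, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a support curve from TSV
#'
#' @param path Path to a TSV written by [write_support_curve()] (columns
#'   `pos_bp`, `score`, optional `## sig_threshold=` / `## chrom=` header).
#' @param sig_threshold Overrides the header threshold when given.
#' @return A `support_curve`.
#' @export
read_support_curve <- function(path, sig_threshold = NULL) {
  hdr <- grep("^##", readLines(path, n = 10L), value = TRUE)
  get_hdr <- function(key) {
    ln <- grep(paste0("^## ", key, "="), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^## ", key, "="), "", ln[1]) else NA_character_
  }
  if (is.null(sig_threshold)) {
    sig_threshold <- suppressWarnings(as.numeric(get_hdr("sig_threshold")))
    if (is.na(sig_threshold)) {
      stop("no sig_threshold in file header; supply one", call. = FALSE)
    }
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  support_curve(df$pos_bp, df$score, sig_threshold, chrom = get_hdr("chrom"))
}
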