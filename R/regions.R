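#' Construct a table of genomic regions
#'
#' Regions use the package-wide coordinate convention: 1-based, inclusive on
#' both ends (the VCF/GFF3 convention). BED input/output converts at the
#' boundary.
#'
#' @param chrom Character vector of chromosome identifiers.
#' @param start_bp,end_bp Integer-valued vectors, 1-based inclusive.
#' @param name Optional region labels.
#' @return A `data.frame` of class `regions` with columns `name`, `chrom`,
#'   `start_bp`, `end_bp`, `size_mbp` (recomputed, 0.1 Mbp precision).
#' @export
regions <- function(chrom, start_bp, end_bp, name = NA_character_) {
  start_bp <- as.numeric(start_bp)
  end_bp <- as.numeric(end_bp)
  if (any(start_bp < 1)) stop("start_bp must be >= 1", call. = FALSE)
  if (any(end_bp < start_bp)) {
    bad <- which(end_bp < start_bp)[1]
    stop(sprintf("region %d: end (%s) before start (%s)",
                 bad, format(end_bp[bad], scientific = FALSE),
                 format(start_bp[bad], scientific = FALSE)), call. = FALSE)
  }
  if (any(end_bp == start_bp)) {
    warning("zero-size region(s) present (start == end)")
  }
  df <- data.frame(name = rep_len(as.character(name), length(chrom)),
                   chrom = as.character(chrom),
                   start_bp = start_bp, end_bp = end_bp,
                   stringsAsFactors = FALSE)
  df$size_mbp <- region_size_mbp(df)
  class(df) <- c("regions", "data.frame")
  df
}

#' Region sizes in Mbp
#'
#' Sizes are always recomputed as `(end_bp - start_bp) / 1e6`, rounded to
#' 0.1 Mbp; a size column in an input table is never trusted for arithmetic
#' (it is retained separately as a report-level value).
#'
#' @param x A `regions` data frame.
#' @return Numeric vector of sizes in Mbp.
#' @export
region_size_mbp <- function(x) {
  round((x$end_bp - x$start_bp) / 1e6, 1)
}

#' Read a region definition table
#'
#' Reads a tab-separated table with columns `name`, `chrom`, `start`, `end`
#' (or `start_mbp`/`end_mbp`, `start_bp`/`end_bp`). Coordinates given in Mbp
#' are expanded to exact base pairs by multiplying by 1e6. Sizes are
#' recomputed from the coordinates; if the table carries its own size
#' column (`size_mbp`) it is kept as `size_printed_mbp`.
#'
#' @param path Path to a TSV file.
#' @param coords Either `"mbp"` or `"bp"`; how `start`/`end` columns are
#'   interpreted when not disambiguated by their names.
#' @return A `regions` data frame (see [regions()]); extra columns of the
#'   input are carried along.
#' @export
read_regions_table <- function(path, coords = c("mbp", "bp")) {
  coords <- match.arg(coords)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  names(tab) <- tolower(names(tab))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    NULL
  }
  start <- pick("start_bp", "start_mbp", "start")
  end <- pick("end_bp", "end_mbp", "end")
  if (is.null(start) || is.null(end)) {
    stop("regions table must have start and end columns", call. = FALSE)
  }
  in_mbp <- ("start_mbp" %in% names(tab)) ||
    (!("start_bp" %in% names(tab)) && coords == "mbp")
  if (in_mbp) {
    start <- round(start * 1e6)
    end <- round(end * 1e6)
  }
  chrom <- pick("chrom", "chr", "gga", "chromosome")
  if (is.null(chrom)) stop("regions table must have a chrom column", call. = FALSE)
  nm <- pick("name", "region_name", "region")
  if (is.null(nm)) nm <- NA_character_
  bad <- which(end < start)
  if (length(bad)) {
    stop(sprintf("regions table row %d ('%s'): end before start",
                 bad[1], nm[bad[1]]), call. = FALSE)
  }
  out <- regions(chrom = chrom, start_bp = start, end_bp = end, name = nm)
  if ("size_mbp" %in% names(tab)) out$size_printed_mbp <- tab[["size_mbp"]]
  for (extra in setdiff(names(tab), c("name", "region_name", "region", "chrom",
                                      "chr", "gga", "chromosome", "start", "end",
                                      "start_mbp", "end_mbp", "start_bp",
                                      "end_bp", "size_mbp"))) {
    out[[extra]] <- tab[[extra]]
  }
  out
}

#' Write a region table as TSV
#'
#' @param x A `regions` data frame.
#' @param path Output path.
#' @export
write_regions_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled fine-mapped growth QTL regions
#'
#' The seven fine-mapped body-weight QTL regions on chromosomes 1-5, 7 and
#' 20 of the divergently selected chicken lines (galGal3 coordinates),
#' shipped as a plain-text fixture. The `size_printed_mbp` column carries
#' the originally reported region sizes, which reflect sub-0.1-Mbp
#' coordinates and therefore do not always equal `end - start` of the
#' rounded Mbp coordinates; `size_mbp` is recomputed from the coordinates.
#'
#' @return A `regions` data frame with one row per QTL region.
#' @export
qtl_regions_table <- function() {
  read_regions_table(system.file("extdata", "qtl_regions.tsv",
                                 package = "divergescan"))
}

#' Bundled selected candidate segments
#'
#' The eight candidate segments selected inside the QTL regions by combined
#' divergence and QTL evidence (galGal3 coordinates), shipped as a
#' plain-text fixture alongside the per-segment QTL-significant sizes and
#' initial gene counts.
#'
#' @return A `regions` data frame with one row per selected segment.
#' @export
selected_segments_table <- function() {
  read_regions_table(system.file("extdata", "selected_segments.tsv",
                                 package = "divergescan"))
}

#' Bundled candidate mutation report
#'
#' The prioritized candidate mutations in the evaluated QTL regions
#' (one or two per region), shipped as a plain-text fixture; `pc`/`ec`/`pe`
#' substitution scores are present only for the non-synonymous coding
#' candidates.
#'
#' @return Data frame with one row per candidate mutation.
#' @export
candidate_mutations_table <- function() {
  read_candidates(system.file("extdata", "candidate_mutations.tsv",
                              package = "divergescan"))
}

# regions <-> GRanges (1-based inclusive on both sides, so direct)
regions_to_granges <- function(x) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start_bp, end = x$end_bp)
  )
  if (!all(is.na(x$name))) gr$name <- x$name
  gr
}

granges_to_regions <- function(gr) {
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  regions(chrom = as.character(GenomicRanges::seqnames(gr)),
          start_bp = GenomicRanges::start(gr),
          end_bp = GenomicRanges::end(gr),
          name = nm)
}

#' Read genomic intervals from a BED file
#'
#' BED files are 0-based half-open; intervals are converted to the internal
#' 1-based inclusive convention on input.
#'
#' @param path Path to a BED file.
#' @return A `regions` data frame.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_regions(gr)
}

#' Write genomic intervals to a BED file
#'
#' Converts from the internal 1-based inclusive convention to BED's 0-based
#' half-open convention; a BED -> internal -> BED round trip is the
#' identity.
#'
#' @param x A `regions` data frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(regions_to_granges(x), path, format = "BED")
  invisible(path)
}

# membership test: positions (chrom, pos) inside any region of x
in_regions <- function(chrom, pos, x) {
  res <- logical(length(pos))
  for (i in seq_len(nrow(x))) {
    res <- res | (chrom == x$chrom[i] & pos >= x$start_bp[i] & pos <= x$end_bp[i])
  }
  res
}
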