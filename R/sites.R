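#' Construct a table of sequenced SNP sites with per-line pooled counts
#'
#' One row per biallelic site, carrying reference/alternate pooled read
#' counts for the two lines (labelled generically `h` = high-selected,
#' `l` = low-selected) and an optional Phred-scaled site quality.
#'
#' @param chrom Chromosome identifiers.
#' @param pos 1-based positions.
#' @param ref,alt Single-base reference and alternate alleles.
#' @param ref_reads_h,alt_reads_h,ref_reads_l,alt_reads_l Non-negative
#'   pooled read counts per line.
#' @param qual Optional Phred-scaled site quality (`NA` allowed).
#' @return A `data.frame` of class `snp_sites`, sorted by position within
#'   chromosome.
#' @export
snp_sites <- function(chrom, pos, ref, alt,
                      ref_reads_h, alt_reads_h, ref_reads_l, alt_reads_l,
                      qual = NA_real_) {
  counts <- cbind(ref_reads_h, alt_reads_h, ref_reads_l, alt_reads_l)
  if (any(counts < 0)) stop("read counts must be non-negative", call. = FALSE)
  if (any(!is.na(qual) & qual < 0)) stop("qual must be non-negative", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   ref_reads_h = as.numeric(ref_reads_h),
                   alt_reads_h = as.numeric(alt_reads_h),
                   ref_reads_l = as.numeric(ref_reads_l),
                   alt_reads_l = as.numeric(alt_reads_l),
                   qual = rep_len(as.numeric(qual), length(pos)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  # duplicate positions only via distinct alternate alleles (split
  # multi-allelics); identical (chrom, pos, alt) rows are ambiguous
  if (anyDuplicated(df[c("chrom", "pos", "alt")])) {
    stop("duplicate site positions are not allowed", call. = FALSE)
  }
  class(df) <- c("snp_sites", "data.frame")
  df
}

#' Read pooled per-line read counts from a VCF file
#'
#' Parses a VCF whose two samples are the sequenced DNA pools of the two
#' lines, taking reference/alternate read counts from the per-sample `AD`
#' field.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param line_sample_map Named character vector mapping the labels `HIGH`
#'   and `LOW` to the two sample names in the VCF.
#' @param strict If `TRUE` (default), multi-allelic and non-SNP records are
#'   an error; otherwise multi-allelic records are split into one site per
#'   alternate allele and non-SNP records are dropped.
#' @return A `snp_sites` data frame.
#' @export
read_pooled_vcf <- function(path,
                            line_sample_map = c(HIGH = "HIGH", LOW = "LOW"),
                            strict = TRUE) {
  stopifnot(all(c("HIGH", "LOW") %in% names(line_sample_map)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) {
    return(snp_sites(character(), numeric(), character(), character(),
                     numeric(), numeric(), numeric(), numeric()))
  }
  samples <- colnames(v@gt)[-1]
  for (lab in c("HIGH", "LOW")) {
    if (!(line_sample_map[[lab]] %in% samples)) {
      stop(sprintf("sample '%s' (line %s) not present in VCF (samples: %s)",
                   line_sample_map[[lab]], lab,
                   paste(samples, collapse = ", ")), call. = FALSE)
    }
  }
  fix <- v@fix
  ad <- vcfR::extract.gt(v, element = "AD")
  parse_ad <- function(x, record) {
    if (is.na(x) || x == ".") return(NULL)
    parts <- suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
    if (any(is.na(parts))) {
      stop(sprintf("malformed AD field in VCF record %d: '%s'", record, x),
           call. = FALSE)
    }
    parts
  }
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1L && strict) {
      stop(sprintf("multi-allelic record %d (%s:%s) in strict mode",
                   i, fix[i, "CHROM"], fix[i, "POS"]), call. = FALSE)
    }
    is_snp <- nchar(ref) == 1L & nchar(alts) == 1L
    if (strict && !all(is_snp)) {
      stop(sprintf("non-SNP record %d (%s:%s) in strict mode",
                   i, fix[i, "CHROM"], fix[i, "POS"]), call. = FALSE)
    }
    ad_h <- parse_ad(ad[i, line_sample_map[["HIGH"]]], i)
    ad_l <- parse_ad(ad[i, line_sample_map[["LOW"]]], i)
    if (is.null(ad_h)) ad_h <- rep(0, length(alts) + 1L)
    if (is.null(ad_l)) ad_l <- rep(0, length(alts) + 1L)
    if (length(ad_h) < length(alts) + 1L || length(ad_l) < length(alts) + 1L) {
      stop(sprintf("AD field of record %d has fewer entries than alleles", i),
           call. = FALSE)
    }
    keep <- which(is_snp)
    if (!length(keep)) next
    out[[i]] <- data.frame(
      chrom = unname(fix[i, "CHROM"]), pos = as.numeric(fix[i, "POS"]),
      ref = unname(ref), alt = unname(alts[keep]),
      ref_reads_h = ad_h[1], alt_reads_h = ad_h[keep + 1L],
      ref_reads_l = ad_l[1], alt_reads_l = ad_l[keep + 1L],
      qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(snp_sites(character(), numeric(), character(), character(),
                     numeric(), numeric(), numeric(), numeric()))
  }
  snp_sites(res$chrom, res$pos, res$ref, res$alt,
            res$ref_reads_h, res$alt_reads_h,
            res$ref_reads_l, res$alt_reads_l, res$qual)
}

#' Write pooled sites as a two-sample VCF
#'
#' Emits a minimal VCF 4.2 file with one sample per line pool and
#' per-sample `AD` (ref,alt read counts); the inverse of
#' [read_pooled_vcf()].
#'
#' @param sites A `snp_sites` data frame.
#' @param path Output path.
#' @param sample_names Names for the two pool samples (HIGH, LOW order).
#' @export
write_pooled_vcf <- function(sites, path, sample_names = c("HIGH", "LOW")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=divergescan",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  qual <- ifelse(is.na(sites$qual), ".", format(sites$qual, trim = TRUE))
  body <- paste(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                ".", sites$ref, sites$alt, qual, ".", ".", "AD",
                paste0(sites$ref_reads_h, ",", sites$alt_reads_h),
                paste0(sites$ref_reads_l, ",", sites$alt_reads_l),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a chip genotype matrix for two labelled lines
#'
#' @param sites Data frame with columns `chrom`, `pos` (marker positions,
#'   sorted within chromosome).
#' @param calls Integer matrix, one row per site and one column per
#'   individual; entries count alternate alleles (0, 1, 2) with `NA` for
#'   missing calls.
#' @param line Character vector (`"HIGH"`/`"LOW"`), one entry per
#'   individual.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, calls, line) {
  calls <- as.matrix(calls)
  line <- as.character(line)
  if (nrow(calls) != nrow(sites)) stop("calls rows must match sites", call. = FALSE)
  if (ncol(calls) != length(line)) {
    stop("every individual needs exactly one line tag", call. = FALSE)
  }
  if (!all(line %in% c("HIGH", "LOW"))) {
    stop("line tags must be HIGH or LOW", call. = FALSE)
  }
  if (!all(is.na(calls) | calls %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("ind%03d", seq_len(ncol(calls)))
  }
  structure(list(sites = as.data.frame(sites)[c("chrom", "pos")],
                 calls = calls, line = line),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d individuals (%d HIGH, %d LOW)\n",
              nrow(x$sites), ncol(x$calls),
              sum(x$line == "HIGH"), sum(x$line == "LOW")))
  invisible(x)
}

#' Write a chip genotype table as TSV
#'
#' Marker rows by individual columns; the line assignment of each
#' individual is stored in a `## line:` header comment so the file is
#' self-contained.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotype_table <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("## line: ",
                    paste(colnames(gm$calls), gm$line, sep = "=",
                          collapse = ",")), con)
  df <- cbind(gm$sites, as.data.frame(gm$calls))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chip genotype table
#'
#' @param path Path to a TSV written by [write_genotype_table()] (or the
#'   same layout: `chrom`, `pos`, one column per individual with 0/1/2/NA
#'   codes).
#' @param line_map Optional named vector mapping individual ids to
#'   `"HIGH"`/`"LOW"`; when absent the `## line:` header comment is used.
#' @return A `genotype_matrix`.
#' @export
read_genotype_table <- function(path, line_map = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(line_map)) {
    if (!startsWith(first, "## line:")) {
      stop("no line assignment: provide line_map or a '## line:' header",
           call. = FALSE)
    }
    spec <- strsplit(sub("^## line:\\s*", "", first), ",", fixed = TRUE)[[1]]
    kv <- strsplit(spec, "=", fixed = TRUE)
    line_map <- stats::setNames(vapply(kv, `[`, "", 2L),
                                vapply(kv, `[`, "", 1L))
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  ids <- setdiff(names(df), c("chrom", "pos"))
  missing_ids <- setdiff(ids, names(line_map))
  if (length(missing_ids)) {
    stop(sprintf("no line tag for individual(s): %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  genotype_matrix(df[c("chrom", "pos")], as.matrix(df[ids]),
                  unname(line_map[ids]))
}
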