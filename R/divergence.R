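#' AB score: proportion of pooled reads agreeing with the reference
#'
#' Per line and site, the fraction of pooled sequencing reads carrying the
#' reference allele, `ref / (ref + alt)`. A site with no reads in the line
#' is `NA` (missing), never 0: absence of coverage is absence of evidence.
#'
#' @param ref_reads,alt_reads Non-negative read counts (vectorized).
#' @return Numeric vector in \[0, 1\], `NA` where `ref + alt == 0`.
#' @examples
#' ab_score(7, 0)  # 1
#' ab_score(3, 9)  # 0.25
#' @export
ab_score <- function(ref_reads, alt_reads) {
  ref_reads <- as.numeric(ref_reads)
  alt_reads <- as.numeric(alt_reads)
  if (any(ref_reads < 0 | alt_reads < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  total <- ref_reads + alt_reads
  ifelse(total == 0, NA_real_, ref_reads / total)
}

#' Per-site between-line divergence from pooled reads
#'
#' Absolute difference of the two per-line AB scores,
#' `|AB_high - AB_low|`; an estimate of the between-line allele frequency
#' difference at the site. `NA` if either line lacks coverage. Symmetric
#' under swapping the lines.
#'
#' @param sites A `snp_sites` data frame (see [snp_sites()]).
#' @return Numeric vector in \[0, 1\] (or `NA`), one value per site.
#' @export
site_divergence <- function(sites) {
  abs(ab_score(sites$ref_reads_h, sites$alt_reads_h) -
        ab_score(sites$ref_reads_l, sites$alt_reads_l))
}

#' Apply the SNP-detection threshold to pooled sites
#'
#' Keeps the sites whose total number of alternate (non-reference) reads,
#' summed over both line pools, reaches `min_alt_total`. The default of 3
#' non-reference reads across both pools (roughly 24x combined depth)
#' trades sensitivity against sequencing-error artifacts.
#'
#' @param sites A `snp_sites` data frame.
#' @param min_alt_total Minimum summed alternate read count (>= 1).
#' @return The filtered `snp_sites`, input order preserved.
#' @export
call_snps <- function(sites, min_alt_total = 3) {
  if (min_alt_total < 1) stop("min_alt_total must be >= 1", call. = FALSE)
  keep <- (sites$alt_reads_h + sites$alt_reads_l) >= min_alt_total
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parameters of the flanking-SNP-value smoother
#'
#' @param window_bp Half-width (bp) of the flanking interval on each side
#'   of the focal SNP; flanking sites within this distance are presumed to
#'   be in strong linkage disequilibrium with it.
#' @param weighting `"uniform"` (default) or `"linear"` (weight decays
#'   linearly with distance from the focal site, reaching 0 just beyond the
#'   window edge).
#' @param min_sites Minimum number of contributing (non-missing) sites for
#'   a value to be produced; fewer gives `NA`.
#' @return A list of class `fsv_params`.
#' @export
fsv_params <- function(window_bp = 40000, weighting = c("uniform", "linear"),
                       min_sites = 1) {
  weighting <- match.arg(weighting)
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  if (min_sites < 1) stop("min_sites must be >= 1", call. = FALSE)
  structure(list(window_bp = window_bp, weighting = weighting,
                 min_sites = min_sites), class = "fsv_params")
}

#' Flanking-SNP value at one focal site
#'
#' Divergence estimate at a SNP that borrows information from flanking
#' SNPs: the weighted mean of the per-site divergence values
#' (`|AB_high - AB_low|`) over all sites within `window_bp` of the focal
#' position, the focal site included. Missing per-site values contribute
#' nothing (they are not counted as zero).
#'
#' @param pos_bp Sorted (strictly increasing) site positions.
#' @param divergence Per-site divergence values aligned with `pos_bp`
#'   (`NA` allowed).
#' @param focal_index Index of the focal site in `pos_bp`.
#' @param params An `fsv_params` object.
#' @return A value in \[0, 1\], or `NA` if fewer than `min_sites`
#'   non-missing sites fall in the window.
#' @export
fsv <- function(pos_bp, divergence, focal_index, params = fsv_params()) {
  if (is.unsorted(pos_bp, strictly = TRUE)) {
    stop("site positions must be sorted strictly increasing", call. = FALSE)
  }
  p0 <- pos_bp[focal_index]
  d <- abs(pos_bp - p0)
  in_win <- d <= params$window_bp & !is.na(divergence)
  if (sum(in_win) < params$min_sites) return(NA_real_)
  w <- if (params$weighting == "uniform") {
    rep(1, sum(in_win))
  } else {
    1 - d[in_win] / (params$window_bp + 1)
  }
  sum(w * divergence[in_win]) / sum(w)
}

#' Flanking-SNP-value track over a set of pooled sites
#'
#' Applies [fsv()] at every site of one chromosome and returns the result
#' as a [value_track()]. Sites are processed with a sliding window over the
#' sorted positions.
#'
#' @param sites A `snp_sites` data frame (single chromosome).
#' @param params An `fsv_params` object.
#' @param divergence Optional precomputed per-site divergence (defaults to
#'   [site_divergence()] of `sites`).
#' @return A `value_track` with one point per site (possibly `NA` values).
#' @export
fsv_track <- function(sites, params = fsv_params(), divergence = NULL) {
  if (length(unique(sites$chrom)) > 1L) {
    stop("fsv_track expects a single chromosome", call. = FALSE)
  }
  if (is.null(divergence)) divergence <- site_divergence(sites)
  pos <- sites$pos
  n <- length(pos)
  vals <- rep(NA_real_, n)
  if (n) {
    lo <- findInterval(pos - params$window_bp - 0.5, pos) + 1L
    hi <- findInterval(pos + params$window_bp + 0.5, pos)
    for (i in seq_len(n)) {
      idx <- lo[i]:hi[i]
      dv <- divergence[idx]
      ok <- !is.na(dv)
      if (sum(ok) < params$min_sites) next
      if (params$weighting == "uniform") {
        vals[i] <- mean(dv[ok])
      } else {
        w <- 1 - abs(pos[idx][ok] - pos[i]) / (params$window_bp + 1)
        vals[i] <- sum(w * dv[ok]) / sum(w)
      }
    }
  }
  value_track(if (n) sites$chrom[1] else NA_character_, pos, vals)
}

#' Between-line allele frequency difference from chip genotypes
#'
#' For one marker, `|p_alt(HIGH) - p_alt(LOW)|` where the per-line
#' alternate allele frequency is the sum of genotype codes over the
#' non-missing individuals of that line divided by twice their number.
#' `NA` if a line has no non-missing call at the marker.
#'
#' @param gm A `genotype_matrix`.
#' @param chrom,pos Marker coordinates (must be present in `gm`).
#' @return A value in \[0, 1\] or `NA`.
#' @export
chip_afd <- function(gm, chrom, pos) {
  i <- which(gm$sites$chrom == chrom & gm$sites$pos == pos)
  if (!length(i)) {
    stop(sprintf("marker %s:%s not present in genotype matrix",
                 chrom, format(pos, scientific = FALSE)), call. = FALSE)
  }
  .chip_afd_rows(gm)[i[1]]
}

.chip_afd_rows <- function(gm) {
  p_line <- function(lab) {
    calls <- gm$calls[, gm$line == lab, drop = FALSE]
    n_ok <- rowSums(!is.na(calls))
    ifelse(n_ok == 0, NA_real_, rowSums(calls, na.rm = TRUE) / (2 * n_ok))
  }
  abs(p_line("HIGH") - p_line("LOW"))
}

#' Chip allele-frequency-difference track
#'
#' [chip_afd()] evaluated at every marker of one chromosome.
#'
#' @param gm A `genotype_matrix`.
#' @param chrom Chromosome to extract (default: the only one present).
#' @return A `value_track`.
#' @export
chip_afd_track <- function(gm, chrom = NULL) {
  if (is.null(chrom)) {
    chrom <- unique(gm$sites$chrom)
    if (length(chrom) != 1L) {
      stop("genotype matrix spans several chromosomes; specify one", call. = FALSE)
    }
  }
  keep <- gm$sites$chrom == chrom
  afd <- .chip_afd_rows(gm)[keep]
  ord <- order(gm$sites$pos[keep])
  value_track(chrom, gm$sites$pos[keep][ord], afd[ord])
}
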