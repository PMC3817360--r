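#' Normalize a QTL support curve onto \[0, 1\]
#'
#' Min-max normalization of the curve's scores within a region:
#' `(s - min) / (max - min)`. A constant curve maps to all zeros (there is
#' no information to rank positions by, and this avoids division by zero).
#'
#' @param curve A `support_curve`.
#' @param region Optional single-row `regions` data frame; points outside
#'   it are dropped before normalizing.
#' @return A `value_track` of normalized scores.
#' @export
normalize_support <- function(curve, region = NULL) {
  pts <- curve$points
  if (!is.null(region)) {
    pts <- pts[pts$pos_bp >= region$start_bp[1] & pts$pos_bp <= region$end_bp[1], ,
               drop = FALSE]
  }
  if (nrow(pts) == 0L) stop("support curve empty within region", call. = FALSE)
  rng <- range(pts$score)
  v <- if (rng[1] == rng[2]) rep(0, nrow(pts)) else (pts$score - rng[1]) / diff(rng)
  value_track(curve$chrom, pts$pos_bp, v)
}

#' Combined data score
#'
#' Fuses the three evidence tracks at one position into a single score:
#' \deqn{CDS = \{[(FSV + AFD_{chip}) / 2] + Q\} / 2}
#' where FSV is the pooled-sequencing divergence, AFD the chip
#' allele-frequency difference and Q the normalized QTL support;
#' equivalently `0.25*fsv + 0.25*afd + 0.5*q`. The QTL evidence therefore
#' carries half the weight and each divergence source a quarter.
#'
#' @param fsv_score,chip_afd,norm_qtl Values in \[0, 1\] (vectorized).
#' @return CDS values in \[0, 1\].
#' @examples
#' cds(0.8, 0.6, 0.9)  # 0.8
#' @export
cds <- function(fsv_score, chip_afd, norm_qtl) {
  for (nm in c("fsv_score", "chip_afd", "norm_qtl")) {
    v <- get(nm)
    if (any(is.na(v)) || any(v < 0 | v > 1)) {
      stop(sprintf("%s must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  ((fsv_score + chip_afd) / 2 + norm_qtl) / 2
}

#' Build the combined-data-score track over a region
#'
#' Evaluates [cds()] at every sequencing-SNP position of the FSV track
#' inside the region. The chip track contributes the value of the nearest
#' chip marker (ties resolved toward the lower position); the QTL track is
#' linearly interpolated between its flanking points (clamped at its
#' ends). Positions where any component is missing are omitted.
#'
#' @param fsv_track,chip_track,qtl_track `value_track`s on one chromosome.
#' @param region Optional single-row `regions` data frame restricting the
#'   evaluation positions.
#' @return A `value_track` of CDS values (possibly empty, with a warning).
#' @export
build_cds_track <- function(fsv_track, chip_track, qtl_track, region = NULL) {
  chroms <- unique(c(fsv_track$chrom, chip_track$chrom, qtl_track$chrom))
  chroms <- chroms[!is.na(chroms)]
  if (length(chroms) > 1L) stop("tracks are on different chromosomes", call. = FALSE)
  chrom <- if (length(chroms)) chroms[1] else NA_character_
  pos <- fsv_track$pos_bp
  f <- fsv_track$value
  if (!is.null(region)) {
    keep <- pos >= region$start_bp[1] & pos <= region$end_bp[1]
    pos <- pos[keep]; f <- f[keep]
  }
  a <- track_nearest(chip_track, pos)
  q <- track_interpolate(qtl_track, pos)
  ok <- !is.na(f) & !is.na(a) & !is.na(q)
  if (!any(ok)) {
    warning("no position has all three evidence tracks; empty CDS track")
    return(value_track(chrom, numeric(), numeric()))
  }
  value_track(chrom, pos[ok], cds(f[ok], a[ok], q[ok]))
}

# value of the nearest track point for each query position (ties -> lower)
track_nearest <- function(track, pos) {
  tp <- track$pos_bp[!is.na(track$value)]
  tv <- track$value[!is.na(track$value)]
  if (!length(tp)) return(rep(NA_real_, length(pos)))
  i <- findInterval(pos, tp)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(tp))
  d_lo <- abs(pos - tp[lo])
  d_hi <- abs(tp[hi] - pos)
  pick <- ifelse(i == 0L, hi, ifelse(i >= length(tp), lo,
                                     ifelse(d_lo <= d_hi, lo, hi)))
  tv[pick]
}

# linear interpolation of a track at query positions, clamped at the ends
track_interpolate <- function(track, pos) {
  tp <- track$pos_bp[!is.na(track$value)]
  tv <- track$value[!is.na(track$value)]
  if (!length(tp)) return(rep(NA_real_, length(pos)))
  if (length(tp) == 1L) return(rep(tv, length(pos)))
  stats::approx(tp, tv, xout = pos, method = "linear", rule = 2)$y
}

#' Segment-selection parameters
#'
#' @param cds_threshold Either a number in \[0, 1\] (minimum CDS) or a
#'   quantile spec string like `"q90"` (the 0.90 quantile of the track's
#'   own values).
#' @param require_qtl_significant Require the raw QTL support at a
#'   position (interpolated) to reach the curve's significance threshold.
#'   On by default; selection in regions whose QTL support never reaches
#'   significance needs this turned off.
#' @param merge_gap_bp Runs separated by less than this many bases are
#'   merged. The default (50 kb, about the scale of the flanking-SNP
#'   window) treats sub-window dips of the noisy site-level score as
#'   noise rather than signal boundaries.
#' @param min_segment_bp Segments spanning fewer bases than this are
#'   dropped.
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(cds_threshold = 0.8,
                             require_qtl_significant = TRUE,
                             merge_gap_bp = 50000, min_segment_bp = 0) {
  if (is.character(cds_threshold)) {
    if (!grepl("^q[0-9]{1,2}$", cds_threshold)) {
      stop("quantile threshold must look like 'q90'", call. = FALSE)
    }
  } else if (cds_threshold < 0 || cds_threshold > 1) {
    stop("cds_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (merge_gap_bp < 0 || min_segment_bp < 0) {
    stop("gap and length parameters must be >= 0", call. = FALSE)
  }
  structure(list(cds_threshold = cds_threshold,
                 require_qtl_significant = require_qtl_significant,
                 merge_gap_bp = merge_gap_bp,
                 min_segment_bp = min_segment_bp),
            class = "selection_params")
}

#' Select high-scoring candidate segments from a CDS track
#'
#' Finds maximal runs of consecutive track positions whose CDS reaches the
#' threshold (and, when required, whose raw QTL support reaches the
#' curve's significance level), merges runs separated by less than
#' `merge_gap_bp`, and drops segments spanning fewer than
#' `min_segment_bp`. Segments extend from the first to the last qualifying
#' position of a run.
#'
#' @param cds_track A `value_track` of CDS values.
#' @param qtl Optional `support_curve` used for the significance
#'   requirement.
#' @param params A `selection_params` object.
#' @param region_name Optional label attached to the returned segments.
#' @return A `regions` data frame of sorted, non-overlapping segments
#'   (zero rows if nothing qualifies).
#' @export
select_segments <- function(cds_track, qtl = NULL,
                            params = selection_params(),
                            region_name = NA_character_) {
  empty <- {
    df <- data.frame(name = character(), chrom = character(),
                     start_bp = numeric(), end_bp = numeric(),
                     size_mbp = numeric(), stringsAsFactors = FALSE)
    class(df) <- c("regions", "data.frame")
    df
  }
  if (nrow(cds_track) == 0L) return(empty)
  thr <- params$cds_threshold
  if (is.character(thr)) {
    p <- as.numeric(sub("^q", "", thr)) / 100
    thr <- stats::quantile(cds_track$value, p, na.rm = TRUE, names = FALSE)
  }
  ok <- !is.na(cds_track$value) & cds_track$value >= thr
  if (params$require_qtl_significant && !is.null(qtl)) {
    qt <- value_track_raw(qtl)
    raw_q <- stats::approx(qt$pos_bp, qt$score, xout = cds_track$pos_bp,
                           method = "linear", rule = 2)$y
    ok <- ok & raw_q >= qtl$sig_threshold
  }
  if (!any(ok)) return(empty)
  pos <- cds_track$pos_bp
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- data.frame(start = pos[starts[runs$values]],
                    end = pos[ends[runs$values]])
  # merge runs closer than merge_gap_bp
  if (nrow(seg) > 1L && params$merge_gap_bp > 0) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      gap <- seg$start[i] - merged$end[nrow(merged)]
      if (gap < params$merge_gap_bp) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  seg <- seg[(seg$end - seg$start) >= params$min_segment_bp, , drop = FALSE]
  if (!nrow(seg)) return(empty)
  suppressWarnings(  # single-point runs give zero-size segments; fine here
    regions(chrom = cds_track$chrom[1], start_bp = seg$start,
            end_bp = seg$end, name = region_name))
}

# support curve points as a plain frame (helper for interpolation)
value_track_raw <- function(curve) curve$points

#' Summarize selected segments against their QTL regions
#'
#' Per-QTL-region and total selected sizes (Mbp, 0.1 precision) and the
#' percentage of the total QTL extent covered by the selection (integer
#' rounding). Every selected segment must fall inside one of the QTL
#' regions. When the QTL table carries originally reported sizes
#' (`size_printed_mbp`), those are used for the QTL totals (they are the
#' report-level sizes); otherwise sizes are recomputed from coordinates.
#'
#' @param qtls A `regions` data frame of QTL regions.
#' @param selected A `regions` data frame of selected segments.
#' @return A list with `per_region` (data frame), `total_selected_mbp`,
#'   `total_qtl_mbp` and `percent_covered`.
#' @export
summarize_selection <- function(qtls, selected) {
  qtl_sizes <- if (!is.null(qtls$size_printed_mbp)) {
    qtls$size_printed_mbp
  } else {
    region_size_mbp(qtls)
  }
  host <- rep(NA_integer_, nrow(selected))
  for (i in seq_len(nrow(selected))) {
    j <- which(qtls$chrom == selected$chrom[i] &
                 qtls$start_bp <= selected$start_bp[i] &
                 qtls$end_bp >= selected$end_bp[i])
    if (!length(j)) {
      stop(sprintf("selected segment %s:%s-%s lies outside every QTL region",
                   selected$chrom[i],
                   format(selected$start_bp[i], scientific = FALSE),
                   format(selected$end_bp[i], scientific = FALSE)),
           call. = FALSE)
    }
    host[i] <- j[1]
  }
  sel_sizes <- region_size_mbp(selected)
  per_region <- data.frame(
    name = qtls$name,
    qtl_size_mbp = qtl_sizes,
    selected_mbp = round(vapply(seq_len(nrow(qtls)), function(j) {
      sum(sel_sizes[host == j])
    }, numeric(1)), 1),
    stringsAsFactors = FALSE)
  total_selected <- round(sum(sel_sizes), 1)
  total_qtl <- round(sum(qtl_sizes), 1)
  list(per_region = per_region,
       total_selected_mbp = total_selected,
       total_qtl_mbp = total_qtl,
       percent_covered = as.integer(round(100 * total_selected / total_qtl)))
}
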