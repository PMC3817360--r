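# Physicochemical property table for the 20 standard amino acids.
# hydropathy: Kyte-Doolittle; volume: residue volume (A^3, Zamyatnin);
# charge: net side-chain charge at physiological pH; polarity: Grantham;
# aromaticity: indicator (His counted half-aromatic).
.aa_properties <- local({
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- cbind(
    hydropathy  = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                    3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    volume      = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1,
                    153.2, 166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0,
                    116.1, 227.8, 193.6, 140.0),
    charge      = c(0, 1, 0, -1, 0, 0, -1, 0, 0.1, 0,
                    0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    polarity    = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
                    4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    aromaticity = c(0, 0, 0, 0, 0, 0, 0, 0, 0.5, 0,
                    0, 0, 0, 1, 0, 0, 0, 1, 1, 0)
  )
  rownames(m) <- aa
  m
})

#' Amino-acid property matrix used by the physicochemical score
#'
#' Returns the 20 x 5 matrix of residue properties (Kyte-Doolittle
#' hydropathy, residue volume, net charge, Grantham polarity, aromaticity)
#' that [pc_score()] standardizes and compares.
#'
#' @return Numeric matrix with one row per standard amino acid
#'   (single-letter rownames) and one column per property.
#' @export
aa_properties <- function() .aa_properties

# z-scored property matrix and the maximum pairwise distance, computed once
.aa_zscored <- scale(.aa_properties)
.aa_dist <- as.matrix(stats::dist(.aa_zscored))
.aa_dist_max <- max(.aa_dist)

.check_aa <- function(aa, arg) {
  bad <- !(aa %in% rownames(.aa_properties))
  if (any(bad)) {
    stop(sprintf("%s contains non-standard amino acid symbol(s): %s",
                 arg, paste(unique(aa[bad]), collapse = ", ")), call. = FALSE)
  }
}

#' Physicochemical substitution score
#'
#' Distance between two amino acids in a standardized property space
#' (hydropathy, volume, charge, polarity, aromaticity; each property
#' z-scored across the 20 residues), scaled so that the most dissimilar of
#' the 190 unordered residue pairs scores exactly 1. The score is symmetric
#' and 0 for an identical substitution.
#'
#' @param aa_from,aa_to Single-letter amino-acid codes (vectorized).
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' pc_score("K", "K") # 0
#' pc_score("K", "I") == pc_score("I", "K")
#' @export
pc_score <- function(aa_from, aa_to) {
  aa_from <- toupper(as.character(aa_from))
  aa_to <- toupper(as.character(aa_to))
  .check_aa(aa_from, "aa_from")
  .check_aa(aa_to, "aa_to")
  .aa_dist[cbind(aa_from, aa_to)] / .aa_dist_max
}

#' Evolutionary-conservation substitution score
#'
#' Conservation-weighted intolerance of replacing `aa_from` by `aa_to` at an
#' alignment column: the frequency of `aa_from` among the aligned residues
#' multiplied by one minus the frequency of `aa_to`. Gaps are excluded from
#' the frequencies (a gap is absence of evidence, not a residue). A
#' perfectly conserved column with an unseen target allele scores 1; a
#' target seen in every sequence scores 0.
#'
#' @param column Character vector of aligned residues at one position, one
#'   per orthologous sequence; `-` and `.` are treated as gaps.
#' @param aa_from,aa_to Single-letter amino-acid codes.
#' @return Score in \[0, 1\].
#' @export
ec_score <- function(column, aa_from, aa_to) {
  column <- toupper(as.character(column))
  if (length(column) == 0L) stop("empty alignment column", call. = FALSE)
  res <- column[!(column %in% c("-", ".", ""))]
  if (length(res) == 0L) stop("alignment column contains only gaps", call. = FALSE)
  aa_from <- toupper(aa_from)
  aa_to <- toupper(aa_to)
  .check_aa(aa_from, "aa_from")
  .check_aa(aa_to, "aa_to")
  if (!(aa_from %in% res)) {
    warning(sprintf("aa_from '%s' not observed in alignment column", aa_from))
  }
  f_from <- mean(res == aa_from)
  f_to <- mean(res == aa_to)
  f_from * (1 - f_to)
}

#' Combined substitution score
#'
#' Product of the physicochemical and evolutionary-conservation scores.
#' Reports render it to two decimals.
#'
#' @param pc,ec Scores in \[0, 1\] (vectorized).
#' @return `pc * ec`.
#' @examples
#' round(pe_score(0.67, 0.63), 2)
#' @export
pe_score <- function(pc, ec) {
  pc <- as.numeric(pc)
  ec <- as.numeric(ec)
  if (any(is.na(pc) | is.na(ec))) stop("pc and ec must be non-missing", call. = FALSE)
  if (any(pc < 0 | pc > 1)) stop("pc outside [0, 1]", call. = FALSE)
  if (any(ec < 0 | ec > 1)) stop("ec outside [0, 1]", call. = FALSE)
  pc * ec
}

#' Score one amino-acid substitution
#'
#' Convenience wrapper combining [pc_score()], [ec_score()] and
#' [pe_score()] for a single substitution.
#'
#' @param aa_from,aa_to Single-letter amino-acid codes.
#' @param column Optional alignment column (see [ec_score()]); when absent
#'   only the physicochemical score is computed and `ec`/`pe` are `NA`.
#' @return One-row data frame with columns `aa_from`, `aa_to`, `pc`, `ec`,
#'   `pe`.
#' @export
score_substitution <- function(aa_from, aa_to, column = NULL) {
  pc <- pc_score(aa_from, aa_to)
  if (is.null(column)) {
    ec <- NA_real_
    pe <- NA_real_
  } else {
    ec <- ec_score(column, aa_from, aa_to)
    pe <- pe_score(pc, ec)
  }
  data.frame(aa_from = aa_from, aa_to = aa_to, pc = pc, ec = ec, pe = pe,
             stringsAsFactors = FALSE)
}

#' Extract one column from a protein multiple alignment
#'
#' @param alignment An `AAStringSet` (e.g. from
#'   [Biostrings::readAAStringSet()]) whose sequences all have equal length,
#'   or a character vector of aligned sequences.
#' @param i Column index (1-based).
#' @return Character vector of residues, one per sequence.
#' @export
alignment_column <- function(alignment, i) {
  if (methods::is(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  widths <- unique(nchar(alignment))
  if (length(widths) != 1L) stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  if (i < 1L || i > widths) stop("column index out of range", call. = FALSE)
  substr(alignment, i, i)
}
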