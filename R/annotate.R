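# Closed consequence vocabulary (summary-table spelling preserved) and
# severity ranks used to reduce per-transcript labels to one per gene.
.consequence_severity <- c(
  "Stop gained, Non-synonymous coding" = 20,
  "Stop gained" = 19,
  "Essential splice site" = 18,
  "Non-synonymous coding, Splice site" = 17,
  "Non-synonymous coding" = 16,
  "Coding unknown" = 15,
  "splice site, Intronic" = 14,
  "Synonymous coding, splice site" = 13,
  "Synonymous coding" = 12,
  "5Prime UTR, Splice site" = 11,
  "3Prime UTR, Splice site" = 10,
  "5Prime UTR" = 9,
  "3Prime UTR" = 8,
  "Within non-coding gene, splice site" = 7,
  "Within mature miRNA" = 6,
  "Within non-coding gene" = 5,
  "Intronic" = 4,
  "Upstream" = 3,
  "Downstream" = 2,
  "Intergenic" = 1)

#' The closed set of consequence labels
#'
#' @return Character vector of every label [classify_variant()] can emit.
#' @export
consequence_vocabulary <- function() names(.consequence_severity)

#' Severity rank of consequence labels
#'
#' Higher is more severe; used for per-gene reduction and candidate
#' ordering.
#'
#' @param label Character vector of consequence labels.
#' @return Integer severity ranks.
#' @export
consequence_severity <- function(label) {
  out <- .consequence_severity[label]
  if (any(is.na(out))) {
    stop(sprintf("unknown consequence label(s): %s",
                 paste(unique(label[is.na(out)]), collapse = ", ")),
         call. = FALSE)
  }
  unname(out)
}

#' Annotation parameters
#'
#' @param flank_bp Up/downstream flank around a transcript within which a
#'   variant is still associated with the gene (default 5 kb, the common
#'   annotation-tool convention).
#' @param essential_splice_bp Intronic bases at each intron end called
#'   essential splice site (default 2: the canonical donor/acceptor
#'   dinucleotides).
#' @param splice_intron_bp Intronic bases from a junction (beyond the
#'   essential two) still labelled splice region (default 8).
#' @param splice_exon_bp Exonic bases adjacent to an internal junction
#'   co-labelled splice site (default 3).
#' @return A list of class `annotation_params`.
#' @export
annotation_params <- function(flank_bp = 5000, essential_splice_bp = 2,
                              splice_intron_bp = 8, splice_exon_bp = 3) {
  structure(list(flank_bp = flank_bp,
                 essential_splice_bp = essential_splice_bp,
                 splice_intron_bp = splice_intron_bp,
                 splice_exon_bp = splice_exon_bp),
            class = "annotation_params")
}

.revcomp_base <- function(b) chartr("ACGTacgt", "TGCAtgca", b)

# consequence of (pos, alt) against one transcript; NULL when unrelated
.tx_consequence <- function(pos, alt, gene, tx, genome, params) {
  ex <- tx$exons
  span <- c(min(ex$start), max(ex$end))
  if (pos < span[1] || pos > span[2]) {
    d <- if (pos < span[1]) span[1] - pos else pos - span[2]
    if (d > params$flank_bp) return(NULL)
    before <- pos < span[1]
    upstream <- (before && gene$strand == "+") || (!before && gene$strand == "-")
    return(list(label = if (upstream) "Upstream" else "Downstream",
                aa_from = NA_character_, aa_to = NA_character_))
  }
  k <- which(ex$start <= pos & ex$end >= pos)
  if (!length(k)) {
    # intronic: distances from the two flanking junctions (1 = first base)
    j <- max(which(ex$end < pos))
    d <- min(pos - ex$end[j], ex$start[j + 1] - pos)
    lab <- if (d <= params$essential_splice_bp) {
      "Essential splice site"
    } else if (d <= params$splice_intron_bp) {
      "splice site, Intronic"
    } else "Intronic"
    return(list(label = lab, aa_from = NA_character_, aa_to = NA_character_))
  }
  k <- k[1]
  near_splice <- (k > 1L && pos - ex$start[k] + 1 <= params$splice_exon_bp) ||
    (k < nrow(ex) && ex$end[k] - pos + 1 <= params$splice_exon_bp)
  add_splice <- function(lab) {
    if (!near_splice) return(lab)
    switch(lab,
           "Synonymous coding" = "Synonymous coding, splice site",
           "Non-synonymous coding" = "Non-synonymous coding, Splice site",
           "5Prime UTR" = "5Prime UTR, Splice site",
           "3Prime UTR" = "3Prime UTR, Splice site",
           "Within non-coding gene" = "Within non-coding gene, splice site",
           lab)
  }
  if (is.null(tx$cds) || !nrow(tx$cds)) {
    lab <- if (gene$biotype == "miRNA") "Within mature miRNA" else "Within non-coding gene"
    return(list(label = add_splice(lab),
                aa_from = NA_character_, aa_to = NA_character_))
  }
  cds_min <- min(tx$cds$start)
  cds_max <- max(tx$cds$end)
  if (pos < cds_min || pos > cds_max) {
    five <- (pos < cds_min) == (gene$strand == "+")
    return(list(label = add_splice(if (five) "5Prime UTR" else "3Prime UTR"),
                aa_from = NA_character_, aa_to = NA_character_))
  }
  ci <- which(tx$cds$start <= pos & tx$cds$end >= pos)
  if (!length(ci)) {
    # inside the CDS genomic extent but not in a CDS span (e.g. a coding
    # intron retained in this exon set): cannot translate
    return(list(label = "Coding unknown",
                aa_from = NA_character_, aa_to = NA_character_))
  }
  ci <- ci[1]
  lens <- tx$cds$end - tx$cds$start + 1
  goff <- if (ci > 1) sum(lens[seq_len(ci - 1)]) else 0
  goff <- goff + (pos - tx$cds$start[ci] + 1)
  total <- sum(lens)
  cds_chars <- character(nrow(tx$cds))
  chrom_seq <- genome[[gene$chrom]]
  for (i in seq_len(nrow(tx$cds))) {
    cds_chars[i] <- as.character(Biostrings::subseq(chrom_seq,
                                                    tx$cds$start[i],
                                                    tx$cds$end[i]))
  }
  cds_seq <- paste(cds_chars, collapse = "")
  if (gene$strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
    cpos <- total - goff + 1
    first_phase <- tx$cds$phase[nrow(tx$cds)]
    alt_tx <- .revcomp_base(alt)
  } else {
    cpos <- goff
    first_phase <- tx$cds$phase[1]
    alt_tx <- alt
  }
  cpos <- cpos - first_phase
  if (cpos < 1) {
    return(list(label = "Coding unknown",
                aa_from = NA_character_, aa_to = NA_character_))
  }
  seq_adj <- substring(cds_seq, first_phase + 1)
  codon_i <- (cpos - 1) %/% 3 + 1
  within <- (cpos - 1) %% 3 + 1
  codon <- toupper(substr(seq_adj, 3 * (codon_i - 1) + 1, 3 * codon_i))
  if (nchar(codon) < 3L) {
    return(list(label = "Coding unknown",
                aa_from = NA_character_, aa_to = NA_character_))
  }
  new_codon <- codon
  substr(new_codon, within, within) <- toupper(alt_tx)
  code <- Biostrings::GENETIC_CODE
  aa_from <- unname(code[codon])
  aa_to <- unname(code[new_codon])
  if (is.na(aa_from) || is.na(aa_to)) {
    return(list(label = "Coding unknown",
                aa_from = NA_character_, aa_to = NA_character_))
  }
  if (aa_from == aa_to) {
    return(list(label = add_splice("Synonymous coding"),
                aa_from = NA_character_, aa_to = NA_character_))
  }
  if (aa_from != "*" && aa_to == "*") {
    return(list(label = "Stop gained", aa_from = aa_from, aa_to = aa_to))
  }
  if (aa_from == "*") {
    # stop-lost read-through: downstream protein unknown
    return(list(label = "Coding unknown",
                aa_from = NA_character_, aa_to = NA_character_))
  }
  list(label = add_splice("Non-synonymous coding"),
       aa_from = aa_from, aa_to = aa_to)
}

#' Classify a variant against gene models
#'
#' Assigns each gene overlapping (or flanking, within `flank_bp`) the site
#' one consequence label from the closed vocabulary
#' ([consequence_vocabulary()]). Per gene, transcript-level labels are
#' reduced by severity; coding effects are computed by codon translation
#' honoring strand and phase (standard genetic code). A gene whose
#' transcripts yield both a stop-gain and a non-synonymous label reports
#' the combined `"Stop gained, Non-synonymous coding"` class.
#'
#' @param site One-row `snp_sites` data frame (or list with `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param genes List of `gene_model` objects.
#' @param genome Named `DNAStringSet` (one sequence per chromosome). The
#'   site's reference allele must match the genome at its position.
#' @param params An `annotation_params` object.
#' @return Data frame with one row per related gene: `gene_id`,
#'   `gene_name`, `consequence`, `aa_from`, `aa_to` (amino-acid change for
#'   coding-change classes, otherwise `NA`). Zero rows for an intergenic
#'   site.
#' @export
classify_variant <- function(site, genes, genome, params = annotation_params()) {
  pos <- as.numeric(site$pos)
  chrom <- as.character(site$chrom)
  ref_gen <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
  if (toupper(ref_gen) != toupper(as.character(site$ref))) {
    stop(sprintf("reference mismatch at %s:%s (genome %s, site %s)",
                 chrom, format(pos, scientific = FALSE), ref_gen, site$ref),
         call. = FALSE)
  }
  rows <- list()
  for (g in genes) {
    if (g$chrom != chrom) next
    labs <- list()
    for (tx in g$transcripts) {
      res <- .tx_consequence(pos, as.character(site$alt), g, tx, genome, params)
      if (!is.null(res)) labs[[length(labs) + 1L]] <- res
    }
    if (!length(labs)) next
    lab_vec <- vapply(labs, `[[`, "", "label")
    has_stop <- any(lab_vec %in% c("Stop gained"))
    has_ns <- any(startsWith(lab_vec, "Non-synonymous"))
    if (has_stop && has_ns) {
      pickv <- labs[[which(lab_vec == "Stop gained")[1]]]
      best_label <- "Stop gained, Non-synonymous coding"
    } else {
      sev <- consequence_severity(lab_vec)
      best_label <- lab_vec[which.max(sev)]
      same <- labs[lab_vec == best_label]
      aa_keys <- vapply(same, function(x) paste(x$aa_from, x$aa_to), "")
      pickv <- same[[order(aa_keys)[1]]]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, gene_name = g$gene_name,
      consequence = best_label,
      aa_from = pickv$aa_from, aa_to = pickv$aa_to,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), gene_name = character(),
                      consequence = character(), aa_from = character(),
                      aa_to = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify every site in a table
#'
#' [classify_variant()] applied across a `snp_sites` table; rows are
#' (site, gene) pairs, so one SNP genic in one gene and flanking another
#' yields two rows. Intergenic sites get a single `"Intergenic"` row with
#' no gene.
#'
#' @inheritParams classify_variant
#' @param sites A `snp_sites` data frame.
#' @return Data frame with columns `chrom`, `pos`, `gene_id`, `gene_name`,
#'   `consequence`, `aa_from`, `aa_to`.
#' @export
classify_variants <- function(sites, genes, genome,
                              params = annotation_params()) {
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cl <- classify_variant(sites[i, ], genes, genome, params)
    if (nrow(cl) == 0L) {
      cl <- data.frame(gene_id = NA_character_, gene_name = NA_character_,
                       consequence = "Intergenic", aa_from = NA_character_,
                       aa_to = NA_character_, stringsAsFactors = FALSE)
    }
    cl$chrom <- sites$chrom[i]
    cl$pos <- sites$pos[i]
    out[[i]] <- cl[c("chrom", "pos", "gene_id", "gene_name", "consequence",
                     "aa_from", "aa_to")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CpG-island relation of a site
#'
#' Whether the site lies in a CpG island and, if so, how that island
#' relates to nearby genes: `"CpG island, coding"` when the site falls in
#' a coding sequence, `"CpG island, upstream"` / `"CpG island,
#' downstream"` when it lies in a gene's flank (gene orientation
#' respected), plain `"CpG island"` otherwise, and `"NONE"` outside all
#' islands.
#'
#' @param site One-row `snp_sites` data frame or list with `chrom`, `pos`.
#' @param islands A `regions` data frame of CpG islands.
#' @param genes List of `gene_model` objects.
#' @param params An `annotation_params` object (flank width).
#' @return A single relation label.
#' @export
cpg_relation <- function(site, islands, genes, params = annotation_params()) {
  chrom <- as.character(site$chrom)
  pos <- as.numeric(site$pos)
  if (!nrow(islands) || !any(in_regions(chrom, pos, islands))) return("NONE")
  rel <- "CpG island"
  best <- 0L  # 3 coding > 2 upstream > 1 downstream
  for (g in genes) {
    if (g$chrom != chrom) next
    cd <- gene_cds_spans(g)
    if (!is.null(cd) && any(cd$start <= pos & cd$end >= pos)) {
      if (best < 3L) { rel <- "CpG island, coding"; best <- 3L }
      next
    }
    sp <- gene_span(g)
    if (pos >= sp[1] && pos <= sp[2]) next
    d <- if (pos < sp[1]) sp[1] - pos else pos - sp[2]
    if (d > params$flank_bp) next
    before <- pos < sp[1]
    upstream <- (before && g$strand == "+") || (!before && g$strand == "-")
    if (upstream && best < 2L) { rel <- "CpG island, upstream"; best <- 2L }
    if (!upstream && best < 1L) { rel <- "CpG island, downstream"; best <- 1L }
  }
  rel
}

#' Growth-related annotation keywords
#'
#' The default keyword list used to retain genes whose functional
#' annotations suggest a role in growth.
#'
#' @return Lowercase character vector of keywords.
#' @export
growth_keywords <- function() {
  c("growth", "development", "morphogenesis", "formation", "proliferation",
    "differentiation", "regeneration", "mineralization", "elongation",
    "biosynthetic", "biogenesis", "organization")
}

#' Filter genes by annotation keywords
#'
#' Keeps the genes any of whose free-text annotation terms contains any
#' keyword as a case-insensitive substring (so `"biosynthetic"` matches
#' `"biosynthetic process"`). Adding a keyword can only grow the result.
#'
#' @param annotations Data frame with columns `gene_id` and `term`
#'   (one row per gene-term pair).
#' @param keywords Character vector of keywords (default
#'   [growth_keywords()]).
#' @return Character vector of unique gene ids passing the filter.
#' @export
keyword_filter <- function(annotations, keywords = growth_keywords()) {
  if (!length(keywords)) stop("keyword set must be non-empty", call. = FALSE)
  keywords <- tolower(keywords)
  terms <- tolower(as.character(annotations$term))
  hit <- rep(FALSE, length(terms))
  for (kw in keywords) hit <- hit | grepl(kw, terms, fixed = TRUE)
  unique(as.character(annotations$gene_id[hit]))
}

#' Assemble and rank candidate mutation records
#'
#' Restricts called SNPs to the selected segments and to genes passing the
#' keyword filter, attaches the consequence label, CpG relation, read
#' support and divergence, scores amino-acid substitutions, and returns
#' the top candidates per segment ordered by allele frequency difference
#' (descending), consequence severity (descending) and combined
#' substitution score (descending), with position as the stable
#' tie-break.
#'
#' @param segments A `regions` data frame of selected segments (the `name`
#'   column labels the report's region column).
#' @param sites A `snp_sites` data frame of called SNPs.
#' @param classifications Output of [classify_variants()] for `sites`.
#' @param islands CpG islands (`regions` data frame).
#' @param genes List of `gene_model` objects.
#' @param afd Per-site allele-frequency-difference estimates aligned with
#'   the rows of `sites` (defaults to [site_divergence()]).
#' @param keep_genes Gene ids passing the keyword filter; only their
#'   variants are reported.
#' @param ec_columns Optional named list mapping `gene_id` to an alignment
#'   column (see [ec_score()]) used to score that gene's substitutions;
#'   genes without a column get `NA` conservation and combined scores.
#' @param k Candidates reported per region (default 2).
#' @param params An `annotation_params` object.
#' @return Data frame of candidate records in report order (columns of
#'   [write_candidates()]).
#' @export
rank_candidates <- function(segments, sites, classifications, islands, genes,
                            keep_genes, afd = NULL, ec_columns = NULL, k = 2,
                            params = annotation_params()) {
  if (is.null(afd)) afd <- site_divergence(sites)
  empty <- data.frame(region = character(), snp_bp = numeric(),
                      gene = character(), snp_location = character(),
                      alt_reads = numeric(), depth = numeric(),
                      qual = numeric(), afd = numeric(), pc = numeric(),
                      ec = numeric(), pe = numeric(),
                      severity = numeric(), stringsAsFactors = FALSE)
  if (!nrow(segments) || !nrow(sites)) return(empty[, -12])
  recs <- list()
  for (i in seq_len(nrow(sites))) {
    seg_hit <- which(segments$chrom == sites$chrom[i] &
                       segments$start_bp <= sites$pos[i] &
                       segments$end_bp >= sites$pos[i])
    if (!length(seg_hit)) next
    cl <- classifications[classifications$chrom == sites$chrom[i] &
                            classifications$pos == sites$pos[i] &
                            !is.na(classifications$gene_id) &
                            classifications$gene_id %in% keep_genes, ,
                          drop = FALSE]
    if (!nrow(cl)) next
    rel <- cpg_relation(sites[i, ], islands, genes, params)
    for (j in seq_len(nrow(cl))) {
      cons <- cl$consequence[j]
      in_island <- rel != "NONE"
      loc <- if (startsWith(cons, "Non-synonymous") ||
                 startsWith(cons, "Stop gained")) {
        aa <- if (!is.na(cl$aa_from[j])) {
          sprintf(" %s/%s", cl$aa_from[j], cl$aa_to[j])
        } else ""
        base <- if (startsWith(cons, "Stop gained")) {
          sprintf("Protein code, stop gained%s", aa)
        } else sprintf("Protein code, NS%s", aa)
        if (in_island) paste0(base, ", CpG island") else base
      } else if (startsWith(cons, "Synonymous")) {
        if (in_island) "Protein code, synonymous, CpG island" else "Protein code, synonymous"
      } else if (in_island) {
        rel
      } else cons
      pc <- ec <- pe <- NA_real_
      if (!is.na(cl$aa_from[j]) && cl$aa_from[j] %in% rownames(aa_properties()) &&
          !is.na(cl$aa_to[j]) && cl$aa_to[j] %in% rownames(aa_properties())) {
        pc <- pc_score(cl$aa_from[j], cl$aa_to[j])
        if (!is.null(ec_columns) && cl$gene_id[j] %in% names(ec_columns)) {
          ec <- ec_score(ec_columns[[cl$gene_id[j]]], cl$aa_from[j], cl$aa_to[j])
          pe <- pe_score(pc, ec)
        } else {
          pc <- NA_real_  # report PC only alongside EC (scores travel together)
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(
        region = segments$name[seg_hit[1]],
        snp_bp = sites$pos[i],
        gene = cl$gene_name[j],
        snp_location = loc,
        alt_reads = sites$alt_reads_h[i] + sites$alt_reads_l[i],
        depth = sites$ref_reads_h[i] + sites$alt_reads_h[i] +
          sites$ref_reads_l[i] + sites$alt_reads_l[i],
        qual = sites$qual[i],
        afd = afd[i],
        pc = pc, ec = ec, pe = pe,
        severity = consequence_severity(cons),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(empty[, -12])
  df <- do.call(rbind, recs)
  ord <- order(df$region, -df$afd, -df$severity,
               -ifelse(is.na(df$pe), -Inf, df$pe), df$snp_bp)
  df <- df[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$region), utils::head, k),
                 use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]
  df$severity <- NULL
  rownames(df) <- NULL
  df
}

#' Count consequences by label and region
#'
#' Summary table of (site, gene) consequence pairs by label and region
#' name, in the fixed vocabulary order, with row and column totals.
#' Intergenic and plain intronic labels are excluded (the summary covers
#' SNPs in functional elements).
#'
#' @param classifications Output of [classify_variants()].
#' @param region_of Character vector of region names aligned with the rows
#'   of `classifications`.
#' @return Data frame of counts: one row per label present, one column per
#'   region plus `Total`.
#' @export
summarize_consequences <- function(classifications, region_of) {
  keep <- !(classifications$consequence %in% c("Intergenic", "Intronic"))
  cl <- classifications[keep, , drop = FALSE]
  region_of <- region_of[keep]
  labs <- intersect(consequence_vocabulary(), unique(cl$consequence))
  regs <- unique(region_of)
  m <- matrix(0L, nrow = length(labs), ncol = length(regs),
              dimnames = list(labs, regs))
  tab <- table(factor(cl$consequence, levels = labs),
               factor(region_of, levels = regs))
  m[] <- as.integer(tab)
  out <- data.frame(location = labs, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$Total <- rowSums(m)
  rbind(out, data.frame(location = "Total",
                        t(colSums(m)), Total = sum(m), check.names = FALSE))
}
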