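#' Construct a gene model
#'
#' A gene with one or more transcripts, each holding exon spans and
#' (for coding transcripts) CDS spans with phase. Coordinates are 1-based
#' inclusive; spans are data frames with `start`/`end` (and `phase` for
#' CDS) sorted by `start`.
#'
#' @param gene_id Stable identifier.
#' @param gene_name Display symbol (defaults to `gene_id`).
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param biotype `"coding"`, `"non-coding"` or `"miRNA"`.
#' @param transcripts Named list; each element is a list with `exons`
#'   (data frame `start`, `end`) and optionally `cds` (data frame `start`,
#'   `end`, `phase`).
#' @param flagged Set when the model failed a consistency check at load
#'   (e.g. CDS length not a multiple of 3); the gene is kept but marked.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, gene_name = gene_id, chrom, strand,
                       biotype = "coding", transcripts, flagged = FALSE) {
  stopifnot(strand %in% c("+", "-"),
            biotype %in% c("coding", "non-coding", "miRNA"))
  for (tx_id in names(transcripts)) {
    tx <- transcripts[[tx_id]]
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop(sprintf("transcript %s: overlapping exons", tx_id), call. = FALSE)
    }
    transcripts[[tx_id]]$exons <- ex
    if (!is.null(tx$cds) && nrow(tx$cds)) {
      cd <- tx$cds[order(tx$cds$start), , drop = FALSE]
      if (is.null(cd$phase)) cd$phase <- 0L
      in_exon <- vapply(seq_len(nrow(cd)), function(i) {
        any(ex$start <= cd$start[i] & ex$end >= cd$end[i])
      }, logical(1))
      if (!all(in_exon)) {
        stop(sprintf("transcript %s: CDS not contained in exons", tx_id),
             call. = FALSE)
      }
      transcripts[[tx_id]]$cds <- cd
    }
  }
  structure(list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
                 strand = strand, biotype = biotype,
                 transcripts = transcripts, flagged = flagged),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("gene_model %s (%s) %s:%d-%d [%s] %s, %d transcript(s)%s\n",
              x$gene_id, x$gene_name, x$chrom, sp[1], sp[2], x$strand,
              x$biotype, length(x$transcripts),
              if (isTRUE(x$flagged)) " (flagged)" else ""))
  invisible(x)
}

# genomic span of a gene (min exon start, max exon end over transcripts)
gene_span <- function(gene) {
  starts <- unlist(lapply(gene$transcripts, function(tx) tx$exons$start))
  ends <- unlist(lapply(gene$transcripts, function(tx) tx$exons$end))
  c(min(starts), max(ends))
}

# union of CDS spans over transcripts (data frame start/end), or NULL
gene_cds_spans <- function(gene) {
  cd <- do.call(rbind, lapply(gene$transcripts, function(tx) {
    if (is.null(tx$cds)) NULL else tx$cds[c("start", "end")]
  }))
  if (is.null(cd) || !nrow(cd)) NULL else cd
}

#' Read gene models from a GFF3 file
#'
#' Assembles one [gene_model()] per `gene` feature from the gene / mRNA /
#' exon / CDS hierarchy of a GFF3 file (`Parent` links). Strand and CDS
#' phase are retained; UTRs are implied (exon minus CDS). A CDS whose
#' total length is not a multiple of 3 (after phase adjustment) yields a
#' warning and a flagged gene, not a dropped one; a CDS without a
#' transcript parent yields a warning and is skipped.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of `gene_model` objects (empty if no genes).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (!nrow(df) || !"type" %in% names(df)) return(list())
  df$type <- as.character(df$type)
  first_chr <- function(x) {
    if (is.null(x)) return(NA_character_)
    vapply(x, function(e) {
      e <- as.character(unlist(e))
      if (length(e)) e[1] else NA_character_
    }, character(1))
  }
  df$ID <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  df$parent1 <- if ("Parent" %in% names(df)) first_chr(df$Parent) else NA_character_
  genes_df <- df[df$type == "gene", , drop = FALSE]
  tx_df <- df[df$type %in% c("mRNA", "transcript", "ncRNA", "miRNA"), , drop = FALSE]
  exon_df <- df[df$type == "exon", , drop = FALSE]
  cds_df <- df[df$type == "CDS", , drop = FALSE]
  orphans <- !is.na(cds_df$parent1) & !(cds_df$parent1 %in% tx_df$ID)
  if (any(orphans) || any(is.na(cds_df$parent1) & nrow(cds_df) > 0)) {
    n_orph <- sum(orphans | is.na(cds_df$parent1))
    if (n_orph > 0) {
      warning(sprintf("%d CDS feature(s) without a transcript parent skipped",
                      n_orph))
      cds_df <- cds_df[!(orphans | is.na(cds_df$parent1)), , drop = FALSE]
    }
  }
  out <- list()
  for (gi in seq_len(nrow(genes_df))) {
    g <- genes_df[gi, ]
    gid <- if (!is.na(g$ID)) g$ID else sprintf("gene%04d", gi)
    gname <- if ("Name" %in% names(genes_df) && !is.na(g$Name)) {
      as.character(g$Name)
    } else gid
    bt <- if ("biotype" %in% names(genes_df) && !is.na(g$biotype)) {
      as.character(g$biotype)
    } else "coding"
    bt <- switch(bt, protein_coding = "coding", miRNA = "miRNA",
                 coding = "coding", `non-coding` = "non-coding",
                 "non-coding")
    txs <- tx_df[tx_df$parent1 %in% gid, , drop = FALSE]
    flagged <- FALSE
    tlist <- list()
    for (ti in seq_len(nrow(txs))) {
      tid <- txs$ID[ti]
      ex <- exon_df[exon_df$parent1 %in% tid, c("start", "end"), drop = FALSE]
      cd <- cds_df[cds_df$parent1 %in% tid, , drop = FALSE]
      if (!nrow(ex)) next
      tx <- list(exons = ex[order(ex$start), , drop = FALSE])
      if (nrow(cd)) {
        phase <- if ("phase" %in% names(cd)) {
          suppressWarnings(as.integer(as.character(cd$phase)))
        } else rep(0L, nrow(cd))
        phase[is.na(phase)] <- 0L
        tx$cds <- data.frame(start = cd$start, end = cd$end, phase = phase)
        ord <- order(tx$cds$start)
        tx$cds <- tx$cds[ord, , drop = FALSE]
        first_phase <- if (g$strand == "-") {
          tx$cds$phase[nrow(tx$cds)]
        } else tx$cds$phase[1]
        cds_len <- sum(tx$cds$end - tx$cds$start + 1) - first_phase
        if (cds_len %% 3 != 0) {
          warning(sprintf("gene %s transcript %s: CDS length %d not a multiple of 3; gene flagged",
                          gid, tid, cds_len))
          flagged <- TRUE
        }
      }
      tlist[[tid]] <- tx
    }
    if (!length(tlist)) {
      # gene with no transcript children: treat its own span as one exon
      tlist <- list(structure(list(
        exons = data.frame(start = g$start, end = g$end)), names = NULL))
      names(tlist) <- paste0(gid, ".t1")
    }
    bt_gene <- if (bt == "coding" &&
                   !any(vapply(tlist, function(t) !is.null(t$cds), logical(1)))) {
      "non-coding"
    } else bt
    out[[gid]] <- gene_model(gid, gname, as.character(g$seqnames),
                             as.character(g$strand), bt_gene, tlist,
                             flagged = flagged)
  }
  out
}

#' Write gene models to a GFF3 file
#'
#' Plain-text GFF3 emission of the gene / mRNA / exon / CDS hierarchy;
#' inverse of [read_gff3()] for the fields the package uses.
#'
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, start, end, strand, phase, attrs) {
    sprintf("%s\tdivergescan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, as.integer(start), as.integer(end), strand,
            phase, attrs)
  }
  for (g in genes) {
    sp <- gene_span(g)
    bt <- switch(g$biotype, coding = "protein_coding", miRNA = "miRNA",
                 "non-coding" = "non_coding", g$biotype)
    lines <- c(lines, fmt(g$chrom, "gene", sp[1], sp[2], g$strand, ".",
                          sprintf("ID=%s;Name=%s;biotype=%s",
                                  g$gene_id, g$gene_name, bt)))
    for (tid in names(g$transcripts)) {
      tx <- g$transcripts[[tid]]
      tsp <- c(min(tx$exons$start), max(tx$exons$end))
      ttype <- if (g$biotype == "coding" && !is.null(tx$cds)) "mRNA" else "transcript"
      lines <- c(lines, fmt(g$chrom, ttype, tsp[1], tsp[2], g$strand, ".",
                            sprintf("ID=%s;Parent=%s", tid, g$gene_id)))
      for (i in seq_len(nrow(tx$exons))) {
        lines <- c(lines, fmt(g$chrom, "exon", tx$exons$start[i],
                              tx$exons$end[i], g$strand, ".",
                              sprintf("ID=%s.e%d;Parent=%s", tid, i, tid)))
      }
      if (!is.null(tx$cds)) {
        for (i in seq_len(nrow(tx$cds))) {
          lines <- c(lines, fmt(g$chrom, "CDS", tx$cds$start[i],
                                tx$cds$end[i], g$strand,
                                as.character(tx$cds$phase[i]),
                                sprintf("ID=%s.c;Parent=%s", tid, tid)))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' UTR spans of a transcript
#'
#' Exonic bases outside the CDS, split into 5' and 3' sets by strand.
#'
#' @param tx A transcript element of a `gene_model`.
#' @param strand `"+"` or `"-"`.
#' @return List with data frames `utr5` and `utr3` (`start`, `end`; zero
#'   rows when absent).
#' @export
transcript_utrs <- function(tx, strand) {
  none <- data.frame(start = numeric(), end = numeric())
  if (is.null(tx$cds) || !nrow(tx$cds)) {
    return(list(utr5 = none, utr3 = none))
  }
  ex <- IRanges::IRanges(tx$exons$start, tx$exons$end)
  cd <- IRanges::IRanges(min(tx$cds$start), max(tx$cds$end))
  utr <- IRanges::setdiff(ex, cd)
  if (!length(utr)) return(list(utr5 = none, utr3 = none))
  df <- data.frame(start = IRanges::start(utr), end = IRanges::end(utr))
  before <- df$end < min(tx$cds$start)
  reset <- function(x) { rownames(x) <- NULL; x }
  if (strand == "+") {
    list(utr5 = reset(df[before, , drop = FALSE]),
         utr3 = reset(df[!before, , drop = FALSE]))
  } else {
    list(utr5 = reset(df[!before, , drop = FALSE]),
         utr3 = reset(df[before, , drop = FALSE]))
  }
}
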