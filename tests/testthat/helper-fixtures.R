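# Shared fixtures: a hand-constructed genome + gene models with known codon
# layout, a mirroring helper for strand-symmetry checks, and independent
# brute-force oracles for the windowed smoother and segment selection.

gbase <- function(genome, pos, chrom = names(genome)[1]) {
  as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
}

other_base <- function(b) setdiff(c("A", "C", "G", "T"), toupper(b))[1]

# One plus-strand three-exon coding gene with a fully known CDS:
#   exon1 2001-2100 (5'UTR 2001-2030, CDS 2031-2100)
#   exon2 2301-2400 (all CDS)
#   exon3 2601-2700 (CDS 2601-2640, 3'UTR 2641-2700)
# CDS codons: ATG AAA ATA GGA then GCT x65 then TAA (210 bp).
# Plus a miRNA gene (15001-15100), a two-exon non-coding gene
# (22001-22100, 22301-22400) and a two-transcript frame-shifted gene at
# 30101-30161 where the base at 30105 is stop-gain in one frame and
# non-synonymous in the other. Genes sit more than one flank width apart
# so single-gene expectations stay clean.
toy_fixture <- function() {
  chrom <- "chrT"
  g <- strrep("ACGT", 10000)  # 40 kb background
  cds_seq <- paste0("ATG", "AAA", "ATA", "GGA", strrep("GCT", 65), "TAA")
  spans <- data.frame(start = c(2031, 2301, 2601), end = c(2100, 2400, 2640))
  off <- 0
  for (i in seq_len(nrow(spans))) {
    len <- spans$end[i] - spans$start[i] + 1
    substr(g, spans$start[i], spans$end[i]) <- substr(cds_seq, off + 1, off + len)
    off <- off + len
  }
  # frame-shift fixture sequence at 30101..30107: A T G T G G C
  substr(g, 30101, 30107) <- "ATGTGGC"
  genome <- Biostrings::DNAStringSet(stats::setNames(g, chrom))
  coding <- gene_model(
    "toyg1", "TOYG1", chrom, "+", "coding",
    list(toyg1.t1 = list(
      exons = data.frame(start = c(2001, 2301, 2601), end = c(2100, 2400, 2700)),
      cds = data.frame(start = spans$start, end = spans$end, phase = c(0, 2, 1)))))
  mirna <- gene_model(
    "toyg2", "TOYG2", chrom, "+", "miRNA",
    list(toyg2.t1 = list(exons = data.frame(start = 15001, end = 15100))))
  noncoding <- gene_model(
    "toyg3", "TOYG3", chrom, "+", "non-coding",
    list(toyg3.t1 = list(
      exons = data.frame(start = c(22001, 22301), end = c(22100, 22400)))))
  twoframe <- gene_model(
    "toyg4", "TOYG4", chrom, "+", "coding",
    list(toyg4.t1 = list(exons = data.frame(start = 30101, end = 30161),
                         cds = data.frame(start = 30101, end = 30160,
                                          phase = 0)),
         toyg4.t2 = list(exons = data.frame(start = 30101, end = 30161),
                         cds = data.frame(start = 30102, end = 30161,
                                          phase = 0))))
  list(genome = genome, chrom = chrom,
       genes = list(toyg1 = coding, toyg2 = mirna, toyg3 = noncoding,
                    toyg4 = twoframe))
}

toy_site <- function(fx, pos, alt = NULL, ref = NULL) {
  if (is.null(ref)) ref <- gbase(fx$genome, pos)
  if (is.null(alt)) alt <- other_base(ref)
  snp_sites(fx$chrom, pos, ref, alt, 5, 5, 5, 5, qual = 50)
}

# reverse-complement a single-chromosome fixture: genome, gene coordinates
# and strands are mirrored; a site at pos maps to L - pos + 1 with
# complemented alleles
mirror_fixture <- function(genes, genome) {
  chrom <- names(genome)[1]
  L <- Biostrings::width(genome)[1]
  mg <- Biostrings::reverseComplement(genome)
  names(mg) <- chrom
  flip <- function(df) {
    out <- data.frame(start = L - df$end + 1, end = L - df$start + 1)
    if (!is.null(df$phase)) out$phase <- df$phase
    out[order(out$start), , drop = FALSE]
  }
  mgenes <- lapply(genes, function(g) {
    txs <- lapply(g$transcripts, function(tx) {
      out <- list(exons = flip(tx$exons))
      if (!is.null(tx$cds)) out$cds <- flip(tx$cds)
      out
    })
    gene_model(g$gene_id, g$gene_name, g$chrom,
               if (g$strand == "+") "-" else "+", g$biotype, txs)
  })
  list(genes = mgenes, genome = mg, pos = function(p) L - p + 1,
       base = function(b) chartr("ACGT", "TGCA", toupper(b)))
}

# brute-force windowed weighted mean over all site pairs
fsv_oracle <- function(pos, div, focal, window_bp, weighting = "uniform",
                       min_sites = 1) {
  num <- den <- 0
  n_used <- 0
  for (j in seq_along(pos)) {
    d <- abs(pos[j] - pos[focal])
    if (d > window_bp || is.na(div[j])) next
    w <- if (weighting == "uniform") 1 else 1 - d / (window_bp + 1)
    num <- num + w * div[j]
    den <- den + w
    n_used <- n_used + 1
  }
  if (n_used < min_sites) NA_real_ else num / den
}

# independent position-by-position segment scan
segments_oracle <- function(track, threshold, merge_gap_bp = 0,
                            min_segment_bp = 0, qtl = NULL) {
  ok <- !is.na(track$value) & track$value >= threshold
  if (!is.null(qtl)) {
    q <- stats::approx(qtl$points$pos_bp, qtl$points$score,
                       xout = track$pos_bp, rule = 2)$y
    ok <- ok & q >= qtl$sig_threshold
  }
  segs <- NULL
  cur <- NULL
  for (j in seq_along(ok)) {
    if (ok[j]) {
      if (is.null(cur)) cur <- c(track$pos_bp[j], track$pos_bp[j])
      else cur[2] <- track$pos_bp[j]
    } else if (!is.null(cur)) {
      segs <- rbind(segs, cur); cur <- NULL
    }
  }
  if (!is.null(cur)) segs <- rbind(segs, cur)
  if (is.null(segs)) return(data.frame(start = numeric(), end = numeric()))
  segs <- data.frame(start = segs[, 1], end = segs[, 2])
  if (merge_gap_bp > 0 && nrow(segs) > 1) {
    i <- 1
    while (i < nrow(segs)) {
      if (segs$start[i + 1] - segs$end[i] < merge_gap_bp) {
        segs$end[i] <- segs$end[i + 1]
        segs <- segs[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
  }
  segs[segs$end - segs$start >= min_segment_bp, , drop = FALSE]
}

random_track <- function(n, chrom = "chrR", max_pos = 1e6) {
  pos <- sort(sample.int(max_pos, n))
  value_track(chrom, pos, runif(n))
}
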