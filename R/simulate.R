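#' Simulation configuration
#'
#' Conditions for the forward simulation of two lines divergently selected
#' from a common base population. Defaults emulate the study design the
#' pipeline assumes: 40 generations of up/down truncation selection on an
#' additive trait, selection acting on standing variation only (no new
#' mutations), ~12x pooled sequencing depth per line and 20 chip-genotyped
#' individuals per line.
#'
#' @param seed Integer seed; every downstream draw is reproducible from it.
#' @param n_generations Generations of divergent selection.
#' @param pop_size Breeding individuals per line per generation.
#' @param n_selected_per_gen Individuals selected as parents each
#'   generation (truncation selection; must not exceed `pop_size`).
#' @param n_markers Segregating sites on the simulated chromosome segment.
#' @param chrom_length_bp Length of the simulated segment.
#' @param causal_pos_bp Position of the selected (causal) locus.
#' @param causal_effect Additive phenotypic effect per alternate allele, in
#'   units of the polygenic standard deviation (phenotype =
#'   `causal_effect * (dosage - 1) + N(0, 1)`).
#' @param causal_block_bp Width of the standing divergent haplotype block
#'   centred on the causal locus: in the base population, marker alleles
#'   inside the block are associated with the causal allele (two ancestral
#'   haplotype classes at intermediate frequency), so divergent selection
#'   drives the lines towards fixation for alternative alleles across the
#'   block, not just at the causal site.
#' @param causal_block_ld Probability that a block marker's allele matches
#'   its haplotype class in the base population (1 = perfect association).
#' @param chip_marker_fraction Fraction of markers present on the
#'   genotyping chip.
#' @param mean_depth_per_line Mean pooled sequencing depth per line
#'   (Poisson).
#' @param chip_individuals_per_line Individuals genotyped on the chip per
#'   line.
#' @param recomb_rate_cM_per_Mb Uniform recombination rate.
#' @param chrom Chromosome label used in all generated files.
#' @param n_genes Genes placed on the segment by the synthetic gene-model
#'   generator.
#' @param qtl_peak_width_bp Gaussian width of the synthetic QTL support
#'   peak.
#' @param qtl_noise_sd Noise added to the synthetic support curve.
#' @param qtl_sig_quantile Quantile of the curve at which its significance
#'   threshold is set.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_generations = 40, pop_size = 30,
                       n_selected_per_gen = 10, n_markers = 1500,
                       chrom_length_bp = 5e6, causal_pos_bp = 2.5e6,
                       causal_effect = 1, causal_block_bp = 1e6,
                       causal_block_ld = 0.95, chip_marker_fraction = 0.1,
                       mean_depth_per_line = 12,
                       chip_individuals_per_line = 20,
                       recomb_rate_cM_per_Mb = 3, chrom = "chr1",
                       n_genes = 6, qtl_peak_width_bp = 1e6,
                       qtl_noise_sd = 0.02, qtl_sig_quantile = 0.6) {
  if (n_selected_per_gen > pop_size) {
    stop("selection stronger than population: n_selected_per_gen > pop_size",
         call. = FALSE)
  }
  stopifnot(n_generations >= 1, pop_size >= 2, n_selected_per_gen >= 1,
            n_markers >= 2, chrom_length_bp > 1,
            causal_pos_bp >= 1, causal_pos_bp <= chrom_length_bp,
            chip_marker_fraction > 0, chip_marker_fraction <= 1,
            mean_depth_per_line > 0,
            chip_individuals_per_line >= 1,
            chip_individuals_per_line <= pop_size)
  structure(as.list(environment()), class = "sim_config")
}

# one meiosis: recombine two parental haplotypes
.make_gamete <- function(h1, h2, pos_morgan, l_morgan) {
  k <- stats::rpois(1, l_morgan)
  phase <- stats::rbinom(1, 1, 0.5)
  if (k == 0L) return(if (phase == 1L) h1 else h2)
  xo <- sort(stats::runif(k, 0, l_morgan))
  seg <- findInterval(pos_morgan, xo)
  ifelse((seg + phase) %% 2L == 0L, h1, h2)
}

#' Simulate two divergently selected lines
#'
#' Evolves a common base population into a high- and a low-selected line
#' by Wright-Fisher reproduction with truncation selection on an additive
#' phenotype controlled by one causal locus plus standard-normal polygenic
#' noise. No new mutations arise: all response is from standing variation.
#' Returns the chip-genotype subset and a truth record.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_lines` with elements `genotypes`
#'   (a [genotype_matrix()] of the chip markers for the sampled
#'   individuals), `truth` (causal position/index, final per-line allele
#'   frequencies at every marker and at the causal locus) and `config`.
#' @export
simulate_lines <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_markers
  pos <- sort(sample.int(config$chrom_length_bp, n))
  causal_i <- which.min(abs(pos - config$causal_pos_bp))
  pos[causal_i] <- config$causal_pos_bp
  pos <- sort(unique(pos))
  n <- length(pos)
  causal_i <- which(pos == config$causal_pos_bp)[1]
  base_freq <- stats::runif(n, 0.05, 0.95)
  base_freq[causal_i] <- 0.5
  n_hap <- 4L * config$pop_size  # base population feeding both lines
  H0 <- matrix(stats::rbinom(n * n_hap, 1L, rep(base_freq, n_hap)), nrow = n)
  # standing divergent haplotype block around the causal locus: each base
  # haplotype belongs to one of two ancestral classes; block marker alleles
  # follow the class with probability causal_block_ld
  in_block <- abs(pos - config$causal_pos_bp) <= config$causal_block_bp / 2
  hap_class <- stats::rbinom(n_hap, 1L, 0.5)
  for (h in seq_len(n_hap)) {
    follows <- stats::runif(sum(in_block)) < config$causal_block_ld
    H0[in_block, h] <- ifelse(follows, hap_class[h],
                              stats::rbinom(sum(in_block), 1L, 0.5))
  }
  H0[causal_i, ] <- hap_class  # the causal allele defines the class
  ind_perm <- sample.int(2L * config$pop_size)
  hap_cols <- function(ind) as.vector(rbind(2L * ind - 1L, 2L * ind))
  H_high <- H0[, hap_cols(ind_perm[seq_len(config$pop_size)]), drop = FALSE]
  H_low <- H0[, hap_cols(ind_perm[config$pop_size + seq_len(config$pop_size)]),
              drop = FALSE]
  rate <- config$recomb_rate_cM_per_Mb / 100 / 1e6  # Morgans per bp
  pos_m <- pos * rate
  l_m <- config$chrom_length_bp * rate
  evolve <- function(H, upward) {
    N <- ncol(H) / 2L
    for (gen in seq_len(config$n_generations)) {
      odd <- seq(1L, 2L * N, 2L)
      dosage <- H[causal_i, odd] + H[causal_i, odd + 1L]
      pheno <- config$causal_effect * (dosage - 1) + stats::rnorm(N)
      sel <- order(pheno, decreasing = upward)[seq_len(config$n_selected_per_gen)]
      Hn <- matrix(0L, nrow(H), 2L * N)
      for (i in seq_len(N)) {
        par <- if (length(sel) >= 2L) sample(sel, 2L) else c(sel, sel)
        Hn[, 2L * i - 1L] <- .make_gamete(H[, 2L * par[1] - 1L],
                                          H[, 2L * par[1]], pos_m, l_m)
        Hn[, 2L * i] <- .make_gamete(H[, 2L * par[2] - 1L],
                                     H[, 2L * par[2]], pos_m, l_m)
      }
      H <- Hn
    }
    H
  }
  H_high <- evolve(H_high, TRUE)
  H_low <- evolve(H_low, FALSE)
  p_high <- rowMeans(H_high)
  p_low <- rowMeans(H_low)
  n_chip <- max(2L, round(n * config$chip_marker_fraction))
  chip_i <- sort(sample.int(n, n_chip))
  sample_calls <- function(H) {
    ids <- sort(sample.int(ncol(H) / 2L, config$chip_individuals_per_line))
    H[chip_i, 2L * ids - 1L, drop = FALSE] + H[chip_i, 2L * ids, drop = FALSE]
  }
  calls <- cbind(sample_calls(H_high), sample_calls(H_low))
  colnames(calls) <- c(sprintf("H%03d", seq_len(config$chip_individuals_per_line)),
                       sprintf("L%03d", seq_len(config$chip_individuals_per_line)))
  gm <- genotype_matrix(data.frame(chrom = config$chrom, pos = pos[chip_i]),
                        calls,
                        rep(c("HIGH", "LOW"),
                            each = config$chip_individuals_per_line))
  truth <- list(causal_pos = pos[causal_i], causal_index = causal_i,
                positions = pos, p_high = p_high, p_low = p_low,
                p_high_causal = p_high[causal_i],
                p_low_causal = p_low[causal_i],
                afd_causal = abs(p_high[causal_i] - p_low[causal_i]),
                chip_index = chip_i)
  structure(list(genotypes = gm, truth = truth, config = config),
            class = "sim_lines")
}

#' Sample pooled sequencing reads from simulated lines
#'
#' Per site and line, depth is Poisson with the configured mean and the
#' alternate read count is binomial at the line's true allele frequency.
#' The reference allele at each site is the genome base when a genome is
#' supplied (alternate drawn among the other bases), otherwise a random
#' base pair. The site quality column is a synthetic confidence proxy
#' (10 x total alternate reads, capped at 255), standing in for the
#' Phred-scaled quality an external caller would provide.
#'
#' @param sim A `sim_lines` object.
#' @param mean_depth Mean pooled depth per line.
#' @param seed Seed for the read draws.
#' @param genome Optional named `DNAStringSet` supplying reference bases.
#' @return A `snp_sites` data frame (sites with zero depth in both lines
#'   are retained with `NA` divergence downstream).
#' @export
sample_pooled_reads <- function(sim, mean_depth = sim$config$mean_depth_per_line,
                                seed = sim$config$seed + 1L, genome = NULL) {
  if (mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
  set.seed(seed)
  tr <- sim$truth
  n <- length(tr$positions)
  bases <- c("A", "C", "G", "T")
  if (is.null(genome)) {
    ref <- sample(bases, n, replace = TRUE)
  } else {
    chrom_seq <- genome[[sim$config$chrom]]
    ref <- strsplit(as.character(Biostrings::extractAt(
      chrom_seq, IRanges::IRanges(tr$positions, width = 1))), "")
    ref <- toupper(vapply(ref, `[`, "", 1L))
  }
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  depth_h <- stats::rpois(n, mean_depth)
  depth_l <- stats::rpois(n, mean_depth)
  alt_h <- stats::rbinom(n, depth_h, tr$p_high)
  alt_l <- stats::rbinom(n, depth_l, tr$p_low)
  qual <- pmin(255, 10 * (alt_h + alt_l))
  snp_sites(chrom = sim$config$chrom, pos = tr$positions, ref = ref,
            alt = alt, ref_reads_h = depth_h - alt_h, alt_reads_h = alt_h,
            ref_reads_l = depth_l - alt_l, alt_reads_l = alt_l, qual = qual)
}

#' Synthesize a QTL support curve peaked at the causal locus
#'
#' Stands in for the support profile of an external QTL scan: a Gaussian
#' peak centred on the causal position, plus optional noise, with the
#' significance threshold set at a configurable quantile of the curve.
#'
#' @param causal_pos Causal position (must lie inside `region`).
#' @param region Single-row `regions` data frame.
#' @param n_points Curve points, evenly spaced across the region.
#' @param peak_height Peak score above baseline.
#' @param peak_width_bp Gaussian standard deviation in bp.
#' @param noise_sd Standard deviation of additive noise (0 = none).
#' @param baseline Baseline score.
#' @param sig_quantile Quantile of the generated scores used as the
#'   significance threshold.
#' @param seed Optional seed (only matters when `noise_sd > 0`).
#' @return A `support_curve`.
#' @export
synth_support_curve <- function(causal_pos, region, n_points = 201,
                                peak_height = 10, peak_width_bp = 1e6,
                                noise_sd = 0, baseline = 0.5,
                                sig_quantile = 0.6, seed = NULL) {
  if (causal_pos < region$start_bp[1] || causal_pos > region$end_bp[1]) {
    stop("causal position outside region", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pos <- unique(round(seq(region$start_bp[1], region$end_bp[1],
                          length.out = n_points)))
  score <- baseline + peak_height * exp(-0.5 * ((pos - causal_pos) / peak_width_bp)^2)
  if (noise_sd > 0) score <- score + stats::rnorm(length(pos), 0, noise_sd)
  support_curve(pos, score, stats::quantile(score, sig_quantile, names = FALSE),
                chrom = region$chrom[1])
}

# non-stop codons of the standard code
.sense_codons <- local({
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
})

# build one synthetic coding gene writing its CDS into the genome string
.make_gene <- function(gene_id, chrom, start, strand, n_exons = 3,
                       exon_len = 300, intron_len = 2000, utr_len = 60) {
  stopifnot((n_exons * exon_len) %% 3 == 0)
  n_codons <- n_exons * exon_len / 3
  codons <- sample(.sense_codons, n_codons - 2L, replace = TRUE)
  codons[4] <- "AAA"  # guaranteed Lys codon for substitution planting
  cds_seq <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  cds <- data.frame(
    start = start + utr_len + (seq_len(n_exons) - 1L) * (exon_len + intron_len),
    end = start + utr_len + (seq_len(n_exons) - 1L) * (exon_len + intron_len) +
      exon_len - 1L)
  exons <- cds
  exons$start[1] <- exons$start[1] - utr_len
  exons$end[n_exons] <- exons$end[n_exons] + utr_len
  # phase in transcript order
  order_tx <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
  lens <- (cds$end - cds$start + 1)[order_tx]
  phase_tx <- c(0L, (3L - cumsum(lens)[-n_exons] %% 3L) %% 3L)
  phase <- integer(n_exons)
  phase[order_tx] <- phase_tx
  cds$phase <- phase
  tx <- list(exons = exons, cds = cds)
  txs <- stats::setNames(list(tx), paste0(gene_id, ".t1"))
  list(gene = gene_model(gene_id, toupper(gene_id), chrom, strand,
                         "coding", txs),
       cds_seq = cds_seq)
}

# genomic coordinate of transcript-orientation CDS position cds_pos
cds_genomic_pos <- function(gene, tx, cds_pos) {
  cd <- tx$cds
  lens <- cd$end - cd$start + 1
  total <- sum(lens)
  goff <- if (gene$strand == "+") cds_pos else total - cds_pos + 1
  cum <- cumsum(lens)
  i <- which(goff <= cum)[1]
  before <- if (i > 1) cum[i - 1] else 0
  cd$start[i] + (goff - before) - 1
}

#' Generate synthetic gene models, genome, CpG islands and annotations
#'
#' Places non-overlapping multi-exon coding genes on both strands across a
#' region, writes valid CDS sequences (start codon, no internal stops,
#' terminal stop, length divisible by 3) into a random genome sequence,
#' puts CpG islands upstream, downstream of or overlapping the coding
#' sequence of alternating genes, and assigns free-text annotation terms
#' that include the growth keywords for designated genes only.
#'
#' @param region Single-row `regions` data frame to populate.
#' @param n_genes Number of genes (error if they cannot be packed).
#' @param seed Seed.
#' @param host_pos Optional position that the first gene is arranged to
#'   contain (e.g. a simulated causal locus).
#' @param growth_gene_ids Gene ids (of `gene1` ... `geneN`) that receive a
#'   growth-keyword annotation term; defaults to the first gene.
#' @param genome_length_bp Length of the generated chromosome sequence
#'   (default: region end plus a margin).
#' @return List with `genes` (list of `gene_model`), `genome`
#'   (`DNAStringSet`), `islands` (`regions`), `annotations` (data frame
#'   `gene_id`, `term`).
#' @export
synth_gene_model <- function(region, n_genes = 6, seed = 1, host_pos = NULL,
                             growth_gene_ids = "gene1",
                             genome_length_bp = NULL) {
  set.seed(seed)
  chrom <- region$chrom[1]
  if (is.null(genome_length_bp)) genome_length_bp <- region$end_bp[1] + 10000
  gene_span_bp <- 60 + 3 * 300 + 2 * 2000 + 60  # .make_gene defaults
  margin <- 12000  # room for flanks and islands between genes
  slot <- (region$end_bp[1] - region$start_bp[1]) / n_genes
  if (slot < gene_span_bp + margin) {
    stop("region too small to pack the requested genes", call. = FALSE)
  }
  genome_chars <- sample(c("A", "C", "G", "T"), genome_length_bp,
                         replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
  genome_str <- paste(genome_chars, collapse = "")
  genes <- list()
  island_rows <- list()
  ann_rows <- list()
  growth_terms <- c("positive regulation of cell proliferation",
                    "skeletal system development",
                    "tissue morphogenesis",
                    "bone mineralization",
                    "growth factor binding")
  neutral_terms <- c("ion transport", "olfactory receptor activity",
                     "DNA repair", "oxidoreductase activity",
                     "membrane component")
  for (gi in seq_len(n_genes)) {
    gid <- paste0("gene", gi)
    strand <- if (gi %% 2 == 1L) "+" else "-"
    start <- round(region$start_bp[1] + (gi - 1) * slot + margin / 2)
    if (gi == 1L && !is.null(host_pos)) {
      start <- round(host_pos - gene_span_bp / 2)
      if (start < region$start_bp[1]) start <- region$start_bp[1]
    }
    made <- .make_gene(gid, chrom, start, strand)
    g <- made$gene
    tx <- g$transcripts[[1]]
    # write the CDS into the genome, transcript orientation respected
    seq_to_place <- if (strand == "+") {
      made$cds_seq
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(made$cds_seq)))
    }
    offset <- 0L
    for (ci in seq_len(nrow(tx$cds))) {
      len <- tx$cds$end[ci] - tx$cds$start[ci] + 1L
      piece <- substr(seq_to_place, offset + 1L, offset + len)
      substr(genome_str, tx$cds$start[ci], tx$cds$end[ci]) <- piece
      offset <- offset + len
    }
    genes[[gid]] <- g
    sp <- gene_span(g)
    tss <- if (strand == "+") sp[1] else sp[2]
    placement <- c("upstream", "downstream", "coding")[(gi - 1L) %% 3L + 1L]
    isl <- switch(placement,
      upstream = if (strand == "+") {
        c(tss - 1500, tss - 300)
      } else c(tss + 300, tss + 1500),
      downstream = if (strand == "+") {
        c(sp[2] + 300, sp[2] + 1500)
      } else c(sp[1] - 1500, sp[1] - 300),
      coding = c(tx$cds$start[1], tx$cds$end[1]))
    island_rows[[gid]] <- data.frame(start = isl[1], end = isl[2])
    terms <- sample(neutral_terms, 2)
    if (gid %in% growth_gene_ids) terms <- c(terms, sample(growth_terms, 1))
    ann_rows[[gid]] <- data.frame(gene_id = gid, term = terms,
                                  stringsAsFactors = FALSE)
  }
  isl_df <- do.call(rbind, island_rows)
  islands <- regions(chrom = chrom, start_bp = isl_df$start,
                     end_bp = isl_df$end,
                     name = sprintf("cpg%02d", seq_len(nrow(isl_df))))
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_str, chrom))
  list(genes = genes, genome = genome, islands = islands,
       annotations = do.call(rbind, ann_rows))
}

#' Plant a codon-changing SNP in a synthetic gene
#'
#' Returns the genomic description of a SNP that converts the guaranteed
#' lysine codon (AAA) of a synthetic gene into another residue, for use as
#' a planted truth in classifier checks. The default target isoleucine
#' (ATA) changes the middle codon base.
#'
#' @param gene A `gene_model` from [synth_gene_model()].
#' @param genome The matching `DNAStringSet`.
#' @param to Target residue: `"I"` (AAA->ATA, non-synonymous) or `"stop"`
#'   (AAA->TAA).
#' @return List with `pos`, `ref`, `alt`, `aa_from`, `aa_to`.
#' @export
plant_codon_snp <- function(gene, genome, to = c("I", "stop")) {
  to <- match.arg(to)
  tx <- gene$transcripts[[1]]
  codon_index <- 5L  # .make_gene puts AAA at codon 5 (ATG + 3 codons before)
  cds_pos <- switch(to, I = (codon_index - 1L) * 3L + 2L,
                    stop = (codon_index - 1L) * 3L + 1L)
  gpos <- cds_genomic_pos(gene, tx, cds_pos)
  ref <- as.character(Biostrings::subseq(genome[[gene$chrom]], gpos, gpos))
  alt_tx <- "T"  # A->T in transcript orientation for both targets
  alt <- if (gene$strand == "+") alt_tx else .revcomp_base(alt_tx)
  list(pos = gpos, ref = ref, alt = alt, aa_from = "K",
       aa_to = if (to == "I") "I" else "*")
}
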