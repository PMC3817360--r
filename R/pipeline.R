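#' Generate a complete synthetic dataset
#'
#' Runs the forward simulation and the synthetic annotation generator and
#' bundles everything the pipeline consumes: pooled sites, chip genotypes,
#' QTL support curve, gene models, genome, CpG islands and gene
#' annotations. The first synthetic gene is arranged to contain the causal
#' locus and carries a growth-keyword annotation term, so end-to-end
#' recovery of the planted signal is well defined.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `config`, `region`,
#'   `sim` (the `sim_lines` object), `genotypes`, `sites`, `support`,
#'   `genes`, `genome`, `islands`, `annotations`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  sim <- simulate_lines(config)
  region <- regions(chrom = config$chrom, start_bp = 1,
                    end_bp = config$chrom_length_bp, name = "SIM1")
  synth <- synth_gene_model(region, n_genes = config$n_genes,
                            seed = config$seed + 101L,
                            host_pos = sim$truth$causal_pos,
                            growth_gene_ids = c("gene1", "gene3"))
  sites <- sample_pooled_reads(sim, seed = config$seed + 202L,
                               genome = synth$genome)
  support <- synth_support_curve(sim$truth$causal_pos, region,
                                 peak_width_bp = config$qtl_peak_width_bp,
                                 noise_sd = config$qtl_noise_sd,
                                 sig_quantile = config$qtl_sig_quantile,
                                 seed = config$seed + 303L)
  structure(list(config = config, region = region, sim = sim,
                 genotypes = sim$genotypes, sites = sites, support = support,
                 genes = synth$genes, genome = synth$genome,
                 islands = synth$islands, annotations = synth$annotations),
            class = "sim_dataset")
}

#' Write a synthetic dataset to standard-format files
#'
#' Emits the dataset in the formats the package reads back: pooled VCF,
#' chip genotype TSV, gene-model GFF3, CpG-island BED, genome FASTA, QTL
#' support TSV, region TSV and annotation TSV. The generated files double
#' as format-conformance fixtures.
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "pooled.vcf"),
    genotypes = file.path(dir, "chip_genotypes.tsv"),
    gff3 = file.path(dir, "genes.gff3"),
    bed = file.path(dir, "cpg_islands.bed"),
    fasta = file.path(dir, "genome.fa"),
    support = file.path(dir, "qtl_support.tsv"),
    regions = file.path(dir, "regions.tsv"),
    annotations = file.path(dir, "annotations.tsv"))
  write_pooled_vcf(ds$sites, paths[["vcf"]])
  write_genotype_table(ds$genotypes, paths[["genotypes"]])
  write_gff3(ds$genes, paths[["gff3"]])
  write_bed(ds$islands, paths[["bed"]])
  Biostrings::writeXStringSet(ds$genome, paths[["fasta"]])
  write_support_curve(ds$support, paths[["support"]])
  write_regions_table(ds$region, paths[["regions"]])
  utils::write.table(ds$annotations, paths[["annotations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Run the full prioritization pipeline on a dataset
#'
#' Applies the SNP-detection threshold, builds the three evidence tracks
#' (flanking-SNP divergence from pooled reads, chip allele-frequency
#' difference, normalized QTL support), fuses them into the combined data
#' score, selects candidate segments, classifies the called SNPs inside
#' the segments against the gene models, applies the growth-keyword gene
#' filter and assembles the ranked candidate report.
#'
#' @param ds A `sim_dataset` (or any list with the same elements).
#' @param fsv A [fsv_params()].
#' @param selection A [selection_params()].
#' @param min_alt_total SNP-detection threshold (summed alternate reads).
#' @param k Candidates reported per region.
#' @param keywords Keyword set for the gene filter.
#' @return A list of class `scan_result` with `segments`, `report`,
#'   `tracks` (fsv, chip, qtl, cds), `called_sites`, `classifications`
#'   and `summary` (selection summary against the region).
#' @export
run_pipeline <- function(ds, fsv = fsv_params(),
                         selection = selection_params(),
                         min_alt_total = 3, k = 2,
                         keywords = growth_keywords()) {
  called <- call_snps(ds$sites, min_alt_total)
  fsv_tr <- fsv_track(called, fsv)
  chip_tr <- chip_afd_track(ds$genotypes)
  qtl_tr <- normalize_support(ds$support, ds$region)
  cds_tr <- build_cds_track(fsv_tr, chip_tr, qtl_tr, ds$region)
  segs <- select_segments(cds_tr, ds$support, selection,
                          region_name = ds$region$name[1])
  in_seg <- if (nrow(segs)) {
    in_regions(called$chrom, called$pos, segs)
  } else rep(FALSE, nrow(called))
  seg_sites <- called[in_seg, , drop = FALSE]
  class(seg_sites) <- class(called)
  cls <- classify_variants(seg_sites, ds$genes, ds$genome)
  keep <- keyword_filter(ds$annotations, keywords)
  report <- rank_candidates(segs, seg_sites, cls, ds$islands, ds$genes,
                            keep, k = k)
  summary <- if (nrow(segs)) {
    summarize_selection(ds$region, segs)
  } else {
    list(per_region = NULL, total_selected_mbp = 0,
         total_qtl_mbp = sum(region_size_mbp(ds$region)),
         percent_covered = 0L)
  }
  structure(list(segments = segs, report = report,
                 tracks = list(fsv = fsv_tr, chip = chip_tr, qtl = qtl_tr,
                               cds = cds_tr),
                 called_sites = called, classifications = cls,
                 summary = summary),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d segment(s) selected (%.1f Mbp, %d%% of region), %d candidate record(s)\n",
              nrow(x$segments), x$summary$total_selected_mbp,
              x$summary$percent_covered, nrow(x$report)))
  invisible(x)
}
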