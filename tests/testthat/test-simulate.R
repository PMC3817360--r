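# small configurations keep the forward simulations quick; the full-default
# recovery experiment lives with the acceptance checks
small_cfg <- function(seed, ...) {
  defaults <- list(n_markers = 120, chrom_length_bp = 1e6,
                   causal_pos_bp = 5e5, causal_block_bp = 2e5, pop_size = 20,
                   n_selected_per_gen = 7, chip_individuals_per_line = 10,
                   n_genes = 2)
  do.call(sim_config,
          c(list(seed = seed), utils::modifyList(defaults, list(...))))
}

test_that("line simulation is deterministic per seed and validates config", {
  a <- simulate_lines(small_cfg(4))
  b <- simulate_lines(small_cfg(4))
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth$p_high, b$truth$p_high)
  c <- simulate_lines(small_cfg(5))
  expect_false(identical(a$truth$p_high, c$truth$p_high))
  expect_error(sim_config(pop_size = 10, n_selected_per_gen = 11),
               "selection stronger than population")
})

test_that("strong divergent selection drives the causal locus apart", {
  afd <- vapply(1:20, function(s) {
    simulate_lines(small_cfg(s, n_generations = 30))$truth$afd_causal
  }, numeric(1))
  expect_gte(mean(afd > 0.8), 0.9)
})

test_that("without a causal effect the divergence stays at drift levels", {
  afd <- vapply(1:12, function(s) {
    simulate_lines(small_cfg(s, causal_effect = 0,
                             n_generations = 15))$truth$afd_causal
  }, numeric(1))
  expect_lt(median(afd), 1)          # no systematic sweep to fixation
  expect_lt(mean(afd), 0.8)
})

test_that("pooled read sampling follows the line allele frequencies", {
  n <- 400
  fake <- list(truth = list(positions = seq(1000, by = 500, length.out = n),
                            p_high = rep(1, n), p_low = rep(0.5, n)),
               config = list(chrom = "chr1", mean_depth_per_line = 12,
                             seed = 1))
  class(fake) <- "sim_lines"
  sites <- sample_pooled_reads(fake, mean_depth = 60, seed = 9)
  ab_h <- ab_score(sites$ref_reads_h, sites$alt_reads_h)
  ab_l <- ab_score(sites$ref_reads_l, sites$alt_reads_l)
  # line fixed for the alternate allele: no reads agree with reference
  expect_true(all(ab_h == 0, na.rm = TRUE))
  # p = 0.5 at high depth: mean AB within a tight binomial band of 0.5
  expect_lt(abs(mean(ab_l, na.rm = TRUE) - 0.5), 3.5 * sqrt(0.25 / (60 * n)))
  # coverage starvation gives mostly missing sites
  starved <- sample_pooled_reads(fake, mean_depth = 0.01, seed = 9)
  expect_gt(mean(is.na(site_divergence(starved))), 0.9)
  again <- sample_pooled_reads(fake, mean_depth = 60, seed = 9)
  expect_identical(sites, again)
  expect_error(sample_pooled_reads(fake, mean_depth = 0), "positive")
})

test_that("synthetic support curves peak at the causal position", {
  rg <- regions("chr1", 1, 1e6, name = "R")
  sc <- synth_support_curve(4e5, rg, noise_sd = 0)
  expect_equal(sc$points$pos_bp[which.max(sc$points$score)], 4e5,
               tolerance = 5e3)
  norm <- normalize_support(sc, rg)
  expect_equal(max(norm$value), 1)
  expect_equal(norm$pos_bp[which.max(norm$value)], 4e5, tolerance = 5e3)
  s1 <- synth_support_curve(4e5, rg, noise_sd = 0.3, seed = 2)
  s2 <- synth_support_curve(4e5, rg, noise_sd = 0.3, seed = 2)
  expect_identical(s1$points, s2$points)
  expect_error(synth_support_curve(2e6, rg), "outside region")
})

test_that("synthetic gene models carry translatable coding sequences", {
  rg <- regions("chr1", 1, 2e5, name = "R")
  out <- synth_gene_model(rg, n_genes = 4, seed = 3)
  expect_length(out$genes, 4L)
  for (g in out$genes) {
    tx <- g$transcripts[[1]]
    pieces <- vapply(seq_len(nrow(tx$cds)), function(i) {
      as.character(Biostrings::subseq(out$genome[[g$chrom]],
                                      tx$cds$start[i], tx$cds$end[i]))
    }, "")
    cds_seq <- paste(pieces, collapse = "")
    if (g$strand == "-") {
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
    }
    expect_equal(nchar(cds_seq) %% 3, 0)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
    expect_equal(substr(prot, 1, 1), "M")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
  # growth keywords attached only where requested
  keep <- keyword_filter(out$annotations)
  expect_true("gene1" %in% keep)
  expect_error(synth_gene_model(regions("chr1", 1, 2e4), n_genes = 10),
               "too small")
})

test_that("planted substitutions are recovered by the classifier", {
  rg <- regions("chr1", 1, 2e5, name = "R")
  out <- synth_gene_model(rg, n_genes = 4, seed = 3)
  for (gid in c("gene1", "gene2")) {  # one gene per strand
    g <- out$genes[[gid]]
    planted <- plant_codon_snp(g, out$genome, to = "I")
    site <- snp_sites(g$chrom, planted$pos, planted$ref, planted$alt,
                      5, 5, 5, 5)
    got <- classify_variant(site, list(g), out$genome)
    expect_equal(got$consequence, "Non-synonymous coding")
    expect_equal(c(got$aa_from, got$aa_to), c("K", "I"))
    stopg <- plant_codon_snp(g, out$genome, to = "stop")
    site2 <- snp_sites(g$chrom, stopg$pos, stopg$ref, stopg$alt, 5, 5, 5, 5)
    expect_equal(classify_variant(site2, list(g), out$genome)$consequence,
                 "Stop gained")
  }
  # island placed upstream of gene1 is seen as such
  g1 <- out$genes$gene1
  sp <- gene_span(g1)
  probe <- if (g1$strand == "+") sp[1] - 1000 else sp[2] + 1000
  expect_equal(cpg_relation(list(chrom = g1$chrom, pos = probe),
                            out$islands, out$genes),
               "CpG island, upstream")
})

test_that("generated datasets round-trip through every format reader", {
  ds <- simulate_dataset(small_cfg(6))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  back_sites <- read_pooled_vcf(paths[["vcf"]])
  expect_equal(back_sites$pos, ds$sites$pos)
  expect_equal(back_sites$alt_reads_h, ds$sites$alt_reads_h)
  back_gm <- read_genotype_table(paths[["genotypes"]])
  expect_equal(back_gm$calls, ds$genotypes$calls)
  expect_equal(back_gm$line, ds$genotypes$line)
  back_genes <- read_gff3(paths[["gff3"]])
  expect_setequal(names(back_genes), names(ds$genes))
  g <- names(ds$genes)[1]
  expect_equal(back_genes[[g]]$transcripts[[1]]$cds,
               ds$genes[[g]]$transcripts[[1]]$cds,
               ignore_attr = TRUE)
  back_isl <- read_bed(paths[["bed"]])
  expect_equal(back_isl$start_bp, ds$islands$start_bp)
  expect_equal(back_isl$end_bp, ds$islands$end_bp)
  back_sc <- read_support_curve(paths[["support"]])
  expect_equal(back_sc$points$score, ds$support$points$score,
               tolerance = 1e-6)
  genome <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(as.character(genome[[1]]), as.character(ds$genome[[1]]))
})

test_that("the full pipeline recovers a planted signal end to end", {
  ds <- simulate_dataset(small_cfg(8, causal_block_bp = 3e5))
  res <- run_pipeline(ds)
  cp <- ds$sim$truth$causal_pos
  expect_gt(nrow(res$segments), 0)
  expect_true(any(res$segments$start_bp <= cp & res$segments$end_bp >= cp))
  expect_true(toupper("gene1") %in% res$report$gene)
  expect_true(all(res$report$afd >= 0 & res$report$afd <= 1))
  expect_true(all(res$classifications$consequence %in%
                    consequence_vocabulary()))
})
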