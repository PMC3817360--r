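test_that("codon-level classification recovers planted coding changes", {
  fx <- toy_fixture()
  cases <- list(
    list(pos = 2035, alt = "T", label = "Non-synonymous coding",
         aa = c("K", "I")),                       # AAA -> ATA
    list(pos = 2037, alt = "G", label = "Non-synonymous coding",
         aa = c("I", "V")),                       # ATA -> GTA
    list(pos = 2042, alt = "G", label = "Synonymous coding",
         aa = c(NA, NA)),                         # GGA -> GGG wobble
    list(pos = 2040, alt = "T", label = "Stop gained",
         aa = c("G", "*")),                       # GGA -> TGA
    list(pos = 2301, alt = "A", label = "Non-synonymous coding, Splice site",
         aa = c("A", "D")))                       # GCT -> GAT, exon edge
  for (cs in cases) {
    site <- toy_site(fx, cs$pos, alt = cs$alt)
    out <- classify_variant(site, fx$genes["toyg1"], fx$genome)
    expect_equal(out$consequence, cs$label, info = cs$pos)
    if (!is.na(cs$aa[1])) {
      expect_equal(c(out$aa_from, out$aa_to), cs$aa, info = cs$pos)
    } else {
      expect_true(is.na(out$aa_from), info = cs$pos)
    }
  }
})

test_that("non-coding placements follow the distance rules", {
  fx <- toy_fixture()
  cases <- list(
    list(pos = 2010, label = "5Prime UTR"),
    list(pos = 2660, label = "3Prime UTR"),
    list(pos = 2101, label = "Essential splice site"),
    list(pos = 2399 + 3, label = "Essential splice site"),  # intron 2 start
    list(pos = 2105, label = "splice site, Intronic"),
    list(pos = 2200, label = "Intronic"),
    list(pos = 1800, label = "Upstream"),      # 201 bp 5' of the TSS
    list(pos = 2900, label = "Downstream"),
    list(pos = 15050, label = "Within mature miRNA"),
    list(pos = 22050, label = "Within non-coding gene"),
    list(pos = 22302, label = "Within non-coding gene, splice site"))
  for (cs in cases) {
    site <- toy_site(fx, cs$pos)
    out <- classify_variant(site, fx$genes[c("toyg1", "toyg2", "toyg3")],
                            fx$genome)
    expect_equal(out$consequence, cs$label, info = cs$pos)
  }
  # beyond the 5 kb flank of everything: no gene relation
  far <- classify_variant(toy_site(fx, 36000), fx$genes["toyg1"], fx$genome)
  expect_equal(nrow(far), 0L)
  full <- classify_variants(toy_site(fx, 36000), fx$genes, fx$genome)
  expect_equal(full$consequence, "Intergenic")
})

test_that("reference mismatches are rejected by name", {
  fx <- toy_fixture()
  bad <- toy_site(fx, 2035, ref = "C", alt = "T")
  expect_error(classify_variant(bad, fx$genes, fx$genome),
               "reference mismatch at chrT:2035")
})

test_that("consequences are invariant under reverse-complementing the locus", {
  fx <- toy_fixture()
  mir <- mirror_fixture(fx$genes, fx$genome)
  positions <- c(2035, 2037, 2042, 2040, 2301, 2010, 2660, 2101, 2105,
                 2200, 1800, 2900, 15050, 22050, 22302)
  for (p in positions) {
    site <- toy_site(fx, p)
    fwd <- classify_variant(site, fx$genes, fx$genome)
    msite <- snp_sites(fx$chrom, mir$pos(p), mir$base(site$ref),
                       mir$base(site$alt), 5, 5, 5, 5)
    rev <- classify_variant(msite, mir$genes, mir$genome)
    expect_equal(rev$consequence[order(rev$gene_id)],
                 fwd$consequence[order(fwd$gene_id)], info = p)
    expect_equal(rev$aa_from[order(rev$gene_id)],
                 fwd$aa_from[order(fwd$gene_id)], info = p)
  }
})

test_that("per-gene reduction is severity-ranked and transcript-order invariant", {
  fx <- toy_fixture()
  site <- toy_site(fx, 30105, ref = "G", alt = "A")
  out <- classify_variant(site, fx$genes["toyg4"], fx$genome)
  # stop-gain in one frame, non-synonymous in the other
  expect_equal(out$consequence, "Stop gained, Non-synonymous coding")
  g <- fx$genes$toyg4
  permuted <- gene_model(g$gene_id, g$gene_name, g$chrom, g$strand,
                         g$biotype, rev(g$transcripts))
  out2 <- classify_variant(site, list(permuted), fx$genome)
  expect_equal(out2$consequence, out$consequence)
  # labels always come from the closed vocabulary
  expect_true(all(out$consequence %in% consequence_vocabulary()))
  expect_gt(consequence_severity("Stop gained"),
            consequence_severity("Synonymous coding"))
  expect_error(consequence_severity("frameshift"), "unknown consequence")
})

test_that("CpG relations combine island overlap with gene orientation", {
  fx <- toy_fixture()
  islands <- regions(fx$chrom, c(1500, 2025, 2800, 9000),
                     c(1900, 2045, 3200, 9100),
                     name = c("i1", "i2", "i3", "i4"))
  genes <- fx$genes["toyg1"]
  expect_equal(cpg_relation(list(chrom = fx$chrom, pos = 1800), islands, genes),
               "CpG island, upstream")
  expect_equal(cpg_relation(list(chrom = fx$chrom, pos = 2040), islands, genes),
               "CpG island, coding")
  expect_equal(cpg_relation(list(chrom = fx$chrom, pos = 2900), islands, genes),
               "CpG island, downstream")
  expect_equal(cpg_relation(list(chrom = fx$chrom, pos = 9050), islands, genes),
               "CpG island")
  expect_equal(cpg_relation(list(chrom = fx$chrom, pos = 4000), islands, genes),
               "NONE")
  # orientation flips with the strand
  mir <- mirror_fixture(fx$genes, fx$genome)
  L <- 40000
  misl <- regions(fx$chrom, L - islands$end_bp + 1, L - islands$start_bp + 1,
                  name = islands$name)
  expect_equal(cpg_relation(list(chrom = fx$chrom, pos = mir$pos(1800)),
                            misl, mir$genes["toyg1"]),
               "CpG island, upstream")
})

test_that("keyword filtering is substring, case-insensitive and monotone", {
  ann <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g4"),
    term = c("positive regulation of cell proliferation", "membrane",
             "ion transport", "Skeletal DEVELOPMENT",
             "fatty acid biosynthetic process"),
    stringsAsFactors = FALSE)
  kept <- keyword_filter(ann)
  expect_setequal(kept, c("g1", "g3", "g4"))
  expect_false("g2" %in% kept)
  # monotone: adding a keyword never removes a gene
  smaller <- keyword_filter(ann, c("proliferation"))
  expect_true(all(smaller %in% kept))
  larger <- keyword_filter(ann, c(growth_keywords(), "transport"))
  expect_true(all(kept %in% larger))
  expect_error(keyword_filter(ann, character()), "non-empty")
  expect_length(growth_keywords(), 12L)
})

test_that("candidate ranking orders by divergence, severity and position", {
  fx <- toy_fixture()
  segs <- regions(fx$chrom, 1, 25000, name = "R1")
  sites <- snp_sites(fx$chrom, c(2035, 2042, 22050), c("A", "G", "C"),
                     c("T", "G", "T")[c(1, 2, 3)],
                     ref_reads_h = c(0, 1, 2), alt_reads_h = c(10, 9, 8),
                     ref_reads_l = c(9, 8, 9), alt_reads_l = c(1, 1, 0),
                     qual = c(182, 90, 60))
  sites$ref <- vapply(sites$pos, function(p) gbase(fx$genome, p), "")
  sites$alt <- vapply(sites$ref, other_base, "")
  sites$alt[sites$pos == 2035] <- "T"
  cls <- classify_variants(sites, fx$genes, fx$genome)
  islands <- regions(fx$chrom, 22001, 22100, name = "cpg1")
  keep <- c("toyg1", "toyg3")
  rep_all <- rank_candidates(segs, sites, cls, islands, fx$genes, keep, k = 3)
  expect_equal(nrow(rep_all), 3L)
  # afd descending within the region
  expect_true(all(diff(rep_all$afd) <= 1e-12))
  expect_match(rep_all$snp_location[rep_all$snp_bp == 2035], "NS K/I")
  expect_match(rep_all$snp_location[rep_all$snp_bp == 22050], "CpG island")
  top1 <- rank_candidates(segs, sites, cls, islands, fx$genes, keep, k = 1)
  expect_equal(nrow(top1), 1L)
  expect_equal(top1$snp_bp, 2035)  # highest afd wins
  # genes failing the keyword screen never appear
  none <- rank_candidates(segs, sites, cls, islands, fx$genes,
                          keep_genes = character())
  expect_equal(nrow(none), 0L)
})

test_that("consequence summaries count site-gene pairs by label and region", {
  fx <- toy_fixture()
  sites <- do.call(rbind, lapply(c(2035, 2042, 2200, 36000),
                                 function(p) toy_site(fx, p)))
  class(sites) <- c("snp_sites", "data.frame")
  cls <- classify_variants(sites, fx$genes["toyg1"], fx$genome)
  region_of <- rep("R1", nrow(cls))
  tab <- summarize_consequences(cls, region_of)
  expect_false(any(c("Intronic", "Intergenic") %in% tab$location))
  expect_equal(tab$R1[tab$location == "Non-synonymous coding"], 1L)
  expect_equal(tab$Total[tab$location == "Total"], 2L)
  expect_true(all(tab$location[tab$location != "Total"] %in%
                    consequence_vocabulary()))
})
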