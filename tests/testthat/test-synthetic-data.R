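test_that("same seed reproduces byte-identical outputs", {
  cfg <- test_sim_config(seed = 5, region_length = 30000L, gene_count = 3,
                         class_density = c(LTR = 0.2, LINE = 0.1,
                                           RC_Helitron = 0.02, DNA = 0.02),
                         n_spurious = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_region(cfg, d1)
  s2 <- simulate_region(cfg, d2)
  for (key in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[key]]),
                     readLines(s2$paths[[key]]),
                     info = key)
  }
})

test_that("emitted annotations round-trip through the parsers losslessly", {
  cfg <- test_sim_config(seed = 23, region_length = 40000L, gene_count = 4,
                         class_density = c(LTR = 0.25, LINE = 0.1,
                                           RC_Helitron = 0.03, DNA = 0.03))
  dir <- withr::local_tempdir()
  sim <- simulate_region(cfg, dir)
  # RepeatMasker dialect: parse -> write -> parse fixpoint
  f1 <- parse_repeatmasker_out(sim$paths$rm_out)
  tmp <- file.path(dir, "roundtrip.out")
  write_repeatmasker_out(f1, tmp)
  f2 <- parse_repeatmasker_out(tmp)
  expect_equal(f1, f2)
  # parsed features equal the planted feature table
  cols <- c("seq_id", "start", "end", "strand", "repeat_name", "raw_class",
            "canonical_class", "score")
  expect_equal(f1[, cols], sim$features[, cols], ignore_attr = TRUE)
  # genome on disk matches the in-memory genome
  back <- Biostrings::readDNAStringSet(sim$paths$fasta)
  expect_equal(as.character(back[[1]]), as.character(sim$genome[[1]]))
})

test_that("truth tables agree exactly with file-derived quantities", {
  cfg <- test_sim_config(seed = 31, region_length = 60000L, gene_count = 5,
                         class_density = c(LTR = 0.3, LINE = 0.15,
                                           RC_Helitron = 0.05, DNA = 0.05))
  dir <- withr::local_tempdir()
  sim <- simulate_region(cfg, dir)
  feats <- parse_repeatmasker_out(sim$paths$rm_out)
  segs <- merge_by_class(feats)
  d <- class_density(segs, sim$region)
  truth <- stats::setNames(sim$truth$repeats$density, sim$truth$repeats$class)
  for (cls in names(truth)) {
    expect_equal(unname(d$densities[[cls]]), unname(truth[[cls]]),
                 tolerance = 1e-12)
  }
  met <- gene_metrics_table(read_gene_models(sim$paths$gff3))
  tg <- sim$truth$genes[order(sim$truth$genes$gene_id), ]
  expect_equal(met$coding_span_size, tg$coding_span_size)
  expect_equal(met$total_intron_size, tg$total_intron_size)
  expect_equal(met$total_cds_size, tg$total_cds_size)
  expect_equal(met$cds_count, tg$cds_count)
})

test_that("planted low-score decoys are removed by the score filter", {
  cfg <- test_sim_config(seed = 37, region_length = 30000L, gene_count = 2,
                         class_density = c(LTR = 0.15, LINE = 0.05,
                                           RC_Helitron = 0.02, DNA = 0.02),
                         n_spurious = 8)
  dir <- withr::local_tempdir()
  sim <- simulate_region(cfg, dir)
  feats <- parse_repeatmasker_out(sim$paths$rm_out)
  # real fragments score >= 0.25/bp on >= 30 bp; decoys 0.05/bp on <= 200 bp
  cutoff <- 0.05 * 200 + 0.1
  kept <- score_filter(feats, cutoff, quiet = TRUE)
  n_decoys <- nrow(feats) - nrow(kept)
  expect_gt(n_decoys, 0)
  expect_true(all(kept$score >= cutoff))
  expect_true(all(feats$score[!feats$score %in% kept$score] < cutoff))
})

test_that("codon gene groups carry their designed bias structure", {
  cfg <- test_sim_config(seed = 41,
                         codon_genes = list(n_per_group = 6,
                                            codons_per_gene = 3000,
                                            gc3_mutational = 0.30,
                                            gc3_selected = 0.65,
                                            reference_depth = 20))
  sim <- simulate_codon_genes(cfg)
  expect_equal(nrow(sim$truth), 18)
  counts <- lapply(sim$sequences, count_codons)
  # finite-sample homozygosity is the unbiased estimator for sampled genes;
  # the group-mean Nc of uniform-usage genes sits at the 61 ceiling
  nc_uniform <- vapply(counts[sim$truth$group == "uniform"], function(cc)
    effective_number_of_codons(cc, "finite_sample"), numeric(1))
  expect_lt(abs(mean(nc_uniform) - 61), 0.5)
  w <- relative_adaptiveness(sim$reference)
  cai <- vapply(counts, function(cc) codon_adaptation_index(cc, w),
                numeric(1))
  expect_gt(mean(cai[sim$truth$group == "selected"]),
            mean(cai[sim$truth$group == "mutational"]))
  empty <- test_sim_config(seed = 41,
                           codon_genes = list(n_per_group = 0,
                                              codons_per_gene = 100,
                                              gc3_mutational = 0.3,
                                              gc3_selected = 0.65,
                                              reference_depth = 5))
  expect_equal(length(simulate_codon_genes(empty)$sequences), 0)
})

test_that("ortholog pairs inflate only the designed introns", {
  base <- test_sim_config(seed = 43, n_pairs = 15)
  noinfl <- test_sim_config(seed = 43, n_pairs = 15, ortholog_factor = 1)
  sim0 <- simulate_ortholog_pairs(noinfl)
  met_a <- gene_metrics_table(sim0$models_a)
  met_b <- gene_metrics_table(sim0$models_b)
  for (i in seq_len(nrow(sim0$pairs))) {
    d <- ortholog_difference(met_a[met_a$gene_id == sim0$pairs$gene_a[i], ],
                             met_b[met_b$gene_id == sim0$pairs$gene_b[i], ])
    expect_equal(d$d_total_intron_size, 0)
    expect_equal(d$d_total_cds_size, 0)
  }
  sim <- simulate_ortholog_pairs(base)
  met_a <- gene_metrics_table(sim$models_a)
  met_b <- gene_metrics_table(sim$models_b)
  # total CDS difference is 0 by construction even with inflation
  for (i in seq_len(nrow(sim$pairs))) {
    d <- ortholog_difference(met_a[met_a$gene_id == sim$pairs$gene_a[i], ],
                             met_b[met_b$gene_id == sim$pairs$gene_b[i], ])
    expect_equal(d$d_total_cds_size, 0)
  }
  infl <- sim$truth$n_inflated > 0
  expect_true(any(infl))
  expect_true(all(sim$truth$total_intron_b[infl] >
                    sim$truth$total_intron_a[infl]))
  expect_true(all(sim$truth$total_intron_b[!infl] ==
                    sim$truth$total_intron_a[!infl]))
})
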