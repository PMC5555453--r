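test_that("codon counting reads frame, skips ambiguity, tallies stops", {
  cc <- count_codons("ATGAAATAA")
  expect_equal(unname(cc[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(sum(cc), 3L)
  cc <- count_codons("ATGNNNAAA")
  expect_equal(sum(cc), 2L)
  expect_equal(attr(cc, "n_ambiguous"), 1L)
  expect_error(count_codons("ATGA"), "divisible by 3")
  expect_equal(sum(count_codons("")), 0L)
})

test_that("minus-strand CDS extraction counts like the reverse complement", {
  cds <- "ATGCATGGGAAATGCTGA"
  genome <- Biostrings::DNAStringSet(c(chr = paste0(
    "TTTT", as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds))), "GGGG")))
  iso <- isoform_model("g", "g.t", "chr", "-",
                       cbind(4L, 4L + nchar(cds)))
  expect_equal(as.character(extract_cds_sequence(iso, genome)), cds)
  expect_equal(count_codons(extract_cds_sequence(iso, genome)),
               count_codons(cds))
})

test_that("Nc hits its boundary values in proportions mode", {
  uniform <- codon_counts(stats::setNames(rep(10L, 64),
                                          names(Biostrings::GENETIC_CODE)))
  expect_equal(effective_number_of_codons(uniform, "proportions"), 61)
  gc <- Biostrings::GENETIC_CODE
  one_per_aa <- vapply(split(names(gc), gc), `[`, character(1), 1)
  one_per_aa <- one_per_aa[names(one_per_aa) != "*"]
  single <- codon_counts(stats::setNames(rep(5L, 20), one_per_aa))
  expect_equal(effective_number_of_codons(single, "proportions"), 20)
  expect_error(effective_number_of_codons(codon_counts(c(ATG = 3L))),
               "no codons")
})

test_that("Nc equals a direct hand evaluation of the homozygosity formula", {
  toy <- codon_counts(c(AAA = 4, AAG = 2,              # Lys, twofold
                        ATT = 3, ATC = 2, ATA = 1,     # Ile, threefold
                        GGT = 2, GGC = 2, GGA = 1, GGG = 1,  # Gly, fourfold
                        TTA = 3, CTG = 3,              # Leu, sixfold
                        ATG = 6))                      # Met, excluded
  f_hat <- function(counts) {
    n <- sum(counts); p <- counts / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  f2 <- f_hat(c(4, 2))
  f3 <- f_hat(c(3, 2, 1))
  f4 <- f_hat(c(2, 2, 1, 1))
  f6 <- f_hat(c(3, 3))
  oracle <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  expect_equal(effective_number_of_codons(toy, "finite_sample"), oracle,
               tolerance = 1e-9)
  # proportions mode against sum(p^2)
  f2p <- sum((c(4, 2) / 6)^2); f3p <- sum((c(3, 2, 1) / 6)^2)
  f4p <- sum((c(2, 2, 1, 1) / 6)^2); f6p <- sum((c(3, 3) / 6)^2)
  expect_equal(effective_number_of_codons(toy, "proportions"),
               2 + 9 / f2p + 1 / f3p + 5 / f4p + 3 / f6p, tolerance = 1e-9)
})

test_that("Nc decreases monotonically from uniform toward one-codon usage", {
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc), gc)
  fams <- fams[!names(fams) %in% c("*")]
  nc_at <- function(lambda) {
    # interpolate each family from uniform (lambda=0) to all-mass-on-first
    counts <- unlist(unname(lapply(fams, function(codons) {
      k <- length(codons)
      p <- rep((1 - lambda) / k, k)
      p[1] <- p[1] + lambda
      stats::setNames(round(p * 600), codons)
    })))
    effective_number_of_codons(codon_counts(counts), "proportions")
  }
  nc <- vapply(seq(0, 0.999, length.out = 10), nc_at, numeric(1))
  expect_true(all(diff(nc) < 0))
  expect_equal(nc[1], 61, tolerance = 0.2)
})

test_that("relative adaptiveness normalizes within families with a floor", {
  w <- suppressWarnings(relative_adaptiveness(codon_counts(c(AAA = 30,
                                                             AAG = 10))))
  expect_equal(unname(w["AAA"]), 1)
  expect_equal(unname(w["AAG"]), 1 / 3)
  w <- suppressWarnings(relative_adaptiveness(codon_counts(c(CAT = 50,
                                                             CAC = 0))))
  expect_equal(unname(w["CAC"]), 0.01)
  uni <- suppressWarnings(relative_adaptiveness(
    codon_counts(stats::setNames(rep(7L, 64),
                                 names(Biostrings::GENETIC_CODE)))))
  expect_true(all(uni == 1))
  expect_length(uni, 59)
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% names(uni)))
  expect_error(relative_adaptiveness(codon_counts(c())), "empty")
})

test_that("CAI is the geometric mean of weights over codon occurrences", {
  ref <- suppressWarnings(relative_adaptiveness(
    codon_counts(stats::setNames(rep(1L, 64),
                                 names(Biostrings::GENETIC_CODE)))))
  gene <- codon_counts(c(AAA = 10, GGG = 5, CAT = 5))
  expect_equal(codon_adaptation_index(gene, ref), 1.0)
  w <- suppressWarnings(relative_adaptiveness(
    codon_counts(c(AAA = 100, AAG = 1, CAT = 100, CAC = 25))))
  gene <- codon_counts(c(AAG = 3, CAC = 2, AAA = 1))
  oracle <- exp((3 * log(0.01) + 2 * log(0.25) + 1 * log(1)) / 6)
  expect_equal(codon_adaptation_index(gene, w), oracle, tolerance = 1e-12)
  # concatenation = length-weighted geometric mean of the parts
  g1 <- codon_counts(c(AAG = 3)); g2 <- codon_counts(c(CAC = 2, AAA = 5))
  cai1 <- codon_adaptation_index(g1, w)
  cai2 <- codon_adaptation_index(g2, w)
  cat_counts <- codon_counts(c(AAG = 3, CAC = 2, AAA = 5))
  expect_equal(codon_adaptation_index(cat_counts, w),
               exp((3 * log(cai1) + 7 * log(cai2)) / 10), tolerance = 1e-12)
  expect_error(codon_adaptation_index(codon_counts(c(ATG = 5)), w),
               "no countable")
})

test_that("equal-usage CAI threshold is the codon-weighted geometric mean", {
  uni <- suppressWarnings(relative_adaptiveness(
    codon_counts(stats::setNames(rep(1L, 64),
                                 names(Biostrings::GENETIC_CODE)))))
  expect_equal(equal_usage_cai(uni), 1.0)
  w2 <- structure(c(AAA = 1, AAG = 0.5), class = "codon_weights")
  expect_equal(equal_usage_cai(w2), sqrt(0.5), tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:10) {
    ref <- codon_counts(stats::setNames(
      sample(0:50, 64, replace = TRUE), names(Biostrings::GENETIC_CODE)))
    w <- suppressWarnings(relative_adaptiveness(ref))
    thr <- equal_usage_cai(w)
    expect_lte(thr, 1)
    expect_gte(thr, min(w))
  }
})

test_that("GC partitions cover coding positions and 4D sites", {
  gc <- gc_partition(codon_counts(c(GGG = 1, AAA = 1)))
  expect_equal(unname(gc[c("GC1", "GC2", "GC3")]), c(0.5, 0.5, 0.5))
  expect_equal(unname(gc["GC_4D"]), 1.0)   # only GGG is fourfold-degenerate
  gc <- gc_partition(codon_counts(c(AAA = 3, TTT = 2, ATA = 1)))
  expect_true(all(gc[c("GC_coding", "GC1", "GC2", "GC3")] == 0))
  expect_error(gc_partition(codon_counts(c())), "no codons")
})

test_that("codon frequencies sum to one within used families", {
  freq <- codon_frequency(codon_counts(c(CAT = 7, CAC = 3)))
  his <- freq[freq$amino_acid == "H", ]
  expect_equal(his$fraction[his$codon == "CAT"], 0.7)
  expect_equal(his$fraction[his$codon == "CAC"], 0.3)
  expect_true(all(is.na(freq$fraction[freq$amino_acid == "K"])))
  met <- codon_frequency(codon_counts(c(ATG = 5)))
  expect_equal(met$fraction[met$codon == "ATG"], 1)
  set.seed(4)
  counts <- codon_counts(stats::setNames(sample(0:30, 64, replace = TRUE),
                                         names(Biostrings::GENETIC_CODE)))
  freq <- codon_frequency(counts)
  sums <- tapply(freq$fraction, freq$amino_acid, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})
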