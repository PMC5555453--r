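# Synonymous-family bookkeeping under the standard genetic code.
# Sixfold families (Leu, Ser, Arg) are kept whole: with degeneracy classes
# 9 x twofold, 1 x threefold (Ile), 5 x fourfold and 3 x sixfold plus the
# two single-codon amino acids, the effective-number-of-codons bounds are
# exactly 20 (= 2+9+1+5+3) and 61 (= 2+18+3+20+18).
genetic_code_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  stops <- codons[aa == "*"]
  fam <- split(codons, aa)
  fam[["*"]] <- NULL
  list(codons = codons, aa = stats::setNames(aa, codons), stops = stops,
       families = fam, degeneracy = vapply(fam, length, integer(1)))
}

ALL_CODONS <- names(Biostrings::GENETIC_CODE)

#' Count codons in a coding sequence
#'
#' The sequence is read in frame from its first base. Codons containing
#' `N` are excluded from the 64-slot tally and counted separately; stop
#' codons are tallied but excluded downstream from every bias statistic.
#'
#' @param cds_sequence character string or [Biostrings::DNAString] over
#'   `A,C,G,T,N`; length must be divisible by 3.
#' @return a `codon_counts` object: named integer vector over the 64
#'   codons with attribute `n_ambiguous`.
#' @examples
#' count_codons("ATGAAATAA")
#' @export
count_codons <- function(cds_sequence) {
  s <- toupper(as.character(cds_sequence))
  if (nchar(s) %% 3 != 0) {
    stop("coding sequence length (", nchar(s), ") is not divisible by 3")
  }
  counts <- stats::setNames(integer(64), ALL_CODONS)
  n_amb <- 0L
  if (nchar(s) > 0) {
    starts <- seq(1, nchar(s), by = 3)
    cod <- substring(s, starts, starts + 2)
    known <- cod %in% ALL_CODONS
    n_amb <- sum(!known)
    tab <- table(cod[known])
    counts[names(tab)] <- as.integer(tab)
  }
  structure(counts, n_ambiguous = n_amb, class = "codon_counts")
}

#' Build a codon-counts object from a named vector
#' @param x named numeric vector (codon -> count); missing codons are 0.
#' @return a `codon_counts` object.
#' @export
codon_counts <- function(x) {
  counts <- stats::setNames(integer(64), ALL_CODONS)
  if (!is.null(names(x))) counts[toupper(names(x))] <- as.integer(x)
  stopifnot(all(counts >= 0))
  structure(counts, n_ambiguous = 0L, class = "codon_counts")
}

#' Wright's effective number of codons (Nc)
#'
#' Nc measures departure from uniform synonymous-codon usage: 61 means all
#' synonymous codons are used equally (no bias), 20 means exactly one codon
#' per amino acid (maximal bias). Per-family homozygosity is
#' `F_hat = (n*sum(p^2) - 1)/(n - 1)` in `finite_sample` mode or
#' `F = sum(p^2)` in `proportions` mode (the infinite-length limit);
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` with each `Fk` the mean
#' homozygosity over the observed k-fold families. Families that are
#' absent, observed once, or (finite-sample mode) with non-positive
#' homozygosity are imputed by the mean of their degeneracy class, or by
#' `1/k` when the whole class is unobserved.
#'
#' @param counts a `codon_counts` object.
#' @param mode `"finite_sample"` (default) or `"proportions"`.
#' @return Nc value (numeric scalar).
#' @export
effective_number_of_codons <- function(counts,
                                       mode = c("finite_sample",
                                                "proportions")) {
  mode <- match.arg(mode)
  fam <- genetic_code_families()
  multi <- fam$families[fam$degeneracy > 1]
  deg <- fam$degeneracy[fam$degeneracy > 1]
  f_hat <- vapply(multi, function(codons) {
    n <- sum(counts[codons])
    if (n == 0) return(NA_real_)
    p <- counts[codons] / n
    if (mode == "proportions") return(sum(p^2))
    if (n < 2) return(NA_real_)
    fh <- (n * sum(p^2) - 1) / (n - 1)
    if (fh <= 0) NA_real_ else fh
  }, numeric(1))
  if (sum(counts[unlist(multi)]) == 0) {
    stop("no codons observed in any synonymous family")
  }
  fbar <- vapply(c(2, 3, 4, 6), function(k) {
    fk <- f_hat[deg == k]
    if (all(is.na(fk))) 1 / k else mean(fk, na.rm = TRUE)
  }, numeric(1))
  2 + 9 / fbar[1] + 1 / fbar[2] + 5 / fbar[3] + 3 / fbar[4]
}

#' Relative adaptiveness weights from a reference gene set
#'
#' Within each synonymous family, `w = count / max(count)`, so the most
#' frequent reference codon has weight 1. Zero-count codons are floored at
#' `w = 0.01`; a family with no reference counts at all is uninformative
#' and gets `w = 1` for every member (with a warning). Single-codon
#' families (Met, Trp) and stop codons are excluded.
#'
#' @param reference `codon_counts` of the reference gene set.
#' @param floor weight assigned to zero-count codons (default 0.01).
#' @return a `codon_weights` object: named numeric vector over the 59
#'   degenerate sense codons, all in (0, 1].
#' @export
relative_adaptiveness <- function(reference, floor = 0.01) {
  if (sum(reference) == 0) stop("empty reference codon counts")
  fam <- genetic_code_families()
  multi <- fam$families[fam$degeneracy > 1]
  w <- numeric(0)
  for (codons in multi) {
    cts <- as.numeric(reference[codons])
    if (max(cts) == 0) {
      warning("reference has no counts for family {",
              paste(codons, collapse = ","), "}; weights set to 1")
      wf <- rep(1, length(codons))
    } else {
      wf <- cts / max(cts)
      wf[wf == 0] <- floor
    }
    w <- c(w, stats::setNames(wf, codons))
  }
  structure(w, class = "codon_weights")
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness of a gene's codons,
#' excluding Met, Trp and stops: `CAI = exp(mean(log w))` over all codon
#' occurrences. 1.0 means every codon is the reference-optimal choice.
#'
#' @param counts `codon_counts` of the gene.
#' @param weights `codon_weights` from [relative_adaptiveness()].
#' @return CAI in (0, 1].
#' @export
codon_adaptation_index <- function(counts, weights) {
  codons <- names(weights)
  n <- as.numeric(counts[codons])
  L <- sum(n)
  if (L == 0) stop("no countable codons after exclusions")
  exp(sum(n * log(as.numeric(weights))) / L)
}

#' CAI of a hypothetical gene with equal synonymous-codon usage
#'
#' The threshold separating mutational-bias-dominated from
#' selection-dominated codon usage: the CAI of a gene that uses each
#' family's synonymous codons equally often, computed as the geometric
#' mean of the weights with every included sense codon weighted equally.
#'
#' @param weights `codon_weights`.
#' @return threshold CAI value.
#' @export
equal_usage_cai <- function(weights) {
  exp(mean(log(as.numeric(weights))))
}

# Codons whose third position is fourfold degenerate: Ala, Gly, Pro, Thr, Val.
FOURFOLD_AA <- c("A", "G", "P", "T", "V")

#' GC partitions of a codon tally
#'
#' GC fraction over all codon positions (`GC_coding`), per position
#' (`GC1`, `GC2`, `GC3`) and at fourfold-degenerate sites (`GC_4D`: third
#' positions of the codons for alanine, glycine, proline, threonine and
#' valine, where any base is synonymous). Stop codons are excluded.
#'
#' @param counts `codon_counts`.
#' @return named numeric vector `GC_coding`, `GC1`, `GC2`, `GC3`, `GC_4D`.
#' @export
gc_partition <- function(counts) {
  fam <- genetic_code_families()
  sense <- setdiff(ALL_CODONS, fam$stops)
  n <- as.numeric(counts[sense])
  if (sum(n) == 0) stop("no codons observed")
  base_at <- function(pos) substring(sense, pos, pos)
  gc_at <- function(pos) {
    sum(n[base_at(pos) %in% c("G", "C")]) / sum(n)
  }
  gc1 <- gc_at(1); gc2 <- gc_at(2); gc3 <- gc_at(3)
  gc_coding <- (sum(n[base_at(1) %in% c("G", "C")]) +
                  sum(n[base_at(2) %in% c("G", "C")]) +
                  sum(n[base_at(3) %in% c("G", "C")])) / (3 * sum(n))
  four <- sense[fam$aa[sense] %in% FOURFOLD_AA]
  n4 <- as.numeric(counts[four])
  gc4 <- if (sum(n4) == 0) NA_real_ else
    sum(n4[substring(four, 3, 3) %in% c("G", "C")]) / sum(n4)
  c(GC_coding = gc_coding, GC1 = gc1, GC2 = gc2, GC3 = gc3, GC_4D = gc4)
}

#' Per-family synonymous codon frequencies
#'
#' For each amino acid, the fraction of each synonymous codon among the
#' family total (e.g. the CAT vs CAC split for histidine). Families with
#' zero counts are reported as missing (`NA`), never 0/0.
#'
#' @param counts `codon_counts`.
#' @return data.frame `amino_acid`, `codon`, `count`, `fraction`.
#' @export
codon_frequency <- function(counts) {
  fam <- genetic_code_families()
  rows <- lapply(names(fam$families), function(aa) {
    codons <- fam$families[[aa]]
    cts <- as.numeric(counts[codons])
    tot <- sum(cts)
    data.frame(amino_acid = aa, codon = codons, count = cts,
               fraction = if (tot > 0) cts / tot else rep(NA_real_,
                                                          length(codons)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full codon-bias diagnostics for one gene
#'
#' @param counts `codon_counts`.
#' @param weights optional `codon_weights`; CAI is `NA` without them.
#' @param nc_mode mode passed to [effective_number_of_codons()].
#' @return one-row data.frame: `Nc`, `CAI`, `GC_coding`, `GC1`, `GC2`,
#'   `GC3`, `GC_4D`, `n_codons`, `n_ambiguous`.
#' @export
codon_bias_result <- function(counts, weights = NULL,
                              nc_mode = "finite_sample") {
  gc <- gc_partition(counts)
  fam <- genetic_code_families()
  data.frame(Nc = effective_number_of_codons(counts, nc_mode),
             CAI = if (is.null(weights)) NA_real_ else
               codon_adaptation_index(counts, weights),
             GC_coding = gc[["GC_coding"]], GC1 = gc[["GC1"]],
             GC2 = gc[["GC2"]], GC3 = gc[["GC3"]], GC_4D = gc[["GC_4D"]],
             n_codons = sum(counts[setdiff(ALL_CODONS, fam$stops)]),
             n_ambiguous = attr(counts, "n_ambiguous"))
}

#' Read a codon weight or count table from TSV
#'
#' Two columns: codon and value (header optional).
#' @param path TSV path.
#' @param as `"weights"` or `"counts"`.
#' @return `codon_weights` or `codon_counts`.
#' @export
read_codon_table <- function(path, as = c("weights", "counts")) {
  as <- match.arg(as)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.numeric(df[[2]])) {  # header row present
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  }
  v <- stats::setNames(as.numeric(df[[2]]), toupper(df[[1]]))
  if (as == "counts") return(codon_counts(v))
  structure(v, class = "codon_weights")
}
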