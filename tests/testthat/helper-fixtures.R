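# Shared fixtures and independent per-base oracles. The oracles deliberately
# work on plain integer/character vectors (one slot per base) so they share
# no code with the interval-algebra implementation they check.

make_feats <- function(start, end, class, name = paste0("rep", seq_along(start)),
                       seq_id = "chr", score = 100, strand = "+") {
  if (length(start) == 0) {
    return(make_feats(0L, 1L, "LINE")[0, , drop = FALSE])
  }
  data.frame(seq_id = seq_id, start = as.integer(start), end = as.integer(end),
             strand = strand, repeat_name = name,
             raw_class = class, canonical_class = class, score = score,
             overridden = FALSE, stringsAsFactors = FALSE)
}

rand_feats <- function(n, L, classes = c("LINE", "LTR", "DNA"),
                       n_names = 4) {
  start <- sample.int(L - 10, n, replace = TRUE) - 1L
  width <- sample.int(min(200L, L - 1L), n, replace = TRUE)
  end <- pmin(start + width, L)
  keep <- start < end
  make_feats(start[keep], end[keep],
             sample(classes, sum(keep), replace = TRUE),
             name = sample(paste0("el", seq_len(n_names)), sum(keep),
                           replace = TRUE))
}

# per-base class labeling: "" = uncovered, class name, or "Overlapping"
oracle_class_map <- function(feats, L) {
  lab <- character(L)
  for (i in seq_len(nrow(feats))) {
    idx <- seq(feats$start[i] + 1L, feats$end[i])
    cls <- feats$canonical_class[i]
    old <- lab[idx]
    lab[idx] <- ifelse(old == "" | old == cls, cls, "Overlapping")
  }
  lab
}

# per-base coverage counting
oracle_coverage <- function(feats, L) {
  cov <- integer(L)
  for (i in seq_len(nrow(feats))) {
    idx <- seq(feats$start[i] + 1L, feats$end[i])
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

# per-base boolean-mask overlap fraction of query vs annotation
oracle_overlap_fraction <- function(query, annot, L) {
  q <- logical(L); a <- logical(L)
  for (i in seq_len(nrow(query))) q[seq(query$start[i] + 1L, query$end[i])] <- TRUE
  for (i in seq_len(nrow(annot))) a[seq(annot$start[i] + 1L, annot$end[i])] <- TRUE
  sum(q & a) / sum(q)
}

# expand merged segments back to a per-base label vector
segments_to_map <- function(segs, L) {
  lab <- character(L)
  for (i in seq_len(nrow(segs))) {
    lab[seq(segs$start[i] + 1L, segs$end[i])] <- segs$canonical_class[i]
  }
  lab
}

# small simulation config for tests (same generative model, smaller region)
test_sim_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed, region_length = 150000L, gene_count = 8,
                   class_density = c(LTR = 0.40, LINE = 0.20,
                                     RC_Helitron = 0.05, DNA = 0.05),
                   intron_meanlog = c(log(70), log(1500)),
                   codon_genes = list(n_per_group = 6, codons_per_gene = 1000,
                                      gc3_mutational = 0.30,
                                      gc3_selected = 0.65,
                                      reference_depth = 20),
                   n_pairs = 25)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

write_mini_out <- function(path, rows) {
  writeLines(c("header line 1", "header line 2", "", rows), path)
}
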