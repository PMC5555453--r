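# ---- synthetic genome generator -------------------------------------------
# Generates genomes, annotations, signal tracks and exact truth tables with
# the statistical structure the comparative analysis assumes: a repeat-dense
# domain with planted, fragmented transposon copies of known classes; coding
# genes with a bimodal intron-size mixture and a controllable GC3 codon
# model; promoter-localized vs body-localized enrichment signals; and
# ortholog pairs with known intron inflation.

#' Default transposon library for the simulator
#'
#' A small library spanning the four transposon classes, with consensus
#' lengths and GC contents typical of LTR/LINE retrotransposons, a
#' rolling-circle Helitron and DNA transposons.
#'
#' @return data.frame `name`, `class` (canonical), `raw_class`, `length`,
#'   `gc`.
#' @export
default_repeat_library <- function() {
  data.frame(
    name = c("LTR-A_sim", "LTR-B_sim", "LINE-A_sim", "LINE-B_sim",
             "Helitron-A_sim", "DNA-A_sim", "DNA-B_sim"),
    class = c("LTR", "LTR", "LINE", "LINE", "RC_Helitron", "DNA", "DNA"),
    raw_class = c("LTR/Gypsy", "LTR/Pao", "LINE/CR1", "LINE/Jockey",
                  "RC/Helitron", "DNA/TcMar-Tc1", "DNA/P"),
    length = c(6000L, 5500L, 4500L, 4000L, 1200L, 1500L, 1600L),
    gc = c(0.45, 0.45, 0.40, 0.40, 0.35, 0.40, 0.40),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults describe a repeat-dense (F-element-like) 1-Mb region: per-class
#' transposon densities LTR 0.421, LINE 0.218, RC/Helitron 0.073, DNA 0.056
#' (total 0.768), 60 coding genes whose intron sizes come from a
#' two-component log-normal mixture (short ~70 bp and long ~4.3 kb
#' components), an AT-rich codon model (GC3 target 0.30), and enrichment
#' signals with a Gaussian promoter peak at each 5' coding-span end plus a
#' uniform body enrichment. Every output is a pure function of the config
#' and its seed.
#'
#' @param seed RNG seed.
#' @param region_length region size in bp.
#' @param seq_id contig name.
#' @param gc_background background GC fraction.
#' @param library transposon library ([default_repeat_library()]).
#' @param class_density named per-class target densities (fractions of the
#'   region; must sum to <= 0.95).
#' @param truncation_range min/max fraction of consensus length retained
#'   by a planted fragment (5'/3' truncation).
#' @param score_per_bp range of alignment score per planted bp.
#' @param n_spurious,spurious_score_per_bp extra low-scoring decoy matches
#'   (for cutoff-score filtering tests).
#' @param gene_count number of genes.
#' @param cds_count_range min/max CDS exons per gene.
#' @param cds_size_meanlog,cds_size_sdlog log-normal CDS exon size model
#'   (sizes rounded to codon multiples).
#' @param intron_meanlog,intron_sdlog two-component log-normal intron-size
#'   mixture (component 1 short, component 2 long).
#' @param intron_weight mixing weight of the short component, in (0, 1).
#' @param gc3 target GC fraction at synonymous third positions.
#' @param signal list: `peak_height`, `peak_width` (sd, bp), `body_level`,
#'   `baseline`, `noise_sd`, `bin` (bedGraph step, bp).
#' @param ortholog_factor intron inflation factor for species-B orthologs
#'   (>= 1).
#' @param ortholog_fraction fraction of (long-component) introns inflated.
#' @param n_pairs ortholog pairs to simulate.
#' @param codon_genes list for [simulate_codon_genes()]: `n_per_group`,
#'   `codons_per_gene`, `gc3_mutational`, `gc3_selected`,
#'   `reference_depth`.
#' @param nesting_allowed allow planted fragments to overlap earlier
#'   fragments (occluding them); truth counts visible bases.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              region_length = 1e6,
                              seq_id = "sim_region",
                              gc_background = 0.40,
                              library = default_repeat_library(),
                              class_density = c(LTR = 0.421, LINE = 0.218,
                                                RC_Helitron = 0.073,
                                                DNA = 0.056),
                              truncation_range = c(0.2, 1),
                              score_per_bp = c(0.25, 0.40),
                              n_spurious = 0,
                              spurious_score_per_bp = 0.05,
                              gene_count = 60,
                              cds_count_range = c(2, 8),
                              cds_size_meanlog = log(180),
                              cds_size_sdlog = 0.35,
                              intron_meanlog = c(log(70), log(4300)),
                              intron_sdlog = c(0.4, 0.6),
                              intron_weight = 0.5,
                              gc3 = 0.30,
                              signal = list(peak_height = 3,
                                            peak_width = 200,
                                            body_level = 1,
                                            baseline = 0.1,
                                            noise_sd = 0.1,
                                            bin = 25),
                              ortholog_factor = 8.6,
                              ortholog_fraction = 1,
                              n_pairs = 40,
                              codon_genes = list(n_per_group = 20,
                                                 codons_per_gene = 3000,
                                                 gc3_mutational = 0.30,
                                                 gc3_selected = 0.65,
                                                 reference_depth = 100),
                              nesting_allowed = FALSE) {
  stopifnot(region_length >= 1000, all(class_density >= 0),
            all(class_density <= 1), sum(class_density) <= 0.95,
            intron_weight > 0, intron_weight < 1,
            gc3 >= 0, gc3 <= 1, ortholog_factor >= 1,
            all(library$class %in% REPEAT_CLASSES))
  structure(as.list(environment()), class = "simulation_config")
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Draw a placement interval of width len from the free space (IRanges,
# 1-based); returns NULL when nothing fits. Gaps are weighted by the number
# of admissible offsets so placement is uniform over positions.
draw_slot <- function(free, len) {
  fits <- free[IRanges::width(free) >= len]
  if (length(fits) == 0) return(NULL)
  w <- IRanges::width(fits) - len + 1
  g <- fits[sample.int(length(fits), 1, prob = w)]
  off <- sample.int(IRanges::width(g) - len + 1, 1) - 1
  IRanges::IRanges(IRanges::start(g) + off, width = len)
}

# Codon sampler hitting an exact expected GC3: amino acids are drawn
# uniformly from the families whose synonymous third-base split makes the
# per-codon GC3 probability exactly the target (all multi-codon families
# except Ile; Met/Trp excluded as non-degenerate).
gc3_exact_families <- function() {
  fam <- genetic_code_families()
  keep <- names(fam$families)[fam$degeneracy > 1 &
                                names(fam$families) != "I"]
  fam$families[keep]
}

# Vectorized codon draw: amino acids sampled uniformly from `families`,
# codon within each family by inverse-CDF over `weight_fn(codons)` weights.
draw_codons <- function(n, families, weight_fn) {
  aa <- sample(names(families), n, replace = TRUE)
  out <- character(n)
  u <- stats::runif(n)
  for (a in unique(aa)) {
    codons <- families[[a]]
    p <- weight_fn(codons)
    cdf <- cumsum(p / sum(p))
    idx <- aa == a
    out[idx] <- codons[findInterval(u[idx], cdf) + 1L]
  }
  out
}

gc3_weight_fn <- function(gc3) {
  function(codons) {
    third_gc <- substring(codons, 3, 3) %in% c("G", "C")
    ifelse(third_gc, gc3, 1 - gc3)
  }
}

sample_codons <- function(n, gc3, families = gc3_exact_families()) {
  draw_codons(n, families, gc3_weight_fn(gc3))
}

# Draw one gene structure: CDS exon sizes (codon multiples) and intron
# sizes from the two-component mixture. Returns sizes only.
draw_gene_structure <- function(config) {
  n_cds <- sample(seq(config$cds_count_range[1], config$cds_count_range[2]),
                  1)
  exon <- 3L * pmax(3L, round(stats::rlnorm(n_cds, config$cds_size_meanlog,
                                            config$cds_size_sdlog) / 3))
  comp <- ifelse(stats::runif(max(n_cds - 1, 0)) < config$intron_weight,
                 1L, 2L)
  intron <- if (n_cds > 1) {
    pmax(30L, round(stats::rlnorm(n_cds - 1,
                                  config$intron_meanlog[comp],
                                  config$intron_sdlog[comp])))
  } else integer(0)
  list(exon = as.integer(exon), intron = as.integer(intron),
       intron_component = comp, span = sum(exon) + sum(intron))
}

#' Simulate a repeat-dense region with genes, annotations and signals
#'
#' Plants fragmented transposon copies until each class's density target
#' is met exactly (the final fragment is trimmed), places genes whose
#' introns and flanks may contain repeats but whose CDS exons never do,
#' writes the CDS codons from the configured GC3 model, and lays two
#' enrichment signals over the region: an "active"-mark signal with a
#' Gaussian peak at each 5' coding-span end and a "silencing"-mark signal
#' uniformly elevated over each coding span, both with seeded noise.
#' All outputs are written under `out_dir` and returned with exact truth
#' tables.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created).
#' @return list: `paths` (fasta, gff3, rm_out, region_bed, signal_active,
#'   signal_body, truth_repeats, truth_genes), `features` (planted repeat
#'   data.frame), `models` (isoform models), `truth` (list of truth
#'   data.frames), `genome` (DNAStringSet).
#' @export
simulate_region <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  L <- as.integer(config$region_length)
  genome_chars <- strsplit(random_dna(L, config$gc_background), "")[[1]]

  # consensus sequences, deterministic under the config seed
  consensus <- lapply(seq_len(nrow(config$library)), function(i)
    strsplit(random_dna(config$library$length[i], config$library$gc[i]),
             "")[[1]])
  names(consensus) <- config$library$name

  # -- gene structures and placement (genes never overlap each other; CDS
  #    exons are reserved before repeat planting) -------------------------
  margin <- 2100L
  structures <- replicate(config$gene_count, draw_gene_structure(config),
                          simplify = FALSE)
  free_genes <- IRanges::IRanges(margin + 1L, L - margin)
  gene_rows <- list()
  for (gi in seq_along(structures)) {
    st <- structures[[gi]]
    slot <- draw_slot(free_genes, st$span)
    if (is.null(slot)) {
      stop("cannot place gene ", gi, " (span ", st$span,
           " bp): region too small for the configured gene load")
    }
    free_genes <- IRanges::setdiff(free_genes, slot)
    gene_rows[[gi]] <- list(structure = st,
                            start = IRanges::start(slot) - 1L,
                            strand = sample(c("+", "-"), 1))
  }

  # -- repeat planting: anywhere except CDS exons ------------------------
  cds_ivs <- do.call(rbind, lapply(gene_rows, function(g) {
    st <- g$structure
    pos <- g$start
    segs <- matrix(NA_integer_, nrow = length(st$exon), ncol = 2)
    for (i in seq_along(st$exon)) {
      segs[i, ] <- c(pos, pos + st$exon[i])
      pos <- pos + st$exon[i] +
        if (i < length(st$exon)) st$intron[i] else 0L
    }
    segs
  }))
  free <- IRanges::setdiff(IRanges::IRanges(1L, L),
                           IRanges::IRanges(cds_ivs[, 1] + 1L, cds_ivs[, 2]))
  feats <- list()
  truth_bp <- stats::setNames(numeric(length(config$class_density)),
                              names(config$class_density))
  for (cls in names(config$class_density)) {
    target <- round(config$class_density[[cls]] * L)
    members <- which(config$library$class == cls)
    if (target > 0 && length(members) == 0) {
      stop("no library element of class ", cls)
    }
    planted <- 0L
    while (planted < target) {
      el <- members[sample.int(length(members), 1)]
      el_len <- config$library$length[el]
      frac <- stats::runif(1, config$truncation_range[1],
                           config$truncation_range[2])
      len <- min(max(30L, round(frac * el_len)), el_len)
      # trim the final fragment so the planted total hits the target exactly
      if (len > target - planted) len <- as.integer(target - planted)
      if (len < 1L) break
      slot <- draw_slot(free, len)
      if (is.null(slot)) {
        mx <- if (length(free)) max(IRanges::width(free)) else 0L
        if (mx < 30L) {
          stop("infeasible density target for class ", cls,
               ": free space exhausted with ", target - planted,
               " bp still to plant")
        }
        len <- min(len, mx)
        slot <- draw_slot(free, len)
      }
      if (!config$nesting_allowed) free <- IRanges::setdiff(free, slot)
      s0 <- IRanges::start(slot) - 1L
      off <- sample.int(el_len - len + 1L, 1) - 1L
      frag <- consensus[[el]][seq(off + 1L, off + len)]
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") {
        frag <- rev(c(A = "T", T = "A", G = "C", C = "G")[frag])
      }
      genome_chars[seq(s0 + 1L, s0 + len)] <- frag
      feats[[length(feats) + 1L]] <- data.frame(
        seq_id = config$seq_id, start = s0, end = s0 + len,
        strand = strand, repeat_name = config$library$name[el],
        raw_class = config$library$raw_class[el], canonical_class = cls,
        score = round(len * stats::runif(1, config$score_per_bp[1],
                                         config$score_per_bp[2]), 1),
        overridden = FALSE, stringsAsFactors = FALSE)
      planted <- planted + len
    }
    truth_bp[[cls]] <- planted
  }
  # decoy low-score matches (not counted in truth densities)
  if (config$n_spurious > 0) {
    for (i in seq_len(config$n_spurious)) {
      len <- sample(50:200, 1)
      slot <- draw_slot(free, len)
      if (is.null(slot)) break
      el <- sample.int(nrow(config$library), 1)
      feats[[length(feats) + 1L]] <- data.frame(
        seq_id = config$seq_id, start = IRanges::start(slot) - 1L,
        end = IRanges::start(slot) - 1L + len, strand = "+",
        repeat_name = config$library$name[el],
        raw_class = config$library$raw_class[el],
        canonical_class = config$library$class[el],
        score = round(len * config$spurious_score_per_bp, 1),
        overridden = FALSE, stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feats)
  if (is.null(features)) features <- empty_repeat_features()

  # occlusion-aware truth when nesting is allowed: visible bases per class
  # (last writer wins, matching what an annotator of the final sequence sees)
  if (config$nesting_allowed && nrow(features) > 0) {
    cmap <- character(L)
    for (i in seq_len(nrow(features))) {
      cmap[seq(features$start[i] + 1L, features$end[i])] <-
        features$canonical_class[i]
    }
    tb <- table(cmap[nzchar(cmap)])
    truth_bp[] <- 0
    truth_bp[names(tb)] <- as.numeric(tb)
  }

  # -- write gene codons into CDS positions ------------------------------
  models <- list()
  truth_gene_rows <- list()
  for (gi in seq_along(gene_rows)) {
    g <- gene_rows[[gi]]
    st <- g$structure
    n_codons <- sum(st$exon) / 3
    codons <- c("ATG", sample_codons(n_codons - 2, config$gc3), "TAA")
    cds_seq <- strsplit(paste(codons, collapse = ""), "")[[1]]
    if (g$strand == "-") {
      cds_seq <- rev(c(A = "T", T = "A", G = "C", C = "G")[cds_seq])
    }
    pos <- g$start
    segs <- matrix(NA_integer_, nrow = length(st$exon), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
    cursor <- 1L
    for (i in seq_along(st$exon)) {
      segs[i, ] <- c(pos, pos + st$exon[i])
      pos <- pos + st$exon[i] + if (i < length(st$exon)) st$intron[i] else 0L
    }
    # genomic leftmost exon first in cds_seq for + strand; for - strand the
    # reverse-complemented CDS occupies the same genomic footprint
    flat <- unlist(lapply(seq_len(nrow(segs)), function(i)
      seq(segs[i, 1] + 1L, segs[i, 2])))
    genome_chars[flat] <- cds_seq
    gene_id <- sprintf("%s_g%03d", config$seq_id, gi)
    models[[gene_id]] <- isoform_model(gene_id, paste0(gene_id, ".t1"),
                                       config$seq_id, g$strand, segs)
    truth_gene_rows[[gi]] <- data.frame(
      gene_id = gene_id,
      coding_span_size = st$span, total_cds_size = sum(st$exon),
      total_intron_size = sum(st$intron), cds_count = length(st$exon),
      median_cds_size = stats::median(st$exon),
      median_intron_size = if (length(st$intron))
        stats::median(st$intron) else NA_real_,
      gc3_target = config$gc3, strand = g$strand,
      tss = if (g$strand == "+") min(segs[, 1]) else max(segs[, 2]),
      span_start = min(segs[, 1]), span_end = max(segs[, 2]),
      stringsAsFactors = FALSE)
  }
  truth_genes <- do.call(rbind, truth_gene_rows)

  # -- signal tracks ------------------------------------------------------
  bin <- config$signal$bin
  starts <- seq(0L, L - 1L, by = bin)
  centers <- starts + bin / 2
  active <- rep(config$signal$baseline, length(starts))
  body <- rep(config$signal$baseline, length(starts))
  for (gi in seq_len(nrow(truth_genes))) {
    tg <- truth_genes[gi, ]
    active <- active + config$signal$peak_height *
      exp(-(centers - tg$tss)^2 / (2 * config$signal$peak_width^2))
    inside <- centers >= tg$span_start & centers < tg$span_end
    body[inside] <- body[inside] + config$signal$body_level
  }
  active <- pmax(0, active + stats::rnorm(length(starts), 0,
                                          config$signal$noise_sd))
  body <- pmax(0, body + stats::rnorm(length(starts), 0,
                                      config$signal$noise_sd))
  track_df <- function(v) data.frame(seq_id = config$seq_id, start = starts,
                                     end = pmin(starts + bin, L),
                                     value = round(v, 5))

  # -- write everything ---------------------------------------------------
  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    rm_out = file.path(out_dir, "repeats.out"),
    region_bed = file.path(out_dir, "region.bed"),
    signal_active = file.path(out_dir, "signal_active.bedgraph"),
    signal_body = file.path(out_dir, "signal_body.bedgraph"),
    truth_repeats = file.path(out_dir, "truth_repeats.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"))
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(genome_chars, collapse = ""), config$seq_id))
  Biostrings::writeXStringSet(genome, paths$fasta)
  write_gff3_models(models, paths$gff3)
  write_repeatmasker_out(features, paths$rm_out)
  region_gr <- GenomicRanges::GRanges(config$seq_id,
                                      IRanges::IRanges(1, L),
                                      name = config$seq_id)
  rtracklayer::export(region_gr, paths$region_bed, format = "BED")
  write_bedgraph(track_df(active), paths$signal_active, drop_zero = FALSE)
  write_bedgraph(track_df(body), paths$signal_body, drop_zero = FALSE)
  truth_repeats <- data.frame(class = names(truth_bp),
                              planted_bp = as.numeric(truth_bp),
                              density = as.numeric(truth_bp) / L,
                              stringsAsFactors = FALSE)
  utils::write.table(truth_repeats, paths$truth_repeats, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_genes, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(paths = paths, features = features, models = models,
       truth = list(repeats = truth_repeats, genes = truth_genes),
       genome = genome,
       region = analysis_region(config$seq_id,
                                data.frame(seq_id = config$seq_id,
                                           start = 0L, end = L)))
}

# GFF3 writer for isoform models (gene -> mRNA -> CDS, 1-based inclusive).
write_gff3_models <- function(models, path) {
  seq_id <- character(0); start <- integer(0); end <- integer(0)
  strand <- character(0); type <- character(0); id <- character(0)
  parent <- list()
  for (m in models) {
    seg <- m$cds_segments
    n_seg <- nrow(seg)
    seq_id <- c(seq_id, rep(m$seq_id, 2 + n_seg))
    start <- c(start, min(seg[, 1]) + 1L, min(seg[, 1]) + 1L, seg[, 1] + 1L)
    end <- c(end, max(seg[, 2]), max(seg[, 2]), seg[, 2])
    strand <- c(strand, rep(m$strand, 2 + n_seg))
    type <- c(type, "gene", "mRNA", rep("CDS", n_seg))
    id <- c(id, m$gene_id, m$isoform_id,
            paste0(m$isoform_id, ".cds", seq_len(n_seg)))
    parent <- c(parent, list(character(0), m$gene_id),
                rep(list(m$isoform_id), n_seg))
  }
  gr <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(start, end),
                               strand = strand)
  gr$type <- type
  gr$ID <- id
  gr$Parent <- IRanges::CharacterList(parent)
  # exon sizes are codon multiples here, so every CDS starts in phase 0
  gr$phase <- ifelse(type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate codon-usage gene groups with known bias regimes
#'
#' Three groups of coding sequences sampled codon-wise: `"uniform"` (equal
#' synonymous usage; no bias), `"mutational"` (AT-shifted wobble bases,
#' agnostic of any reference weights) and `"selected"` (shifted toward the
#' GC-ending codons that dominate the reference set). A deep reference
#' codon tally drawn from the selected regime is returned for computing
#' relative-adaptiveness weights.
#'
#' @param config a [simulation_config()] (`codon_genes` settings used).
#' @param out_dir optional directory to write `codon_genes.fa`,
#'   `codon_truth.tsv` and `reference_counts.tsv`.
#' @return list `sequences` (named character), `truth` (data.frame
#'   `gene_id`, `group`, `gc3_target`, `n_codons`), `reference`
#'   (`codon_counts`), `paths`.
#' @export
simulate_codon_genes <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  cg <- config$codon_genes
  fam <- genetic_code_families()
  multi <- fam$families[fam$degeneracy > 1]
  gen_gene <- function(group) {
    wfn <- switch(group,
                  uniform = function(codons) rep(1, length(codons)),
                  mutational = gc3_weight_fn(cg$gc3_mutational),
                  selected = gc3_weight_fn(cg$gc3_selected))
    codons <- draw_codons(cg$codons_per_gene, multi, wfn)
    paste(c("ATG", codons, "TAA"), collapse = "")
  }
  groups <- c("uniform", "mutational", "selected")
  seqs <- character(0)
  truth <- list()
  for (g in groups) {
    for (i in seq_len(cg$n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      seqs[[id]] <- gen_gene(g)
      truth[[id]] <- data.frame(
        gene_id = id, group = g,
        gc3_target = switch(g, uniform = 0.5,
                            mutational = cg$gc3_mutational,
                            selected = cg$gc3_selected),
        n_codons = cg$codons_per_gene, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  # deep reference from the selected regime
  ref_counts <- count_codons(paste(replicate(cg$reference_depth,
                                             gen_gene("selected")),
                                   collapse = ""))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(out_dir, "codon_genes.fa"),
                  truth = file.path(out_dir, "codon_truth.tsv"),
                  reference = file.path(out_dir, "reference_counts.tsv"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), paths$fasta)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(codon = names(ref_counts),
                                  count = as.integer(ref_counts)),
                       paths$reference, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(sequences = seqs, truth = truth, reference = ref_counts,
       paths = paths)
}

#' Simulate ortholog pairs with known intron inflation
#'
#' Species-B genes copy the species-A exon structure exactly (total CDS
#' difference is 0 by construction); a configured fraction of the
#' long-component introns is inflated by the configured factor, emulating
#' the selective expansion of a subset of introns. Genes are laid head to
#' tail on one virtual contig per species.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory for `species_a.gff3`,
#'   `species_b.gff3`, `pairs.tsv`, `ortholog_truth.tsv`.
#' @return list `models_a`, `models_b` (isoform model lists), `pairs`
#'   (data.frame `gene_a`, `gene_b`), `truth` (per-pair inflation record),
#'   `paths`.
#' @export
simulate_ortholog_pairs <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  spacer <- 1000L
  models_a <- list()
  models_b <- list()
  pairs <- list()
  truth <- list()
  pos_a <- 0L
  pos_b <- 0L
  for (i in seq_len(config$n_pairs)) {
    st <- draw_gene_structure(config)
    intron_b <- st$intron
    inflate <- logical(length(intron_b))
    if (length(intron_b)) {
      long <- st$intron_component == 2L
      inflate <- long & stats::runif(length(intron_b)) <
        config$ortholog_fraction
      intron_b[inflate] <- as.integer(round(intron_b[inflate] *
                                              config$ortholog_factor))
    }
    build <- function(start, exon, intron) {
      segs <- matrix(NA_integer_, nrow = length(exon), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
      pos <- start
      for (k in seq_along(exon)) {
        segs[k, ] <- c(pos, pos + exon[k])
        pos <- pos + exon[k] + if (k < length(exon)) intron[k] else 0L
      }
      segs
    }
    ga <- sprintf("speciesA_g%03d", i)
    gb <- sprintf("speciesB_g%03d", i)
    segs_a <- build(pos_a, st$exon, st$intron)
    segs_b <- build(pos_b, st$exon, intron_b)
    strand <- sample(c("+", "-"), 1)
    models_a[[ga]] <- isoform_model(ga, paste0(ga, ".t1"), "contigA",
                                    strand, segs_a)
    models_b[[gb]] <- isoform_model(gb, paste0(gb, ".t1"), "contigB",
                                    strand, segs_b)
    pos_a <- max(segs_a[, 2]) + spacer
    pos_b <- max(segs_b[, 2]) + spacer
    pairs[[i]] <- data.frame(gene_a = ga, gene_b = gb,
                             stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      gene_a = ga, gene_b = gb, n_introns = length(st$intron),
      n_inflated = sum(inflate),
      total_intron_a = sum(st$intron), total_intron_b = sum(intron_b),
      median_intron_a = if (length(st$intron))
        stats::median(st$intron) else NA_real_,
      median_intron_b = if (length(intron_b))
        stats::median(intron_b) else NA_real_,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  truth <- do.call(rbind, truth)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gff_a = file.path(out_dir, "species_a.gff3"),
                  gff_b = file.path(out_dir, "species_b.gff3"),
                  pairs = file.path(out_dir, "pairs.tsv"),
                  truth = file.path(out_dir, "ortholog_truth.tsv"))
    write_gff3_models(models_a, paths$gff_a)
    write_gff3_models(models_b, paths$gff_b)
    utils::write.table(pairs, paths$pairs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(models_a = models_a, models_b = models_b, pairs = pairs,
       truth = truth, paths = paths)
}
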