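#' Validate a run configuration
#'
#' Accepts a YAML file path or an R list. All errors are collected and
#' reported together, not first-fail. Recognized keys: `genome_fasta`,
#' `gff3`, `repeat_out`, `regions_bed`, `tracks` (named list of bedGraph
#' paths), `weights_tsv`, `reference_counts_tsv`, `ortholog_pairs_tsv`,
#' `expression_tsv`, `min_score`, `alpha`, `tm` (list for [tm_params()]),
#' `span_length`, `flank`, `seed`, `out_dir`. Missing `alpha` defaults to
#' 0.05 (the conventional type I error rate), missing metagene geometry to
#' the 3-kb span / 2-kb flank standard.
#'
#' @param config path to a YAML document or a list.
#' @return a validated `run_config` list, or an error listing every
#'   problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  errors <- character(0)
  known <- c("genome_fasta", "gff3", "repeat_out", "regions_bed", "tracks",
             "weights_tsv", "reference_counts_tsv", "ortholog_pairs_tsv",
             "expression_tsv", "min_score", "alpha", "tm", "span_length",
             "flank", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  for (key in c("genome_fasta", "gff3", "repeat_out", "regions_bed")) {
    if (is.null(config[[key]])) {
      errors <- c(errors, paste0("mandatory key '", key, "' is missing"))
    } else if (!file.exists(config[[key]])) {
      errors <- c(errors, paste0(key, ": file not found: ", config[[key]]))
    }
  }
  for (key in c("weights_tsv", "reference_counts_tsv", "ortholog_pairs_tsv",
                "expression_tsv")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      errors <- c(errors, paste0(key, ": file not found: ", config[[key]]))
    }
  }
  if (!is.null(config$tracks)) {
    if (is.null(names(config$tracks)) || any(!nzchar(names(config$tracks)))) {
      errors <- c(errors, "tracks must be a named list of bedGraph paths")
    } else {
      for (nm in names(config$tracks)) {
        if (!file.exists(config$tracks[[nm]])) {
          errors <- c(errors, paste0("tracks$", nm, ": file not found: ",
                                     config$tracks[[nm]]))
        }
      }
    }
  }
  if (is.null(config$alpha)) config$alpha <- 0.05
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    errors <- c(errors, "alpha must be in (0, 1)")
  }
  if (is.null(config$span_length)) config$span_length <- 3000
  if (is.null(config$flank)) config$flank <- 2000
  if (is.null(config$seed)) config$seed <- 1L
  tm <- config$tm
  config$tm <- tryCatch(
    do.call(tm_params, if (is.null(tm)) list() else tm),
    error = function(e) {
      errors <<- c(errors, paste0("tm: ", conditionMessage(e)))
      NULL
    })
  if (length(errors) == 0 && !is.null(config$regions_bed)) {
    regs <- tryCatch(read_regions_bed(config$regions_bed),
                     error = function(e) {
                       errors <<- c(errors, paste0("regions_bed: ",
                                                   conditionMessage(e)))
                       NULL
                     })
    if (!is.null(regs) && anyDuplicated(names(regs))) {
      errors <- c(errors, "region names are not unique")
    }
  }
  if (length(errors)) {
    stop("invalid run configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  structure(config, class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full comparative analysis
#'
#' Executes the pipeline over one configuration: repeat ledger (parse,
#' optional score filter, class-aware merge, per-region densities and
#' top-repeat tables), gene architecture (most comprehensive isoform,
#' coding-span metrics, region partition), codon bias (per-gene Nc, CAI
#' against supplied weights or reference counts, GC partition tables and
#' per-family codon frequencies per region), melting-temperature and
#' signal metagenes, and the Kruskal-Wallis/Dunn group comparisons of the
#' gene metrics across regions. Optional stages without inputs (tracks,
#' weights, expression matrix) are skipped with a manifest note. All
#' tables are written as TSV under `out_dir` together with a manifest
#' recording the seed, a config hash, and per-table row counts; a rerun
#' with the same config produces identical tables and hash.
#'
#' @param config a validated `run_config` (or anything
#'   [validate_config()] accepts).
#' @param force overwrite an existing run directory (default FALSE).
#' @return a `report_bundle` list (invisibly): `densities`, `top_repeats`,
#'   `gene_metrics`, `partitions`, `codon_bias`, `gc_tables`,
#'   `codon_freq`, `metagenes`, `comparisons`, `manifest`.
#' @export
run_compare <- function(config, force = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
      stop("output directory ", out_dir,
           " already contains a run; use force = TRUE or a new directory")
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  set.seed(config$seed)
  t0 <- Sys.time()
  skipped <- character(0)
  bundle <- list()

  # ---- repeat ledger ----
  regions <- read_regions_bed(config$regions_bed)
  features <- parse_repeatmasker_out(config$repeat_out)
  stage_log("repeats", "parsed %d fragments over %d region(s)",
            nrow(features), length(regions))
  if (!is.null(config$min_score)) {
    features <- score_filter(features, config$min_score)
  }
  transposons <- features[features$canonical_class !=
                            "Simple_LowComplexity", , drop = FALSE]
  segments <- merge_by_class(transposons)
  dens_rows <- lapply(regions, function(r) {
    d <- class_density(segments, r)
    data.frame(region = r$name,
               class = c(names(d$densities), "total"),
               density = round(c(d$densities, d$total), 4),
               stringsAsFactors = FALSE)
  })
  # report regions ordered by total transposon density, densest first
  totals <- vapply(dens_rows, function(d)
    d$density[d$class == "total"], numeric(1))
  bundle$densities <- do.call(rbind, c(dens_rows[order(-totals)],
                                       make.row.names = FALSE))
  bundle$top_repeats <- do.call(rbind, c(lapply(regions, function(r) {
    t <- top_repeat_table(transposons, r, n = 10)
    if (nrow(t)) cbind(region = r$name, t) else NULL
  }), make.row.names = FALSE))

  # ---- gene architecture ----
  models <- read_gene_models(config$gff3)
  metrics <- gene_metrics_table(models)
  # assign genes to regions by coding-span midpoint
  metrics$region <- NA_character_
  picked <- lapply(split(models,
                         vapply(models, function(m) m$gene_id,
                                character(1))),
                   select_comprehensive_isoform)
  for (r in regions) {
    for (m in picked) {
      mid <- (min(m$cds_segments[, 1]) + max(m$cds_segments[, 2])) / 2
      hit <- any(r$intervals$seq_id == m$seq_id &
                   r$intervals$start <= mid & mid < r$intervals$end)
      if (hit) metrics$region[metrics$gene_id == m$gene_id] <- r$name
    }
  }
  # log-scale companion columns (pseudocount of 1) for plotting tables
  for (col in c("coding_span_size", "total_intron_size", "total_cds_size",
                "median_cds_size", "median_intron_size")) {
    metrics[[paste0("log10_", col)]] <- log10(metrics[[col]] + 1)
  }
  bundle$gene_metrics <- metrics
  stage_log("genes", "%d genes (%d isoforms)", nrow(metrics), length(models))
  bundle$partitions <- do.call(rbind, c(lapply(regions, function(r) {
    p <- partition_regions(models, r)
    data.frame(region = r$name, space = names(p$bp), bp = as.numeric(p$bp),
               fraction = round(as.numeric(p$bp) / r$total_bp, 4),
               stringsAsFactors = FALSE)
  }), make.row.names = FALSE))

  # ---- codon bias ----
  genome <- Biostrings::readDNAStringSet(config$genome_fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  weights <- NULL
  if (!is.null(config$weights_tsv)) {
    weights <- read_codon_table(config$weights_tsv, as = "weights")
  } else if (!is.null(config$reference_counts_tsv)) {
    weights <- relative_adaptiveness(
      read_codon_table(config$reference_counts_tsv, as = "counts"))
  } else {
    skipped <- c(skipped, "CAI (no weights or reference counts supplied)")
  }
  gene_counts <- lapply(picked, function(m)
    count_codons(extract_cds_sequence(m, genome)))
  bias <- do.call(rbind, c(lapply(names(gene_counts), function(g)
    cbind(gene_id = g, codon_bias_result(gene_counts[[g]], weights))),
    make.row.names = FALSE))
  bias$region <- metrics$region[match(bias$gene_id, metrics$gene_id)]
  bundle$codon_bias <- bias
  pooled <- lapply(regions, function(r) {
    ids <- metrics$gene_id[!is.na(metrics$region) & metrics$region == r$name]
    if (length(ids) == 0) return(NULL)
    codon_counts(Reduce(`+`, lapply(gene_counts[ids], as.integer)) |>
                   stats::setNames(ALL_CODONS))
  })
  bundle$gc_tables <- do.call(rbind, c(lapply(names(pooled), function(rn) {
    if (is.null(pooled[[rn]])) return(NULL)
    gc <- gc_partition(pooled[[rn]])
    data.frame(region = rn, metric = names(gc),
               pct = round(100 * as.numeric(gc), 1),
               stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  bundle$codon_freq <- do.call(rbind, c(lapply(names(pooled), function(rn) {
    if (is.null(pooled[[rn]])) return(NULL)
    cbind(region = rn, codon_frequency(pooled[[rn]]))
  }), make.row.names = FALSE))
  if (!is.null(weights)) {
    stage_log("codons", "equal-usage CAI threshold: %.4f",
              equal_usage_cai(weights))
  }

  # ---- metagenes ----
  bundle$metagenes <- list()
  by_region_models <- lapply(regions, function(r) {
    ids <- metrics$gene_id[!is.na(metrics$region) & metrics$region == r$name]
    picked[ids]
  })
  for (rn in names(by_region_models)) {
    mods <- by_region_models[[rn]]
    if (length(mods) == 0) next
    bundle$metagenes[[paste0("tm_", rn)]] <-
      tm_metagene(mods, genome, config$tm, config$span_length, config$flank)
  }
  if (!is.null(config$tracks)) {
    seq_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
    for (tn in names(config$tracks)) {
      track <- read_bedgraph(config$tracks[[tn]])
      for (rn in names(by_region_models)) {
        mods <- by_region_models[[rn]]
        if (length(mods) == 0) next
        bundle$metagenes[[paste(tn, rn, sep = "_")]] <-
          signal_metagene(track, mods, config$span_length, config$flank,
                          seq_lengths)
      }
    }
  } else {
    skipped <- c(skipped, "signal metagenes (no tracks supplied)")
  }

  # ---- statistics across regions ----
  comparisons <- list()
  for (metric in c("coding_span_size", "total_intron_size",
                   "total_cds_size", "cds_count", "median_cds_size",
                   "median_intron_size")) {
    groups <- split(metrics[[metric]][!is.na(metrics$region)],
                    metrics$region[!is.na(metrics$region)])
    groups <- lapply(groups, function(v) v[!is.na(v)])
    groups <- groups[lengths(groups) > 0]
    if (length(groups) >= 2) {
      comparisons[[metric]] <- dunn_holm(groups, alpha = config$alpha)
    }
  }
  for (metric in c("Nc", "CAI")) {
    vals <- bias[[metric]]
    groups <- split(vals[!is.na(bias$region) & !is.na(vals)],
                    bias$region[!is.na(bias$region) & !is.na(vals)])
    groups <- groups[lengths(groups) > 0]
    if (length(groups) >= 2) {
      comparisons[[metric]] <- dunn_holm(groups, alpha = config$alpha)
    }
  }
  if (!is.null(config$expression_tsv)) {
    expr <- utils::read.table(config$expression_tsv, header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    # expected tidy columns: gene_id, group, then one column per sample
    for (smp in setdiff(names(expr), c("gene_id", "group"))) {
      groups <- split(expr[[smp]], expr$group)
      comparisons[[paste0("expression_", smp)]] <-
        c(kruskal_wallis(groups), list(alpha = config$alpha))
    }
  } else {
    skipped <- c(skipped, "expression comparison (no expression matrix)")
  }
  bundle$comparisons <- comparisons

  # ---- manifest + writers ----
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("domainscape")),
    seed = config$seed, alpha = config$alpha,
    config_hash = rlang::hash(cfg_for_hash),
    skipped = skipped,
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2),
    tables = lapply(bundle[c("densities", "top_repeats", "gene_metrics",
                             "partitions", "codon_bias", "gc_tables",
                             "codon_freq")],
                    function(t) if (is.null(t)) 0L else nrow(t)))
  bundle$manifest <- manifest
  if (!is.null(out_dir)) {
    wt <- function(df, name) {
      if (!is.null(df) && nrow(df)) {
        utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    wt(bundle$densities, "densities")
    wt(bundle$top_repeats, "top_repeats")
    wt(bundle$gene_metrics, "gene_metrics")
    wt(bundle$partitions, "partitions")
    wt(bundle$codon_bias, "codon_bias")
    wt(bundle$gc_tables, "gc_tables")
    wt(bundle$codon_freq, "codon_freq")
    for (nm in names(bundle$metagenes)) {
      wt(bundle$metagenes[[nm]], paste0("metagene_", nm))
    }
    comp_rows <- do.call(rbind, c(lapply(names(comparisons), function(nm) {
      cm <- comparisons[[nm]]
      if (is.null(cm$pairs) || nrow(cm$pairs) == 0) {
        data.frame(metric = nm, group_a = NA, group_b = NA, z = NA,
                   p_value = cm$kw$p_value %||% cm$p_value, adj_p = NA,
                   reject = NA, kw_p = cm$kw$p_value %||% cm$p_value)
      } else {
        cbind(metric = nm, cm$pairs, kw_p = cm$kw$p_value)
      }
    }), make.row.names = FALSE))
    wt(comp_rows, "comparisons")
    # manifest as YAML (plain text, deterministic field order)
    yaml::write_yaml(manifest[c("package_version", "seed", "alpha",
                                "config_hash", "skipped", "tables")],
                     file.path(out_dir, "manifest.yaml"))
    if (length(skipped)) {
      stage_log("manifest", "skipped: %s", paste(skipped, collapse = "; "))
    }
  }
  invisible(structure(bundle, class = "report_bundle"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
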