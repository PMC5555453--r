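#' Read coding gene models from a GFF3 file
#'
#' Consumes only `CDS` features, grouped into isoforms via their `Parent`
#' attribute and into genes via the parent mRNA's own `Parent`; exon and
#' UTR features are ignored, matching an annotation set that covers only
#' the coding regions. Coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path GFF3 file path.
#' @return list of isoform models; each is a list with `gene_id`,
#'   `isoform_id`, `seq_id`, `strand`, and `cds_segments` (two-column
#'   matrix `start`,`end`, sorted genomically). Isoforms whose CDS spans
#'   multiple sequences or strands are rejected with an error.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mrna <- gr[gr$type %in% c("mRNA", "transcript")]
  tx_gene <- stats::setNames(
    vapply(mrna$Parent, function(p) if (length(p)) as.character(p[[1]]) else
      NA_character_, character(1)),
    as.character(mrna$ID))
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) return(list())
  parents <- cds$Parent
  idx <- rep(seq_along(cds), lengths(parents))
  tx <- as.character(unlist(parents))
  cds_df <- data.frame(tx = tx,
                       seq_id = as.character(GenomicRanges::seqnames(cds))[idx],
                       start = GenomicRanges::start(cds)[idx] - 1L,
                       end = GenomicRanges::end(cds)[idx],
                       strand = as.character(GenomicRanges::strand(cds))[idx],
                       stringsAsFactors = FALSE)
  lapply(split(cds_df, cds_df$tx), function(d) {
    if (length(unique(d$seq_id)) > 1 || length(unique(d$strand)) > 1) {
      stop("isoform '", d$tx[[1]],
           "' has CDS on multiple sequences or strands (trans-splicing is",
           " not supported)")
    }
    gene <- tx_gene[[d$tx[[1]]]]
    if (is.null(gene) || is.na(gene)) gene <- d$tx[[1]]
    isoform_model(gene_id = gene, isoform_id = d$tx[[1]],
                  seq_id = d$seq_id[[1]], strand = d$strand[[1]],
                  cds_segments = cbind(start = d$start, end = d$end))
  })
}

#' Construct an isoform model
#'
#' @param gene_id,isoform_id identifiers.
#' @param seq_id sequence name.
#' @param strand `"+"` or `"-"`.
#' @param cds_segments two-column matrix (`start`, `end`), 0-based
#'   half-open; stored sorted by genomic start. Segments must not overlap.
#'   A total CDS length not divisible by 3 is flagged (`frame_ok = FALSE`),
#'   not an error.
#' @return an `isoform_model` list.
#' @export
isoform_model <- function(gene_id, isoform_id, seq_id, strand, cds_segments) {
  stopifnot(nrow(cds_segments) >= 1, all(cds_segments[, 1] < cds_segments[, 2]))
  seg <- cds_segments[order(cds_segments[, 1]), , drop = FALSE]
  if (nrow(seg) > 1 && any(seg[-1, 1] < seg[-nrow(seg), 2])) {
    stop("overlapping CDS segments in isoform '", isoform_id, "'")
  }
  colnames(seg) <- c("start", "end")
  structure(list(gene_id = gene_id, isoform_id = isoform_id, seq_id = seq_id,
                 strand = strand, cds_segments = seg,
                 frame_ok = sum(seg[, 2] - seg[, 1]) %% 3 == 0),
            class = "isoform_model")
}

#' Select the most comprehensive isoform of a gene
#'
#' The most comprehensive isoform is the one with the largest total coding
#' exon size; ties are broken by the lexicographically smallest isoform id
#' so the choice is deterministic.
#'
#' @param isoforms non-empty list of isoform models for one gene.
#' @return the selected isoform model.
#' @export
select_comprehensive_isoform <- function(isoforms) {
  if (length(isoforms) == 0) stop("no isoforms supplied")
  tot <- vapply(isoforms, function(im)
    sum(im$cds_segments[, 2] - im$cds_segments[, 1]), numeric(1))
  ids <- vapply(isoforms, function(im) im$isoform_id, character(1))
  isoforms[[order(-tot, ids)[1]]]
}

#' Coding-span architecture metrics for one isoform
#'
#' The coding span runs from the leftmost CDS base to the rightmost
#' (start codon to stop codon, introns included); introns are the gaps
#' between genomically adjacent CDS segments, so
#' `coding_span_size == total_cds_size + total_intron_size` always holds.
#' The median intron size is undefined (`NA`) for single-segment genes.
#' Strand affects none of the sizes.
#'
#' @param isoform an [isoform_model()].
#' @return one-row data.frame: `gene_id`, `isoform_id`, `coding_span_size`,
#'   `total_intron_size`, `total_cds_size`, `cds_count`,
#'   `median_cds_size`, `median_intron_size`.
#' @export
coding_metrics <- function(isoform) {
  seg <- isoform$cds_segments
  lens <- seg[, 2] - seg[, 1]
  introns <- if (nrow(seg) > 1) seg[-1, 1] - seg[-nrow(seg), 2] else numeric(0)
  data.frame(gene_id = isoform$gene_id, isoform_id = isoform$isoform_id,
             coding_span_size = max(seg[, 2]) - min(seg[, 1]),
             total_intron_size = sum(introns),
             total_cds_size = sum(lens),
             cds_count = nrow(seg),
             median_cds_size = stats::median(lens),
             median_intron_size = if (length(introns)) stats::median(introns)
               else NA_real_,
             stringsAsFactors = FALSE)
}

#' Metrics table for the most comprehensive isoform of every gene
#'
#' @param models list of isoform models (e.g. from [read_gene_models()]).
#' @return data.frame with one row per gene.
#' @export
gene_metrics_table <- function(models) {
  genes <- split(models, vapply(models, function(m) m$gene_id, character(1)))
  out <- do.call(rbind, lapply(genes, function(g)
    coding_metrics(select_comprehensive_isoform(g))))
  rownames(out) <- NULL
  out
}

#' Partition a region into coding, intronic and intergenic space
#'
#' Coding space is the union of all CDS segments; intronic space is the
#' union of within-coding-span gaps minus coding space (so bases inside one
#' gene's intron but another gene's exon count as coding); intergenic space
#' is everything else. The three sets partition the region exactly.
#'
#' @param models list of isoform models (most comprehensive per gene is
#'   selected internally per gene id).
#' @param region an [analysis_region()].
#' @return list of data.frames `coding`, `intronic`, `intergenic`
#'   (`seq_id`, `start`, `end`) plus `bp` (named totals).
#' @export
partition_regions <- function(models, region) {
  genes <- split(models, vapply(models, function(m) m$gene_id, character(1)))
  picked <- lapply(genes, select_comprehensive_isoform)
  seg_df <- do.call(rbind, lapply(picked, function(m)
    data.frame(seq_id = m$seq_id, start = m$cds_segments[, 1],
               end = m$cds_segments[, 2], stringsAsFactors = FALSE)))
  span_df <- do.call(rbind, lapply(picked, function(m)
    data.frame(seq_id = m$seq_id, start = min(m$cds_segments[, 1]),
               end = max(m$cds_segments[, 2]), stringsAsFactors = FALSE)))
  out <- list(coding = NULL, intronic = NULL, intergenic = NULL)
  acc <- list(coding = list(), intronic = list(), intergenic = list())
  for (i in seq_len(nrow(region$intervals))) {
    iv <- region$intervals[i, ]
    reg_ir <- IRanges::IRanges(iv$start + 1L, iv$end)
    to_ir <- function(df) {
      if (is.null(df)) return(IRanges::IRanges())
      d <- df[df$seq_id == iv$seq_id, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    }
    cod <- IRanges::intersect(to_ir(seg_df), reg_ir)
    spans <- IRanges::intersect(to_ir(span_df), reg_ir)
    intr <- IRanges::setdiff(spans, cod)
    inter <- IRanges::setdiff(reg_ir, spans)
    to_df <- function(ir) {
      if (length(ir) == 0) return(NULL)
      data.frame(seq_id = iv$seq_id, start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir), stringsAsFactors = FALSE)
    }
    acc$coding[[i]] <- to_df(cod)
    acc$intronic[[i]] <- to_df(intr)
    acc$intergenic[[i]] <- to_df(inter)
  }
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  for (k in names(acc)) {
    d <- do.call(rbind, acc[[k]])
    out[[k]] <- if (is.null(d)) empty else d
  }
  out$bp <- vapply(out[c("coding", "intronic", "intergenic")],
                   function(d) sum(d$end - d$start), numeric(1))
  out
}

#' Ortholog difference record between two genes
#'
#' Per-metric difference `a - b` (species A ortholog minus species B
#' ortholog), so positive coding-span differences mean the A gene is
#' larger. Antisymmetric under swapping the pair. The median-intron
#' difference is `NA` when either side is undefined.
#'
#' @param a,b one-row metric frames from [coding_metrics()].
#' @param pair_id optional label for the pair.
#' @return one-row data.frame of differences.
#' @export
ortholog_difference <- function(a, b, pair_id = NULL) {
  cols <- c("coding_span_size", "total_intron_size", "total_cds_size",
            "cds_count", "median_cds_size", "median_intron_size")
  d <- as.data.frame(as.list(unlist(a[1, cols]) - unlist(b[1, cols])))
  names(d) <- paste0("d_", cols)
  cbind(data.frame(pair_id = if (is.null(pair_id))
    paste(a$gene_id, b$gene_id, sep = "|") else pair_id,
    gene_a = a$gene_id, gene_b = b$gene_id,
    stringsAsFactors = FALSE), d)
}

#' Extract the coding sequence of an isoform from a genome
#'
#' Concatenates the CDS segments in transcript orientation
#' (reverse-complemented for minus-strand genes).
#'
#' @param isoform an [isoform_model()].
#' @param genome a [Biostrings::DNAStringSet] keyed by sequence name.
#' @return a [Biostrings::DNAString] of the coding sequence.
#' @export
extract_cds_sequence <- function(isoform, genome) {
  chrom <- genome[[isoform$seq_id]]
  seg <- isoform$cds_segments
  parts <- lapply(seq_len(nrow(seg)), function(i)
    Biostrings::subseq(chrom, seg[i, 1] + 1L, seg[i, 2]))
  cds <- do.call(Biostrings::xscat, parts)
  if (isoform$strand == "-") cds <- Biostrings::reverseComplement(cds)
  cds
}
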