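# Canonical repeat classes used throughout the density accounting.
REPEAT_CLASSES <- c("LINE", "LTR", "DNA", "RC_Helitron", "Satellite",
                    "Simple_LowComplexity", "Other", "Overlapping")

#' Map a raw repeat class/family string to a canonical class
#'
#' RepeatMasker annotation files print classes such as `"LINE/CR1"` or
#' `"LTR/Gypsy"`; density accounting groups these into a small set of
#' canonical classes (LINE and LTR retrotransposons, DNA transposons,
#' rolling-circle Helitrons, satellites, simple/low-complexity repeats).
#' The mapping is prefix-based and total: any unrecognized string maps to
#' `"Other"`. `"Overlapping"` is never produced here; it only arises from
#' [merge_by_class()] where fragments of different classes overlap.
#'
#' @param raw_class character vector of class strings as printed in the
#'   source annotation (e.g. `"RC/Helitron"`).
#' @return character vector of canonical class names.
#' @examples
#' normalize_repeat_class(c("LINE/CR1", "LTR/Gypsy", "RC/Helitron", "ARTEFACT"))
#' @export
normalize_repeat_class <- function(raw_class) {
  out <- rep("Other", length(raw_class))
  rc <- as.character(raw_class)
  out[startsWith(rc, "LINE")] <- "LINE"
  out[startsWith(rc, "LTR")] <- "LTR"
  out[startsWith(rc, "DNA")] <- "DNA"
  out[startsWith(rc, "RC") | startsWith(rc, "Helitron")] <- "RC_Helitron"
  out[startsWith(rc, "Satellite")] <- "Satellite"
  out[rc %in% c("Simple_repeat", "Low_complexity") |
        startsWith(rc, "Simple_repeat") | startsWith(rc, "Low_complexity")] <-
    "Simple_LowComplexity"
  out
}

#' Parse a RepeatMasker `.out` annotation file
#'
#' Reads the standard `.out` dialect: three header lines followed by
#' whitespace-delimited rows with Smith-Waterman score, divergence
#' percentages, query sequence, 1-based inclusive begin/end, strand
#' (`+` or `C`), repeat name and repeat class/family. Coordinates are
#' converted to the package-internal 0-based half-open convention.
#'
#' @param path path to a `.out` file.
#' @param keep_overridden keep rows flagged with a trailing `*` (matches
#'   overridden by a higher-scoring hit). Default `TRUE`, which reproduces
#'   cumulative-fragment-size accounting.
#' @return data.frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `repeat_name`, `raw_class`, `canonical_class`, `score`, `overridden`.
#' @export
parse_repeatmasker_out <- function(path, keep_overridden = TRUE) {
  lines <- readLines(path)
  body <- if (length(lines) > 3) lines[-(1:3)] else character(0)
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(empty_repeat_features())
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    if (length(f) < 11) {
      stop(sprintf("malformed RepeatMasker row at line %d of %s", i + 3, path))
    }
    score <- suppressWarnings(as.numeric(f[[1]]))
    beg <- suppressWarnings(as.integer(f[[6]]))
    end <- suppressWarnings(as.integer(f[[7]]))
    if (is.na(score) || is.na(beg) || is.na(end) || beg > end) {
      stop(sprintf("malformed RepeatMasker row at line %d of %s", i + 3, path))
    }
    strand <- if (f[[9]] == "C") "-" else if (f[[9]] == "+") "+" else "*"
    overridden <- f[[length(f)]] == "*"
    data.frame(seq_id = f[[5]], start = beg - 1L, end = end,
               strand = strand, repeat_name = f[[10]], raw_class = f[[11]],
               score = score, overridden = overridden,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$canonical_class <- normalize_repeat_class(out$raw_class)
  if (!keep_overridden) out <- out[!out$overridden, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("seq_id", "start", "end", "strand", "repeat_name", "raw_class",
          "canonical_class", "score", "overridden")]
}

empty_repeat_features <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), repeat_name = character(0),
             raw_class = character(0), canonical_class = character(0),
             score = numeric(0), overridden = logical(0),
             stringsAsFactors = FALSE)
}

#' Write repeat features in the RepeatMasker `.out` dialect
#'
#' Inverse of [parse_repeatmasker_out()]; used by the synthetic-genome
#' generator so emitted annotations round-trip through the parser.
#'
#' @param features data.frame as returned by [parse_repeatmasker_out()]
#'   (0-based half-open coordinates).
#' @param path output file path.
#' @export
write_repeatmasker_out <- function(features, path) {
  hdr <- c(
    paste("  SW  perc perc perc  query     position in query    matching",
          "repeat          position in repeat"),
    paste("score  div. del. ins.  sequence  begin end   (left)   repeat",
          "class/family      begin end (left)  ID"),
    "")
  rows <- character(0)
  if (nrow(features) > 0) {
    strand <- ifelse(features$strand == "-", "C", "+")
    overridden <- if (!is.null(features$overridden)) features$overridden else
      rep(FALSE, nrow(features))
    rows <- sprintf("%6.1f %4.1f %4.1f %4.1f %s %d %d (0) %s %s %s 1 %d (0) %d%s",
                    features$score, 1.0, 0.0, 0.0, features$seq_id,
                    features$start + 1L, features$end, strand,
                    features$repeat_name, features$raw_class,
                    features$end - features$start, seq_len(nrow(features)),
                    ifelse(overridden, " *", ""))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Merge repeat fragments with class-conflict reclassification
#'
#' Overlapping fragments of the same canonical class are merged into a
#' single segment; bases covered by fragments of two or more different
#' classes become `"Overlapping"` segments. Only the bases actually shared
#' between classes are reclassified; the non-overlapping flanks of a
#' partially overlapping fragment keep the fragment's own class, so
#' class-specific base counts are conserved outside the shared bases.
#' Fragments on different sequences are never merged together.
#'
#' @param features repeat-feature data.frame (`seq_id`, `start`, `end`,
#'   `canonical_class`, `repeat_name`). Simple/low-complexity rows should be
#'   excluded by the caller when emulating `-nolow` transposon accounting.
#' @return data.frame of non-overlapping sorted segments per `seq_id` with
#'   columns `seq_id`, `start`, `end`, `canonical_class`,
#'   `contributing_names` (comma-joined, sorted).
#' @export
merge_by_class <- function(features) {
  if (nrow(features) == 0) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), canonical_class = character(0),
                      contributing_names = character(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(features$start < features$end))
  pieces <- lapply(split(features, features$seq_id), function(fs) {
    ir <- IRanges::IRanges(fs$start + 1L, fs$end)
    d <- IRanges::disjoin(ir)
    hits <- IRanges::findOverlaps(d, ir)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    cls <- vapply(split(fs$canonical_class[sh], qh), function(cc) {
      u <- unique(cc)
      if (length(u) > 1L) "Overlapping" else u
    }, character(1))
    nms <- vapply(split(fs$repeat_name[sh], qh),
                  function(nn) paste(sort(unique(nn)), collapse = ","),
                  character(1))
    idx <- as.integer(names(cls))
    seg <- data.frame(start = IRanges::start(d)[idx] - 1L,
                      end = IRanges::end(d)[idx],
                      canonical_class = unname(cls),
                      contributing_names = unname(nms),
                      stringsAsFactors = FALSE)
    seg <- seg[order(seg$start), , drop = FALSE]
    # fuse abutting segments of identical class
    keep <- integer(0)
    for (i in seq_len(nrow(seg))) {
      if (length(keep) > 0) {
        j <- keep[length(keep)]
        if (seg$start[i] == seg$end[j] &&
            seg$canonical_class[i] == seg$canonical_class[j]) {
          seg$end[j] <- seg$end[i]
          nn <- unique(c(strsplit(seg$contributing_names[j], ",")[[1]],
                         strsplit(seg$contributing_names[i], ",")[[1]]))
          seg$contributing_names[j] <- paste(sort(nn), collapse = ",")
          next
        }
      }
      keep <- c(keep, i)
    }
    seg <- seg[keep, , drop = FALSE]
    seg$seq_id <- fs$seq_id[[1]]
    seg
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("seq_id", "start", "end", "canonical_class", "contributing_names")]
}

#' Define a named analysis region
#'
#' @param name region label (e.g. `"F_element"`).
#' @param intervals data.frame with `seq_id`, `start`, `end`
#'   (0-based half-open); intervals must not overlap within the region.
#' @return an `analysis_region` list with `name`, `intervals`, `total_bp`.
#' @export
analysis_region <- function(name, intervals) {
  stopifnot(is.character(name), length(name) == 1,
            all(c("seq_id", "start", "end") %in% names(intervals)),
            all(intervals$start < intervals$end))
  for (iv in split(intervals, intervals$seq_id)) {
    ir <- IRanges::IRanges(iv$start + 1L, iv$end)
    if (sum(IRanges::width(IRanges::reduce(ir))) != sum(IRanges::width(ir)))
      stop("intervals overlap within region '", name, "'")
  }
  total <- sum(intervals$end - intervals$start)
  if (total <= 0) stop("region '", name, "' has zero total length")
  structure(list(name = name, intervals = intervals, total_bp = total),
            class = "analysis_region")
}

#' Read analysis regions from a BED file
#'
#' One `analysis_region` per distinct BED name field (column 4); unnamed
#' records are grouped under `"region"`.
#' @param path BED file path.
#' @return named list of `analysis_region` objects.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    rep("region", length(gr))
  nm[is.na(nm)] <- "region"
  df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), name = nm,
                   stringsAsFactors = FALSE)
  lapply(split(df, df$name), function(d)
    analysis_region(d$name[[1]], d[, c("seq_id", "start", "end")]))
}

# Clip a (seq_id,start,end) frame to a region; drops empty intersections.
clip_to_region <- function(df, region) {
  pieces <- lapply(seq_len(nrow(region$intervals)), function(i) {
    iv <- region$intervals[i, ]
    sub <- df[df$seq_id == iv$seq_id & df$end > iv$start & df$start < iv$end, ,
              drop = FALSE]
    if (nrow(sub) == 0) return(sub)
    sub$start <- pmax(sub$start, iv$start)
    sub$end <- pmin(sub$end, iv$end)
    sub
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- df[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class repeat density of a region
#'
#' Densities are fractions of region length covered by merged segments of
#' each canonical class (segments are clipped to the region first), so the
#' per-class values sum to the total density and the total cannot exceed 1.
#'
#' @param segments merged segments from [merge_by_class()].
#' @param region an [analysis_region()].
#' @return list with `region`, `densities` (named numeric per class
#'   present), and `total`.
#' @export
class_density <- function(segments, region) {
  if (region$total_bp <= 0) stop("region has zero length")
  clipped <- clip_to_region(segments, region)
  if (nrow(clipped) == 0) {
    return(list(region = region$name,
                densities = stats::setNames(numeric(0), character(0)),
                total = 0))
  }
  bp <- tapply(clipped$end - clipped$start, clipped$canonical_class, sum)
  dens <- as.numeric(bp) / region$total_bp
  names(dens) <- names(bp)
  list(region = region$name, densities = dens, total = sum(dens))
}

#' Rank the most common repeats in a region by cumulative fragment size
#'
#' Fragment counts are counts of annotation rows (unmerged), and the
#' "% of all repeat bp" denominator is the unmerged cumulative fragment
#' size over all repeats in the region — both matching how top-repeat
#' tables are conventionally tabulated from RepeatMasker output. Ties in
#' cumulative size are broken lexicographically by repeat name.
#'
#' @param features unmerged repeat features.
#' @param region an [analysis_region()].
#' @param n number of rows to return (>= 1).
#' @return data.frame ranked by `total_size` descending with columns
#'   `repeat_name`, `total_size`, `fragment_count`, `canonical_class`,
#'   `pct_region`, `pct_repeat`.
#' @export
top_repeat_table <- function(features, region, n = 10) {
  stopifnot(n >= 1)
  clipped <- clip_to_region(features, region)
  if (nrow(clipped) == 0) {
    return(data.frame(repeat_name = character(0), total_size = integer(0),
                      fragment_count = integer(0),
                      canonical_class = character(0),
                      pct_region = numeric(0), pct_repeat = numeric(0)))
  }
  clipped$len <- clipped$end - clipped$start
  agg <- aggregate(cbind(total_size = len) ~ repeat_name, clipped, sum)
  cnt <- aggregate(cbind(fragment_count = len) ~ repeat_name, clipped, length)
  cls <- clipped[!duplicated(clipped$repeat_name),
                 c("repeat_name", "canonical_class")]
  tab <- merge(merge(agg, cnt, by = "repeat_name"), cls, by = "repeat_name")
  total_repeat_bp <- sum(clipped$len)
  tab$pct_region <- 100 * tab$total_size / region$total_bp
  tab$pct_repeat <- 100 * tab$total_size / total_repeat_bp
  tab <- tab[order(-tab$total_size, tab$repeat_name), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, n)
}

#' Filter repeat features by alignment score
#'
#' Keeps features with `score >= min_score`; the count and cumulative size
#' of removed features are attached as attributes and reported via message,
#' mirroring the cutoff-score filtering used to remove spurious
#' foreign-genome matches.
#'
#' @param features repeat features with a `score` column.
#' @param min_score finite numeric cutoff.
#' @param quiet suppress the log message.
#' @return filtered data.frame with attributes `n_removed`, `bp_removed`.
#' @export
score_filter <- function(features, min_score, quiet = FALSE) {
  stopifnot(is.finite(min_score) || is.infinite(min_score))
  keep <- features$score >= min_score
  removed <- features[!keep, , drop = FALSE]
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(removed)
  attr(out, "bp_removed") <- sum(removed$end - removed$start)
  if (!quiet && nrow(removed) > 0) {
    message(sprintf("score_filter: removed %d features (%d bp) below %.1f",
                    nrow(removed), attr(out, "bp_removed"), min_score))
  }
  out
}

#' Attribute foreign-genome matches to annotated repeats
#'
#' Computes the fraction of query-match bases (union over matches) that
#' overlap any annotated repeat, and a per-repeat-name breakdown of the
#' overlapped bases — the forensic used to show that apparent endosymbiont
#' matches in a host assembly are mostly transposon remnants.
#'
#' @param query_matches features for the foreign matches.
#' @param annotations features for the repeat annotation.
#' @return list with `status` (`"ok"` or `"no matches"`), `fraction`
#'   (overall bp fraction, `NA` when no matches), `query_bp`, and
#'   `per_name` data.frame (`repeat_name`, `overlap_bp`, `share` of query
#'   bp) ranked by overlapped bp.
#' @export
overlap_attribution <- function(query_matches, annotations) {
  if (nrow(query_matches) == 0) {
    return(list(status = "no matches", fraction = NA_real_, query_bp = 0L,
                per_name = data.frame(repeat_name = character(0),
                                      overlap_bp = integer(0),
                                      share = numeric(0))))
  }
  seqs <- unique(query_matches$seq_id)
  q_bp <- 0L
  ov_bp <- 0L
  name_bp <- list()
  for (s in seqs) {
    q <- query_matches[query_matches$seq_id == s, , drop = FALSE]
    a <- annotations[annotations$seq_id == s, , drop = FALSE]
    qu <- IRanges::reduce(IRanges::IRanges(q$start + 1L, q$end))
    q_bp <- q_bp + sum(IRanges::width(qu))
    if (nrow(a) == 0) next
    au <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
    ov_bp <- ov_bp + sum(IRanges::width(IRanges::intersect(qu, au)))
    for (nm in unique(a$repeat_name)) {
      an <- a[a$repeat_name == nm, , drop = FALSE]
      anu <- IRanges::reduce(IRanges::IRanges(an$start + 1L, an$end))
      bp <- sum(IRanges::width(IRanges::intersect(qu, anu)))
      name_bp[[nm]] <- (if (is.null(name_bp[[nm]])) 0L else name_bp[[nm]]) + bp
    }
  }
  per_name <- data.frame(repeat_name = names(name_bp),
                         overlap_bp = as.integer(unlist(name_bp)),
                         stringsAsFactors = FALSE)
  if (nrow(per_name) > 0) {
    per_name$share <- per_name$overlap_bp / q_bp
    per_name <- per_name[order(-per_name$overlap_bp, per_name$repeat_name), ,
                         drop = FALSE]
    rownames(per_name) <- NULL
  } else {
    per_name$share <- numeric(0)
  }
  list(status = "ok", fraction = ov_bp / q_bp, query_bp = q_bp,
       per_name = per_name)
}

#' Build per-base alignment coverage tracks
#'
#' Counts, for every base of each target sequence, the number of match
#' intervals containing it (e.g. host-assembly alignments collated against
#' a foreign assembly).
#'
#' @param matches data.frame with `seq_id`, `start`, `end` (0-based
#'   half-open) on the target coordinates.
#' @param target_lengths named integer vector of target sequence lengths.
#' @return named list per `seq_id`: list with `runs` (data.frame `start`,
#'   `end`, `count`) and `max_coverage`.
#' @export
coverage_track <- function(matches, target_lengths) {
  stopifnot(!is.null(names(target_lengths)))
  bad <- !(matches$seq_id %in% names(target_lengths)) |
    matches$end > target_lengths[matches$seq_id] | matches$start < 0
  if (any(bad)) {
    i <- which(bad)[[1]]
    stop(sprintf("match %d (%s:%d-%d) exceeds declared target length",
                 i, matches$seq_id[i], matches$start[i], matches$end[i]))
  }
  out <- lapply(names(target_lengths), function(s) {
    len <- target_lengths[[s]]
    m <- matches[matches$seq_id == s, , drop = FALSE]
    if (nrow(m) == 0) {
      return(list(runs = data.frame(start = 0L, end = len, count = 0L),
                  max_coverage = 0L))
    }
    cov <- IRanges::coverage(IRanges::IRanges(m$start + 1L, m$end),
                             width = len)
    ends <- cumsum(S4Vectors::runLength(cov))
    runs <- data.frame(start = c(0L, ends[-length(ends)]), end = ends,
                       count = as.integer(S4Vectors::runValue(cov)))
    list(runs = runs, max_coverage = max(runs$count))
  })
  names(out) <- names(target_lengths)
  out
}

#' Write a coverage (or generic step) track as bedGraph
#'
#' @param track output of [coverage_track()] or a data.frame with
#'   `seq_id`, `start`, `end`, `value`.
#' @param path output file path.
#' @param drop_zero omit zero-valued runs (default TRUE).
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  if (is.data.frame(track)) {
    df <- track
    names(df)[names(df) == "count"] <- "value"
  } else {
    df <- do.call(rbind, lapply(names(track), function(s) {
      r <- track[[s]]$runs
      data.frame(seq_id = s, start = r$start, end = r$end, value = r$count)
    }))
  }
  if (drop_zero) df <- df[df$value != 0, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%s", df$seq_id, as.integer(df$start),
                       as.integer(df$end), format(df$value, trim = TRUE,
                                                  scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph file as a step-value data.frame
#'
#' @param path bedGraph file path.
#' @return data.frame `seq_id`, `start`, `end`, `value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = as.numeric(gr$score), stringsAsFactors = FALSE)
}
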