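# Nearest-neighbor thermodynamic parameters (Breslauer et al. 1986):
# enthalpy in kcal/mol, entropy in cal/(mol K), both as positive magnitudes
# of the (negative) formation values, for the duplex stack whose top strand
# reads 5'->3'. Initiation entropy: -16.8 eu when the duplex contains at
# least one G/C pair, -20.1 eu when it is all A/T.
NN_TABLES <- list(
  breslauer1986 = list(
    dH = c(AA = 9.1, AT = 8.6, TA = 6.0, CA = 5.8, GT = 6.5, CT = 7.8,
           GA = 5.6, CG = 11.9, GC = 11.1, GG = 11.0,
           TT = 9.1, TG = 5.8, AC = 6.5, AG = 7.8, TC = 5.6, CC = 11.0),
    dS = c(AA = 24.0, AT = 23.9, TA = 16.9, CA = 12.9, GT = 17.3, CT = 20.8,
           GA = 13.5, CG = 27.8, GC = 26.7, GG = 26.6,
           TT = 24.0, TG = 12.9, AC = 17.3, AG = 20.8, TC = 13.5, CC = 26.6),
    init_S_gc = -16.8, init_S_at = -20.1))

#' Melting-temperature calculation parameters
#'
#' @param window sliding-window size in bp (default 9, the length of the
#'   RNA-DNA hybrid in the transcription elongation complex).
#' @param step step size in bp (default 1).
#' @param dna_conc total strand concentration in nM (default 50).
#' @param salt_conc monovalent salt concentration in mM (default 50).
#' @param table nearest-neighbor table id (currently `"breslauer1986"`).
#' @return a `tm_params` list.
#' @export
tm_params <- function(window = 9, step = 1, dna_conc = 50, salt_conc = 50,
                      table = "breslauer1986") {
  stopifnot(window >= 2, step >= 1, dna_conc > 0, salt_conc > 0,
            table %in% names(NN_TABLES))
  structure(list(window = as.integer(window), step = as.integer(step),
                 dna_conc = dna_conc, salt_conc = salt_conc, table = table),
            class = "tm_params")
}

#' Sliding-window DNA melting temperature
#'
#' Nearest-neighbor thermodynamics:
#' `Tm(degC) = 1000*dH / (dS + R*ln(Ct/4)) - 273.15 + 16.6*log10([Na+])`,
#' with `dH` (kcal/mol) and `dS` (cal/mol/K) summed over the window's
#' stacked base pairs plus the duplex-initiation entropy term, `Ct` the
#' total strand concentration (mol/L) and `[Na+]` in mol/L. One value per
#' window start position (step-spaced); windows containing `N` yield `NA`.
#'
#' @param seq nucleotide string (or DNAString).
#' @param params a [tm_params()] object.
#' @return numeric vector of Tm in degrees Celsius, empty when the
#'   sequence is shorter than the window.
#' @export
window_tm <- function(seq, params = tm_params()) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  w <- params$window
  if (n < w) return(numeric(0))
  tab <- NN_TABLES[[params$table]]
  bases <- strsplit(s, "")[[1]]
  pairs <- paste0(bases[-n], bases[-1])
  dh <- unname(tab$dH[pairs])       # NA for pairs containing N
  ds <- unname(tab$dS[pairs])
  is_gc <- bases %in% c("G", "C")
  valid <- bases %in% c("A", "C", "G", "T")
  cum <- function(x) c(0, cumsum(ifelse(is.na(x), 0, x)))
  cum_dh <- cum(dh); cum_ds <- cum(ds)
  cum_na <- c(0, cumsum(!valid))
  cum_gc <- c(0, cumsum(is_gc))
  starts <- seq(1L, n - w + 1L, by = params$step)
  # window [i, i+w-1] uses stacks i..i+w-2
  sum_dh <- cum_dh[starts + w - 1] - cum_dh[starts]
  sum_ds <- cum_ds[starts + w - 1] - cum_ds[starts]
  n_bad <- cum_na[starts + w] - cum_na[starts]
  n_gc <- cum_gc[starts + w] - cum_gc[starts]
  init_s <- ifelse(n_gc > 0, tab$init_S_gc, tab$init_S_at)
  R <- 1.987
  ct <- params$dna_conc * 1e-9
  na_molar <- params$salt_conc * 1e-3
  # formation enthalpies/entropies are negative; the table stores magnitudes
  tm <- 1000 * (-sum_dh) / ((-sum_ds + init_s) + R * log(ct / 4)) - 273.15 +
    16.6 * log10(na_molar)
  tm[n_bad > 0] <- NA_real_
  tm
}

#' Poisson log-likelihood enrichment ratio of two signal tracks
#'
#' Per base, with `x = treatment + p` and `y = control + p`:
#' `LLR = sign(x - y) * (x*ln(x/y) - x + y) / ln(10)`, the signed log10
#' likelihood ratio between Poisson models with means `x` vs `y` evaluated
#' at the observed treatment level — the comparison a peak caller's
#' logLR track computes between a ChIP sample and its input control.
#' Positive values mean enrichment, negative depletion, 0 where the
#' tracks agree. Bases absent from a track count as 0 signal.
#'
#' @param treatment,control step tracks (data.frame `seq_id`, `start`,
#'   `end`, `value`), values must be non-negative.
#' @param pseudocount symmetric pseudocount (default 1e-5).
#' @return step track data.frame of LLR values.
#' @export
loglik_enrichment <- function(treatment, control, pseudocount = 1e-5) {
  if (any(treatment$value < 0) || any(control$value < 0)) {
    stop("signal tracks must be non-negative")
  }
  seqs <- union(unique(treatment$seq_id), unique(control$seq_id))
  pieces <- lapply(seqs, function(s) {
    t <- treatment[treatment$seq_id == s, , drop = FALSE]
    c_ <- control[control$seq_id == s, , drop = FALSE]
    bounds <- sort(unique(c(t$start, t$end, c_$start, c_$end)))
    if (length(bounds) < 2) return(NULL)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    lookup <- function(df) {
      v <- numeric(length(starts))
      if (nrow(df) == 0) return(v)
      o <- order(df$start)
      idx <- findInterval(starts, df$start[o])
      hit <- idx > 0 & starts < df$end[o][pmax(idx, 1)]
      v[hit] <- df$value[o][idx[hit]]
      v
    }
    x <- lookup(t) + pseudocount
    y <- lookup(c_) + pseudocount
    llr <- ifelse(x == y, 0,
                  sign(x - y) * (x * log(x / y) - x + y) / log(10))
    data.frame(seq_id = s, start = starts, end = ends, value = llr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Rescale a per-position profile to a target length
#'
#' Linear interpolation onto `target_length` evenly spaced points spanning
#' the original index range; endpoints are preserved exactly. Missing
#' values propagate: an output point whose flanking source values include
#' `NA` is `NA`, never interpolated across.
#'
#' @param values numeric vector (length >= 2).
#' @param target_length output length (>= 2).
#' @return numeric vector of length `target_length`.
#' @export
rescale_profile <- function(values, target_length) {
  n <- length(values)
  stopifnot(n >= 2, target_length >= 2)
  xout <- seq(1, n, length.out = target_length)
  i0 <- pmax(1L, floor(xout))
  i1 <- pmin(n, ceiling(xout))
  frac <- xout - i0
  v0 <- values[i0]
  v1 <- values[i1]
  out <- (1 - frac) * v0 + frac * v1
  out[i0 == i1] <- values[i0[i0 == i1]]
  out[is.na(v0) | is.na(v1)] <- NA_real_
  out
}

#' Aggregate per-gene profiles into a metagene
#'
#' Each gene contributes an upstream flank, a coding-span profile rescaled
#' to a common length, and a downstream flank (all in transcript
#' orientation, upstream = 5'). The metagene value at each position is the
#' median over contributing genes, ignoring missing values; the number of
#' genes contributing is recorded per position. The axis runs from
#' `-flank` through the standardized span (`span_length + 1` points) to
#' `+flank`.
#'
#' @param per_gene_profiles list; each element a list with `upstream`,
#'   `span`, `downstream` numeric vectors (flanks of length `flank`; spans
#'   of any length >= 2).
#' @param span_length standardized span length S (default 3000).
#' @param flank flank length F (default 2000).
#' @return data.frame `position` (-F .. S+F), `median`, `n`.
#' @export
build_metagene <- function(per_gene_profiles, span_length = 3000,
                           flank = 2000) {
  if (length(per_gene_profiles) == 0) stop("no gene profiles supplied")
  axis_len <- span_length + 1 + 2 * flank
  mat <- vapply(per_gene_profiles, function(p) {
    up <- p$upstream
    dn <- p$downstream
    stopifnot(length(up) == flank, length(dn) == flank)
    sp <- if (length(p$span) == span_length + 1) p$span else
      rescale_profile(p$span, span_length + 1)
    c(up, sp, dn)
  }, numeric(axis_len))
  med <- apply(mat, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else stats::median(v)
  })
  n_contrib <- apply(mat, 1, function(v) sum(!is.na(v)))
  data.frame(position = seq(-flank, span_length + flank), median = med,
             n = n_contrib)
}

#' Cubic smoothing spline fit with ordinary cross-validation
#'
#' Fits `stats::smooth.spline(cv = TRUE)` (leave-one-out ordinary
#' cross-validation for the smoothing parameter) to the defined positions
#' of a profile and returns fitted values at those positions; fewer than
#' 10 defined points passes the profile through unchanged with a warning.
#'
#' @param values per-position values (may contain `NA`).
#' @param positions optional x axis (default index).
#' @return numeric vector like `values` with smoothed values where
#'   defined.
#' @export
smooth_spline_fit <- function(values, positions = seq_along(values)) {
  ok <- !is.na(values)
  if (sum(ok) < 10) {
    warning("fewer than 10 defined positions; returning profile unsmoothed")
    return(values)
  }
  fit <- stats::smooth.spline(positions[ok], values[ok], cv = TRUE,
                              keep.data = FALSE)
  out <- values
  out[ok] <- stats::predict(fit, positions[ok])$y
  out
}

#' Extract a strand-aware per-base signal profile around a coding span
#'
#' Pulls per-base values from a step track across a gene's coding span and
#' its flanks; for minus-strand genes the three vectors are reversed and
#' swapped so that `upstream` is always 5'. Flank bases beyond the contig
#' bounds are filled with `NA` and flagged.
#'
#' @param track step track data.frame (`seq_id`, `start`, `end`, `value`);
#'   absent bases read as 0.
#' @param isoform an [isoform_model()].
#' @param flank flank size in bp (default 2000).
#' @param seq_length contig length; defaults to the track's last end.
#' @return list `upstream`, `span`, `downstream` numeric vectors with
#'   attribute `truncated` (logical).
#' @export
signal_profile <- function(track, isoform, flank = 2000, seq_length = NULL) {
  tr <- track[track$seq_id == isoform$seq_id, , drop = FALSE]
  if (is.null(seq_length)) {
    seq_length <- if (nrow(tr) > 0) max(tr$end) else
      max(isoform$cds_segments[, 2]) + flank
  }
  span_start <- min(isoform$cds_segments[, 1])
  span_end <- max(isoform$cds_segments[, 2])
  per_base <- function(from, to) {  # 0-based half-open, may exceed bounds
    pos <- seq(from, to - 1)
    v <- numeric(length(pos))
    if (nrow(tr) > 0) {
      o <- order(tr$start)
      idx <- findInterval(pos, tr$start[o])
      hit <- idx > 0 & pos < tr$end[o][pmax(idx, 1)]
      v[hit] <- tr$value[o][idx[hit]]
    }
    v[pos < 0 | pos >= seq_length] <- NA_real_
    v
  }
  left <- per_base(span_start - flank, span_start)
  span <- per_base(span_start, span_end)
  right <- per_base(span_end, span_end + flank)
  truncated <- anyNA(left) || anyNA(right)
  if (isoform$strand == "-") {
    out <- list(upstream = rev(right), span = rev(span),
                downstream = rev(left))
  } else {
    out <- list(upstream = left, span = span, downstream = right)
  }
  attr(out, "truncated") <- truncated
  out
}

#' Melting-temperature metagene over a set of genes
#'
#' Computes the sliding-window Tm track of each gene's coding span plus
#' flanks directly from the genome sequence, rescales spans to the
#' standard length and aggregates by position-wise median.
#'
#' @param models list of isoform models (most comprehensive per gene).
#' @param genome [Biostrings::DNAStringSet].
#' @param params [tm_params()].
#' @param span_length,flank metagene geometry.
#' @param smooth also fit the smoothing spline (default TRUE).
#' @return metagene data.frame (`position`, `median`, `n`, and `smoothed`
#'   when requested).
#' @export
tm_metagene <- function(models, genome, params = tm_params(),
                        span_length = 3000, flank = 2000, smooth = TRUE) {
  profs <- lapply(models, function(m) {
    chrom <- genome[[m$seq_id]]
    span_start <- min(m$cds_segments[, 1])
    span_end <- max(m$cds_segments[, 2])
    from <- span_start - flank
    to <- span_end + flank
    lo <- max(from, 0)
    hi <- min(to, length(chrom))
    tm <- window_tm(Biostrings::subseq(chrom, lo + 1, hi), params)
    # pad to per-base length (one value per window start; tail windows
    # incomplete -> NA), then add out-of-bounds NA padding
    vals <- c(tm, rep(NA_real_, (hi - lo) - length(tm)))
    vals <- c(rep(NA_real_, lo - from), vals, rep(NA_real_, to - hi))
    up <- vals[seq_len(flank)]
    sp <- vals[seq(flank + 1, flank + (span_end - span_start))]
    dn <- vals[seq(flank + (span_end - span_start) + 1, length(vals))]
    if (m$strand == "-") {
      list(upstream = rev(dn), span = rev(sp), downstream = rev(up))
    } else {
      list(upstream = up, span = sp, downstream = dn)
    }
  })
  mg <- build_metagene(profs, span_length, flank)
  if (smooth) mg$smoothed <- smooth_spline_fit(mg$median, mg$position)
  mg
}

#' Signal metagene over a set of genes
#'
#' @param track step track (e.g. an LLR track from [loglik_enrichment()]).
#' @param models list of isoform models.
#' @param span_length,flank metagene geometry.
#' @param seq_lengths optional named contig lengths.
#' @param smooth also fit the smoothing spline (default TRUE).
#' @return metagene data.frame.
#' @export
signal_metagene <- function(track, models, span_length = 3000, flank = 2000,
                            seq_lengths = NULL, smooth = TRUE) {
  profs <- lapply(models, function(m)
    signal_profile(track, m, flank,
                   seq_length = if (is.null(seq_lengths)) NULL else
                     seq_lengths[[m$seq_id]]))
  mg <- build_metagene(profs, span_length, flank)
  if (smooth) mg$smoothed <- smooth_spline_fit(mg$median, mg$position)
  mg
}
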