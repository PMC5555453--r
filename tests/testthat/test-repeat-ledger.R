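test_that("parse_repeatmasker_out converts coordinates and classes", {
  path <- withr::local_tempfile(fileext = ".out")
  write_mini_out(path, c(
    " 1234 10.1 0.5 0.2 chr2L 101 200 (500) + DNAREP1_DM RC/Helitron 1 100 (0) 1",
    "  800  5.0 0.1 0.1 chr2L 300 450 (250) C Gypsy-1_DSim-I LTR/Gypsy 1 151 (0) 2",
    "   90  5.0 0.1 0.1 chr2L 500 520 (180) + CR1-2_DAn LINE/CR1 1 21 (0) 3 *"))
  f <- parse_repeatmasker_out(path)
  expect_equal(nrow(f), 3)
  expect_equal(f$start[1], 100L)       # 1-based inclusive -> 0-based half-open
  expect_equal(f$end[1], 200L)
  expect_equal(f$end[1] - f$start[1], 100L)
  expect_equal(f$canonical_class, c("RC_Helitron", "LTR", "LINE"))
  expect_equal(f$strand, c("+", "-", "+"))
  expect_equal(f$score[2], 800)
  expect_true(f$overridden[3])
  expect_equal(nrow(parse_repeatmasker_out(path, keep_overridden = FALSE)), 2)
})

test_that("parser handles empty files and reports malformed rows by line", {
  path <- withr::local_tempfile(fileext = ".out")
  write_mini_out(path, character(0))
  expect_equal(nrow(parse_repeatmasker_out(path)), 0)
  write_mini_out(path, "only five fields here x")
  expect_error(parse_repeatmasker_out(path), "line 4")
})

test_that("repeat class normalization is prefix-based and total", {
  expect_equal(normalize_repeat_class(c("LINE/CR1", "LTR/Gypsy", "LTR/Pao",
                                        "DNA/TcMar-Tc1", "RC/Helitron",
                                        "Helitron", "Satellite/W-chromosome",
                                        "Simple_repeat", "Low_complexity",
                                        "ARTEFACT", "Unknown")),
               c("LINE", "LTR", "LTR", "DNA", "RC_Helitron", "RC_Helitron",
                 "Satellite", "Simple_LowComplexity", "Simple_LowComplexity",
                 "Other", "Other"))
})

test_that("merge_by_class reclassifies only the shared bases", {
  # same-class overlap merges into one segment
  s <- merge_by_class(make_feats(c(0, 80), c(100, 150), c("LINE", "LINE")))
  expect_equal(nrow(s), 1)
  expect_equal(c(s$start, s$end), c(0L, 150L))
  expect_equal(s$canonical_class, "LINE")
  # different-class overlap: flanks keep their class, overlap reclassified
  s <- merge_by_class(make_feats(c(0, 80), c(100, 150), c("LINE", "LTR")))
  expect_equal(s$start, c(0L, 80L, 100L))
  expect_equal(s$end, c(80L, 100L, 150L))
  expect_equal(s$canonical_class, c("LINE", "Overlapping", "LTR"))
  # disjoint features pass through
  s <- merge_by_class(make_feats(c(0, 60), c(50, 90), c("LINE", "DNA")))
  expect_equal(nrow(s), 2)
  expect_equal(s$canonical_class, c("LINE", "DNA"))
})

test_that("merge_by_class partitions covered bases exactly (per-base oracle)", {
  set.seed(42)
  for (rep in 1:25) {
    L <- sample(200:2000, 1)
    feats <- rand_feats(sample(2:25, 1), L)
    segs <- merge_by_class(feats)
    # non-overlapping and sorted within seq_id
    expect_true(all(segs$start < segs$end))
    expect_true(all(diff(segs$start) > 0))
    expect_true(all(segs$start[-1] >= segs$end[-nrow(segs)]))
    expect_identical(segments_to_map(segs, L), oracle_class_map(feats, L))
  }
})

test_that("class density matches direct fractions and is order/split invariant", {
  region <- analysis_region("r", data.frame(seq_id = "chr", start = 0L,
                                            end = 1000L))
  segs <- merge_by_class(make_feats(100, 350, "LINE"))
  d <- class_density(segs, region)
  expect_equal(unname(d$densities[["LINE"]]), 0.25)
  expect_equal(d$total, 0.25)
  expect_equal(class_density(merge_by_class(make_feats(integer(0),
                                                       integer(0),
                                                       character(0))),
                             region)$total, 0)
  # splitting a feature into abutting same-class fragments changes nothing
  set.seed(7)
  feats <- rand_feats(12, 1500)
  region2 <- analysis_region("r2", data.frame(seq_id = "chr", start = 0L,
                                              end = 1500L))
  split_feats <- do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    if (f$end - f$start < 4) return(f)
    mid <- f$start + (f$end - f$start) %/% 2
    rbind(transform(f, end = mid), transform(f, start = mid))
  }))
  shuffled <- split_feats[sample.int(nrow(split_feats)), ]
  d1 <- class_density(merge_by_class(feats), region2)
  d2 <- class_density(merge_by_class(shuffled), region2)
  expect_equal(d1$densities[sort(names(d1$densities))],
               d2$densities[sort(names(d2$densities))])
})

test_that("top repeat table ranks by cumulative size with deterministic ties", {
  region <- analysis_region("r", data.frame(seq_id = "chr", start = 0L,
                                            end = 1000L))
  feats <- make_feats(c(0, 150, 400, 700), c(100, 350, 500, 800),
                      c("LINE", "LINE", "DNA", "DNA"),
                      name = c("alpha", "alpha", "zeta", "beta"))
  tab <- top_repeat_table(feats, region, n = 10)
  expect_equal(tab$repeat_name, c("alpha", "beta", "zeta"))
  expect_equal(tab$total_size, c(300L, 100L, 100L))   # beta before zeta: tie
  expect_equal(tab$fragment_count, c(2L, 1L, 1L))
  expect_equal(tab$pct_region, c(30, 10, 10))
  expect_equal(tab$pct_repeat, c(60, 20, 20))
  expect_equal(nrow(top_repeat_table(feats, region, n = 2)), 2)
})

test_that("score filtering keeps high scores and is monotone in the cutoff", {
  feats <- make_feats(c(0, 200), c(100, 300), c("LINE", "LINE"),
                      score = c(100, 300))
  kept <- score_filter(feats, 255.6, quiet = TRUE)
  expect_equal(kept$score, 300)
  expect_equal(attr(kept, "n_removed"), 1L)
  expect_equal(nrow(score_filter(feats, -Inf, quiet = TRUE)), 2)
  set.seed(1)
  feats <- rand_feats(40, 5000)
  feats$score <- runif(nrow(feats), 0, 500)
  for (pair in list(c(50, 200), c(100, 400))) {
    lo <- score_filter(feats, pair[1], quiet = TRUE)
    hi <- score_filter(feats, pair[2], quiet = TRUE)
    expect_true(all(hi$score %in% lo$score))
  }
})

test_that("overlap attribution matches the boolean-mask oracle", {
  q <- make_feats(0, 100, "Other", name = "wAna_hit")
  a <- make_feats(50, 150, "LINE", name = "CR1")
  res <- overlap_attribution(q, a)
  expect_equal(res$fraction, 0.5)
  expect_equal(res$per_name$repeat_name, "CR1")
  expect_equal(res$per_name$share, 0.5)
  expect_equal(overlap_attribution(q, q)$fraction, 1.0)
  none <- overlap_attribution(q[0, ], a)
  expect_equal(none$status, "no matches")
  expect_true(is.na(none$fraction))
  set.seed(13)
  for (rep in 1:20) {
    L <- 3000
    q <- rand_feats(sample(3:15, 1), L)
    a <- rand_feats(sample(3:15, 1), L)
    expect_equal(overlap_attribution(q, a)$fraction,
                 oracle_overlap_fraction(q, a, L))
  }
})

test_that("coverage tracks count interval membership per base", {
  m <- data.frame(seq_id = "t", start = c(0L, 5L), end = c(10L, 15L))
  tr <- coverage_track(m, c(t = 20L))
  expect_equal(tr$t$max_coverage, 2L)
  expect_equal(tr$t$runs$count, c(1L, 2L, 1L, 0L))
  expect_equal(tr$t$runs$start, c(0L, 5L, 10L, 15L))
  empty <- coverage_track(m[0, ], c(t = 20L))
  expect_equal(empty$t$runs$count, 0L)
  expect_error(coverage_track(data.frame(seq_id = "t", start = 0L,
                                         end = 30L), c(t = 20L)),
               "exceeds")
  set.seed(5)
  for (rep in 1:15) {
    L <- sample(100:800, 1)
    m <- rand_feats(sample(1:20, 1), L)
    m$seq_id <- "t"
    tr <- coverage_track(m[, c("seq_id", "start", "end")],
                         c(t = as.integer(L)))
    per_base <- rep(tr$t$runs$count, tr$t$runs$end - tr$t$runs$start)
    expect_equal(per_base, oracle_coverage(m, L))
    expect_equal(tr$t$max_coverage, max(per_base))
  }
})

test_that("bedGraph round-trips through write and read", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  df <- data.frame(seq_id = "c", start = c(0L, 10L, 30L),
                   end = c(10L, 30L, 35L), value = c(1.5, 0.25, 3))
  write_bedgraph(df, path)
  back <- read_bedgraph(path)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$value, df$value)
})
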