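test_that("window Tm matches a hand-summed thermodynamic oracle", {
  s <- "ACGTACGTA"
  # stacks: AC CG GT TA AC CG GT TA, summed from the published table
  dH <- 2 * (6.5 + 11.9 + 6.5 + 6.0)
  dS <- 2 * (17.3 + 27.8 + 17.3 + 16.9)
  init_S <- -16.8                      # window contains G/C
  ct <- 50e-9
  oracle <- 1000 * (-dH) / ((-dS + init_S) + 1.987 * log(ct / 4)) - 273.15 +
    16.6 * log10(0.05)
  tm <- window_tm(s)
  expect_length(tm, 1)                 # len(seq) == window -> one value
  expect_equal(tm, oracle, tolerance = 0.01)
})

test_that("Tm ordering follows GC content and N yields missing windows", {
  expect_gt(window_tm("GGGGGGGGG"), window_tm("AAAAAAAAA"))
  tm_by_gc <- vapply(0:9, function(k)
    window_tm(paste0(strrep("G", k), strrep("A", 9 - k))), numeric(1))
  expect_true(all(diff(tm_by_gc) > 0))
  expect_equal(window_tm("AAAA"), numeric(0))   # shorter than window
  tm <- window_tm("AANAAAAAAAAAA")
  expect_true(all(is.na(tm[1:3])))              # windows crossing the N
  expect_true(all(!is.na(tm[-(1:3)])))
  # one value per start position at step 1
  expect_length(window_tm(strrep("ACGT", 10)), 40 - 9 + 1)
})

test_that("log-likelihood enrichment equals the Poisson log-PMF oracle", {
  t0 <- data.frame(seq_id = "c", start = 0L, end = 10L, value = 5)
  expect_equal(loglik_enrichment(t0, t0)$value, 0)
  c0 <- data.frame(seq_id = "c", start = 0L, end = 10L, value = 2)
  expect_gt(loglik_enrichment(t0, c0)$value, 0)
  expect_lt(loglik_enrichment(c0, t0)$value, 0)
  expect_error(loglik_enrichment(transform(t0, value = -1), c0),
               "non-negative")
  log_pmf <- function(x, lambda) x * log(lambda) - lambda - lgamma(x + 1)
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    bounds <- sort(sample(0:500, n + 1))
    mk <- function() data.frame(seq_id = "c", start = bounds[-(n + 1)],
                                end = bounds[-1],
                                value = round(runif(n, 0, 20), 3))
    tr <- mk(); ct <- mk()
    llr <- loglik_enrichment(tr, ct, pseudocount = 1e-5)
    x <- tr$value + 1e-5; y <- ct$value + 1e-5
    oracle <- (log_pmf(x, x) - log_pmf(x, y)) / log(10)
    expect_equal(llr$value, ifelse(x == y, 0, sign(x - y) * abs(oracle)),
                 tolerance = 1e-9)
    # swapping treatment and control flips every enrichment call
    rev_llr <- loglik_enrichment(ct, tr, pseudocount = 1e-5)
    expect_equal(sign(llr$value), -sign(rev_llr$value))
  }
})

test_that("profile rescaling interpolates linearly and preserves endpoints", {
  expect_equal(rescale_profile(rep(2.5, 7), 11), rep(2.5, 11))
  x <- c(1, 4, 2, 8)
  expect_equal(rescale_profile(x, 4), x)        # identity at target length
  ramp <- seq(0, 1, length.out = 11)
  out <- rescale_profile(ramp, 31)
  expect_equal(out, seq(0, 1, length.out = 31), tolerance = 1e-12)
  # missing values propagate, never interpolated across
  withNA <- c(0, NA, 2, 3)
  out <- rescale_profile(withNA, 7)
  expect_true(anyNA(out))
  expect_equal(out[1], 0)
  expect_equal(out[7], 3)
  # monotone profiles keep min/max; idempotent at target length
  mono <- cumsum(runif(20))
  expect_equal(range(rescale_profile(mono, 50)), range(mono))
  expect_equal(rescale_profile(mono, 20), mono)
})

test_that("metagene aggregation is a position-wise median over genes", {
  prof <- list(upstream = 1:3 / 10, span = c(0, 5, 10, 5, 0),
               downstream = 3:1 / 10)
  mg <- build_metagene(list(prof), span_length = 4, flank = 3)
  expect_equal(nrow(mg), 4 + 1 + 2 * 3)
  expect_equal(mg$median, c(prof$upstream, prof$span, prof$downstream))
  expect_equal(mg$position[1], -3)
  two <- build_metagene(list(
    list(upstream = rep(1, 2), span = rep(4, 5), downstream = rep(1, 2)),
    list(upstream = rep(-1, 2), span = rep(-4, 5), downstream = rep(-1, 2))),
    span_length = 4, flank = 2)
  expect_true(all(two$median == 0))
  expect_true(all(two$n == 2))
  expect_error(build_metagene(list()), "no gene profiles")
})

test_that("spline smoothing reproduces lines and denoises a known sine", {
  x <- 1:50
  line <- 0.5 * x + 2
  expect_equal(smooth_spline_fit(line, x), line, tolerance = 1e-6)
  expect_equal(smooth_spline_fit(rep(3, 30)), rep(3, 30), tolerance = 1e-6)
  expect_warning(out <- smooth_spline_fit(c(1, 2, 3)), "fewer than 10")
  expect_equal(out, c(1, 2, 3))
  set.seed(14)
  x <- seq(0, 4 * pi, length.out = 200)
  truth <- sin(x)
  noisy <- truth + rnorm(200, 0, 0.3)
  fit <- smooth_spline_fit(noisy, x)
  expect_lt(sqrt(mean((fit - truth)^2)), sqrt(mean((noisy - truth)^2)))
})

test_that("signal profiles are strand-aware and match per-base lookup", {
  # mirrored track: gene on + at [100,200) and gene on - at the mirrored
  # position read identical oriented profiles
  L <- 1000L
  vals <- data.frame(seq_id = "c", start = 0:(L - 1), end = 1:L,
                     value = sin(seq(0, 6, length.out = L)))
  plus <- isoform_model("gp", "gp.t", "c", "+", cbind(100L, 200L))
  minus <- isoform_model("gm", "gm.t", "c", "-",
                         cbind(L - 200L, L - 100L))
  mirror <- vals
  mirror$value <- rev(mirror$value)
  p1 <- signal_profile(vals, plus, flank = 50, seq_length = L)
  p2 <- signal_profile(mirror, minus, flank = 50, seq_length = L)
  expect_equal(p1$upstream, p2$upstream)
  expect_equal(p1$span, p2$span)
  expect_equal(p1$downstream, p2$downstream)
  # zero track -> zero profiles
  zero <- data.frame(seq_id = "c", start = 0L, end = L, value = 0)
  pz <- signal_profile(zero, plus, flank = 50, seq_length = L)
  expect_true(all(unlist(pz) == 0))
  # per-base dictionary oracle on a small contig with sparse runs
  set.seed(2)
  runs <- data.frame(seq_id = "c", start = c(0L, 40L, 120L),
                     end = c(20L, 90L, 180L), value = c(1.5, -2, 7))
  dict <- numeric(200)
  for (i in seq_len(nrow(runs))) {
    dict[seq(runs$start[i] + 1, runs$end[i])] <- runs$value[i]
  }
  iso <- isoform_model("g", "g.t", "c", "+", cbind(60L, 150L))
  pr <- signal_profile(runs, iso, flank = 30, seq_length = 200L)
  expect_equal(pr$upstream, dict[31:60])
  expect_equal(pr$span, dict[61:150])
  expect_equal(pr$downstream, dict[151:180])
  # flank beyond the contig is NA-filled and flagged
  edge <- isoform_model("g2", "g2.t", "c", "+", cbind(10L, 60L))
  pe <- signal_profile(runs, edge, flank = 30, seq_length = 200L)
  expect_true(attr(pe, "truncated"))
  expect_true(all(is.na(pe$upstream[1:20])))
})

test_that("planted promoter and body signals shape the metagene as expected", {
  cfg <- test_sim_config(seed = 29, region_length = 80000L, gene_count = 5,
                         class_density = c(LTR = 0.2, LINE = 0.1,
                                           RC_Helitron = 0.03, DNA = 0.03),
                         intron_meanlog = c(log(70), log(600)))
  dir <- withr::local_tempdir()
  sim <- simulate_region(cfg, dir)
  models <- lapply(sim$models, identity)
  active <- read_bedgraph(sim$paths$signal_active)
  body <- read_bedgraph(sim$paths$signal_body)
  mg_a <- signal_metagene(active, models, span_length = 1000, flank = 1000,
                          smooth = FALSE)
  mg_b <- signal_metagene(body, models, span_length = 1000, flank = 1000,
                          smooth = FALSE)
  # active mark peaks at the 5' end (axis position 0 = span start)
  expect_lt(abs(mg_a$position[which.max(mg_a$median)]), 150)
  # silencing mark: span mean exceeds flank mean
  span_idx <- mg_b$position >= 0 & mg_b$position <= 1000
  expect_gt(mean(mg_b$median[span_idx], na.rm = TRUE),
            mean(mg_b$median[!span_idx], na.rm = TRUE))
})
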