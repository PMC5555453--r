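#' Kruskal-Wallis rank sum test across groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `g - 1` degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups named list of >= 2 numeric vectors, each non-empty.
#' @return list `H`, `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("every group must contain at least one value")
  }
  kt <- stats::kruskal.test(unlist(groups),
                            factor(rep(seq_along(groups),
                                       lengths(groups))))
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = sum(lengths(groups)))
}

#' Dunn post hoc pairwise tests with Holm step-down correction
#'
#' Pairwise z statistics from the pooled ranks with tie correction:
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))` with
#' `T = sum(t^3 - t)` over tie groups. Unadjusted two-sided normal
#' p-values are corrected by the Holm-Bonferroni step-down, under which
#' the rejected hypotheses always form a prefix of the p-ordered list. By
#' the stated workflow the post hoc only runs after the Kruskal-Wallis
#' test rejects at `alpha`; set `gatekeep = FALSE` to override.
#'
#' @param groups named list of >= 2 numeric vectors.
#' @param alpha family-wise error rate (default 0.05).
#' @param gatekeep require KW rejection first (default TRUE).
#' @return list with `kw` (the Kruskal-Wallis result), `alpha`,
#'   `performed`, and `pairs`: data.frame `group_a`, `group_b`, `z`,
#'   `p_value`, `adj_p`, `reject`.
#' @export
dunn_holm <- function(groups, alpha = 0.05, gatekeep = TRUE) {
  stopifnot(length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal_wallis(groups)
  if (gatekeep && kw$p_value > alpha) {
    return(list(kw = kw, alpha = alpha, performed = FALSE,
                pairs = data.frame(group_a = character(0),
                                   group_b = character(0), z = numeric(0),
                                   p_value = numeric(0), adj_p = numeric(0),
                                   reject = logical(0))))
  }
  x <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_core <- N * (N + 1) / 12 - tie_term
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  combos <- utils::combn(names(groups), 2)
  z <- apply(combos, 2, function(pr) {
    (mean_r[[pr[1]]] - mean_r[[pr[2]]]) /
      sqrt(var_core * (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  adj <- stats::p.adjust(p, method = "holm")
  # Holm rejection sequence: step down in order of unadjusted p, stop at
  # the first non-rejection.
  o <- order(p)
  reject <- logical(length(p))
  for (i in seq_along(o)) {
    if (adj[o[i]] <= alpha) reject[o[i]] <- TRUE else break
  }
  list(kw = kw, alpha = alpha, performed = TRUE,
       pairs = data.frame(group_a = combos[1, ], group_b = combos[2, ],
                          z = z, p_value = p, adj_p = adj, reject = reject,
                          stringsAsFactors = FALSE))
}

#' Upper-tail hypergeometric enrichment test
#'
#' `P(X >= k)` for an observed overlap of `k` between a sample of `n`
#' draws and `K` successes in a population of `N`, computed by the exact
#' combinatorial sum `sum_j C(K,j) C(N-K,n-j) / C(N,n)` for `N <= 1000`
#' and via log-gamma beyond — the gene-set enrichment question "is the
#' overlap between these two gene sets larger than chance".
#'
#' @param N population size.
#' @param K successes in population.
#' @param n sample size.
#' @param k observed successes in sample.
#' @return list `N`, `K`, `n`, `k`, `p_value`.
#' @export
hypergeom_upper <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0)
  if (K > N || n > N || k > min(K, n)) {
    stop("invalid hypergeometric configuration: need k <= min(K, n) <= N")
  }
  j <- seq(k, min(K, n))
  if (N <= 1000) {
    p <- sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  } else {
    lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    p <- sum(exp(lp))
  }
  list(N = N, K = K, n = n, k = k, p_value = min(p, 1))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Midranks for ties; `p` from `t = rho*sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom (two-sided). Constant input yields an explicit
#' undefined status rather than a numeric answer.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @return list `status` (`"ok"`/`"undefined"`), `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(status = "undefined", rho = NA_real_, p_value = NA_real_,
                n = length(x)))
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  list(status = "ok", rho = rho, p_value = p, n = n)
}

# Generalized cross-validation score of a loess fit:
# n * RSS / (n - trace(L))^2.
loess_gcv <- function(fit) {
  n <- length(fit$residuals)
  n * sum(fit$residuals^2) / (n - fit$trace.hat)^2
}

#' Local regression trend with GCV-selected span
#'
#' Degree-1 LOESS with tricube weights. The span is selected by
#' generalized cross-validation (trace of the smoother matrix) on an
#' initial non-robust pass over a span grid; the final fit reruns at the
#' chosen span with bisquare robustness iterations
#' (`family = "symmetric"`), the setting used to read Nc-vs-CAI
#' scatterplots where an inverted-V trend separates mutational-bias-driven
#' from selection-driven codon bias.
#'
#' @param x,y numeric vectors (>= 10 points).
#' @param span_grid candidate spans (default `seq(0.2, 0.95, 0.05)`).
#' @param robust_iterations bisquare iterations for the final fit
#'   (default 4).
#' @return list `x`, `y`, `fitted` (at the input x, input order), `span`,
#'   `degree`, `robust_iterations`, `gcv`.
#' @export
loess_trend <- function(x, y, span_grid = seq(0.2, 0.95, by = 0.05),
                        robust_iterations = 4) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) stop("loess_trend needs at least 10 points")
  scores <- vapply(span_grid, function(sp) {
    f <- tryCatch(
      suppressWarnings(stats::loess(y ~ x, span = sp, degree = 1,
                                    family = "gaussian",
                                    control = stats::loess.control(
                                      surface = "direct"))),
      error = function(e) NULL)
    if (is.null(f)) Inf else loess_gcv(f)
  }, numeric(1))
  if (all(!is.finite(scores))) stop("no span in the grid produced a fit")
  span <- span_grid[which.min(scores)]
  fit <- suppressWarnings(stats::loess(
    y ~ x, span = span, degree = 1, family = "symmetric",
    control = stats::loess.control(surface = "direct",
                                   iterations = robust_iterations + 1)))
  list(x = x, y = y, fitted = stats::predict(fit, data.frame(x = x)),
       span = span, degree = 1, robust_iterations = robust_iterations,
       gcv = min(scores))
}
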