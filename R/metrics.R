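#' Docking enrichment at a percentile
#'
#' DE_x% = 100 * h / n: the percentage of all actives (n) recovered among
#' the top x fraction of the ranked library. The top-k cut uses
#' round-half-up of `x * N`, with a floor of one compound. With a 2%
#' active fraction the best achievable DE is 100% at the 2% percentile and
#' 25% at the 0.5% percentile (only a quarter of the actives fit).
#'
#' @param screen A [ranked_screen()].
#' @param x Fraction of the library in (0, 1] (0.02 means the top 2%).
#' @return Percentage in \[0, 100\].
#' @export
docking_enrichment <- function(screen, x) {
  stopifnot(inherits(screen, "ranked_screen"))
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1)
    stop("x must be a fraction in (0, 1]")
  k <- max(1L, as.integer(round_half_up(x * screen$N)))
  h <- sum(active_ranks(screen) <= k)
  100 * h / screen$n
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC. With ranks r_i of the n
#' actives in a library of N compounds and active ratio R_a = n/N:
#' \deqn{BEDROC = \frac{\sum_i e^{-\alpha r_i/N}}
#'   {R_a (1-e^{-\alpha})/(e^{\alpha/N}-1)}
#'   \times \frac{R_a \sinh(\alpha/2)}{\cosh(\alpha/2)-\cosh(\alpha/2-\alpha R_a)}
#'   + \frac{1}{1-e^{\alpha(1-R_a)}}}
#' The score lies in \[0, 1\] and depends only on the ranks of the actives,
#' never on the raw scores; larger `alpha` concentrates the weight on
#' earlier ranks (see [weight_fraction()] for the calibration).
#'
#' @param screen A [ranked_screen()].
#' @param alpha Positive weighting rate. When `alpha * R_a >= 1` the
#'   classical interpretation of the score degrades; a warning is issued.
#' @return Score in \[0, 1\].
#' @export
bedroc <- function(screen, alpha) {
  stopifnot(inherits(screen, "ranked_screen"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive real")
  N <- screen$N; n <- screen$n; Ra <- screen$R_a
  if (n == 0L || n == N) stop("degenerate screen: R_a must lie in (0, 1)")
  if (alpha * Ra >= 1)
    warning("alpha * R_a >= 1: BEDROC's probabilistic reading is degraded")
  r <- active_ranks(screen)
  scale1 <- sum(exp(-alpha * r / N)) /
    (Ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  scale2 <- Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra))
  val <- scale1 * scale2 + 1 / (1 - exp(alpha * (1 - Ra)))
  min(1, max(0, val))   # guard against sub-epsilon overshoot of the bounds
}

#' Share of BEDROC weight carried by the top fraction of a ranking
#'
#' The exponential weight e^{-alpha * r/N} integrated over the top fraction
#' `x` of normalized ranks, relative to the whole library:
#' `(1 - exp(-alpha * x)) / (1 - exp(-alpha))`. At alpha = 80.5 the top 2%
#' of ranks carry 80% of the score; alpha = 321.9 puts 80% on the top
#' 0.5% and alpha = 20.0 on the top 8%.
#'
#' @param alpha Positive weighting rate (vectorized).
#' @param x Fraction of the library in (0, 1] (vectorized).
#' @return Fraction(s) in (0, 1].
#' @export
weight_fraction <- function(alpha, x) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (any(x <= 0 | x > 1)) stop("x must lie in (0, 1]")
  (1 - exp(-alpha * x)) / (1 - exp(-alpha))
}

#' Solve for the alpha matching a percentile/weight calibration
#'
#' Finds the `alpha` such that the top fraction `x` of ranks carries the
#' fraction `w` of the total BEDROC weight, i.e. inverts
#' [weight_fraction()] by bracketed root finding.
#'
#' @param x Top fraction in (0, 1).
#' @param w Target weight share in (0, 1); must exceed `x` (the weight
#'   share tends to `x` as alpha tends to 0).
#' @param interval Search bracket for alpha.
#' @return The matching alpha (relative tolerance 1e-8).
#' @export
alpha_for_fraction <- function(x, w, interval = c(1e-8, 1e6)) {
  if (x <= 0 || x >= 1) stop("x must lie in (0, 1)")
  if (w <= 0 || w >= 1) stop("w must lie in (0, 1)")
  if (w <= x) stop("w must exceed x (weight share -> x as alpha -> 0)")
  f <- function(a) weight_fraction(a, x) - w
  if (f(interval[1]) * f(interval[2]) > 0) stop("no root in bracket")
  uniroot(f, interval, tol = 1e-8 * max(1, interval[1]))$root
}

#' Success indicator for a BEDROC score
#'
#' A target counts as a success when the score strictly exceeds the
#' threshold (default 0.5).
#'
#' @param bedroc_score Numeric score(s) in \[0, 1\].
#' @param threshold Success threshold.
#' @return Logical vector.
#' @export
success <- function(bedroc_score, threshold = 0.5) {
  stopifnot(all(bedroc_score >= 0 & bedroc_score <= 1))
  bedroc_score > threshold
}

#' Net balance between two programs
#'
#' Delta-p(a/b): over a shared target set, the number of targets where
#' program a scores strictly higher than program b, minus the number where
#' it scores lower, divided by the number of targets considered. Exact
#' ties count for neither side. With `restrict_to_success`, only targets
#' where at least one of the two programs succeeds (max score > threshold)
#' enter the comparison, and the denominator is that subset's size.
#'
#' @param a,b Named numeric vectors mapping target id to BEDROC score;
#'   the name sets must coincide.
#' @param restrict_to_success Restrict to targets won by either program.
#' @param threshold Success threshold for the restriction.
#' @return Delta-p in \[-1, 1\].
#' @export
net_balance <- function(a, b, restrict_to_success = FALSE, threshold = 0.5) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("a and b must be named by target id")
  if (!setequal(names(a), names(b))) {
    diff <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    stop("target sets differ: ", paste(diff, collapse = ", "))
  }
  b <- b[names(a)]
  if (restrict_to_success) {
    keep <- pmax(a, b) > threshold
    if (!any(keep)) stop("restricted subset is empty")
    a <- a[keep]; b <- b[keep]
  }
  (sum(a > b) - sum(a < b)) / length(a)
}

#' Per-target metric table
#'
#' Computes docking enrichment at each percentile and BEDROC at each alpha
#' for every screen in a collection.
#'
#' @param screens Named list of [ranked_screen()] objects.
#' @param alphas Numeric vector of BEDROC alphas (default [bedroc_alphas]).
#' @param percentiles Numeric vector of DE fractions.
#' @return Data frame with one row per target: `target_id`, `DE_<pct>`
#'   columns (percent) and `BEDROC_<alpha>` columns.
#' @export
metrics_table <- function(screens, alphas = bedroc_alphas,
                          percentiles = c(0.005, 0.02, 0.08)) {
  rows <- lapply(screens, function(s) {
    de <- vapply(percentiles, function(x) docking_enrichment(s, x), 0)
    bd <- vapply(alphas, function(a) bedroc(s, a), 0)
    row <- data.frame(target_id = s$target_id, stringsAsFactors = FALSE)
    row[paste0("DE_", percentiles * 100)] <- as.list(de)
    row[paste0("BEDROC_", unname(alphas))] <- as.list(bd)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise net-balance matrix
#'
#' @param scores Named list of named score vectors, one per program, all
#'   over the same target set.
#' @inheritParams net_balance
#' @return Square matrix of Delta-p(a/b), rows = a, columns = b.
#' @export
net_balance_matrix <- function(scores, restrict_to_success = FALSE,
                               threshold = 0.5) {
  progs <- names(scores)
  m <- matrix(0, length(progs), length(progs),
              dimnames = list(progs, progs))
  for (i in progs) for (j in progs) if (i != j)
    m[i, j] <- net_balance(scores[[i]], scores[[j]],
                           restrict_to_success = restrict_to_success,
                           threshold = threshold)
  m
}
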