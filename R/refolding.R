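#' Normalize percent-refolded data to a non-native probability time course
#'
#' Converts percent refolded to the probability of being non-native,
#' `p_nn = (100 - percent_refolded) / 100`, clipping to \[0, 1\] and flagging
#' raw values outside \[0, 100\] (a common digitization artifact).
#'
#' @param data Data frame with a time column (minutes, ascending) and a
#'   percent-refolded column.
#' @param time_col,percent_col,error_col Column names; `error_col` (percent
#'   units) is optional and becomes per-point `sigma` in probability units.
#' @param label Free-text label.
#' @return A `refolding_timecourse` tibble with columns `t`, `p_nn`, `sigma`,
#'   `out_of_range`.
#' @export
normalize_refolding <- function(data, time_col = "time_min",
                                percent_col = "percent_refolded",
                                error_col = NULL, label = "") {
  data <- as_tibble(data)
  t <- data[[time_col]]
  pct <- data[[percent_col]]
  if (anyNA(t) || anyNA(pct) || !all(is.finite(pct))) {
    abort_invalid("time and percent values must be finite")
  }
  if (is.unsorted(t, strictly = TRUE)) {
    abort_invalid("time must be strictly ascending")
  }
  flags <- pct < 0 | pct > 100
  p_nn <- pmin(1, pmax(0, (100 - pct) / 100))
  sigma <- if (!is.null(error_col)) data[[error_col]] / 100 else NULL
  new_refolding_timecourse(t, p_nn, sigma = sigma, label = label,
                           flags = flags)
}

biexp_objective <- function(t, p) {
  force(t); force(p)
  function(par) {
    pred <- biexp_pnn(t, par[1], 10^par[2], 10^par[3])
    sum((p - pred)^2)
  }
}

#' Fit the two-pathway biexponential refolding model
#'
#' Least-squares fit of \eqn{P_{NN}(t) = a_0 e^{-k_1 t} + a_1 e^{-k_2 t}}
#' with the constraint \eqn{a_0 + a_1 = 1} imposed exactly by substitution.
#' Rates are optimized on the log10 scale with box bounds \[-30, 2\]
#' (spanning slow rates down to ~1e-23/min without underflow), from a
#' multi-start grid: `k1` seeded at the first e-fold crossing time, `k2` at
#' `1/duration * 10^-m` for m = 0..6. A fitted `k2` below the measurability
#' limit for the course duration (see [measurability_limit()]) is flagged
#' `"lower-bound-only"`: its plateau `a1` is identifiable but the rate is at
#' best an order of magnitude.
#'
#' @param tc A `refolding_timecourse` (from [normalize_refolding()] or
#'   [gen_timecourse()]).
#' @return A `biexp_fit` object; see [tidy.biexp_fit()] and
#'   [glance.biexp_fit()].
#' @export
fit_biexponential <- function(tc) {
  stopifnot(inherits(tc, "refolding_timecourse"))
  t <- tc$t; p <- tc$p_nn
  if (length(t) < 4) abort_invalid("at least 4 points required")
  if (diff(range(p)) == 0) abort_invalid("p_nn values are all identical")
  duration <- max(t)

  # k1 start: time at which the fast phase has decayed by one e-fold
  plateau <- p[length(p)]
  drop_frac <- (p - plateau) / max(p[1] - plateau, 1e-6)
  cross <- t[which(drop_frac <= exp(-1))[1]]
  k1_starts <- unique(pmax(1e-6, c(
    if (!is.na(cross) && cross > 0) 1 / cross,
    1 / duration * c(1, 10, 100))))
  k2_starts <- 1 / duration * 10^-(0:6)
  a0_starts <- unique(pmin(0.999, pmax(0.001, c(1 - plateau, 0.5))))

  obj <- biexp_objective(t, p)
  best <- NULL
  for (a0s in a0_starts) for (k1s in k1_starts) for (k2s in k2_starts) {
    fit <- tryCatch(
      optim(c(a0s, log10(k1s), log10(k2s)), obj, method = "L-BFGS-B",
            lower = c(0, -30, -30), upper = c(1, 2, 2),
            control = list(maxit = 1000, factr = 1e2)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort_invalid("biexponential fit failed from all starts")
  converged <- best$convergence == 0

  # Levenberg-Marquardt polish from the best multistart solution
  polish <- tryCatch({
    fit <- minpack.lm::nls.lm(
      par = best$par,
      fn = function(par) p - biexp_pnn(t, min(max(par[1], 0), 1),
                                       10^par[2], 10^par[3]),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
    list(par = c(min(max(fit$par[1], 0), 1),
                 pmin(pmax(fit$par[2:3], -30), 2)),
         value = sum(fit$fvec^2))
  }, error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    best <- polish
    converged <- TRUE
  }

  a0 <- best$par[1]; k1 <- 10^best$par[2]; k2 <- 10^best$par[3]
  if (k2 > k1) {  # the model is symmetric in its two phases; order them
    tmp <- k1; k1 <- k2; k2 <- tmp
    a0 <- 1 - a0
  }
  # degenerate single-exponential data: one amplitude ~0 makes the other
  # phase's rate meaningless; canonicalize so the live phase is (a0, k1)
  unidentifiable <- (1 - a0) < 1e-3 || a0 < 1e-3
  if (a0 < 1e-3) {
    a0 <- 1 - a0
    k1 <- k2
    k2 <- min(k2, 10^best$par[2])
  }
  fitted <- biexp_pnn(t, a0, k1, k2)
  k2_min <- measurability_limit(duration)
  flag <- if (k2 < k2_min) "lower-bound-only" else "measurable"
  structure(list(
    a0 = a0, a1 = 1 - a0, k1 = k1, k2 = k2,
    k2_upper = NA_real_, k2_lower = NA_real_,
    slow_time_constant = if (k2 > 0) 1 / k2 else Inf,
    residuals = p - fitted, fitted = fitted, t = t, p_nn = p,
    sigma = tc$sigma, duration = duration, sse = best$value,
    converged = converged, k2_flag = flag,
    k2_unidentifiable = unidentifiable,
    label = attr(tc, "label")), class = "biexp_fit")
}

#' Envelope bounds on the slow rate constant
#'
#' Refits the biexponential model to the data shifted up and down by the
#' per-point uncertainty (`sigma` where reported, else a 1\% default) and
#' returns the extreme `k2` values of the two envelope fits. This envelope
#' refit is one concrete reading of error-bar propagation onto the slow
#' rate; it yields zero-width bounds when `sigma = 0`.
#'
#' @param tc The time course used in the fit.
#' @param fit A converged [fit_biexponential()] result.
#' @param sigma_default Uncertainty (probability units) used where the data
#'   report none; default 0.01.
#' @return The `fit`, with `k2_lower` and `k2_upper` filled in
#'   (`k2_lower <= k2_upper`); bounds are `NA` if an envelope fit fails.
#' @export
k2_bounds <- function(tc, fit, sigma_default = 0.01) {
  stopifnot(inherits(fit, "biexp_fit"))
  if (!fit$converged) abort_invalid("fit did not converge; bounds undefined")
  sigma <- tc$sigma
  if (all(is.na(sigma))) sigma <- rep(sigma_default, nrow(tc))
  envelope_k2 <- function(shift) {
    p <- pmin(1, pmax(0, tc$p_nn + shift))
    env <- tryCatch(
      fit_biexponential(new_refolding_timecourse(tc$t, p, label = "envelope")),
      error = function(e) NULL)
    if (is.null(env)) NA_real_ else env$k2
  }
  if (all(sigma == 0)) {
    ks <- c(fit$k2, fit$k2)
  } else {
    ks <- c(envelope_k2(sigma), envelope_k2(-sigma))
  }
  if (anyNA(ks)) {
    fit$k2_lower <- NA_real_
    fit$k2_upper <- NA_real_
    warning("envelope refit failed; k2 bounds unavailable", call. = FALSE)
  } else {
    fit$k2_lower <- min(ks)
    fit$k2_upper <- max(ks)
  }
  fit
}

#' Wald-Wolfowitz runs test on fit residuals
#'
#' Tests whether the sign pattern of residuals is random; a systematic
#' (non-random) pattern under a single-exponential fit is the diagnostic
#' that the two-pathway model is needed. Normal approximation to the runs
#' distribution, one-sided against too few runs (systematic misfit clusters
#' residual signs; an excess of runs is not evidence of structure here);
#' zero residuals are dropped.
#'
#' @param residuals Numeric residual vector (>= 8 values).
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A list with `n_runs`, `statistic` (z), `p_value`, and `verdict`
#'   (`"non-random"` or `"random-consistent"`).
#' @export
runs_test_residuals <- function(residuals, alpha = 0.05) {
  r <- residuals[residuals != 0]
  if (length(residuals) < 8) abort_invalid("at least 8 residuals required")
  s <- sign(r)
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0) {
    return(list(n_runs = 1L, statistic = -Inf, p_value = 0,
                verdict = "non-random",
                note = "all residuals share one sign (degenerate case)"))
  }
  runs <- 1L + sum(s[-1] != s[-n])
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(sigma2)
  p <- pnorm(z)
  list(n_runs = runs, statistic = z, p_value = p,
       verdict = if (p < alpha) "non-random" else "random-consistent")
}

#' Slowest measurable rate for a given experimental duration
#'
#' Rule of thumb for the slow phase: a linear decrease in \eqn{P_{NN}} can be
#' resolved when its characteristic decay time is at most ten times the
#' course duration, so `k2_min = 1 / (10 * duration)`. Fitted `k2` below
#' this limit should be read as order-of-magnitude only.
#'
#' @param duration Experimental duration in minutes (> 0).
#' @return `k2_min` in 1/min.
#' @export
measurability_limit <- function(duration) {
  check_number(duration, "duration", lower = .Machine$double.xmin)
  1 / (10 * duration)
}

#' Order-of-magnitude slow folding time constant
#'
#' @param k2 Slow rate constant (1/min, > 0).
#' @return `10^round(log10(1/k2))`, minutes.
#' @export
time_constant_order <- function(k2) {
  if (any(k2 <= 0)) abort_invalid("k2 must be positive")
  10^round(log10(1 / k2))
}

#' Convert a slow time constant to years
#'
#' Plain unit conversion (525960 minutes per Julian-ish year of 365.25 days).
#'
#' @param minutes Time in minutes.
#' @return Time in years.
#' @export
minutes_to_years <- function(minutes) minutes / (60 * 24 * 365.25)

#' @importFrom stats pnorm
NULL

#' @rdname fit_biexponential
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("Biexponential refolding fit%s\n",
              if (nzchar(x$label %||% "")) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  a0 = %.4f  a1 = %.4f\n", x$a0, x$a1))
  cat(sprintf("  k1 = %.4g /min   k2 = %.4g /min (%s)\n",
              x$k1, x$k2, x$k2_flag))
  if (!is.na(x$k2_lower)) {
    cat(sprintf("  k2 bounds: [%.4g, %.4g]\n", x$k2_lower, x$k2_upper))
  }
  cat(sprintf("  slow time constant ~ %.3g min (order 10^%d min)\n",
              x$slow_time_constant,
              as.integer(round(log10(time_constant_order(x$k2))))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy a biexponential fit
#'
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble(term = c("a0", "a1", "k1", "k2"),
         estimate = c(x$a0, x$a1, x$k1, x$k2))
}

#' One-row fit summary
#'
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @return Tibble with amplitudes, rates, bounds, flags, SSE, and the
#'   order-of-magnitude slow time constant.
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble(a0 = x$a0, a1 = x$a1, k1 = x$k1, k2 = x$k2,
         k2_lower = x$k2_lower, k2_upper = x$k2_upper,
         slow_time_constant = x$slow_time_constant,
         time_constant_order = time_constant_order(x$k2),
         k2_flag = x$k2_flag, converged = x$converged, sse = x$sse)
}

#' @export
generics::tidy

#' @export
generics::glance
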