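#' Classify trajectory frames as bound or unbound
#'
#' Thresholds the per-frame intermolecular contact count: a frame is bound
#' when `contacts >= threshold`. When no threshold is given it defaults to
#' the midpoint between the two modes of the contact histogram (two-means
#' split), mirroring the manual per-system choice made when the two-state
#' behaviour is inspected by eye; the threshold actually used is recorded.
#'
#' @param data Data frame with a `contacts` column (one row per frame).
#' @param threshold Contact-count threshold (> 0), or `NULL` for the
#'   two-means default.
#' @param contacts_col Column holding the contact counts.
#' @return The data with a logical `bound` column; attributes `p_complex`
#'   (bound fraction) and `threshold`.
#' @export
classify_bound <- function(data, threshold = NULL, contacts_col = "contacts") {
  data <- as_tibble(data)
  contacts <- data[[contacts_col]]
  if (length(contacts) == 0) abort_invalid("empty contact series")
  if (any(contacts < 0)) abort_invalid("contact counts must be >= 0")
  if (is.null(threshold)) {
    km <- kmeans(contacts, centers = range(contacts) + c(0, .Machine$double.eps))
    threshold <- mean(km$centers)
  }
  check_number(threshold, "threshold", lower = .Machine$double.xmin)
  data$bound <- contacts >= threshold
  attr(data, "p_complex") <- mean(data$bound)
  attr(data, "threshold") <- threshold
  data
}

# Avogadro's number times litres per cubic Angstrom: converts a
# per-volume association measure to mol/L
KD_CONV <- 6.022e23 * 1e-27

#' Dissociation constant from bound occupancy in a finite volume
#'
#' For a single chaperone and single client in a simulation volume `V`
#' (cubic Angstrom), the unbound probabilities are both `1 - p_complex`, and
#' \deqn{K_D = \frac{(1-p)^2}{p} \cdot \frac{1}{V} \cdot
#'   \frac{1}{6.022\times10^{23} \times 10^{-27}}} in mol/L.
#'
#' @param p_complex Bound probability, strictly inside (0, 1); the endpoints
#'   correspond to censored estimates (no unbinding / no binding observed)
#'   and raise an error.
#' @param volume Simulation volume in cubic Angstrom.
#' @return K_D in mol/L.
#' @export
kd <- function(p_complex, volume) {
  check_number(volume, "volume", lower = .Machine$double.xmin)
  if (any(p_complex <= 0 | p_complex >= 1)) {
    abort_invalid(
      "p_complex must lie strictly in (0, 1); boundary estimates are censored")
  }
  ((1 - p_complex)^2 / p_complex) / volume / KD_CONV
}

#' Volume of a sphere of given radius
#'
#' @param radius_A Radius in Angstrom (160 for the GroEL box, 200 for
#'   DnaK/HtpG).
#' @return Volume in cubic Angstrom.
#' @export
sphere_volume <- function(radius_A) 4 / 3 * pi * radius_A^3

#' K_D with confidence interval from replicate trajectories
#'
#' Computes a per-replicate K_D by thresholding each contact trajectory,
#' then the mean and t-based 95\% confidence interval across replicates.
#' Replicates whose bound fraction hits 0 or 1 are censored (no K_D number
#' is fabricated for them); the interval is computed on the rest with a
#' warning.
#'
#' @param trajectories List of data frames with a `contacts` column.
#' @param volume Simulation volume, cubic Angstrom.
#' @param threshold Contact threshold passed to [classify_bound()].
#' @param conf_level Confidence level (default 0.95).
#' @param reference Optional reference K_D (mol/L) for a log2 ratio (e.g.
#'   the folded-state estimate).
#' @return A `binding_estimate` list: `kd_mean`, `ci95`, `replicate_kds`,
#'   `p_complex` (per replicate), `n_censored`, `log2_ratio_vs_reference`,
#'   `volume`, `threshold`.
#' @export
kd_replicates <- function(trajectories, volume, threshold = NULL,
                          conf_level = 0.95, reference = NULL) {
  if (length(trajectories) < 2) abort_invalid("at least 2 replicates required")
  ps <- vapply(trajectories, function(tr) {
    attr(classify_bound(tr, threshold = threshold), "p_complex")
  }, numeric(1))
  ok <- ps > 0 & ps < 1
  if (any(!ok)) {
    warning(sum(!ok), " replicate(s) censored (bound fraction 0 or 1); ",
            "CI computed on the remainder", call. = FALSE)
  }
  kds <- kd(ps[ok], volume)
  m <- mean(kds)
  ci <- if (length(kds) > 1 && sd(kds) > 0) {
    half <- qt(1 - (1 - conf_level) / 2, df = length(kds) - 1) *
      sd(kds) / sqrt(length(kds))
    c(m - half, m + half)
  } else c(m, m)
  structure(list(
    kd_mean = m, ci95 = ci, replicate_kds = kds, p_complex = ps,
    n_censored = sum(!ok),
    log2_ratio_vs_reference = if (is.null(reference)) NA_real_ else
      log2(m / reference),
    volume = volume, threshold = threshold), class = "binding_estimate")
}

#' @rdname kd_replicates
#' @param x A `binding_estimate`.
#' @param ... Unused.
#' @export
glance.binding_estimate <- function(x, ...) {
  tibble(kd_mean = x$kd_mean, ci_lower = x$ci95[1], ci_upper = x$ci95[2],
         n_replicates = length(x$replicate_kds), n_censored = x$n_censored,
         log2_ratio_vs_reference = x$log2_ratio_vs_reference)
}

#' Odds ratio of binding with attractive interactions on vs off
#'
#' Double ratio \eqn{(P_{X,on}/P_{X,off}) / (P_{F,on}/P_{F,off})} comparing
#' a conformational state X (unfolded or misfolded) against the folded
#' reference. When replicate-level probabilities are supplied (vectors), the
#' ratio is computed from the replicate means and a two-tailed one-sample
#' t-test of the per-replicate log odds ratios against 0 gives the p-value.
#'
#' @param p_on,p_off Binding probabilities for the comparison state with
#'   attractions on/off (scalars or replicate vectors, in (0, 1)).
#' @param p_ref_on,p_ref_off The folded-reference probabilities.
#' @param comparison Label, e.g. `"U/F"` or `"M/F"`.
#' @return An `odds_ratio_result` list: `ratio`, `p_value` (NA without
#'   replicates), `comparison`.
#' @export
odds_ratio <- function(p_on, p_off, p_ref_on, p_ref_off,
                       comparison = "U/F") {
  all_p <- c(p_on, p_off, p_ref_on, p_ref_off)
  if (any(all_p <= 0 | all_p >= 1)) {
    abort_invalid(paste("all probabilities must lie strictly in (0, 1);",
                        "a zero denominator makes the ratio inestimable"))
  }
  ratio <- (mean(p_on) / mean(p_off)) / (mean(p_ref_on) / mean(p_ref_off))
  p_value <- NA_real_
  n <- length(p_on)
  if (n > 1 && all(lengths(list(p_off, p_ref_on, p_ref_off)) == n)) {
    lr <- log(p_on / p_off) - log(p_ref_on / p_ref_off)
    if (sd(lr) > 0) p_value <- t.test(lr, mu = 0)$p.value
  }
  structure(list(ratio = ratio, p_value = p_value, comparison = comparison),
            class = "odds_ratio_result")
}

#' Two-tailed permutation test on a difference of group means
#'
#' Shuffles group labels and compares the absolute difference of means; ties
#' count as at least as extreme, so identical groups give p = 1. Exact
#' enumeration of all label assignments is used when there are at most
#' `max_exact` of them, otherwise `n_perm` random shuffles.
#'
#' @param group_a,group_b Numeric vectors (>= 3 values each), e.g. replicate
#'   K_D estimates of two conformational states.
#' @param n_perm Number of random permutations (>= 100).
#' @param seed Integer seed for the random shuffles.
#' @param max_exact Enumeration cutoff (default 20000 assignments).
#' @return List with `p_value`, `observed` (difference of means), `exact`.
#' @export
permutation_ratio_test <- function(group_a, group_b, n_perm = 10000,
                                   seed = 1L, max_exact = 20000) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    abort_invalid("each group needs >= 3 replicates")
  }
  if (n_perm < 100) abort_invalid("n_perm must be >= 100")
  pooled <- c(group_a, group_b)
  na <- length(group_a); n <- length(pooled)
  obs <- mean(group_a) - mean(group_b)
  tot <- sum(pooled)
  stat_from_idx <- function(idx) {
    sa <- sum(pooled[idx])
    sa / na - (tot - sa) / (n - na)
  }
  if (choose(n, na) <= max_exact) {
    combs <- utils::combn(n, na)
    perm <- apply(combs, 2, stat_from_idx)
    exact <- TRUE
  } else {
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      stat_from_idx(sample.int(n, na))
    }, numeric(1)))
    exact <- FALSE
  }
  p <- mean(abs(perm) >= abs(obs) - 1e-12)
  list(p_value = p, observed = obs, exact = exact)
}
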