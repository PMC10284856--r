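GROEL_SPECIES <- c("G", "G7ATP", "G7ATPU", "G7ATPUES", "G7ADPUES",
                   "ES", "ATP7", "F", "M", "U", "G7ADP")

#' Rate constants of the single-ring GroEL/GroES ATP cycle
#'
#' @param k1 ATP binding rate (1/(uM min); the seven ATP are treated as one
#'   bundle species).
#' @param k2 Client (unfolded protein) binding rate (1/(uM min)).
#' @param k3 GroES binding rate (1/(uM min)).
#' @param k4 ATP hydrolysis rate (1/min).
#' @param k5 Protein release rate (1/min).
#' @param k6 Spontaneous (bulk) folding rate (1/min).
#' @param k7 Basal hydrolysis rate (1/min).
#' @param k8 ADP release rate (1/min).
#' @return A `groel_rates` list. All rates must be non-negative; bimolecular
#'   rates (k1, k2, k3) are per uM per minute, unimolecular rates per minute.
#' @export
groel_rates <- function(k1 = 0, k2 = 0, k3 = 0, k4 = 0,
                        k5 = 0, k6 = 0, k7 = 0, k8 = 0) {
  r <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
         k7 = k7, k8 = k8)
  if (any(!is.finite(r)) || any(r < 0)) {
    abort_invalid("all rates must be finite and >= 0")
  }
  structure(as.list(r), class = "groel_rates")
}

#' Initial concentrations for the GroEL reaction network
#'
#' The 11 species of the single-ring cycle, in uM. `ATP7` is the
#' concentration of seven-ATP bundles (the model treats the 7 ATP that load
#' one ring as a single species); see [atp_consumed()] for the accounting.
#'
#' @param G Free single-ring GroEL.
#' @param G7ATP GroEL-ATP complex.
#' @param G7ATPU GroEL-ATP-unfolded-client complex.
#' @param G7ATPUES GroEL-ATP-client-GroES complex.
#' @param G7ADPUES GroEL-ADP-client-GroES complex (post-hydrolysis).
#' @param ES Free GroES.
#' @param ATP7 Seven-ATP bundles.
#' @param F,M,U Folded, misfolded, unfolded client protein.
#' @param G7ADP GroEL-ADP complex (basal cycle).
#' @return A named numeric vector of length 11.
#' @export
groel_state <- function(G = 0, G7ATP = 0, G7ATPU = 0, G7ATPUES = 0,
                        G7ADPUES = 0, ES = 0, ATP7 = 0, F = 0, M = 0,
                        U = 0, G7ADP = 0) {
  s <- c(G = G, G7ATP = G7ATP, G7ATPU = G7ATPU, G7ATPUES = G7ATPUES,
         G7ADPUES = G7ADPUES, ES = ES, ATP7 = ATP7, F = F, M = M,
         U = U, G7ADP = G7ADP)
  if (any(!is.finite(s)) || any(s < 0)) {
    abort_invalid("concentrations must be finite and >= 0")
  }
  s
}

#' Folding/misfolding partition coefficients
#'
#' Fractions of client molecules released into the folded or misfolded state
#' per GroEL cycle (`groel` context) or per spontaneous folding event
#' (`bulk` context); the remainder, `1 - phi_F - phi_M`, is released still
#' unfolded. In the bulk channel a folding event always resolves to F or M,
#' so client mass is conserved only when the bulk pair sums to 1; a warning
#' is raised otherwise.
#'
#' @param phi_F_groel,phi_M_groel GroEL-context coefficients, each in
#'   \[0, 1\], summing to at most 1.
#' @param phi_F_bulk,phi_M_bulk Bulk-context coefficients.
#' @return A `partition_coefficients` list.
#' @export
partition_coefficients <- function(phi_F_groel = 0, phi_M_groel = 0,
                                   phi_F_bulk = 1, phi_M_bulk = 0) {
  p <- c(phi_F_groel, phi_M_groel, phi_F_bulk, phi_M_bulk)
  if (any(p < 0 | p > 1)) abort_invalid("phi values must lie in [0, 1]")
  if (phi_F_groel + phi_M_groel > 1 + 1e-12) {
    abort_invalid("phi_F + phi_M must be <= 1 in the GroEL context")
  }
  if (abs(phi_F_bulk + phi_M_bulk - 1) > 1e-9) {
    warning("bulk phi_F + phi_M != 1: spontaneous folding events will not ",
            "conserve client mass", call. = FALSE)
  }
  structure(list(phi_F_groel = phi_F_groel, phi_M_groel = phi_M_groel,
                 phi_F_bulk = phi_F_bulk, phi_M_bulk = phi_M_bulk),
            class = "partition_coefficients")
}

#' Time derivatives of the GroEL reaction network
#'
#' Mass-action right-hand side of the single-ring ATP cycle: GroEL loads a
#' seven-ATP bundle, binds unfolded client, is capped by GroES, hydrolyses,
#' and releases the client partitioned into folded/misfolded/unfolded by the
#' GroEL-context phis; free unfolded client also folds spontaneously at
#' `k6`, partitioned by the bulk phis. The basal (client-free) cycle
#' hydrolyses GroEL-bound ATP at `k7` and releases ADP at `k8`.
#'
#' @param state Named concentration vector from [groel_state()].
#' @param rates A [groel_rates()].
#' @param phis A [partition_coefficients()].
#' @return Named derivative vector (uM/min).
#' @export
groel_rhs <- function(state, rates, phis) {
  s <- state; r <- rates; ph <- phis
  v_bind_atp <- r$k1 * s[["G"]] * s[["ATP7"]]
  v_bind_u <- r$k2 * s[["G7ATP"]] * s[["U"]]
  v_bind_es <- r$k3 * s[["G7ATPU"]] * s[["ES"]]
  v_hydro <- r$k4 * s[["G7ATPUES"]]
  v_release <- r$k5 * s[["G7ADPUES"]]
  v_bulk <- r$k6 * s[["U"]]
  v_basal <- r$k7 * s[["G7ATP"]]
  v_adp_off <- r$k8 * s[["G7ADP"]]
  c(G = -v_bind_atp + v_release + v_adp_off,
    G7ATP = v_bind_atp - v_bind_u - v_basal,
    G7ATPU = v_bind_u - v_bind_es,
    G7ATPUES = v_bind_es - v_hydro,
    G7ADPUES = v_hydro - v_release,
    ES = -v_bind_es + v_release,
    ATP7 = -v_bind_atp,
    F = ph$phi_F_groel * v_release + ph$phi_F_bulk * v_bulk,
    M = ph$phi_M_groel * v_release + ph$phi_M_bulk * v_bulk,
    U = -v_bind_u +
      (1 - ph$phi_F_groel - ph$phi_M_groel) * v_release - v_bulk,
    G7ADP = v_basal - v_adp_off)
}

#' Integrate the GroEL reaction network
#'
#' Stiff-capable integration (lsoda) of the 11-species cycle. Client, GroEL
#' and GroES totals are conserved by the network's structure; small negative
#' excursions within the integrator tolerance are clipped to zero.
#'
#' @param initial [groel_state()] at t = 0.
#' @param rates [groel_rates()].
#' @param phis [partition_coefficients()].
#' @param t_grid Ascending times in minutes, starting at 0.
#' @param rtol,atol Integrator tolerances (default 1e-8 relative, 1e-10 uM
#'   absolute).
#' @return A `groel_trajectory` tibble: `time` plus one column per species.
#' @export
groel_integrate <- function(initial, rates, phis, t_grid,
                            rtol = 1e-8, atol = 1e-10) {
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE)) {
    abort_invalid("t_grid must be strictly ascending and start at 0")
  }
  # positional right-hand side (hot path: avoids name lookups)
  k <- unlist(rates, use.names = FALSE)
  pFg <- phis$phi_F_groel; pMg <- phis$phi_M_groel
  pFb <- phis$phi_F_bulk; pMb <- phis$phi_M_bulk
  deriv <- function(t, y, parms) {
    v1 <- k[1] * y[1] * y[7]    # G + 7ATP
    v2 <- k[2] * y[2] * y[10]   # G|7ATP + U
    v3 <- k[3] * y[3] * y[6]    # G|7ATP|U + ES
    v4 <- k[4] * y[4]           # hydrolysis
    v5 <- k[5] * y[5]           # release
    v6 <- k[6] * y[10]          # bulk folding
    v7 <- k[7] * y[2]           # basal hydrolysis
    v8 <- k[8] * y[11]          # ADP release
    list(c(-v1 + v5 + v8,
           v1 - v2 - v7,
           v2 - v3,
           v3 - v4,
           v4 - v5,
           -v3 + v5,
           -v1,
           pFg * v5 + pFb * v6,
           pMg * v5 + pMb * v6,
           -v2 + (1 - pFg - pMg) * v5 - v6,
           v7 - v8))
  }
  sol <- deSolve::lsoda(y = initial, times = t_grid, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort_invalid("ODE integration failed (istate %d)",
                  attr(sol, "istate")[1])
  }
  out <- as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  for (sp in GROEL_SPECIES) out[[sp]] <- pmax(out[[sp]], 0)
  attr(out, "initial") <- initial
  attr(out, "rates") <- rates
  attr(out, "phis") <- phis
  class(out) <- c("groel_trajectory", class(out))
  out
}

#' Simulated non-native probability
#'
#' \eqn{P_{NN}^{sim}(t) = 1 - [F](t) / [U]_0}.
#'
#' @param trajectory A `groel_trajectory`.
#' @param u0 Initial client concentration (uM, > 0).
#' @param t_points Times (minutes) within the integrated range.
#' @return Numeric vector of \eqn{P_{NN}^{sim}} values.
#' @export
p_nn_sim <- function(trajectory, u0, t_points) {
  check_number(u0, "u0", lower = .Machine$double.xmin)
  rng <- range(trajectory$time)
  if (any(t_points < rng[1] | t_points > rng[2])) {
    abort_invalid("t_points outside integrated range [%g, %g]",
                  rng[1], rng[2])
  }
  f <- approx(trajectory$time, trajectory$F, xout = t_points)$y
  1 - f / u0
}

#' Grid fit of the GroEL partition coefficients
#'
#' Scans `phi_F` over 0.001 to 1.001 in steps of 0.001 (the grid endpoint is
#' deliberately preserved; candidates beyond the simplex are dropped by the
#' constraint anyway), sets `phi_M = Peq / (1 - Peq) * phi_F` from the
#' experimental non-native plateau `Peq`, skips candidates with
#' `phi_F + phi_M > 1`, integrates the network for each remaining candidate,
#' and ranks candidates primarily by Pearson R^2 between simulated and
#' experimental \eqn{P_{NN}}, breaking ties by total absolute error.
#'
#' @param experiment A `refolding_timecourse`.
#' @param initial [groel_state()]; its `U` entry is the initial client
#'   concentration.
#' @param rates [groel_rates()].
#' @param phi_bulk Length-2 numeric, bulk-context `c(phi_F, phi_M)` held
#'   fixed during the scan (default all-folded bulk).
#' @param peq_method `"final"` (plateau = last point, default) or `"last2"`
#'   (mean of the last two points).
#' @param phi_grid Candidate `phi_F` values (default the 0.001..1.001 grid).
#' @param r2_tol R^2 is nearly flat in `phi_F` on well-fitting data, so all
#'   candidates within `r2_tol` of the maximum R^2 are treated as tied and
#'   resolved by absolute error (default 1e-6).
#' @param rtol,atol Integrator tolerances used during the scan.
#' @return A `phi_fit` list: `phis` (the best [partition_coefficients()]),
#'   `pearson_r2`, `abs_error`, `peq`, and the scanned `candidates` tibble.
#' @export
fit_phis <- function(experiment, initial, rates,
                     phi_bulk = c(1, 0),
                     peq_method = c("final", "last2"),
                     phi_grid = seq(0.001, 1.001, by = 0.001),
                     r2_tol = 1e-6, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(experiment, "refolding_timecourse"))
  peq_method <- match.arg(peq_method)
  p <- experiment$p_nn
  peq <- if (peq_method == "final") p[length(p)] else mean(utils::tail(p, 2))
  if (peq >= 1) {
    abort_invalid("P_NN^eq = 1 (no folding observed): phi ratio undefined")
  }
  ratio <- peq / (1 - peq)
  u0 <- initial[["U"]]
  t_exp <- experiment$t
  t_grid <- sort(unique(c(0, t_exp)))

  keep <- phi_grid * (1 + ratio) <= 1 + 1e-12
  cand <- phi_grid[keep]
  if (!length(cand)) abort_invalid("no feasible phi_F candidates")
  score <- vapply(cand, function(pf) {
    phis <- partition_coefficients(pf, ratio * pf,
                                   phi_bulk[1], phi_bulk[2])
    traj <- groel_integrate(initial, rates, phis, t_grid,
                            rtol = rtol, atol = atol)
    sim <- p_nn_sim(traj, u0, t_exp)
    r2 <- if (sd(sim) == 0 || sd(p) == 0) 0 else cor(sim, p)^2
    c(r2 = r2, abs_error = sum(abs(sim - p)))
  }, numeric(2))
  candidates <- tibble(phi_F = cand, phi_M = ratio * cand,
                       r2 = score[1, ], abs_error = score[2, ])
  tied <- candidates$r2 >= max(candidates$r2) - r2_tol
  best <- which(tied)[which.min(candidates$abs_error[tied])]
  structure(list(
    phis = partition_coefficients(candidates$phi_F[best],
                                  candidates$phi_M[best],
                                  phi_bulk[1], phi_bulk[2]),
    pearson_r2 = candidates$r2[best],
    abs_error = candidates$abs_error[best],
    peq = peq, candidates = candidates), class = "phi_fit")
}

#' ATP consumed along a trajectory
#'
#' Cumulative ATP usage, `accounting = "bundle7"` (default) multiplies the
#' depleted bundle concentration by 7 to report individual ATP molecules;
#' `"literal"` reports bundle units as stored in the state vector.
#'
#' @param trajectory A `groel_trajectory`.
#' @param accounting `"bundle7"` or `"literal"`.
#' @return Tibble with `time` and `atp_consumed_uM` (monotone nondecreasing).
#' @export
atp_consumed <- function(trajectory, accounting = c("bundle7", "literal")) {
  accounting <- match.arg(accounting)
  mult <- if (accounting == "bundle7") 7 else 1
  tibble(time = trajectory$time,
         atp_consumed_uM = mult * (trajectory$ATP7[1] - trajectory$ATP7))
}

#' @rdname fit_phis
#' @param x A `phi_fit`.
#' @param ... Unused.
#' @export
glance.phi_fit <- function(x, ...) {
  tibble(phi_F = x$phis$phi_F_groel, phi_M = x$phis$phi_M_groel,
         pearson_r2 = x$pearson_r2, abs_error = x$abs_error, peq = x$peq)
}
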