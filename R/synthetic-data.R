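#' Specification for a synthetic refolding time course
#'
#' Defines the forward model of two-pathway refolding,
#' \eqn{P_{NN}(t) = a_0 e^{-k_1 t} + a_1 e^{-k_2 t}}, plus an additive
#' Gaussian noise level, from which [gen_timecourse()] draws data with known
#' ground truth.
#'
#' @param a0,a1 Initial probabilities of the fast- and slow-folding
#'   subpopulations; must sum to 1.
#' @param k1,k2 Fast and slow refolding rate constants (1/min), `k1 > k2 >= 0`.
#' @param duration Length of the time course in minutes.
#' @param n_points Number of time points (>= 3), evenly spaced from 0.
#' @param noise_sd Standard deviation of additive Gaussian noise, in
#'   probability units (default 0.01, i.e. 1\% uncertainty).
#' @param seed Integer seed; every stochastic draw is reproducible.
#' @return A `timecourse_spec` list.
#' @export
timecourse_spec <- function(a0, a1 = 1 - a0, k1, k2, duration = 150,
                            n_points = 30, noise_sd = 0.01, seed = 1L) {
  check_number(a0, "a0", 0, 1)
  check_number(a1, "a1", 0, 1)
  if (abs(a0 + a1 - 1) > 1e-12) {
    abort_invalid("invariant violated: a0 + a1 must equal 1 (got %g)", a0 + a1)
  }
  check_number(k1, "k1", lower = 0)
  check_number(k2, "k2", lower = 0)
  if (!(k1 > k2)) abort_invalid("invariant violated: k1 > k2 required")
  check_number(duration, "duration", lower = 1e-12)
  check_number(n_points, "n_points", lower = 3)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(a0 = a0, a1 = a1, k1 = k1, k2 = k2, duration = duration,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 seed = seed),
            class = "timecourse_spec")
}

#' Biexponential survival of the non-native state
#'
#' @param t Time in minutes.
#' @param a0 Fast-phase amplitude; slow amplitude is `a1 = 1 - a0` unless
#'   given.
#' @param k1,k2 Rate constants (1/min).
#' @param a1 Slow-phase amplitude.
#' @return \eqn{P_{NN}(t)}.
#' @export
biexp_pnn <- function(t, a0, k1, k2, a1 = 1 - a0) {
  a0 * exp(-k1 * t) + a1 * exp(-k2 * t)
}

#' Generate a refolding time course with known parameters
#'
#' Draws \eqn{P_{NN}(t)} on an even time grid from the biexponential forward
#' model; with `noise_sd = 0` the values equal the analytic curve exactly,
#' otherwise i.i.d. Gaussian noise is added and the result clipped to
#' \[0, 1\].
#'
#' @param spec A [timecourse_spec()].
#' @param label Free-text label stored on the result.
#' @return A `refolding_timecourse` tibble with columns `t` (min), `p_nn`,
#'   `sigma`, and attributes `label` and `truth` (the generating spec).
#' @export
gen_timecourse <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "timecourse_spec"))
  t <- seq(0, spec$duration, length.out = spec$n_points)
  p <- biexp_pnn(t, spec$a0, spec$k1, spec$k2, spec$a1)
  if (spec$noise_sd > 0) {
    p <- with_seed(spec$seed, p + rnorm(length(p), 0, spec$noise_sd))
    p <- pmin(1, pmax(0, p))
  }
  new_refolding_timecourse(t, p, sigma = rep(spec$noise_sd, length(t)),
                           label = label, truth = spec)
}

new_refolding_timecourse <- function(t, p_nn, sigma = NULL, label = "",
                                     truth = NULL, flags = NULL) {
  if (length(t) != length(p_nn) || length(t) < 3) {
    abort_invalid("invariant violated: len(t) = len(p_nn) >= 3 required")
  }
  if (is.unsorted(t, strictly = TRUE)) {
    abort_invalid("invariant violated: t must be strictly increasing")
  }
  if (any(p_nn < 0 | p_nn > 1)) {
    abort_invalid("invariant violated: p_nn must lie in [0, 1]")
  }
  out <- tibble(t = t, p_nn = p_nn,
                sigma = if (is.null(sigma)) NA_real_ else sigma)
  if (!is.null(flags)) out$out_of_range <- flags
  attr(out, "label") <- label
  attr(out, "truth") <- truth
  class(out) <- c("refolding_timecourse", class(out))
  out
}

#' Specification for a two-state bound/unbound contact trajectory
#'
#' @param p_bound_target Stationary probability of the bound state (0, 1).
#' @param mean_dwell_bound Mean dwell time in the bound state, frames (>= 1).
#' @param n_frames Number of frames.
#' @param contact_level_bound,contact_level_unbound Poisson means for the
#'   per-frame intermolecular contact count in each state; bound must exceed
#'   unbound.
#' @param seed Integer seed.
#' @return A `binding_traj_spec` list.
#' @export
binding_traj_spec <- function(p_bound_target, mean_dwell_bound = 50,
                              n_frames = 1e4, contact_level_bound = 50,
                              contact_level_unbound = 3, seed = 1L) {
  check_number(p_bound_target, "p_bound_target", 1e-12, 1 - 1e-12)
  check_number(mean_dwell_bound, "mean_dwell_bound", lower = 1)
  check_number(n_frames, "n_frames", lower = 2)
  check_number(contact_level_bound, "contact_level_bound", lower = 0)
  check_number(contact_level_unbound, "contact_level_unbound", lower = 0)
  if (!(contact_level_bound > contact_level_unbound)) {
    abort_invalid("invariant violated: bound contact mean must exceed unbound")
  }
  # exit probabilities of the two-state chain implied by dwell + stationarity
  q_b <- 1 / mean_dwell_bound
  q_u <- q_b * p_bound_target / (1 - p_bound_target)
  if (q_u > 1) {
    abort_invalid(paste0(
      "unreachable stationary target: p_bound %.3f with bound dwell %.1f ",
      "frames requires unbound exit probability %.3f > 1"),
      p_bound_target, mean_dwell_bound, q_u)
  }
  structure(list(p_bound_target = p_bound_target,
                 mean_dwell_bound = mean_dwell_bound,
                 n_frames = as.integer(n_frames),
                 contact_level_bound = contact_level_bound,
                 contact_level_unbound = contact_level_unbound,
                 q_b = q_b, q_u = q_u, seed = seed),
            class = "binding_traj_spec")
}

#' Generate a two-state Markov contact trajectory
#'
#' Simulates a bound/unbound Markov chain whose stationary bound probability
#' equals the spec target and whose bound dwell times are geometric with the
#' requested mean, then emits Poisson contact counts conditional on the state.
#' Ground-truth state labels are returned alongside the counts.
#'
#' @param spec A [binding_traj_spec()].
#' @param system_label Free-text system label.
#' @return A tibble with columns `frame`, `contacts`, `bound_true`, plus
#'   attributes `truth` (the spec) and `system_label`.
#' @export
gen_contact_trajectory <- function(spec, system_label = "synthetic") {
  stopifnot(inherits(spec, "binding_traj_spec"))
  n <- spec$n_frames
  with_seed(spec$seed, {
    state <- integer(n)
    state[1] <- rbinom(1, 1, spec$p_bound_target)  # start at stationarity
    flips <- runif(n)
    for (i in seq_len(n - 1)) {
      state[i + 1] <- if (state[i] == 1L) {
        if (flips[i] < spec$q_b) 0L else 1L
      } else {
        if (flips[i] < spec$q_u) 1L else 0L
      }
    }
    lambda <- ifelse(state == 1L, spec$contact_level_bound,
                     spec$contact_level_unbound)
    contacts <- rpois(n, lambda)
  })
  out <- tibble(frame = seq_len(n), contacts = contacts,
                bound_true = state == 1L)
  attr(out, "truth") <- spec
  attr(out, "system_label") <- system_label
  out
}

#' Specification for an analytically linked loop/thread toy structure
#'
#' @param loop_radius Loop radius in Angstrom.
#' @param n_loop_beads Number of beads forming the loop (>= 8).
#' @param thread_offset Numeric length-2 (x, y) displacement of the threading
#'   axis from the loop centroid, Angstrom.
#' @param thread_length Length of the straight threading segment, Angstrom.
#' @param handedness +1 or -1; the sign of the planted linking number.
#' @return A `toy_link_spec` list.
#' @export
toy_link_spec <- function(loop_radius = 10, n_loop_beads = 20,
                          thread_offset = c(0, 0), thread_length = 80,
                          handedness = 1L) {
  check_number(loop_radius, "loop_radius", lower = 1)
  check_number(n_loop_beads, "n_loop_beads", lower = 8)
  check_number(thread_length, "thread_length", lower = 4 * loop_radius)
  if (!handedness %in% c(-1L, 1L)) {
    abort_invalid("handedness must be +1 or -1")
  }
  if (length(thread_offset) != 2 || !all(is.finite(thread_offset))) {
    abort_invalid("thread_offset must be a finite (x, y) pair")
  }
  structure(list(loop_radius = loop_radius,
                 n_loop_beads = as.integer(n_loop_beads),
                 thread_offset = thread_offset,
                 thread_length = thread_length,
                 handedness = as.integer(handedness)),
            class = "toy_link_spec")
}

# single-chain toy: loop beads on a circle, C-tail routed outside the loop,
# then vertically along an axis at `axis_xy`; piercing iff the axis falls
# inside the loop
toy_chain_coords <- function(spec, axis_xy, n_app = NULL) {
  R <- spec$loop_radius
  n <- spec$n_loop_beads
  L <- spec$thread_length
  gap <- 2 * pi / n  # opening between first and last loop bead
  theta <- seq(gap / 2, 2 * pi - gap / 2, length.out = n)
  loop <- cbind(R * cos(theta), R * sin(theta), 0)
  ds <- 3.8
  # radial excursion outside the loop, at the loop's plane
  r_out <- seq(R + ds, 2.5 * R, by = ds)
  last_th <- theta[n]
  excur <- cbind(r_out * cos(last_th), r_out * sin(last_th), 0)
  # descend outside the loop to the bottom plane
  z_down <- seq(-ds, -L / 2, by = -ds)
  x_d <- 2.5 * R * cos(last_th); y_d <- 2.5 * R * sin(last_th)
  down <- cbind(x_d, y_d, z_down)
  # approach the axis underneath the loop plane
  if (is.null(n_app)) {
    n_app <- max(2L, ceiling(sqrt((x_d - axis_xy[1])^2 +
                                  (y_d - axis_xy[2])^2) / ds))
  }
  sfrac <- seq_len(n_app) / n_app
  approach <- cbind(x_d + sfrac * (axis_xy[1] - x_d),
                    y_d + sfrac * (axis_xy[2] - y_d), -L / 2)
  # vertical run: the candidate threading segment
  z_up <- seq(-L / 2 + ds, L / 2, by = ds)
  thread <- cbind(axis_xy[1], axis_xy[2], z_up)
  coords <- rbind(loop, excur, down, approach, thread)
  list(coords = coords, loop_idx = seq_len(n),
       thread_idx = nrow(coords) - nrow(thread) + seq_len(nrow(thread)))
}

#' Generate a native/misfolded toy pair with known linking number
#'
#' Both structures share a circular backbone loop closed by the contact
#' between its first and last beads. In the misfolded structure the
#' C-terminal tail threads the loop along its central axis, giving a discrete
#' Gauss linking number equal to `handedness`; in the native structure the
#' same tail runs outside the loop and the linking number rounds to 0.
#'
#' @param spec A [toy_link_spec()].
#' @return A list with `native` and `misfolded` (`calpha_structure` tibbles),
#'   `loop_contact` (the closing residue pair), and `thread_residues`.
#' @export
gen_entangled_toy <- function(spec) {
  stopifnot(inherits(spec, "toy_link_spec"))
  axis_mis <- spec$thread_offset
  axis_nat <- spec$thread_offset + c(4 * spec$loop_radius, 0)
  # both chains share residue numbering, so use a common approach length
  ds <- 3.8
  reach <- function(axis) {
    th <- 2 * pi - pi / spec$n_loop_beads
    sqrt((2.5 * spec$loop_radius * cos(th) - axis[1])^2 +
           (2.5 * spec$loop_radius * sin(th) - axis[2])^2)
  }
  n_app <- max(2L, ceiling(max(reach(axis_mis), reach(axis_nat)) / ds))
  mis <- toy_chain_coords(spec, axis_xy = axis_mis, n_app = n_app)
  nat <- toy_chain_coords(spec, axis_xy = axis_nat, n_app = n_app)
  if (spec$handedness == -1L) {
    mis$coords[, 3] <- -mis$coords[, 3]
    nat$coords[, 3] <- -nat$coords[, 3]
  }
  # degenerate-geometry guard: the threading run must clear the loop beads
  d <- as.matrix(stats::dist(rbind(mis$coords[mis$loop_idx, , drop = FALSE],
                                   mis$coords[mis$thread_idx, , drop = FALSE])))
  nl <- length(mis$loop_idx)
  if (min(d[seq_len(nl), -seq_len(nl)]) < 1.5) {
    abort_invalid("degenerate geometry: thread intersects loop beads")
  }
  to_struct <- function(ch) {
    xyz <- ch$coords
    calpha_structure(tibble(residue = seq_len(nrow(xyz)),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                     synthetic = TRUE)
  }
  list(native = to_struct(nat), misfolded = to_struct(mis),
       loop_contact = c(1L, spec$n_loop_beads),
       thread_residues = mis$thread_idx)
}

#' Specification for a synthetic LiP-MS half-tryptic peptide dataset
#'
#' @param protein_length Protein length in residues.
#' @param n_cutsites Unique proteinase-K cut sites per time point.
#' @param aa_propensities Named non-negative weights per residue type giving
#'   the relative PK cut propensity; defaults to uniform over the 20 amino
#'   acids.
#' @param effect_sites Data frame with columns `residue` and `sign` (+1/-1);
#'   peptides overlapping `residue` +/- 5 receive a log2 abundance ratio of
#'   the planted sign, and cut-site propensity within that window is
#'   multiplied by `effect_boost` (a conformational change both raises local
#'   PK accessibility and sets the direction of the abundance change).
#' @param effect_boost Multiplier on cut-site propensity within +/- 5 of an
#'   effect site (default 8).
#' @param n_timepoints Number of LiP-MS time points.
#' @param seed Integer seed.
#' @return A `lipms_sim_spec` list.
#' @export
lipms_sim_spec <- function(protein_length, n_cutsites,
                           aa_propensities = NULL, effect_sites = NULL,
                           effect_boost = 8, n_timepoints = 3, seed = 1L) {
  check_number(protein_length, "protein_length", lower = 10)
  check_number(n_cutsites, "n_cutsites", lower = 1)
  if (n_cutsites > protein_length) {
    abort_invalid("n_cutsites (%d) exceeds protein_length (%d)",
                  n_cutsites, protein_length)
  }
  if (is.null(aa_propensities)) {
    aa_propensities <- setNames(rep(1, 20), AA_TYPES)
  }
  if (any(aa_propensities < 0) || all(aa_propensities == 0)) {
    abort_invalid("aa_propensities must be >= 0 and not all zero")
  }
  if (!is.null(effect_sites)) {
    effect_sites <- as_tibble(effect_sites)
    stopifnot(all(c("residue", "sign") %in% names(effect_sites)))
    if (any(effect_sites$residue < 1 | effect_sites$residue > protein_length)) {
      abort_invalid("effect sites must lie within [1, protein_length]")
    }
  }
  structure(list(protein_length = as.integer(protein_length),
                 n_cutsites = as.integer(n_cutsites),
                 aa_propensities = aa_propensities,
                 effect_sites = effect_sites, effect_boost = effect_boost,
                 n_timepoints = as.integer(n_timepoints), seed = seed),
            class = "lipms_sim_spec")
}

AA_TYPES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate a synthetic LiP-MS peptide table
#'
#' Draws a random protein sequence, samples unique PK cut sites per time
#' point with probability proportional to the per-type cut propensity, and
#' forms half-tryptic peptides extending from each cut site to the nearest
#' downstream trypsin site (K/R, or the chain end). Peptides overlapping a
#' planted effect site within +/- 5 residues carry a log2 abundance ratio of
#' the planted sign; all other ratios are standard-normal noise.
#'
#' @param spec A [lipms_sim_spec()].
#' @param protein_id Identifier written into the peptide table.
#' @return A list with `peptides` (tibble: protein, start, end, cut_site,
#'   log2_ratio, timepoint, significant), `proteome` (tibble: aa, freq from
#'   the generated sequence), and `sequence` (character vector of residues).
#' @export
gen_lipms_dataset <- function(spec, protein_id = "SYNTH1") {
  stopifnot(inherits(spec, "lipms_sim_spec"))
  L <- spec$protein_length
  with_seed(spec$seed, {
    sequence <- sample(AA_TYPES, L, replace = TRUE)
    w <- spec$aa_propensities[sequence]
    w[is.na(w)] <- 0
    if (!is.null(spec$effect_sites)) {
      for (res in spec$effect_sites$residue) {
        win <- max(1L, res - 5L):min(L, res + 5L)
        w[win] <- w[win] * spec$effect_boost
      }
    }
    if (sum(w > 0) < spec$n_cutsites) {
      abort_invalid("fewer residues with positive propensity than n_cutsites")
    }
    tryp <- which(sequence %in% c("K", "R"))
    tabs <- lapply(seq_len(spec$n_timepoints), function(tp) {
      sites <- sort(sample.int(L, spec$n_cutsites, prob = w))
      end <- vapply(sites, function(s) {
        nxt <- tryp[tryp >= s]
        if (length(nxt)) nxt[1] else L
      }, integer(1))
      ratio <- rnorm(spec$n_cutsites)
      if (!is.null(spec$effect_sites)) {
        for (k in seq_len(nrow(spec$effect_sites))) {
          res <- spec$effect_sites$residue[k]
          sgn <- spec$effect_sites$sign[k]
          hit <- sites <= res + 5 & end >= res - 5
          ratio[hit] <- sgn * abs(rnorm(sum(hit), mean = 1.5, sd = 0.5))
        }
      }
      tibble(protein = protein_id, start = sites, end = end,
             cut_site = sites, log2_ratio = ratio,
             timepoint = sprintf("t%d", tp), significant = TRUE)
    })
  })
  peptides <- dplyr::bind_rows(tabs)
  proteome <- tibble(aa = AA_TYPES,
                     freq = as.numeric(table(factor(sequence, AA_TYPES)) / L))
  list(peptides = peptides, proteome = proteome, sequence = sequence)
}
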