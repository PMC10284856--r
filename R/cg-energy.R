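# Static evaluator for the C-alpha coarse-grained potential: virtual bonds,
# torsions, double-well bond angles, Debye-Hueckel electrostatics, 12-10-6
# native contacts, and weak 12-10-6 non-native repulsion. Evaluation only --
# no dynamics.

COULOMB_KCAL <- 332.0636  # e^2 / (4 pi eps0), kcal*Angstrom/(mol*e^2)

#' Assign coarse-grained charges from residue types
#'
#' Lysine and arginine get +e, glutamate and aspartate -e, all others 0.
#'
#' @param residue_types Character vector of one-letter residue codes.
#' @return Numeric charges in units of e.
#' @export
assign_charges <- function(residue_types) {
  q <- numeric(length(residue_types))
  q[residue_types %in% c("K", "R")] <- 1
  q[residue_types %in% c("D", "E")] <- -1
  q
}

#' Coarse-grained force-field parameters
#'
#' @param kb Bond stiffness, kcal/(mol A^2).
#' @param r0 Bond rest length, Angstrom.
#' @param torsions Data frame of dihedral cosine terms: `i` (dihedral index,
#'   1-based over consecutive quadruples), `j` (multiplicity 1..4), `k_phi`
#'   (kcal/mol), `delta` (phase, radians); `NULL` skips the term.
#' @param angles List with `gamma`, `k_alpha`, `theta_alpha`, `eps_alpha`,
#'   `k_beta`, `theta_beta` for the double-well bond-angle potential
#'   (radians, kcal/mol); `NULL` skips the term.
#' @param charges Per-residue charges in e (see [assign_charges()]); `NULL`
#'   skips electrostatics.
#' @param native_pairs Data frame `i`, `j`, `eps` (kcal/mol, the contact
#'   well depth `n_ij*eps_HB + eta*eps_ij`), `sigma` (Angstrom, native
#'   distance / 2^(1/6)).
#' @param eps_nn Non-native well depth, kcal/mol (default 0.000132).
#' @param sigma_nn Non-native collision diameter, Angstrom.
#' @param l_D Debye length, Angstrom (default 10).
#' @param eps_r Relative dielectric constant (default 78.5).
#' @param nb_min_sep Minimum |i - j| entering the nonbonded (electrostatic
#'   and pair) sums; bonded neighbours below it are excluded (default 4,
#'   configurable because the exclusion convention is inherited, not
#'   derived).
#' @return A `cg_params` list.
#' @export
cg_params <- function(kb = 50, r0 = 3.81, torsions = NULL, angles = NULL,
                      charges = NULL, native_pairs = NULL,
                      eps_nn = 0.000132, sigma_nn = 5.0,
                      l_D = 10, eps_r = 78.5, nb_min_sep = 4) {
  check_number(l_D, "l_D", lower = .Machine$double.xmin)
  check_number(eps_r, "eps_r", lower = .Machine$double.xmin)
  if (!is.null(native_pairs)) {
    native_pairs <- as_tibble(native_pairs)
    stopifnot(all(c("i", "j", "eps", "sigma") %in% names(native_pairs)))
    if (any(native_pairs$sigma <= 0)) abort_invalid("sigma_ij must be > 0")
  }
  structure(list(kb = kb, r0 = r0, torsions = torsions, angles = angles,
                 charges = charges, native_pairs = native_pairs,
                 eps_nn = eps_nn, sigma_nn = sigma_nn, l_D = l_D,
                 eps_r = eps_r, nb_min_sep = nb_min_sep),
            class = "cg_params")
}

dihedral_angles <- function(xyz) {
  n <- nrow(xyz)
  if (n < 4) return(numeric(0))
  b1 <- xyz[2:(n - 2), , drop = FALSE] - xyz[1:(n - 3), , drop = FALSE]
  b2 <- xyz[3:(n - 1), , drop = FALSE] - xyz[2:(n - 2), , drop = FALSE]
  b3 <- xyz[4:n, , drop = FALSE] - xyz[3:(n - 1), , drop = FALSE]
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

bond_angles <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3) return(numeric(0))
  u <- xyz[1:(n - 2), , drop = FALSE] - xyz[2:(n - 1), , drop = FALSE]
  v <- xyz[3:n, , drop = FALSE] - xyz[2:(n - 1), , drop = FALSE]
  acos(pmin(1, pmax(-1, rowSums(u * v) /
                      sqrt(rowSums(u^2) * rowSums(v^2)))))
}

pair_12_10_6 <- function(r, eps, sigma) {
  sr <- sigma / r
  eps * (13 * sr^12 - 18 * sr^10 + 4 * sr^6)
}

#' Evaluate the coarse-grained potential energy of a configuration
#'
#' Returns the six-term breakdown (bond, torsion, angle, electrostatic,
#' native 12-10-6, non-native 12-10-6) and the total, kcal/mol. Terms whose
#' parameters are absent evaluate to 0.
#'
#' @param structure A `calpha_structure` (or n x 3 coordinate matrix).
#' @param params A [cg_params()].
#' @return A `cg_energy` list: `total` and `terms` (named numeric).
#' @export
cg_energy <- function(structure, params) {
  stopifnot(inherits(params, "cg_params"))
  xyz <- if (is.matrix(structure)) structure else coords_matrix(structure)
  if (!all(is.finite(xyz))) abort_invalid("coordinates must be finite")
  n <- nrow(xyz)

  bond_vec <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                              xyz[-n, , drop = FALSE])^2))
  e_bond <- sum(params$kb * (bond_vec - params$r0)^2)

  e_torsion <- 0
  if (!is.null(params$torsions) && n >= 4) {
    phi <- dihedral_angles(xyz)
    tt <- params$torsions
    e_torsion <- sum(tt$k_phi * (1 + cos(tt$j * phi[tt$i] - tt$delta)))
  }

  e_angle <- 0
  if (!is.null(params$angles) && n >= 3) {
    th <- bond_angles(xyz)
    a <- params$angles
    wa <- -a$gamma * (a$k_alpha * (th - a$theta_alpha)^2 + a$eps_alpha)
    wb <- -a$gamma * a$k_beta * (th - a$theta_beta)^2
    # log-sum-exp, stabilized
    mx <- pmax(wa, wb)
    e_angle <- sum(-(mx + log(exp(wa - mx) + exp(wb - mx))) / a$gamma)
  }

  d <- as.matrix(stats::dist(xyz))
  sep <- abs(row(d) - col(d))
  nb <- upper.tri(d) & sep >= params$nb_min_sep

  e_elec <- 0
  if (!is.null(params$charges)) {
    q <- params$charges
    qq <- outer(q, q)
    idx <- which(nb & qq != 0)
    if (length(idx)) {
      r <- d[idx]
      if (any(r == 0)) abort_invalid("overlapping beads in pair term")
      e_elec <- sum(COULOMB_KCAL * qq[idx] / (params$eps_r * r) *
                      exp(-r / params$l_D))
    }
  }

  e_native <- 0
  native_mask <- matrix(FALSE, n, n)
  if (!is.null(params$native_pairs) && nrow(params$native_pairs)) {
    np <- params$native_pairs
    native_mask[cbind(np$i, np$j)] <- TRUE
    native_mask[cbind(np$j, np$i)] <- TRUE
    r <- d[cbind(np$i, np$j)]
    if (any(r == 0)) abort_invalid("overlapping beads in pair term")
    e_native <- sum(pair_12_10_6(r, np$eps, np$sigma))
  }

  nn_idx <- which(nb & !native_mask)
  e_nonnative <- 0
  if (length(nn_idx)) {
    r <- d[nn_idx]
    if (any(r == 0)) abort_invalid("overlapping beads in pair term")
    e_nonnative <- sum(pair_12_10_6(r, params$eps_nn, params$sigma_nn))
  }

  terms <- c(bond = e_bond, torsion = e_torsion, angle = e_angle,
             electrostatic = e_elec, native = e_native,
             nonnative = e_nonnative)
  structure(list(total = sum(terms), terms = terms), class = "cg_energy")
}

#' Read coarse-grained parameters from a YAML file
#'
#' The file carries a scalar block (`kb`, `r0`, `eps_nn`, `sigma_nn`, `l_D`,
#' `eps_r`, `nb_min_sep`), an optional `charges` sequence, and either an
#' inline `native_pairs` list of `[i, j, eps, sigma]` rows or a
#' `native_pairs_file` path to a whitespace-delimited table with those
#' columns.
#'
#' @param path YAML file path.
#' @return A [cg_params()] object.
#' @export
read_cg_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  pairs <- NULL
  if (!is.null(cfg$native_pairs)) {
    pairs <- do.call(rbind, lapply(cfg$native_pairs, as.numeric))
    pairs <- tibble(i = pairs[, 1], j = pairs[, 2],
                    eps = pairs[, 3], sigma = pairs[, 4])
  } else if (!is.null(cfg$native_pairs_file)) {
    pairs <- as_tibble(utils::read.table(
      file.path(dirname(path), cfg$native_pairs_file), header = TRUE))
  }
  cg_params(kb = cfg$kb %||% 50, r0 = cfg$r0 %||% 3.81,
            charges = cfg$charges,
            native_pairs = pairs,
            eps_nn = cfg$eps_nn %||% 0.000132,
            sigma_nn = cfg$sigma_nn %||% 5.0,
            l_D = cfg$l_D %||% 10, eps_r = cfg$eps_r %||% 78.5,
            nb_min_sep = cfg$nb_min_sep %||% 4)
}
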