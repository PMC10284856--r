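# Discrete Gauss linking machinery for non-covalent lasso entanglements:
# a backbone loop closed by a native contact (i, j) threaded by an N- or
# C-terminal tail. Linking numbers are estimated by the midpoint
# discretization of the Gauss double integral over segment pairs.

# midpoint Gauss double sum between two polylines given as vertex matrices
gauss_double_sum <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2 || nB < 2) return(0)
  dA <- A[-1, , drop = FALSE] - A[-nA, , drop = FALSE]
  dB <- B[-1, , drop = FALSE] - B[-nB, , drop = FALSE]
  if (any(rowSums(dA^2) == 0) || any(rowSums(dB^2) == 0)) {
    abort_invalid("zero-length segment in Gauss sum")
  }
  RA <- (A[-1, , drop = FALSE] + A[-nA, , drop = FALSE]) / 2
  RB <- (B[-1, , drop = FALSE] + B[-nB, , drop = FALSE]) / 2
  total <- 0
  for (i in seq_len(nrow(dA))) {
    r <- sweep(RB, 2, RA[i, ], "-")          # RB - RA_i, per row
    cx <- cbind(dA[i, 2] * dB[, 3] - dA[i, 3] * dB[, 2],
                dA[i, 3] * dB[, 1] - dA[i, 1] * dB[, 3],
                dA[i, 1] * dB[, 2] - dA[i, 2] * dB[, 1])
    d3 <- rowSums(r^2)^1.5
    total <- total - sum(rowSums(cx * r) / d3)  # (RA-RB) dot (dA x dB)
  }
  total / (4 * pi)
}

# per-segment contributions of the second polyline (used for crossing
# localization)
gauss_segment_contrib <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  dA <- A[-1, , drop = FALSE] - A[-nA, , drop = FALSE]
  dB <- B[-1, , drop = FALSE] - B[-nB, , drop = FALSE]
  RA <- (A[-1, , drop = FALSE] + A[-nA, , drop = FALSE]) / 2
  RB <- (B[-1, , drop = FALSE] + B[-nB, , drop = FALSE]) / 2
  contrib <- numeric(nrow(dB))
  for (i in seq_len(nrow(dA))) {
    r <- sweep(RB, 2, RA[i, ], "-")
    cx <- cbind(dA[i, 2] * dB[, 3] - dA[i, 3] * dB[, 2],
                dA[i, 3] * dB[, 1] - dA[i, 1] * dB[, 3],
                dA[i, 1] * dB[, 2] - dA[i, 2] * dB[, 1])
    d3 <- rowSums(r^2)^1.5
    contrib <- contrib - rowSums(cx * r) / d3
  }
  contrib / (4 * pi)
}

close_loop_coords <- function(loop) {
  rbind(loop, loop[1, ])  # append the virtual closure segment back to start
}

#' Gauss linking number between a contact-closed loop and a tail
#'
#' Discrete Gauss double sum over all segment pairs of the loop (closed by a
#' straight virtual segment between its two ends) and the thread polyline.
#'
#' @param loop Coordinate matrix (n x 3, n >= 3) of the loop residues in
#'   chain order; the closure segment from the last row back to the first is
#'   added automatically when `close_loop = TRUE`.
#' @param thread Coordinate matrix (m x 3, m >= 2) of the tail residues.
#' @param close_loop Append the virtual closure segment (default `TRUE`).
#' @return List with `raw` (the Gauss sum) and `rounded` (nearest integer,
#'   half away from zero).
#' @export
linking_number <- function(loop, thread, close_loop = TRUE) {
  loop <- as.matrix(loop); thread <- as.matrix(thread)
  if (nrow(loop) < 3) abort_invalid("loop needs >= 3 segments")
  if (nrow(thread) < 2) abort_invalid("thread needs >= 1 segment")
  if (close_loop) loop <- close_loop_coords(loop)
  raw <- gauss_double_sum(loop, thread)
  list(raw = raw, rounded = as.integer(round_half_away(raw)))
}

# partial linking numbers of contact (i, j) with both terminal tails;
# i, j are row positions in the coordinate matrix
partial_linking <- function(xyz, i, j, tail_excl = 5) {
  loop <- close_loop_coords(xyz[i:j, , drop = FALSE])
  n <- nrow(xyz)
  gN <- if (i - tail_excl - 1 >= 2) {
    gauss_double_sum(loop, xyz[seq_len(i - tail_excl - 1), , drop = FALSE])
  } else 0
  gC <- if (j + tail_excl + 1 <= n - 1) {
    gauss_double_sum(loop, xyz[(j + tail_excl + 1):n, , drop = FALSE])
  } else 0
  list(g_n_raw = gN, g_c_raw = gC,
       g_n = as.integer(round_half_away(gN)),
       g_c = as.integer(round_half_away(gC)))
}

#' Native contact map from a reference structure
#'
#' Residue pairs whose C-alpha distance is at most `cutoff` and whose
#' sequence separation is at least `min_separation`; when a
#' secondary-structure mask is available (on the structure or passed here),
#' both partners must lie inside masked-in elements.
#'
#' @param native A `calpha_structure`.
#' @param cutoff Distance cutoff, Angstrom (default 8).
#' @param min_separation Minimum |i - j| in residues (default 4).
#' @param ss_mask Optional logical per-residue mask overriding the one
#'   stored on the structure.
#' @return A `native_contact_map` tibble with columns `i`, `j` (row
#'   positions in the structure), `res_i`, `res_j`, `dist`.
#' @export
native_contacts <- function(native, cutoff = 8, min_separation = 4,
                            ss_mask = NULL) {
  xyz <- coords_matrix(native)
  n <- nrow(xyz)
  if (is.null(ss_mask)) ss_mask <- attr(native, "ss_mask")
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  sep_ok <- abs(native$residue[pairs[, 2]] - native$residue[pairs[, 1]]) >=
    min_separation
  pairs <- pairs[sep_ok, , drop = FALSE]
  if (!is.null(ss_mask)) {
    keep <- ss_mask[pairs[, 1]] & ss_mask[pairs[, 2]]
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0) abort_invalid("empty native contact map")
  out <- tibble(i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
                res_i = native$residue[pairs[, 1]],
                res_j = native$residue[pairs[, 2]],
                dist = d[pairs])
  out <- dplyr::arrange(out, .data$i, .data$j)
  attr(out, "n_res") <- n
  attr(out, "cutoff") <- cutoff
  attr(out, "min_separation") <- min_separation
  attr(out, "ss_restricted") <- !is.null(ss_mask)
  class(out) <- c("native_contact_map", class(out))
  out
}

#' Fraction of native contacts formed in a frame
#'
#' A native contact counts as formed when its current C-alpha distance is at
#' most `tolerance_factor` times its native distance.
#'
#' @param frame A `calpha_structure` with the same chain length as the
#'   native reference.
#' @param map A [native_contacts()] map.
#' @param tolerance_factor Formed-contact tolerance (default 1.2).
#' @return Q in \[0, 1\].
#' @export
q_frame <- function(frame, map, tolerance_factor = 1.2) {
  xyz <- coords_matrix(frame)
  n_ref <- attr(map, "n_res")
  if (!is.null(n_ref) && nrow(xyz) != n_ref) {
    abort_invalid("frame has %d residues but the contact map expects %d",
                  nrow(xyz), n_ref)
  }
  cur <- sqrt(rowSums((xyz[map$i, , drop = FALSE] -
                         xyz[map$j, , drop = FALSE])^2))
  mean(cur <= tolerance_factor * map$dist)
}

#' Windowed-mode Q series and long-lived misfold classification
#'
#' Computes the mode of Q inside a sliding window (stride one frame), with
#' Q binned so that each formable-contact count is its own bin, and calls a
#' trajectory long-lived misfolded when no window mode ever reaches the
#' native-ensemble reference.
#'
#' @param q Numeric vector of per-frame Q values.
#' @param window Window length in frames (<= length of the series); chosen
#'   to correspond to the 15-ns averaging window at the trajectory's frame
#'   spacing.
#' @param reference Mean windowed-mode Q of the native-state ensemble.
#' @param n_contacts Number of native contacts (sets the bin width `1 /
#'   n_contacts`).
#' @return A `q_mode_series` tibble with `window_start` and `q_mode`;
#'   attributes `verdict` (`"long-lived misfolded"` or `"folded"`) and
#'   `reference`.
#' @export
q_mode <- function(q, window, reference, n_contacts) {
  if (is.null(reference) || is.na(reference)) {
    abort_invalid("native-ensemble reference is unset")
  }
  nq <- length(q)
  if (window > nq) abort_invalid("window longer than series")
  bins <- round(q * n_contacts)
  starts <- seq_len(nq - window + 1L)
  modes <- vapply(starts, function(s) {
    tab <- tabulate(bins[s:(s + window - 1L)] + 1L)
    (which.max(tab) - 1L) / n_contacts
  }, numeric(1))
  out <- tibble(window_start = starts, q_mode = modes)
  attr(out, "reference") <- reference
  attr(out, "verdict") <- if (max(modes) < reference) {
    "long-lived misfolded"
  } else "folded"
  class(out) <- c("q_mode_series", class(out))
  out
}

classify_change <- function(g_native, g_current) {
  if (g_native == g_current) "none"
  else if (abs(g_current) > abs(g_native)) "gain"
  else if (abs(g_current) < abs(g_native)) "loss"
  else "switch"
}

#' Entanglement change metric G between a frame and the native state
#'
#' Over the native contacts that are formed in the current structure, counts
#' those whose total rounded linking number (N-tail plus C-tail partials)
#' differs from the native structure's, normalized by the total number of
#' native contacts:
#' \deqn{G = \frac{1}{N}\sum_{(i,j)} \Theta\left((i,j) \in nc \cap g(i,j)
#'   \neq g^{native}(i,j)\right)}
#' One record is emitted per discordant contact; crossing residues are
#' localized on the structure in which the entanglement is present (the
#' frame for a gain, the native structure for a loss).
#'
#' @param frame,native `calpha_structure`s of equal length.
#' @param map [native_contacts()] of the native structure.
#' @param tolerance_factor Formed-contact tolerance (default 1.2).
#' @param tail_excl Residues adjacent to each loop terminus excluded from
#'   the tails (default 5).
#' @return A `g_metric_result` list: `G`, `n_changed`, `n_contacts`, and
#'   `records` (one row per discordant contact: contact indices, raw and
#'   rounded partials in both structures, totals, change types, loop length,
#'   crossing residues).
#' @export
g_metric <- function(frame, native, map, tolerance_factor = 1.2,
                     tail_excl = 5) {
  if (nrow(frame) != nrow(native)) abort_invalid("chain length mismatch")
  xyz_f <- coords_matrix(frame)
  xyz_n <- coords_matrix(native)
  cur <- sqrt(rowSums((xyz_f[map$i, , drop = FALSE] -
                         xyz_f[map$j, , drop = FALSE])^2))
  formed <- cur <= tolerance_factor * map$dist
  recs <- list()
  n_changed <- 0L
  for (k in which(formed)) {
    i <- map$i[k]; j <- map$j[k]
    pf <- partial_linking(xyz_f, i, j, tail_excl)
    pn <- partial_linking(xyz_n, i, j, tail_excl)
    g_cur <- pf$g_n + pf$g_c
    g_nat <- pn$g_n + pn$g_c
    if (g_cur != g_nat) {
      n_changed <- n_changed + 1L
      type_n <- classify_change(pn$g_n, pf$g_n)
      type_c <- classify_change(pn$g_c, pf$g_c)
      cross <- locate_crossings(xyz_f, xyz_n, i, j, pf, pn, tail_excl)
      recs[[length(recs) + 1L]] <- tibble(
        i = i, j = j, g_native = g_nat, g_current = g_cur,
        g_n_raw = pf$g_n_raw, g_c_raw = pf$g_c_raw,
        g_n = pf$g_n, g_c = pf$g_c,
        g_n_native = pn$g_n, g_c_native = pn$g_c,
        change_type_n = type_n, change_type_c = type_c,
        n_crossings_n = length(cross$n_tail),
        n_crossings_c = length(cross$c_tail),
        crossings_n = list(cross$n_tail), crossings_c = list(cross$c_tail),
        loop_length = j - i)
    }
  }
  records <- if (length(recs)) dplyr::bind_rows(recs) else tibble()
  structure(list(G = n_changed / nrow(map), n_changed = n_changed,
                 n_contacts = nrow(map), records = records),
            class = "g_metric_result")
}

# crossings for a discordant contact, per tail, on the structure where the
# entanglement is present (gain -> current frame, loss -> native)
locate_crossings <- function(xyz_f, xyz_n, i, j, pf, pn, tail_excl) {
  pick <- function(g_f, g_n) if (abs(g_f) >= abs(g_n)) xyz_f else xyz_n
  n_res <- nrow(xyz_f)
  out <- list(n_tail = integer(0), c_tail = integer(0))
  if (pf$g_n != pn$g_n) {
    xyz <- pick(pf$g_n, pn$g_n)
    tail_idx <- seq_len(i - tail_excl - 1)
    if (length(tail_idx) >= 2) {
      out$n_tail <- tryCatch(
        crossing_residues(xyz[i:j, , drop = FALSE],
                          xyz[tail_idx, , drop = FALSE],
                          residue_ids = tail_idx),
        error = function(e) integer(0))
    }
  }
  if (pf$g_c != pn$g_c) {
    xyz <- pick(pf$g_c, pn$g_c)
    tail_idx <- (j + tail_excl + 1):n_res
    if (tail_idx[1] <= n_res - 1) {
      out$c_tail <- tryCatch(
        crossing_residues(xyz[i:j, , drop = FALSE],
                          xyz[tail_idx, , drop = FALSE],
                          residue_ids = tail_idx),
        error = function(e) integer(0))
    }
  }
  out
}

#' Tail residues piercing a contact-closed loop
#'
#' Localizes the crossing to the tail segments carrying the dominant
#' per-segment Gauss contribution, one per unit of the rounded linking
#' number (an approximation to surface-triangulation piercing detection;
#' selected segments are kept at least two apart so multiple threadings
#' resolve to distinct residues).
#'
#' @param loop Loop coordinates (chain order; closure added internally).
#' @param thread Tail coordinates.
#' @param residue_ids Residue ids of the tail rows (default 1..m).
#' @return Integer residue ids of the piercing tail residues.
#' @export
crossing_residues <- function(loop, thread, residue_ids = NULL) {
  loop <- as.matrix(loop); thread <- as.matrix(thread)
  lk <- linking_number(loop, thread)
  n_cross <- abs(lk$rounded)
  if (n_cross < 1) {
    abort_invalid("loop and thread are unlinked; no crossing to localize")
  }
  contrib <- gauss_segment_contrib(close_loop_coords(loop), thread)
  if (is.null(residue_ids)) residue_ids <- seq_len(nrow(thread))
  ord <- order(-abs(contrib))
  chosen <- integer(0)
  for (s in ord) {
    if (length(chosen) == n_cross) break
    if (all(abs(chosen - s) >= 2)) chosen <- c(chosen, s)
  }
  sort(residue_ids[chosen])
}

#' Cluster degenerate entanglement changes
#'
#' Records are merged when they agree on all six discrete descriptors
#' (number of crossings and rounded partial linking number for each tail,
#' and the change type for each tail) and every pair of corresponding
#' crossing residues lies within `residue_window` of each other (connected
#' components of that relation). Each cluster is represented by the record
#' with the minimal loop length, ties broken by the smaller loop start.
#'
#' @param records The `records` tibble from [g_metric()] (non-empty).
#' @param residue_window Crossing-residue merge window (default 5).
#' @return List with `clusters` (the records plus a `cluster` column) and
#'   `representatives` (one row per cluster).
#' @export
cluster_entanglements <- function(records, residue_window = 5) {
  if (is.null(records) || nrow(records) == 0) {
    abort_invalid("no entanglement records to cluster")
  }
  n <- nrow(records)
  key <- paste(records$n_crossings_n, records$n_crossings_c,
               records$g_n, records$g_c,
               records$change_type_n, records$change_type_c)
  all_cross <- function(k) sort(c(records$crossings_n[[k]],
                                  records$crossings_c[[k]]))
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (key[a] == key[b]) {
      ca <- all_cross(a); cb <- all_cross(b)
      adj[a, b] <- length(ca) == length(cb) &&
        (length(ca) == 0 || all(abs(ca - cb) <= residue_window))
    }
  }
  cluster <- integer(n)
  cur <- 0L
  for (a in seq_len(n)) {
    if (cluster[a] == 0L) {
      cur <- cur + 1L
      frontier <- a
      while (length(frontier)) {
        cluster[frontier] <- cur
        frontier <- which(cluster == 0L &
                            apply(adj[, frontier, drop = FALSE], 1, any))
      }
    }
  }
  records$cluster <- cluster
  reps <- records |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(.data$loop_length, .data$i, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  list(clusters = records, representatives = reps)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-point accessibility: each residue bead is covered with `n_points`
#' golden-spiral points at radius `r + probe`; a point is accessible when it
#' falls outside every neighbouring bead's probe-expanded sphere.
#'
#' @param structure A `calpha_structure`.
#' @param radii Per-residue bead radii, Angstrom (scalar or vector).
#' @param probe Probe radius, Angstrom (default 1.4, water).
#' @param n_points Sample points per sphere (default 960).
#' @return Tibble with `residue` and `sasa` (square Angstrom).
#' @export
sasa <- function(structure, radii = 3.0, probe = 1.4, n_points = 960) {
  if (probe < 0) abort_invalid("probe radius must be >= 0")
  xyz <- coords_matrix(structure)
  n <- nrow(xyz)
  radii <- rep(radii, length.out = n)
  # golden-spiral unit sphere points
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  unit <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  d2 <- as.matrix(stats::dist(xyz))^2
  out <- numeric(n)
  for (a in seq_len(n)) {
    ra <- radii[a] + probe
    nb <- which(d2[a, ] < (ra + max(radii) + probe)^2 & seq_len(n) != a)
    pts <- sweep(unit * ra, 2, xyz[a, ], "+")
    acc <- rep(TRUE, n_points)
    for (b in nb) {
      rb2 <- (radii[b] + probe)^2
      acc <- acc & (rowSums(sweep(pts, 2, xyz[b, ], "-")^2) >= rb2)
      if (!any(acc)) break
    }
    out[a] <- sum(acc) / n_points * 4 * pi * ra^2
  }
  tibble(residue = structure$residue, sasa = out)
}

#' Per-residue change in solvent accessibility between two structures
#'
#' @param structure_a,structure_b `calpha_structure`s with matching residue
#'   ids (typically misfolded vs native).
#' @param radii,probe,n_points Passed to [sasa()].
#' @return Tibble with `residue` and `delta_sasa` (`a` minus `b`).
#' @export
delta_sasa <- function(structure_a, structure_b, radii = 3.0, probe = 1.4,
                       n_points = 960) {
  sa <- sasa(structure_a, radii, probe, n_points)
  sb <- sasa(structure_b, radii, probe, n_points)
  m <- dplyr::inner_join(sa, sb, by = "residue",
                         suffix = c("_a", "_b"))
  tibble(residue = m$residue, delta_sasa = m$sasa_a - m$sasa_b)
}

#' Hydrophobic SASA subtotal
#'
#' @param sasa_tbl Output of [sasa()].
#' @param hydrophobic_residues Residue ids belonging to the hydrophobic set.
#' @return Summed area over the hydrophobic residues, square Angstrom.
#' @export
hydrophobic_sasa <- function(sasa_tbl, hydrophobic_residues) {
  sum(sasa_tbl$sasa[sasa_tbl$residue %in% hydrophobic_residues])
}
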