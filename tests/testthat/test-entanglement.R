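straight_chain <- function(n, spacing = 3.8) {
  calpha_structure(tibble::tibble(residue = seq_len(n),
                                  x = spacing * (seq_len(n) - 1),
                                  y = 0, z = 0), synthetic = TRUE)
}

test_that("native contact maps honour cutoff, separation, and masks", {
  # residues 1 and 6 placed 7.9 apart; 1 and 4 within cutoff but |i-j| = 3
  s <- calpha_structure(tibble::tibble(
    residue = 1:6,
    x = c(0, 3.8, 7.6, 3.8, 0, 0),
    y = c(0, 0, 0, 3, 3, 7.9),
    z = 0), synthetic = TRUE)
  map <- native_contacts(s, cutoff = 8, min_separation = 4)
  expect_true(any(map$i == 1 & map$j == 6))
  expect_false(any(map$i == 1 & map$j == 4))
  # masking out one partner of every contact empties the map
  mask <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  expect_error(native_contacts(s, 8, 4, ss_mask = mask), "empty")
})

test_that("fraction of native contacts is 1 at home, 0 extended, monotone", {
  toy <- toy_fixture()
  nat <- toy$native
  map <- toy$map
  expect_equal(q_frame(nat, map), 1)
  ext <- straight_chain(nrow(nat))
  expect_equal(q_frame(ext, map), 0)
  # constructed fixture: displace half the contacts beyond tolerance
  s <- straight_chain(30)
  s$y <- c(rep(0, 15), rep(0, 15))
  m2 <- tibble::tibble(i = c(1L, 2L, 3L, 4L), j = c(6L, 7L, 8L, 9L),
                       res_i = c(1L, 2L, 3L, 4L), res_j = c(6L, 7L, 8L, 9L),
                       dist = rep(5 * 3.8, 4))
  class(m2) <- c("native_contact_map", class(m2))
  frame <- s
  frame$x[8:9] <- frame$x[8:9] + 100  # breaks contacts (3,8) and (4,9)
  expect_equal(q_frame(frame, m2), 0.5)
})

test_that("windowed Q modes classify long-lived misfolding", {
  const <- q_mode(rep(0.8, 50), window = 10, reference = 0.92,
                  n_contacts = 10)
  expect_true(all(const$q_mode == 0.8))
  expect_identical(attr(const, "verdict"), "long-lived misfolded")
  reaching <- q_mode(c(rep(0.8, 30), rep(0.95, 20)), window = 10,
                     reference = 0.92, n_contacts = 20)
  expect_identical(attr(reaching, "verdict"), "folded")
  # binned mode of a 70/30 bimodal window
  qs <- c(rep(0.9, 7), rep(0.6, 3))
  bi <- q_mode(qs, window = 10, reference = 0.99, n_contacts = 10)
  expect_equal(bi$q_mode[1], 0.9)
  expect_error(q_mode(rep(0.5, 5), 10, 0.9, 10), "window")
  expect_error(q_mode(rep(0.5, 5), 2, NA, 10), "reference")
})

test_that("discrete linking numbers agree with the exact-segment oracle", {
  toy <- toy_fixture()
  loop <- coords_of(toy$misfolded, 1:toy$loop_contact[2])
  thread <- coords_of(toy$misfolded, toy$thread_residues)
  lk <- linking_number(loop, thread)
  expect_identical(lk$rounded, 1L)
  expect_lt(abs(lk$raw - oracle_gauss_link(loop, thread)), 0.05)
  # polygonal circle + axial segment also has a closed form
  theta <- seq(0, 2 * pi, length.out = 41)[-41]
  circ <- cbind(10 * cos(theta), 10 * sin(theta), 0)
  seg <- cbind(0, 0, seq(-40, 40, by = 4))
  lk2 <- linking_number(circ, seg)
  expect_equal(lk2$raw, oracle_circle_axis(10, -40, 40), tolerance = 0.01)
  expect_identical(lk2$rounded, 1L)
})

test_that("linking numbers are invariant under rigid motions", {
  toy <- toy_fixture()
  loop <- coords_of(toy$misfolded, 1:toy$loop_contact[2])
  thread <- coords_of(toy$misfolded, toy$thread_residues)
  base <- linking_number(loop, thread)$raw
  ang <- c(0.3, -1.1, 2.0)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  rot <- function(m) sweep(m %*% t(Rx %*% Rz), 2, c(5, -3, 12), "+")
  expect_lt(abs(linking_number(rot(loop), rot(thread))$raw - base), 1e-9)
})

test_that("the G metric is 0 at home, 1/N for one changed contact, 0 with no formed contacts", {
  toy <- toy_fixture()
  nat <- toy$native
  mis <- toy$misfolded
  # native against itself
  g0 <- g_metric(nat, nat, toy$map)
  expect_equal(g0$G, 0)
  # map with the loop contact plus two thread-side contacts that never
  # change their (zero) linking: G = 1/3
  tr <- toy$thread_residues
  extra_pairs <- cbind(tr[c(2, 8)], tr[c(6, 12)])
  d_extra <- sqrt(rowSums((coords_of(nat, extra_pairs[, 1]) -
                             coords_of(nat, extra_pairs[, 2]))^2))
  map3 <- tibble::tibble(
    i = c(toy$map$i, extra_pairs[, 1]), j = c(toy$map$j, extra_pairs[, 2]),
    res_i = c(toy$map$res_i, extra_pairs[, 1]),
    res_j = c(toy$map$res_j, extra_pairs[, 2]),
    dist = c(toy$map$dist, d_extra))
  class(map3) <- c("native_contact_map", class(map3))
  gm <- g_metric(mis, nat, map3)
  expect_equal(gm$G, 1 / 3)
  expect_equal(gm$records$g_current[1], 1)
  expect_equal(gm$records$g_native[1], 0)
  # blowing the frame apart leaves no formed contacts: empty sum, G = 0
  blown <- mis
  blown[, c("x", "y", "z")] <- blown[, c("x", "y", "z")] * 10
  expect_equal(g_metric(blown, nat, map3)$G, 0)
})

test_that("G is invariant under rigid motions of the frame", {
  toy <- toy_fixture()
  mis <- toy$misfolded
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  xyz <- coords_of(mis) %*% t(R)
  moved <- mis
  moved$x <- xyz[, 1] + 3; moved$y <- xyz[, 2] - 8; moved$z <- xyz[, 3] + 1
  expect_equal(g_metric(moved, toy$native, toy$map)$G,
               g_metric(mis, toy$native, toy$map)$G)
})

test_that("crossing residues localize single and double threadings", {
  toy <- toy_fixture()
  loop <- coords_of(toy$misfolded, 1:toy$loop_contact[2])
  thread <- coords_of(toy$misfolded, toy$thread_residues)
  cr <- crossing_residues(loop, thread, residue_ids = toy$thread_residues)
  expect_length(cr, 1)
  # the crossing segment sits where the thread pierces the loop plane (z=0)
  z_at <- toy$misfolded$z[match(cr, toy$misfolded$residue)]
  expect_lt(abs(z_at), 8)
  # double threading: up through the loop, around the outside, up again
  up1 <- cbind(0, 0, seq(-30, 30, by = 4))
  over <- cbind(seq(4, 28, by = 4), 0, 30)
  down <- cbind(28, 0, seq(26, -30, by = -4))
  back <- cbind(seq(24, 8, by = -4), 0, -30)
  up2 <- cbind(5, 0, seq(-26, 30, by = 4))
  th2 <- rbind(up1, over, down, back, up2)
  theta <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- cbind(12 * cos(theta), 12 * sin(theta), 0)
  lk <- linking_number(circ, th2)
  expect_identical(abs(lk$rounded), 2L)
  cr2 <- crossing_residues(circ, th2)
  expect_length(cr2, 2)
  expect_gt(abs(diff(cr2)), 2)
  # unlinked pair errors
  far <- sweep(thread, 2, c(500, 0, 0), "+")
  expect_error(crossing_residues(loop, far), "unlinked")
})

test_that("degenerate entanglements cluster by descriptor and crossing window", {
  rec <- function(i, j, gn, gc, tn, tc, crossings, loop_len) {
    tibble::tibble(i = i, j = j, g_native = 0, g_current = gn + gc,
                   g_n_raw = gn, g_c_raw = gc, g_n = gn, g_c = gc,
                   g_n_native = 0, g_c_native = 0,
                   change_type_n = tn, change_type_c = tc,
                   n_crossings_n = 0L, n_crossings_c = length(crossings),
                   crossings_n = list(integer(0)),
                   crossings_c = list(crossings),
                   loop_length = loop_len)
  }
  two_same <- dplyr::bind_rows(rec(1, 20, 0, 1, "none", "gain", 50L, 19),
                               rec(2, 21, 0, 1, "none", "gain", 52L, 19))
  cl <- cluster_entanglements(two_same)
  expect_identical(max(cl$clusters$cluster), 1L)
  # crossings 6 apart split
  split6 <- dplyr::bind_rows(rec(1, 20, 0, 1, "none", "gain", 50L, 19),
                             rec(2, 21, 0, 1, "none", "gain", 56L, 19))
  expect_identical(max(cluster_entanglements(split6)$clusters$cluster), 2L)
  # minimal-loop representative
  trio <- dplyr::bind_rows(rec(1, 41, 0, 1, "none", "gain", 50L, 40),
                           rec(5, 30, 0, 1, "none", "gain", 51L, 25),
                           rec(2, 62, 0, 1, "none", "gain", 52L, 60))
  reps <- cluster_entanglements(trio)$representatives
  expect_identical(nrow(reps), 1L)
  expect_identical(reps$loop_length, 25)
  expect_error(cluster_entanglements(tibble::tibble()), "no entanglement")
})

test_that("Shrake-Rupley areas match closed forms and bury caged beads", {
  lone <- straight_chain(1)
  a <- sasa(lone, radii = 3, probe = 1.4, n_points = 960)$sasa
  expect_lt(abs(a - 4 * pi * 4.4^2) / (4 * pi * 4.4^2), 0.01)
  # bead enclosed by a dense cage is inaccessible
  k <- 1:80 - 0.5
  phi <- acos(1 - 2 * k / 80)
  th <- pi * (1 + sqrt(5)) * k
  cage <- cbind(5 * sin(phi) * cos(th), 5 * sin(phi) * sin(th), 5 * cos(phi))
  caged <- calpha_structure(tibble::tibble(
    residue = 1:81, x = c(0, cage[, 1]), y = c(0, cage[, 2]),
    z = c(0, cage[, 3])), synthetic = TRUE)
  out <- sasa(caged, radii = 3, probe = 1.4)
  expect_lt(out$sasa[1], 1)
  # identical structures: zero exposure change everywhere
  toy <- toy_fixture()
  dzero <- delta_sasa(toy$native, toy$native)
  expect_true(all(dzero$delta_sasa == 0))
  expect_error(sasa(lone, radii = 3, probe = -1), "probe")
})

test_that("Q decreases monotonically as contacts are displaced", {
  s <- straight_chain(20)
  m <- tibble::tibble(i = 1:4, j = 6:9, res_i = 1:4, res_j = 6:9,
                      dist = rep(5 * 3.8, 4))
  class(m) <- c("native_contact_map", class(m))
  qs <- vapply(0:4, function(k) {
    frame <- s
    if (k > 0) frame$x[6:(5 + k)] <- frame$x[6:(5 + k)] + 100
    q_frame(frame, m)
  }, numeric(1))
  expect_true(all(diff(qs) <= 0))
  expect_equal(qs[1], 1)
  expect_equal(qs[5], 0)
})
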