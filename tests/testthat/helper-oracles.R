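# Independent oracles, kept separate from the package's own algorithms.

# Exact Gauss linking integral between two straight segments via the
# Klenin-Langowski solid-angle formula; summed over all segment pairs this
# evaluates the continuum Gauss double integral exactly for polylines,
# providing an oracle independent of the package's midpoint discretization.
oracle_segment_pair <- function(p1, p2, p3, p4) {
  r12 <- p2 - p1; r34 <- p4 - p3
  r13 <- p3 - p1; r14 <- p4 - p1
  r23 <- p3 - p2; r24 <- p4 - p2
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) return(NULL)
    v / n
  }
  n1 <- unit(cross3(r13, r14)); n2 <- unit(cross3(r14, r24))
  n3 <- unit(cross3(r24, r23)); n4 <- unit(cross3(r23, r13))
  if (is.null(n1) || is.null(n2) || is.null(n3) || is.null(n4)) return(0)
  clamp <- function(x) min(1, max(-1, x))
  omega <- asin(clamp(sum(n1 * n2))) + asin(clamp(sum(n2 * n3))) +
    asin(clamp(sum(n3 * n4))) + asin(clamp(sum(n4 * n1)))
  s <- sign(sum(cross3(r34, r12) * r13))
  omega * s / (4 * pi)
}

oracle_gauss_link <- function(loop, thread, close_loop = TRUE) {
  loop <- as.matrix(loop)
  if (close_loop) loop <- rbind(loop, loop[1, ])
  thread <- as.matrix(thread)
  total <- 0
  for (i in seq_len(nrow(loop) - 1)) {
    for (j in seq_len(nrow(thread) - 1)) {
      total <- total + oracle_segment_pair(loop[i, ], loop[i + 1, ],
                                           thread[j, ], thread[j + 1, ])
    }
  }
  total
}

# closed form: linking integral of a circle of radius R in the z = 0 plane
# (centered at the origin) with the axial segment from z1 to z2
oracle_circle_axis <- function(R, z1, z2) {
  0.5 * (z2 / sqrt(z2^2 + R^2) - z1 / sqrt(z1^2 + R^2))
}

# direct unit-conversion dissociation-constant oracle
oracle_kd <- function(p_complex, volume_A3) {
  p_unbound <- 1 - p_complex
  per_A3 <- (p_unbound * p_unbound / p_complex) / volume_A3   # 1 / A^3
  per_A3 / (6.022e23 * 1e-27)                                 # mol / L
}
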