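# Consistency between predicted entangled conformations and LiP-MS
# evidence: binary overlap (O) and sign-agreement (S) matrices, their
# per-timepoint means, and a permutation null drawn from a theoretical
# half-tryptic peptide distribution.

peptide_window <- function(cut_site, protein_length, cut_window = 5) {
  seq(max(1L, cut_site - cut_window), min(protein_length, cut_site + cut_window))
}

entanglement_residue_sets <- function(records, structure,
                                      crossing_radius = 8) {
  if (nrow(records) == 0) abort_invalid("no entanglement records supplied")
  xyz <- coords_matrix(structure)
  d <- as.matrix(stats::dist(xyz))
  lapply(seq_len(nrow(records)), function(k) {
    cross <- c(records$crossings_n[[k]], records$crossings_c[[k]])
    if (length(cross) == 0) {
      abort_invalid("entanglement record %d has no crossing residues", k)
    }
    rows <- match(cross, structure$residue)
    near <- which(apply(d[rows, , drop = FALSE] <= crossing_radius, 2, any))
    sort(structure$residue[near])
  })
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 0 else length(intersect(a, b)) / u
}

#' Overlap matrix between entanglements and LiP-MS cut sites
#'
#' For each representative entanglement `e` (residues within
#' `crossing_radius` Angstrom of its crossing residues, by C-alpha distance
#' in `structure`) and each significant peptide `l` (residues within
#' `cut_window` of its PK cut site), `O[e, l] = 1` iff the Jaccard index of
#' the two residue sets is positive.
#'
#' @param records Representative entanglement records (from [g_metric()] /
#'   [cluster_entanglements()]), with crossing residues.
#' @param peptides LiP-MS peptide tibble (`cut_site`, `log2_ratio`,
#'   `timepoint`, `significant`); only significant rows are used.
#' @param structure The `calpha_structure` supplying distances (which
#'   structure is used is an explicit choice, typically the representative
#'   misfolded conformation).
#' @param cut_window Half-width of the cut-site window (default 5).
#' @param crossing_radius Crossing neighbourhood radius, Angstrom (default 8).
#' @return Binary matrix (entanglements x peptides) with the Jaccard values
#'   in attribute `jaccard` and the filtered peptides in attribute
#'   `peptides`.
#' @export
overlap_matrix <- function(records, peptides, structure, cut_window = 5,
                           crossing_radius = 8) {
  peptides <- dplyr::filter(as_tibble(peptides), .data$significant)
  if (nrow(peptides) == 0) abort_invalid("no significant peptides")
  sets_e <- entanglement_residue_sets(records, structure, crossing_radius)
  L <- max(structure$residue)
  sets_l <- lapply(peptides$cut_site, peptide_window, protein_length = L,
                   cut_window = cut_window)
  J <- outer(seq_along(sets_e), seq_along(sets_l),
             Vectorize(function(e, l) jaccard(sets_e[[e]], sets_l[[l]])))
  O <- (J > 0) * 1L
  attr(O, "jaccard") <- J
  attr(O, "peptides") <- peptides
  O
}

#' Sign-agreement matrix gated by overlap
#'
#' `S[e, l] = 1` when `O[e, l] = 1` and the sign of the simulated change in
#' solvent exposure at the cut site matches the sign of the experimental
#' log2 refolded/native abundance ratio. A zero on either side agrees with
#' nothing.
#'
#' @param O Output of [overlap_matrix()].
#' @param delta_sasa_sim Simulated solvent-exposure change per peptide
#'   (vector, one per column of `O`) or per (entanglement, peptide) matrix.
#' @param log2_ratios Experimental log2 R/N per peptide; defaults to the
#'   `log2_ratio` column of the peptides attached to `O`.
#' @return Binary matrix of the same shape as `O`.
#' @export
sign_matrix <- function(O, delta_sasa_sim, log2_ratios = NULL) {
  if (is.null(log2_ratios)) log2_ratios <- attr(O, "peptides")$log2_ratio
  if (is.matrix(delta_sasa_sim)) {
    if (!all(dim(delta_sasa_sim) == dim(O))) abort_invalid("shape mismatch")
    ds <- delta_sasa_sim
  } else {
    if (length(delta_sasa_sim) != ncol(O)) {
      abort_invalid("need one delta-SASA value per peptide")
    }
    ds <- matrix(delta_sasa_sim, nrow(O), ncol(O), byrow = TRUE)
  }
  if (any(O == 1 & is.na(ds))) {
    abort_invalid("delta-SASA missing for an overlapping (e, l) pair")
  }
  rs <- matrix(sign(log2_ratios), nrow(O), ncol(O), byrow = TRUE)
  S <- (O == 1 & !is.na(ds) & sign(ds) != 0 & sign(ds) == rs) * 1L
  attr(S, "peptides") <- attr(O, "peptides")
  S
}

#' Per-timepoint consistency statistics
#'
#' Means of the overlap and sign matrices restricted to each timepoint's
#' peptides.
#'
#' @param O,S Matrices from [overlap_matrix()] and [sign_matrix()].
#' @param timepoints Timepoint label per peptide; defaults to the peptides
#'   attached to `O`.
#' @return Tibble with `timepoint`, `o_stat`, `s_stat`, `n_peptides`.
#' @export
consistency_stats <- function(O, S, timepoints = NULL) {
  if (length(O) == 0) abort_invalid("empty matrices")
  if (is.null(timepoints)) timepoints <- attr(O, "peptides")$timepoint
  tps <- unique(timepoints)
  dplyr::bind_rows(lapply(tps, function(tp) {
    cols <- which(timepoints == tp)
    tibble(timepoint = tp,
           o_stat = mean(O[, cols, drop = FALSE]),
           s_stat = mean(S[, cols, drop = FALSE]),
           n_peptides = length(cols))
  }))
}

#' Average simulated exposure change around each cut site
#'
#' @param delta_sasa_res Per-residue exposure differences (misfolded minus
#'   native), as returned by [delta_sasa()].
#' @param cut_sites Cut-site residues.
#' @param protein_length Protein length.
#' @param cut_window Window half-width (default 5; the window, rather than
#'   the bare cut site, is the default residue set entering the average).
#' @return Numeric vector, one mean delta-SASA per cut site.
#' @export
cutsite_delta_sasa <- function(delta_sasa_res, cut_sites, protein_length,
                               cut_window = 5) {
  vapply(cut_sites, function(s) {
    win <- peptide_window(s, protein_length, cut_window)
    mean(delta_sasa_res$delta_sasa[delta_sasa_res$residue %in% win])
  }, numeric(1))
}

#' Intrinsic proteinase-K cut-site propensity model
#'
#' Per residue type, the intrinsic cut probability is the observed cut
#' frequency divided by the proteome frequency,
#' \eqn{P_{intrinsic}(AA) = P_{observed}(AA) / P_{proteome}(AA)}; types
#' absent from the proteome are excluded with a warning rather than
#' producing infinities. An optional joint table of peptide length and
#' internal trypsin-site count captures the differential digestion times of
#' the two proteases.
#'
#' @param observed_aa Residue types at the observed PK cut sites.
#' @param proteome Tibble with `aa` and `freq` (summing to 1).
#' @param length_table Optional tibble `length`, `n_tryp`, `prob`.
#' @return A `cutsite_model` list: `p_observed`, `p_proteome`,
#'   `p_intrinsic` (named by residue type), `length_table`.
#' @export
build_cutsite_model <- function(observed_aa, proteome, length_table = NULL) {
  if (length(observed_aa) == 0) abort_invalid("empty observed cut-site set")
  proteome <- as_tibble(proteome)
  p_prot <- setNames(proteome$freq, proteome$aa)
  if (abs(sum(p_prot) - 1) > 1e-6) {
    abort_invalid("proteome frequencies must sum to 1")
  }
  p_obs <- table(factor(observed_aa, levels = names(p_prot)))
  p_obs <- setNames(as.numeric(p_obs) / length(observed_aa), names(p_prot))
  zero <- p_prot == 0 & p_obs > 0
  if (any(zero)) {
    warning("residue type(s) absent from proteome excluded: ",
            paste(names(p_prot)[zero], collapse = ", "), call. = FALSE)
  }
  p_int <- ifelse(p_prot > 0, p_obs / p_prot, NA_real_)
  structure(list(p_observed = p_obs, p_proteome = p_prot,
                 p_intrinsic = p_int, length_table = length_table),
            class = "cutsite_model")
}

#' Enumerate candidate half-tryptic peptides of a sequence
#'
#' Every residue is a potential PK cut site; each site yields up to two
#' half-tryptic peptides, extending to the nearest trypsin boundary (after
#' a K/R) downstream and upstream (or the chain ends).
#'
#' @param sequence Character vector of one-letter residue codes.
#' @return Tibble: `cut_site`, `start`, `end`, `aa` (cut-site residue
#'   type), `length`, `n_tryp` (internal trypsin sites).
#' @export
enumerate_half_tryptic <- function(sequence) {
  L <- length(sequence)
  tryp <- which(sequence %in% c("K", "R"))
  cs <- rep(seq_len(L), each = 2L)
  starts <- integer(2L * L); ends <- integer(2L * L)
  for (s in seq_len(L)) {
    nxt <- tryp[tryp >= s]; prv <- tryp[tryp < s]
    # downstream peptide: PK end at s, trypsin end after the next K/R
    starts[2 * s - 1] <- s
    ends[2 * s - 1] <- if (length(nxt)) nxt[1] else L
    # upstream peptide: trypsin start after the previous K/R, PK end at s
    starts[2 * s] <- if (length(prv)) prv[length(prv)] + 1L else 1L
    ends[2 * s] <- s
  }
  out <- dplyr::distinct(tibble(cut_site = cs, start = starts, end = ends))
  out$aa <- sequence[out$cut_site]
  out$length <- out$end - out$start + 1L
  out$n_tryp <- vapply(seq_len(nrow(out)), function(k) {
    sum(tryp > out$start[k] & tryp < out$end[k])
  }, integer(1))
  out
}

candidate_accept_probs <- function(candidates, model) {
  p1 <- model$p_intrinsic[candidates$aa]
  p1[is.na(p1)] <- 0
  mx <- max(p1)
  if (mx == 0) abort_invalid("all intrinsic acceptance probabilities are 0")
  p1 <- p1 / mx  # scaled to a valid acceptance probability
  p2 <- rep(1, nrow(candidates))
  if (!is.null(model$length_table)) {
    lt <- model$length_table
    key <- paste(candidates$length, candidates$n_tryp)
    p2 <- lt$prob[match(key, paste(lt$length, lt$n_tryp))]
    p2[is.na(p2)] <- 0
    if (max(p2) > 0) p2 <- p2 / max(p2)
  }
  list(p1 = as.numeric(p1), p2 = p2)
}

#' Draw a random set of PK cut sites from the theoretical distribution
#'
#' Rejection sampling as in the null construction: candidate half-tryptic
#' peptides are chosen uniformly with replacement; a candidate is accepted
#' when two independent uniforms fall below its (scaled) intrinsic cut-site
#' probability and its length/trypsin-count probability, and its cut site
#' is added if not already present, until `n_sites` unique sites are held.
#'
#' @param model A [build_cutsite_model()].
#' @param sequence Protein sequence (one-letter codes).
#' @param n_sites Number of unique cut sites to draw.
#' @param seed Integer seed.
#' @param candidates Optional precomputed [enumerate_half_tryptic()] table.
#' @param max_iter Iteration guard (default 1e6).
#' @return Sorted integer vector of `n_sites` unique cut-site residues.
#' @export
sample_random_cutsites <- function(model, sequence, n_sites, seed = 1L,
                                   candidates = NULL, max_iter = 1e6) {
  if (is.null(candidates)) candidates <- enumerate_half_tryptic(sequence)
  if (n_sites > length(unique(candidates$cut_site))) {
    abort_invalid("n_sites exceeds the number of candidate cut sites")
  }
  pr <- candidate_accept_probs(candidates, model)
  K <- nrow(candidates)
  with_seed(seed, {
    sites <- integer(0)
    iter <- 0
    while (length(sites) < n_sites) {
      iter <- iter + 1
      if (iter > max_iter) abort_invalid("acceptance sampling stalled")
      batch <- max(16L, 4L * (n_sites - length(sites)))
      idx <- sample.int(K, batch, replace = TRUE)
      acc <- runif(batch) < pr$p1[idx] & runif(batch) < pr$p2[idx]
      new <- candidates$cut_site[idx[acc]]
      sites <- unique(c(sites, new))
    }
    sort(sites[seq_len(n_sites)])
  })
}

#' Consistency of predicted entanglements with LiP-MS peptides
#'
#' Builds the overlap and sign matrices and the per-timepoint statistics in
#' one call.
#'
#' @inheritParams overlap_matrix
#' @param delta_sasa_res Per-residue simulated exposure change (misfolded
#'   minus native), as from [delta_sasa()].
#' @return A `consistency_result` list: `O`, `S`, `stats` (per-timepoint
#'   tibble), `peptides`, plus the window/radius settings used.
#' @export
lipms_consistency <- function(records, peptides, structure, delta_sasa_res,
                              cut_window = 5, crossing_radius = 8) {
  O <- overlap_matrix(records, peptides, structure, cut_window,
                      crossing_radius)
  peps <- attr(O, "peptides")
  L <- max(structure$residue)
  ds <- cutsite_delta_sasa(delta_sasa_res, peps$cut_site, L, cut_window)
  S <- sign_matrix(O, ds)
  structure(list(O = O, S = S,
                 stats = consistency_stats(O, S),
                 peptides = peps, cut_window = cut_window,
                 crossing_radius = crossing_radius,
                 delta_sasa_res = delta_sasa_res), class = "consistency_result")
}

#' Permutation p-value for LiP-MS consistency
#'
#' Draws random cut-site sets from the theoretical half-tryptic distribution
#' (by default one shared set per permutation, truncated to each
#' timepoint's observed number of unique cut sites; observed peptide ratio
#' signs are retained and paired with the drawn sites), recomputes the two
#' statistics, and counts a permutation as at least as consistent as
#' observed when at least two timepoints -- one of them the longest --
#' show exceedance of both statistics. With `ties = "count"` (default) a
#' drawn statistic equal to the observed one counts as exceedance, which
#' keeps the test's type-I error near its nominal level on these discrete
#' statistics; `ties = "strict"` applies the strict inequality, which is
#' sharply anti-conservative (see the methods vignette). The p-value is
#' the plain exceedance fraction, with no continuity correction.
#'
#' @param result A [lipms_consistency()] result.
#' @param model A [build_cutsite_model()].
#' @param sequence Protein sequence (one-letter codes).
#' @param records,structure The entanglement records and distance structure
#'   used for the observed statistics.
#' @param longest_timepoint Label of the longest experimental timepoint.
#' @param n_perm Number of permutations (>= 1000 recommended; default
#'   10000).
#' @param seed Integer seed.
#' @param shared_sites Draw one site set shared across timepoints (default
#'   `TRUE`, one theoretical set per permutation); `FALSE` redraws
#'   independently per timepoint.
#' @param ties `"count"` (ties count as exceedance, default) or `"strict"`.
#' @return List with `p_value`, `n_exceed`, `n_perm`, and `null_stats` (the
#'   per-permutation statistics, timepoints x 2 x n_perm array collapsed to
#'   a tibble).
#' @export
permutation_pvalue <- function(result, model, sequence, records, structure,
                               longest_timepoint, n_perm = 10000, seed = 1L,
                               shared_sites = TRUE,
                               ties = c("count", "strict")) {
  ties <- match.arg(ties)
  stats <- result$stats
  if (nrow(stats) < 2) {
    abort_invalid("the exceedance rule needs >= 2 timepoints")
  }
  if (!longest_timepoint %in% stats$timepoint) {
    abort_invalid("longest_timepoint not among the declared timepoints")
  }
  candidates <- enumerate_half_tryptic(sequence)
  pr <- candidate_accept_probs(candidates, model)
  w <- pr$p1 * pr$p2
  if (all(w == 0)) abort_invalid("all acceptance probabilities are 0")

  # per-site precomputation: overlap fraction and sign-conditional
  # agreement fraction against the fixed entanglement sets
  L <- max(structure$residue)
  sets_e <- entanglement_residue_sets(records, structure,
                                      result$crossing_radius)
  site_o <- vapply(seq_len(L), function(s) {
    win <- peptide_window(s, L, result$cut_window)
    mean(vapply(sets_e, function(se) jaccard(se, win) > 0, logical(1)))
  }, numeric(1))
  ds_site <- cutsite_delta_sasa(result$delta_sasa_res, seq_len(L), L,
                                result$cut_window)
  sgn_site <- sign(ds_site)
  sgn_site[is.na(sgn_site)] <- 0

  peps <- result$peptides
  tps <- stats$timepoint
  n_t <- stats$n_peptides
  signs_t <- lapply(tps, function(tp) sign(peps$log2_ratio[peps$timepoint == tp]))
  # weighted successive sampling without replacement over candidate
  # peptides reproduces accepted-draw order; unique cut sites are kept
  usite <- unique(candidates$cut_site)
  site_w <- vapply(split(w, candidates$cut_site)[as.character(usite)],
                   max, numeric(1))
  ok <- site_w > 0
  usite <- usite[ok]; site_w <- site_w[ok]
  draw_sites <- function(n) {
    usite[sample.int(length(usite), n, prob = site_w)]
  }

  obs_o <- stats$o_stat; obs_s <- stats$s_stat
  is_longest <- tps == longest_timepoint
  with_seed(seed, {
    n_exceed <- 0L
    null_o <- matrix(NA_real_, n_perm, length(tps))
    null_s <- matrix(NA_real_, n_perm, length(tps))
    for (p in seq_len(n_perm)) {
      shared <- if (shared_sites) draw_sites(max(n_t)) else NULL
      exceed <- logical(length(tps))
      for (k in seq_along(tps)) {
        sites <- if (shared_sites) shared[seq_len(n_t[k])] else
          draw_sites(n_t[k])
        o_p <- mean(site_o[sites])
        sg <- signs_t[[k]]
        s_p <- mean(ifelse(sgn_site[sites] != 0 & sgn_site[sites] == sg,
                           site_o[sites], 0))
        null_o[p, k] <- o_p; null_s[p, k] <- s_p
        exceed[k] <- if (ties == "count") {
          o_p >= obs_o[k] && s_p >= obs_s[k]
        } else {
          o_p > obs_o[k] && s_p > obs_s[k]
        }
      }
      if (sum(exceed) >= 2 && any(exceed & is_longest)) {
        n_exceed <- n_exceed + 1L
      }
    }
  })
  list(p_value = n_exceed / n_perm, n_exceed = n_exceed, n_perm = n_perm,
       null_stats = tibble(
         perm = rep(seq_len(n_perm), times = length(tps)),
         timepoint = rep(tps, each = n_perm),
         o_stat = as.vector(null_o), s_stat = as.vector(null_s)))
}

#' @rdname lipms_consistency
#' @param x A `consistency_result`.
#' @param ... Unused.
#' @export
glance.consistency_result <- function(x, ...) {
  tidyr::pivot_wider(x$stats, names_from = "timepoint",
                     values_from = c("o_stat", "s_stat", "n_peptides"))
}
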