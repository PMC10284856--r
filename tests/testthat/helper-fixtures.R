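# Shared fixtures built in code at test time.

coords_of <- function(structure, rows = seq_len(nrow(structure))) {
  as.matrix(structure[rows, c("x", "y", "z")])
}

# default toy lasso pair plus the contact map holding only its closing
# contact (the distance-based map would pick up incidental loop contacts)
toy_fixture <- function(spec = toy_link_spec()) {
  toy <- gen_entangled_toy(spec)
  i <- toy$loop_contact[1]; j <- toy$loop_contact[2]
  d0 <- sqrt(sum((coords_of(toy$native, i) - coords_of(toy$native, j))^2))
  map <- tibble::tibble(i = i, j = j, res_i = i, res_j = j, dist = d0)
  class(map) <- c("native_contact_map", class(map))
  toy$map <- map
  toy
}

# the frozen LiP-MS study fixture: a 162-residue lasso chain with one
# gained entanglement (crossing near residue 123) and a fixed simulated
# exposure-change field (burial at the crossing, noise elsewhere)
lipms_fixture <- function() {
  toy <- toy_fixture(toy_link_spec(loop_radius = 15, n_loop_beads = 30,
                                   thread_length = 300))
  gm <- g_metric(toy$misfolded, toy$native, toy$map)
  reps <- cluster_entanglements(gm$records)$representatives
  cross <- unlist(c(reps$crossings_n, reps$crossings_c))[1]
  L <- nrow(toy$native)
  ds <- withr::with_seed(99, tibble::tibble(
    residue = seq_len(L), delta_sasa = stats::rnorm(L, 0, 3)))
  ds$delta_sasa[abs(ds$residue - cross) <= 6] <- -20
  list(toy = toy, reps = reps, cross = cross, L = L, delta_sasa = ds)
}

# one synthetic LiP-MS dataset on the fixture; mode "null" has pure-noise
# ratios, mode "signal" plants a burial effect on the true crossing
lipms_dataset <- function(fx, seed, mode = c("null", "signal")) {
  mode <- match.arg(mode)
  es <- if (mode == "signal") {
    data.frame(residue = fx$cross, sign = -1)
  } else NULL
  spec <- lipms_sim_spec(protein_length = fx$L, n_cutsites = 15,
                         effect_sites = es, n_timepoints = 3, seed = seed)
  gen_lipms_dataset(spec)
}

lipms_pvalue <- function(fx, d, seed, n_perm = 1000, ...) {
  res <- lipms_consistency(fx$reps, d$peptides, fx$toy$misfolded,
                           fx$delta_sasa)
  model <- build_cutsite_model(d$sequence[unique(d$peptides$cut_site)],
                               d$proteome)
  permutation_pvalue(res, model, d$sequence, fx$reps, fx$toy$misfolded,
                     longest_timepoint = "t3", n_perm = n_perm,
                     seed = seed, ...)$p_value
}

# literature-flavoured single-ring cycle rates (uM, min); bimolecular rates
# per uM per min
default_rates <- function() {
  groel_rates(k1 = 1, k2 = 1, k3 = 1, k4 = 2, k5 = 1, k6 = 0.02,
              k7 = 0.01, k8 = 0.1)
}

default_state <- function() {
  groel_state(G = 1, ES = 2, ATP7 = 500, U = 2)
}

random_rates <- function() {
  groel_rates(k1 = runif(1, 0.05, 2), k2 = runif(1, 0.05, 2),
              k3 = runif(1, 0.05, 2), k4 = runif(1, 0.1, 5),
              k5 = runif(1, 0.1, 2), k6 = runif(1, 0, 0.1),
              k7 = runif(1, 0, 0.05), k8 = runif(1, 0.02, 0.5))
}

random_phis <- function() {
  f <- runif(1, 0.05, 0.9)
  m <- runif(1, 0, 1 - f)
  fb <- runif(1)
  partition_coefficients(f, m, fb, 1 - fb)
}

# best single-exponential fit (for residual-randomness diagnostics)
single_exp_residuals <- function(tc) {
  obj <- function(par) {
    sum((tc$p_nn - (par[1] * exp(-10^par[2] * tc$t) + 1 - par[1]))^2)
  }
  best <- optim(c(0.7, -1), obj, method = "L-BFGS-B",
                lower = c(0, -10), upper = c(1, 2))
  tc$p_nn - (best$par[1] * exp(-10^best$par[2] * tc$t) + 1 - best$par[1])
}
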