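test_that("frame classification counts bound frames", {
  d <- data.frame(frame = 1:5, contacts = c(2, 3, 50, 60, 2))
  cb <- classify_bound(d, threshold = 20)
  expect_equal(attr(cb, "p_complex"), 0.4)
  expect_identical(cb$bound, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  all_low <- classify_bound(data.frame(contacts = c(1, 2, 3)), threshold = 10)
  expect_equal(attr(all_low, "p_complex"), 0)
  expect_error(classify_bound(data.frame(contacts = numeric(0)), 5), "empty")
})

test_that("classification recovers a planted bound fraction", {
  spec <- binding_traj_spec(p_bound_target = 0.3, mean_dwell_bound = 20,
                            n_frames = 1e5, seed = 12)
  cb <- classify_bound(gen_contact_trajectory(spec), threshold = 20)
  expect_lt(abs(attr(cb, "p_complex") - 0.3), 0.01)
  # default two-means threshold lands in the inter-mode gap
  cb2 <- classify_bound(gen_contact_trajectory(spec))
  expect_gt(attr(cb2, "threshold"), 3)
  expect_lt(attr(cb2, "threshold"), 50)
})

test_that("dissociation constants match the unit-conversion oracle", {
  v <- sphere_volume(160)
  expect_equal(kd(0.5, v), oracle_kd(0.5, v))
  expect_equal(kd(0.5, v) * 1e6, 48.4, tolerance = 0.01)  # ~48 uM
  # inside the simulated 20-790 uM band
  expect_gt(kd(0.5, v) * 1e6, 20)
  expect_lt(kd(0.5, v) * 1e6, 790)
  # limits and scalings
  expect_lt(kd(0.999, v), kd(0.5, v))
  expect_equal(kd(0.5, 2 * v), kd(0.5, v) / 2)
  expect_error(kd(1, v), "censored")
  expect_error(kd(0, v), "censored")
})

test_that("K_D from classified synthetic trajectories matches the generator truth", {
  p_true <- 0.4
  v <- sphere_volume(160)
  spec <- binding_traj_spec(p_bound_target = p_true, mean_dwell_bound = 30,
                            n_frames = 2e5, seed = 21)
  cb <- classify_bound(gen_contact_trajectory(spec), threshold = 20)
  k_est <- kd(attr(cb, "p_complex"), v)
  k_true <- oracle_kd(p_true, v)
  expect_lt(abs(k_est - k_true) / k_true, 0.10)  # Monte-Carlo error
})

test_that("threshold choice inside the inter-mode gap barely moves K_D", {
  spec <- binding_traj_spec(p_bound_target = 0.4, mean_dwell_bound = 50,
                            n_frames = 2e5, contact_level_bound = 80,
                            contact_level_unbound = 3, seed = 31)
  tr <- gen_contact_trajectory(spec)
  v <- sphere_volume(160)
  kds <- vapply(c(20, 30, 40, 50), function(th) {
    kd(attr(classify_bound(tr, threshold = th), "p_complex"), v)
  }, numeric(1))
  expect_lt(diff(range(kds)) / mean(kds), 0.05)
})

test_that("replicate K_D intervals behave and cover the truth", {
  v <- sphere_volume(160)
  spec <- binding_traj_spec(p_bound_target = 0.5, mean_dwell_bound = 20,
                            n_frames = 2e4, seed = 1)
  tr <- gen_contact_trajectory(spec)
  est <- kd_replicates(list(tr, tr, tr), volume = v, threshold = 20)
  expect_equal(est$ci95[1], est$ci95[2])  # identical replicates: width 0
  expect_equal(est$log2_ratio_vs_reference, NA_real_)
  self_ref <- kd_replicates(list(tr, tr), volume = v, threshold = 20,
                            reference = est$kd_mean)
  expect_equal(self_ref$log2_ratio_vs_reference, 0)

  k_true <- oracle_kd(0.5, v)
  covered <- vapply(1:100, function(trial) {
    trajs <- lapply(1:5, function(r) {
      gen_contact_trajectory(binding_traj_spec(
        p_bound_target = 0.5, mean_dwell_bound = 20, n_frames = 2e4,
        seed = 1000 * trial + r))
    })
    ci <- kd_replicates(trajs, volume = v, threshold = 20)$ci95
    ci[1] <= k_true && k_true <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("odds ratios compare binding with attractions on and off", {
  expect_equal(odds_ratio(0.4, 0.4, 0.4, 0.4)$ratio, 1)
  expect_error(odds_ratio(0, 0.5, 0.5, 0.5), "strictly")
  # attraction doubling the bound occupancy of U only, estimated from
  # simulated two-state chains, gives a ratio near 2
  sim_p <- function(p, seed) {
    tr <- gen_contact_trajectory(binding_traj_spec(
      p_bound_target = p, mean_dwell_bound = 10, n_frames = 5e4,
      seed = seed))
    attr(classify_bound(tr, threshold = 20), "p_complex")
  }
  r <- odds_ratio(sim_p(0.2, 1), sim_p(0.1, 2), sim_p(0.3, 3), sim_p(0.3, 4))
  expect_equal(r$ratio, 2, tolerance = 0.15)
})

test_that("null odds ratios across replicate states stay near 1", {
  withr::with_seed(5, {
    hits <- vapply(1:100, function(trial) {
      sim_p <- function(seeds) vapply(seeds, function(s) {
        tr <- gen_contact_trajectory(binding_traj_spec(
          p_bound_target = 0.4, mean_dwell_bound = 20, n_frames = 5000,
          seed = s))
        attr(classify_bound(tr, threshold = 20), "p_complex")
      }, numeric(1))
      base <- 40000 * trial
      r <- odds_ratio(sim_p(base + 1:6), sim_p(base + 11:16),
                      sim_p(base + 21:26), sim_p(base + 31:36),
                      comparison = "M/F")
      abs(log(r$ratio)) < log(1.5) && r$p_value > 0.05
    }, logical(1))
    expect_gte(sum(hits), 90)
  })
})

test_that("permutation test on replicate groups is exact, powered, calibrated", {
  g <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  same <- permutation_ratio_test(g, g, n_perm = 500, seed = 1)
  expect_true(same$exact)
  expect_equal(same$p_value, 1)
  # strong separation
  sep <- permutation_ratio_test(g, g + 10 * sd(g), n_perm = 500, seed = 1)
  expect_lt(sep$p_value, 0.01)
  expect_error(permutation_ratio_test(g[1:2], g, 500), ">= 3")
  expect_error(permutation_ratio_test(g, g, n_perm = 50), "n_perm")
  # type-I error at nominal 0.05 under the null
  withr::with_seed(77, {
    rej <- vapply(1:2000, function(i) {
      a <- rnorm(5)
      b <- rnorm(5)
      permutation_ratio_test(a, b, n_perm = 300, seed = i)$p_value < 0.05
    }, logical(1))
    expect_gte(mean(rej), 0.03)
    expect_lte(mean(rej), 0.07)
  })
})

test_that("frame thinning leaves the K_D estimate unchanged in expectation", {
  spec <- binding_traj_spec(p_bound_target = 0.4, mean_dwell_bound = 25,
                            n_frames = 2e5, seed = 44)
  tr <- gen_contact_trajectory(spec)
  v <- sphere_volume(160)
  full <- kd(attr(classify_bound(tr, threshold = 20), "p_complex"), v)
  thin <- tr[seq(1, nrow(tr), by = 5), ]
  thinned <- kd(attr(classify_bound(thin, threshold = 20), "p_complex"), v)
  expect_lt(abs(thinned - full) / full, 0.05)
})
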