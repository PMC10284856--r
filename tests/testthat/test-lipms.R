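test_that("overlap gating follows the Jaccard index of residue windows", {
  fx <- lipms_fixture()
  L <- fx$L
  mk_pep <- function(sites) {
    tibble::tibble(protein = "P", start = sites, end = pmin(L, sites + 8),
                   cut_site = sites, log2_ratio = -1, timepoint = "t1",
                   significant = TRUE)
  }
  # cut site right at the crossing overlaps; a distant one does not
  O <- overlap_matrix(fx$reps, mk_pep(c(fx$cross - 1, 10)),
                      fx$toy$misfolded)
  expect_identical(O[1, ], c(1L, 0L))
  J <- attr(O, "jaccard")
  expect_gt(J[1, 1], 0)
  expect_equal(J[1, 2], 0)
  # identical sets give J = 1
  set_e <- foldtrap:::entanglement_residue_sets(fx$reps, fx$toy$misfolded,
                                                8)[[1]]
  expect_equal(foldtrap:::jaccard(set_e, set_e), 1)
  # non-significant peptides are excluded up front
  pep0 <- mk_pep(fx$cross)
  pep0$significant <- FALSE
  expect_error(overlap_matrix(fx$reps, pep0, fx$toy$misfolded),
               "significant")
})

test_that("sign agreement is gated by overlap and kills zero signs", {
  O <- matrix(c(1L, 1L, 0L), nrow = 1)
  attr(O, "peptides") <- tibble::tibble(log2_ratio = c(-2, 1, -3))
  S <- sign_matrix(O, delta_sasa_sim = c(-5, -5, -5))
  expect_identical(as.integer(S), c(1L, 0L, 0L))
  # zero simulated change never agrees
  S0 <- sign_matrix(O, delta_sasa_sim = c(0, 0, 0))
  expect_true(all(S0 == 0))
  expect_error(sign_matrix(O, delta_sasa_sim = c(NA, 1, 1)), "missing")
})

test_that("consistency statistics are per-timepoint matrix means", {
  O <- matrix(c(1L, 1L, 1L, 0L), nrow = 2)
  S <- matrix(c(1L, 0L, 0L, 0L), nrow = 2)
  attr(O, "peptides") <- tibble::tibble(timepoint = c("t1", "t2"))
  st <- consistency_stats(O, S)
  expect_equal(st$o_stat, c(1, 0.5))
  expect_equal(st$s_stat, c(0.5, 0))
  o1 <- matrix(1L, 2, 2)
  attr(o1, "peptides") <- tibble::tibble(timepoint = c("t1", "t1"))
  st1 <- consistency_stats(o1, o1)
  expect_equal(st1$o_stat, 1)
  expect_equal(st1$s_stat, 1)
  expect_error(consistency_stats(matrix(integer(0)), matrix(integer(0)),
                                 character(0)), "empty")
})

test_that("the intrinsic cut-site model follows the frequency ratio", {
  prot <- tibble::tibble(aa = c("A", "G", "S", "V"),
                         freq = c(0.25, 0.25, 0.25, 0.25))
  m <- build_cutsite_model(c("A", "G", "S", "V"), prot)
  expect_true(all(m$p_intrinsic == 1))
  m2 <- build_cutsite_model(c("A", "A", "G", "V"), prot)
  expect_equal(unname(m2$p_intrinsic["A"]), 2)
  prot0 <- tibble::tibble(aa = c("A", "G", "S", "W"),
                          freq = c(0.5, 0.25, 0.25, 0))
  expect_warning(build_cutsite_model(c("A", "W"), prot0), "excluded")
  expect_error(build_cutsite_model(character(0), prot), "empty")
})

test_that("half-tryptic enumeration tracks trypsin boundaries", {
  seqv <- c("A", "G", "K", "S", "V", "R", "T")
  cand <- enumerate_half_tryptic(seqv)
  # downstream peptide from site 4 runs to the next K/R at 6
  expect_true(any(cand$cut_site == 4 & cand$start == 4 & cand$end == 6))
  # upstream peptide from site 5 starts after the previous K/R at 3
  expect_true(any(cand$cut_site == 5 & cand$start == 4 & cand$end == 5))
  expect_true(all(cand$start <= cand$cut_site & cand$cut_site <= cand$end))
})

test_that("rejection sampling of cut sites respects the propensity model", {
  fx <- lipms_fixture()
  d <- lipms_dataset(fx, seed = 3)
  model <- build_cutsite_model(d$sequence[unique(d$peptides$cut_site)],
                               d$proteome)
  s1 <- sample_random_cutsites(model, d$sequence, 10, seed = 5)
  s2 <- sample_random_cutsites(model, d$sequence, 10, seed = 5)
  expect_identical(s1, s2)                 # fixed seed, identical draws
  expect_length(unique(s1), 10)
  # degenerate all-accept model: every candidate type equally intrinsic
  prot <- tibble::tibble(aa = AA <- unique(d$sequence),
                         freq = as.numeric(table(factor(d$sequence, AA))) /
                           length(d$sequence))
  m1 <- build_cutsite_model(d$sequence, prot)
  expect_length(sample_random_cutsites(m1, d$sequence, 25, seed = 1), 25)
  # large-sample frequencies follow p_intrinsic x availability
  big <- table(unlist(lapply(1:300, function(s) {
    d$sequence[sample_random_cutsites(model, d$sequence, 15, seed = s)]
  })))
  pr <- model$p_intrinsic[names(big)]
  avail <- table(factor(d$sequence, names(big)))
  expected <- pr * as.numeric(avail)
  expected <- expected / sum(expected)
  p <- chisq.test(as.numeric(big), p = expected)$p.value
  expect_gt(p, 0.01)
})

test_that("the permutation p-value honours its degenerate contracts", {
  fx <- lipms_fixture()
  d <- lipms_dataset(fx, seed = 17, mode = "signal")
  res <- lipms_consistency(fx$reps, d$peptides, fx$toy$misfolded,
                           fx$delta_sasa)
  model <- build_cutsite_model(d$sequence[unique(d$peptides$cut_site)],
                               d$proteome)
  # maximal observed statistics cannot be strictly exceeded
  res_max <- res
  res_max$stats$o_stat <- 1
  res_max$stats$s_stat <- 1
  p_max <- permutation_pvalue(res_max, model, d$sequence, fx$reps,
                              fx$toy$misfolded, "t3", n_perm = 200,
                              seed = 1, ties = "strict")$p_value
  expect_equal(p_max, 0)
  # all-zero observed statistics are beaten by almost any draw here
  res0 <- res
  res0$stats$o_stat <- 0
  res0$stats$s_stat <- 0
  p0 <- permutation_pvalue(res0, model, d$sequence, fx$reps,
                           fx$toy$misfolded, "t3", n_perm = 200,
                           seed = 1)$p_value
  expect_gt(p0, 0.5)
  # a single timepoint leaves the rule undefined
  res1 <- res
  res1$stats <- res1$stats[1, ]
  expect_error(permutation_pvalue(res1, model, d$sequence, fx$reps,
                                  fx$toy$misfolded, "t1", 200, 1),
               "timepoints")
  expect_error(permutation_pvalue(res, model, d$sequence, fx$reps,
                                  fx$toy$misfolded, "t9", 200, 1),
               "longest")
})

test_that("planted crossing signals yield small permutation p-values", {
  fx <- lipms_fixture()
  ps <- vapply(1:20, function(s) {
    lipms_pvalue(fx, lipms_dataset(fx, seed = 500 + s, mode = "signal"),
                 seed = s, n_perm = 500)
  }, numeric(1))
  expect_gte(sum(ps < 0.05), 17)
  # S is gated by O, so the per-timepoint statistics are ordered
  d <- lipms_dataset(fx, seed = 2, mode = "signal")
  res <- lipms_consistency(fx$reps, d$peptides, fx$toy$misfolded,
                           fx$delta_sasa)
  expect_true(all(res$stats$s_stat <= res$stats$o_stat))
  expect_true(all(res$S <= res$O))
})
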