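# Synthetic-study generator and its ground truth.

test_that("generation is bit-reproducible per seed", {
  d <- study_design(n_features = 40, seed = 8, drift_amplitude = 0.2)
  a <- generate_feature_table(d)
  b <- generate_feature_table(d)
  expect_identical(a$table$areas, b$table$areas)
  expect_identical(a$table$ratings, b$table$ratings)
  expect_identical(a$truth$differential, b$truth$differential)
  # different seed differs
  c <- generate_feature_table(study_design(n_features = 40, seed = 9,
                                           drift_amplitude = 0.2))
  expect_false(identical(a$table$areas, c$table$areas))
})

test_that("the design mirrors the exposure-trial layout", {
  d <- study_design(seed = 1)
  sim <- generate_feature_table(d)
  s <- sim$table$samples
  expect_equal(sum(s$role == "solvent_control"), 3L)
  expect_equal(sum(s$role == "medium_control"), 3L)
  counts <- table(s$group[s$role == "study"], s$timepoint[s$role == "study"])
  expect_true(all(counts == 4L))  # quadruplicates per cell
  expect_gte(sum(s$role == "qc"), 6L)
  expect_false(anyDuplicated(s$injection_order) > 0)
  # pairing: every exposed sample has a control partner
  exp_pairs <- s$pair_id[s$role == "study" & s$group == "exposed"]
  ctl_pairs <- s$pair_id[s$role == "study" & s$group == "control"]
  expect_setequal(exp_pairs, ctl_pairs)
})

test_that("infeasible configurations are rejected", {
  expect_error(study_design(fraction_differential = 1.2), "\\[0, 1\\]")
})

test_that("planted effects land on the recorded features with the stated size", {
  d <- study_design(n_features = 100, fraction_differential = 0.1,
                    log2_effect = 2, censor_mu = 1, sigma_log = 0.01,
                    drift_amplitude = 0, seed = 4)
  sim <- generate_feature_table(d)
  tr <- sim$truth$differential
  expect_equal(nrow(tr), 10L)
  s <- sim$table$samples
  expo <- s$role == "study" & s$group == "exposed" & s$timepoint == "t1"
  ctl <- s$role == "study" & s$group == "control" & s$timepoint == "t1"
  for (i in seq_len(nrow(tr))) {
    j <- match(tr$feature_id[i], sim$table$features$feature_id)
    lfc <- log2(mean(sim$table$areas[j, expo]) /
                  mean(sim$table$areas[j, ctl]))
    expect_equal(lfc, tr$sign[i] * 2, tolerance = 0.1)
  }
})

test_that("censoring produces the model-implied missingness fraction", {
  d <- study_design(n_features = 10000, replicates = 1,
                    timepoints = "t0", qc_lead = 2, qc_every = 100,
                    n_blank = 0, n_solvent = 0, n_medium = 0,
                    fraction_differential = 0, seed = 12)
  sim <- generate_feature_table(d)
  st <- sim$table$samples$role == "study"
  observed <- mean(is.na(sim$table$areas[, st]))
  # oracle: numerically integrate the censoring probability over the
  # intensity model (log X ~ N(meanlog, sdlog^2 + sigma_log^2))
  sd_tot <- sqrt(d$sdlog^2 + d$sigma_log^2)
  expected <- integrate(function(z) {
    plogis((log(d$censor_mu) - (d$meanlog + sd_tot * z)) / d$censor_scale) *
      dnorm(z)
  }, -8, 8)$value
  expect_lt(abs(observed - expected), 0.02)
})

test_that("the spiked series is recovered exactly at 5 ppm", {
  sim <- generate_feature_table(study_design(n_features = 200, seed = 3))
  sim <- spike_biotransformation_series(sim, seed = 3)
  expect_equal(nrow(sim$truth$spiked), 17L)
  cand <- enumerate_biotransformations("C10H14N2",
                                       default_transformations(),
                                       max_depth = 2)
  m <- match_expected(cand, sim$table, tol_ppm = 5)
  hit <- intersect(unique(m$feature_id), sim$truth$spiked$feature_id)
  expect_setequal(hit, sim$truth$spiked$feature_id)  # 0 false negatives
  # spiked features exist only in exposed samples
  s <- sim$table$samples
  sp <- match(sim$truth$spiked$feature_id, sim$table$features$feature_id)
  expo <- s$role == "study" & s$group == "exposed"
  expect_false(any(is.na(sim$table$areas[sp, expo])))
  expect_true(all(is.na(sim$table$areas[sp, !expo])))
})

test_that("jitter beyond the tolerance breaks recovery", {
  sim <- generate_feature_table(study_design(n_features = 50, seed = 6))
  sim <- spike_biotransformation_series(sim, jitter_ppm = 10, seed = 6)
  cand <- enumerate_biotransformations("C10H14N2",
                                       default_transformations(),
                                       max_depth = 2)
  m <- match_expected(cand, sim$table, tol_ppm = 5)
  hit <- intersect(unique(m$feature_id), sim$truth$spiked$feature_id)
  expect_lt(length(hit), 17L)
})

test_that("the abundance profile makes the lactam product the top peak", {
  sim <- generate_feature_table(study_design(n_features = 50, seed = 2))
  sim <- spike_biotransformation_series(sim, seed = 2)
  sp <- sim$truth$spiked
  s <- sim$table$samples
  expo <- s$role == "study" & s$group == "exposed"
  mean_area <- vapply(sp$feature_id, function(id) {
    j <- match(id, sim$table$features$feature_id)
    mean(sim$table$areas[j, expo])
  }, numeric(1))
  expect_equal(sp$label[which.max(mean_area)], "4")
})

test_that("family spectra share shifted scaffold fragments; seeds reproduce", {
  sim <- generate_feature_table(study_design(n_features = 30, seed = 7))
  sim <- spike_biotransformation_series(sim, seed = 7)
  sp1 <- generate_spectra(sim$truth, seed = 7)
  sp2 <- generate_spectra(sim$truth, seed = 7)
  expect_equal(sp1, sp2)
  parent <- sp1[[1]]
  child <- sp1[[2]]
  shift <- child$precursor_mz - parent$precursor_mz
  shared <- sum(vapply(child$mz, function(f)
    any(abs(f - shift - parent$mz) < 1e-6), logical(1)))
  expect_gte(shared / length(parent$mz), 0.6)
})
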