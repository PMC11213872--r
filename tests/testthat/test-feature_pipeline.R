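# Quality-control, filtering and normalization stages.

test_that("peak-rating filter is strict at the boundary", {
  areas <- matrix(100, 3, 6)
  ratings <- rbind(rep(6, 6),            # above 5 everywhere -> kept
                   rep(5, 6),            # exactly 5 -> removed (strict)
                   c(6, 6, 6, 6, 6, 4))  # above 5 in 5 samples -> kept
  tab <- toy_table(areas, ratings = ratings)
  out <- filter_by_peak_rating(tab, min_rating = 5, min_samples = 5)
  expect_setequal(out$features$feature_id, c("f1", "f3"))
  # missing ratings -> instructive rejection
  tab$ratings <- NULL
  expect_error(filter_by_peak_rating(tab), "ratings")
})

test_that("empty tables pass through the rating filter", {
  tab <- toy_table(matrix(numeric(0), 0, 6),
                   ratings = matrix(numeric(0), 0, 6))
  out <- filter_by_peak_rating(tab)
  expect_equal(nrow(out$areas), 0L)
})

test_that("imputation is an identity on complete tables and is seeded", {
  set.seed(1)
  areas <- matrix(rlnorm(60, 10), 6, 10)
  tab <- toy_table(areas)
  out <- impute_missing(tab, seed = 3)
  expect_identical(out$areas, tab$areas)

  areas[2, 4] <- NA; areas[5, 7] <- NA
  tab <- toy_table(areas)
  a <- impute_missing(tab, seed = 3)
  b <- impute_missing(tab, seed = 3)
  expect_identical(a$areas, b$areas)
  expect_false(any(is.na(a$areas)))
  # observed entries untouched
  expect_identical(a$areas[!is.na(areas)], areas[!is.na(areas)])
  # detection mask preserved
  expect_false(a$detected[2, 4])
})

test_that("imputation tracks a collinear partner feature", {
  set.seed(42)
  base <- rlnorm(20, 8, 0.8)
  areas <- rbind(base, base * 2, matrix(rlnorm(8 * 20, 8, 0.5), 8))
  miss_val <- areas[1, 5]
  areas[1, 5] <- NA
  tab <- toy_table(areas)
  out <- impute_missing(tab, seed = 1)
  # prediction should sit near the collinear prediction areas[2,5]/2
  expect_lt(abs(out$areas[1, 5] - areas[2, 5] / 2) / (areas[2, 5] / 2), 0.05)
})

test_that("all-missing features are rejected, >50% missing flagged", {
  areas <- matrix(rlnorm(40, 8), 4, 10)
  areas[1, ] <- NA
  expect_error(impute_missing(toy_table(areas)), "f1")
  areas[1, ] <- rlnorm(10, 8)
  areas[2, 1:6] <- NA
  expect_warning(impute_missing(toy_table(areas), seed = 1), "f2")
})

test_that("RSD filter applies non-strict bounds on QC RSD", {
  # QC values with known RSDs: (100,100,100) -> 0%; (10,100,190) -> 90%
  rsd <- function(v) 100 * sd(v) / mean(v)
  expect_equal(rsd(c(10, 100, 190)), 90)
  report <- data.frame(feature_id = c("f1", "f2", "f3", "f4"),
                       rsd_before = c(0, 90, 50, 30),
                       rsd_after = c(0, 10, 25, 25.6),
                       constant = FALSE)
  tab <- toy_table(matrix(1, 4, 6))
  out <- rsd_filter(tab, report)
  # f2 fails before-bound, f4 fails after-bound, f3 sits exactly on both
  expect_setequal(out$features$feature_id, c("f1", "f3"))
})

test_that("usable-hits filter keeps features present in >=80% of one cell", {
  n <- 16  # exposed/control x t1/t4, 4 replicates
  samples <- data.frame(
    sample_id = paste0("s", 1:n), role = "study",
    group = rep(c("exposed", "control"), each = 8),
    timepoint = rep(rep(c("t1", "t4"), each = 4), 2),
    pair_id = paste0("p", rep(1:8, 2)), injection_order = 1:n)
  areas <- matrix(100, 3, n)
  areas[1, samples$group == "control"] <- NA      # full in exposed cells
  areas[2, seq(1, n, by = 4)] <- NA               # 3/4 in every cell
  features <- data.frame(feature_id = paste0("f", 1:3), mz = 1:3 + 100,
                         rt = 5, ion = "[M+H]+", polarity = "pos")
  tab <- feature_table(areas, samples, features)
  out <- usable_hits_filter(tab, 0.80)
  expect_setequal(out$features$feature_id, c("f1", "f3"))
})

test_that("median normalization scales to the max sample median", {
  areas <- cbind(rep(50, 5), rep(100, 5)) * matrix(c(1, 2, 3, 4, 5), 5, 2)
  # sample medians: 150 and 300 -> factors 2 and 1
  tab <- toy_table(areas)
  out <- normalize_median(tab)
  expect_equal(out$areas[, 1], tab$areas[, 1] * 2)
  expect_equal(out$areas[, 2], tab$areas[, 2])
  meds <- apply(out$areas, 2, median)
  expect_equal(meds, rep(max(meds), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # single sample and all-equal matrices unchanged
  one <- toy_table(matrix(c(1, 2, 3), 3, 1))
  expect_equal(normalize_median(one)$areas, one$areas)
  eq <- toy_table(matrix(5, 3, 4))
  expect_equal(normalize_median(eq)$areas, eq$areas)
  # zero-median sample is named in the rejection
  z <- toy_table(cbind(c(0, 0, 1), c(1, 2, 3)))
  expect_error(normalize_median(z), "s1")
})

test_that("log/Pareto scaling has the stated variance identity", {
  set.seed(7)
  areas <- matrix(rlnorm(50, 8, 1), 5, 10)
  tab <- toy_table(areas)
  out <- log_pareto(tab)
  lx <- log(areas)
  for (j in 1:5) {
    expect_equal(mean(out$areas[j, ]), 0, tolerance = 1e-12)
    expect_equal(stats::var(out$areas[j, ]), sd(lx[j, ]), tolerance = 1e-9)
  }
  # constant features are dropped with a log record
  areas2 <- rbind(areas, rep(3, 10))
  out2 <- log_pareto(toy_table(areas2))
  expect_equal(nrow(out2$areas), 5L)
  # non-positive entries rejected with the offender count
  areas3 <- areas; areas3[1, 1] <- 0
  expect_error(log_pareto(toy_table(areas3)), "1 non-positive")
})

test_that("QC drift correction preserves QC medians and reduces drift", {
  d <- study_design(n_features = 60, drift_amplitude = 0.5,
                    fraction_differential = 0, seed = 7)
  sim <- generate_feature_table(d)
  tab <- suppressWarnings(impute_missing(sim$table, seed = 2))
  res <- qc_correct(tab, seed = 2)
  qc <- which(tab$samples$role == "qc")
  nc <- !res$report$constant
  med_raw <- apply(tab$areas[nc, qc, drop = FALSE], 1, median)
  med_cor <- apply(res$table$areas[nc, qc, drop = FALSE], 1, median)
  expect_equal(med_cor, med_raw, tolerance = 1e-9)
  expect_lt(median(res$report$rsd_after, na.rm = TRUE),
            median(res$report$rsd_before, na.rm = TRUE))
  expect_gt(mean(res$report$rsd_after <= 25, na.rm = TRUE),
            mean(res$report$rsd_before <= 25, na.rm = TRUE))
})

test_that("drift-free tables are essentially unchanged by correction", {
  d <- study_design(n_features = 50, drift_amplitude = 0,
                    fraction_differential = 0, seed = 9, censor_mu = 1)
  sim <- generate_feature_table(d)
  tab <- impute_missing(sim$table, seed = 1)
  res <- qc_correct(tab, seed = 1)
  st <- which(tab$samples$role == "study")
  rel <- abs(res$table$areas[, st] - tab$areas[, st]) / tab$areas[, st]
  # correction stays within the QC technical-noise floor (log-sd 0.05)
  expect_gt(mean(rel < 0.05), 0.95)
  expect_lt(median(rel), 0.02)
})

test_that("correction commutes with a global rescaling of one feature", {
  d <- study_design(n_features = 30, drift_amplitude = 0.3,
                    fraction_differential = 0, seed = 5, censor_mu = 1)
  sim <- generate_feature_table(d)
  tab <- impute_missing(sim$table, seed = 1)
  res1 <- qc_correct(tab, seed = 11)
  tab2 <- tab
  tab2$areas[3, ] <- tab2$areas[3, ] * 1024
  res2 <- qc_correct(tab2, seed = 11)
  expect_equal(res2$table$areas[3, ], res1$table$areas[3, ] * 1024,
               tolerance = 1e-6)
  # other features untouched by the rescaling
  expect_equal(res2$table$areas[7, ], res1$table$areas[7, ],
               tolerance = 1e-6)
})

test_that("constant-QC features pass through correction unchanged", {
  areas <- matrix(rlnorm(8 * 12, 8), 8, 12)
  areas[4, ] <- 500  # constant everywhere, incl. QCs
  roles <- rep(c("qc", "study"), 6)
  tab <- toy_table(areas, roles = roles)
  res <- qc_correct(tab, seed = 1)
  expect_true(res$report$constant[4])
  expect_identical(res$table$areas[4, ], tab$areas[4, ])
  # fewer than 5 QCs is a rejection
  tab2 <- toy_table(areas, roles = c(rep("qc", 4), rep("study", 8)))
  expect_error(qc_correct(tab2, seed = 1), "5 QC")
})

test_that("stage counts are monotone and recorded in the QC report", {
  d <- study_design(n_features = 80, drift_amplitude = 0.3, seed = 21)
  sim <- generate_feature_table(d)
  proc <- process_pipeline(sim$table, seed = 1)
  rep <- qc_report(proc$processed)
  expect_true(all(diff(rep$n_features) <= 0))
  expect_equal(rep$n_features[nrow(rep)], nrow(proc$processed$areas))
})

test_that("feature tables round-trip through CSV sidecars", {
  d <- study_design(n_features = 20, seed = 2)
  sim <- generate_feature_table(d)
  stem <- file.path(withr::local_tempdir(), "tab")
  write_feature_table(sim$table, stem)
  back <- read_feature_table(stem)
  expect_equal(back$areas, sim$table$areas, tolerance = 1e-12)
  expect_equal(back$features$mz, sim$table$features$mz)
  expect_equal(back$samples$injection_order,
               sim$table$samples$injection_order)
})
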