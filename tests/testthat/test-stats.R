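# Paired tests, discriminant selection, refits, ratios, PCA.

test_that("paired t-test matches the textbook computation", {
  # 4 pairs with hand-computed statistic
  ex <- c(10, 12, 11, 13); ct <- c(9, 10, 10, 11)
  d <- ex - ct            # 1, 2, 1, 2 -> mean 1.5, sd 0.5774
  tstat <- mean(d) / (sd(d) / 2)
  res <- paired_t_tests(matrix(c(ex, ct), ncol = 1),
                        exposed = 1:4, control = 5:8)
  expect_equal(res$t, tstat, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(tstat), 3), tolerance = 1e-12)
  expect_equal(res$direction, "increase")
})

test_that("degenerate paired differences hit the documented guards", {
  m <- cbind(c(5, 5, 5, 5, 5, 5, 5, 5))  # identical pairs
  res <- paired_t_tests(m, exposed = 1:4, control = 5:8)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # constant non-zero difference -> p underflow guard
  m2 <- cbind(c(6, 6, 6, 6, 5, 5, 5, 5))
  res2 <- paired_t_tests(m2, exposed = 1:4, control = 5:8)
  expect_lt(res2$p, 1e-12)
  expect_equal(res2$direction, "increase")
})

test_that("pairing uses metadata and warns on unpaired samples", {
  areas <- matrix(rlnorm(3 * 9, 8), 3, 9)
  samples <- data.frame(
    sample_id = paste0("s", 1:9), role = "study",
    group = c(rep("exposed", 5), rep("control", 4)),
    timepoint = "t1",
    pair_id = c(paste0("p", 1:5), paste0("p", 1:4)),
    injection_order = 1:9)
  features <- data.frame(feature_id = paste0("f", 1:3), mz = 101:103,
                         rt = 5, ion = "[M+H]+", polarity = "pos")
  tab <- feature_table(areas, samples, features)
  expect_warning(res <- paired_t_tests(tab, timepoint = "t1"), "s5")
  expect_equal(nrow(res), 3L)
})

test_that("triple-criterion selection respects all gates and VIP order", {
  model <- structure(list(
    cv_anova_p = 0.01,
    feature_ids = c("a", "b", "c", "d"),
    vip = c(a = 2.0, b = 1.49, c = 1.8, d = 1.7),
    pcorr = c(a = 0.8, b = 0.9, c = 0.4, d = -0.7)), class = "opls_da")
  tests <- data.frame(feature_id = c("a", "b", "c", "d"),
                      p = c(1e-6, 0.01, 0.01, 0.04),
                      direction = c("decrease", "increase", "increase",
                                    "increase"))
  sel <- select_discriminant(model, tests)
  # b fails VIP (1.49 < 1.5), c fails |pcorr| (0.4 < 0.5)
  expect_equal(sel$feature_id, c("a", "d"))  # VIP descending
  expect_equal(attr(sel, "status"), "ok")
  expect_equal(sel$direction[1], "decrease")

  model$cv_anova_p <- 0.2
  sel2 <- select_discriminant(model, tests)
  expect_equal(nrow(sel2), 0L)
  expect_equal(attr(sel2, "status"), "model not significant")
})

test_that("excluding features refits and compares models", {
  d <- study_design(n_features = 60, fraction_differential = 0.1,
                    log2_effect = 3, censor_mu = 1, seed = 13)
  sim <- generate_feature_table(d)
  pr <- log_pareto(normalize_median(impute_missing(sim$table, seed = 1)))
  keep <- pr$samples$role != "study" |
    (pr$samples$timepoint == "t1" &
       pr$samples$group %in% c("exposed", "control"))
  sub <- ft_subset(pr, samples = which(keep))
  ids <- sub$features$feature_id
  truth <- sim$truth$differential$feature_id
  noise_ids <- setdiff(ids, truth)[1:5]

  # empty exclusion -> identical statistics
  both <- exclude_features_and_refit(sub, character(0), seed = 1)
  expect_identical(both$full$q2, both$reduced$q2)

  # excluding pure noise barely moves Q2
  both2 <- exclude_features_and_refit(sub, noise_ids, seed = 1)
  expect_lt(abs(both2$full$q2 - both2$reduced$q2), 0.05)

  # excluding the true signals destroys the model
  both3 <- exclude_features_and_refit(sub, intersect(truth, ids), seed = 1)
  expect_gt(both3$reduced$cv_anova_p, 0.05)

  expect_error(exclude_features_and_refit(sub, "nope", seed = 1), "unknown")
  expect_error(exclude_features_and_refit(sub, ids, seed = 1), "every")
})

test_that("abundance-ratio tests behave under nulls, shifts and scaling", {
  set.seed(11)
  n <- 16
  samples <- data.frame(
    sample_id = paste0("s", 1:n), role = "study",
    group = rep(c("exposed", "control"), each = 8),
    timepoint = rep(rep(c("t1", "t4"), each = 4), 2),
    pair_id = paste0("p", c(1:8, 1:8)), injection_order = 1:n)
  areas <- matrix(rlnorm(3 * n, 8, 0.1), 3, n)
  features <- data.frame(feature_id = c("pro", "cit", "arg"),
                         mz = c(116, 176, 175), rt = 5, ion = "[M+H]+",
                         polarity = "pos")
  # numerator = denominator -> p = 1
  areas[2, ] <- areas[1, ]
  tab <- feature_table(areas, samples, features)
  res <- amino_acid_ratio_tests(tab, list(c("pro", "cit")))
  expect_equal(res$p, 1)

  # 2-fold shift in the numerator for exposed only -> significant
  areas2 <- areas
  areas2[1, samples$group == "exposed"] <-
    areas2[1, samples$group == "exposed"] * 2
  tab2 <- feature_table(areas2, samples, features)
  res2 <- amino_acid_ratio_tests(tab2, list(c("pro", "arg")))
  expect_lt(res2$p, 0.05)
  expect_equal(res2$direction, "increase")

  # invariance to global per-sample scaling
  tab3 <- tab2
  tab3$areas <- sweep(tab2$areas, 2, runif(n, 0.5, 2), `*`)
  res3 <- amino_acid_ratio_tests(tab3, list(c("pro", "arg")))
  expect_equal(res3$p, res2$p, tolerance = 1e-9)

  # missing member skipped with a warning
  expect_warning(res4 <- amino_acid_ratio_tests(tab2, list(c("pro", "orn"))),
                 "skipped")
  expect_equal(nrow(res4), 0L)
})

test_that("PCA returns orthonormal loadings and honest variance shares", {
  set.seed(3)
  x <- matrix(rnorm(20 * 8), 20, 8)
  res <- run_pca(x, n_components = 3)
  expect_equal(crossprod(res$loadings), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(res$explained) <= 1e-12))
  # rank-1 matrix -> PC1 explains everything
  r1 <- outer(rnorm(10), rnorm(5))
  res1 <- run_pca(r1, n_components = 1)
  expect_equal(res1$explained[1], 1, tolerance = 1e-9)
  expect_warning(run_pca(r1, n_components = 4), "rank")
})

test_that("QCs cluster tighter than groups separate in drift-free data", {
  d <- study_design(n_features = 80, fraction_differential = 0.2,
                    log2_effect = 2, censor_mu = 1, seed = 19)
  sim <- generate_feature_table(d)
  pr <- log_pareto(normalize_median(impute_missing(sim$table, seed = 1)))
  res <- run_pca(pr, n_components = 2)
  roles <- pr$samples$role[match(res$sample_ids, pr$samples$sample_id)]
  qc_scores <- res$scores[roles == "qc", , drop = FALSE]
  st_scores <- res$scores[roles == "study", , drop = FALSE]
  mean_dist <- function(s) mean(dist(s))
  expect_lt(mean_dist(qc_scores), mean_dist(st_scores))
})
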