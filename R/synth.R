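# Synthetic-study generator. Emulates the structure of a two-group,
# multi-timepoint cell-exposure LC-HRMS experiment with pooled-QC
# injections: log-normal baseline intensities, group x timepoint effects on
# a chosen fraction of features, multiplicative injection-order drift with
# per-feature sensitivity, intensity-censored missingness, fabricated peak
# ratings, and an optional spiked biotransformation series with exact
# theoretical masses. Every draw is reproducible from the seed, and the
# ground truth of what was planted is returned alongside the table.

#' Study design configuration for the synthetic generator
#'
#' Defaults mirror the exposure-trial design the pipeline targets:
#' exposed/control groups in quadruplicate at t0/t1/t4, six leading pooled
#' QC injections plus one QC every eighth injection, and three each of
#' blank, solvent-control and medium-control preparations.
#'
#' @param n_features Total features before filtering (default 300).
#' @param replicates Replicates per group x timepoint cell (default 4).
#' @param timepoints Timepoint labels (default t0, t1, t4).
#' @param qc_lead Leading QC injections (default 6).
#' @param qc_every A QC is injected after every this many study samples
#'   (default 8).
#' @param n_blank,n_solvent,n_medium Control preparations (default 3 each).
#' @param fraction_differential Fraction of features given a true group
#'   effect (default 0.10).
#' @param log2_effect True |log2 fold change| of differential features in
#'   exposed samples at t1/t4 (default 1, i.e. 2-fold).
#' @param meanlog,sdlog Log-normal baseline intensity parameters (defaults
#'   log(1e6) and 1.2).
#' @param sigma_log Biological + technical log-sd of study samples
#'   (default 0.2); QCs use `sigma_qc` (default 0.05).
#' @param sigma_qc Technical log-sd of QC injections.
#' @param drift_amplitude Multiplicative drift amplitude `a`: the drift
#'   factor runs linearly from `1 - a` to `1 + a` across the injection
#'   sequence (default 0, no drift).
#' @param drift_shape `"linear"` or `"sine"` (one full period across the
#'   run).
#' @param censor_mu Intensity scale of the missingness model: the
#'   probability that an entry is censored is
#'   `plogis((log(censor_mu) - log(x)) / censor_scale)` (defaults:
#'   `exp(meanlog - 2 * sdlog)` and 0.6).
#' @param censor_scale Steepness of the censoring curve.
#' @param rating_k Intensity at which the fabricated peak rating crosses 5
#'   (rating = `10 x / (x + rating_k)` plus noise; default `exp(meanlog)`,
#'   calibrated so roughly half of the low-intensity features fail the
#'   rating filter).
#' @param seed Integer seed.
#' @return A `study_design` configuration list.
#' @export
study_design <- function(n_features = 300L, replicates = 4L,
                         timepoints = c("t0", "t1", "t4"),
                         qc_lead = 6L, qc_every = 8L,
                         n_blank = 3L, n_solvent = 3L, n_medium = 3L,
                         fraction_differential = 0.10, log2_effect = 1,
                         meanlog = log(1e6), sdlog = 1.2,
                         sigma_log = 0.2, sigma_qc = 0.05,
                         drift_amplitude = 0,
                         drift_shape = c("linear", "sine"),
                         censor_mu = NULL, censor_scale = 0.6,
                         rating_k = NULL, seed = 1L) {
  if (fraction_differential < 0 || fraction_differential > 1) {
    stop("fraction_differential must be in [0, 1]", call. = FALSE)
  }
  cfg <- list(n_features = n_features, replicates = replicates,
              timepoints = timepoints, qc_lead = qc_lead,
              qc_every = qc_every, n_blank = n_blank,
              n_solvent = n_solvent, n_medium = n_medium,
              fraction_differential = fraction_differential,
              log2_effect = log2_effect, meanlog = meanlog, sdlog = sdlog,
              sigma_log = sigma_log, sigma_qc = sigma_qc,
              drift_amplitude = drift_amplitude,
              drift_shape = match.arg(drift_shape),
              censor_mu = censor_mu %||% exp(meanlog - 2 * sdlog),
              censor_scale = censor_scale,
              rating_k = rating_k %||% exp(meanlog), seed = seed)
  class(cfg) <- "study_design"
  cfg
}

.sample_sheet <- function(cfg) {
  rows <- list()
  add <- function(id, role, group, tp, pair) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = id, role = role, group = group, timepoint = tp,
      pair_id = pair, stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_blank)) add(paste0("blank_", i), "blank", "none", NA, NA)
  for (i in seq_len(cfg$n_solvent)) add(paste0("solvent_", i),
                                        "solvent_control", "none", NA, NA)
  for (i in seq_len(cfg$n_medium)) add(paste0("medium_", i),
                                       "medium_control", "none", NA, NA)
  qc_n <- 0L
  for (i in seq_len(cfg$qc_lead)) {
    qc_n <- qc_n + 1L
    add(paste0("qc_", qc_n), "qc", "none", NA, NA)
  }
  # randomized study injections with a QC after every qc_every-th
  study <- expand.grid(timepoint = cfg$timepoints,
                       group = c("exposed", "control"),
                       rep = seq_len(cfg$replicates),
                       stringsAsFactors = FALSE)
  study <- study[sample.int(nrow(study)), , drop = FALSE]
  for (k in seq_len(nrow(study))) {
    s <- study[k, ]
    add(sprintf("%s_%s_r%d", s$group, s$timepoint, s$rep), "study",
        s$group, s$timepoint, sprintf("%s_r%d", s$timepoint, s$rep))
    if (k %% cfg$qc_every == 0L) {
      qc_n <- qc_n + 1L
      add(paste0("qc_", qc_n), "qc", "none", NA, NA)
    }
  }
  qc_n <- qc_n + 1L
  add(paste0("qc_", qc_n), "qc", "none", NA, NA)  # closing QC
  sheet <- do.call(rbind, rows)
  sheet$injection_order <- seq_len(nrow(sheet))
  sheet
}

.drift_curve <- function(order, n_total, amplitude, shape) {
  u <- (order - 1) / max(n_total - 1, 1)
  base <- switch(shape,
                 linear = 2 * u - 1,
                 sine = sin(2 * pi * u))
  1 + amplitude * base
}

#' Generate a synthetic feature table with known ground truth
#'
#' @param config A [study_design()] configuration.
#' @return List with `table` (a `feature_table`) and `truth` (list:
#'   `differential` data.frame of planted feature ids with effect sign and
#'   size, `drift` data.frame of per-feature drift sensitivities, `config`).
#' @export
generate_feature_table <- function(config = study_design()) {
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  sheet <- .sample_sheet(cfg)
  n_s <- nrow(sheet)
  p <- cfg$n_features
  n_diff <- round(cfg$fraction_differential * p)
  if (n_diff > p) stop("more differential features than features", call. = FALSE)

  feature_ids <- sprintf("F%04d", seq_len(p))
  mz <- sort(stats::runif(p, 60, 860))
  rt <- stats::runif(p, 0.5, 29.5)
  polarity <- sample(c("pos", "neg"), p, replace = TRUE, prob = c(0.7, 0.3))
  ion <- ifelse(polarity == "pos", "[M+H]+", "[M-H]-")

  baseline <- stats::rlnorm(p, cfg$meanlog, cfg$sdlog)
  diff_idx <- if (n_diff > 0L) sort(sample.int(p, n_diff)) else integer(0)
  diff_sign <- sample(c(-1, 1), n_diff, replace = TRUE)
  gamma <- stats::runif(p, 0.5, 1.5)  # per-feature drift sensitivity

  # log-scale signal per feature x sample before drift
  lsig <- matrix(log(baseline), p, n_s)
  is_qc <- sheet$role == "qc"
  is_study <- sheet$role == "study"
  is_ctrlprep <- sheet$role %in% c("blank", "solvent_control",
                                   "medium_control")
  lsig[, is_study] <- lsig[, is_study] +
    matrix(stats::rnorm(p * sum(is_study), 0, cfg$sigma_log), p)
  lsig[, is_qc] <- lsig[, is_qc] +
    matrix(stats::rnorm(p * sum(is_qc), 0, cfg$sigma_qc), p)
  lsig[, is_ctrlprep] <- lsig[, is_ctrlprep] + log(0.02) +
    matrix(stats::rnorm(p * sum(is_ctrlprep), 0, cfg$sigma_log), p)

  # planted effects: exposed samples at t1 and t4
  if (n_diff > 0L) {
    hit <- which(is_study & sheet$group == "exposed" &
                   sheet$timepoint %in% c("t1", "t4"))
    lsig[diff_idx, hit] <- lsig[diff_idx, hit] +
      diff_sign * cfg$log2_effect * log(2)
  }

  # multiplicative drift applied after the effects
  drift <- .drift_curve(sheet$injection_order, n_s, cfg$drift_amplitude,
                        cfg$drift_shape)
  ldrift <- outer(gamma, log(pmax(drift, 1e-6)))
  x <- exp(lsig + ldrift)

  # intensity-censored missingness
  pmiss <- stats::plogis((log(cfg$censor_mu) - log(x)) / cfg$censor_scale)
  miss <- matrix(stats::runif(p * n_s), p, n_s) < pmiss
  areas <- x
  areas[miss] <- NA_real_

  rating <- 10 * x / (x + cfg$rating_k) +
    matrix(stats::rnorm(p * n_s, 0, 0.5), p, n_s)
  rating <- pmin(pmax(rating, 0), 10)
  rating[miss] <- NA_real_

  features <- data.frame(feature_id = feature_ids, mz = mz, rt = rt,
                         ion = ion, polarity = polarity,
                         stringsAsFactors = FALSE)
  tab <- feature_table(areas, sheet, features, ratings = rating)
  truth <- list(
    differential = data.frame(
      feature_id = feature_ids[diff_idx],
      sign = diff_sign,
      log2_effect = rep(cfg$log2_effect, n_diff),
      stringsAsFactors = FALSE),
    drift = data.frame(feature_id = feature_ids, gamma = gamma,
                       stringsAsFactors = FALSE),
    config = cfg)
  list(table = tab, truth = truth)
}

#' Default nicotine biotransformation series
#'
#' Seventeen products of the parent alkaloid as transformation chains,
#' including formula-level positional isomers (distinct retention times,
#' identical formula): nor-compound, dehydro-nor isomers, the lactam and
#' its oxidation isomers, N-oxide/hydroxy isomers, ring-opened keto and
#' hydroxy acids, glycine and acetyl conjugates.
#'
#' @return data.frame with `label`, `chain` (list column of transformation
#'   keys) and `rel_abundance` (lactam-dominant profile).
#' @export
default_nicotine_series <- function() {
  entry <- function(label, chain, ab) {
    data.frame(label = label, chain = I(list(chain)), rel_abundance = ab,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    entry("2",  "demethylation", 0.40),
    entry("3a", c("demethylation", "desaturation"), 0.05),
    entry("3b", c("demethylation", "desaturation"), 0.04),
    entry("3c", c("demethylation", "desaturation"), 0.03),
    entry("4",  c("desaturation", "oxidation"), 1.00),
    entry("5a", "oxidation", 0.06),
    entry("5b", "oxidation", 0.08),
    entry("5c", "oxidation", 0.30),
    entry("6",  "deamination_keto", 0.10),
    entry("7",  "deamination_hydroxy", 0.07),
    entry("8a", c("desaturation", "dioxidation"), 0.04),
    entry("8b", c("desaturation", "dioxidation"), 0.03),
    entry("8c", c("desaturation", "dioxidation"), 0.05),
    entry("9",  c("demethylation", "oxidation"), 0.04),
    entry("10", "glycine_conjugation", 0.02),
    entry("11", c("oxidation", "acetylation"), 0.03),
    entry("12", "dioxidation", 0.02)
  ))
}

#' Spike a biotransformation series into a synthetic table
#'
#' Adds one feature per product (per requested ion) at its exact
#' theoretical m/z (optionally ppm-jittered), present only in exposed study
#' samples with the given relative abundance profile. Products whose m/z
#' would collide with an existing feature within 1 ppm are jittered away
#' and logged in the truth record.
#'
#' @param sim Output of [generate_feature_table()], or a `feature_table`.
#' @param parent Parent `elemental_formula` or string (default nicotine,
#'   `"C10H14N2"`).
#' @param series data.frame as from [default_nicotine_series()].
#' @param ions Ion species for the spiked features (default `"[M+H]+"`).
#' @param top_intensity Peak area of the most abundant product in exposed
#'   samples (default `5e7`).
#' @param jitter_ppm Uniform m/z jitter half-width in ppm (default 0; keep
#'   at or below 2 for realistic mass accuracy).
#' @param transformations Transformation set resolving the chain keys.
#' @param seed Integer seed.
#' @return List with `table` (augmented `feature_table`) and `truth`
#'   (augmented with a `spiked` data.frame: `feature_id`, `label`,
#'   `product_formula`, `chain`, `ion`, `theoretical_mz`, `spiked_mz`).
#' @export
spike_biotransformation_series <- function(sim, parent = "C10H14N2",
                                           series = default_nicotine_series(),
                                           ions = "[M+H]+",
                                           top_intensity = 5e7,
                                           jitter_ppm = 0,
                                           transformations = default_transformations(),
                                           seed = 1L) {
  if (inherits(sim, "feature_table")) sim <- list(table = sim, truth = list())
  tab <- sim$table
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 101L)

  parent_f <- parse_formula(parent)
  exposed <- which(tab$samples$role == "study" &
                     tab$samples$group == "exposed")
  n_s <- ncol(tab$areas)
  rows <- list(); areas <- list(); ratings <- list(); det <- list()
  for (i in seq_len(nrow(series))) {
    chain <- series$chain[[i]]
    f <- parent_f
    for (key in chain) {
      tr <- transformations[[key]]
      if (is.null(tr)) stop("unknown transformation key: ", key,
                            call. = FALSE)
      f <- formula_add(f, tr$delta)
    }
    for (ion in ions) {
      theo <- ion_mz(f, ion)
      mz <- theo
      if (jitter_ppm > 0) {
        mz <- mz * (1 + stats::runif(1, -jitter_ppm, jitter_ppm) * 1e-6)
      }
      collide <- any(abs(ppm_error(mz, tab$features$mz)) <= 1)
      if (collide) mz <- mz * (1 + 2.5e-6)
      fid <- sprintf("BT_%s_%s", series$label[i], gsub("[^A-Za-z0-9]", "",
                                                       ion))
      a <- rep(NA_real_, n_s)
      a[exposed] <- series$rel_abundance[i] * top_intensity *
        exp(stats::rnorm(length(exposed), 0, 0.15))
      r <- rep(NA_real_, n_s); r[exposed] <- 9
      d <- rep(FALSE, n_s); d[exposed] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, mz = mz,
        rt = stats::runif(1, 3, 14), ion = ion,
        polarity = if (grepl("\\+$", ion)) "pos" else "neg",
        label = series$label[i], product_formula = format(f),
        chain = paste(chain, collapse = " > "),
        theoretical_mz = theo, collided = collide,
        stringsAsFactors = FALSE)
      areas[[length(areas) + 1L]] <- a
      ratings[[length(ratings) + 1L]] <- r
      det[[length(det) + 1L]] <- d
    }
  }
  meta <- do.call(rbind, rows)
  new_features <- rbind(tab$features,
                        meta[, c("feature_id", "mz", "rt", "ion",
                                 "polarity")])
  new_areas <- rbind(tab$areas, do.call(rbind, areas))
  new_ratings <- if (!is.null(tab$ratings)) {
    rbind(tab$ratings, do.call(rbind, ratings))
  }
  new_det <- rbind(tab$detected, do.call(rbind, det))
  out <- feature_table(new_areas, tab$samples, new_features,
                       ratings = new_ratings, detected = new_det,
                       log = tab$log)
  truth <- sim$truth
  truth$spiked <- data.frame(
    feature_id = meta$feature_id, label = meta$label,
    product_formula = meta$product_formula, chain = meta$chain,
    ion = meta$ion, theoretical_mz = meta$theoretical_mz,
    spiked_mz = meta$mz, collided = meta$collided,
    stringsAsFactors = FALSE)
  truth$parent <- format(parent_f)
  list(table = out, truth = truth)
}

#' Generate MS2 spectra for a spiked biotransformation family
#'
#' The parent compound gets a scaffold of random fragments; each spiked
#' product inherits a large share (default 80%) of those fragment masses
#' shifted by its precursor-mass difference, plus a few minor unique
#' fragments, so that modified-cosine networking can recover the family.
#' Optional decoy spectra carry unrelated random fragments.
#'
#' @param truth Truth record from [spike_biotransformation_series()] (needs
#'   `spiked` and `parent`).
#' @param n_scaffold Scaffold fragments of the parent (default 10).
#' @param share Fraction of scaffold fragments inherited by each product
#'   (default 0.8).
#' @param n_decoys Unrelated decoy spectra to append (default 0).
#' @param parent_ion Ion species of the parent spectrum.
#' @param seed Integer seed.
#' @return List of `ms2_spectrum` (parent first, then products, then
#'   decoys).
#' @export
generate_spectra <- function(truth, n_scaffold = 10L, share = 0.8,
                             n_decoys = 0L, parent_ion = "[M+H]+",
                             seed = 1L) {
  stopifnot(!is.null(truth$spiked), !is.null(truth$parent))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 202L)

  parent_mz <- ion_mz(truth$parent, parent_ion)
  scaffold_mz <- sort(stats::runif(n_scaffold, 45, parent_mz - 25))
  scaffold_int <- stats::runif(n_scaffold, 30, 100)

  specs <- list(ms2_spectrum("parent", parent_mz, scaffold_mz,
                             scaffold_int))
  for (i in seq_len(nrow(truth$spiked))) {
    pmz <- truth$spiked$theoretical_mz[i]
    shift <- pmz - parent_mz
    n_keep <- max(3L, round(share * n_scaffold))
    keep <- sort(sample.int(n_scaffold, n_keep))
    frag <- scaffold_mz[keep] + shift
    inten <- scaffold_int[keep]
    ok <- frag > 30 & frag < pmz + 1
    frag <- frag[ok]; inten <- inten[ok]
    n_extra <- sample(2:4, 1L)
    frag <- c(frag, stats::runif(n_extra, 45, pmz - 25))
    inten <- c(inten, stats::runif(n_extra, 1, 8))
    specs[[length(specs) + 1L]] <- ms2_spectrum(
      truth$spiked$feature_id[i], pmz, frag, inten)
  }
  for (d in seq_len(n_decoys)) {
    pmz <- stats::runif(1, 150, 600)
    n <- sample(5:12, 1L)
    specs[[length(specs) + 1L]] <- ms2_spectrum(
      paste0("decoy_", d), pmz, sort(stats::runif(n, 45, pmz - 10)),
      stats::runif(n, 5, 100))
  }
  specs
}
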