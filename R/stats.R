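# Univariate tests, PCA quality assessment and discriminant-feature
# selection on processed feature tables.

#' Principal component analysis of a processed table
#'
#' Data-quality PCA over all non-blank samples (QC plus study): pooled QC
#' injections clustering tightly relative to the study groups indicates the
#' absence of instrumental drift.
#'
#' @param x Processed `feature_table` or samples x features matrix.
#' @param n_components Number of components to keep (truncated to the
#'   matrix rank with a warning when too large).
#' @param include_qc Keep QC samples in the score space (default TRUE).
#' @return List with `scores`, `loadings` (orthonormal columns),
#'   `explained` (fraction of variance per component) and `sample_ids`.
#' @export
run_pca <- function(x, n_components = 2L, include_qc = TRUE) {
  if (inherits(x, "feature_table")) {
    idx <- which(x$samples$role %in% c("study", if (include_qc) "qc"))
    ids <- x$samples$sample_id[idx]
    mat <- t(x$areas[, idx, drop = FALSE])
  } else {
    mat <- as.matrix(x)
    ids <- rownames(mat)
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1L] * 1e-12)
  if (n_components > rank) {
    warning("n_components truncated to matrix rank ", rank, call. = FALSE)
    n_components <- rank
  }
  keep <- seq_len(n_components)
  list(scores = pc$x[, keep, drop = FALSE],
       loadings = pc$rotation[, keep, drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[keep],
       sample_ids = ids)
}

.paired_design <- function(samples, timepoint = NULL) {
  idx <- which(samples$role == "study" &
                 samples$group %in% c("exposed", "control"))
  if (!is.null(timepoint)) idx <- idx[samples$timepoint[idx] == timepoint]
  s <- samples[idx, , drop = FALSE]
  exp_i <- idx[s$group == "exposed"]
  ctl_i <- idx[s$group == "control"]
  m <- match(samples$pair_id[exp_i], samples$pair_id[ctl_i])
  unpaired <- c(exp_i[is.na(m)], ctl_i[!seq_along(ctl_i) %in% m[!is.na(m)]])
  if (length(unpaired) > 0L) {
    warning("unpaired study sample(s) excluded: ",
            paste(samples$sample_id[unpaired], collapse = ", "),
            call. = FALSE)
  }
  keep <- !is.na(m)
  list(exposed = exp_i[keep], control = ctl_i[m[keep]])
}

#' Paired t-tests per feature
#'
#' Classical paired t statistic between exposed and control samples sharing
#' a pairing id, per feature, with two-sided p-values. Zero-variance
#' non-zero differences hit the underflow guard and report p below 1e-12.
#'
#' @param x A `feature_table` (typically log-scale processed values) or a
#'   samples x features matrix.
#' @param timepoint Optional timepoint to restrict the comparison to, when
#'   `x` is a `feature_table`.
#' @param exposed,control Row indices of paired samples (matched order);
#'   required when `x` is a matrix, derived from metadata otherwise.
#' @return data.frame: `feature_id`, `t`, `p`, `mean_diff`, `direction`
#'   (`"increase"`/`"decrease"` in exposed, `"none"` for exact zeros).
#' @export
paired_t_tests <- function(x, timepoint = NULL, exposed = NULL,
                           control = NULL) {
  if (inherits(x, "feature_table")) {
    d <- .paired_design(x$samples, timepoint)
    exposed <- d$exposed; control <- d$control
    mat <- t(x$areas)
    ids <- x$features$feature_id
  } else {
    mat <- as.matrix(x)
    if (is.null(exposed) || is.null(control)) {
      stop("matrix input requires exposed/control index vectors",
           call. = FALSE)
    }
    ids <- colnames(mat)
    if (is.null(ids)) ids <- paste0("f", seq_len(ncol(mat)))
  }
  stopifnot(length(exposed) == length(control), length(exposed) >= 2L)
  d <- mat[exposed, , drop = FALSE] - mat[control, , drop = FALSE]
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2L, stats::sd)
  tstat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- ifelse(is.finite(tstat),
              2 * stats::pt(-abs(tstat), df = n - 1L),
              1e-16)
  p[s == 0 & m == 0] <- 1
  data.frame(feature_id = ids, t = tstat, p = p, mean_diff = m,
             direction = ifelse(m > 0, "increase",
                                ifelse(m < 0, "decrease", "none")),
             stringsAsFactors = FALSE)
}

#' Select discriminant features by the triple criterion
#'
#' Intersection of VIP >= `vip_min`, |p(corr)| >= `pcorr_min` from the
#' OPLS-DA model and p <= `p_max` from the paired univariate test, applied
#' only when the model itself is significant by CV-ANOVA; a non-significant
#' model yields an empty list with status `"model not significant"`.
#' Features are returned in decreasing VIP order.
#'
#' @param model Fitted `opls_da` model.
#' @param tests Paired-test results from [paired_t_tests()] covering the
#'   model features.
#' @param vip_min Minimum VIP (default 1.5).
#' @param pcorr_min Minimum absolute p(corr) (default 0.50).
#' @param p_max Maximum univariate p (default 0.05).
#' @param model_p_max CV-ANOVA significance gate (default 0.05).
#' @param direction_table Optional `feature_table` of normalized pre-log
#'   areas; when supplied, directions are recomputed on that scale
#'   (matching the relative-concentration semantics of reported tables).
#' @param adjust_p Multiple-testing correction for the univariate p-values
#'   (`"none"`, the default, or any [stats::p.adjust()] method such as
#'   `"BH"`).
#' @return data.frame of `discriminant features`: `feature_id`, `vip`,
#'   `pcorr`, `p`, `direction`, sorted by VIP descending; attribute
#'   `status` is `"ok"` or `"model not significant"`.
#' @export
select_discriminant <- function(model, tests, vip_min = 1.5,
                                pcorr_min = 0.50, p_max = 0.05,
                                model_p_max = 0.05,
                                direction_table = NULL,
                                adjust_p = "none") {
  empty <- data.frame(feature_id = character(0), vip = numeric(0),
                      pcorr = numeric(0), p = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (model$cv_anova_p > model_p_max) {
    attr(empty, "status") <- "model not significant"
    return(empty)
  }
  ids <- model$feature_ids
  ti <- match(ids, tests$feature_id)
  p <- tests$p[ti]
  if (adjust_p != "none") p <- stats::p.adjust(p, method = adjust_p)
  dirn <- tests$direction[ti]
  if (!is.null(direction_table)) {
    dd <- .paired_design(direction_table$samples)
    raw <- t(direction_table$areas)[, ids, drop = FALSE]
    md <- colMeans(raw[dd$exposed, , drop = FALSE] -
                     raw[dd$control, , drop = FALSE])
    dirn <- ifelse(md > 0, "increase", ifelse(md < 0, "decrease", "none"))
  }
  sel <- which(model$vip >= vip_min & abs(model$pcorr) >= pcorr_min &
                 !is.na(p) & p <= p_max)
  out <- data.frame(feature_id = ids[sel], vip = model$vip[sel],
                    pcorr = model$pcorr[sel], p = p[sel],
                    direction = dirn[sel], stringsAsFactors = FALSE)
  out <- out[order(-out$vip), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "status") <- "ok"
  out
}

#' Refit an OPLS-DA model after excluding features
#'
#' Used to check whether the class separation survives removal of, e.g.,
#' parent-compound biotransformation products that would otherwise dominate
#' the model. Both the full and the reduced model are returned for
#' side-by-side comparison.
#'
#' @param x Processed `feature_table` or samples x features matrix.
#' @param exclude Character vector of feature ids to drop (must be a subset
#'   of the feature ids present).
#' @param y,... Passed to [opls_da()].
#' @return List with `full` and `reduced` `opls_da` models.
#' @export
exclude_features_and_refit <- function(x, exclude, y = NULL, ...) {
  if (inherits(x, "feature_table")) {
    ids <- x$features$feature_id
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    ids <- colnames(x)
  }
  bad <- setdiff(exclude, ids)
  if (length(bad)) {
    stop("exclusion list contains unknown feature id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(ids, exclude)
  if (length(keep) == 0L) {
    stop("exclusion would remove every feature", call. = FALSE)
  }
  full <- opls_da(x, y = y, ...)
  reduced_x <- if (inherits(x, "feature_table")) {
    ft_subset(x, features = keep)
  } else {
    x[, keep, drop = FALSE]
  }
  reduced <- opls_da(reduced_x, y = y, ...)
  list(full = full, reduced = reduced)
}

#' Paired tests on metabolite abundance ratios
#'
#' For each (numerator, denominator) feature pair, the per-sample ratio of
#' normalized peak areas is formed, log-transformed, and compared between
#' exposed and control pairs with a paired t-test. Ratios are invariant to
#' global per-sample scaling, which makes them robust readouts of pathway
#' disturbances (urea-cycle style ratios such as proline/citrulline or
#' arginine/ornithine).
#'
#' @param table Normalized pre-log `feature_table` with positive entries.
#' @param pairs data.frame with columns `numerator` and `denominator`
#'   (feature ids), or a list of length-2 character vectors.
#' @param timepoint Optional timepoint restriction.
#' @return data.frame per ratio: `numerator`, `denominator`, `t`, `p`,
#'   `direction`; pairs with a missing member are skipped with a warning.
#' @export
amino_acid_ratio_tests <- function(table, pairs, timepoint = NULL) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- data.frame(numerator = vapply(pairs, `[`, character(1), 1L),
                        denominator = vapply(pairs, `[`, character(1), 2L),
                        stringsAsFactors = FALSE)
  }
  d <- .paired_design(table$samples, timepoint)
  ids <- table$features$feature_id
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    ni <- match(pairs$numerator[i], ids)
    di <- match(pairs$denominator[i], ids)
    if (is.na(ni) || is.na(di)) {
      warning("ratio ", pairs$numerator[i], "/", pairs$denominator[i],
              " skipped: member not in table", call. = FALSE)
      next
    }
    lr <- log(table$areas[ni, ] / table$areas[di, ])
    diff <- lr[d$exposed] - lr[d$control]
    n <- length(diff)
    m <- mean(diff); s <- stats::sd(diff)
    tstat <- if (s > 0) m / (s / sqrt(n)) else if (m == 0) 0 else Inf * sign(m)
    p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), n - 1L) else 1e-16
    if (s == 0 && m == 0) p <- 1
    out[[length(out) + 1L]] <- data.frame(
      numerator = pairs$numerator[i], denominator = pairs$denominator[i],
      t = tstat, p = p,
      direction = ifelse(m > 0, "increase",
                         ifelse(m < 0, "decrease", "none")),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(numerator = character(0), denominator = character(0),
                      t = numeric(0), p = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
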