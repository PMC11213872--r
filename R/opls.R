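# Orthogonal projections to latent structures discriminant analysis
# (OPLS-DA), written from the NIPALS formulation: one predictive component
# whose weight vector is the covariance direction between X and the class
# vector, plus 0..K orthogonal components that strip class-uncorrelated
# systematic variation from X before the predictive score is formed.

.center_cols <- function(x) sweep(x, 2L, colMeans(x), `-`)

# Core fit on centered matrices. Returns weights/scores/loadings.
.opls_core <- function(xc, yc, n_orth) {
  w <- drop(crossprod(xc, yc)) / drop(crossprod(yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("class vector uncorrelated with every feature",
                    call. = FALSE)
  w <- w / nw
  p <- ncol(xc)
  w_o <- p_o <- t_o <- NULL
  xe <- xc
  k_used <- 0L
  if (n_orth > 0L) {
    w_o <- matrix(0, p, n_orth); p_o <- matrix(0, p, n_orth)
    t_o <- matrix(0, nrow(xc), n_orth)
    for (k in seq_len(n_orth)) {
      tt <- drop(xe %*% w)
      pl <- drop(crossprod(xe, tt)) / drop(crossprod(tt))
      wo <- pl - drop(crossprod(w, pl)) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12) break
      wo <- wo / nwo
      to <- drop(xe %*% wo)
      po <- drop(crossprod(xe, to)) / drop(crossprod(to))
      xe <- xe - tcrossprod(to, po)
      w_o[, k] <- wo; p_o[, k] <- po; t_o[, k] <- to
      k_used <- k
    }
    if (k_used < n_orth) {
      w_o <- w_o[, seq_len(k_used), drop = FALSE]
      p_o <- p_o[, seq_len(k_used), drop = FALSE]
      t_o <- t_o[, seq_len(k_used), drop = FALSE]
    }
    if (k_used == 0L) { w_o <- p_o <- t_o <- NULL }
  }
  t_pred <- drop(xe %*% w)
  p_pred <- drop(crossprod(xe, t_pred)) / drop(crossprod(t_pred))
  q <- drop(crossprod(yc, t_pred)) / drop(crossprod(t_pred))
  list(w = w, p = p_pred, q = q, t = t_pred,
       w_o = w_o, p_o = p_o, t_o = t_o, n_orth = k_used)
}

.opls_predict_core <- function(core, xnew_centered) {
  xe <- xnew_centered
  if (!is.null(core$w_o)) {
    for (k in seq_len(ncol(core$w_o))) {
      to <- drop(xe %*% core$w_o[, k])
      xe <- xe - tcrossprod(to, core$p_o[, k])
    }
  }
  drop(xe %*% core$w) * core$q
}

.make_folds <- function(n, n_folds, seed) {
  n_folds <- min(n_folds, n)
  perm <- sample.int(n)  # caller sets the RNG state
  sizes <- rep(n %/% n_folds, n_folds)
  sizes[seq_len(n %% n_folds)] <- sizes[seq_len(n %% n_folds)] + 1L
  fold <- integer(n)
  fold[perm] <- rep(seq_len(n_folds), times = sizes)
  fold
}

# Cross-validated PRESS for a fixed number of orthogonal components.
.opls_press <- function(x, y01, n_orth, fold) {
  press <- 0
  for (f in unique(fold)) {
    tr <- fold != f; te <- !tr
    mx <- colMeans(x[tr, , drop = FALSE])
    my <- mean(y01[tr])
    xc <- sweep(x[tr, , drop = FALSE], 2L, mx, `-`)
    yc <- y01[tr] - my
    core <- tryCatch(.opls_core(xc, yc, n_orth), error = function(e) NULL)
    if (is.null(core)) { press <- press + sum((y01[te] - my)^2); next }
    xte <- sweep(x[te, , drop = FALSE], 2L, mx, `-`)
    yhat <- my + .opls_predict_core(core, xte)
    press <- press + sum((y01[te] - yhat)^2)
  }
  press
}

#' Fit an OPLS-DA model
#'
#' Fits a two-class discriminant model with exactly one predictive component
#' and up to `max_orth` orthogonal components. Orthogonal components are
#' added one at a time while each raises the 7-fold cross-validated Q2 by
#' more than `delta_q2`; the model reports its shape as `"1 + K"`.
#' Cross-validation folds are contiguous blocks of a seeded permutation of
#' the samples, so the fit is deterministic given the data and `seed`.
#'
#' @param x A processed (log/Pareto) `feature_table`, or a samples x
#'   features numeric matrix.
#' @param y Two-level class labels, one per sample. When `x` is a
#'   `feature_table` and `y` is omitted, study samples are used and labelled
#'   by their `group` metadata.
#' @param max_orth Maximum orthogonal components (default 3).
#' @param n_folds Cross-validation folds (default 7, reduced to the sample
#'   count when fewer samples are available).
#' @param delta_q2 Minimum Q2 improvement to accept another orthogonal
#'   component (default 0.01).
#' @param seed Seed for the fold assignment.
#' @return An `opls_da` object with elements `components` (e.g. `"1 + 2"`),
#'   `r2x`, `r2y`, `q2` (cumulative), `press`, `cv_anova_p`, `vip`,
#'   `pcorr`, `scores` (predictive score vector `t`), `orth_scores`,
#'   `weights`, `loadings`, plus the training data summary needed for
#'   prediction.
#' @export
opls_da <- function(x, y = NULL, max_orth = 3L, n_folds = 7L,
                    delta_q2 = 0.01, seed = 1L) {
  dat <- .as_model_matrix(x, y)
  x <- dat$x; y <- dat$y
  lev <- levels(y)
  if (nlevels(y) != 2L) {
    stop("OPLS-DA requires exactly two classes (got ",
         nlevels(y), ")", call. = FALSE)
  }
  if (min(table(y)) < 3L) {
    stop("each class needs at least 3 samples", call. = FALSE)
  }
  if (ncol(x) == 0L) stop("no features in the model matrix", call. = FALSE)
  y01 <- as.numeric(y == lev[2L])
  n <- nrow(x)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- .make_folds(n, n_folds, seed)

  ss_y <- sum((y01 - mean(y01))^2)
  q2 <- numeric(max_orth + 1L)
  press <- numeric(max_orth + 1L)
  for (k in 0:max_orth) {
    press[k + 1L] <- .opls_press(x, y01, k, fold)
    q2[k + 1L] <- 1 - press[k + 1L] / ss_y
  }
  n_orth <- 0L
  while (n_orth < max_orth &&
         q2[n_orth + 2L] - q2[n_orth + 1L] > delta_q2) {
    n_orth <- n_orth + 1L
  }

  mx <- colMeans(x); my <- mean(y01)
  xc <- sweep(x, 2L, mx, `-`)
  yc <- y01 - my
  core <- .opls_core(xc, yc, n_orth)
  n_orth <- core$n_orth

  yhat <- my + core$q * core$t
  r2y <- 1 - sum((y01 - yhat)^2) / ss_y
  ssx <- sum(xc^2)
  ssx_expl <- sum(core$t^2) * sum(core$p^2)
  if (!is.null(core$t_o)) {
    ssx_expl <- ssx_expl +
      sum(vapply(seq_len(ncol(core$t_o)), function(k)
        sum(core$t_o[, k]^2) * sum(core$p_o[, k]^2), numeric(1)))
  }
  r2x <- ssx_expl / ssx

  model <- structure(list(
    components = paste0("1 + ", n_orth),
    n_orth = n_orth,
    r2x = r2x, r2y = r2y,
    q2 = q2[n_orth + 1L], q2_path = q2,
    press = press[n_orth + 1L],
    n = n, n_features = ncol(x), ss_y = ss_y,
    scores = core$t, orth_scores = core$t_o,
    weights = core$w, loadings = core$p, q = core$q,
    orth_weights = core$w_o, orth_loadings = core$p_o,
    x_means = mx, y_mean = my, y = y01, y_levels = lev,
    fold = fold, seed = seed,
    feature_ids = colnames(x), x_centered = xc
  ), class = "opls_da")
  model$vip <- vip(model)
  model$pcorr <- pcorr(model)
  model$cv_anova_p <- cv_anova(model)
  model
}

.as_model_matrix <- function(x, y) {
  if (inherits(x, "feature_table")) {
    idx <- .study_idx(x)
    mat <- t(x$areas[, idx, drop = FALSE])
    if (is.null(y)) y <- x$samples$group[idx]
    colnames(mat) <- x$features$feature_id
    x <- mat
  } else {
    x <- as.matrix(x)
    if (ncol(x) == 0L) stop("no features in the model matrix", call. = FALSE)
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  if (is.null(y)) stop("class labels required", call. = FALSE)
  keep <- !is.na(y)
  list(x = x[keep, , drop = FALSE], y = droplevels(factor(y[keep])))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.opls_da <- function(x, ...) {
  cat("<opls_da> components ", x$components,
      sprintf("  R2X %.3f  R2Y %.3f  Q2 %.3f  CV-ANOVA p %.3g\n",
              x$r2x, x$r2y, x$q2, x$cv_anova_p), sep = "")
  invisible(x)
}

#' Predict class scores for new samples
#'
#' @param object An `opls_da` model.
#' @param newdata Samples x features matrix with the training feature set.
#' @param ... Unused.
#' @return Numeric predictions on the 0/1 class coding scale.
#' @export
predict.opls_da <- function(object, newdata, ...) {
  xte <- sweep(as.matrix(newdata), 2L, object$x_means, `-`)
  core <- list(w = object$weights, q = object$q,
               w_o = object$orth_weights, p_o = object$orth_loadings)
  object$y_mean + .opls_predict_core(core, xte)
}

#' Variable importance in the projection
#'
#' VIP over the single predictive component:
#' `VIP_j = sqrt(p) * |w_j| / ||w||`, so the mean squared VIP is exactly 1.
#' Features with VIP above ~1 contribute more than average to the class
#' separation.
#'
#' @param model An `opls_da` model.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  w <- model$weights
  v <- sqrt(length(w)) * abs(w) / sqrt(sum(w^2))
  names(v) <- model$feature_ids
  v
}

#' Correlation-scaled loadings p(corr)
#'
#' Pearson correlation of each (processed) feature with the predictive
#' score vector `t`; bounded in `[-1, 1]`. Zero-variance features get 0.
#'
#' @param model An `opls_da` model.
#' @return Named numeric vector in `[-1, 1]`.
#' @export
pcorr <- function(model) {
  xc <- model$x_centered
  tt <- model$scores
  sds <- sqrt(colSums(xc^2))
  st <- sqrt(sum((tt - mean(tt))^2))
  pc <- rep(0, ncol(xc))
  ok <- sds > 0 & st > 0
  if (any(ok)) {
    pc[ok] <- drop(crossprod(xc[, ok, drop = FALSE], tt - mean(tt))) /
      (sds[ok] * st)
  }
  names(pc) <- model$feature_ids
  pc
}

#' CV-ANOVA significance of an OPLS-DA model
#'
#' F-test comparing the cross-validated predictive residual sum of squares
#' (PRESS) against the total corrected sum of squares of the class vector:
#' with A model components (predictive + orthogonal) and n samples,
#' `F = ((SS_tot - PRESS)/A) / (PRESS/(n - 1 - A))` on `(A, n - 1 - A)`
#' degrees of freedom. Models whose cross-validated predictions explain
#' nothing (PRESS >= SS_tot) get p = 1.
#'
#' @param model An `opls_da` model.
#' @return p-value in `[0, 1]`.
#' @export
cv_anova <- function(model) {
  a <- 1L + model$n_orth
  df2 <- model$n - 1L - a
  if (df2 <= 0L) return(1)
  ss_reg <- model$ss_y - model$press
  if (ss_reg <= 0) return(1)
  f <- (ss_reg / a) / (model$press / df2)
  stats::pf(f, a, df2, lower.tail = FALSE)
}
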