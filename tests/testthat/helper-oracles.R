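# Independent oracles used across tests. These deliberately re-derive
# results through a different route than the package implementation.

# Plain 1-component NIPALS PLS regression: the reference for the
# OPLS-DA predictive component when no orthogonal components are fitted.
nipals_pls1 <- function(x, y) {
  x <- as.matrix(x)
  mx <- colMeans(x); my <- mean(y)
  xc <- sweep(x, 2L, mx, `-`); yc <- y - my
  w <- drop(t(xc) %*% yc)
  w <- w / sqrt(sum(w^2))
  tt <- drop(xc %*% w)
  q <- sum(yc * tt) / sum(tt^2)
  list(w = w, scores = tt, q = q,
       fitted = my + q * tt,
       predict = function(newx) {
         nc <- sweep(as.matrix(newx), 2L, mx, `-`)
         my + q * drop(nc %*% w)
       })
}

# Brute-force biotransformation enumeration: all transformation sequences
# up to a depth, then deduplication by product formula string.
brute_force_products <- function(parent, transformations, max_depth) {
  apply_chain <- function(f, chain) {
    for (tr in chain) {
      f <- tryCatch(formula_add(f, tr$delta), error = function(e) NULL)
      if (is.null(f)) return(NULL)
    }
    f
  }
  res <- character(0)
  chains <- list(list())
  for (d in seq_len(max_depth)) {
    chains <- unlist(lapply(chains, function(ch) {
      lapply(transformations, function(tr) c(ch, list(tr)))
    }), recursive = FALSE)
    for (ch in chains) {
      f <- apply_chain(parse_formula(parent), ch)
      if (!is.null(f)) res <- c(res, format(f))
    }
    chains <- chains  # sequences of length d feed length d+1
  }
  unique(res)
}

# Small balanced two-group feature table built entirely in code.
toy_table <- function(areas, roles = NULL, groups = NULL, timepoints = NULL,
                      pair_ids = NULL, ratings = NULL) {
  p <- nrow(areas); n <- ncol(areas)
  samples <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    role = roles %||% rep("study", n),
    group = groups %||% rep(c("exposed", "control"), length.out = n),
    timepoint = timepoints %||% rep("t1", n),
    pair_id = pair_ids %||% paste0("p", rep(seq_len(ceiling(n / 2)), 2)[seq_len(n)]),
    injection_order = seq_len(n),
    stringsAsFactors = FALSE)
  features <- data.frame(
    feature_id = sprintf("f%d", seq_len(p)),
    mz = 100 + seq_len(p), rt = rep(5, p),
    ion = rep("[M+H]+", p), polarity = rep("pos", p),
    stringsAsFactors = FALSE)
  feature_table(areas, samples, features, ratings = ratings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
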