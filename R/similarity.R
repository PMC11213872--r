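#' Modified-cosine spectral similarity
#'
#' Pairwise similarity between two fragment spectra on a 0-100 scale.
#' Fragment pairs are candidate matches when their m/z agree within
#' `frag_tol` either directly or after shifting one spectrum by the
#' precursor-mass difference (so that biotransformation-shifted fragments
#' still align). Candidates are resolved to a one-to-one matching greedily
#' in decreasing order of intensity product (first-come at exact ties), and
#' the score is the cosine of the matched intensity pairs:
#' `100 * sum(Ia*Ib over matches) / (||Ia|| * ||Ib||)`.
#'
#' The score is symmetric, 100 for identical spectra, and 0 when no
#' fragments can be matched.
#'
#' @param a,b `ms2_spectrum` objects.
#' @param frag_tol Fragment mass tolerance in Da (default 0.0025, i.e.
#'   2.5 mmu).
#' @return List with `score` (0-100), `matches` (matched fragment count),
#'   and `coverage` (percent of total fragment intensity of the
#'   lower-intensity spectrum explained by matched peaks).
#' @export
spectral_similarity <- function(a, b, frag_tol = 0.0025) {
  stopifnot(inherits(a, "ms2_spectrum"), inherits(b, "ms2_spectrum"))
  if (length(a$mz) == 0L || length(b$mz) == 0L) {
    warning("empty spectrum; similarity 0", call. = FALSE)
    return(list(score = 0, matches = 0L, coverage = 0))
  }
  shift <- b$precursor_mz - a$precursor_mz

  # candidate pairs: direct match or precursor-shift match
  cand <- NULL
  for (sh in unique(c(0, shift))) {
    d <- abs(outer(a$mz + sh, b$mz, `-`))
    idx <- which(d <= frag_tol, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      cand <- rbind(cand, cbind(idx, shifted = as.integer(sh != 0)))
    }
  }
  if (is.null(cand) || nrow(cand) == 0L) {
    return(list(score = 0, matches = 0L, coverage = 0))
  }
  cand <- cand[!duplicated(cand[, 1:2, drop = FALSE]), , drop = FALSE]
  prod <- a$intensity[cand[, 1L]] * b$intensity[cand[, 2L]]
  # greedy in decreasing intensity product; ties broken on symmetric keys
  # (sum and absolute difference of the two m/z) so the score does not
  # depend on argument order
  mza <- a$mz[cand[, 1L]]; mzb <- b$mz[cand[, 2L]]
  o <- order(-prod, mza + mzb, abs(mza - mzb))
  used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
  sel <- integer(0)
  for (k in o) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      sel <- c(sel, k)
    }
  }
  num <- sum(prod[sel])
  den <- sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2))
  score <- if (den > 0) 100 * num / den else 0

  tot_a <- sum(a$intensity); tot_b <- sum(b$intensity)
  cov_a <- 100 * sum(a$intensity[cand[sel, 1L]]) / tot_a
  cov_b <- 100 * sum(b$intensity[cand[sel, 2L]]) / tot_b
  coverage <- if (tot_a <= tot_b) cov_a else cov_b

  list(score = score, matches = length(sel), coverage = coverage)
}
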