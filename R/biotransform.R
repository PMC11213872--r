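#' Default biotransformation reaction set
#'
#' Formula-level phase-I/phase-II reactions covering the classes invoked for
#' nicotine metabolites: demethylation, desaturation, oxidation,
#' di-oxidation, reduction, hydration, two ring-opening oxidative-deamination
#' surrogates yielding the pyridyl keto and hydroxy acids, glycine
#' conjugation and acetylation. Each transformation is a named formula delta
#' (atoms added minus atoms removed).
#'
#' @return A named list of transformations; each element has `name` and
#'   `delta` (named numeric vector of atom-count changes).
#' @export
default_transformations <- function() {
  tf <- function(name, delta) list(name = name, delta = delta)
  list(
    demethylation   = tf("demethylation (-CH2)",   c(C = -1, H = -2)),
    desaturation    = tf("desaturation (-H2)",     c(H = -2)),
    oxidation       = tf("oxidation (+O)",         c(O = 1)),
    dioxidation     = tf("di-oxidation (+2O)",     c(O = 2)),
    reduction       = tf("reduction (+H2)",        c(H = 2)),
    hydration       = tf("hydration (+H2O)",       c(H = 2, O = 1)),
    deamination_keto = tf("oxidative deamination to keto acid (-CH5N +3O)",
                          c(C = -1, H = -5, N = -1, O = 3)),
    deamination_hydroxy = tf("oxidative deamination to hydroxy acid (-CH3N +3O)",
                             c(C = -1, H = -3, N = -1, O = 3)),
    glycine_conjugation = tf("glycine conjugation (+C2H3NO)",
                             c(C = 2, H = 3, N = 1, O = 1)),
    acetylation     = tf("acetylation (+C2H2O)",   c(C = 2, H = 2, O = 1))
  )
}

#' Enumerate theoretical biotransformation products of a parent compound
#'
#' Applies chains of up to `max_depth` transformations to the parent formula
#' and returns all distinct product formulas with their expected m/z for
#' every requested ion species. Deduplication is by product formula only;
#' positional isomers are indistinguishable at the formula level and are
#' resolved downstream by retention time. Chains that would drive an atom
#' count negative are skipped silently (recorded in the `skipped` attribute).
#'
#' @param parent Parent `elemental_formula` or string.
#' @param transformations List of transformations as from
#'   [default_transformations()].
#' @param max_depth Maximum chain length (default 2).
#' @param ions Adduct labels for which expected m/z are computed
#'   (default `"[M+H]+"`).
#' @param include_parent Keep the untransformed parent as a depth-0
#'   candidate (default TRUE).
#' @return A data.frame of candidates: `parent`, `chain`, `product_formula`,
#'   `depth`, and one `mz_<ion>` column per ion, plus a `formulas` attribute
#'   holding the product `elemental_formula` objects.
#' @examples
#' cand <- enumerate_biotransformations("C10H14N2",
#'   default_transformations(), max_depth = 2)
#' subset(cand, product_formula == "C10H12N2O")  # cotinine
#' @export
enumerate_biotransformations <- function(parent,
                                         transformations = default_transformations(),
                                         max_depth = 2L,
                                         ions = "[M+H]+",
                                         include_parent = TRUE) {
  stopifnot(max_depth >= 1L || (max_depth == 0L && include_parent))
  parent <- parse_formula(parent)
  ions <- vapply(ions, .normalize_ion_label, character(1))

  seen <- new.env(parent = emptyenv())
  out <- list()
  skipped <- character(0)
  push <- function(f, chain, depth) {
    key <- format(f)
    prev <- get0(key, envir = seen)
    if (!is.null(prev) && prev <= depth) return(FALSE)
    assign(key, depth, envir = seen)
    out[[key]] <<- list(formula = f, chain = chain, depth = depth)
    TRUE
  }
  if (include_parent) push(parent, character(0), 0L)

  frontier <- list(list(formula = parent, chain = character(0), depth = 0L))
  while (length(frontier) > 0L) {
    nxt <- list()
    for (node in frontier) {
      if (node$depth >= max_depth) next
      for (tr in transformations) {
        f2 <- tryCatch(formula_add(node$formula, tr$delta), error = function(e) NULL)
        if (is.null(f2)) {
          skipped <- c(skipped, paste(c(node$chain, tr$name), collapse = " > "))
          next
        }
        chain2 <- c(node$chain, tr$name)
        if (push(f2, chain2, node$depth + 1L)) {
          nxt[[length(nxt) + 1L]] <- list(formula = f2, chain = chain2,
                                          depth = node$depth + 1L)
        }
      }
    }
    frontier <- nxt
  }

  rows <- lapply(out, function(cand) {
    mzs <- vapply(ions, function(i) ion_mz(cand$formula, i), numeric(1))
    c(list(parent = format(parent),
           chain = paste(cand$chain, collapse = " > "),
           product_formula = format(cand$formula),
           depth = cand$depth),
      as.list(stats::setNames(mzs, paste0("mz_", ions))))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  rownames(df) <- NULL
  df <- df[order(df$depth, df$product_formula), , drop = FALSE]
  attr(df, "formulas") <- lapply(df$product_formula, parse_formula)
  attr(df, "skipped") <- skipped
  class(df) <- c("biotransformation_candidates", "data.frame")
  df
}

#' Match expected biotransformation products against observed features
#'
#' Compares every candidate expected m/z (over all its ion columns) with the
#' m/z of every feature, keeping pairs within the ppm tolerance. One
#' candidate may match several features (positional isomers at different
#' retention times); all matches are preserved.
#'
#' @param candidates From [enumerate_biotransformations()].
#' @param features A `feature_table`, or a data.frame with columns
#'   `feature_id` and `mz`.
#' @param tol_ppm Mass tolerance in ppm (default 5, the peak-picking
#'   tolerance).
#' @return data.frame with one row per (candidate, ion, feature) match:
#'   `product_formula`, `chain`, `ion`, `expected_mz`, `feature_id`,
#'   `observed_mz`, `ppm`.
#' @export
match_expected <- function(candidates, features, tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  if (inherits(features, "feature_table")) features <- features$features
  stopifnot(all(c("feature_id", "mz") %in% names(features)))
  mz_cols <- grep("^mz_", names(candidates), value = TRUE)
  res <- list()
  for (col in mz_cols) {
    ion <- sub("^mz_", "", col)
    for (i in seq_len(nrow(candidates))) {
      expected <- candidates[[col]][i]
      ppm <- ppm_error(features$mz, expected)
      hit <- which(abs(ppm) <= tol_ppm)
      if (length(hit) > 0L) {
        res[[length(res) + 1L]] <- data.frame(
          product_formula = candidates$product_formula[i],
          chain = candidates$chain[i],
          ion = ion,
          expected_mz = expected,
          feature_id = features$feature_id[hit],
          observed_mz = features$mz[hit],
          ppm = ppm[hit],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(product_formula = character(0), chain = character(0),
                      ion = character(0), expected_mz = numeric(0),
                      feature_id = character(0), observed_mz = numeric(0),
                      ppm = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a candidate list to CSV
#'
#' Long format: one row per candidate x ion species, with columns
#' `parent`, `chain`, `product_formula`, `ion`, `expected_mz`, `depth`.
#'
#' @param candidates From [enumerate_biotransformations()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_candidates_csv <- function(candidates, path) {
  mz_cols <- grep("^mz_", names(candidates), value = TRUE)
  long <- do.call(rbind, lapply(mz_cols, function(col) {
    data.frame(parent = candidates$parent,
               chain = candidates$chain,
               product_formula = candidates$product_formula,
               ion = sub("^mz_", "", col),
               expected_mz = candidates[[col]],
               depth = candidates$depth,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
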