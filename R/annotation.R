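# Library matching and MSI-style identification confidence levels.
# Level 1: matched to an authentic in-house standard by >= 2 independent
# orthogonal properties (m/z + retention time, or m/z + MS2).
# Level 2: putative, by MS2 spectral similarity to a spectral library.
# Level 3: class-level only (externally supplied class label).
# Level 4: unidentified/unclassified.

#' Compound library entry
#'
#' @param name Compound name.
#' @param formula Neutral `elemental_formula` or string.
#' @param rt Expected retention time in minutes (optional; NA when the
#'   entry comes from a spectral library without the local LC method).
#' @param ion Preferred ion label (default `"[M+H]+"`).
#' @param spectrum Optional reference `ms2_spectrum`.
#' @param is_standard TRUE when the entry is backed by an authentic
#'   standard run in-house (required for level-1 identification).
#' @param class_label Optional externally supplied compound-class label.
#' @return A `library_entry`.
#' @export
library_entry <- function(name, formula, rt = NA_real_, ion = "[M+H]+",
                          spectrum = NULL, is_standard = TRUE,
                          class_label = NA_character_) {
  f <- parse_formula(formula)
  if (!is.na(rt) && rt < 0) stop("retention time must be >= 0", call. = FALSE)
  structure(list(name = name, formula = f, rt = rt,
                 ion = .normalize_ion_label(ion),
                 mz = ion_mz(f, ion), spectrum = spectrum,
                 is_standard = is_standard, class_label = class_label),
            class = "library_entry")
}

#' Match one feature against a compound library
#'
#' Evidence types accumulate independently per entry: `mz` (feature m/z
#' within ppm tolerance of the entry's ion m/z), `rt` (within the retention
#' time tolerance) and `ms2` (spectral similarity at or above the cutoff).
#' Only entries with at least m/z evidence are returned, ranked by evidence
#' count and then similarity.
#'
#' @param feature List or one-row data.frame with `feature_id`, `mz`,
#'   and optionally `rt`.
#' @param library List of `library_entry`.
#' @param spectrum Optional `ms2_spectrum` of the feature.
#' @param mz_tol_ppm Mass tolerance in ppm (default 5).
#' @param rt_tol_min Retention-time tolerance in minutes (default 0.2).
#' @param ms2_cutoff Spectral-similarity cutoff 0-100 (default 85).
#' @return data.frame of candidates: `feature_id`, `compound`, `formula`,
#'   `evidence` (comma-joined evidence set), `n_evidence`, `similarity`,
#'   `is_standard`, `class_label`.
#' @export
match_library <- function(feature, library, spectrum = NULL,
                          mz_tol_ppm = 5, rt_tol_min = 0.2,
                          ms2_cutoff = 85) {
  stopifnot(length(library) > 0L)
  if (is.data.frame(feature)) feature <- as.list(feature[1L, ])
  out <- list()
  for (entry in library) {
    if (abs(ppm_error(feature$mz, entry$mz)) > mz_tol_ppm) next
    evidence <- "mz"
    sim <- NA_real_
    if (!is.null(feature$rt) && !is.na(feature$rt) && !is.na(entry$rt) &&
        abs(feature$rt - entry$rt) <= rt_tol_min) {
      evidence <- c(evidence, "rt")
    }
    if (!is.null(spectrum) && !is.null(entry$spectrum)) {
      sim <- spectral_similarity(spectrum, entry$spectrum)$score
      if (sim >= ms2_cutoff) evidence <- c(evidence, "ms2")
    }
    out[[length(out) + 1L]] <- data.frame(
      feature_id = feature$feature_id, compound = entry$name,
      formula = format(entry$formula),
      evidence = paste(evidence, collapse = ","),
      n_evidence = length(evidence), similarity = sim,
      is_standard = entry$is_standard,
      class_label = entry$class_label, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(feature_id = character(0), compound = character(0),
                      formula = character(0), evidence = character(0),
                      n_evidence = integer(0), similarity = numeric(0),
                      is_standard = logical(0), class_label = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$n_evidence, -ifelse(is.na(res$similarity), -1,
                                            res$similarity)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign an MSI-style identification level
#'
#' Deterministic and order-independent over the candidate list: the best
#' candidate (most evidence, then highest similarity) decides the level.
#'
#' @param candidates From [match_library()] for one feature (possibly
#'   empty).
#' @param class_label Externally supplied compound-class label for the
#'   feature (from class-prediction tools), used for level 3 when no
#'   library match exists.
#' @return One-row data.frame: `feature_id`, `annotation`, `level`
#'   (1-4), `evidence`, `similarity`.
#' @export
assign_level <- function(candidates, class_label = NA_character_) {
  if (nrow(candidates) == 0L) {
    lvl <- if (!is.na(class_label)) 3L else 4L
    return(data.frame(feature_id = NA_character_,
                      annotation = if (!is.na(class_label)) class_label else
                        "unknown",
                      level = lvl, evidence = if (!is.na(class_label))
                        "class_only" else "",
                      similarity = NA_real_, stringsAsFactors = FALSE))
  }
  best <- candidates[1L, ]
  ev <- strsplit(best$evidence, ",", fixed = TRUE)[[1]]
  orthogonal <- intersect(ev, c("mz", "rt", "ms2"))
  lvl <- if (length(orthogonal) >= 2L && isTRUE(best$is_standard)) {
    1L
  } else if ("ms2" %in% ev) {
    2L
  } else if (!is.na(class_label) ||
             (!is.na(best$class_label) && nzchar(best$class_label))) {
    3L
  } else {
    4L
  }
  ann <- if (lvl <= 2L) best$compound else if (lvl == 3L) {
    if (!is.na(class_label)) class_label else best$class_label
  } else "unknown"
  data.frame(feature_id = best$feature_id, annotation = ann, level = lvl,
             evidence = best$evidence, similarity = best$similarity,
             stringsAsFactors = FALSE)
}

#' Verify an MS2-based annotation against an authentic standard spectrum
#'
#' A putative identity is refuted when the feature spectrum scores below
#' the similarity cutoff against the authentic standard; the annotation is
#' then demoted to class level (3) when a class label exists, otherwise to
#' unknown (4).
#'
#' @param annotation One-row data.frame from [assign_level()].
#' @param feature_spectrum `ms2_spectrum` of the feature (NULL ->
#'   unverifiable).
#' @param standard_spectrum `ms2_spectrum` of the authentic standard
#'   (NULL -> unverifiable).
#' @param ms2_cutoff Similarity cutoff (default 85).
#' @param class_label Fallback class label used on demotion.
#' @return The annotation with added columns `status`
#'   (`"confirmed"`, `"refuted"` or `"unverifiable"`) and
#'   `standard_similarity`; refuted annotations have their level demoted.
#' @export
verify_against_standard <- function(annotation, feature_spectrum,
                                    standard_spectrum, ms2_cutoff = 85,
                                    class_label = NA_character_) {
  if (is.null(feature_spectrum) || is.null(standard_spectrum)) {
    annotation$status <- "unverifiable"
    annotation$standard_similarity <- NA_real_
    return(annotation)
  }
  sim <- spectral_similarity(feature_spectrum, standard_spectrum)$score
  annotation$standard_similarity <- sim
  if (sim >= ms2_cutoff) {
    annotation$status <- "confirmed"
  } else {
    annotation$status <- "refuted"
    annotation$level <- if (!is.na(class_label)) 3L else 4L
    annotation$annotation <- if (!is.na(class_label)) class_label else
      "unknown"
  }
  annotation
}

#' Demo compound library
#'
#' A small built-in library for examples and closed-loop tests: the
#' nicotine biotransformation series (nicotine, cotinine, nornicotine,
#' nicotine-N-oxide, the ring-opened keto/hydroxy acids, glycine and
#' acetyl conjugates, NNK) plus polar metabolites relevant to the
#' exposure study (amino acids, nucleobases, purine/polyamine pathway
#' members). Retention times and MS2 spectra are synthetic stand-ins
#' generated from the formulas, not measured values.
#'
#' @param with_spectra Attach synthetic reference spectra (default TRUE).
#' @param seed Seed for the synthetic spectra.
#' @return List of `library_entry`.
#' @export
demo_library <- function(with_spectra = TRUE, seed = 42L) {
  defs <- list(
    list("nicotine",              "C10H14N2",    6.20, "[M+H]+"),
    list("cotinine",              "C10H12N2O",   7.10, "[M+H]+"),
    list("nornicotine",           "C9H12N2",     6.45, "[M+H]+"),
    list("nicotine-N-oxide",      "C10H14N2O",   8.30, "[M+H]+"),
    list("hydroxynicotine",       "C10H14N2O",   6.25, "[M+H]+"),
    list("hydroxycotinine",       "C10H12N2O2",  9.05, "[M+H]+"),
    list("pyridyl keto acid",     "C9H9NO3",    11.80, "[M+H]+"),
    list("pyridyl hydroxy acid",  "C9H11NO3",   12.40, "[M+H]+"),
    list("nicotine glycine conjugate", "C12H17N3O", 10.10, "[M+H]+"),
    list("acetoxynicotine",       "C12H16N2O2",  5.80, "[M+H]+"),
    list("NNK",                   "C10H13N3O2",  4.90, "[M+H]+"),
    list("methylthioadenosine",   "C11H15N5O3S", 6.55, "[M+H]+"),
    list("cytosine",              "C4H5N3O",    10.35, "[M+H]+"),
    list("uric acid",             "C5H4N4O3",   13.76, "[M-H]-"),
    list("l-glutamate",           "C5H9NO4",    15.34, "[M-H]-"),
    list("l-glutamine",           "C5H10N2O3",  14.90, "[M+H]+"),
    list("l-proline",             "C5H9NO2",    12.90, "[M+H]+"),
    list("l-citrulline",          "C6H13N3O3",  15.10, "[M+H]+"),
    list("l-arginine",            "C6H14N4O2",  16.80, "[M+H]+"),
    list("l-ornithine",           "C5H12N2O2",  17.20, "[M+H]+"),
    list("l-lysine",              "C6H14N2O2",  17.00, "[M+H]+"),
    list("l-histidine",           "C6H9N3O2",   15.70, "[M+H]+"),
    list("l-phenylalanine",       "C9H11NO2",    8.90, "[M+H]+"),
    list("l-tyrosine",            "C9H11NO3",   10.60, "[M+H]+"),
    list("l-tryptophan",          "C11H12N2O2",  9.40, "[M+H]+"),
    list("l-methionine",          "C5H11NO2S",  11.70, "[M+H]+"),
    list("l-cystine",             "C6H12N2O4S2", 15.80, "[M+H]+"),
    list("glutathione",           "C10H17N3O6S", 14.20, "[M+H]+"),
    list("S-adenosylmethionine",  "C15H22N6O5S", 18.50, "[M+H]+"),
    list("spermidine",            "C7H19N3",    19.60, "[M+H]+"),
    list("putrescine",            "C4H12N2",    18.90, "[M+H]+"),
    list("adenine",               "C5H5N5",      7.80, "[M+H]+"),
    list("adenosine",             "C10H13N5O4",  9.20, "[M+H]+"),
    list("hypoxanthine",          "C5H4N4O",    10.90, "[M-H]-"),
    list("xanthine",              "C5H4N4O2",   12.10, "[M-H]-"),
    list("uracil",                "C4H4N2O2",    9.80, "[M-H]-"),
    list("thymine",               "C5H6N2O2",    8.60, "[M-H]-"),
    list("5-methylcytosine",      "C5H7N3O",     9.95, "[M+H]+"),
    list("maleamic acid",         "C4H5NO3",    15.55, "[M-H]-"),
    list("N-acetylneuraminic acid", "C11H19NO9", 16.89, "[M+H]+"),
    list("deoxycytidine",         "C9H13N3O4",  10.34, "[M+H]+")
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(defs, function(d) {
    sp <- NULL
    if (with_spectra) {
      sp <- .synthetic_reference_spectrum(d[[1L]], d[[2L]], d[[4L]])
    }
    library_entry(d[[1L]], d[[2L]], rt = d[[3L]], ion = d[[4L]],
                  spectrum = sp)
  })
}

# Deterministic pseudo-fragmentation used for the demo library: fragments
# are reproducible per compound name so that identical compounds always get
# identical reference spectra.
.synthetic_reference_spectrum <- function(name, formula, ion) {
  pmz <- ion_mz(formula, ion)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  set.seed(h %% 100000L)
  n <- sample(5:12, 1L)
  frag <- sort(stats::runif(n, min = 40, max = pmz - 1))
  inten <- stats::runif(n, 1, 100)
  ms2_spectrum(id = name, precursor_mz = pmz, mz = frag, intensity = inten)
}

#' Read / write a compound library as CSV (plus optional MSP spectra)
#'
#' CSV columns: `name`, `formula`, `rt`, `ion`, `is_standard`,
#' `class_label`. Spectra travel in a sidecar `.msp` keyed by compound
#' name.
#'
#' @param library List of `library_entry`.
#' @param path CSV path; a sidecar `<path>.msp` is written when any entry
#'   carries a spectrum.
#' @return `write_library`: the path invisibly; `read_library`: a list of
#'   `library_entry`.
#' @export
write_library <- function(library, path) {
  df <- do.call(rbind, lapply(library, function(e) {
    data.frame(name = e$name, formula = format(e$formula), rt = e$rt,
               ion = e$ion, is_standard = e$is_standard,
               class_label = e$class_label, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  specs <- Filter(Negate(is.null), lapply(library, `[[`, "spectrum"))
  if (length(specs) > 0L) {
    write_spectra(specs, paste0(path, ".msp"), format = "msp")
  }
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  specs <- list()
  msp <- paste0(path, ".msp")
  if (file.exists(msp)) {
    sl <- read_spectra(msp, format = "msp")
    specs <- stats::setNames(sl, vapply(sl, `[[`, character(1), "id"))
  }
  lapply(seq_len(nrow(df)), function(i) {
    library_entry(df$name[i], df$formula[i], rt = df$rt[i], ion = df$ion[i],
                  spectrum = specs[[df$name[i]]],
                  is_standard = df$is_standard[i],
                  class_label = df$class_label[i])
  })
}
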