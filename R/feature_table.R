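#' Feature table container
#'
#' The object every pipeline stage transforms: a features x samples matrix of
#' peak areas plus sample and feature metadata. Missing values (`NA`) encode
#' peaks not detected in a sample; the original detection mask is preserved
#' through imputation so presence-based filters operate on pre-imputation
#' detection.
#'
#' @param areas Numeric matrix, features in rows, samples in columns. `NA`
#'   marks a missing (undetected) peak; present values must be >= 0.
#' @param samples data.frame with one row per column of `areas`:
#'   `sample_id`, `role` (one of `"qc"`, `"study"`, `"blank"`,
#'   `"solvent_control"`, `"medium_control"`), `group` (`"exposed"`,
#'   `"control"`, `"none"`), `timepoint` (`"t0"`, `"t1"`, `"t4"` or `NA`),
#'   `pair_id` (pairing of exposed/control replicates), `injection_order`
#'   (unique positive integer).
#' @param features data.frame with one row per row of `areas`:
#'   `feature_id`, `mz` (> 0), `rt` (minutes, >= 0), `ion`, `polarity`
#'   (`"pos"` or `"neg"`).
#' @param ratings Optional numeric matrix of per-sample peak ratings in
#'   `[0, 10]`, same dimensions as `areas`.
#' @param detected Optional logical matrix of the original detection mask;
#'   defaults to `!is.na(areas)`.
#' @param log List of stage records (see [qc_report()]); usually left empty.
#' @param positive Require non-negative areas (TRUE for raw peak areas, the
#'   default; FALSE for tables on a transformed scale such as log/Pareto).
#' @return A `feature_table` object.
#' @export
feature_table <- function(areas, samples, features, ratings = NULL,
                          detected = NULL, log = list(), positive = TRUE) {
  areas <- as.matrix(areas)
  stopifnot(is.numeric(areas))
  if (nrow(samples) != ncol(areas)) {
    stop("samples metadata rows must match area matrix columns", call. = FALSE)
  }
  if (nrow(features) != nrow(areas)) {
    stop("features metadata rows must match area matrix rows", call. = FALSE)
  }
  req_s <- c("sample_id", "role", "group", "timepoint", "pair_id",
             "injection_order")
  req_f <- c("feature_id", "mz", "rt", "ion", "polarity")
  miss <- setdiff(req_s, names(samples))
  if (length(miss)) stop("samples metadata lacks: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(req_f, names(features))
  if (length(miss)) stop("features metadata lacks: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples$injection_order)) {
    stop("injection_order must be unique per sample", call. = FALSE)
  }
  if (anyDuplicated(features$feature_id)) {
    stop("feature_id must be unique", call. = FALSE)
  }
  if (positive && any(areas < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative where present", call. = FALSE)
  }
  if (any(features$mz <= 0) || any(features$rt < 0)) {
    stop("features require mz > 0 and rt >= 0", call. = FALSE)
  }
  rownames(areas) <- features$feature_id
  colnames(areas) <- samples$sample_id
  if (is.null(detected)) detected <- !is.na(areas)
  dimnames(detected) <- dimnames(areas)
  if (!is.null(ratings)) {
    ratings <- as.matrix(ratings)
    stopifnot(all(dim(ratings) == dim(areas)))
    dimnames(ratings) <- dimnames(areas)
  }
  structure(list(areas = areas, samples = as.data.frame(samples),
                 features = as.data.frame(features), ratings = ratings,
                 detected = detected, log = log),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$areas), " features x ", ncol(x$areas),
      " samples\n", sep = "")
  cat("  roles: ", paste(sprintf("%s=%d", names(table(x$samples$role)),
                                 table(x$samples$role)), collapse = ", "),
      "\n", sep = "")
  n_na <- sum(is.na(x$areas))
  cat("  missing entries: ", n_na, sprintf(" (%.1f%%)",
      100 * n_na / length(x$areas)), "\n", sep = "")
  if (length(x$log)) {
    cat("  stages: ", paste(vapply(x$log, `[[`, character(1), "stage"),
                            collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$areas)

#' Subset a feature table by feature and/or sample index
#'
#' @param table A `feature_table`.
#' @param features Row (feature) index: logical, integer or feature ids.
#' @param samples Column (sample) index: logical, integer or sample ids.
#' @return A `feature_table`.
#' @export
ft_subset <- function(table, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(table$areas)) else features
  si <- if (is.null(samples)) seq_len(ncol(table$areas)) else samples
  if (is.character(fi)) fi <- match(fi, table$features$feature_id)
  if (is.character(si)) si <- match(si, table$samples$sample_id)
  out <- table
  out$areas <- table$areas[fi, si, drop = FALSE]
  out$samples <- table$samples[si, , drop = FALSE]
  out$features <- table$features[fi, , drop = FALSE]
  if (!is.null(table$ratings)) {
    out$ratings <- table$ratings[fi, si, drop = FALSE]
  }
  out$detected <- table$detected[fi, si, drop = FALSE]
  out
}

.log_stage <- function(table, stage, ...) {
  rec <- c(list(stage = stage, n_features = nrow(table$areas),
                n_samples = ncol(table$areas)), list(...))
  table$log[[length(table$log) + 1L]] <- rec
  table
}

.qc_idx <- function(table) which(table$samples$role == "qc")
.study_idx <- function(table) which(table$samples$role == "study")

#' Per-stage QC report of a processed table
#'
#' @param table A `feature_table` that has been through pipeline stages.
#' @return data.frame of stage records (stage name, feature and sample
#'   counts, stage parameters flattened to character).
#' @export
qc_report <- function(table) {
  if (length(table$log) == 0L) {
    return(data.frame(stage = character(0), n_features = integer(0),
                      n_samples = integer(0), details = character(0)))
  }
  do.call(rbind, lapply(table$log, function(rec) {
    extra <- rec[setdiff(names(rec), c("stage", "n_features", "n_samples"))]
    data.frame(stage = rec$stage, n_features = rec$n_features,
               n_samples = rec$n_samples,
               details = paste(names(extra),
                               vapply(extra, function(v)
                                 paste(format(v), collapse = ","),
                                 character(1)),
                               sep = "=", collapse = "; "),
               stringsAsFactors = FALSE)
  }))
}

#' Read / write a feature table as wide CSV plus metadata sidecars
#'
#' The wide table has features as rows (first column `feature_id`) and
#' samples as columns; sample and feature metadata travel in two sidecar
#' CSVs. `write_feature_table("dir/stem")` emits `stem_areas.csv`,
#' `stem_samples.csv`, `stem_features.csv` (and `stem_ratings.csv` when
#' ratings are present); `read_feature_table` reverses it.
#'
#' @param table A `feature_table`.
#' @param stem Path stem for the CSV trio.
#' @return `write_feature_table`: the stem, invisibly.
#'   `read_feature_table`: a `feature_table`.
#' @export
write_feature_table <- function(table, stem) {
  aw <- data.frame(feature_id = table$features$feature_id, table$areas,
                   check.names = FALSE)
  utils::write.csv(aw, paste0(stem, "_areas.csv"), row.names = FALSE)
  utils::write.csv(table$samples, paste0(stem, "_samples.csv"),
                   row.names = FALSE)
  utils::write.csv(table$features, paste0(stem, "_features.csv"),
                   row.names = FALSE)
  if (!is.null(table$ratings)) {
    rw <- data.frame(feature_id = table$features$feature_id, table$ratings,
                     check.names = FALSE)
    utils::write.csv(rw, paste0(stem, "_ratings.csv"), row.names = FALSE)
  }
  invisible(stem)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(stem) {
  aw <- utils::read.csv(paste0(stem, "_areas.csv"), check.names = FALSE)
  samples <- utils::read.csv(paste0(stem, "_samples.csv"))
  features <- utils::read.csv(paste0(stem, "_features.csv"))
  areas <- as.matrix(aw[, -1, drop = FALSE])
  ratings <- NULL
  rp <- paste0(stem, "_ratings.csv")
  if (file.exists(rp)) {
    rw <- utils::read.csv(rp, check.names = FALSE)
    ratings <- as.matrix(rw[, -1, drop = FALSE])
  }
  feature_table(areas, samples, features, ratings = ratings,
                positive = !any(areas < 0, na.rm = TRUE))
}
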