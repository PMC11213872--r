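#' MS2 fragment spectrum
#'
#' @param id Spectrum/feature identifier.
#' @param precursor_mz Precursor m/z (> 0).
#' @param rt Retention time in minutes (optional).
#' @param polarity `"pos"` or `"neg"` (optional).
#' @param collision_energy Label such as `"NCE35"` (optional).
#' @param mz Fragment m/z vector; must stay below `precursor_mz + 1.5`
#'   (isotope guard).
#' @param intensity Relative intensities, rescaled to a base peak of 100.
#' @return An `ms2_spectrum` with peaks sorted by m/z.
#' @export
ms2_spectrum <- function(id, precursor_mz, mz, intensity, rt = NA_real_,
                         polarity = NA_character_,
                         collision_energy = NA_character_) {
  stopifnot(precursor_mz > 0, length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (any(mz >= precursor_mz + 1.5)) {
    stop("fragment m/z above precursor + 1.5 (isotope guard)", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (length(intensity) > 0L && max(intensity) > 0) {
    intensity <- 100 * intensity / max(intensity)
  }
  structure(list(id = as.character(id), precursor_mz = precursor_mz,
                 rt = rt, polarity = polarity,
                 collision_energy = collision_energy,
                 mz = mz, intensity = intensity),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2_spectrum> ", x$id, "  precursor m/z ",
      sprintf("%.4f", x$precursor_mz), "  ", length(x$mz), " peaks\n",
      sep = "")
  invisible(x)
}

#' Read MS2 spectra from MGF or NIST-style MSP text
#'
#' Both dialects are plain text: MGF records live between `BEGIN IONS` /
#' `END IONS` with `PEPMASS=`, `TITLE=`, `RTINSECONDS=` headers; MSP records
#' start at `Name:` with `PrecursorMZ:` and `Num Peaks:` headers followed by
#' m/z-intensity pairs. Malformed records (e.g. missing precursor) are
#' skipped with a line-numbered warning.
#'
#' @param path File path.
#' @param format `"mgf"` or `"msp"`; guessed from the extension by default.
#' @return List of `ms2_spectrum`.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "msp")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.msp$", path, ignore.case = TRUE)) "msp" else "mgf"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "mgf") .read_mgf(lines) else .read_msp(lines)
}

.read_mgf <- function(lines) {
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (toupper(trimws(lines[i])) != "BEGIN IONS") { i <- i + 1L; next }
    start <- i
    j <- i + 1L
    hdr <- list(); mz <- numeric(0); inten <- numeric(0)
    while (j <= length(lines) && toupper(trimws(lines[j])) != "END IONS") {
      ln <- trimws(lines[j])
      if (grepl("=", ln, fixed = TRUE)) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        hdr[[toupper(kv[1L])]] <- paste(kv[-1L], collapse = "=")
      } else if (nzchar(ln)) {
        vals <- as.numeric(strsplit(ln, "[[:space:]]+")[[1]])
        mz <- c(mz, vals[1L]); inten <- c(inten, vals[2L])
      }
      j <- j + 1L
    }
    prec <- suppressWarnings(
      as.numeric(strsplit(hdr[["PEPMASS"]] %||% "", "[[:space:]]+")[[1]][1L]))
    if (length(prec) == 0L || is.na(prec)) {
      warning("MGF record at line ", start,
              " skipped: missing or invalid PEPMASS", call. = FALSE)
    } else {
      rt <- suppressWarnings(as.numeric(hdr[["RTINSECONDS"]] %||% NA)) / 60
      out[[length(out) + 1L]] <- ms2_spectrum(
        id = hdr[["TITLE"]] %||% paste0("spectrum_", length(out) + 1L),
        precursor_mz = prec, mz = mz, intensity = inten, rt = rt,
        polarity = .charge_polarity(hdr[["CHARGE"]]))
    }
    i <- j + 1L
  }
  out
}

.charge_polarity <- function(ch) {
  if (is.null(ch)) return(NA_character_)
  if (grepl("-", ch, fixed = TRUE)) "neg" else "pos"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_msp <- function(lines) {
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^Name:", lines[i], ignore.case = TRUE)) { i <- i + 1L; next }
    start <- i
    hdr <- list()
    while (i <= n && grepl("^[A-Za-z][A-Za-z0-9_ ]*:", lines[i])) {
      kv <- sub("^([^:]+):[[:space:]]*(.*)$", "\\1\t\\2", lines[i])
      kv <- strsplit(kv, "\t", fixed = TRUE)[[1]]
      hdr[[toupper(trimws(kv[1L]))]] <- if (length(kv) > 1L) kv[2L] else ""
      i <- i + 1L
    }
    npk <- suppressWarnings(as.integer(hdr[["NUM PEAKS"]] %||% NA))
    mz <- numeric(0); inten <- numeric(0)
    while (i <= n && nzchar(trimws(lines[i])) &&
           !grepl("^Name:", lines[i], ignore.case = TRUE)) {
      vals <- as.numeric(strsplit(trimws(lines[i]), "[[:space:];]+")[[1]])
      mz <- c(mz, vals[1L]); inten <- c(inten, vals[2L])
      i <- i + 1L
    }
    prec <- suppressWarnings(as.numeric(hdr[["PRECURSORMZ"]] %||% NA))
    if (is.na(prec)) {
      warning("MSP record at line ", start,
              " skipped: missing PrecursorMZ", call. = FALSE)
    } else {
      if (!is.na(npk) && npk != length(mz)) {
        warning("MSP record at line ", start, ": Num Peaks (", npk,
                ") disagrees with ", length(mz), " peak lines", call. = FALSE)
      }
      out[[length(out) + 1L]] <- ms2_spectrum(
        id = hdr[["NAME"]], precursor_mz = prec, mz = mz, intensity = inten,
        rt = suppressWarnings(as.numeric(hdr[["RETENTIONTIME"]] %||% NA)))
    }
  }
  out
}

#' Write MS2 spectra to MGF or NIST-style MSP text
#'
#' Round-trips with [read_spectra()] (m/z and relative intensities to five
#' decimals).
#'
#' @param spectra List of `ms2_spectrum`.
#' @param path Output path.
#' @param format `"mgf"` or `"msp"`; guessed from the extension by default.
#' @return The path, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("auto", "mgf", "msp")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.msp$", path, ignore.case = TRUE)) "msp" else "mgf"
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    if (format == "mgf") {
      writeLines(c("BEGIN IONS",
                   paste0("TITLE=", s$id),
                   paste0("PEPMASS=", sprintf("%.5f", s$precursor_mz)),
                   if (!is.na(s$rt)) paste0("RTINSECONDS=",
                                            sprintf("%.3f", s$rt * 60)),
                   sprintf("%.5f %.5f", s$mz, s$intensity),
                   "END IONS", ""), con)
    } else {
      writeLines(c(paste0("Name: ", s$id),
                   paste0("PrecursorMZ: ", sprintf("%.5f", s$precursor_mz)),
                   if (!is.na(s$rt)) paste0("RetentionTime: ",
                                            sprintf("%.3f", s$rt)),
                   paste0("Num Peaks: ", length(s$mz)),
                   sprintf("%.5f %.5f", s$mz, s$intensity),
                   ""), con)
    }
  }
  invisible(path)
}
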