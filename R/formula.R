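# Monoisotopic atomic masses (Da), CODATA/IUPAC most-abundant isotopes.
.MONOISOTOPIC <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Cl = 34.96885268,
  Na = 22.9897692809,
  K  = 38.96370668
)

.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS <- .MONOISOTOPIC[["H"]] - .ELECTRON_MASS

#' Elemental formula objects
#'
#' An `elemental_formula` is a named integer vector of atom counts over the
#' supported element alphabet (C, H, N, O, S, P, Cl, Na, K). Formulas are the
#' backbone of all exact-mass arithmetic: biotransformation screening, adduct
#' m/z computation and library matching.
#'
#' @param x A Hill-style formula string (e.g. `"C10H14N2"`), or a named
#'   numeric vector of atom counts.
#' @return An object of class `elemental_formula`.
#' @examples
#' parse_formula("C10H14N2")       # nicotine
#' parse_formula(c(C = 4, H = 5, N = 3, O = 1))  # cytosine
#' @export
parse_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    counts <- .parse_formula_string(x)
  } else if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    stop("supply a formula string or a named count vector", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.MONOISOTOPIC))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("atom counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("formula must contain at least one atom",
                                 call. = FALSE)
  out <- integer(length(.MONOISOTOPIC))
  names(out) <- names(.MONOISOTOPIC)
  out[names(counts)] <- as.integer(counts)
  structure(out, class = "elemental_formula")
}

.parse_formula_string <- function(s) {
  s <- gsub("[[:space:]_]", "", s)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(toks)) != nchar(s)) {
    stop("cannot parse formula string: ", s, call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", toks)
  num <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(num == "", 1L, as.integer(num))
  tapply(n, sym, sum)
}

#' @export
format.elemental_formula <- function(x, ...) {
  # Hill order: C, H, then alphabetical
  els <- names(x)[x > 0]
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e) {
    if (x[[e]] == 1L) e else paste0(e, x[[e]])
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "  (",
      sprintf("%.5f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' @export
as.character.elemental_formula <- function(x, ...) format(x)

#' Add or subtract atom counts between formulas
#'
#' Used when applying biotransformation deltas and adduct composition
#' changes. Subtraction that would drive any count negative signals an error.
#'
#' @param f An `elemental_formula`.
#' @param delta Named numeric vector of atom counts to add (negative values
#'   remove atoms), or an `elemental_formula`.
#' @return An `elemental_formula`, or an error if a count would go negative.
#' @export
formula_add <- function(f, delta) {
  f <- parse_formula(f)
  d <- .as_delta(delta)
  out <- unclass(f)
  out[names(d)] <- out[names(d)] + d
  if (any(out < 0)) {
    stop("formula arithmetic yields negative atom count", call. = FALSE)
  }
  parse_formula(out)
}

.as_delta <- function(delta) {
  if (inherits(delta, "elemental_formula")) delta <- unclass(delta)
  if (!is.numeric(delta) || is.null(names(delta))) {
    stop("delta must be a named numeric vector", call. = FALSE)
  }
  unknown <- setdiff(names(delta), names(.MONOISOTOPIC))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  delta
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of atom counts times monoisotopic atomic masses (most abundant
#' isotope per element), deterministic to better than 1e-6 Da.
#'
#' @param formula An `elemental_formula` or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C10H14N2")  # nicotine, 162.1157
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  sum(unclass(f) * .MONOISOTOPIC[names(f)])
}

#' Mass of a pure delta (may be negative)
#' @noRd
.delta_mass <- function(delta) {
  d <- .as_delta(delta)
  sum(d * .MONOISOTOPIC[names(d)])
}
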