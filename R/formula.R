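# Monoisotopic masses of the lightest stable isotope (u), IUPAC/CODATA.
# Frozen in code so m/z values are bit-stable across platforms.
MONOISOTOPIC_MASS <- c(
  C  = 12.0,          # exact by definition
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  S  = 31.97207117,
  F  = 18.99840316,
  Cl = 34.96885268,
  Br = 78.91833760,
  P  = 30.97376200,
  I  = 126.90447190
)

ELECTRON_MASS <- 0.00054858

#' Parse a molecular formula
#'
#' Parses a plain-text molecular formula such as \code{"C24H28N3O3"} into
#' named element counts. An element symbol without a following number has
#' an implicit count of one.
#'
#' @param text formula string: element symbols (from the supported table:
#'   C, H, N, O, S, F, Cl, Br, P, I) each followed by an optional positive
#'   integer count.
#' @return An object of class \code{MolecularFormula}: a named integer
#'   vector of element counts, in Hill order (C, H, then alphabetical).
#' @examples
#' parseFormula("C24H28N3O3")
#' @seealso [monoisotopicMz()], [formatFormula()]
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop(sprintf("formula '%s' contains unparseable characters", text))
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  unknown <- setdiff(sym, names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stop(sprintf("unknown element symbol '%s' in formula '%s'",
                 unknown[1], text))
  if (any(is.na(cnt) | cnt < 1L))
    stop(sprintf("element counts in '%s' must be positive integers", text))
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out <- out[hillOrder(names(out))]
  class(out) <- "MolecularFormula"
  out
}

hillOrder <- function(symbols) {
  if ("C" %in% symbols) {
    first <- intersect(c("C", "H"), symbols)
    c(first, sort(setdiff(symbols, first)))
  } else {
    sort(symbols)
  }
}

#' Render a formula in canonical Hill order
#'
#' @param formula a \code{MolecularFormula} from [parseFormula()] or a
#'   named count vector.
#' @return Single string, carbon then hydrogen then remaining elements
#'   alphabetically; unit counts are omitted.
#' @export
formatFormula <- function(formula) {
  counts <- unclass(formula)
  counts <- counts[hillOrder(names(counts))]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' @export
print.MolecularFormula <- function(x, ...) {
  cat("MolecularFormula:", formatFormula(x), "\n")
  invisible(x)
}

#' Exact monoisotopic m/z of an ion
#'
#' Computes the monoisotopic mass-to-charge ratio of an ion whose full
#' elemental composition is given (adduct atoms included, as in an
#' \eqn{[M+H]^+} formula): the sum of lightest-isotope atomic masses,
#' minus one electron mass per positive charge, divided by the charge.
#'
#' @param formula \code{MolecularFormula} or formula string.
#' @param charge positive integer charge (default 1).
#' @param digits decimals used for the rounded return value (default 5,
#'   the usual HRMS reporting convention); use \code{NULL} for the
#'   unrounded value.
#' @return m/z in u per elementary charge.
#' @examples
#' monoisotopicMz("C24H28N3O3")  # [M+H]+ ion, 406.21252
#' @export
monoisotopicMz <- function(formula, charge = 1L, digits = 5) {
  if (is.character(formula)) formula <- parseFormula(formula)
  counts <- unclass(formula)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("charge must be a positive integer")
  missing <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(missing))
    stop(sprintf("no monoisotopic mass for element '%s'", missing[1]))
  mass <- sum(counts * MONOISOTOPIC_MASS[names(counts)])
  mz <- (mass - charge * ELECTRON_MASS) / charge
  if (is.null(digits)) mz else round(mz, digits)
}
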