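#' Parse an elemental formula
#'
#' Turns a Hill-style formula string (e.g. `"C6H12O6"`) into a named count
#' vector.  Only integer and decimal counts are supported; parenthesised
#' groups are not (the bundled models do not need them).
#'
#' @param x formula string, or `NA` for an unknown composition.
#' @return named numeric vector of element counts (empty for `NA`/`""`).
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(x) {
  if (length(x) != 1L) stop_dynafba("dynafba_formula_error", "one formula at a time")
  if (is.na(x) || !nzchar(x)) return(setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x, perl = TRUE)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (!nzchar(paste(parts, collapse = "")) ||
      nchar(paste(parts, collapse = "")) != nchar(x)) {
    stop_dynafba("dynafba_formula_error", "cannot parse formula: ", x)
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  n  <- sub("^[A-Z][a-z]?", "", parts)
  n  <- ifelse(nzchar(n), as.numeric(n), 1)
  tapply(n, el, sum)[unique(el)]
}

# integer-valued atomic masses used by the toy fixture so that mass closure
# is exact by hand
ATOMIC_MASS <- c(C = 12, H = 1, N = 14, O = 16, P = 31, S = 32)

#' Molecular weight from a formula
#'
#' @param x formula string.
#' @return weight in g/mmol (integer atomic masses; `NA` if unknown element).
#' @export
formula_weight <- function(x) {
  cnt <- parse_formula(x)
  if (!length(cnt)) return(NA_real_)
  if (!all(names(cnt) %in% names(ATOMIC_MASS))) return(NA_real_)
  sum(cnt * ATOMIC_MASS[names(cnt)]) / 1000
}

# element count of one metabolite formula (0 if absent)
element_count <- function(formula, element) {
  cnt <- parse_formula(formula)
  if (element %in% names(cnt)) unname(cnt[[element]]) else 0
}
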