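#' Parse an elemental gross formula of biomass
#'
#' Gross formulas give the average elemental composition of biomass per fixed
#' carbon count, e.g. `"C6.0H9.7O2.635N0.937"` for chlorella.  Counts may be
#' non-integer (they are averages over a population) and default to 1 when
#' omitted, so `"C6H12O6"` is glucose.
#'
#' @param text A single string over the elements C, H, O, N, each followed by
#'   an optional decimal count.  An existing `gross_formula` is returned
#'   unchanged.
#' @return An object of class `gross_formula`: a list with numeric fields
#'   `c`, `h`, `o`, `n` (moles per formula unit).
#' @examples
#' gross_formula("C6.0H9.7O2.635N0.937")
#' gross_formula("C6H12O6")
#' @export
gross_formula <- function(text) {
  if (inherits(text, "gross_formula")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single formula string", call. = FALSE)
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("empty formula string", call. = FALSE)
  tokens <- regmatches(s, gregexpr("[A-Za-z][0-9]*\\.?[0-9]*", s))[[1]]
  if (paste(tokens, collapse = "") != s) {
    bad <- sub(paste(tokens, collapse = ""), "", s, fixed = TRUE)
    stop("cannot parse formula near \"", substr(bad, 1, 8), "\"", call. = FALSE)
  }
  counts <- c(C = 0, H = 0, O = 0, N = 0)
  for (tok in tokens) {
    el <- substr(tok, 1, 1)
    if (!el %in% names(counts))
      stop("unsupported element \"", el, "\" in formula (only C, H, O, N)",
           call. = FALSE)
    num <- substr(tok, 2, nchar(tok))
    cnt <- if (nzchar(num)) suppressWarnings(as.numeric(num)) else 1
    if (is.na(cnt) || cnt < 0)
      stop("invalid count in token \"", tok, "\"", call. = FALSE)
    counts[el] <- counts[el] + cnt
  }
  structure(list(c = unname(counts["C"]), h = unname(counts["H"]),
                 o = unname(counts["O"]), n = unname(counts["N"])),
            class = "gross_formula")
}

#' @export
print.gross_formula <- function(x, ...) {
  cat(sprintf("<gross formula> C%g H%g O%g N%g\n", x$c, x$h, x$o, x$n))
  invisible(x)
}

#' Reduce a gross formula to its carbon-hydrogen residue
#'
#' Under the open-nitrogen-loop convention, nitrogen is taken up as ammonium
#' (or urea) so each N notionally leaves the formula with 3 H, and oxygen
#' leaves as water taking 2 H each.  What remains is a CnHm residue that
#' carries the photosynthetic gas-exchange stoichiometry: chlorella
#' (C6.0 H9.7 O2.635 N0.937) reduces to C6.0 H1.62 and spirulina
#' (C6.0 H10.84 O2.06 N0.87) to C6.0 H4.11.
#'
#' @param f A [gross_formula()] (or a formula string).
#' @return An object of class `biomass_residue` with fields `n_c` (mol C) and
#'   `m_h` (mol H).
#' @examples
#' reduce_to_residue("C6.0H10.84O2.06N0.87")   # C6 H4.11
#' @export
reduce_to_residue <- function(f) {
  f <- gross_formula(f)
  if (f$c <= 0) stop("residue requires c > 0", call. = FALSE)
  m_h <- f$h - 3 * f$n - 2 * f$o
  if (m_h < 0)
    stop(sprintf(paste0("infeasible reduction: removing N as NH3 and O as ",
                        "H2O needs %.4g H but the formula has only %.4g"),
                 3 * f$n + 2 * f$o, f$h), call. = FALSE)
  structure(list(n_c = f$c, m_h = m_h), class = "biomass_residue")
}

#' @export
print.biomass_residue <- function(x, ...) {
  cat(sprintf("<residue> C%g H%g\n", x$n_c, x$m_h))
  invisible(x)
}

as_residue <- function(x) {
  if (inherits(x, "biomass_residue")) return(x)
  reduce_to_residue(x)
}

#' Oxygen released per carbon dioxide absorbed
#'
#' Volume (= mole, ideal gas) ratio of O2 released to CO2 absorbed when
#' biomass with residue CnHm is synthesised.  The default `"residue"`
#' convention charges one extra O2 per 2 residue H on top of the equimolar
#' carbohydrate exchange, giving 1 + m/(2n); this is the convention that
#' reproduces the reported chlorella and spirulina ratios (1.13 and 1.3425 L
#' O2 per L CO2).  The `"balanced"` mode instead uses the fully
#' oxygen-balanced photosynthesis equation n CO2 + (n + m/4) O2 equivalent,
#' giving 1 + m/(4n).
#'
#' @param r A `biomass_residue` (or a gross formula / string, reduced first).
#' @param convention `"residue"` (default) or `"balanced"`.
#' @return Numeric ratio, L O2 per L CO2.
#' @examples
#' o2_per_co2(reduce_to_residue("C6.0H10.84O2.06N0.87"))  # 1.3425
#' @export
o2_per_co2 <- function(r, convention = c("residue", "balanced")) {
  convention <- match.arg(convention)
  r <- as_residue(r)
  if (r$n_c <= 0) stop("residue carbon must be positive", call. = FALSE)
  if (r$m_h < 0) stop("residue hydrogen must be non-negative", call. = FALSE)
  denom <- if (convention == "residue") 2 else 4
  1 + r$m_h / (denom * r$n_c)
}

#' Assimilation quotient of a biomass
#'
#' The assimilation quotient AQ is the ratio of CO2 absorbed to O2 released
#' (the reciprocal of the photosynthetic quotient): the reciprocal of
#' [o2_per_co2()].
#'
#' @inheritParams o2_per_co2
#' @return Numeric AQ (dimensionless, in (0, 1] for residues with m_h >= 0).
#' @examples
#' assimilation_quotient("C6H12O6")  # carbohydrate: exactly 1
#' @export
assimilation_quotient <- function(r, convention = c("residue", "balanced")) {
  1 / o2_per_co2(r, convention)
}

#' Reproduce reported assimilation values with their rounding path
#'
#' Reported stoichiometry tables round at each stage: the residue hydrogen is
#' rounded first, then the O2:CO2 volume ratio, and the AQ is the reciprocal
#' of the *rounded* ratio (1/1.13 = 0.885, whereas the unrounded 1/1.1333
#' would give 0.882).  This helper applies that path explicitly.
#'
#' @param f Gross formula (object or string).
#' @param h_digits Digits to round the residue hydrogen to (chlorella tables
#'   use 1, spirulina 2).
#' @param ratio_digits Digits to round the O2:CO2 ratio to (2 and 4
#'   respectively).
#' @param aq_digits Digits for the final AQ (default 3).
#' @param convention Passed to [o2_per_co2()].
#' @return List with `residue`, `o2_per_co2`, `aq` (all rounded as requested).
#' @examples
#' aq_report("C6.0H9.7O2.635N0.937", h_digits = 1, ratio_digits = 2)
#' @export
aq_report <- function(f, h_digits = 2, ratio_digits = 4, aq_digits = 3,
                      convention = c("residue", "balanced")) {
  convention <- match.arg(convention)
  r <- reduce_to_residue(f)
  r$m_h <- round(r$m_h, h_digits)
  ratio <- round(o2_per_co2(r, convention), ratio_digits)
  list(residue = r, o2_per_co2 = ratio, aq = round(1 / ratio, aq_digits))
}

#' Assimilation quotient of a two-species mixture
#'
#' The mixture AQ is the mass-fraction-weighted mean of the two pure-culture
#' quotients: AQ = f_a * aq_a + (1 - f_a) * aq_b.  A culture with mass
#' fraction 0.6 of the AQ = 0.885 species and 0.4 of the AQ = 0.745 species
#' has AQ = 0.829.
#'
#' @param f_a Mass fraction of species A, in \[0, 1\].
#' @param aq_a,aq_b Pure-culture assimilation quotients.
#' @return Numeric mixture AQ.
#' @seealso [fraction_for_aq()] for the inverse.
#' @export
mixture_aq <- function(f_a, aq_a, aq_b) {
  if (any(!is.finite(f_a)) || any(f_a < 0) || any(f_a > 1))
    stop("mass fraction must lie in [0, 1]", call. = FALSE)
  f_a * aq_a + (1 - f_a) * aq_b
}

#' Mass fraction achieving a target mixture assimilation quotient
#'
#' Inverts [mixture_aq()]: the mass fraction of species A needed so that the
#' mixed culture has assimilation quotient `aq_target`.
#'
#' @param aq_target Desired mixture AQ; must lie between `aq_a` and `aq_b`.
#' @param aq_a,aq_b Pure-culture assimilation quotients (must differ).
#' @return Mass fraction of species A in \[0, 1\].
#' @export
fraction_for_aq <- function(aq_target, aq_a, aq_b) {
  if (aq_a == aq_b)
    stop("species quotients are equal; any composition gives the same AQ",
         call. = FALSE)
  lo <- min(aq_a, aq_b); hi <- max(aq_a, aq_b)
  if (!is.finite(aq_target) || aq_target < lo || aq_target > hi)
    stop(sprintf("target AQ %.4g outside the achievable range [%.4g, %.4g]",
                 aq_target, lo, hi), call. = FALSE)
  (aq_target - aq_b) / (aq_a - aq_b)
}

#' Respiratory quotient of complete oxidation
#'
#' For a nitrogen-free substrate CcHhOo, complete oxidation
#' CcHhOo + (c + h/4 - o/2) O2 -> c CO2 + h/2 H2O gives a respiratory
#' quotient RQ = c / (c + h/4 - o/2): 1.0 for carbohydrates, about 0.7 for
#' fats.  Amino-acid oxidation is excluded in this first approximation, so
#' formulas containing nitrogen are rejected.
#'
#' @param f Gross formula (object or string) with `n = 0` and `c > 0`.
#' @return Numeric RQ (CO2 released : O2 consumed).
#' @examples
#' respiratory_quotient("C6H12O6")   # 1
#' respiratory_quotient("C16H32O2")  # palmitic acid, 16/23
#' @export
respiratory_quotient <- function(f) {
  f <- gross_formula(f)
  if (f$n > 0)
    stop("respiratory quotient is defined here only for N-free substrates",
         call. = FALSE)
  if (f$c <= 0) stop("substrate must contain carbon", call. = FALSE)
  o2 <- f$c + f$h / 4 - f$o / 2
  if (o2 <= 0)
    stop("substrate is already fully oxidised (no O2 demand)", call. = FALSE)
  f$c / o2
}
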