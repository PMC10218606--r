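# Monoisotopic masses of the most abundant isotope of each supported element.
# IUPAC 2021 atomic-mass evaluation, truncated past the precision needed for
# small-molecule adduct identification (<= 1e-4 Da on typical formulas).
.isotope_masses <- c(
  H  = 1.00782503207,
  C  = 12.00000000000,
  N  = 14.00307400443,
  O  = 15.99491461957,
  F  = 18.99840316273,
  Na = 22.98976928196,
  P  = 30.97376199842,
  S  = 31.97207117440,
  Cl = 34.96885268200,
  K  = 38.96370648640,
  Br = 78.91833760000,
  I  = 126.90447190000,
  Se = 79.91652180000
)

# Mass added to a neutral molecule on protonation ([M+H]+), standard MS
# convention (proton mass, not H-atom mass).
.proton_mass <- 1.00728

#' Parse a Hill-notation molecular formula
#'
#' Parses strings such as `"C19H18O"` or `"C10H17N3O6S"` into a named integer
#' vector of element counts. Only elements present in the built-in
#' monoisotopic-mass table are accepted.
#'
#' @param s A single formula string (element symbols with optional counts,
#'   e.g. `"H2O"`).
#' @return An object of class `chem_formula`: a named integer vector of
#'   strictly positive element counts, ordered in Hill convention.
#' @examples
#' parse_formula("C19H18O")
#' parse_formula("H2O")
#' @seealso [format_formula()], [monoisotopic_mass()], [adduct_formula()]
#' @export
parse_formula <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  pieces <- regmatches(s, list(m))[[1]]
  if (paste(pieces, collapse = "") != s) {
    covered <- rep(FALSE, nchar(s))
    for (i in seq_along(m)) {
      covered[m[i] + seq_len(attr(m, "match.length")[i]) - 1L] <- TRUE
    }
    bad <- substr(s, which(!covered)[1], which(!covered)[1])
    stop(sprintf("malformed formula '%s': unexpected token '%s'", s, bad),
         call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", pieces)
  cnts <- sub("^[A-Z][a-z]?", "", pieces)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  unknown <- setdiff(syms, names(.isotope_masses))
  if (length(unknown)) {
    stop(sprintf("unknown element symbol '%s' in formula '%s'",
                 unknown[1], s), call. = FALSE)
  }
  if (any(cnts < 1L | is.na(cnts))) {
    stop(sprintf("element counts must be >= 1 in formula '%s'", s),
         call. = FALSE)
  }
  counts <- tapply(cnts, syms, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  new_chem_formula(out)
}

new_chem_formula <- function(counts) {
  counts <- counts[hill_order(names(counts))]
  structure(counts, class = "chem_formula")
}

# Hill convention: C first, then H, then all other elements alphabetically;
# without carbon, everything alphabetical.
hill_order <- function(elements) {
  if ("C" %in% elements) {
    rest <- sort(setdiff(elements, c("C", "H")))
    match(intersect(c("C", "H", rest), elements), elements)
  } else {
    order(elements)
  }
}

#' Format a formula in canonical Hill notation
#'
#' @param f A `chem_formula` (or a string, which is parsed first).
#' @return A single canonical Hill-notation string; `parse_formula()` of the
#'   result reproduces `f`.
#' @export
format_formula <- function(f) {
  f <- as_chem_formula(f)
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

as_chem_formula <- function(f) {
  if (inherits(f, "chem_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) {
    return(new_chem_formula(stats::setNames(as.integer(f), names(f))))
  }
  stop("cannot interpret object as a molecular formula", call. = FALSE)
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums most-abundant-isotope masses weighted by element counts.
#'
#' @param f A `chem_formula` or Hill-notation string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")       # 18.0106
#' monoisotopic_mass("C19H18O")   # 262.1358
#' @export
monoisotopic_mass <- function(f) {
  f <- as_chem_formula(f)
  missing_el <- setdiff(names(f), names(.isotope_masses))
  if (length(missing_el)) {
    stop(sprintf("unsupported element '%s' (not in isotope-mass table)",
                 missing_el[1]), call. = FALSE)
  }
  sum(.isotope_masses[names(f)] * unclass(f))
}

#' Molecular formula of a Michael adduct
#'
#' Conjugate addition of a thiol across the activated C=C double bond adds the
#' whole thiol to the acceptor: the adduct formula is the element-wise sum and
#' its monoisotopic mass is exactly the sum of the component masses.
#'
#' @param chalcone,thiol `chem_formula` objects or formula strings.
#' @return The adduct `chem_formula`.
#' @examples
#' adduct_formula("C19H18O", "C10H17N3O6S")  # IIb + GSH -> C29H35N3O7S
#' @export
adduct_formula <- function(chalcone, thiol) {
  a <- as_chem_formula(chalcone)
  b <- as_chem_formula(thiol)
  els <- union(names(a), names(b))
  counts <- vapply(els, function(e) {
    sum(c(unclass(a)[e], unclass(b)[e]), na.rm = TRUE)
  }, numeric(1))
  new_chem_formula(stats::setNames(as.integer(counts), els))
}

#' Ion masses for MS adduct identification
#'
#' @param f A `chem_formula` or formula string (the neutral molecule M).
#' @return Named numeric vector with the neutral monoisotopic mass and the
#'   `[M+H]+` / `[M-H]-` ion masses in Da.
#' @export
ion_masses <- function(f) {
  m <- monoisotopic_mass(f)
  c(M = m, `M+H` = m + .proton_mass, `M-H` = m - .proton_mass)
}
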