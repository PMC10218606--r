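#' Thiolate (ionized) fraction of a thiol at a given pH
#'
#' Henderson-Hasselbalch speciation of the thiol group:
#' `f = 1 / (1 + 10^(pKa - pH))`. The thiolate anion is by far the stronger
#' nucleophile, so this fraction largely controls the apparent rate of
#' thiol-Michael addition across pH.
#'
#' @param pKa Acid dissociation constant of the thiol group (e.g. 8.83 for
#'   glutathione, 9.52 for N-acetylcysteine).
#' @param pH Solution pH (for mixed-solvent incubations, the virtual pH of
#'   the mixture).
#' @return The ionized fraction, strictly between 0 and 1; exactly 0.5 at
#'   `pH == pKa`. Vectorized over both arguments.
#' @examples
#' thiolate_fraction(8.83, 7.4)  # ~0.036: ~3.6% of GSH ionized at pH 7.4
#' thiolate_fraction(9.52, 6.8)  # ~0.002: NAC almost fully protonated
#' @export
thiolate_fraction <- function(pKa, pH) {
  if (!is.numeric(pKa) || !is.numeric(pH) || any(!is.finite(pKa)) ||
      any(!is.finite(pH))) {
    stop("pKa and pH must be finite numeric values", call. = FALSE)
  }
  1 / (1 + 10^(pKa - pH))
}

#' Construct a thiol species
#'
#' @param name Species name (e.g. `"GSH"`).
#' @param formula Hill-notation molecular formula of the neutral thiol.
#' @param pKa Acid constant of the thiol group, in (0, 14).
#' @return An object of class `thiol_species` with fields `name`, `formula`
#'   (a `chem_formula`) and `pKa`.
#' @export
thiol_species <- function(name, formula, pKa) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(pKa) || length(pKa) != 1L || !is.finite(pKa) ||
      pKa <= 0 || pKa >= 14) {
    stop("thiol pKa must lie in (0, 14)", call. = FALSE)
  }
  structure(
    list(name = name, formula = as_chem_formula(formula), pKa = pKa),
    class = "thiol_species"
  )
}

#' @export
print.thiol_species <- function(x, ...) {
  cat(sprintf("<thiol> %s (%s), pKa %.2f\n",
              x$name, format_formula(x$formula), x$pKa))
  invisible(x)
}

#' Built-in species registry
#'
#' Names, formulas and (for thiols) pKa values of the compounds handled by
#' the package: glutathione (GSH), N-acetylcysteine (NAC), the benzosuberone
#' chalcone analogs IIb (4'-methyl) and IIc (4'-methoxy) and their open-chain
#' counterparts Ib and Ic.
#'
#' @return A data.frame with columns `name`, `formula`, `pKa` (NA for
#'   non-thiols) and `role` (`"thiol"` or `"chalcone"`).
#' @export
species_registry <- function() {
  path <- system.file("extdata", "species.csv", package = "chalkin",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up a registry entry by name
#'
#' @param name Registry name (case-sensitive, e.g. `"GSH"`, `"IIb"`).
#' @return For thiols, a `thiol_species`; otherwise a list with `name` and
#'   `formula`.
#' @export
registry_lookup <- function(name) {
  reg <- species_registry()
  row <- reg[reg$name == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("'%s' not found in species registry (known: %s)",
                 name, paste(reg$name, collapse = ", ")), call. = FALSE)
  }
  if (!is.na(row$pKa)) {
    thiol_species(row$name, row$formula, row$pKa)
  } else {
    list(name = row$name, formula = as_chem_formula(row$formula))
  }
}
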