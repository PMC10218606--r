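#' Global conceptual-DFT reactivity descriptors
#'
#' From frontier-orbital energies: gap `dE = E_LUMO - E_HOMO`, chemical
#' potential `mu = (E_HOMO + E_LUMO)/2`, hardness `eta` and the
#' electrophilicity index `omega = mu^2 / (2 eta)`. The hardness convention
#' here equates `eta` with the full HOMO-LUMO gap, the convention under
#' which the electrophilicity indices of the reference descriptor table are
#' reproduced (the textbook definition with an extra 1/2 factor halves
#' `eta` and doubles `omega`).
#'
#' @param E_HOMO,E_LUMO Frontier-orbital energies in kcal/mol;
#'   `E_LUMO > E_HOMO` is required.
#' @return Object of class `descriptor_set` with fields `gap`, `mu`, `eta`,
#'   `omega` (all kcal/mol).
#' @examples
#' global_descriptors(-183.24, -35.98)  # omega ~ 40.79 kcal/mol
#' @export
global_descriptors <- function(E_HOMO, E_LUMO) {
  if (!is.finite(E_HOMO) || !is.finite(E_LUMO)) {
    stop("orbital energies must be finite", call. = FALSE)
  }
  gap <- E_LUMO - E_HOMO
  if (gap <= 0) {
    stop("degenerate system: E_LUMO must exceed E_HOMO", call. = FALSE)
  }
  mu <- (E_HOMO + E_LUMO) / 2
  eta <- gap
  structure(
    list(gap = gap, mu = mu, eta = eta, omega = mu^2 / (2 * eta)),
    class = "descriptor_set"
  )
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf(
    "gap %.3f | mu %.3f | eta %.3f | omega %.3f kcal/mol\n",
    x$gap, x$mu, x$eta, x$omega))
  invisible(x)
}

#' Koopmans ionization potential and electron affinity
#'
#' `I = -E_HOMO` (ability to donate electrons), `A = -E_LUMO` (ability to
#' accept electrons); `I - A` equals the HOMO-LUMO gap.
#'
#' @inheritParams global_descriptors
#' @return Named vector `c(I = , A = )` in kcal/mol.
#' @export
koopmans_IA <- function(E_HOMO, E_LUMO) {
  if (!is.finite(E_HOMO) || !is.finite(E_LUMO)) {
    stop("orbital energies must be finite", call. = FALSE)
  }
  c(I = -E_HOMO, A = -E_LUMO)
}

#' Condensed Fukui indices from an atomic-charge triplet
#'
#' Finite-difference condensation of the Fukui function (the derivative of
#' the electron density with respect to electron number at fixed external
#' potential) onto atoms, from partial charges of the N-1, N and N+1
#' electron systems at fixed geometry:
#' `f+ = q(N) - q(N+1)`, `f- = q(N-1) - q(N)`, `f0 = (f+ + f-)/2`, dual
#' descriptor `df = f+ - f-`. Each of `f+` and `f-` sums to 1 (one electron
#' redistributed), the dual descriptor to 0.
#'
#' @param q_Nminus1,q_N,q_Nplus1 Equal-length numeric vectors of per-atom
#'   partial charges (electrons) for the three electron counts, aligned in
#'   atom order.
#' @param tol Tolerance on the +-1 e difference between total charges of
#'   adjacent states (default 1e-3).
#' @return Data.frame with columns `f_plus`, `f_minus`, `f_zero`, `dual`.
#' @export
condensed_fukui <- function(q_Nminus1, q_N, q_Nplus1, tol = 1e-3) {
  n <- length(q_N)
  if (length(q_Nminus1) != n || length(q_Nplus1) != n) {
    stop("charge vectors must have equal length (aligned atom order)",
         call. = FALSE)
  }
  if (abs(sum(q_Nminus1) - sum(q_N) - 1) > tol ||
      abs(sum(q_N) - sum(q_Nplus1) - 1) > tol) {
    stop("total charges of adjacent states must differ by exactly +1 e",
         call. = FALSE)
  }
  f_plus <- q_N - q_Nplus1
  f_minus <- q_Nminus1 - q_N
  data.frame(f_plus = f_plus, f_minus = f_minus,
             f_zero = (f_plus + f_minus) / 2,
             dual = f_plus - f_minus)
}

#' Local (per-atom) electrophilicity
#'
#' Partitions the global electrophilicity index over atoms through the
#' nucleophilic-attack Fukui index: `omega_k = omega * f+_k`. The largest
#' `omega_k` marks the predicted site of nucleophilic attack (the
#' beta-carbon of the enone in Michael acceptors).
#'
#' @param ds A `descriptor_set` (or a scalar omega in kcal/mol).
#' @param f_plus Per-atom `f+` vector, normalized to 1.
#' @param tol Normalization tolerance (default 1e-3).
#' @return Numeric vector `omega_k`, summing to omega.
#' @export
local_electrophilicity <- function(ds, f_plus, tol = 1e-3) {
  omega <- if (inherits(ds, "descriptor_set")) ds$omega else ds
  if (abs(sum(f_plus) - 1) > tol) {
    stop("f_plus must be normalized (sum to 1)", call. = FALSE)
  }
  omega * f_plus
}

.bohr_per_angstrom <- 1.8897259886

#' Point-charge system for electrostatic-potential evaluation
#'
#' @param kind Character vector: `"nucleus"` or `"electron"` per source.
#' @param q For nuclei the nuclear charge Z (positive integer, e); for
#'   electron sources the magnitude of the negative charge (e).
#' @param xyz Numeric matrix (n x 3) of positions.
#' @param unit `"bohr"` (default) or `"angstrom"`; positions are converted
#'   to bohr so potentials come out in atomic units.
#' @return Object of class `point_charge_system`.
#' @export
point_charge_system <- function(kind, q, xyz, unit = c("bohr", "angstrom")) {
  unit <- match.arg(unit)
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, length(kind) == nrow(xyz), length(q) == nrow(xyz))
  if (!all(kind %in% c("nucleus", "electron"))) {
    stop("kind must be 'nucleus' or 'electron'", call. = FALSE)
  }
  if (any(!is.finite(xyz)) || any(!is.finite(q))) {
    stop("positions and charges must be finite", call. = FALSE)
  }
  zn <- q[kind == "nucleus"]
  if (any(zn <= 0) || any(zn != round(zn))) {
    stop("nuclear charges must be positive integers", call. = FALSE)
  }
  if (unit == "angstrom") xyz <- xyz * .bohr_per_angstrom
  structure(list(kind = kind, q = q, xyz = xyz),
            class = "point_charge_system")
}

#' Electrostatic potential of a point-charge system
#'
#' Point-charge discretization of the molecular electrostatic potential:
#' `V(r) = sum_A Z_A / |r - R_A| - sum_i q_i / |r - r_i|` (nuclei minus
#' electron-charge contributions), in atomic units.
#'
#' @param sys A [point_charge_system()].
#' @param points Numeric matrix (m x 3) of evaluation points, in the same
#'   unit the system was built with bohr after construction.
#' @param unit Unit of `points` (`"bohr"` default, `"angstrom"` converted).
#' @return Numeric vector of potentials, atomic units (hartree/e).
#' @export
electrostatic_potential <- function(sys, points,
                                    unit = c("bohr", "angstrom")) {
  stopifnot(inherits(sys, "point_charge_system"))
  unit <- match.arg(unit)
  points <- matrix(as.numeric(points), ncol = 3)
  if (unit == "angstrom") points <- points * .bohr_per_angstrom
  signed <- ifelse(sys$kind == "nucleus", sys$q, -sys$q)
  vapply(seq_len(nrow(points)), function(i) {
    d <- sqrt(rowSums(sweep(sys$xyz, 2, points[i, ])^2))
    if (any(d < 1e-6)) {
      stop(sprintf(
        "evaluation point (%g, %g, %g) coincides with a charge site",
        points[i, 1], points[i, 2], points[i, 3]), call. = FALSE)
    }
    sum(signed / d)
  }, numeric(1))
}

#' Descriptor table for a set of species
#'
#' Applies [global_descriptors()] and [koopmans_IA()] to each row of an
#' orbital-energy table.
#'
#' @param oe Data.frame with columns `species`, `E_HOMO_kcal_mol`,
#'   `E_LUMO_kcal_mol`, or a path to such a CSV.
#' @return Data.frame with one row per species and columns `species`,
#'   `E_HOMO`, `E_LUMO`, `gap`, `mu`, `eta`, `omega`, `I`, `A`; rows whose
#'   energies are degenerate carry `NA` descriptors and a message in
#'   `note`.
#' @export
descriptor_table <- function(oe) {
  if (is.character(oe)) oe <- utils::read.csv(oe, stringsAsFactors = FALSE)
  need <- c("species", "E_HOMO_kcal_mol", "E_LUMO_kcal_mol")
  if (!all(need %in% names(oe))) {
    stop(sprintf("orbital-energy table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(oe)), function(i) {
    h <- oe$E_HOMO_kcal_mol[i]; l <- oe$E_LUMO_kcal_mol[i]
    base <- data.frame(species = oe$species[i], E_HOMO = h, E_LUMO = l)
    res <- tryCatch({
      d <- global_descriptors(h, l)
      ia <- koopmans_IA(h, l)
      cbind(base, data.frame(gap = d$gap, mu = d$mu, eta = d$eta,
                             omega = d$omega, I = ia[["I"]], A = ia[["A"]],
                             note = ""))
    }, error = function(e) {
      cbind(base, data.frame(gap = NA_real_, mu = NA_real_, eta = NA_real_,
                             omega = NA_real_, I = NA_real_, A = NA_real_,
                             note = conditionMessage(e)))
    })
    res
  })
  do.call(rbind, rows)
}
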