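# Independent oracles and fixture builders used across tests.

# Algebraic equilibrium of the one-channel reversible system
# k1*E*T = kr1*A with E = E0 - A, T = T0 - A: quadratic in A, physical root.
algebraic_equilibrium <- function(k1, kr1, E0, T0) {
  K <- k1 / kr1
  a <- K
  b <- -(K * (E0 + T0) + 1)
  cc <- K * E0 * T0
  A <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  list(A = A, E = E0 - A, T = T0 - A)
}

# Build a timecourse object directly from vectors (unit under test bypassed).
make_tc <- function(time, E, Z = 0, a1 = 0, a2 = 0, meta = list()) {
  n <- length(time)
  df <- data.frame(time_min = time,
                   E_area = rep_len(E, n), Z_area = rep_len(Z, n),
                   adduct1_area = rep_len(a1, n),
                   adduct2_area = rep_len(a2, n))
  chalkin:::new_timecourse(df, meta = meta)
}

# Random valid charge triplet: one electron redistributed per state change.
random_charge_triplet <- function(n, seed) {
  set.seed(seed)
  qN <- round(runif(n, -0.5, 0.5), 3)
  wp <- runif(n); wp <- wp / sum(wp)
  wm <- runif(n); wm <- wm / sum(wm)
  list(q_Nminus1 = qN + wm, q_N = qN, q_Nplus1 = qN - wp,
       f_plus_true = wp, f_minus_true = wm)
}

# Random point-charge system within a unit box.
random_pcs <- function(n_nuc, n_el, seed) {
  set.seed(seed)
  kind <- c(rep("nucleus", n_nuc), rep("electron", n_el))
  q <- c(sample(1:8, n_nuc, replace = TRUE), runif(n_el, 0.1, 2))
  xyz <- matrix(runif(3 * (n_nuc + n_el), -1, 1), ncol = 3)
  point_charge_system(kind, q, xyz)
}

# Unit direction perpendicular to a system's dipole moment (about the
# origin), along which the far field is monopole-dominated.
far_field_direction <- function(sys) {
  signed <- ifelse(sys$kind == "nucleus", sys$q, -sys$q)
  p <- colSums(sys$xyz * signed)
  if (sqrt(sum(p^2)) < 1e-12) return(c(1, 0, 0))
  v <- if (abs(p[1]) < abs(p[3])) c(1, 0, 0) else c(0, 0, 1)
  d <- v - sum(v * p) * p / sum(p^2)
  d / sqrt(sum(d^2))
}

# Default noiseless study conditions.
study_conditions <- function(...) incubation_conditions(...)

gsh <- function() thiol_species("GSH", "C10H17N3O6S", 8.83)
nac <- function() thiol_species("NAC", "C5H9NO3S", 9.52)
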