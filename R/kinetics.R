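#' Incubation conditions
#'
#' Describes one thiol-chalcone incubation: buffered pH (aqueous thiol
#' solution and virtual pH of the methanol-containing mixture), temperature,
#' initial concentrations at a 10:1 thiol:chalcone molar ratio, and the HPLC
#' sampling grid (first sample at 15 min, then every 30 min to 315 min, 11
#' samples).
#'
#' @param pH_aqueous pH of the aqueous thiol solution before mixing.
#' @param pH_virtual Virtual pH of the incubation mixture; used for thiol
#'   speciation.
#' @param temperature Incubation temperature in degrees Celsius (metadata
#'   only; rate constants are taken as given at this temperature).
#' @param chalcone0 Initial chalcone concentration, mol/L.
#' @param thiol0 Initial total thiol concentration, mol/L.
#' @param timepoints Sampling times in minutes, strictly increasing,
#'   non-negative.
#' @return An object of class `incubation_conditions`.
#' @export
incubation_conditions <- function(pH_aqueous = 8.0, pH_virtual = 7.4,
                                  temperature = 37,
                                  chalcone0 = 4.92e-3, thiol0 = 4.92e-2,
                                  timepoints = c(15, seq(45, 315, by = 30))) {
  stopifnot(is.numeric(timepoints), length(timepoints) >= 1L)
  if (any(timepoints < 0) || any(diff(timepoints) <= 0)) {
    stop("timepoints must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (chalcone0 <= 0 || thiol0 < 0) {
    stop("initial concentrations must be positive (thiol0 may be 0 for a control run)",
         call. = FALSE)
  }
  structure(
    list(pH_aqueous = pH_aqueous, pH_virtual = pH_virtual,
         temperature = temperature, chalcone0 = chalcone0, thiol0 = thiol0,
         timepoints = as.numeric(timepoints)),
    class = "incubation_conditions"
  )
}

#' Kinetic parameters of the reversible addition network
#'
#' The network has one (E)-chalcone pool, two adduct channels (the two
#' chromatographically resolved diastereomer populations), a (Z)-chalcone
#' pool fed exclusively by retro-Michael elimination, and the free thiol.
#'
#' @param k_add1,k_add2 Second-order addition rate constants of the thiolate
#'   toward adduct channels 1 and 2, 1/(M min).
#' @param neutral_scale Dimensionless factor (<= 1) scaling the thiolate rate
#'   constants for the much less nucleophilic neutral-thiol pathway.
#' @param k_retro1,k_retro2 First-order retro-Michael rate constants, 1/min.
#' @param phi_Z Fraction of retro-Michael events that release the
#'   (Z)-chalcone instead of regenerating the (E)-parent, in \[0, 1\].
#' @param z_reactive If `TRUE`, the (Z)-isomer itself undergoes addition at
#'   `z_rate_scale` times the (E) rates; off by default.
#' @param z_rate_scale Rate scale for (Z) re-addition when `z_reactive`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_add1, k_add2 = 0, neutral_scale = 0,
                           k_retro1 = 0, k_retro2 = 0, phi_Z = 0,
                           z_reactive = FALSE, z_rate_scale = 0) {
  rates <- c(k_add1, k_add2, k_retro1, k_retro2, z_rate_scale)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rate constants must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(phi_Z) || phi_Z < 0 || phi_Z > 1) {
    stop("phi_Z must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(neutral_scale) || neutral_scale < 0 || neutral_scale > 1) {
    stop("neutral_scale must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(k_add1 = k_add1, k_add2 = k_add2, neutral_scale = neutral_scale,
         k_retro1 = k_retro1, k_retro2 = k_retro2, phi_Z = phi_Z,
         z_reactive = isTRUE(z_reactive), z_rate_scale = z_rate_scale),
    class = "kinetic_params"
  )
}

#' HPLC-UV observation model
#'
#' Maps concentrations to chromatographic peak areas: a linear
#' (Beer-Lambert) response per species with multiplicative Gaussian noise.
#'
#' @param response_factors Named positive vector (`E`, `Z`, `adduct1`,
#'   `adduct2`): peak area units per mol/L at the detection wavelength.
#' @param noise_sd Relative standard deviation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Integer seed making the noise reproducible.
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(response_factors = c(E = 1e5, Z = 1e5,
                                                   adduct1 = 1e5,
                                                   adduct2 = 1e5),
                              noise_sd = 0, seed = 1L) {
  need <- c("E", "Z", "adduct1", "adduct2")
  if (!all(need %in% names(response_factors)) ||
      any(response_factors[need] <= 0)) {
    stop("response_factors must be positive and named E, Z, adduct1, adduct2",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(response_factors = response_factors[need],
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "observation_model"
  )
}

#' Effective per-channel addition rate constants at a given pH
#'
#' Combines the thiolate and neutral-thiol pathways weighted by the
#' Henderson-Hasselbalch speciation:
#' `k_eff_i = k_add_i * (f + neutral_scale * (1 - f))` with `f` the thiolate
#' fraction at the given pH.
#'
#' @param params A [kinetic_params()] object.
#' @param thiol A [thiol_species()] (or a bare numeric pKa).
#' @param pH The pH used for speciation (virtual pH of the mixture).
#' @return Named vector `c(adduct1 = , adduct2 = )` of effective
#'   second-order rate constants, 1/(M min).
#' @export
effective_addition_rate <- function(params, thiol, pH) {
  stopifnot(inherits(params, "kinetic_params"))
  pKa <- if (inherits(thiol, "thiol_species")) thiol$pKa else thiol
  f <- thiolate_fraction(pKa, pH)
  w <- f + params$neutral_scale * (1 - f)
  c(adduct1 = params$k_add1 * w, adduct2 = params$k_add2 * w)
}

# Right-hand side of the reaction network ODE. States in mol/L:
# E  (E)-chalcone, Z (Z)-chalcone, A1/A2 adduct channels, T free thiol.
.network_rhs <- function(t, y, p) {
  add1 <- p$k1e * y["E"] * y["T"]
  add2 <- p$k2e * y["E"] * y["T"]
  ret1 <- p$kr1 * y["A1"]
  ret2 <- p$kr2 * y["A2"]
  zadd1 <- if (p$z_on) p$k1e * p$zscale * y["Z"] * y["T"] else 0
  zadd2 <- if (p$z_on) p$k2e * p$zscale * y["Z"] * y["T"] else 0
  list(c(
    E  = -(add1 + add2) + (1 - p$phi) * (ret1 + ret2),
    Z  = p$phi * (ret1 + ret2) - (zadd1 + zadd2),
    A1 = add1 + zadd1 - ret1,
    A2 = add2 + zadd2 - ret2,
    T  = -(add1 + add2 + zadd1 + zadd2) + ret1 + ret2
  ))
}

# Run a block of code with a temporary RNG state seeded from `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one incubation and its HPLC-UV read-out
#'
#' Integrates the reversible thiol-Michael network with adaptive step
#' control (relative tolerance 1e-9, so that the chalcone and thiol mass
#' balances hold to better than 1e-8 relative) and applies the observation
#' model at `t = 0` and every requested sampling time.
#'
#' @param cond [incubation_conditions()].
#' @param params [kinetic_params()].
#' @param obs [observation_model()].
#' @param thiol [thiol_species()] providing the pKa for speciation.
#' @return A `timecourse` object: a data.frame with columns `time_min`,
#'   `E_area`, `Z_area`, `adduct1_area`, `adduct2_area`; the noiseless
#'   concentration matrix is attached as attribute `"concentrations"` and
#'   run metadata as attribute `"meta"`.
#' @export
simulate_incubation <- function(cond, params, obs, thiol) {
  stopifnot(inherits(cond, "incubation_conditions"),
            inherits(params, "kinetic_params"),
            inherits(obs, "observation_model"))
  keff <- effective_addition_rate(params, thiol, cond$pH_virtual)
  times <- unique(c(0, cond$timepoints))
  y0 <- c(E = cond$chalcone0, Z = 0, A1 = 0, A2 = 0, T = cond$thiol0)
  p <- list(k1e = keff[["adduct1"]], k2e = keff[["adduct2"]],
            kr1 = params$k_retro1, kr2 = params$k_retro2,
            phi = params$phi_Z, z_on = params$z_reactive,
            zscale = params$z_rate_scale)
  sol <- deSolve::ode(y = y0, times = times, func = .network_rhs, parms = p,
                      method = "lsoda", rtol = 1e-9,
                      atol = 1e-12 * max(cond$chalcone0, cond$thiol0, 1e-9))
  if (any(!is.finite(sol)) || nrow(sol) < length(times)) {
    stop("ODE integration failed (non-finite solution or early stop); ",
         "check rate constants for stiffness or inconsistency",
         call. = FALSE)
  }
  conc <- as.data.frame(sol)
  neg_tol <- 1e-8 * cond$chalcone0
  if (any(conc[-1] < -neg_tol)) {
    stop("model inconsistency: concentration more negative than solver tolerance",
         call. = FALSE)
  }
  conc[-1][conc[-1] < 0] <- 0

  rf <- obs$response_factors
  pure <- cbind(E = conc$E, Z = conc$Z, adduct1 = conc$A1, adduct2 = conc$A2)
  areas <- sweep(pure, 2, rf, "*")
  if (obs$noise_sd > 0) {
    noise <- with_seed(obs$seed,
                       matrix(stats::rnorm(length(areas), 0, obs$noise_sd),
                              nrow = nrow(areas)))
    areas <- pmax(areas * (1 + noise), 0)
  }
  tc <- data.frame(time_min = conc$time,
                   E_area = areas[, "E"], Z_area = areas[, "Z"],
                   adduct1_area = areas[, "adduct1"],
                   adduct2_area = areas[, "adduct2"])
  thiol_name <- if (inherits(thiol, "thiol_species")) thiol$name else NA
  new_timecourse(tc,
                 meta = list(thiol = thiol_name,
                             pH_aqueous = cond$pH_aqueous,
                             pH_virtual = cond$pH_virtual,
                             seed = obs$seed,
                             noise_sd = obs$noise_sd),
                 concentrations = conc)
}

#' Thiol-free control run: the 0-min reference peak area
#'
#' Mirrors the experimental protocol for the initial (0 min) peak area: the
#' chalcone is incubated without thiol, so its concentration stays at
#' `chalcone0`, and the mean observed (E)-peak area across the sampling grid
#' estimates A0.
#'
#' @param cond [incubation_conditions()] (its `thiol0` is ignored).
#' @param obs [observation_model()].
#' @return The control-derived reference area A0 (scalar).
#' @export
simulate_control_area0 <- function(cond, obs) {
  n <- length(cond$timepoints)
  area <- rep(obs$response_factors[["E"]] * cond$chalcone0, n)
  if (obs$noise_sd > 0) {
    area <- with_seed(obs$seed + 1000003L,
                      pmax(area * (1 + stats::rnorm(n, 0, obs$noise_sd)), 0))
  }
  mean(area)
}
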