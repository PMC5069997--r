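# Dual thermodynamics.
#
# The energy tables are taken at the table temperature T0; the formal
# temperature T appears only in the Boltzmann exponent RT.  Temperature
# derivatives of ln Z* are taken in the formal temperature by central
# finite differences (the tables stay fixed), which yields the dual
# expected energy <E*> = R T0^2 d/dT ln Z*(s0,T0,T) |_{T=T0} without any
# enthalpy tables.

.lnz_at_T <- function(target, params, mode, temp, opts, scale = NULL) {
  p2 <- params
  p2$temperature <- temp
  p2$RT <- params$gas_constant * temp
  st <- dual_pf(target, p2, mode, scale = scale,
                bulge_convention = opts$bulge,
                small_internal = opts$small_internal)
  log_dual_partition(st)
}

.lnz_profile_at_T <- function(target, params, mode, temp, opts) {
  p2 <- params
  p2$temperature <- temp
  p2$RT <- params$gas_constant * temp
  st <- dual_pf(target, p2, mode, gc_resolved = TRUE,
                bulge_convention = opts$bulge,
                small_internal = opts$small_internal)
  log(st$Z_total) + target$n * log(st$scale)
}

#' Log dual Boltzmann probability of a sequence
#'
#' `ln p*(a) = -E(a, s0)/RT - ln Z*(s0)` for a sequence compatible with
#' the target and its constraints.
#'
#' @param sequence RNA sequence string.
#' @param state a `dual_pf` object.
#' @return the log probability; `-Inf` (with a diagnostic attribute) when
#'   the sequence is incompatible with the target or its constraints.
#' @export
dual_probability <- function(sequence, state) {
  stopifnot(inherits(state, "dual_pf"))
  tg <- state$target
  v <- nt_to_int(sequence)
  if (length(v) != tg$n)
    stop("sequence length does not match the target")
  ok <- all(vapply(seq_len(tg$n), function(q) v[q] %in% tg$allowed[[q]], TRUE))
  E <- energy_of_structure(sequence, tg, state$params, state$mode,
                           state$opts$bulge, state$opts$small_internal)
  if (!ok || is.infinite(E))
    return(structure(-Inf, diagnostic = "sequence incompatible with target or constraints"))
  -E / state$params$RT - log_dual_partition(state)
}

#' Dual expected energy by formal-temperature differentiation
#'
#' The Boltzmann-expected energy over all compatible sequences,
#' `<E*> = sum_a E(a,s0) p*(a)`, computed as
#' `R T0^2` times the central finite difference of `ln Z*(s0, T0, T)` in
#' the formal temperature at `T = T0` (table energies fixed).
#'
#' @inheritParams dual_pf
#' @param h temperature step in Kelvin (default 0.01).
#' @param gc_resolved if `TRUE`, returns the per-GC-class expected
#'   energies `<E*(s0,k)>` as a vector over `k = 0..n` (NaN for empty
#'   classes).
#' @return kcal/mol.
#' @export
dual_expected_energy <- function(target, params = turner_params(),
                                 mode = c("d2", "d0"), h = 0.01,
                                 gc_resolved = FALSE,
                                 bulge_convention = c("stack", "literal"),
                                 small_internal = c("tables", "generic")) {
  if (is.character(target)) target <- parse_target(target)
  mode <- match.arg(mode)
  opts <- .resolve_opts(bulge_convention, small_internal)
  if (h <= 0) stop("step h must be positive")
  t0 <- params$temperature
  R <- params$gas_constant
  if (!gc_resolved) {
    up <- .lnz_at_T(target, params, mode, t0 + h, opts)
    dn <- .lnz_at_T(target, params, mode, t0 - h, opts)
    d <- (up - dn) / (2 * h)
    if (!is.finite(d))
      stop(if (is.nan(d)) "finite difference underflow; increase h"
           else "target infeasible")
    return(R * t0^2 * d)
  }
  up <- .lnz_profile_at_T(target, params, mode, t0 + h, opts)
  dn <- .lnz_profile_at_T(target, params, mode, t0 - h, opts)
  R * t0^2 * (up - dn) / (2 * h)
}

#' Dual thermodynamic summary
#'
#' `ln Z*`, the dual ensemble free energy `G* = -RT ln Z*`, the dual
#' expected energy `<E*>` (finite difference, see
#' [dual_expected_energy()]), the dual entropy
#' `S* = (<E*> - G*) / T`, and the dual heat capacity
#' `C*_p = d<E*>/dT` (central difference of the expected energy in the
#' formal temperature).
#'
#' @inheritParams dual_expected_energy
#' @return a list with components `ln_Z`, `G`, `E`, `S`, `Cp` (units
#'   kcal/mol, kcal/(mol K) for `S`, kcal/(mol K) for `Cp`).
#' @export
dual_thermo <- function(target, params = turner_params(),
                        mode = c("d2", "d0"), h = 0.01,
                        bulge_convention = c("stack", "literal"),
                        small_internal = c("tables", "generic")) {
  if (is.character(target)) target <- parse_target(target)
  mode <- match.arg(mode)
  opts <- .resolve_opts(bulge_convention, small_internal)
  t0 <- params$temperature
  R <- params$gas_constant
  lz <- vapply(c(t0 - h, t0, t0 + h),
               function(tt) .lnz_at_T(target, params, mode, tt, opts), 0)
  lnZ <- lz[2L]
  G <- -R * t0 * lnZ
  Eexp <- R * t0^2 * (lz[3L] - lz[1L]) / (2 * h)
  S <- (Eexp - G) / t0
  # <E*>(T +- h) by one-sided pairs around the shifted temperatures
  e_at <- function(tt) {
    l2 <- vapply(c(tt - h, tt + h),
                 function(u) .lnz_at_T(target, params, mode, u, opts), 0)
    R * tt^2 * (l2[2L] - l2[1L]) / (2 * h)
  }
  Cp <- (e_at(t0 + h) - e_at(t0 - h)) / (2 * h)
  list(ln_Z = lnZ, G = G, E = Eexp, S = S, Cp = Cp)
}

#' @rdname dual_thermo
#' @export
dual_entropy <- function(target, params = turner_params(),
                         mode = c("d2", "d0"), h = 0.01, ...) {
  dual_thermo(target, params, mode, h, ...)$S
}

#' @rdname dual_thermo
#' @export
dual_heat_capacity <- function(target, params = turner_params(),
                               mode = c("d2", "d0"), h = 0.01, ...) {
  dual_thermo(target, params, mode, h, ...)$Cp
}

#' Fold change of expected versus realised energy
#'
#' The ratio `<E(s)> / E(a0, s)` comparing the Boltzmann-expected energy
#' of all sequences on a structure with the energy of one reference
#' sequence on the same structure.
#'
#' @param expected_energy `<E>` in kcal/mol.
#' @param reference_energy `E(a0, s)` in kcal/mol; must be non-zero.
#' @return the dimensionless ratio.
#' @export
fold_change <- function(expected_energy, reference_energy) {
  if (any(reference_energy == 0))
    stop("fold change undefined: reference energy is zero")
  expected_energy / reference_energy
}
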