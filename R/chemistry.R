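#' Fraction of hormone in the protonated (membrane-permeant) form
#'
#' Weak-acid hormones such as gibberellin partition between a protonated,
#' uncharged form that crosses lipid membranes passively and an anionic form
#' that requires carrier proteins.  The protonated share in a compartment is
#' set by its pH and the hormone's dissociation constant:
#' \deqn{1 / (1 + 10^{pH - pK}).}
#'
#' @param pH Compartment pH.
#' @param pK Equilibrium dissociation constant of the hormone.
#' @return Fraction in `[0, 1]`; vectorised over `pH` and `pK`.
#' @examples
#' protonatedFraction(5.3, 4.2)  # apoplast, ~0.074
#' protonatedFraction(7.0, 4.2)  # cytoplasm, ~0.0016
#' @export
protonatedFraction <- function(pH, pK) {
  1 / (1 + 10^(pH - pK))
}

#' Goldman-Hodgkin-Katz voltage factor
#'
#' The GHK weighting \eqn{q(\phi) = \phi / (e^\phi - 1)} applied to anion
#' transport across a membrane held at scaled potential
#' \eqn{\phi = F V / (R T)}.  The singularity at \eqn{\phi = 0} is removable
#' (limit 1) and is evaluated by a series for small arguments; for large
#' negative \eqn{\phi} the function is computed as \eqn{-\phi e^{-\phi}
#' /(e^{-\phi} - 1)}-free form to avoid overflow.
#'
#' @param phi Scaled membrane potential (dimensionless), any real value.
#' @return Positive weight; `ghkFactor(0) == 1`.  Satisfies the identity
#'   `ghkFactor(-phi) == ghkFactor(phi) * exp(phi)`.
#' @export
ghkFactor <- function(phi) {
  out <- numeric(length(phi))
  small <- abs(phi) < 1e-6
  # removable singularity: q = 1 - phi/2 + phi^2/12 + O(phi^4)
  out[small] <- 1 - phi[small] / 2 + phi[small]^2 / 12
  p <- phi[!small]
  # expm1 keeps precision near 0; for p << 0, p/expm1(p) -> -p (stable)
  out[!small] <- p / expm1(p)
  out
}

#' Physiological and transport parameters of a hormone in a cell file
#'
#' Bundles the compartment pH values, membrane potentials, permeabilities
#' and apoplastic diffusivity that determine hormone movement between the
#' cytoplasm, vacuole and apoplast.  Defaults are not supplied; use
#' [gaPhysiology()] for the gibberellin parameterisation in *Arabidopsis*
#' root tissue.
#'
#' @param pK Dissociation constant.
#' @param pH_apo,pH_cyt,pH_vac Apoplastic, cytoplasmic and vacuolar pH.
#' @param V_mem,V_ton Potential across the plasma membrane and the tonoplast
#'   (volts, signed; inside-negative values are negative).
#' @param T_abs Absolute temperature (K).
#' @param P_pass,P_imp,P_exp,P_plas Passive, plasma-membrane importer,
#'   tonoplast exporter and plasmodesmatal permeabilities (micrometre/s).
#' @param D_apo Apoplastic diffusivity (micrometre^2/s).
#' @param C_up Upstream hormone concentration (micromolar).
#' @param F_D Faraday constant (C/mol).
#' @param R_gas Universal gas constant (J/mol/K).
#' @return An object of class `hormone_physiology`.
#' @export
hormonePhysiology <- function(pK, pH_apo, pH_cyt, pH_vac,
                              V_mem, V_ton, T_abs,
                              P_pass, P_imp, P_exp, P_plas,
                              D_apo, C_up = 1,
                              F_D = 96500, R_gas = 8.31) {
  perms <- c(P_pass = P_pass, P_imp = P_imp, P_exp = P_exp, P_plas = P_plas)
  if (any(perms < 0)) stop("permeabilities must be non-negative")
  if (T_abs <= 0) stop("T_abs must be positive")
  if (D_apo <= 0) stop("D_apo must be positive")
  structure(list(
    pK = pK, pH_apo = pH_apo, pH_cyt = pH_cyt, pH_vac = pH_vac,
    V_mem = V_mem, V_ton = V_ton, T_abs = T_abs,
    P_pass = P_pass, P_imp = P_imp, P_exp = P_exp, P_plas = P_plas,
    D_apo = D_apo, C_up = C_up, F_D = F_D, R_gas = R_gas
  ), class = "hormone_physiology")
}

#' @export
print.hormone_physiology <- function(x, ...) {
  cat("Hormone physiology\n")
  cat(sprintf("  pK %.2f | pH apo/cyt/vac %.2f/%.2f/%.2f\n",
              x$pK, x$pH_apo, x$pH_cyt, x$pH_vac))
  cat(sprintf("  V_mem %.0f mV, V_ton %.0f mV at %g K\n",
              1e3 * x$V_mem, 1e3 * x$V_ton, x$T_abs))
  cat(sprintf("  P (um/s): pass %.3g imp %.3g exp %.3g plas %.3g; D_apo %g um^2/s\n",
              x$P_pass, x$P_imp, x$P_exp, x$P_plas, x$D_apo))
  invisible(x)
}

#' Gibberellin parameter set for Arabidopsis root tissue
#'
#' Literature estimates of the chemistry and transport parameters for GA4:
#' apoplastic pH 5.3, cytoplasmic pH 7, vacuolar pH 5.5, pK 4.2, membrane
#' potential -120 mV, tonoplast potential -30 mV, oocyte-derived
#' permeabilities for the passive pathway and the NPF importer/exporter
#' proteins, and the measured apoplastic diffusivity of 32 um^2/s.
#'
#' @return A [hormonePhysiology()] object.
#' @export
gaPhysiology <- function() {
  hormonePhysiology(
    pK = 4.2, pH_apo = 5.3, pH_cyt = 7, pH_vac = 5.5,
    V_mem = -0.120, V_ton = -0.030, T_abs = 300,
    P_pass = 0.333, P_imp = 0.017, P_exp = 0.556, P_plas = 0.81,
    D_apo = 32, C_up = 1
  )
}

#' Partition and GHK factors for a hormone physiology
#'
#' Computes the protonated fractions in apoplast (`A1`), cytoplasm (`B1`)
#' and vacuole (`C1`), and the GHK anion-transport weights for the plasma
#' membrane (`A2`, `B2`) and the tonoplast (`B3`, `C3`):
#' `A2 = q(phi_mem) (1 - A1)`, `B2 = q(-phi_mem) (1 - B1)`,
#' `B3 = q(phi_ton) (1 - B1)`, `C3 = q(-phi_ton) (1 - C1)`, where
#' `phi_mem = F V_mem / (R T)` and similarly for the tonoplast.
#'
#' @param phys A [hormonePhysiology()] object.
#' @return A list of class `partition_factors` with fields `A1`, `B1`, `C1`,
#'   `A2`, `B2`, `B3`, `C3`, `phi_mem`, `phi_ton`.
#' @export
partitionFactors <- function(phys) {
  stopifnot(inherits(phys, "hormone_physiology"))
  phi_mem <- phys$F_D * phys$V_mem / (phys$R_gas * phys$T_abs)
  phi_ton <- phys$F_D * phys$V_ton / (phys$R_gas * phys$T_abs)
  A1 <- protonatedFraction(phys$pH_apo, phys$pK)
  B1 <- protonatedFraction(phys$pH_cyt, phys$pK)
  C1 <- protonatedFraction(phys$pH_vac, phys$pK)
  structure(list(
    A1 = A1, B1 = B1, C1 = C1,
    A2 = ghkFactor(phi_mem) * (1 - A1),
    B2 = ghkFactor(-phi_mem) * (1 - B1),
    B3 = ghkFactor(phi_ton) * (1 - B1),
    C3 = ghkFactor(-phi_ton) * (1 - C1),
    phi_mem = phi_mem, phi_ton = phi_ton
  ), class = "partition_factors")
}

.mutants <- c("wild_type", "no_cyt_importer", "no_ton_importer", "double")

# zero the carrier permeabilities knocked out by a loss-of-function mutant
applyMutant <- function(phys, mutant) {
  mutant <- match.arg(mutant, .mutants)
  if (mutant %in% c("no_cyt_importer", "double")) phys$P_imp <- 0
  if (mutant %in% c("no_ton_importer", "double")) phys$P_exp <- 0
  phys
}

#' Effective membrane permeabilities
#'
#' Combines passive and carrier-mediated transport into one effective
#' permeability per membrane crossing direction:
#' \deqn{P_{ca} = B_1 P_{pass} + B_2 P_{imp}, \quad
#'       P_{ac} = A_1 P_{pass} + A_2 P_{imp},}
#' \deqn{P_{cv} = B_1 P_{pass} + B_3 P_{exp}, \quad
#'       P_{vc} = C_1 P_{pass} + C_3 P_{exp},}
#' together with the quasi-static concentration ratios
#' `ratio_a = P_ca / P_ac` (apoplast : cytoplasm) and
#' `ratio_v = P_cv / P_vc` (vacuole : cytoplasm).
#'
#' @param phys A [hormonePhysiology()] object (dimensional permeabilities).
#' @param mutant One of `"wild_type"`, `"no_cyt_importer"` (plasma-membrane
#'   importer knocked out, `P_imp = 0`), `"no_ton_importer"` (tonoplast
#'   carrier knocked out, `P_exp = 0`) or `"double"` (both).
#' @return A list of class `effective_permeabilities` with fields `P_ca`,
#'   `P_ac`, `P_cv`, `P_vc` (same units as the inputs), `ratio_a`, `ratio_v`.
#' @export
effectivePermeabilities <- function(phys, mutant = "wild_type") {
  phys <- applyMutant(phys, mutant)
  pf <- partitionFactors(phys)
  P_ca <- pf$B1 * phys$P_pass + pf$B2 * phys$P_imp
  P_ac <- pf$A1 * phys$P_pass + pf$A2 * phys$P_imp
  P_cv <- pf$B1 * phys$P_pass + pf$B3 * phys$P_exp
  P_vc <- pf$C1 * phys$P_pass + pf$C3 * phys$P_exp
  if (P_ac == 0 || P_vc == 0)
    stop("all permeabilities are zero: concentration ratios are undefined")
  structure(list(
    P_ca = P_ca, P_ac = P_ac, P_cv = P_cv, P_vc = P_vc,
    ratio_a = P_ca / P_ac, ratio_v = P_cv / P_vc,
    mutant = match.arg(mutant, .mutants)
  ), class = "effective_permeabilities")
}

#' Dimensionless model parameters for a cell file
#'
#' Non-dimensionalises a physiology and a file geometry into the parameter
#' set used by the discrete and continuum models: `eps` (cell length : file
#' length), `lambda` (apoplast thickness : cell length), `omega` (cell
#' width : cell length), the vacuolar fraction `phi`, and all permeabilities
#' scaled by the apoplastic diffusive rate `D_apo / (l_ref + a)`.  Time is
#' scaled with `L0^2 / D_apo`, the apoplastic diffusion time across the
#' whole file; the scale is recorded in `time_scale_s`.
#'
#' @param phys A [hormonePhysiology()] object.
#' @param geom A [cellFileGeometry()] object; its `l_av` is the reference
#'   cell length.
#' @param mutant Mutant flag, see [effectivePermeabilities()].
#' @param plasmodesmata Logical; `FALSE` sets the plasmodesmatal
#'   permeability to zero (closed plasmodesmata).
#' @return An object of class `cell_params` holding the dimensionless
#'   groups, the effective permeabilities `P_ca`, `P_ac`, `P_cv`, `P_vc`,
#'   the ratios `Pa`, `Pv`, and the originating `phys`/`geom`.
#' @seealso [rescaledParams()] for the short-cell / long-cell limit
#'   variables.
#' @export
nondimensionalize <- function(phys, geom, mutant = "wild_type",
                              plasmodesmata = TRUE) {
  stopifnot(inherits(phys, "hormone_physiology"),
            inherits(geom, "cell_file_geometry"))
  phys <- applyMutant(phys, mutant)
  if (!plasmodesmata) phys$P_plas <- 0
  l_ref <- geom$l_av
  if (l_ref <= 0) stop("reference cell length must be positive")
  scale <- (l_ref + geom$a) / phys$D_apo
  ep <- effectivePermeabilities(phys, "wild_type")  # mutant already applied
  structure(list(
    eps = 1 / geom$N,
    lambda = geom$a / l_ref,
    omega = geom$w / l_ref,
    phi = geom$fractions,
    P_pass = scale * phys$P_pass, P_imp = scale * phys$P_imp,
    P_exp = scale * phys$P_exp, P_plas = scale * phys$P_plas,
    P_ca = scale * ep$P_ca, P_ac = scale * ep$P_ac,
    P_cv = scale * ep$P_cv, P_vc = scale * ep$P_vc,
    Pa = ep$ratio_a, Pv = ep$ratio_v,
    l_ref = l_ref, L0 = geom$L0,
    time_scale_s = geom$L0^2 / phys$D_apo,
    mutant = match.arg(mutant, .mutants),
    plasmodesmata = plasmodesmata,
    phys = phys, geom = geom
  ), class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Dimensionless cell-file parameters\n")
  cat(sprintf("  eps %.3g  lambda %.4g  omega %.4g  phi %s\n",
              x$eps, x$lambda, x$omega,
              paste(signif(unique(x$phi), 3), collapse = "/")))
  cat(sprintf("  P_ca %.3g  P_ac %.3g  P_cv %.3g  P_vc %.3g  P_plas %.3g\n",
              x$P_ca, x$P_ac, x$P_cv, x$P_vc, x$P_plas))
  cat(sprintf("  Pa %.4g  Pv %.4g  (mutant: %s, plasmodesmata %s)\n",
              x$Pa, x$Pv, x$mutant, if (x$plasmodesmata) "open" else "closed"))
  cat(sprintf("  time scale %.3g s, L0 %.4g um\n", x$time_scale_s, x$L0))
  invisible(x)
}

#' Rescaled limit variables for the asymptotic regimes
#'
#' The short-cell regime treats the apoplast aspect ratio and the
#' apoplast:cytoplasm ratio as order-`eps` quantities and the
#' cytoplasm-to-apoplast permeability as order-`eps^2`; the long-cell regime
#' additionally rescales the width ratio.  This helper returns the
#' order-one limit variables `lambda_t = lambda/eps`, `Pa_t = Pa/eps`,
#' `Pca_b = P_ca/eps^2`, `omega_t = omega/eps`, `lambda_b = lambda/eps^2`.
#'
#' @param params A `cell_params` object from [nondimensionalize()].
#' @return Named list of rescaled variables.
#' @export
rescaledParams <- function(params) {
  with(params, list(
    lambda_t = lambda / eps, Pa_t = Pa / eps, Pca_b = P_ca / eps^2,
    omega_t = omega / eps, lambda_b = lambda / eps^2
  ))
}

#' Preset dimensionless parameter sets for gibberellin transport
#'
#' Convenience wrapper building the short-cell (20 um, vacuolar fraction
#' 0.1) or long-cell (200 um, vacuolar fraction 0.91) *Arabidopsis*
#' parameterisation with 20 cells, 10 um width and 0.5 um apoplast.
#'
#' @param cells `"short"` or `"long"`.
#' @param mutant Mutant flag, see [effectivePermeabilities()].
#' @param plasmodesmata Logical, open (`TRUE`) or closed plasmodesmata.
#' @return A `cell_params` object.
#' @export
gaParams <- function(cells = c("short", "long"), mutant = "wild_type",
                     plasmodesmata = TRUE) {
  cells <- match.arg(cells)
  nondimensionalize(gaPhysiology(), gaGeometry(cells),
                    mutant = mutant, plasmodesmata = plasmodesmata)
}
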