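# Diagnostics for the advective velocity induced by spatial gradients in
# cell length and vacuolar fraction: a file stores hormone differently in
# large-vacuole versus small-vacuole cells, so the ratio of cytoplasmic to
# area-averaged concentration varies along the file and its gradient sets
# the sign and size of the induced velocity.

#' Cytoplasmic to area-averaged concentration ratio
#'
#' In the quasi-static regime the hormone concentrations in all
#' compartments are proportional to the cytoplasmic one, so the ratio of
#' the cytoplasmic concentration `C` to the area-weighted cell average is
#' the purely geometric quantity `V_cell / V`, with `V_cell = (l +
#' lambda)(omega + lambda)` the dimensionless cell area and `V` the
#' effective capacitance.
#'
#' @param l Dimensionless cell length (vectorised).
#' @param phi Vacuolar fraction (vectorised).
#' @param params A `cell_params` object.
#' @return The ratio `C / C_avg` (> 0; equal to 1 when `phi = 0` and
#'   `lambda = 0`).
#' @export
concentrationRatio <- function(l, phi, params) {
  V <- transportGroupings(params, l, phi)$V
  (l + params$lambda) * (params$omega + params$lambda) / V
}

#' Spatial gradient of the concentration ratio
#'
#' Closed-form `d/dx (C / C_avg)` along a static profile.  The `general`
#' case is
#' \deqn{-\frac{\omega(\omega+\lambda)}{V^2}\Big(
#'   (l^2 \phi_x + \lambda l \phi_x + \lambda\phi l_x)(\mathcal{P}_v - 1)
#'   + \lambda l_x (1 - \mathcal{P}_a)\Big);}
#' the special cases isolate the mechanism: `vacuole_only` (`lambda = 0`),
#' `apoplast_only` (`phi = 0`), `transverse_only` (only the cross walls
#' between cells retained) and `constant_cytoplasm` (cytoplasmic area
#' `sigma = (1 - phi) l` uniform, so length and fraction gradients are
#' tied).
#'
#' @param profile A static `length_profile`.
#' @param params A `cell_params` object.
#' @param x Positions (vectorised).
#' @param case One of `"general"`, `"vacuole_only"`, `"apoplast_only"`,
#'   `"transverse_only"`, `"constant_cytoplasm"`.
#' @return Gradient values at `x`.
#' @export
ratioGradient <- function(profile, params, x = 0,
                          case = c("general", "vacuole_only",
                                   "apoplast_only", "transverse_only",
                                   "constant_cytoplasm")) {
  case <- match.arg(case)
  l <- profile$l(x, 0); phi <- profile$phi(x, 0)
  lx <- profile$dl_dx(x, 0); px <- profile$dphi_dx(x, 0)
  lam <- params$lambda; om <- params$omega
  Pa <- params$Pa; Pv <- params$Pv
  switch(case,
    general = {
      V <- transportGroupings(params, l, phi)$V
      -om * (om + lam) / V^2 *
        ((l^2 * px + lam * l * px + lam * phi * lx) * (Pv - 1) +
           lam * lx * (1 - Pa))
    },
    vacuole_only = -px * (Pv - 1) / (1 + phi * (Pv - 1))^2,
    apoplast_only = -lx * om * lam * (1 - Pa) * (om + lam) /
      (om * l + lam * (om + lam + l) * Pa)^2,
    transverse_only = -lx * lam * (1 - Pa) / (l + lam * Pa)^2,
    constant_cytoplasm = {
      sigma <- (1 - phi) * l
      V <- transportGroupings(params, l, phi)$V
      -om * (om + lam) * ((sigma + lam) * (Pv - 1) + lam * (1 - Pa)) /
        V^2 * lx
    })
}

#' Induced effective velocity of a static graded file
#'
#' For non-growing cells the homogenised advective velocity can be written
#' in terms of the concentration-ratio gradient:
#' \deqn{U_{eff}(x) = \frac{K(l+\lambda)+M}{\omega+\lambda}
#'   \frac{d}{dx}\left(\frac{\mathcal{V}}{V}\right),}
#' so its sign is the sign of `d/dx (C / C_avg)`.  Identical to the
#' direct expression in [effectiveCoefficients()].
#'
#' @param profile A static `length_profile`.
#' @param params A `cell_params` object.
#' @param x Positions (vectorised).
#' @return `U_eff` at `x`.
#' @export
inducedVelocity <- function(profile, params, x = 0) {
  l <- profile$l(x, 0); phi <- profile$phi(x, 0)
  g <- transportGroupings(params, l, phi)
  (g$K * (l + params$lambda) + g$M) / (params$omega + params$lambda) *
    ratioGradient(profile, params, x, "general")
}

#' Vacuolar-uptake threshold for a positive induced velocity
#'
#' For a file whose cytoplasmic area `sigma = (1 - phi) l` is constant
#' and whose cell lengths increase along the file, the induced velocity is
#' positive exactly when the vacuole:cytoplasm concentration ratio is
#' small enough:
#' \deqn{\mathcal{P}_v < \frac{\sigma + \lambda \mathcal{P}_a}
#'   {\sigma + \lambda}.}
#' A knocked-out tonoplast carrier (`Pv = B1/C1 << 1`) satisfies this, so
#' such mutants transport hormone faster through an elongating zone.
#'
#' @param sigma Constant dimensionless cytoplasmic area.
#' @param lam Dimensionless apoplast thickness.
#' @param ratio_a Apoplast:cytoplasm concentration ratio `Pa`.
#' @return The threshold on `Pv`.
#' @export
positiveVelocityThreshold <- function(sigma, lam, ratio_a) {
  (sigma + lam * ratio_a) / (sigma + lam)
}
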