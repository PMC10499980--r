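#' Effective diffusivity of a static uniform cell file
#'
#' The homogenised diffusion coefficient of the macroscopic cytoplasmic
#' concentration for a file of identical static cells:
#' \deqn{D_{eff} = \frac{(1+\lambda)(\omega P_{ca}/2 + \omega P_{plas} +
#'   \lambda \mathcal{P}_a)}{(1-\phi)\omega + \phi\omega\mathcal{P}_v +
#'   \lambda(1+\omega+\lambda)\mathcal{P}_a}}
#' in units of the apoplastic diffusivity, on the file-scale diffusion
#' time.  The three numerator terms are the cell-to-cell (membrane),
#' plasmodesmatal and apoplastic transport pathways.
#'
#' @param params A `cell_params` object from [nondimensionalize()], or any
#'   list with fields `lambda`, `omega`, `phi`, `P_ca`, `P_plas`, `Pa`,
#'   `Pv`.
#' @param phi Vacuolar fraction override; defaults to `params$phi[1]`.
#' @return Dimensionless effective diffusivity.
#' @export
staticEffectiveDiffusivity <- function(params, phi = params$phi[1]) {
  lam <- params$lambda; om <- params$omega
  (1 + lam) * (om * params$P_ca / 2 + om * params$P_plas + lam * params$Pa) /
    ((1 - phi) * om + phi * om * params$Pv +
       lam * (1 + om + lam) * params$Pa)
}

#' Limit-regime effective diffusivities
#'
#' Closed-form diffusivities in the physically relevant asymptotic
#' regimes.  Without plasmodesmata, both the short-cell and long-cell
#' regimes rescale time as `t = t_bar / eps^2`, and
#' \deqn{\bar D_{eff} = \frac{\omega \bar P_{ca}/2 +
#'   \tilde\lambda \tilde{\mathcal{P}}_a}{(1-\phi)\omega +
#'   \phi\omega\mathcal{P}_v}}
#' (short cells; the long-cell form replaces `omega`, `lambda` with their
#' rescaled counterparts, which leaves the value of the ratio
#' expressed in original variables with an extra `1/eps` on the apoplastic
#' term).  With open plasmodesmata no time rescaling is needed and
#' \deqn{D_{eff} = P_{plas} / (1 - \phi + \phi \mathcal{P}_v).}
#'
#' @param params A `cell_params` object.
#' @param regime One of `"short_no_plas"`, `"long_no_plas"`,
#'   `"plasmodesmata"`.
#' @param phi Vacuolar fraction override.
#' @return List with `D_eff` (in the regime's time scale), `time_scale`
#'   (`"t_bar"` when time is rescaled by `eps^2`, else `"t"`),
#'   `share_cell_to_cell` and `share_apoplast` (numerator fractions of the
#'   membrane and apoplastic pathways), and `D_eff_dimensional`
#'   (micrometre^2/s, rescaling included).
#' @export
limitDiffusivity <- function(params,
                             regime = c("short_no_plas", "long_no_plas",
                                        "plasmodesmata"),
                             phi = params$phi[1]) {
  regime <- match.arg(regime)
  r <- rescaledParams(params)
  if (regime == "plasmodesmata") {
    D <- params$P_plas / (1 - phi + phi * params$Pv)
    return(list(D_eff = D, time_scale = "t",
                share_cell_to_cell = 0, share_apoplast = 0,
                D_eff_dimensional = D * params$phys$D_apo))
  }
  if (regime == "short_no_plas") {
    num_cc <- params$omega * r$Pca_b / 2
    num_ap <- r$lambda_t * r$Pa_t
    den <- (1 - phi) * params$omega + phi * params$omega * params$Pv
  } else {
    num_cc <- r$omega_t * r$Pca_b / 2
    num_ap <- r$lambda_b * r$Pa_t
    den <- (1 - phi) * r$omega_t + phi * r$omega_t * params$Pv
  }
  D <- (num_cc + num_ap) / den
  list(D_eff = D, time_scale = "t_bar",
       share_cell_to_cell = num_cc / (num_cc + num_ap),
       share_apoplast = num_ap / (num_cc + num_ap),
       D_eff_dimensional = D * params$eps^2 * params$phys$D_apo)
}

#' Effective diffusivity of a loss-of-function mutant
#'
#' Knocking out the plasma-membrane importer sets `P_imp = 0` (so
#' `P_ca = B1 P_pass`, `Pa = B1/A1`), knocking out the tonoplast carrier
#' sets `P_exp = 0` (so `Pv = B1/C1`).  The mutant diffusivity is the
#' general formula evaluated with the mutant-adjusted permeabilities,
#' never a separate expression.
#'
#' @param params A `cell_params` object (its `phys`/`geom` are re-derived
#'   under the mutant flag).
#' @param mutant Mutant flag, see [effectivePermeabilities()].
#' @param regime `NULL` for the unscaled formula of
#'   [staticEffectiveDiffusivity()], or a regime for [limitDiffusivity()].
#' @return Dimensionless effective diffusivity (scalar for `regime =
#'   NULL`, otherwise the [limitDiffusivity()] list).
#' @export
mutantDiffusivity <- function(params, mutant, regime = NULL) {
  p <- nondimensionalize(params$phys, params$geom, mutant = mutant,
                         plasmodesmata = params$plasmodesmata)
  if (is.null(regime)) staticEffectiveDiffusivity(p)
  else limitDiffusivity(p, regime)
}

#' Series solution of the static transport problem
#'
#' Separation-of-variables solution of `C_t = D_eff C_xx` on `[0, 1]` with
#' `C(0, t) = 1`, no flux at `x = 1` and `C(x, 0) = 0`:
#' \deqn{C = 1 - \frac{4}{\pi}\sum_{k\ge 0} \frac{1}{2k+1}
#'   \sin\left(\frac{(2k+1)\pi x}{2}\right)
#'   e^{-D_{eff} (2k+1)^2 \pi^2 t / 4}.}
#'
#' @param x Positions in `[0, 1]` (vector).
#' @param t Time (scalar), same scale as `D_eff`.
#' @param D_eff Effective diffusivity.
#' @param n_terms Number of series terms (>= 1).
#' @return Concentrations at `x`; attribute `"truncation_bound"` holds an
#'   upper bound on the truncation error.
#' @export
analyticStaticSolution <- function(x, t, D_eff, n_terms = 100) {
  stopifnot(n_terms >= 1)
  k <- seq_len(n_terms) - 1
  m <- 2 * k + 1
  decay <- exp(-D_eff * m^2 * pi^2 * t / 4)
  S <- sin(outer(x, m, function(xx, mm) mm * pi * xx / 2)) %*% (decay / m)
  out <- 1 - (4 / pi) * as.numeric(S)
  mN <- 2 * n_terms + 1
  # geometric-tail bound on the dropped terms
  q <- exp(-2 * D_eff * pi^2 * t * (mN + 1))
  attr(out, "truncation_bound") <-
    (4 / pi) * exp(-D_eff * mN^2 * pi^2 * t / 4) / (mN * max(1e-300, 1 - q))
  out
}

#' Lumped transport groupings K, M and the effective capacitance V
#'
#' @param params A `cell_params` object.
#' @param l Local dimensionless cell length.
#' @param phi Local vacuolar fraction.
#' @return List with `K`, `M`, `V`:
#'   `K = (omega P_ca / 2 + omega P_plas) / (1 + lambda)`,
#'   `M = lambda Pa`,
#'   `V = omega (1 - phi) l + omega phi l Pv + lambda (omega + lambda + l) Pa`.
#' @export
transportGroupings <- function(params, l = 1, phi = params$phi[1]) {
  lam <- params$lambda; om <- params$omega
  list(
    K = (om * params$P_ca / 2 + om * params$P_plas) / (1 + lam),
    M = lam * params$Pa,
    V = om * (1 - phi) * l + om * phi * l * params$Pv +
      lam * (om + lam + l) * params$Pa
  )
}

# time derivative of V along a profile (chain rule on l(t), phi(t))
capacitanceRate <- function(params, profile, x, t) {
  l <- profile$l(x, t); phi <- profile$phi(x, t)
  lp <- profile$dl_dt(x, t); pp <- profile$dphi_dt(x, t)
  params$omega * ((1 - phi) * lp - pp * l) +
    params$omega * params$Pv * (pp * l + phi * lp) +
    params$lambda * params$Pa * lp
}

# spatial derivative of V along a profile
capacitanceGradient <- function(params, profile, x, t) {
  l <- profile$l(x, t); phi <- profile$phi(x, t)
  lx <- profile$dl_dx(x, t); px <- profile$dphi_dx(x, t)
  params$omega * ((1 - phi) * lx - px * l) +
    params$omega * params$Pv * (px * l + phi * lx) +
    params$lambda * params$Pa * lx
}

#' Effective coefficients of the homogenised transport equation
#'
#' For a prescribed length/vacuolar-fraction profile the macroscopic
#' cytoplasmic concentration obeys the reaction-advection-diffusion
#' equation `C_t + (U_eff C)_x = (D_eff C_x)_x - Q_eff C` with
#' \deqn{U_{eff} = u + \frac{K(l+\lambda)+M}{V} l_x -
#'   \frac{(K(l+\lambda)+M)(l+\lambda)}{V^2} V_x, \quad
#'   D_{eff} = \frac{(K(l+\lambda)+M)(l+\lambda)}{V},}
#' \deqn{Q_{eff} = \frac{u}{V} V_x - \partial_x U_{eff} + \frac{V_t}{V},}
#' where `u` is the growth velocity.  `D_cell` is the inter-cellular
#' diffusivity `(1+lambda)^2 (K + M/(l+lambda)) / V` appearing after the
#' transform to the fixed unit domain for identical growing cells.
#'
#' @param params A `cell_params` object.
#' @param profile A `length_profile`.
#' @param x Positions (vector).
#' @param t Time (scalar).
#' @return List of vectors `U_eff`, `D_eff`, `Q_eff`, `D_cell`, `V`, `u`,
#'   plus scalars `K`, `M`.
#' @export
effectiveCoefficients <- function(params, profile, x = 0, t = 0) {
  l <- profile$l(x, t)
  phi <- profile$phi(x, t)
  g <- transportGroupings(params, l, phi)
  lam <- params$lambda
  u <- growthVelocity(profile, lam)(x, t)
  lx <- profile$dl_dx(x, t)
  Vx <- capacitanceGradient(params, profile, x, t)
  Vt <- capacitanceRate(params, profile, x, t)
  KM <- g$K * (l + lam) + g$M
  D <- KM * (l + lam) / g$V
  U <- u + KM / g$V * lx - D * Vx / g$V
  # dU/dx: analytic for the profile kinds in use (all have constant l_x,
  # phi_x or no spatial dependence)
  dU <- switch(profile$kind,
    static_uniform = rep(0, length(x)),
    linear_time = ,
    exponential_division = profile$dl_dt(x, t) / (l + lam),  # du/dx, l_x = 0
    linear_space = {
      eps_h <- 1e-6
      Uf <- function(xx) {
        ll <- profile$l(xx, t); pp <- profile$phi(xx, t)
        gg <- transportGroupings(params, ll, pp)
        KM2 <- gg$K * (ll + lam) + gg$M
        KM2 / gg$V * profile$dl_dx(xx, t) -
          KM2 * (ll + lam) / gg$V^2 * capacitanceGradient(params, profile, xx, t)
      }
      (Uf(x + eps_h) - Uf(x - eps_h)) / (2 * eps_h)
    })
  Q <- u * Vx / g$V - dU + Vt / g$V
  list(U_eff = U, D_eff = D, Q_eff = Q,
       D_cell = (1 + lam)^2 * (g$K + g$M / (l + lam)) / g$V,
       V = g$V, u = u, K = g$K, M = g$M)
}

#' Growth-dilution balance parameter
#'
#' For identical cells elongating at constant rate `kappa` by vacuolar
#' expansion, the long-time concentration profile is set by
#' \deqn{\beta = \frac{\kappa(\omega\mathcal{P}_v + \lambda\mathcal{P}_a)}
#'   {(1+\lambda)(\omega P_{ca}/2 + \omega P_{plas})},}
#' the ratio of growth-induced dilution to effective diffusive transport
#' over the whole file.
#'
#' @param params A `cell_params` object.
#' @param kappa Dimensionless growth rate.
#' @return `beta` (dimensionless, >= 0 for `kappa >= 0`).
#' @export
betaParameter <- function(params, kappa) {
  lam <- params$lambda; om <- params$omega
  kappa * (om * params$Pv + lam * params$Pa) /
    ((1 + lam) * (om * params$P_ca / 2 + om * params$P_plas))
}

#' Steady concentration profile of a linearly growing file
#'
#' In the fixed unit domain the balance of diffusion and dilution admits
#' the non-uniform steady state
#' \deqn{C_{eq}(\xi) = \cosh(\sqrt\beta\,\xi) -
#'   \tanh(\sqrt\beta)\sinh(\sqrt\beta\,\xi)
#'   = \cosh(\sqrt\beta\,(1-\xi)) / \cosh(\sqrt\beta),}
#' with `C_eq(0) = 1` and zero slope at `xi = 1`.  The second form is used
#' for numerical stability at large `beta`.
#'
#' @param xi Positions in the fixed unit domain (vector).
#' @param beta Balance parameter, `>= 0`; `beta = 0` gives `C == 1`.
#' @return Steady-state concentrations.
#' @export
steadyStateGrowing <- function(xi, beta) {
  stopifnot(beta >= 0)
  if (beta == 0) return(rep(1, length(xi)))
  s <- sqrt(beta)
  # cosh(s (1 - xi)) / cosh(s), written with exp to avoid overflow
  exp(s * (1 - xi) - s) * (1 + exp(-2 * s * (1 - xi))) / (1 + exp(-2 * s))
}

#' Solve the macroscopic transport equation by the method of lines
#'
#' Integrates the homogenised equation for the profile's regime:
#' * `static_uniform` - pure diffusion `C_t = D_eff C_xx` with the
#'   constant coefficient of [staticEffectiveDiffusivity()];
#' * `linear_space` - static graded file in the `x` frame,
#'   `C_t = D(x) C_xx + (D'(x) - U(x)) C_x` (the sink `-U'C` cancels
#'   against the conservative advection term);
#' * `linear_time`, `exponential_division` - identical growing cells,
#'   solved on the fixed unit domain: `C_t = D_cell(t) C_xixi - Q(t) C`
#'   with `Q = V_t / V`; division runs are integrated piecewise between
#'   division instants with the concentration carried across each event.
#'
#' Boundary conditions: `C = 1` at the upstream end (imposed from the
#' first positive time; initial data are zero) and zero flux downstream,
#' or both ends sealed with `upstream = "sealed"`.
#'
#' @param params A `cell_params` object.
#' @param profile A `length_profile`.
#' @param t_eval Output times (dimensionless, file-diffusion scale).
#' @param n_grid Number of grid intervals (default 100).
#' @param upstream `"dirichlet"` (default) or `"sealed"`.
#' @param C0 Initial condition: scalar or vector on the interior nodes.
#' @param rtol,atol Solver tolerances.
#' @return Object of class `continuum_solution`: `t`, node positions `xi`
#'   on `[0, 1]`, concentration matrix `C` (`length(t)` rows, `n_grid + 1`
#'   columns including the upstream node), and `x_of_xi(t)` mapping the
#'   fixed domain to the laboratory frame (identity for static profiles).
#' @export
solveContinuum <- function(params, profile, t_eval, n_grid = 100,
                           upstream = c("dirichlet", "sealed"), C0 = 0,
                           rtol = 1e-8, atol = 1e-10) {
  upstream <- match.arg(upstream)
  n <- n_grid
  h <- 1 / n
  xi <- seq(0, 1, length.out = n + 1)
  dirichlet <- upstream == "dirichlet"
  # interior unknowns: nodes 2..n+1 (node 1 clamped) for dirichlet,
  # all nodes for sealed
  moving <- profile$kind %in% c("linear_time", "exponential_division")

  if (moving) {
    rhs <- function(t, y, p) {
      co <- effectiveCoefficients(params, profile, 0, t)
      # in the fixed unit domain the advective part of the material
      # derivative cancels, leaving dilution Q = V_t / V only
      Q <- capacitanceRate(params, profile, 0, t) / co$V
      C <- if (dirichlet) c(1, y) else y
      nn <- length(C)
      Cxx <- c(0, diff(C, differences = 2), 0) / h^2
      # sealed left end / reflecting right end via ghost mirrors
      Cxx[nn] <- 2 * (C[nn - 1] - C[nn]) / h^2
      if (!dirichlet) Cxx[1] <- 2 * (C[2] - C[1]) / h^2
      dC <- co$D_cell * Cxx - Q * C
      list(if (dirichlet) dC[-1] else dC)
    }
  } else {
    l <- profile$l(xi, 0)
    co <- effectiveCoefficients(params, profile, xi, 0)
    D <- co$D_eff
    U <- co$U_eff
    # dD/dx analytic-through-centred-differences on a fine stencil
    epsh <- 1e-6
    Dfun <- function(xx) {
      cc <- effectiveCoefficients(params, profile, xx, 0)
      cc$D_eff
    }
    Dx <- (Dfun(xi + epsh) - Dfun(xi - epsh)) / (2 * epsh)
    adv <- Dx - U
    rhs <- function(t, y, p) {
      C <- if (dirichlet) c(1, y) else y
      nn <- length(C)
      Cxx <- c(0, diff(C, differences = 2), 0) / h^2
      Cxx[nn] <- 2 * (C[nn - 1] - C[nn]) / h^2
      if (!dirichlet) Cxx[1] <- 2 * (C[2] - C[1]) / h^2
      Cx <- c(0, (C[3:nn] - C[1:(nn - 2)]) / (2 * h), 0)
      dC <- D * Cxx + adv * Cx
      list(if (dirichlet) dC[-1] else dC)
    }
  }

  ny <- if (dirichlet) n else n + 1
  y0 <- rep(C0, length.out = ny)
  times <- unique(sort(c(0, t_eval)))

  if (profile$kind == "exponential_division") {
    Td <- profile$pars$T_div
    mu <- profile$pars$mu
    lamd <- profile$pars$lambda
    phi0 <- profile$pars$phi0
    # rhs with the generation index frozen for one inter-division segment,
    # so the coefficient jump happens exactly at the segment boundary
    segRhs <- function(gen) {
      lfun <- function(t) (1 - lamd * (1 - 2^(-gen))) * exp(mu * (t - Td * gen))
      function(t, y, p) {
        ld <- lfun(t)
        g <- transportGroupings(params, ld, phi0)
        # the fixed-domain transform follows the whole-file span, which
        # grows as the undivided exponential l = e^(mu t); the per-cell
        # coefficients use the divided length l_d
        lspan <- exp(mu * t)
        Dc <- (g$K * (ld + params$lambda) + g$M) * (ld + params$lambda) /
          g$V * (1 + params$lambda)^2 / (lspan + params$lambda)^2
        Vt <- (params$omega * (1 - phi0) + params$omega * phi0 * params$Pv +
                 params$lambda * params$Pa) * mu * ld
        Q <- Vt / g$V
        C <- if (dirichlet) c(1, y) else y
        nn <- length(C)
        Cxx <- c(0, diff(C, differences = 2), 0) / h^2
        Cxx[nn] <- 2 * (C[nn - 1] - C[nn]) / h^2
        if (!dirichlet) Cxx[1] <- 2 * (C[2] - C[1]) / h^2
        dC <- Dc * Cxx - Q * C
        list(if (dirichlet) dC[-1] else dC)
      }
    }
    breaks <- seq(0, max(times), by = Td)
    allt <- sort(unique(c(times, breaks)))
    out <- matrix(NA_real_, length(allt), ny)
    out[1, ] <- y0
    cur <- y0; tprev <- 0
    for (k in 2:length(allt)) {
      gen <- findInterval(tprev, breaks, left.open = FALSE) - 1
      sol <- deSolve::ode(cur, c(tprev, allt[k]), segRhs(gen), NULL,
                          method = "lsoda", rtol = rtol, atol = atol)
      cur <- sol[nrow(sol), -1]
      out[k, ] <- cur
      tprev <- allt[k]
    }
    keep <- allt %in% times
    tfull <- allt[keep]; Y <- out[keep, , drop = FALSE]
  } else {
    sol <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    tfull <- sol[, 1]
    Y <- sol[, -1, drop = FALSE]
  }

  C <- if (dirichlet) cbind(1, Y) else Y
  dimnames(C) <- NULL
  if (dirichlet && times[1] == 0) C[1, 1] <- C0[1]  # IC has the jump at x=0
  keep <- tfull %in% t_eval
  lam <- params$lambda
  x_of_xi <- function(t) {
    if (!moving) return(xi)
    if (profile$kind == "exponential_division") {
      # the domain follows the undivided exponential span
      xi * (exp(profile$pars$mu * t) + lam) / (1 + lam)
    } else {
      xi * (profile$l(0, t) + lam) / (1 + lam)
    }
  }
  structure(list(t = tfull[keep], xi = xi, C = C[keep, , drop = FALSE],
                 x_of_xi = x_of_xi, params = params, profile = profile),
            class = "continuum_solution")
}

#' @export
print.continuum_solution <- function(x, ...) {
  cat(sprintf("Continuum solution: %d times x %d nodes (profile '%s')\n",
              length(x$t), length(x$xi), x$profile$kind))
  invisible(x)
}
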