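#' Geometry of a file of cells
#'
#' A cell file is modelled as `N` cells of width `w` separated by apoplast
#' walls of thickness `a`.  Lengths (and vacuolar fractions) are recorded
#' for `N + 1` cells because the model domain runs from the centre of the
#' first cell to the centre of cell `N + 1`.  The initial file length is
#' `L0 = l_1/2 + sum(l_2..l_N) + l_{N+1}/2 + N a`, which for a uniform file
#' reduces to `N (l + a)`; the average cell length is `l_av = L0/N - a`.
#'
#' @param N Number of cells spanned by the domain.
#' @param w Cell width (micrometre).
#' @param a Apoplast thickness (micrometre).
#' @param lengths Cell lengths (micrometre): a scalar for a uniform file or
#'   a vector of `N + 1` per-cell lengths.
#' @param fractions Vacuolar area fractions in `(0, 1)`: scalar or vector
#'   of `N + 1`.
#' @return An object of class `cell_file_geometry`.
#' @export
cellFileGeometry <- function(N, w, a, lengths, fractions) {
  if (length(lengths) == 1) lengths <- rep(lengths, N + 1)
  if (length(fractions) == 1) fractions <- rep(fractions, N + 1)
  stopifnot(length(lengths) == N + 1, length(fractions) == N + 1)
  if (any(lengths <= 0)) stop("cell lengths must be positive")
  if (any(fractions <= 0 | fractions >= 1))
    stop("vacuolar fractions must lie strictly between 0 and 1")
  L0 <- lengths[1] / 2 + sum(lengths[seq(2, N)]) + lengths[N + 1] / 2 + N * a
  structure(list(
    N = N, w = w, a = a, lengths = lengths, fractions = fractions,
    l_av = L0 / N - a, L0 = L0
  ), class = "cell_file_geometry")
}

#' @export
print.cell_file_geometry <- function(x, ...) {
  cat(sprintf(
    "Cell file: %d cells, width %g um, apoplast %g um\n  lengths %s um, l_av %.4g um, L0 %.4g um\n",
    x$N, x$w, x$a,
    if (length(unique(x$lengths)) == 1) sprintf("%g (uniform)", x$lengths[1])
    else sprintf("%.3g..%.3g (graded)", x$lengths[1], x$lengths[x$N + 1]),
    x$l_av, x$L0))
  invisible(x)
}

#' Preset short-cell and long-cell file geometries
#'
#' Twenty cells of 10 um width with 0.5 um apoplast walls; short cells are
#' 20 um with vacuolar fraction 0.1 (meristem-like), long cells 200 um with
#' fraction 0.91 (mature zone; same cytoplasmic area as the short cells,
#' elongation being driven by vacuolar expansion).
#'
#' @param cells `"short"` or `"long"`.
#' @return A [cellFileGeometry()] object.
#' @export
gaGeometry <- function(cells = c("short", "long")) {
  cells <- match.arg(cells)
  if (cells == "short") cellFileGeometry(20, 10, 0.5, 20, 0.1)
  else cellFileGeometry(20, 10, 0.5, 200, 0.91)
}

#' Cell-centre positions along a file
#'
#' Positions of the cell centres in the continuum coordinate `x` on
#' `[0, 1]`, anchored at the centre of cell 1.  Successive centres are
#' separated by half of each neighbouring cell plus one apoplast wall,
#' normalised by the file length `N (1 + lambda)` in units of the average
#' cell length:
#' `x_i = (l_1/2 + sum_{j=2}^{i-1} l_j + l_i/2 + (i-1) lambda) / (N (1+lambda))`.
#'
#' @param lengths Dimensionless cell lengths (units of the average cell
#'   length), one per cell, `N + 1` entries.
#' @param lam Dimensionless apoplast thickness `lambda`.
#' @param N Cell count; defaults to `length(lengths) - 1`.
#' @return Vector of `N + 1` positions with `x[1] == 0`; for a
#'   self-consistent file `x[N + 1] == 1`.
#' @export
cellCenters <- function(lengths, lam, N = length(lengths) - 1) {
  if (any(lengths <= 0)) stop("cell lengths must be positive")
  stopifnot(length(lengths) == N + 1)
  steps <- (lengths[-(N + 1)] / 2 + lengths[-1] / 2 + lam) / (N * (1 + lam))
  c(0, cumsum(steps))
}

#' Fit a linearly graded cell file from its end cells
#'
#' Constructs the unique static file whose cell lengths follow a linear
#' profile `l(x) = alpha x + nu` (dimensionless, in units of the average
#' cell length) when each cell's length equals the profile evaluated at its
#' own centre.  Only the first and last cell lengths are prescribed; the
#' remaining lengths, the average length and the file length follow from a
#' damped fixed-point iteration on the file length (the undamped centre map
#' oscillates).  Vacuolar fractions vary linearly in `x` between the two
#' end values.
#'
#' @param l1,lN1 Lengths of cell 1 and cell `N + 1` (micrometre).
#' @param phi1,phiN1 Vacuolar fractions of the end cells.
#' @param N Cell count.
#' @param a Apoplast thickness (micrometre).
#' @param tol Relative convergence tolerance on the average cell length.
#' @param max_iter Iteration cap; non-convergence signals inconsistent
#'   inputs.
#' @return List with `l_av`, `L` (micrometre), `alpha`, `nu`, per-cell
#'   `lengths_um` and `fractions` (`N + 1` each), centres `x` in `[0, 1]`,
#'   `lambda`, the fitted [cellFileGeometry()] as `geometry`, and the
#'   matching [linearSpaceProfile()] as `profile`.
#' @examples
#' f <- fitLinearFile(20, 200, 0.1, 0.9, N = 20, a = 0.5)
#' f$l_av   # ~78.5 um
#' f$alpha  # ~2.29
#' @export
fitLinearFile <- function(l1, lN1, phi1, phiN1, N = 20, a = 0.5,
                          tol = 1e-10, max_iter = 1000) {
  stopifnot(l1 > 0, lN1 > 0)
  L <- N * ((l1 + lN1) / 2 + a)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- (lN1 - l1) / L            # dimensional slope d l / d x
    x <- l <- numeric(N + 1)
    l[1] <- l1
    for (i in 2:(N + 1)) {
      # centre recurrence with l_i = l1 + s x_i solved for x_i
      x[i] <- (x[i - 1] + l[i - 1] / 2 + a + l1 / 2) / (1 - s / 2)
      l[i] <- l1 + s * x[i]
    }
    L_new <- L + 0.5 * (x[N + 1] - L)
    if (abs(L_new - L) < tol * L) {
      L <- L_new
      converged <- TRUE
      break
    }
    L <- L_new
  }
  if (!converged) stop("linear-file fit did not converge: inconsistent inputs")
  l_av <- L / N - a
  xn <- x / L
  fr <- phi1 + (phiN1 - phi1) * xn
  alpha <- (lN1 - l1) / l_av
  nu <- l1 / l_av
  list(
    l_av = l_av, L = L, alpha = alpha, nu = nu,
    lengths_um = l, fractions = fr, x = xn, lambda = a / l_av,
    iterations = it,
    geometry = cellFileGeometry(N, 10, a, l, pmin(pmax(fr, 1e-6), 1 - 1e-6)),
    profile = linearSpaceProfile(alpha, nu, phi1, phiN1)
  )
}

#' Vacuolar fraction after elongation by vacuolar expansion
#'
#' When a cell elongates purely by vacuole enlargement its cytoplasmic area
#' `(1 - phi) l` is conserved, so `phi = 1 - (1 - phi0) l0 / l`.
#'
#' @param l Current cell length.
#' @param l0 Initial cell length.
#' @param phi0 Initial vacuolar fraction.
#' @return Vacuolar fraction at length `l`.
#' @export
vacuolarExpansionFraction <- function(l, l0, phi0) {
  if (any(l < l0 * (1 - phi0)))
    stop("cell shorter than its conserved cytoplasmic area: phi would be negative")
  1 - (1 - phi0) * l0 / l
}

#' Area-preserving average vacuolar fraction of a graded file
#'
#' The uniform fraction that preserves the total vacuolar area of a graded
#' file, with half weight on the two end cells (whose centres delimit the
#' domain): `phi_av = (phi_1 l_1 / 2 + sum_{j=2}^{N} phi_j l_j +
#' phi_{N+1} l_{N+1} / 2) / (N l_av)`.
#'
#' @param lengths Per-cell lengths (`N + 1`), any consistent unit.
#' @param fractions Per-cell vacuolar fractions (`N + 1`).
#' @param l_av Average cell length in the same unit as `lengths`.
#' @return The average vacuolar fraction.
#' @export
averageVacuolarFraction <- function(lengths, fractions, l_av) {
  N <- length(lengths) - 1
  stopifnot(length(fractions) == N + 1)
  w <- c(0.5, rep(1, N - 1), 0.5)
  sum(w * fractions * lengths) / (N * l_av)
}

#' Synchronous division schedule
#'
#' Exponential growth at relative elongation rate `mu` with synchronous
#' division every `T_div` time units; a cell divides exactly when it has
#' doubled, which fixes `mu = log(2) / T_div`.
#'
#' @param T_div Dimensionless inter-division time.
#' @param lambda Dimensionless apoplast thickness (units of the initial
#'   cell length).
#' @return Object of class `division_schedule` with `mu`, `T_div`, `lambda`.
#' @export
divisionSchedule <- function(T_div, lambda) {
  stopifnot(T_div > 0, lambda >= 0)
  structure(list(mu = log(2) / T_div, T_div = T_div, lambda = lambda),
            class = "division_schedule")
}

#' Cell length under exponential growth with synchronous division
#'
#' Between divisions every cell elongates exponentially; at each division
#' the mother's length is split into two equal daughters plus one new
#' apoplast wall of thickness `lambda`, giving
#' \deqn{l_d(t) = (1 - \lambda (1 - 2^{-\lfloor t/T \rfloor}))
#'   e^{\mu (t - T \lfloor t/T \rfloor)}.}
#' The function is discontinuous exactly at the division instants `t = nT`,
#' where it takes the post-division (right-limit) value.
#'
#' @param t Dimensionless time (vectorised).
#' @param sched A [divisionSchedule()].
#' @return Cell length(s) in units of the initial cell length.
#' @export
divisionLength <- function(t, sched) {
  stopifnot(inherits(sched, "division_schedule"), all(t >= 0))
  n <- floor(t / sched$T_div)
  (1 - sched$lambda * (1 - 2^(-n))) * exp(sched$mu * (t - sched$T_div * n))
}

# ---- prescribed length/fraction profiles -------------------------------

newProfile <- function(kind, l, dl_dx, dl_dt, phi, dphi_dx, dphi_dt, pars) {
  structure(list(kind = kind, l = l, dl_dx = dl_dx, dl_dt = dl_dt,
                 phi = phi, dphi_dx = dphi_dx, dphi_dt = dphi_dt,
                 pars = pars),
            class = "length_profile")
}

#' @export
print.length_profile <- function(x, ...) {
  cat(sprintf("Length profile '%s'", x$kind))
  if (length(x$pars))
    cat(": ", paste(names(x$pars), signif(unlist(x$pars), 4),
                    sep = " = ", collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Static uniform length profile
#'
#' All cells have dimensionless length 1 and a fixed vacuolar fraction.
#'
#' @param phi0 Vacuolar fraction.
#' @return A `length_profile` of kind `static_uniform`.
#' @export
staticUniformProfile <- function(phi0) {
  newProfile("static_uniform",
             l = function(x, t) rep(1, length(x)),
             dl_dx = function(x, t) rep(0, length(x)),
             dl_dt = function(x, t) rep(0, length(x)),
             phi = function(x, t) rep(phi0, length(x)),
             dphi_dx = function(x, t) rep(0, length(x)),
             dphi_dt = function(x, t) rep(0, length(x)),
             pars = list(phi0 = phi0))
}

#' Identical cells growing linearly in time
#'
#' Every cell has length `l(t) = kappa t + 1` (units of the initial
#' length).  With `vacuolar_expansion = TRUE` growth is attributed to
#' vacuole enlargement, so the cytoplasmic area is conserved and
#' `phi(t) = 1 - (1 - phi0) / l(t)`; otherwise the fraction stays at
#' `phi0`.
#'
#' @param kappa Dimensionless linear growth rate (a Peclet-like number
#'   comparing elongation with apoplastic diffusion along the file).
#' @param phi0 Initial vacuolar fraction.
#' @param vacuolar_expansion Logical, see above.
#' @return A `length_profile` of kind `linear_time`.
#' @export
linearTimeProfile <- function(kappa, phi0, vacuolar_expansion = TRUE) {
  lfun <- function(x, t) rep(kappa * t + 1, length(x))
  if (vacuolar_expansion) {
    phif <- function(x, t) rep(vacuolarExpansionFraction(kappa * t + 1, 1, phi0),
                               length(x))
    dphit <- function(x, t) rep((1 - phi0) * kappa / (kappa * t + 1)^2, length(x))
  } else {
    phif <- function(x, t) rep(phi0, length(x))
    dphit <- function(x, t) rep(0, length(x))
  }
  newProfile("linear_time",
             l = lfun,
             dl_dx = function(x, t) rep(0, length(x)),
             dl_dt = function(x, t) rep(kappa, length(x)),
             phi = phif,
             dphi_dx = function(x, t) rep(0, length(x)),
             dphi_dt = dphit,
             pars = list(kappa = kappa, phi0 = phi0,
                         vacuolar_expansion = vacuolar_expansion))
}

#' Static file with linearly graded lengths and vacuolar fractions
#'
#' Lengths follow `l(x) = alpha x + nu` and fractions
#' `phi(x) = phi1 + (phiN1 - phi1) x` on the unit domain, both in units of
#' the average cell length; see [fitLinearFile()] for constructing a
#' self-consistent parameterisation from dimensional end cells.
#'
#' @param alpha Dimensionless length slope.
#' @param nu Dimensionless first-cell length.
#' @param phi1,phiN1 Vacuolar fractions of the first and last cell.
#' @return A `length_profile` of kind `linear_space`.
#' @export
linearSpaceProfile <- function(alpha, nu, phi1, phiN1) {
  newProfile("linear_space",
             l = function(x, t) alpha * x + nu,
             dl_dx = function(x, t) rep(alpha, length(x)),
             dl_dt = function(x, t) rep(0, length(x)),
             phi = function(x, t) phi1 + (phiN1 - phi1) * x,
             dphi_dx = function(x, t) rep(phiN1 - phi1, length(x)),
             dphi_dt = function(x, t) rep(0, length(x)),
             pars = list(alpha = alpha, nu = nu, phi1 = phi1, phiN1 = phiN1))
}

#' Identical cells with exponential growth and synchronous division
#'
#' Cell length follows [divisionLength()]; the vacuolar fraction is held
#' constant (vacuoles stay small in meristematic tissue, growth being both
#' cytoplasmic and vacuolar).  The time derivative `mu * l_d` applies
#' between division instants.
#'
#' @param sched A [divisionSchedule()].
#' @param phi0 Constant vacuolar fraction (default 0.1).
#' @return A `length_profile` of kind `exponential_division`.
#' @export
divisionProfile <- function(sched, phi0 = 0.1) {
  newProfile("exponential_division",
             l = function(x, t) rep(divisionLength(t, sched), length(x)),
             dl_dx = function(x, t) rep(0, length(x)),
             dl_dt = function(x, t) rep(sched$mu * divisionLength(t, sched),
                                        length(x)),
             phi = function(x, t) rep(phi0, length(x)),
             dphi_dx = function(x, t) rep(0, length(x)),
             dphi_dt = function(x, t) rep(0, length(x)),
             pars = list(mu = sched$mu, T_div = sched$T_div,
                         lambda = sched$lambda, phi0 = phi0, sched = sched))
}

#' Growth velocity field of a cell file
#'
#' The material velocity `u(x, t)` of the file relative to the anchored
#' centre of cell 1, obtained from cell-number conservation
#' `d/dx (u / (l + lambda)) = (1 / (l + lambda)^2) dl/dt` with
#' `u(0, t) = 0`.  Static profiles give `u = 0`; identical growing cells
#' give the exact linear field `u = x (dl/dt) / (l + lambda)`.
#'
#' @param profile A `length_profile`.
#' @param lam Dimensionless apoplast thickness.
#' @return A function `u(x, t)`.
#' @export
growthVelocity <- function(profile, lam) {
  switch(profile$kind,
    static_uniform = ,
    linear_space = function(x, t) rep(0, length(x)),
    linear_time = ,
    exponential_division = function(x, t) {
      x * profile$dl_dt(0, t) / (profile$l(0, t) + lam)
    },
    stop("unknown profile kind: ", profile$kind)
  )
}
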