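# The discrete model tracks, for a file of N cells, the dimensionless
# hormone concentration in the cytoplasm (c), vacuole (v) and three
# apoplastic compartments per cell: the transverse wall downstream of the
# cell (f), the corner linking it to the longitudinal path (g) and the
# longitudinal strip running alongside the cell (h).  c_1 and h_1 are
# clamped by the upstream boundary (c_1 = boundary value, h_1 = Pa * c_1,
# the quasi-static apoplastic level), and the downstream end uses ghost
# reflections c_{N+1} = c_{N-1}, h_{N+1} = h_{N-1}.  The evolved unknowns
# are c_2..c_N, v_1..v_N, f_1..f_N, g_1..g_N, h_2..h_N: 5N - 2 equations.

stateIndex <- function(N) {
  list(c = seq_len(N - 1),
       v = (N - 1) + seq_len(N),
       f = (2 * N - 1) + seq_len(N),
       g = (3 * N - 1) + seq_len(N),
       h = (4 * N - 1) + seq_len(N - 1))
}

# all compartment fluxes, vectorised over cells.
#   c_full, h_full: length N (clamped first entries included)
#   v, f, g:        length N
#   l_ext:          N + 1 cell lengths (ghost cell N+1 included)
#   c_ghost, h_ghost: downstream ghost values
# "in" vectors are aligned with their source wall: Jfc_in[k] is the flux
# from wall k into cell k + 1, Jgh_in[k] from corner k into strip k + 1.
discreteFluxes <- function(c_full, v, f, g, h_full, params, l_ext,
                           c_ghost, h_ghost) {
  N <- length(c_full)
  lam <- params$lambda
  om <- params$omega
  c_ext <- c(c_full, c_ghost)
  h_ext <- c(h_full, h_ghost)
  kgh <- 2 * (1 + lam) / (l_ext[-1] + lam)   # strip/corner exchange, cell i+1
  kh <- 2 * (1 + lam) / (l_ext[seq_len(N)] + lam)
  list(
    J_cf = params$P_ca * c_full - params$P_ac * f,
    J_cv = params$P_cv * c_full - params$P_vc * v,
    Jfc_in = params$P_ac * f - params$P_ca * c_ext[-1],
    J_ch = params$P_ca * c_full - params$P_ac * h_full,
    J_fg = 2 * (1 + lam) / (om + lam) * (f - g),
    Jgh_in = kgh * (g - h_ext[-1]),
    J_hg = kh * (h_full - g),
    J_cc = params$P_plas * (c_ext[-1] - c_full)
  )
}

#' Compartment fluxes of the discrete model
#'
#' Evaluates every inter-compartment flux for a given file state: membrane
#' exchange cytoplasm-wall (`J_cf`, and `Jfc_in` from wall `k` into cell
#' `k + 1`), cytoplasm-vacuole (`J_cv`), cytoplasm-longitudinal strip
#' (`J_ch`), apoplastic diffusion wall-corner (`J_fg`), corner-strip
#' (`Jgh_in` into the next cell's strip, `J_hg` back into the same cell's
#' corner) and plasmodesmatal cytoplasm-cytoplasm (`J_cc`).  All fluxes
#' are linear in the concentrations.
#'
#' @param state List with vectors `c`, `v`, `f`, `g`, `h` of length `N`
#'   (`c[1]`, `h[1]` are the upstream boundary values).
#' @param params A `cell_params` object.
#' @param lengths Dimensionless per-cell lengths: scalar or `N + 1` values
#'   (the extra entry is the ghost cell).
#' @param downstream Ghost rule: `"reflect"` (`c_{N+1} = c_{N-1}`) or
#'   `"copy"` (`c_{N+1} = c_N`).
#' @return Named list of flux vectors.
#' @export
compartmentFluxes <- function(state, params, lengths = 1,
                              downstream = c("reflect", "copy")) {
  downstream <- match.arg(downstream)
  N <- length(state$c)
  if (length(lengths) == 1) lengths <- rep(lengths, N + 1)
  stopifnot(length(lengths) == N + 1)
  if (any(lengths <= 0)) stop("cell lengths must be positive")
  gi <- if (downstream == "reflect") N - 1 else N
  discreteFluxes(state$c, state$v, state$f, state$g, state$h, params,
                 lengths, c_ghost = state$c[gi], h_ghost = state$h[gi])
}

# assemble the time derivatives of the amount-form state
#   y: packed state; amounts for c, v, h; concentrations for f, g
#   l: per-cell lengths (N + 1 with ghost), phi: per-cell fractions (N)
#   dl, dphi: their time derivatives (unused here: amounts absorb them)
growingRhs <- function(y, params, l, phi, c_up, downstream) {
  N <- length(phi)
  ix <- stateIndex(N)
  eps <- params$eps; lam <- params$lambda; om <- params$omega
  Ups <- params$Pa * c_up
  ln <- l[seq_len(N)]
  c_full <- c(c_up, y[ix$c] / ((1 - phi[-1]) * ln[-1]))
  v <- y[ix$v] / (phi * ln)
  f <- y[ix$f]
  g <- y[ix$g]
  h_full <- c(Ups, y[ix$h] / ln[-1])
  gi <- if (downstream == "reflect") N - 1 else N
  Jl <- discreteFluxes(c_full, v, f, g, h_full, params, l,
                       c_ghost = c_full[gi], h_ghost = h_full[gi])
  i <- 2:N
  dac <- (1 + lam) / (eps^2 * om) *
    (om * (Jl$Jfc_in[i - 1] - Jl$J_cf[i] + Jl$J_cc[i] - Jl$J_cc[i - 1]) -
       ln[i] * Jl$J_ch[i] - 2 * sqrt(phi[i]) * (ln[i] + om) * Jl$J_cv[i])
  dav <- (1 + lam) / (eps^2 * om) *
    2 * sqrt(phi) * (ln + om) * Jl$J_cv
  df <- (1 + lam) / (eps^2 * lam * om) *
    (om * (Jl$J_cf - Jl$Jfc_in) - lam * Jl$J_fg)
  dg <- (1 + lam) / (eps^2 * lam) *
    (Jl$J_hg - Jl$Jgh_in + Jl$J_fg)
  dah <- (1 + lam) / (eps^2 * lam) *
    (ln[i] * Jl$J_ch[i] + lam * (Jl$Jgh_in[i - 1] - Jl$J_hg[i]))
  c(dac, dav, df, dg, dah)
}

#' Time derivatives of the static discrete system
#'
#' Right-hand side of the `5N - 2` equations for identical static cells in
#' concentration form, with the left-hand capacitance prefactors divided
#' through.  The state packing is `c(c_2..c_N, v_1..v_N, f_1..f_N,
#' g_1..g_N, h_2..h_N)`.  Exposed for direct inspection (e.g. verifying
#' the quasi-static fixed point `c = 1`, `v = Pv`, `f = g = h = Pa`);
#' simulations use [simulateDiscrete()].
#'
#' @param y Packed state vector of length `5 N - 2`.
#' @param params A `cell_params` object (geometry fixes `N`).
#' @param c_up Upstream cytoplasmic boundary value.
#' @param downstream Ghost rule, see [compartmentFluxes()].
#' @param phi Vacuolar fraction.
#' @return Vector of time derivatives, same packing as `y`.
#' @export
rhsStatic <- function(y, params, c_up = 1, downstream = "reflect",
                      phi = params$phi[1]) {
  N <- params$geom$N
  ix <- stateIndex(N)
  eps <- params$eps; lam <- params$lambda; om <- params$omega
  c_full <- c(c_up, y[ix$c])
  v <- y[ix$v]; f <- y[ix$f]; g <- y[ix$g]
  h_full <- c(params$Pa * c_up, y[ix$h])
  gi <- if (downstream == "reflect") N - 1 else N
  Jl <- discreteFluxes(c_full, v, f, g, h_full, params, rep(1, N + 1),
                       c_ghost = c_full[gi], h_ghost = h_full[gi])
  i <- 2:N
  dc <- (1 + lam) / ((1 - phi) * eps^2 * om) *
    (om * (Jl$Jfc_in[i - 1] - Jl$J_cf[i] + Jl$J_cc[i] - Jl$J_cc[i - 1]) -
       Jl$J_ch[i] - 2 * sqrt(phi) * (1 + om) * Jl$J_cv[i])
  dv <- (1 + lam) / (phi * eps^2 * om) * 2 * sqrt(phi) * (1 + om) * Jl$J_cv
  df <- (1 + lam) / (eps^2 * lam * om) *
    (om * (Jl$J_cf - Jl$Jfc_in) - lam * Jl$J_fg)
  dg <- (1 + lam) / (eps^2 * lam) * (Jl$J_hg - Jl$Jgh_in + Jl$J_fg)
  dh <- (1 + lam) / (eps^2 * lam) *
    (Jl$J_ch[i] + lam * (Jl$Jgh_in[i - 1] - Jl$J_hg[i]))
  c(dc, dv, df, dg, dh)
}

#' Time derivatives of the growing discrete system
#'
#' Right-hand side for a file with per-cell lengths `l_i(t)` and vacuolar
#' fractions `phi_i(t)`.  The state stores conserved amounts for the
#' compartments whose capacitance changes with growth (`(1 - phi_i) l_i
#' c_i`, `phi_i l_i v_i`, `l_i h_i`) and concentrations for the
#' fixed-size wall and corner compartments, packed as in [rhsStatic()].
#' With `l = 1` and constant `phi` the dynamics reduce exactly to the
#' static system.
#'
#' @param y Packed amount-form state of length `5 N - 2`.
#' @param params A `cell_params` object.
#' @param l Per-cell dimensionless lengths, `N + 1` values (ghost cell
#'   included).
#' @param phi Per-cell vacuolar fractions, `N` values.
#' @param c_up Upstream cytoplasmic boundary value.
#' @param downstream Ghost rule, see [compartmentFluxes()].
#' @return Vector of time derivatives of the packed amounts.
#' @export
rhsGrowing <- function(y, params, l, phi, c_up = 1, downstream = "reflect") {
  growingRhs(y, params, l, phi, c_up, downstream)
}

# pack/unpack helpers for the amount form
packAmounts <- function(c_int, v, f, g, h_int, l, phi) {
  N <- length(phi)
  c(c_int * (1 - phi[-1]) * l[2:N], v * phi * l[seq_len(N)],
    f, g, h_int * l[2:N])
}

unpackState <- function(y, params, l, phi, c_up) {
  N <- length(phi)
  ix <- stateIndex(N)
  ln <- l[seq_len(N)]
  list(c = c(c_up, y[ix$c] / ((1 - phi[-1]) * ln[-1])),
       v = y[ix$v] / (phi * ln),
       f = y[ix$f], g = y[ix$g],
       h = c(params$Pa * c_up, y[ix$h] / ln[-1]))
}

# per-cell lengths/fractions as functions of time for a profile
profileLengths <- function(params, profile) {
  N <- params$geom$N
  if (is.null(profile) || profile$kind == "static_uniform") {
    phi0 <- if (is.null(profile)) params$phi[1] else profile$pars$phi0
    function(t) list(l = rep(1, N + 1), phi = rep(phi0, N))
  } else if (profile$kind == "linear_space") {
    l <- params$geom$lengths / params$l_ref
    phi <- params$geom$fractions[seq_len(N)]
    function(t) list(l = l, phi = phi)
  } else {
    function(t) {
      list(l = rep(profile$l(0, t), N + 1),
           phi = rep(profile$phi(0, t), N))
    }
  }
}

#' Simulate the discrete multicellular transport model
#'
#' Integrates the full `5N - 2` compartmental ODE system from
#' hormone-free initial conditions, for static identical cells, identical
#' cells growing in time, or a static spatially graded file.  Growing
#' files are evolved in conserved-amount variables (capacitance times
#' concentration), so dilution enters exactly through the product rule;
#' concentrations are recovered for output.  The system is stiff (the
#' apoplastic corner compartments relax on an `eps^2 lambda^2` time
#' scale) and is integrated with a BDF-capable solver; for the
#' time-invariant cases the exact constant Jacobian of the linear flux
#' operator is supplied.
#'
#' @param params A `cell_params` object (its geometry fixes `N`; for
#'   `linear_space` profiles the per-cell lengths come from the fitted
#'   geometry).
#' @param t_eval Output times (dimensionless, file-diffusion scale).
#' @param profile `NULL` (static uniform at `params$phi`) or a
#'   `length_profile` of kind `static_uniform`, `linear_time` or
#'   `linear_space`.
#' @param boundary_value Upstream cytoplasmic concentration (the
#'   longitudinal apoplast boundary scales with it as `Pa *
#'   boundary_value`).
#' @param downstream Downstream ghost rule, see [compartmentFluxes()].
#' @param rtol,atol Solver tolerances.
#' @return Object of class `file_trajectory`: `t` and matrices `c`, `v`,
#'   `f`, `g`, `h` (`length(t)` rows, `N` columns; `c[, 1]` and `h[, 1]`
#'   are the boundary values), plus `centers(t)` giving cell-centre
#'   positions in units of the initial file length.
#' @export
simulateDiscrete <- function(params, t_eval, profile = NULL,
                             boundary_value = 1,
                             downstream = c("reflect", "copy"),
                             rtol = 1e-8, atol = 1e-10) {
  downstream <- match.arg(downstream)
  N <- params$geom$N
  lenAt <- profileLengths(params, profile)
  ny <- 5 * N - 2
  y0 <- rep(0, ny)
  times <- unique(sort(c(0, t_eval)))
  static <- is.null(profile) ||
    profile$kind %in% c("static_uniform", "linear_space")

  if (static) {
    L0 <- lenAt(0)
    rhsf <- function(t, y, p)
      list(growingRhs(y, params, L0$l, L0$phi, boundary_value, downstream))
    # exact Jacobian of the linear operator, assembled column by column
    base <- growingRhs(y0, params, L0$l, L0$phi, boundary_value, downstream)
    A <- vapply(seq_len(ny), function(j) {
      e <- numeric(ny); e[j] <- 1
      growingRhs(e, params, L0$l, L0$phi, boundary_value, downstream) - base
    }, numeric(ny))
    sol <- deSolve::ode(y0, times, rhsf, NULL, method = "lsode",
                        jactype = "fullusr",
                        jacfunc = function(t, y, p) A,
                        rtol = rtol, atol = atol)
  } else {
    rhsf <- function(t, y, p) {
      Lt <- lenAt(t)
      list(growingRhs(y, params, Lt$l, Lt$phi, boundary_value, downstream))
    }
    sol <- deSolve::ode(y0, times, rhsf, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
  }

  keep <- sol[, 1] %in% t_eval
  tt <- sol[keep, 1]
  Y <- sol[keep, -1, drop = FALSE]
  mats <- lapply(c("c", "v", "f", "g", "h"), function(s) {
    matrix(NA_real_, length(tt), N)
  })
  names(mats) <- c("c", "v", "f", "g", "h")
  for (r in seq_along(tt)) {
    Lt <- lenAt(tt[r])
    st <- unpackState(Y[r, ], params, Lt$l, Lt$phi, boundary_value)
    for (s in names(mats)) mats[[s]][r, ] <- st[[s]]
  }
  centers <- function(t) {
    # cellCenters normalises by N (1 + lambda), i.e. by the *initial*
    # file length, so growing files extend beyond x = 1 as they should
    cellCenters(lenAt(t)$l, params$lambda, N)
  }
  structure(c(list(t = tt), mats,
              list(centers = centers, params = params, profile = profile,
                   N = N)),
            class = "file_trajectory")
}

#' @export
print.file_trajectory <- function(x, ...) {
  cat(sprintf("Discrete file trajectory: %d cells, %d output times (t %g..%g)\n",
              x$N, length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' Simulate a growing file with synchronous cell divisions
#'
#' Identical cells elongate exponentially (relative rate `mu = log(2) /
#' T_div`) and all divide simultaneously whenever they double: each mother
#' of length `l` is replaced by two daughters of length `(l - lambda) / 2`
#' separated by a fresh apoplast wall, so the file length is continuous
#' across events.  Daughters inherit the mother's cytoplasmic and
#' vacuolar concentrations and its longitudinal-strip value; the newly
#' created wall/corner compartments start at the quasi-static apoplastic
#' level `Pa * c_mother`.  The vacuolar fraction is held constant.
#'
#' @param params A `cell_params` object whose geometry describes the
#'   initial file (its `N` is the starting cell count and its `l_av` the
#'   initial cell length).
#' @param sched A [divisionSchedule()]; `sched$lambda` must equal
#'   `params$lambda`.
#' @param n_events Number of division events to simulate.
#' @param t_eval Optional additional output times; events and `t_end =
#'   n_events * T_div` are always included.
#' @param boundary_value Upstream cytoplasmic concentration.
#' @param rtol,atol Solver tolerances.
#' @return List of class `division_trajectory` with `snapshots` (one per
#'   output time: `t`, `N`, concentration vectors and `lengths`),
#'   `event_times`, and `counts` (cell count after each event).
#' @export
simulateWithDivision <- function(params, sched, n_events,
                                 t_eval = NULL, boundary_value = 1,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(sched, "division_schedule"))
  if (abs(sched$lambda - params$lambda) > 1e-12)
    stop("schedule lambda must match the dimensionless apoplast thickness")
  Td <- sched$T_div
  t_end <- n_events * Td
  outs <- sort(unique(c(t_eval, seq(0, n_events) * Td)))
  outs <- outs[outs <= t_end]

  N <- params$geom$N
  y <- rep(0, 5 * N - 2)
  l_gen <- 1                      # cell length at the current segment start
  t_cur <- 0
  snapshots <- list()
  counts <- integer(0)

  record <- function(t, y, N, l) {
    st <- unpackState(unname(y), params, rep(l, N + 1),
                      rep(params$phi[1], N), boundary_value)
    list(t = t, N = N, c = st$c, v = st$v, f = st$f, g = st$g, h = st$h,
         lengths = rep(l, N))
  }

  if (0 %in% outs)
    snapshots[[1]] <- record(0, y, N, l_gen)

  for (ev in seq_len(n_events)) {
    seg_start <- (ev - 1) * Td
    seg_end <- ev * Td
    lfun <- function(t) l_gen * exp(sched$mu * (t - seg_start))
    rhsf <- function(t, y, p) {
      l <- lfun(t)
      list(growingRhs(y, params, rep(l, N + 1), rep(params$phi[1], N),
                      boundary_value, "reflect"))
    }
    seg_outs <- outs[outs > seg_start & outs <= seg_end]
    times <- unique(sort(c(seg_start, seg_outs, seg_end)))
    sol <- deSolve::ode(y, times, rhsf, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    for (r in which(times %in% seg_outs))
      snapshots[[length(snapshots) + 1]] <-
        record(times[r], sol[r, -1], N, lfun(times[r]))
    y <- sol[nrow(sol), -1]

    # division event at t = ev * Td: double the file
    l_m <- lfun(seg_end)
    st <- unpackState(y, params, rep(l_m, N + 1), rep(params$phi[1], N),
                      boundary_value)
    l_d <- (l_m - params$lambda) / 2
    if (l_d <= 0) stop("apoplast thicker than the daughter cells")
    idx <- rep(seq_len(N), each = 2)            # mother of each daughter
    c2 <- st$c[idx]; v2 <- st$v[idx]; h2 <- st$h[idx]
    newwall <- rep(c(TRUE, FALSE), N)           # odd daughters: new wall
    f2 <- ifelse(newwall, params$Pa * st$c[idx], st$f[idx])
    g2 <- ifelse(newwall, params$Pa * st$c[idx], st$g[idx])
    N <- 2 * N
    phi2 <- rep(params$phi[1], N)
    l2 <- rep(l_d, N + 1)
    y <- packAmounts(c2[-1], v2, f2, g2, h2[-1], l2, phi2)
    l_gen <- l_d
    counts <- c(counts, N)
    snapshots[[length(snapshots) + 1]] <- record(seg_end, y, N, l_d)
  }

  structure(list(snapshots = snapshots, event_times = seq_len(n_events) * Td,
                 counts = counts, params = params, sched = sched),
            class = "division_trajectory")
}

#' @export
print.division_trajectory <- function(x, ...) {
  cat(sprintf("Division run: %d events, final cell count %d\n",
              length(x$event_times),
              if (length(x$counts)) x$counts[length(x$counts)]
              else x$params$geom$N))
  invisible(x)
}
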