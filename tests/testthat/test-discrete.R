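test_that("all fluxes vanish at the quasi-static equilibrium", {
  p <- ga_short_np
  N <- p$geom$N
  st <- list(c = rep(1, N), v = rep(p$Pv, N), f = rep(p$Pa, N),
             g = rep(p$Pa, N), h = rep(p$Pa, N))
  fl <- compartmentFluxes(st, p)
  for (J in fl) expect_equal(max(abs(J)), 0, tolerance = 1e-14)
})

test_that("plasmodesmatal flux follows the cytoplasmic difference", {
  p <- gaParams("short")  # open plasmodesmata, P_plas ~ 0.52
  st <- list(c = c(1, 0), v = c(0, 0), f = c(0, 0), g = c(0, 0), h = c(0, 0))
  p2 <- p; p2$geom$N <- 2
  fl <- compartmentFluxes(st, p2)
  expect_equal(fl$J_cc[1], p$P_plas * (0 - 1))
  expect_rel(-fl$J_cc[1], 0.52)
  # equal neighbours exchange nothing
  st$c <- c(0.4, 0.4)
  expect_equal(compartmentFluxes(st, p2)$J_cc[1], 0)
})

test_that("static right-hand side matches a hand-assembled three-cell file", {
  geom <- cellFileGeometry(3, 10, 0.5, 20, 0.1)
  p <- nondimensionalize(gaPhysiology(), geom, plasmodesmata = TRUE)
  set.seed(42)
  y <- runif(13)
  got <- rhsStatic(y, p)

  # independent assembly, written out index by index from the flux rules
  lam <- p$lambda; om <- p$omega; eps <- p$eps; phi <- p$phi[1]
  Pca <- p$P_ca; Pac <- p$P_ac; Pcv <- p$P_cv; Pvc <- p$P_vc; Ppl <- p$P_plas
  cc <- c(1, y[1], y[2], y[1])            # c_1..c_3 plus ghost c_4 = c_2
  v <- y[3:5]; f <- y[6:8]; g <- y[9:11]
  hh <- c(p$Pa, y[12], y[13], y[12])      # h_1..h_3 plus ghost h_4 = h_2
  Jcf <- Pca * cc[1:3] - Pac * f
  Jcv <- Pcv * cc[1:3] - Pvc * v
  Jfc <- Pac * f - Pca * cc[2:4]          # entry i is J_fc(i+1)
  Jch <- Pca * cc[1:3] - Pac * hh[1:3]
  Jfg <- 2 * (1 + lam) / (om + lam) * (f - g)
  Jgh <- 2 * (g - hh[2:4])                # entry i is J_gh(i+1)
  Jhg <- 2 * (hh[1:3] - g)
  Jcc <- Ppl * (cc[2:4] - cc[1:3])
  dc <- (1 + lam) / ((1 - phi) * eps^2 * om) *
    (om * (Jfc[1:2] - Jcf[2:3] + Jcc[2:3] - Jcc[1:2]) - Jch[2:3] -
       2 * sqrt(phi) * (1 + om) * Jcv[2:3])
  dv <- (1 + lam) / (phi * eps^2 * om) * 2 * sqrt(phi) * (1 + om) * Jcv
  df <- (1 + lam) / (eps^2 * lam * om) * (om * (Jcf - Jfc) - lam * Jfg)
  dg <- (1 + lam) / (eps^2 * lam) * (Jhg - Jgh + Jfg)
  dh <- (1 + lam) / (eps^2 * lam) * (Jch[2:3] + lam * (Jgh[1:2] - Jhg[2:3]))
  expect_equal(got, c(dc, dv, df, dg, dh), tolerance = 1e-12)

  # the quasi-static state is an exact fixed point
  yeq <- c(rep(1, 2), rep(p$Pv, 3), rep(p$Pa, 3), rep(p$Pa, 3), rep(p$Pa, 2))
  expect_equal(max(abs(rhsStatic(yeq, p))), 0, tolerance = 1e-10)
})

test_that("the static file relaxes to the quasi-static steady state", {
  p <- ga_short_np
  tr <- simulateDiscrete(p, t_eval = 20 / p$eps^2)
  expect_equal(max(abs(tr$c[1, ] - 1)), 0, tolerance = 1e-4)
  expect_equal(max(abs(tr$v[1, ] - p$Pv)), 0, tolerance = 1e-3)
  expect_equal(max(abs(tr$f[1, ] - p$Pa)), 0, tolerance = 1e-4)
  expect_equal(max(abs(tr$g[1, ] - p$Pa)), 0, tolerance = 1e-4)
  expect_equal(max(abs(tr$h[1, ] - p$Pa)), 0, tolerance = 1e-4)
})

test_that("interior compartments track the quasi-static ratios during transients", {
  p <- ga_short_np
  tr <- simulateDiscrete(p, t_eval = 0.5 / p$eps^2)
  interior <- 3:18
  qs_tol <- 1.5 * p$eps   # ratios hold to O(eps) during transients
  expect_lt(max(abs(tr$f[1, interior] / tr$c[1, interior] - p$Pa)) / p$Pa,
            qs_tol)
  expect_lt(max(abs(tr$g[1, interior] / tr$c[1, interior] - p$Pa)) / p$Pa,
            qs_tol)
  expect_lt(max(abs(tr$h[1, interior] / tr$c[1, interior] - p$Pa)) / p$Pa,
            qs_tol)
  expect_lt(max(abs(tr$v[1, interior] / tr$c[1, interior] - p$Pv)) / p$Pv,
            qs_tol)
})

test_that("trajectories are linear in the upstream boundary value", {
  p <- ga_short_np
  tt <- c(0.1, 1) / p$eps^2
  a <- simulateDiscrete(p, t_eval = tt, boundary_value = 1)
  b <- simulateDiscrete(p, t_eval = tt, boundary_value = 2.5)
  expect_equal(b$c, 2.5 * a$c, tolerance = 1e-7)
  expect_equal(b$v, 2.5 * a$v, tolerance = 1e-7)
  # zero boundary data leave the file empty
  z <- simulateDiscrete(p, t_eval = tt, boundary_value = 0)
  expect_equal(max(abs(z$c[, -1])), 0, tolerance = 1e-12)
})

test_that("zero growth rate reduces the growing system to the static one", {
  p <- ga_short_np
  tt <- c(0.1, 0.5) / p$eps^2
  a <- simulateDiscrete(p, t_eval = tt)
  b <- simulateDiscrete(p, t_eval = tt,
                        profile = linearTimeProfile(0, 0.1,
                                                    vacuolar_expansion = FALSE))
  expect_equal(b$c, a$c, tolerance = 1e-6)
  expect_equal(b$h, a$h, tolerance = 1e-6)
})

test_that("the alternative downstream closure only perturbs the file end", {
  p <- ga_short_np
  tt <- c(0.1, 0.5, 1, 4) / p$eps^2
  a <- simulateDiscrete(p, t_eval = tt, downstream = "reflect")
  b <- simulateDiscrete(p, t_eval = tt, downstream = "copy")
  # upstream half of the file is insensitive to the closure choice
  expect_lt(max(abs(a$c[, 1:10] - b$c[, 1:10])), 0.01)
})

test_that("synchronous division doubles the file and conserves its length", {
  geom <- cellFileGeometry(2, 10, 0.5, 5, 0.1)
  p <- nondimensionalize(gaPhysiology(), geom, plasmodesmata = FALSE)
  sched <- divisionSchedule(10, p$lambda)
  dv <- simulateWithDivision(p, sched, n_events = 3)
  expect_equal(dv$counts, 2 * 2^(1:3))
  # spans immediately before and after each event agree
  for (ev in 1:3) {
    at_ev <- Filter(function(s) isTRUE(all.equal(s$t, ev * 10)), dv$snapshots)
    expect_length(at_ev, 2)
    spans <- vapply(at_ev, function(s) sum(s$lengths + p$lambda), numeric(1))
    expect_equal(spans[1], spans[2], tolerance = 1e-10)
    # daughters inherit the mother's cytoplasmic concentrations
    pre <- at_ev[[1]]; post <- at_ev[[2]]
    expect_equal(post$c, pre$c[rep(seq_len(pre$N), each = 2)],
                 tolerance = 1e-10)
  }
})
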