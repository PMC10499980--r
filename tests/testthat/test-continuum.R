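test_that("effective diffusivity reproduces the tabulated regime values", {
  # without plasmodesmata (file-scale time rescaled by eps^2)
  expect_rel(limitDiffusivity(ga_short_np, "short_no_plas")$D_eff, 0.35)
  expect_rel(limitDiffusivity(ga_long_np, "long_no_plas")$D_eff, 0.63)
  # with plasmodesmata (no time rescaling)
  expect_rel(limitDiffusivity(ga_short_pl, "plasmodesmata")$D_eff, 0.43)
  expect_rel(limitDiffusivity(ga_long_pl, "plasmodesmata")$D_eff, 1.70)
  # the unscaled one-formula diffusivity agrees with the short-cell limit
  expect_rel(staticEffectiveDiffusivity(ga_short_np) / ga_short_np$eps^2,
             0.35)
  # dimensional value for short cells
  expect_rel(limitDiffusivity(ga_short_np, "short_no_plas")$D_eff_dimensional,
             28e-3)
})

test_that("apoplast-dominated geometry recovers free apoplastic diffusion", {
  p <- ga_short_np
  p$lambda <- 1e8
  expect_equal(staticEffectiveDiffusivity(p), 1, tolerance = 1e-6)
})

test_that("pathway decomposition attributes the diffusivity correctly", {
  s <- limitDiffusivity(ga_short_np, "short_no_plas")
  l <- limitDiffusivity(ga_long_np, "long_no_plas")
  expect_lt(abs(s$share_cell_to_cell - 0.40), 0.02)
  expect_lt(abs(l$share_cell_to_cell - 0.87), 0.02)
  expect_equal(s$share_cell_to_cell + s$share_apoplast, 1)
})

test_that("mutant diffusivities follow from knocked-out permeabilities", {
  # tabulated loss-of-function values, short/long, without plasmodesmata
  expect_rel(mutantDiffusivity(ga_short_np, "no_cyt_importer",
                               "short_no_plas")$D_eff, 0.41)
  expect_rel(mutantDiffusivity(ga_long_np, "no_cyt_importer",
                               "long_no_plas")$D_eff, 0.37)
  expect_rel(mutantDiffusivity(ga_short_np, "no_ton_importer",
                               "short_no_plas")$D_eff, 0.48)
  expect_rel(mutantDiffusivity(ga_long_np, "no_ton_importer",
                               "long_no_plas")$D_eff, 15.71)
  expect_rel(mutantDiffusivity(ga_short_np, "double",
                               "short_no_plas")$D_eff, 0.56)
  expect_rel(mutantDiffusivity(ga_long_np, "double",
                               "long_no_plas")$D_eff, 9.14)
  # with open plasmodesmata the cytoplasmic importer is irrelevant
  expect_equal(mutantDiffusivity(ga_short_pl, "no_cyt_importer",
                                 "plasmodesmata")$D_eff,
               limitDiffusivity(ga_short_pl, "plasmodesmata")$D_eff)
  expect_equal(mutantDiffusivity(ga_long_pl, "double", "plasmodesmata")$D_eff,
               mutantDiffusivity(ga_long_pl, "no_ton_importer",
                                 "plasmodesmata")$D_eff)
  expect_rel(mutantDiffusivity(ga_short_pl, "no_ton_importer",
                               "plasmodesmata")$D_eff, 0.58)
  expect_rel(mutantDiffusivity(ga_long_pl, "no_ton_importer",
                               "plasmodesmata")$D_eff, 42.18)
})

test_that("mutant formulas equal the general expression with substituted chemistry", {
  # the knockout closed forms, coded independently here from the
  # partition factors, must agree exactly with the package's route of
  # re-deriving permeabilities under the mutant flag
  phys <- gaPhysiology()
  pf <- partitionFactors(phys)
  for (preset in list(ga_short_pl, ga_long_pl)) {
    lam <- preset$lambda; om <- preset$omega; phi <- preset$phi[1]
    Pp <- preset$P_pass; Ppl <- preset$P_plas
    Pv_wt <- preset$Pv
    no_cyt <- (1 + lam) *
      (om * pf$B1 * Pp / 2 + om * Ppl + lam * pf$B1 / pf$A1) /
      ((1 - phi) * om + phi * om * Pv_wt +
         lam * (om + lam + 1) * pf$B1 / pf$A1)
    no_ton <- (1 + lam) *
      (om * preset$P_ca / 2 + om * Ppl + lam * preset$Pa) /
      ((1 - phi) * om + phi * om * pf$B1 / pf$C1 +
         lam * (om + lam + 1) * preset$Pa)
    dbl <- (1 + lam) *
      (om * pf$B1 * Pp / 2 + om * Ppl + lam * pf$B1 / pf$A1) /
      ((1 - phi) * om + phi * om * pf$B1 / pf$C1 +
         lam * (om + lam + 1) * pf$B1 / pf$A1)
    expect_equal(mutantDiffusivity(preset, "no_cyt_importer"), no_cyt,
                 tolerance = 1e-12)
    expect_equal(mutantDiffusivity(preset, "no_ton_importer"), no_ton,
                 tolerance = 1e-12)
    expect_equal(mutantDiffusivity(preset, "double"), dbl,
                 tolerance = 1e-12)
  }
})

test_that("coefficient specialisations collapse onto one another", {
  set.seed(7)
  for (rep in 1:10) {
    p <- randomParams()
    # static uniform: U = 0, Q = 0, D equals the closed form
    co <- effectiveCoefficients(p, staticUniformProfile(p$phi), x = 0.3)
    expect_equal(co$U_eff, 0)
    expect_equal(co$Q_eff, 0)
    expect_equal(co$D_eff, staticEffectiveDiffusivity(p), tolerance = 1e-12)
    # identical growing cells at t = 0 (l = 1): D matches the static form,
    # U is the linear growth field, Q is pure dilution minus stretching
    kappa <- runif(1, 1e-4, 0.05)
    prof <- linearTimeProfile(kappa, p$phi)
    cog <- effectiveCoefficients(p, prof, x = 0.4, t = 0)
    expect_equal(cog$D_eff, staticEffectiveDiffusivity(p), tolerance = 1e-12)
    expect_equal(cog$u, 0.4 * kappa / (1 + p$lambda), tolerance = 1e-12)
    # vacuolar-expansion identity dV/dt = (omega Pv + lambda Pa) dl/dt
    Vdot <- cellfile:::capacitanceRate(p, prof, 0, 0)
    expect_equal(Vdot, (p$omega * p$Pv + p$lambda * p$Pa) * kappa,
                 tolerance = 1e-12)
    # spatially graded static file with zero gradient equals static formula
    cos <- effectiveCoefficients(p, linearSpaceProfile(0, 1, p$phi, p$phi),
                                 x = 0.6)
    expect_equal(cos$D_eff, staticEffectiveDiffusivity(p), tolerance = 1e-12)
    expect_equal(cos$U_eff, 0, tolerance = 1e-12)
  }
})

test_that("series solution solves the static problem", {
  D <- staticEffectiveDiffusivity(ga_short_np)
  xs <- seq(0, 1, 0.05)
  expect_equal(as.numeric(analyticStaticSolution(xs, 1e4, D, 50)),
               rep(1, length(xs)), tolerance = 1e-6)
  expect_equal(analyticStaticSolution(0, 0.01 / D, D, 500)[1], 1,
               tolerance = 1e-6)
  # cross-solver oracle: method of lines against the series
  sol <- solveContinuum(ga_short_np, staticUniformProfile(0.1),
                        t_eval = 0.5 / ga_short_np$eps^2)
  Cs <- analyticStaticSolution(sol$xi, sol$t[1], D, 200)
  expect_lt(max(abs(sol$C[1, ] - Cs)), 1e-3)
})

test_that("growth-dilution balance parameter matches the growing-file analysis", {
  expect_rel(betaParameter(ga_short_np, 0.001), 7.5)
  expect_equal(betaParameter(ga_short_np, 0), 0)
  # steady profile: unit value upstream, zero slope at the far end
  expect_equal(steadyStateGrowing(0, 7.5), 1)
  expect_equal(steadyStateGrowing(seq(0, 1, 0.2), 0), rep(1, 6))
  h <- 1e-6
  for (b in c(0.3, 7.5, 75)) {
    slope <- (steadyStateGrowing(1, b) - steadyStateGrowing(1 - h, b)) / h
    expect_lt(abs(slope), 1e-4)
  }
  # stable at large beta
  expect_true(all(is.finite(steadyStateGrowing(seq(0, 1, 0.1), 1e4))))
})

test_that("growing solutions approach the balanced steady profile", {
  p <- ga_short_np
  prof <- linearTimeProfile(0.01, 0.1)
  sol <- solveContinuum(p, prof, t_eval = c(1000, 3000))
  Ceq <- steadyStateGrowing(sol$xi, betaParameter(p, 0.01))
  d1 <- max(abs(sol$C[1, ] - Ceq))
  d2 <- max(abs(sol$C[2, ] - Ceq))
  expect_lt(d2, d1)        # still converging towards the steady profile
  expect_lt(d2, 0.02)
})

test_that("diffusivity under division becomes periodic, under growth monotone", {
  p <- ga_short_np
  # pure linear growth: D_eff(t) eventually increases monotonically
  prof <- linearTimeProfile(0.01, 0.1)
  tt <- seq(200, 1000, 25)
  Dg <- vapply(tt, function(t) effectiveCoefficients(p, prof, 0, t)$D_eff,
               numeric(1))
  expect_true(all(diff(Dg) > 0))
  # growth with synchronous division: D_eff(t) locks onto the period
  geom <- cellFileGeometry(2, 10, 0.5, 5, 0.1)
  pd <- nondimensionalize(gaPhysiology(), geom, plasmodesmata = FALSE)
  sched <- divisionSchedule(10, pd$lambda)
  dprof <- divisionProfile(sched, 0.1)
  # approach to periodicity is geometric (the closed-form length settles
  # like 2^-n): successive period-to-period deviations must shrink and
  # eventually become negligible
  dev_at <- function(t0) {
    tg <- seq(t0, t0 + 10, 0.25)
    Da <- vapply(tg, function(t)
      effectiveCoefficients(pd, dprof, 0, t)$D_eff, numeric(1))
    Db <- vapply(tg + 10, function(t)
      effectiveCoefficients(pd, dprof, 0, t)$D_eff, numeric(1))
    expect_true(all(is.finite(Da)) && all(Da > 0))
    max(abs(Da - Db)) / max(Da)
  }
  devs <- vapply(c(20, 40, 60, 80), dev_at, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[4], 1e-4)
})

test_that("a sealed static file conserves total hormone", {
  p <- ga_short_np
  n <- 80
  C0 <- exp(-10 * seq(0, 1, length.out = n + 1)^2)  # smooth initial load
  sol <- solveContinuum(p, staticUniformProfile(0.1),
                        t_eval = c(0, 50, 500, 5000), upstream = "sealed",
                        n_grid = n, C0 = C0)
  # V is uniform for identical cells: the integral of C must be conserved
  mass <- apply(sol$C, 1, function(r) sum((r[-1] + r[-(n + 1)]) / 2) / n)
  expect_lt(max(abs(mass - mass[1])), 1e-6)
  # and the profile flattens to its mean
  expect_equal(unname(sol$C[4, ]), rep(mass[1], n + 1), tolerance = 1e-3)
})

test_that("discrete and continuum division runs agree once the file is fine", {
  geom <- cellFileGeometry(2, 10, 0.5, 5, 0.1)
  p <- nondimensionalize(gaPhysiology(), geom, plasmodesmata = FALSE)
  Td <- 10 * 3600 / p$time_scale_s    # ten-hour inter-division time
  sched <- divisionSchedule(Td, p$lambda)
  prof <- divisionProfile(sched, 0.1)
  t_cmp <- 5.5 * Td
  dv <- simulateWithDivision(p, sched, n_events = 6, t_eval = t_cmp)
  sol <- solveContinuum(p, prof, t_eval = t_cmp)
  s <- Filter(function(z) isTRUE(all.equal(z$t, t_cmp)), dv$snapshots)[[1]]
  x <- cellCenters(c(s$lengths, s$lengths[1]), p$lambda, s$N)
  xi <- x[seq_len(s$N)] / x[s$N + 1]
  Ci <- approx(sol$xi, sol$C[1, ], xout = xi)$y
  # agreement is limited by cell granularity next to the clamped boundary
  # cell and the O(lambda) domain closure (lambda = 0.1 here)
  expect_lt(max(abs(s$c - Ci)), 0.08)
})
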