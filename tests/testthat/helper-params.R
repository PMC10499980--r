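# Shared fixtures: gibberellin presets with closed plasmodesmata (the
# baseline regime for most comparisons) and the dimensionless tolerance
# used against printed two-significant-figure values.
ga_short_np <- gaParams("short", plasmodesmata = FALSE)
ga_long_np <- gaParams("long", plasmodesmata = FALSE)
ga_short_pl <- gaParams("short", plasmodesmata = TRUE)
ga_long_pl <- gaParams("long", plasmodesmata = TRUE)

tol2sf <- 0.03  # printed values are rounded to 2 significant figures

expect_rel <- function(object, expected, tol = tol2sf) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

# random dimensionless parameter set with the structural fields used by
# the coefficient formulas (not tied to any physiology)
randomParams <- function() {
  list(eps = 0.05,
       lambda = runif(1, 0.001, 0.2),
       omega = runif(1, 0.05, 2),
       phi = runif(1, 0.05, 0.9),
       P_ca = runif(1, 1e-4, 0.05),
       P_ac = 1, P_cv = 1, P_vc = 1,
       P_plas = sample(c(0, runif(1, 0, 2)), 1),
       Pa = runif(1, 0.005, 1.5),
       Pv = runif(1, 0.05, 4))
}
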