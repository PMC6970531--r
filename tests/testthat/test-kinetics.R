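random_scheme <- function() {
  ## random valid 4-state landscape: wells in [-6, 2], barriers above wells
  G <- runif(4, -6, 2)
  B <- pmax(G[1:3], G[2:4]) + runif(3, 0, 4)
  Bf <- G[4] + runif(1, 0, 6)
  rates_from_landscape(energy_landscape(G, B, Bf),
                       prefactor = 1, rnap_activity = runif(1, 0.5, 2))
}

test_that("landscape validation rejects barriers below flanking wells", {
  expect_error(energy_landscape(c(0, -1), c(-2), 0), "below a flanking well")
  expect_error(energy_landscape(c(0, -1, -2, -3), c(1, 1), 0), "length 3")
  expect_error(energy_landscape(c(0, -1), c(1), -2), "final barrier")
  land <- energy_landscape(c(0, -1), c(0), 0)   # barrier exactly at a well: ok
  expect_s3_class(land, "energy_landscape")
})

test_that("rates follow the Arrhenius mapping and detailed balance", {
  ## zero effective barrier: rate equals the prefactor
  flat <- energy_landscape(c(0, 0), c(0), 0)
  sch <- rates_from_landscape(flat, prefactor = 3)
  expect_equal(sch$k_fwd, 3)
  expect_equal(sch$k_rev, 3)
  expect_equal(sch$k_cat, 3)

  ## barrier 1 kBT above the well: rate = prefactor * e^-1
  one <- rates_from_landscape(energy_landscape(c(0, 0), c(1), 1))
  expect_equal(one$k_fwd, exp(-1))

  set.seed(31)
  for (i in 1:50) {
    G <- runif(4, -5, 1)
    B <- pmax(G[1:3], G[2:4]) + runif(3, 0, 3)
    land <- energy_landscape(G, B, G[4] + 1)
    sch <- rates_from_landscape(land, prefactor = runif(1, 0.1, 10))
    expect_equal(sch$k_fwd / sch$k_rev, exp(G[1:3] - G[2:4]),
                 tolerance = 1e-12)
  }

  ## rnap activity scales the first forward rate and K_B only
  land <- preset_landscapes()$inhibited_hypothetical
  s1 <- rates_from_landscape(land, rnap_activity = 1)
  s2 <- rates_from_landscape(land, rnap_activity = 2.5)
  expect_equal(s2$k_fwd[1] / s1$k_fwd[1], 2.5)
  expect_equal(s2$k_fwd[-1], s1$k_fwd[-1])
  expect_equal(s2$K_B / s1$K_B, 2.5)
})

test_that("steady state reaches the limiting cases", {
  ## two-state P <-> RPo -> output with fast, tight binding: flux -> k_cat
  land2 <- energy_landscape(c(0, -8), c(0.5), -1,
                            state_names = c("R+P", "RPo"))
  fr <- steady_state_flux(rates_from_landscape(land2))
  expect_equal(fr$occupancies[["RPo"]], 1, tolerance = 5e-3)
  expect_equal(fr$flux_J, exp(-(-1 - -8)), tolerance = 1e-2)

  ## k_cat -> 0 recovers Boltzmann occupancies of the landscape
  G <- c(0, -0.5, -1.0, -2.0)
  land <- energy_landscape(G, c(2, 1.5, 2.5), final_barrier_G = 40)
  fr0 <- steady_state_flux(rates_from_landscape(land))
  boltz <- exp(-G) / sum(exp(-G))
  expect_equal(unname(fr0$occupancies), boltz, tolerance = 1e-8)
})

test_that("occupancies are a probability vector for random schemes", {
  set.seed(32)
  for (i in 1:100) {
    fr <- steady_state_flux(random_scheme())
    expect_true(all(fr$occupancies >= 0))
    expect_equal(sum(fr$occupancies), 1, tolerance = 1e-10)
    expect_gte(fr$flux_J, 0)
  }
})

test_that("linear solve agrees with master-equation integration", {
  set.seed(33)
  for (i in 1:50) {
    sch <- random_scheme()
    a <- steady_state_flux(sch)
    b <- ode_steady_state(sch)
    expect_equal(b$flux_J, a$flux_J, tolerance = 1e-8)
    expect_equal(unname(b$occupancies), unname(a$occupancies),
                 tolerance = 1e-8)
  }
})

test_that("the steady state is unique: independent of the initial condition", {
  set.seed(34)
  sch <- random_scheme()
  from_free <- ode_steady_state(sch, init = c(1, 0, 0, 0))
  from_open <- ode_steady_state(sch, init = c(0, 0, 0, 1))
  expect_equal(unname(from_free$occupancies), unname(from_open$occupancies),
               tolerance = 1e-9)
  expect_error(ode_steady_state(sch, init = c(1, 1, 0, 0)), "sum to 1")
})

test_that("perturbations act locally and leave equilibria of barriers fixed", {
  land <- preset_landscapes()$inhibited_hypothetical

  same <- apply_perturbation(land)
  expect_equal(same$state_G, land$state_G)
  expect_equal(same$barrier_G, land$barrier_G)

  ## lowering barrier i multiplies both rates by e^delta, ratio unchanged
  delta <- -0.8
  pert <- apply_perturbation(land, delta_barrier = c("2" = delta))
  s0 <- rates_from_landscape(land); s1 <- rates_from_landscape(pert)
  expect_equal(s1$k_fwd[2] / s0$k_fwd[2], exp(-delta), tolerance = 1e-12)
  expect_equal(s1$k_rev[2] / s0$k_rev[2], exp(-delta), tolerance = 1e-12)
  expect_equal(s1$k_fwd[2] / s1$k_rev[2], s0$k_fwd[2] / s0$k_rev[2],
               tolerance = 1e-12)
  expect_equal(s1$k_fwd[c(1, 3)], s0$k_fwd[c(1, 3)])

  ## lowering state RP2 leaves the non-adjacent first equilibrium unchanged
  pst <- apply_perturbation(land, delta_state = c("3" = -1))
  sp <- rates_from_landscape(pst)
  expect_equal(sp$k_fwd[1] / sp$k_rev[1], s0$k_fwd[1] / s0$k_rev[1])

  ## driving a barrier below a well is refused, original untouched
  expect_error(apply_perturbation(land, delta_barrier = c("3" = -10)),
               "below a flanking well")
  expect_equal(land$barrier_G, preset_landscapes()$inhibited_hypothetical$barrier_G)
})

test_that("monotonicity: lowering the output barrier raises flux; off-bottleneck barriers barely matter", {
  land <- preset_landscapes()$activated_hypothetical
  base <- steady_state_flux(rates_from_landscape(land))$flux_J
  faster_out <- apply_perturbation(land, delta_final = -1)
  expect_gt(steady_state_flux(rates_from_landscape(faster_out))$flux_J, base)

  ## the R+P <-> RP1 barrier is far from rate-limiting here
  pert <- apply_perturbation(land, delta_barrier = c("1" = -1))
  with_pert <- steady_state_flux(rates_from_landscape(pert))$flux_J
  expect_lt(abs(with_pert / base - 1), 0.01)
})

test_that("scenarios reproduce differential regulation from a shared perturbation", {
  presets <- preset_landscapes()

  tr_inh <- traR_scenario(presets$inhibited_hypothetical)
  tr_act <- traR_scenario(presets$activated_hypothetical)
  expect_lt(tr_inh$fold_change, 1)
  expect_gt(tr_act$fold_change, 1)
  expect_equal(tr_inh$regulation, "inhibition")
  expect_equal(tr_act$regulation, "activation")

  s_inh <- sigma11_deletion_scenario(presets$inhibited_hypothetical)
  s_act <- sigma11_deletion_scenario(presets$activated_hypothetical)
  expect_equal(s_inh$fold_change, 1, tolerance = 0.01)
  expect_gt(s_act$fold_change, 10)

  ## null perturbations give fold change exactly 1
  null_tr <- traR_scenario(presets$inhibited_hypothetical, 0, 0, 0)
  expect_equal(null_tr$fold_change, 1, tolerance = 1e-12)
  null_s <- sigma11_deletion_scenario(presets$activated_hypothetical, 0)
  expect_equal(null_s$fold_change, 1, tolerance = 1e-12)

  ## TraR gating: forcing dissociation before output can only reduce flux
  gated <- traR_scenario(presets$activated_hypothetical, f_dissoc = 0.25)
  expect_lt(gated$perturbed$flux_J, tr_act$perturbed$flux_J)
})

test_that("scenarios never modify the initial binding step", {
  for (land in preset_landscapes()) {
    s0 <- rates_from_landscape(land)
    ## rebuild the perturbed landscapes the scenarios apply and check the
    ## R+P <-> RP1 rates are untouched
    tr_pert <- apply_perturbation(land,
                                  delta_barrier = c("2" = -1.5, "3" = -2.5),
                                  delta_state = c("3" = -1))
    s11_pert <- apply_perturbation(land, delta_barrier = c("3" = -3.5))
    for (pert in list(tr_pert, s11_pert)) {
      sp <- rates_from_landscape(pert)
      expect_equal(sp$k_fwd[1], s0$k_fwd[1])
      expect_equal(sp$k_rev[1], s0$k_rev[1])
      expect_equal(sp$K_B, s0$K_B)
    }
  }
})

test_that("landscape configs round trip and resolve presets", {
  land <- preset_landscapes()$activated_hypothetical
  path <- withr::local_tempfile(fileext = ".cfg")
  write_landscape_config(land, path)
  back <- read_landscape_config(path)
  expect_equal(back$state_G, land$state_G)
  expect_equal(back$barrier_G, land$barrier_G)
  expect_equal(back$final_barrier_G, land$final_barrier_G)
  expect_equal(back$state_names, land$state_names)

  via_preset <- read_landscape_config("presets:inhibited_hypothetical")
  expect_equal(via_preset$state_G, c(0, -0.5, -1, -2))
  expect_error(read_landscape_config("presets:nope"), "unknown preset")
})
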