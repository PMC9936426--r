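# normalized input, sigmoid, switch, integrator, steady states

test_that("compute_omega covers all four input cases of the model", {
  net <- interactome(edges = toy_edges("A", "T", "activates",
                                       "I", "T", "inhibits",
                                       "A", "U", "activates",
                                       "I", "V", "inhibits"))
  st <- c(A = 1, I = 0, T = 0, U = 0, V = 0)
  # single full activator saturates omega
  expect_equal(compute_omega(net, "U", st)$omega, 1)
  expect_equal(compute_omega(net, "U", st)$case, "activators_only")
  # single full inhibitor zeroes omega
  st2 <- c(A = 0, I = 1, T = 0, U = 0, V = 0)
  expect_equal(compute_omega(net, "V", st2)$omega, 0)
  expect_equal(compute_omega(net, "V", st2)$case, "inhibitors_only")
  # half activator: omega = 2 * 0.5 / 1.5 = 2/3
  st3 <- c(A = 0.5, I = 0, T = 0, U = 0, V = 0)
  expect_equal(compute_omega(net, "U", st3)$omega, 2 / 3)
  # saturated activator and inhibitor: inhibition dominates
  st4 <- c(A = 1, I = 1, T = 0, U = 0, V = 0)
  expect_equal(compute_omega(net, "T", st4)$omega, 0)
  expect_equal(compute_omega(net, "T", st4)$case, "mixed")
  # no inputs: omega defined as 0 (pure decay)
  expect_equal(compute_omega(net, "A", st)$omega, 0)
  expect_equal(compute_omega(net, "A", st)$case, "no_inputs")
})

test_that("sigmoid anchors hold to machine precision for h in {1,10,100}", {
  for (h in c(1, 10, 100)) {
    expect_equal(sigmoid_response(0, h), 0, tolerance = 1e-14)
    expect_equal(sigmoid_response(0.5, h), 0.5, tolerance = 1e-14)
    expect_equal(sigmoid_response(1, h), 1, tolerance = 1e-14)
  }
  # independent closed-form evaluation at omega = 2/3, h = 10
  expect_equal(sigmoid_response(2 / 3, 10), 0.8457591237, tolerance = 1e-9)
  # strictly increasing
  w <- seq(0, 1, by = 0.01)
  expect_true(all(diff(sigmoid_response(w, 10)) > 0))
  expect_error(sigmoid_response(1.2), class = "cnet_domain_error")
  expect_error(sigmoid_response(-0.1), class = "cnet_domain_error")
  expect_error(sigmoid_response(0.5, h = -1), class = "cnet_domain_error")
})

test_that("time_derivative matches hand-evaluated rates", {
  net <- interactome(nodes = "X")
  # isolated unclamped node: pure decay
  expect_equal(unname(time_derivative(c(X = 0.7), net)["X"]), -0.7)
  chain <- toy_chain()
  cfg <- integration_config(clamp = c(SRC = 1))
  # fixed point: S(1) - 1 = 0
  d <- time_derivative(c(SRC = 1, SNK = 1), chain, cfg)
  expect_equal(unname(d["SNK"]), 0, tolerance = 1e-12)
  expect_equal(unname(d["SRC"]), 0)
  # composition of the omega and sigmoid oracles
  d2 <- time_derivative(c(SRC = 0.5, SNK = 0), chain, cfg)
  expect_equal(unname(d2["SNK"]), 0.8457591237, tolerance = 1e-9)
})

test_that("the RGD switch rewrites and restores the topology exactly", {
  net <- make_motif("rgd_switch_motif")
  base_sig <- edge_signature(net)
  low <- effective_topology(net, c(RGD = 0.4, FN = 1, integrinA = 0,
                                   integrinB = 0, actin = 0))
  expect_false(any(low$switched))
  expect_identical(sort(sprintf("%s|%s|%s|%.12g", low$edges$source,
                                low$edges$target, low$edges$sign,
                                low$edges$weight)), base_sig)

  hi <- effective_topology(net, c(RGD = 0.6, FN = 1, integrinA = 0,
                                  integrinB = 0, actin = 0))
  expect_true(all(hi$switched))
  e <- hi$edges
  expect_setequal(e$sign[e$target == "actin"], "inhibits")
  expect_false(any(e$source == "FN"))
  expect_setequal(e$target[e$source == "RGD"], c("integrinA", "integrinB"))

  # exactly at threshold: unswitched branch (strictly-above policy)
  at <- effective_topology(net, c(RGD = 0.5, FN = 1, integrinA = 0,
                                  integrinB = 0, actin = 0))
  expect_false(any(at$switched))

  # toggling across the threshold restores the base edge set exactly
  again <- effective_topology(net, c(RGD = 0.4, FN = 1, integrinA = 0,
                                     integrinB = 0, actin = 0))
  expect_identical(sort(sprintf("%s|%s|%s|%.12g", again$edges$source,
                                again$edges$target, again$edges$sign,
                                again$edges$weight)), base_sig)
})

test_that("simulate_network integrates the chain to its fixed point", {
  chain <- toy_chain()
  traj <- simulate_network(chain, fast_config(clamp = c(SRC = 1)))
  expect_true(traj$converged)
  snk <- traj$states[, "SNK"]
  expect_true(all(diff(snk) >= -1e-12))  # monotone rise
  expect_equal(unname(traj$steady_state["SNK"]), 1, tolerance = 1e-6)

  # all-zero initial state of a pure-activation network stays at zero
  act_net <- make_random_network(10, 20, inhibitor_fraction = 0, seed = 3)
  traj0 <- simulate_network(act_net, fast_config())
  expect_true(traj0$converged)
  expect_true(all(traj0$steady_state == 0))

  # half-clamped source: fixed point S(2/3)
  st <- find_steady_state(chain, clamps = c(SRC = 0.5), fast_config())
  expect_equal(unname(st$values["SNK"]), 0.8457591237, tolerance = 1e-6)
})

test_that("clamped nodes are bit-identical at every recorded time point", {
  net <- load_reduced_network()
  cfg <- integration_config(t_max = 5, clamp = c(TRPV4 = 1, a5b1 = 0.3))
  traj <- simulate_network(net, cfg)
  expect_true(all(traj$states[, "TRPV4"] == 1))
  expect_true(all(traj$states[, "a5b1"] == 0.3))
})

test_that("trajectories stay inside [0,1] and respect invalid inputs", {
  net <- make_random_network(15, 45, 0.5, seed = 21)
  traj <- simulate_network(net, fast_config(),
                           initial = stats::setNames(
                             rep(c(0.2, 0.9), length.out = 15),
                             net$nodes$id))
  expect_true(all(traj$states >= 0 & traj$states <= 1))
  expect_error(
    simulate_network(net, initial = stats::setNames(rep(2, 15), net$nodes$id)),
    class = "cnet_validation_error")
  expect_error(integration_config(clamp = c(A = 1.5)),
               class = "cnet_validation_error")
})

test_that("RK4 agrees with explicit Euler at dt/100 on fixture motifs", {
  for (motif in c("single_chain", "inhibitor_only", "double_activator")) {
    net <- make_motif(motif)
    clamps <- switch(motif,
                     single_chain = c(SRC = 0.5),
                     inhibitor_only = c(I = 0.25),
                     double_activator = c(A = 1, B = 0))
    rk <- find_steady_state(net, clamps, integration_config(t_max = 30))
    eu <- find_steady_state(net, clamps,
                            integration_config(dt = 0.0001, t_max = 30,
                                               method = "euler"))
    expect_true(rk$converged && eu$converged)
    expect_equal(rk$values, eu$values, tolerance = 1e-5)
  }
})

test_that("steady states match the damped fixed-point oracle", {
  chain <- toy_chain()
  fp1 <- fixed_point_oracle(chain, clamps = c(SRC = 1))
  expect_true(fp1$converged)
  expect_equal(unname(fp1$state["SNK"]), 1, tolerance = 1e-8)
  fp <- fixed_point_oracle(chain, clamps = c(SRC = 0.5))
  expect_equal(unname(fp$state["SNK"]), 0.8457591237, tolerance = 1e-8)

  # inhibitor-only node with its inhibitor held low rests fully ON
  inh <- make_motif("inhibitor_only")
  st <- find_steady_state(inh, clamps = c(I = 0), fast_config())
  expect_equal(unname(st$values["T"]), 1, tolerance = 1e-6)

  # toggle motif: clamping one side high shuts the other down
  tog <- make_motif("toggle")
  st_a <- find_steady_state(tog, clamps = c(A = 1), fast_config())
  expect_equal(unname(st_a$values["B"]), 0, tolerance = 1e-6)
  fp_a <- fixed_point_oracle(tog, clamps = c(A = 1))
  expect_equal(st_a$values, fp_a$state, tolerance = 1e-6)

  # RGD switch motif: actin fixed point strictly lower under RGD = 1
  rgd <- make_motif("rgd_switch_motif")
  lo <- fixed_point_oracle(rgd, clamps = c(FN = 1, RGD = 0))
  hi <- fixed_point_oracle(rgd, clamps = c(FN = 1, RGD = 1))
  expect_true(lo$state["actin"] > hi$state["actin"])
  expect_equal(unname(lo$state["actin"]), 1, tolerance = 1e-6)
  expect_equal(unname(hi$state["actin"]), 0, tolerance = 1e-6)
})

test_that("sustained oscillations fall back to a window average", {
  net <- interactome(edges = toy_edges("A", "B", "inhibits",
                                       "B", "C", "inhibits",
                                       "C", "A", "inhibits"),
                     name = "repressilator")
  st <- find_steady_state(net, config = integration_config(t_max = 50),
                          initial = c(A = 0.9, B = 0.1, C = 0.5))
  expect_false(st$converged)
  expect_true(st$oscillating)
  expect_true(all(st$values >= 0 & st$values <= 1))
})

test_that("omega is monotone in activators and antitone in inhibitors", {
  net <- interactome(edges = toy_edges("A", "T", "activates",
                                       "B", "T", "activates",
                                       "I", "T", "inhibits"))
  st <- c(A = 0.3, B = 0.6, I = 0.4, T = 0)
  base <- compute_omega(net, "T", st)$omega
  up_act <- st; up_act["A"] <- 0.8
  expect_gte(compute_omega(net, "T", up_act)$omega, base)
  up_inh <- st; up_inh["I"] <- 0.9
  expect_lte(compute_omega(net, "T", up_inh)$omega, base)
})
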