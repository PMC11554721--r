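test_that("normalized Hill constraints hold exactly for both shipped parameter sets", {
  for (pars in list(c(EC50 = 0.55, n = 1.25), c(EC50 = 0.5, n = 1.4))) {
    EC50 <- pars[["EC50"]]; n <- pars[["n"]]
    for (W in c(1, 0.5, 2)) {
      expect_identical(hill_plus(0, W, n, EC50), 0)
      expect_equal(hill_plus(EC50, W, n, EC50), 0.5 * W, tolerance = 1e-14)
      expect_equal(hill_plus(1, W, n, EC50), W, tolerance = 1e-14)
    }
    expect_equal(hill_minus(EC50, 1, n, EC50), 0.5, tolerance = 1e-14)
  }
  # monotone increasing on [0, 1]
  y <- seq(0, 1, length.out = 101)
  expect_true(all(diff(hill_plus(y, 1, 1.4, 0.5)) > 0))
})

test_that("the Hill scaling constant matches its defining formula and rejects invalid pairs", {
  B_expected <- (0.5^1.4 - 1) / (2 * 0.5^1.4 - 1)
  expect_equal(hill_B(0.5, 1.4), B_expected, tolerance = 1e-14)
  expect_equal(B_expected, 2.5649, tolerance = 1e-4)
  expect_error(hill_B(0.8, 2), "EC50")
  expect_error(net_edge("x", EC50 = 0.8, n = 2), "EC50")
})

test_that("logic gates satisfy their algebraic identities", {
  expect_equal(gate_or(0, 0), 0)
  expect_equal(gate_and(1, 1), 1)
  expect_equal(gate_and(0, 0), 0)  # 0/0 guarded
  for (f in c(0.1, 0.5, 1)) expect_equal(gate_and(f, f), f)
  expect_equal(gate_and_not(1, 0), 1)  # inhibitor fully off
  expect_equal(gate_and_not(0.3, 1), 0)  # inhibitor fully on
  set.seed(21)
  a <- stats::runif(10); b <- stats::runif(10)
  expect_equal(gate_and(a, b), gate_and(b, a))
  expect_equal(gate_or(a, b), gate_or(b, a))
  # AND_NOT is not symmetric in its arguments
  expect_false(isTRUE(all.equal(gate_and_not(0.8, 0.2),
                                gate_and_not(0.2, 0.8))))
})

test_that("network rhs is zero at a fixed point and knockdown forces zero output", {
  net <- fixture_network("three_node")
  y <- steady_state(net)
  rhs <- network_rhs(net, y, c(stress = 0.5))
  expect_lt(max(abs(rhs)), 1e-12)
  # y_max = 0 knockdown
  net_kd <- net
  net_kd$nodes$y_max[net_kd$nodes$name == "collagen"] <- 0
  y_kd <- steady_state(net_kd)
  expect_equal(unname(y_kd[["collagen"]]), 0)
})

test_that("topological steady state agrees with ODE integration and is init-independent", {
  set.seed(22)
  for (preset in c("three_node", "five_node")) {
    net <- fixture_network(preset)
    y_prop <- steady_state(net, method = "propagate")
    y_ode <- steady_state(net, method = "ode")
    expect_equal(y_prop, y_ode, tolerance = 1e-8)
    # two random initializations agree (uniqueness on these fixtures)
    nm <- net$nodes$name
    y1 <- steady_state(net, method = "ode",
                       y_init = stats::setNames(stats::runif(length(nm)), nm))
    y2 <- steady_state(net, method = "ode",
                       y_init = stats::setNames(stats::runif(length(nm)), nm))
    expect_equal(y1, y2, tolerance = 1e-8)
  }
})

test_that("trajectories stay inside the activation box", {
  net <- fixture_network("five_node")
  nm <- net$nodes$name
  inputs <- c(stress = 0.9, NO = 0.1)
  sol <- deSolve::lsoda(
    y = stats::setNames(c(0.9, 0.1, 1, 1, 1), nm), times = seq(0, 20, 0.1),
    func = function(t, y, p) {
      y[names(inputs)] <- inputs
      list(network_rhs(net, y, inputs))
    }, rtol = 1e-8, atol = 1e-10)
  ymax <- net$nodes$y_max
  expect_true(all(sol[, -1] >= -1e-8))
  expect_true(all(t(sol[, -1]) <= pmax(1, ymax) + 1e-8))
})

test_that("steady state equals the fixed point found by an independent root finder", {
  net <- fixture_network("five_node")
  y_star <- steady_state(net)
  free <- net$nodes$name[net$nodes$role != "input"]
  # residual of f_i ymax - y_i at the reported steady state, per node
  for (n in free) {
    i <- match(n, net$nodes$name)
    f <- vesselgr:::eval_tree(net$influences[[n]], y_star)
    expect_equal(unname(y_star[[n]]), f * net$nodes$y_max[i],
                 tolerance = 1e-10)
  }
})

test_that("input scaling passes through the baseline and saturates correctly", {
  expect_equal(scale_input(100, 100, 0.5, 0.2), 0.2, tolerance = 1e-14)
  expect_equal(scale_input(1e9, 100, 0.5, 0.2), 1, tolerance = 1e-6)
  expect_equal(scale_input(-1e9, 100, 0.5, 0.2), 0, tolerance = 1e-6)
  # y_i0 = 0.5 centers the sigmoid: beta = 0
  expect_equal(scale_input(100, 100, 2, 0.5), 0.5)
  q <- seq(50, 150, 5)
  expect_true(all(diff(scale_input(q, 100, 0.5, 0.2)) > 0))
})

test_that("normalized output deviation behaves as a relative change", {
  expect_equal(delta_psi(0.4, 0.4), 0)
  expect_equal(delta_psi(0.8, 0.4), 1)
  expect_error(delta_psi(0.5, 0), "baseline")
  # fibrillar collagen is the average of the two collagen outputs
  net <- baseline_init(fixture_network("intramural_standin"))
  y0c <- mean(net$y0[c("colI", "colIII")])
  y <- steady_state(net, fixed_inputs = c(
    stress = 0.3, NO = 0.5, ET1 = 0.5, AngII = 0, integrins = 0.2,
    SACs = 0.2))
  expect_equal(delta_psi(mean(y[c("colI", "colIII")]), y0c),
               (mean(y[c("colI", "colIII")]) - y0c) / y0c)
  expect_gt(delta_psi(mean(y[c("colI", "colIII")]), y0c), 0)
})

test_that("baseline initialization yields zero deviations and finite outputs for all fixtures", {
  for (preset in c("three_node", "five_node", "ec_standin",
                   "intramural_standin")) {
    net <- baseline_init(fixture_network(preset))
    outs <- net$nodes$name[net$nodes$role == "output"]
    expect_true(all(net$y0[outs] > 0))
    expect_true(all(is.finite(net$y0)))
    expect_equal(unname(delta_psi(net$y0[outs], net$y0[outs])),
                 rep(0, length(outs)))
  }
})

test_that("the stand-in networks carry the documented input/output signatures", {
  ec <- fixture_network("ec_standin")
  expect_setequal(ec$nodes$name[ec$nodes$role == "input"], "wss")
  expect_setequal(ec$nodes$name[ec$nodes$role == "output"], c("NO", "ET1"))
  im <- fixture_network("intramural_standin")
  expect_setequal(im$nodes$name[im$nodes$role == "input"],
                  c("stress", "NO", "ET1", "AngII", "integrins", "SACs"))
  expect_setequal(im$nodes$name[im$nodes$role == "output"],
                  c("colI", "colIII", "proliferation", "actomyosin"))
  # directional responses: NO production rises with WSS, ET1 falls
  ec <- baseline_init(ec)
  y_hi <- steady_state(ec, fixed_inputs = c(wss = 0.7))
  expect_gt(y_hi[["NO"]], ec$y0[["NO"]])
  expect_lt(y_hi[["ET1"]], ec$y0[["ET1"]])
})

test_that("malformed networks are rejected at construction", {
  nodes <- data.frame(name = c("a", "b"), tau = 1, y_max = 1,
                      role = c("input", "output"), baseline = c(0.5, NA))
  expect_error(signaling_network(nodes, list(c = net_edge("a"))),
               "undeclared")
  expect_error(signaling_network(nodes, list(b = net_edge("zzz"))),
               "undeclared")
  expect_error(signaling_network(nodes, list(a = net_edge("b"))),
               "input")
  nodes_nb <- nodes; nodes_nb$baseline <- NA_real_
  expect_error(signaling_network(nodes_nb, list(b = net_edge("a"))),
               "baseline")
})
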