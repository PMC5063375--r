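test_that("power-law rates follow the mass-action product with 0^0 = 1", {
  G <- matrix(c(1, 0), nrow = 1)
  expect_equal(unname(evaluate_rates(c(3, 5), 2, G)), 6)

  G0 <- matrix(0, nrow = 1, ncol = 3)
  expect_equal(unname(evaluate_rates(c(0, 2, 7), 4.2, G0)), 4.2)

  toy <- toy_network()
  v <- evaluate_rates(c(1, 0.25), toy$alpha_basal, toy$G)
  expect_equal(unname(v[2]), 1)          # v2 = 1 * x1^0.5 at x1 = 1

  # fractional order at zero concentration gives a zero rate, not NaN
  expect_equal(unname(evaluate_rates(c(0, 1), 1, matrix(c(0.5, 0), 1))), 0)
  expect_error(evaluate_rates(c(-1, 1), 1, G), "negative concentration")
  expect_error(evaluate_rates(c(1, 1), -1, G), "negative rate constant")
})

test_that("steady-state residual is zero at consistent basal states and tracks imbalances", {
  toy <- toy_network()
  expect_true(toy$consistent)
  expect_equal(max(abs(steady_state_residual(toy, toy$x_basal))), 0,
               tolerance = 1e-12)

  # doubling x1: species 1 balance becomes a1 - a2*sqrt(2), species 2
  # gains the extra transfer flux
  r <- steady_state_residual(toy, c(2, 0.25))
  expect_equal(unname(r[1]), 1 - sqrt(2), tolerance = 1e-12)
  expect_equal(unname(r[2]), sqrt(2) - 1, tolerance = 1e-12)

  for (seed in 1:4) {
    net <- generate_random_gma(7, n_controls = 2, seed = seed)
    res <- steady_state_residual(net, net$x_basal)
    expect_lt(max(abs(res)), 1e-10)
  }
})

test_that("log-space and linear-space formulations agree on random states", {
  for (seed in 1:5) {
    net <- generate_random_gma(6 + seed %% 3, n_controls = 1, seed = seed)
    set.seed(seed + 100)
    y <- stats::rnorm(length(net$species_names), sd = 0.7)
    a_hat <- log(net$alpha_basal) + stats::rnorm(length(net$alpha_basal), sd = 0.3)
    lt <- log_transform_constraints(net, y, a_hat)
    v_lin <- evaluate_rates(exp(y), exp(a_hat), net$G)
    expect_equal(unname(lt$v), unname(v_lin), tolerance = 1e-12)
    r_lin <- steady_state_residual(net, exp(y), exp(a_hat))
    scale <- max(1, abs(r_lin))
    expect_lt(max(abs(lt$residual - r_lin) / scale), 1e-10)
  }
  # exp(0) = 1 everywhere
  net <- toy_network()
  lt0 <- log_transform_constraints(net, c(0, 0), c(0, 0, 0))
  expect_equal(unname(lt0$v), c(1, 1, 1))
  expect_equal(unname(lt0$x), c(1, 1))
})

test_that("Newton and ODE-integration paths converge to the toy closed form", {
  toy <- toy_network()
  st <- solve_steady_state(toy, options = list(x0 = c(3, 0.01)))
  expect_true(st$converged)
  expect_equal(unname(st$x), c(1, 0.25), tolerance = 1e-8)

  st_ode <- solve_steady_state(toy, options = list(x0 = c(3, 0.01),
                                                   max_iter = 0,
                                                   method = "auto"))
  expect_equal(unname(st_ode$x), c(1, 0.25), tolerance = 1e-6)

  # non-convergence is an explicit flag, never silent
  st_bad <- solve_steady_state(toy, options = list(max_iter = 0,
                                                   method = "newton",
                                                   x0 = c(5, 5)))
  expect_false(st_bad$converged)
})

test_that("deficiency perturbations scale the rate constant as (1 - delta/100)", {
  toy <- toy_network()
  p50 <- apply_deficiency(toy, "r_in", 50)
  expect_equal(unname(p50$disease), 0.5)
  p100 <- apply_deficiency(toy, "r_in", 100)
  expect_equal(unname(p100$disease), 0)
  expect_error(apply_deficiency(toy, "nope", 50), "unknown reaction")
  expect_error(apply_deficiency(toy, "r_in", 120), "delta_percent")

  # closed form under the halved influx
  st <- solve_steady_state(toy, p50)
  expect_equal(unname(st$x), c(0.25, 0.0625), tolerance = 1e-8)

  # diseased reactions cannot be re-regulated on top
  expect_error(combine_perturbations(p50, perturbation(activity_fold = c(r_in = 2))),
               "cannot be regulated")
})

test_that("fold changes are ratios to the reference state", {
  toy <- toy_network()
  hs <- solve_steady_state(toy)
  fc_id <- fold_changes(hs, hs)
  expect_true(all(fc_id$species$fold == 1))
  expect_true(all(fc_id$flux$fold == 1))

  st <- solve_steady_state(toy, apply_deficiency(toy, "r_in", 50))
  fc <- fold_changes(st, hs)
  expect_equal(fc$species$fold, c(0.25, 0.25), tolerance = 1e-8)

  # zero reference reported as undefined, not infinity
  ref0 <- hs; ref0$x[1] <- 0
  fc0 <- fold_changes(st, ref0)
  expect_true(is.na(fc0$species$fold[1]))
  expect_equal(fc0$species$status[1], "undefined")
})

test_that("downstream concentration falls monotonically with deficiency severity", {
  toy <- toy_network()
  deltas <- seq(0, 100, by = 10)
  x2 <- vapply(deltas, function(d) {
    solve_steady_state(toy, apply_deficiency(toy, "r_in", d))$x[[2]]
  }, numeric(1))
  expect_true(all(diff(x2) <= 1e-12))
  expect_lt(x2[length(x2)], 1e-6)   # complete knockout collapses the pool
})

test_that("flux balance holds per species at converged steady states", {
  for (seed in c(2, 9)) {
    net <- generate_random_gma(7, n_controls = 1, seed = seed)
    st <- solve_steady_state(net, perturbation(activity_fold = c(a2 = 0.5)))
    expect_true(st$converged)
    influx <- pmax(net$N, 0) %*% st$v + pmax(net$B, 0) %*% st$u
    efflux <- -pmin(net$N, 0) %*% st$v - pmin(net$B, 0) %*% st$u
    expect_equal(as.numeric(influx), as.numeric(efflux), tolerance = 1e-7)
  }
})
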