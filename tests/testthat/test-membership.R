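test_that("fuzzy-equal membership has the plateau, bounds and printed-table behaviour", {
  sp <- fold_spec("equal")
  expect_equal(fuzzy_equal_grade(1, sp), 1)
  expect_equal(fuzzy_equal_grade(0.1, sp), 0)
  expect_equal(fuzzy_equal_grade(0.05, sp), 0)
  expect_equal(fuzzy_equal_grade(10, sp), 0)
  expect_equal(fuzzy_equal_grade(15, sp), 0)
  # grades printed for extracellular dopamine under disease and treatment
  expect_equal(fuzzy_equal_grade(0.486, sp), 0.43, tolerance = 0.01)
  expect_equal(fuzzy_equal_grade(0.806, sp), 0.784, tolerance = 0.01)
  expect_error(membership_spec("equal", x_LB = 2, x_basal_LB = 1,
                               x_basal_UB = 1, x_UB = 10), "breakpoints")
})

test_that("fuzzy-minimize membership is 1 below basal and linear to the bound", {
  sp <- fold_spec("minimize")
  expect_equal(fuzzy_min_grade(0.241, sp), 1)
  expect_equal(fuzzy_min_grade(1, sp), 1)
  expect_equal(fuzzy_min_grade(10, sp), 0)
  expect_equal(fuzzy_min_grade(12, sp), 0)
  expect_equal(fuzzy_min_grade(1.512, sp), 0.943, tolerance = 0.01)
  expect_equal(fuzzy_min_grade(6.953, sp), 0.339, tolerance = 0.01)
})

test_that("recomputed grades reproduce the printed treatment table", {
  tab <- vm50_fold_grade_table()
  tab$recomputed <- vapply(seq_len(nrow(tab)), function(i) {
    membership_grade(tab$fold[i], fold_spec(tab$kind[i]))
  }, numeric(1))
  ok <- abs(tab$recomputed - tab$grade) <= 0.01
  # every non-anomalous cell agrees; the two flagged cells do not fit any
  # monotone rule consistent with the rest of their own columns
  expect_true(all(ok[!tab$anomaly]))
  expect_false(any(ok[tab$anomaly]))
})

test_that("all branch shapes are monotone bijections with shared endpoints", {
  vals <- seq(0.11, 0.99, length.out = 30)
  for (shape in c("linear", "exponential", "hyperbolic", "inverse")) {
    sp <- membership_spec("equal", x_LB = 0.1, x_basal_LB = 1,
                          x_basal_UB = 1, x_UB = 10, shape = shape)
    g <- fuzzy_equal_grade(vals, sp)
    expect_true(all(diff(g) > 0), info = shape)
    expect_true(all(g >= 0 & g <= 1), info = shape)
    expect_equal(fuzzy_equal_grade(1, sp), 1, info = shape)
    expect_equal(fuzzy_equal_grade(0.1, sp), 0, info = shape)
  }
  knots <- cbind(c(0.3, 0.7), c(0.1, 0.9))
  sp <- membership_spec("minimize", x_basal_UB = 1, x_UB = 10,
                        shape = "piecewise-linear", shape_param = knots)
  g <- fuzzy_min_grade(seq(1.1, 9.9, length.out = 25), sp)
  expect_true(all(diff(g) < 0))
})

test_that("grades stay in [0,1] and respect monotonicity on random inputs", {
  set.seed(42)
  for (rep in 1:20) {
    b <- sort(stats::runif(4, 0, 10))
    sp_eq <- membership_spec("equal", b[1], b[2], b[3], b[4])
    v <- sort(stats::runif(50, -1, 12))
    g <- fuzzy_equal_grade(v, sp_eq)
    expect_true(all(g >= 0 & g <= 1))
    # unimodal: non-decreasing then non-increasing
    peak <- which.max(g)
    expect_true(all(diff(g[seq_len(peak)]) >= -1e-12))
    expect_true(all(diff(g[peak:length(g)]) <= 1e-12))
    sp_min <- membership_spec("minimize", x_basal_UB = b[2], x_UB = b[4] + 1)
    gm <- fuzzy_min_grade(v, sp_min)
    expect_true(all(diff(gm) <= 1e-12))
  }
})

test_that("target-count factor is the normalized count penalty", {
  expect_equal(target_count_factor(1, 10), 1)
  expect_equal(target_count_factor(1, 3), 1)
  expect_equal(target_count_factor(6, 6), 0)
  expect_equal(target_count_factor(4, 6), 0.4)
  expect_equal(target_count_factor(0, 10), 1)  # healthy reference evaluation
  expect_error(target_count_factor(7, 6), "more targets")
})

test_that("design grading aggregates by minimum and applies the count factor", {
  net <- generate_random_gma(6, n_controls = 1, seed = 5)
  sets <- objective_sets(TE = net$meta$therapeutic, AE = "TOX", Z_UB = 10)
  specs <- build_default_memberships(net, sets)
  st <- solve_steady_state(net)
  rep0 <- grade_design(net, st, sets, specs, n_targets = 1)
  expect_equal(rep0$lambda, 1)
  expect_equal(rep0$overall, 1)

  st2 <- solve_steady_state(net, perturbation(activity_fold = c(a2 = 0.3)))
  rep1 <- grade_design(net, st2, sets, specs, n_targets = 1)
  expect_true(all(rep1$grades >= 0 & rep1$grades <= 1))
  expect_equal(rep1$lambda, min(rep1$grades))
  expect_lte(rep1$overall, rep1$lambda)

  # same state, one more selected target: overall strictly decreases
  rep2 <- grade_design(net, st2, sets, specs, n_targets = 2)
  expect_equal(rep2$lambda, rep1$lambda)
  expect_lt(rep2$overall, rep1$overall)

  # a zero grade forces lambda and overall to zero
  sp0 <- build_default_memberships(net, sets,
           overrides = stats::setNames(list(
             membership_spec("minimize", x_basal_UB = 1e-6, x_UB = 2e-6)),
             "TOX"))
  rep3 <- grade_design(net, st2, sets, sp0, n_targets = 1)
  expect_equal(rep3$lambda, 0)
  expect_equal(rep3$overall, 0)

  # non-converged states are graded infeasible
  st_bad <- st2; st_bad$converged <- FALSE
  rep4 <- grade_design(net, st_bad, sets, specs, n_targets = 1)
  expect_equal(rep4$lambda, 0)
  expect_false(rep4$feasible)
})

test_that("default memberships invert to the calibrated fold breakpoints", {
  net <- load_dopamine_model()
  sets <- dopamine_objective_sets(net)
  specs <- build_default_memberships(net, sets)
  dae <- specs$species[["DA-e"]]       # basal 400
  expect_equal(c(dae$x_LB, dae$x_basal_LB, dae$x_basal_UB, dae$x_UB),
               c(40, 400, 400, 4000))
  dq <- specs$species[["DOPA-Q"]]      # basal 5, minimized
  expect_equal(dq$kind, "minimize")
  expect_equal(c(dq$x_basal_UB, dq$x_UB), c(5, 50))
  # overriding one spec leaves the rest untouched
  ov <- build_default_memberships(net, sets, overrides = stats::setNames(
    list(membership_spec("minimize", x_basal_UB = 5, x_UB = 20)), "DOPA-Q"))
  expect_equal(ov$species[["DOPA-Q"]]$x_UB, 20)
  expect_equal(ov$species[["DA-e"]]$x_UB, 4000)
})
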