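test_that("an empty selection on a healthy problem is fully satisfied at basal", {
  sp <- small_problem(seed = 3, delta = 0)
  prob <- decision_problem(sp$net, objective_sets(TE = sp$net$meta$therapeutic,
                                                  AE = "TOX", Z_UB = 6))
  dp <- solve_fixed_targets(prob, character(0))
  expect_equal(dp$lambda, 1)
  expect_equal(dp$overall, 1)
  expect_equal(unname(dp$state$alpha), unname(sp$net$alpha_basal))
})

test_that("unselected targets stay exactly at basal (switched-bound collapse)", {
  sp <- small_problem(seed = 7, delta = 60)
  dp <- solve_fixed_targets(sp$problem, "a3")
  others <- setdiff(names(dp$state$alpha), c("a3", "a1"))
  expect_identical(unname(dp$state$alpha[others]),
                   unname(sp$net$alpha_basal[others]))
  # the diseased reaction carries its restricted activity
  expect_equal(dp$state$alpha[["a1"]], 0.4 * sp$net$alpha_basal[["a1"]])
})

test_that("single-target solves match a dense grid-search oracle", {
  sp <- small_problem(seed = 7, delta = 60)
  for (tg in c("a3", "a8", "u1")) {
    lam_star <- solve_fixed_targets(sp$problem, tg)$lambda
    lam_grid <- lambda_grid_oracle(sp$problem, tg, n_grid = 200)
    expect_equal(lam_star, lam_grid, tolerance = 0.01,
                 info = paste("target", tg))
    expect_gte(lam_star, lam_grid - 0.01)
  }
})

test_that("two-target solves match a 2-D grid oracle and dominate single targets", {
  sp <- small_problem(seed = 7, delta = 60)
  prob <- sp$problem
  net <- sp$net
  dp2 <- solve_fixed_targets(prob, c("a3", "a8"), list(seed = 2, n_starts = 6))
  # coarse 2-D oracle
  folds <- exp(seq(log(0.1), log(10), length.out = 41))
  lam2 <- max(vapply(folds, function(f1) {
    max(vapply(folds, function(f2) {
      pert <- combine_perturbations(sp$dis,
        perturbation(activity_fold = c(a3 = f1, a8 = f2)))
      st <- solve_steady_state(net, pert)
      grade_design(net, st, prob$sets, prob$specs, 2)$lambda
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(dp2$lambda, lam2, tolerance = 0.01)

  # superset never does worse than the best of its members
  lam_a3 <- solve_fixed_targets(prob, "a3")$lambda
  lam_a8 <- solve_fixed_targets(prob, "a8")$lambda
  expect_gte(dp2$lambda, max(lam_a3, lam_a8) - 0.01)
})

test_that("treatment presets evaluate in fixed and optimized modes", {
  sp <- small_problem(seed = 5, delta = 0)
  prob <- decision_problem(sp$net, objective_sets(TE = sp$net$meta$therapeutic,
                                                  AE = "TOX", Z_UB = 6))
  # fixing everything at basal in a healthy problem keeps all grades at 1
  fixed <- evaluate_treatment(prob, c(a2 = 1, a3 = 1), mode = "fixed")
  expect_equal(fixed$report$T, 1)
  expect_equal(fixed$report$A, 1)
  expect_equal(fixed$report$V, 1)

  # optimizing a preset equals solving with those targets selected
  spd <- small_problem(seed = 5, delta = 50)
  opt <- evaluate_treatment(spd$problem, "a3", mode = "optimize",
                            options = list(seed = 4))
  direct <- solve_fixed_targets(spd$problem, "a3", list(seed = 4))
  expect_equal(opt$lambda, direct$lambda, tolerance = 1e-9)
})

test_that("diseased and unknown targets are rejected", {
  sp <- small_problem(seed = 7, delta = 60)
  expect_error(solve_fixed_targets(sp$problem, "a1"), "diseased")
  expect_error(solve_fixed_targets(sp$problem, "zz"), "not regulable")
  expect_error(solve_fixed_targets(sp$problem, paste0("a", 2:9)),
               "Z_UB")
})
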