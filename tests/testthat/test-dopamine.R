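test_that("the packaged dopamine network has the documented structure", {
  net <- load_dopamine_model()
  expect_length(net$species_names, 34)
  expect_length(net$reaction_names, 68)
  expect_identical(net$control_names, c("u_t", "u_l", "u_d"))
  expect_length(net$meta$independents, 18)
  expect_true(net$consistent)
  expect_true(isTRUE(net$meta$synthetic))

  # healthy-state concentrations of the reported metabolites
  hs <- solve_steady_state(net)
  expect_true(hs$converged)
  expect_equal(hs$x[["DA-e"]], 400, tolerance = 1e-6)
  expect_equal(hs$x[["DOPA-Q"]], 5, tolerance = 1e-6)
  expect_equal(hs$x[["3-MT"]], 20, tolerance = 1e-6)
  expect_equal(hs$x[["DA-Q"]], 10, tolerance = 1e-6)
  expect_equal(hs$x[["HO"]], 2, tolerance = 1e-6)
})

test_that("loading rejects files with the wrong shape", {
  net <- generate_random_gma(6, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_gma_model(net, tmp)
  expect_error(load_dopamine_model(tmp), "dimensions")
})

test_that("scenario names map to the documented deficiency restrictions", {
  net <- load_dopamine_model()
  vm50 <- dopamine_scenario(net, "VM50")
  vmat2 <- net$meta$aliases$VMAT2
  expect_equal(unname(vm50$disease[vmat2]),
               0.5 * net$alpha_basal[[vmat2]])
  th100 <- dopamine_scenario(net, "TH100")
  expect_equal(unname(th100$disease[net$meta$aliases$TH]), 0)
  expect_identical(dopamine_scenario(net, "HS")$disease, numeric(0))
  expect_error(dopamine_scenario(net, "XX50"), "unknown scenario")
})

test_that("extracellular dopamine falls monotonically with VMAT2 deficiency and collapses when severe", {
  net <- load_dopamine_model()
  deltas <- c(50, 70, 90, 95)
  dae <- vapply(deltas, function(d) {
    st <- solve_steady_state(net, dopamine_scenario(net, paste0("VM", d)))
    expect_true(st$converged)
    st$x[["DA-e"]]
  }, numeric(1))
  expect_true(all(diff(dae) < 0))
  st95 <- solve_steady_state(net, dopamine_scenario(net, "VM95"))
  expect_true(st95$effectively_zero[["DA-e"]])
  st70 <- solve_steady_state(net, dopamine_scenario(net, "VM70"))
  expect_false(st70$effectively_zero[["DA-e"]])
})

test_that("complete TH deficiency keeps dopamine nonzero via the decarboxylase bypass", {
  net <- load_dopamine_model()
  st <- solve_steady_state(net, dopamine_scenario(net, "TH100"))
  expect_true(st$converged)
  expect_gt(st$x[["DA-e"]], 1)
  expect_false(st$effectively_zero[["DA-e"]])
})

test_that("drug presets name exactly the documented model variables", {
  net <- load_dopamine_model()
  al <- net$meta$aliases
  expect_identical(drug_preset(net, "diet"), "u_t")
  expect_identical(drug_preset(net, "L-DOPA"), "u_l")
  expect_identical(drug_preset(net, "DA-agonist"), "u_d")
  expect_setequal(drug_preset(net, "COMT-inhibitor"),
                  c(al$`COMT-e`, al$`COMT-DOPAC`))
  expect_setequal(drug_preset(net, "MAOI"),
                  c(al$MAO, al$`MAO-3MT`, al$`MAO-e`))
  expect_error(drug_preset(net, "aspirin"), "unknown preset")
})

test_that("scenario tables report per-row results and survive per-cell failures", {
  net <- load_dopamine_model()
  tab <- run_scenario_table(net, c("HS", "VM50"))
  expect_equal(tab$summary$scenario, c("HS", "VM50"))
  expect_equal(tab$summary$T[1], 1)
  expect_lt(tab$summary$T[2], 1)
  expect_true(all(c("fold", "grade", "status") %in% names(tab$folds)))
  expect_setequal(unique(tab$folds$status),
                  c("Therapeutic", "Toxic", "ROS", "RNS"))

  # an unknown scenario fails its own row, not the table
  mixed <- run_scenario_table(net, c("HS", "nonsense"))
  expect_equal(mixed$summary$status[1], "ok")
  expect_match(mixed$summary$status[2], "failed")
})

test_that("a treatment preset improves the therapeutic grade of a deficient state", {
  net <- load_dopamine_model()
  untreated <- run_scenario_table(net, "VM50")
  treated <- run_scenario_table(net, "VM50", preset = "MAOI",
                                options = list(seed = 1, n_starts = 4,
                                               maxit = 120))
  expect_gt(treated$summary$T, untreated$summary$T)
  expect_identical(treated$summary$targets,
                   paste(drug_preset(net, "MAOI"), collapse = "|"))
})
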