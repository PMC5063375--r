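# Shared fixtures: built in code, no files.

# small pathway network with a mid-chain disease lesion, used by the
# inner-solver and outer-search tests
small_problem <- function(seed = 7, delta = 60, Z_UB = 6, n_species = 6) {
  net <- generate_random_gma(n_species, n_controls = 1, seed = seed)
  sets <- objective_sets(TE = net$meta$therapeutic, AE = "TOX", Z_UB = Z_UB)
  dis <- apply_deficiency(net, "a1", delta)
  list(net = net,
       dis = dis,
       problem = decision_problem(net, sets, scenario = dis))
}

# grid-search oracle for the single-target continuous subproblem
lambda_grid_oracle <- function(prob, target, n_grid = 200) {
  net <- prob$network
  eval_at <- function(val) {
    pert <- if (target %in% net$reaction_names) {
      perturbation(activity_fold = stats::setNames(val, target))
    } else {
      perturbation(controls = stats::setNames(val, target))
    }
    st <- solve_steady_state(net, combine_perturbations(prob$scenario, pert))
    grade_design(net, st, prob$sets, prob$specs, 1)$lambda
  }
  grid <- if (target %in% net$reaction_names) {
    exp(seq(log(prob$bounds$fold_lb), log(prob$bounds$fold_ub),
            length.out = n_grid))
  } else if (net$u_basal[[target]] > 0) {
    net$u_basal[[target]] * exp(seq(log(prob$bounds$fold_lb),
                                    log(prob$bounds$fold_ub),
                                    length.out = n_grid))
  } else {
    seq(prob$bounds$u_lb, prob$bounds$u_ub, length.out = n_grid)
  }
  max(vapply(grid, eval_at, numeric(1)))
}

# concentration fold changes and adverse/therapeutic satisfaction grades
# printed for the VM50 scenario and four drug classes; the two cells whose
# printed grades are inconsistent with any single monotone linear rule are
# flagged as anomalies and excluded from calibration checks
vm50_fold_grade_table <- function() {
  df <- rbind(
    data.frame(metabolite = "DA-e",    kind = "equal",    column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(0.486, 0.673, 0.806, 0.735, 1.0),
               grade = c(0.43, 0.636, 0.784, 0.756, 1.0)),
    data.frame(metabolite = "DOPA-Q",  kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.512, 7.962, 5.429, 3.192, 2.634),
               grade = c(0.943, 0.226, 0.508, 1.0, 0.818)),
    data.frame(metabolite = "3-MT",    kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.101, 1.057, 1.032, 0.1, 1.035),
               grade = c(0.989, 0.994, 0.996, 1.0, 0.996)),
    data.frame(metabolite = "DOPAL-e", kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(0.241, 0.457, 0.653, 0.262, 0.706),
               grade = c(1.0, 1.0, 1.0, 1.0, 1.0)),
    data.frame(metabolite = "DA-Q",    kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.548, 4.413, 6.953, 3.593, 2.801),
               grade = c(0.939, 0.621, 0.339, 0.712, 0.8)),
    data.frame(metabolite = "DOPAL",   kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.095, 1.271, 1.463, 1.294, 0.738),
               grade = c(0.989, 0.97, 0.949, 0.967, 1.0)),
    data.frame(metabolite = "DOPAC-Q", kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.127, 1.446, 1.672, 1.41, 0.757),
               grade = c(0.986, 0.95, 0.925, 0.954, 1.0)),
    data.frame(metabolite = "O2-",     kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.182, 1.857, 2.042, 1.613, 0.921),
               grade = c(0.98, 0.905, 0.884, 0.932, 1.0)),
    data.frame(metabolite = "H2O2",    kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.13, 1.543, 1.694, 1.422, 0.872),
               grade = c(0.986, 0.94, 0.923, 0.953, 1.0)),
    data.frame(metabolite = "H2O2-e",  kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(0.763, 0.854, 0.915, 0.344, 0.97),
               grade = c(1.0, 1.0, 1.0, 1.0, 1.0)),
    data.frame(metabolite = "HO",      kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.287, 2.471, 3.001, 2.074, 0.758),
               grade = c(0.968, 0.837, 0.778, 0.881, 1.0)),
    data.frame(metabolite = "HO-NO2",  kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.24, 2.301, 2.553, 1.862, 0.961),
               grade = c(0.973, 0.855, 0.827, 0.904, 1.0)),
    data.frame(metabolite = "NO2",     kind = "minimize", column = c("VM50", "L-DOPA", "DA-AG", "COMT", "MAOI"),
               fold = c(1.144, 1.77, 1.902, 1.508, 1.002),
               grade = c(0.984, 0.914, 0.9, 0.943, 1.0)))
  df$anomaly <- (df$metabolite == "DA-e" & df$column == "COMT") |
    (df$metabolite == "DOPA-Q" & df$column == "COMT")
  df
}

# linear membership on the fold scale used throughout the calibration:
# therapeutic rises from 0 at fold 0.1 to 1 at fold 1; adverse species
# hold 1 up to fold 1 and fall to 0 at fold 10
fold_spec <- function(kind) {
  if (kind == "equal")
    membership_spec("equal", x_LB = 0.1, x_basal_LB = 1, x_basal_UB = 1,
                    x_UB = 10)
  else membership_spec("minimize", x_basal_UB = 1, x_UB = 10)
}
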