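#' Load the packaged presynaptic dopamine network
#'
#' Loads the synthetic stand-in model of the presynaptic dopamine
#' metabolic pathway shipped with the package
#' (\code{extdata/dopamine_gma_synthetic.json}). The network has the
#' documented dimensions of published presynaptic dopamine models --
#' 34 dependent metabolites, 68 power-law reactions, 3 external controls
#' (tyrosine intake \code{u_t}, exogenous L-DOPA \code{u_l}, dopamine
#' dosing \code{u_d}) and 18 independent variables recorded as metadata --
#' and the named pathway chemistry (TH, AADC, VMAT2, vesicular release,
#' DAT reuptake, MAO, COMT, quinone and ROS/RNS branches). Its rate
#' constants are back-solved from a designed basal flux distribution and
#' are \emph{not} the parameters of any published model: quantitative
#' outputs are illustrative, while the qualitative disease regimes
#' (monotone dopamine loss with VMAT2 deficiency, extracellular dopamine
#' collapse for severe deficiency, the DOPA-decarboxylase bypass under
#' complete TH deficiency) are reproduced.
#'
#' @param path optional path to an alternative model file in the same
#'   format.
#' @return a consistent \code{gma_network}. Loading fails if the file
#'   does not have the expected dimensions or a consistent basal state.
#' @export
load_dopamine_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dopamine_gma_synthetic.json",
                        package = "fmdd", mustWork = TRUE)
  net <- read_gma_model(path)
  if (length(net$species_names) != 34 || length(net$reaction_names) != 68 ||
      length(net$control_names) != 3)
    stop("dopamine model file has unexpected dimensions")
  if (length(net$meta$independents) != 18)
    stop("dopamine model file must record 18 independent variables")
  if (!isTRUE(net$consistent))
    stop("dopamine model basal state failed its consistency check")
  net
}

#' Disease scenarios for the dopamine network
#'
#' The eight standard scenarios: VMAT2 deficiencies of 50, 70, 90 and 95
#' percent (VM50--VM95) and tyrosine-hydroxylase deficiencies of 50, 70,
#' 90 and 100 percent (TH50--TH100), plus the healthy state \code{HS}.
#' Each maps to a deficiency perturbation
#' \eqn{\alpha^{DS} = (1-\delta/100)\alpha^{basal}} on the VMAT2 or TH
#' reaction.
#'
#' @param network the dopamine \code{gma_network} (for alias resolution).
#' @param name scenario name; one of \code{"HS"}, \code{"VM50"},
#'   \code{"VM70"}, \code{"VM90"}, \code{"VM95"}, \code{"TH50"},
#'   \code{"TH70"}, \code{"TH90"}, \code{"TH100"}, or a free-form
#'   \code{"VM<delta>"} / \code{"TH<delta>"}.
#' @return a \code{gma_perturbation}.
#' @export
dopamine_scenario <- function(network, name) {
  if (identical(name, "HS")) return(perturbation())
  m <- regmatches(name, regexec("^(VM|TH)([0-9]+)$", name))[[1]]
  if (length(m) != 3) stop("unknown scenario name: ", name)
  delta <- as.numeric(m[3])
  enzyme <- if (m[2] == "VM") "VMAT2" else "TH"
  reaction <- network$meta$aliases[[enzyme]]
  if (is.null(reaction)) stop("model does not alias enzyme ", enzyme)
  apply_deficiency(network, reaction, delta)
}

#' Standard objective sets for the dopamine network
#'
#' Therapeutic effect: extracellular dopamine (DA-e) close to its healthy
#' level. Adverse effects: the toxic species (DOPA-Q, 3-MT, DOPAL,
#' DOPAL-e, DOPAC-Q, DA-Q), the reactive oxygen species (O2-, H2O2,
#' H2O2-e, HO) and the reactive nitrogen species (HO-NO2, NO2), all
#' fuzzy-minimized. Variation effects: every regulable enzyme activity
#' plus the three external controls.
#'
#' @param network the dopamine \code{gma_network}.
#' @param Z_UB target-count upper bound.
#' @return an \code{objective_sets}.
#' @export
dopamine_objective_sets <- function(network, Z_UB = 10) {
  meta <- network$meta
  objective_sets(TE = as.character(meta$therapeutic),
                 AE = c(unlist(meta$toxic), unlist(meta$ros), unlist(meta$rns)),
                 Z_UB = Z_UB)
}

#' Adverse/therapeutic status labels for dopamine metabolites
#'
#' @param network the dopamine \code{gma_network}.
#' @return named character vector mapping species to
#'   \code{"Therapeutic"}, \code{"Toxic"}, \code{"ROS"} or \code{"RNS"}.
#' @export
dopamine_status <- function(network) {
  meta <- network$meta
  c(stats::setNames(rep("Therapeutic", length(meta$therapeutic)),
                    unlist(meta$therapeutic)),
    stats::setNames(rep("Toxic", length(meta$toxic)), unlist(meta$toxic)),
    stats::setNames(rep("ROS", length(meta$ros)), unlist(meta$ros)),
    stats::setNames(rep("RNS", length(meta$rns)), unlist(meta$rns)))
}

#' Treatment presets for current Parkinson's disease drug classes
#'
#' Maps drug classes to the model variables they act on: diet control to
#' tyrosine intake \code{u_t}; L-DOPA preparations (Madopar, Sinemet) to
#' the exogenous L-DOPA control \code{u_l}; dopamine agonists
#' (bromocriptine, pergolide, pramipexole, ropinirole) to the dopamine
#' dosing control \code{u_d}; COMT inhibitors (entacapone, tolcapone) to
#' the two COMT activities; MAO inhibitors (selegiline, rasagiline) to
#' the three MAO activities.
#'
#' @param network the dopamine \code{gma_network}.
#' @param name one of \code{"diet"}, \code{"L-DOPA"}, \code{"DA-agonist"},
#'   \code{"COMT-inhibitor"}, \code{"MAOI"}; \code{NULL} lists all presets.
#' @return character vector of target names (or a named list of all).
#' @export
drug_preset <- function(network, name = NULL) {
  al <- network$meta$aliases
  presets <- list(
    "diet" = "u_t",
    "L-DOPA" = "u_l",
    "DA-agonist" = "u_d",
    "COMT-inhibitor" = as.character(c(al$`COMT-e`, al$`COMT-DOPAC`)),
    "MAOI" = as.character(c(al$MAO, al$`MAO-3MT`, al$`MAO-e`)))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) stop("unknown preset: ", name)
  presets[[name]]
}

#' Tabulate scenarios, optionally under treatment
#'
#' For each scenario, solves the diseased steady state, reports fold
#' changes of the status metabolites relative to the healthy state with
#' their adverse/therapeutic satisfaction grades, and (if a preset or
#' search configuration is given) the treated design with its T/A/V
#' grades. Solver failures are reported per row rather than aborting the
#' table.
#'
#' @param network the dopamine \code{gma_network}.
#' @param scenarios character vector of scenario names.
#' @param preset optional drug-preset name applied to every scenario
#'   (levels co-optimized by the inner solve).
#' @param search optional \code{\link{nhde_config}}; when given, a target
#'   search is run per scenario instead of a preset.
#' @param Z_UB target-count bound for grading.
#' @param options inner-solver options.
#' @return list with \code{summary} (scenario, status, T, A, V, lambda,
#'   overall, targets) and \code{folds} (long data frame: scenario,
#'   metabolite, basal, fold, grade, status).
#' @export
run_scenario_table <- function(network, scenarios, preset = NULL,
                               search = NULL, Z_UB = 10, options = list()) {
  sets <- dopamine_objective_sets(network, Z_UB = Z_UB)
  status <- dopamine_status(network)
  healthy <- solve_steady_state(network)
  rows <- list(); folds <- list()
  for (sc in scenarios) {
    res <- tryCatch({
      pert <- dopamine_scenario(network, sc)
      prob <- decision_problem(network, sets, scenario = pert)
      dp <- if (!is.null(search)) {
        nhde_search(prob, search)$best
      } else if (!is.null(preset)) {
        evaluate_treatment(prob, drug_preset(network, preset),
                           options = options)
      } else {
        solve_fixed_targets(prob, character(0), options)
      }
      st <- dp$state
      fc <- fold_changes(st, healthy)$species
      fc <- fc[fc$name %in% names(status), ]
      grade <- vapply(seq_len(nrow(fc)), function(i) {
        spx <- prob$specs$species[[fc$name[i]]]
        if (is.null(spx)) NA_real_ else membership_grade(fc$value[i], spx)
      }, numeric(1))
      folds[[sc]] <- data.frame(scenario = sc, metabolite = fc$name,
                                basal = fc$reference, fold = round(fc$fold, 3),
                                grade = round(grade, 3),
                                status = status[fc$name],
                                effectively_zero = st$effectively_zero[fc$name],
                                stringsAsFactors = FALSE, row.names = NULL)
      data.frame(scenario = sc, status = "ok",
                 T = round(dp$report$T, 3), A = round(dp$report$A, 3),
                 V = round(dp$report$V, 3), lambda = round(dp$lambda, 3),
                 overall = round(dp$overall, 3),
                 targets = paste(dp$targets, collapse = "|"),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(scenario = sc, status = paste("failed:", conditionMessage(e)),
                 T = NA_real_, A = NA_real_, V = NA_real_,
                 lambda = NA_real_, overall = NA_real_, targets = "",
                 stringsAsFactors = FALSE)
    })
    rows[[sc]] <- res
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       folds = if (length(folds)) do.call(rbind, c(folds, list(make.row.names = FALSE)))
               else NULL)
}
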