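#' Define a target-design decision problem
#'
#' Bundles a network, objective sets, membership specifications, decision
#' bounds and a disease/treatment scenario into the continuous decision
#' problem solved for each candidate target subset: maximize the overall
#' satisfaction grade \eqn{\lambda} subject to the steady-state equality
#' constraints, the switched bounds that pin unselected targets to basal,
#' and every membership grade \eqn{\eta \ge \lambda}.
#'
#' @param network a \code{gma_network}.
#' @param sets an \code{objective_sets}.
#' @param specs membership specs; default
#'   \code{build_default_memberships(network, sets)}.
#' @param scenario a \code{gma_perturbation} holding disease restrictions
#'   (its disease reactions are added to the excluded set).
#' @param bounds list: \code{fold_lb}/\code{fold_ub} activity-fold bounds
#'   for selected targets (default 0.1 and 10, i.e. log-space bounds of
#'   \eqn{\pm\ln 10}); \code{u_lb}/\code{u_ub} absolute bounds for
#'   zero-basal controls (default 0 and 10).
#' @return object of class \code{decision_problem}.
#' @export
decision_problem <- function(network, sets, specs = NULL,
                             scenario = perturbation(), bounds = list()) {
  sets$DS <- union(sets$DS, names(scenario$disease))
  if (is.null(specs)) specs <- build_default_memberships(network, sets)
  b <- utils::modifyList(list(fold_lb = 0.1, fold_ub = 10, u_lb = 0, u_ub = 10),
                         bounds)
  ref <- solve_steady_state(network)
  if (!ref$converged) stop("network has no resolvable healthy steady state")
  structure(list(network = network, sets = sets, specs = specs,
                 scenario = scenario, bounds = b, healthy = ref),
            class = "decision_problem")
}

# normalised [0,1] coordinates <-> concrete target values
target_var_info <- function(problem, targets) {
  net <- problem$network
  lapply(targets, function(nm) {
    if (nm %in% net$reaction_names) {
      list(name = nm, type = "activity",
           lo = log(problem$bounds$fold_lb), hi = log(problem$bounds$fold_ub),
           basal01 = (0 - log(problem$bounds$fold_lb)) /
             (log(problem$bounds$fold_ub) - log(problem$bounds$fold_lb)))
    } else if (nm %in% net$control_names) {
      b <- net$u_basal[[nm]]
      if (b > 0) {
        list(name = nm, type = "control_fold",
             lo = log(problem$bounds$fold_lb), hi = log(problem$bounds$fold_ub),
             basal01 = (0 - log(problem$bounds$fold_lb)) /
               (log(problem$bounds$fold_ub) - log(problem$bounds$fold_lb)))
      } else {
        list(name = nm, type = "control_abs",
             lo = problem$bounds$u_lb, hi = problem$bounds$u_ub,
             basal01 = (0 - problem$bounds$u_lb) /
               (problem$bounds$u_ub - problem$bounds$u_lb))
      }
    } else stop("unknown target: ", nm)
  })
}

vars_to_perturbation <- function(problem, info, theta01) {
  af <- numeric(0); cv <- numeric(0)
  net <- problem$network
  for (i in seq_along(info)) {
    vi <- info[[i]]
    val <- vi$lo + pmin(pmax(theta01[i], 0), 1) * (vi$hi - vi$lo)
    if (vi$type == "activity") {
      af <- c(af, stats::setNames(exp(val), vi$name))
    } else if (vi$type == "control_fold") {
      cv <- c(cv, stats::setNames(net$u_basal[[vi$name]] * exp(val), vi$name))
    } else {
      cv <- c(cv, stats::setNames(val, vi$name))
    }
  }
  combine_perturbations(problem$scenario,
                        perturbation(activity_fold = af, controls = cv))
}

#' Solve the continuous decision problem for a fixed target subset
#'
#' For a fixed selection of regulated targets, searches their activity
#' folds (log scale) and control values within bounds for the point
#' maximizing the minimum membership grade \eqn{\lambda}. One decision
#' variable uses a dense grid refined by golden-section search; several
#' use multistart Nelder-Mead from the basal point plus Latin-hypercube
#' starts. Ties in \eqn{\lambda} are broken toward the smallest total
#' deviation from basal. Deterministic for a fixed seed.
#'
#' @param problem a \code{decision_problem}.
#' @param targets character vector of selected target names (activities or
#'   controls, excluding diseased reactions); may be empty.
#' @param options list: \code{n_starts} (default 8), \code{seed},
#'   \code{maxit} per start (default 200), \code{grid_n} for the 1-D path
#'   (default 41), \code{ss_options} passed to the steady-state solver.
#' @return object of class \code{design_point}: list with \code{targets},
#'   \code{values} (named: activity folds / control values), \code{state},
#'   \code{report} (a \code{grade_report}), \code{lambda}, \code{overall},
#'   \code{feasible}.
#' @export
solve_fixed_targets <- function(problem, targets = character(0), options = list()) {
  opt <- utils::modifyList(list(n_starts = 8, seed = 1, maxit = 200,
                                grid_n = 41, ss_options = list()), options)
  sets <- problem$sets
  if (length(targets) > sets$Z_UB) stop("more targets than Z_UB allows")
  bad <- intersect(targets, sets$DS)
  if (length(bad)) stop("diseased reactions cannot be targets: ",
                        paste(bad, collapse = ", "))
  reg <- regulable_targets(problem$network, sets)
  unknown <- setdiff(targets, reg$all)
  if (length(unknown)) stop("not regulable: ", paste(unknown, collapse = ", "))
  info <- target_var_info(problem, targets)
  d <- length(info)

  eval_point <- function(theta01) {
    pert <- vars_to_perturbation(problem, info, theta01)
    st <- solve_steady_state(problem$network, pert,
                             utils::modifyList(opt$ss_options, list()))
    rep <- grade_design(problem$network, st, sets, problem$specs,
                        n_targets = length(targets))
    list(state = st, report = rep, lambda = rep$lambda)
  }
  # tie-break score: lambda minus a vanishing penalty on deviation from basal
  score_of <- function(theta01) {
    ev <- eval_point(theta01)
    dev <- if (d) mean(abs(theta01 - vapply(info, `[[`, numeric(1), "basal01"))) else 0
    ev$lambda - 1e-6 * dev
  }

  if (d == 0) {
    ev <- eval_point(numeric(0))
    return(structure(list(targets = targets, values = numeric(0),
                          state = ev$state, report = ev$report,
                          lambda = ev$lambda, overall = ev$report$overall,
                          feasible = ev$lambda > 0 && ev$state$converged),
                     class = "design_point"))
  }

  best_theta <- vapply(info, `[[`, numeric(1), "basal01")
  best_score <- score_of(best_theta)
  if (d == 1) {
    grid <- seq(0, 1, length.out = opt$grid_n)
    sc <- vapply(grid, score_of, numeric(1))
    i <- which.max(sc)
    if (sc[i] > best_score) { best_score <- sc[i]; best_theta <- grid[i] }
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    o <- stats::optimize(score_of, c(lo, hi), maximum = TRUE,
                         tol = 1e-4)
    if (o$objective > best_score) { best_score <- o$objective; best_theta <- o$maximum }
  } else {
    set.seed(opt$seed)
    starts <- rbind(matrix(best_theta, nrow = 1),
                    lhs::randomLHS(max(1, opt$n_starts - 1), d))
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(starts[s, ], function(th) -score_of(th),
                        method = "Nelder-Mead",
                        control = list(maxit = opt$maxit, reltol = 1e-6))
      th <- pmin(pmax(o$par, 0), 1)
      sc <- -o$value
      if (sc > best_score) { best_score <- sc; best_theta <- th }
    }
  }
  ev <- eval_point(best_theta)
  pert <- vars_to_perturbation(problem, info, best_theta)
  vals <- c(pert$activity_fold, pert$controls)
  structure(list(targets = targets, values = vals[names(vals) %in%
                                                    vapply(info, `[[`, character(1), "name")],
                 state = ev$state, report = ev$report,
                 lambda = ev$lambda, overall = ev$report$overall,
                 feasible = ev$lambda > 0 && ev$state$converged),
            class = "design_point")
}

#' @export
print.design_point <- function(x, ...) {
  cat(sprintf("design point: {%s} lambda=%.3f overall=%.3f%s\n",
              paste(x$targets, collapse = ", "), x$lambda, x$overall,
              if (!x$feasible) " [infeasible]" else ""))
  if (length(x$values)) {
    cat("  values:", paste(sprintf("%s=%.4g", names(x$values), x$values),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate a treatment preset
#'
#' Applies a named set of treatment targets to a decision problem. In
#' \code{"optimize"} mode the preset targets are made regulable and their
#' levels co-optimized by \code{\link{solve_fixed_targets}} (the usual
#' reading of a drug class acting on fixed targets with a tunable dose);
#' in \code{"fixed"} mode explicit activity folds / control values are
#' evaluated as given.
#'
#' @param problem a \code{decision_problem}.
#' @param preset character vector of target names, or (for
#'   \code{mode = "fixed"}) a named numeric vector of activity folds and
#'   control values.
#' @param mode \code{"optimize"} or \code{"fixed"}.
#' @param options passed to \code{\link{solve_fixed_targets}}.
#' @return a \code{design_point}.
#' @export
evaluate_treatment <- function(problem, preset, mode = c("optimize", "fixed"),
                               options = list()) {
  mode <- match.arg(mode)
  if (mode == "optimize") {
    return(solve_fixed_targets(problem, as.character(preset), options))
  }
  stopifnot(is.numeric(preset), !is.null(names(preset)))
  net <- problem$network
  af <- preset[names(preset) %in% net$reaction_names]
  cv <- preset[names(preset) %in% net$control_names]
  pert <- combine_perturbations(problem$scenario,
                                perturbation(activity_fold = af, controls = cv))
  st <- solve_steady_state(net, pert)
  rep <- grade_design(net, st, problem$sets, problem$specs,
                      n_targets = length(preset))
  structure(list(targets = names(preset), values = preset, state = st,
                 report = rep, lambda = rep$lambda, overall = rep$overall,
                 feasible = rep$lambda > 0 && st$converged),
            class = "design_point")
}
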