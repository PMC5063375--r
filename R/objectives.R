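#' Objective sets of a target-design problem
#'
#' Partitions the model into the index sets of the design problem:
#' therapeutic-effect species (fuzzy-equal to their healthy level),
#' adverse-effect species (fuzzy-minimized), regulable variation-effect
#' targets (enzyme activities and external controls, graded on how little
#' they deviate from basal), and disease reactions, which are fixed by the
#' disease restriction and excluded from regulation.
#'
#' @param TE character vector of therapeutic species names.
#' @param AE character vector of adverse species names.
#' @param VE_activities regulable reaction names; \code{NULL} means all
#'   reactions not in \code{DS}.
#' @param VE_controls regulable control names; \code{NULL} means all
#'   controls.
#' @param DS disease reaction names (excluded from regulation).
#' @param Z_UB upper bound on the number of simultaneously regulated
#'   targets (integer, at least 2).
#' @return object of class \code{objective_sets}.
#' @export
objective_sets <- function(TE, AE = character(0), VE_activities = NULL,
                           VE_controls = NULL, DS = character(0), Z_UB = 10) {
  if (Z_UB < 2) stop("Z_UB must be at least 2")
  if (!is.null(VE_activities) && length(intersect(VE_activities, DS)))
    stop("disease reactions cannot be regulable")
  structure(list(TE = TE, AE = AE, VE_activities = VE_activities,
                 VE_controls = VE_controls, DS = DS, Z_UB = as.integer(Z_UB)),
            class = "objective_sets")
}

# concrete regulable target names for a network under given sets
regulable_targets <- function(network, sets) {
  acts <- if (is.null(sets$VE_activities)) network$reaction_names else sets$VE_activities
  acts <- setdiff(acts, sets$DS)
  ctrls <- if (is.null(sets$VE_controls)) network$control_names else sets$VE_controls
  list(activities = acts, controls = ctrls, all = c(acts, ctrls))
}

#' Build default membership specifications
#'
#' Constructs linear membership functions scaled to the basal state:
#' therapeutic species get a fuzzy-equal membership rising from 0 at
#' \code{te_lb_fold} times basal to 1 at basal (degenerate plateau) and
#' falling back to 0 at \code{te_ub_fold} times basal; adverse species get
#' a fuzzy-minimize membership with its plateau at basal and zero grade at
#' \code{ae_ub_fold} times basal. Variation-effect targets are graded on
#' their fold change from basal activity with a fuzzy-equal membership
#' (zero at \code{ve_lb_fold} and \code{ve_ub_fold}). Controls with a
#' positive basal value are treated like activities; zero-basal controls
#' (dosing inputs absent in the healthy state) get a fuzzy-minimize
#' membership on their absolute value, zero-grade at \code{u_min_ub}.
#' Every rule can be overridden per objective via \code{overrides}.
#'
#' @param network a \code{gma_network}.
#' @param sets an \code{objective_sets}.
#' @param rules list of calibration folds; see Details above. Defaults:
#'   \code{te_lb_fold = 0.1}, \code{te_ub_fold = 10}, \code{ae_ub_fold = 10},
#'   \code{ve_lb_fold = 0.1}, \code{ve_ub_fold = 10}, \code{u_min_ub = 10}.
#' @param overrides named list of \code{membership_spec} objects replacing
#'   individual defaults (names: species, \code{".activity_fold"}, or
#'   control names).
#' @return list with \code{species} (named specs, absolute units),
#'   \code{activity_fold} (shared spec on the fold scale) and
#'   \code{control} (named specs).
#' @export
build_default_memberships <- function(network, sets, rules = list(),
                                      overrides = list()) {
  rl <- utils::modifyList(list(te_lb_fold = 0.1, te_ub_fold = 10,
                               ae_ub_fold = 10, ve_lb_fold = 0.1,
                               ve_ub_fold = 10, u_min_ub = 10), rules)
  species <- list()
  for (nm in sets$TE) {
    b <- network$x_basal[[nm]]
    species[[nm]] <- membership_spec("equal", x_LB = rl$te_lb_fold * b,
                                     x_basal_LB = b, x_basal_UB = b,
                                     x_UB = rl$te_ub_fold * b)
  }
  for (nm in sets$AE) {
    b <- network$x_basal[[nm]]
    species[[nm]] <- membership_spec("minimize", x_basal_UB = b,
                                     x_UB = rl$ae_ub_fold * b)
  }
  activity_fold <- membership_spec("equal", x_LB = rl$ve_lb_fold,
                                   x_basal_LB = 1, x_basal_UB = 1,
                                   x_UB = rl$ve_ub_fold)
  ctrl <- list()
  reg <- regulable_targets(network, sets)
  for (nm in reg$controls) {
    b <- network$u_basal[[nm]]
    ctrl[[nm]] <- if (b > 0) {
      membership_spec("equal", x_LB = rl$ve_lb_fold * b, x_basal_LB = b,
                      x_basal_UB = b, x_UB = rl$ve_ub_fold * b)
    } else {
      membership_spec("minimize", x_basal_UB = 0, x_UB = rl$u_min_ub)
    }
  }
  specs <- list(species = species, activity_fold = activity_fold, control = ctrl)
  for (nm in names(overrides)) {
    if (nm == ".activity_fold") specs$activity_fold <- overrides[[nm]]
    else if (nm %in% names(specs$control)) specs$control[[nm]] <- overrides[[nm]]
    else specs$species[[nm]] <- overrides[[nm]]
  }
  specs
}

#' Target-count factor
#'
#' Normalized penalty on the number of simultaneously regulated targets:
#' \eqn{(Z^{UB} - \sum z)/(Z^{UB} - 1)}, equal to 1 for a single target and
#' decreasing linearly as targets are added. An empty selection (healthy
#' reference evaluation) yields 1.
#'
#' @param n_targets number of selected targets \eqn{\sum z}.
#' @param Z_UB upper bound on the target count (> 1).
#' @return scalar in \code{[0, 1]}.
#' @export
target_count_factor <- function(n_targets, Z_UB) {
  if (Z_UB <= 1) stop("Z_UB must exceed 1")
  if (n_targets > Z_UB) stop("more targets selected than Z_UB allows")
  if (n_targets == 0) return(1)
  (Z_UB - n_targets) / (Z_UB - 1)
}

#' Grade a candidate design
#'
#' Evaluates every membership grade for a solved state: therapeutic and
#' adverse grades on concentrations, variation grades on the fold changes
#' of regulated activities and on control values. The overall satisfaction
#' grade \eqn{\lambda} is the minimum grade, and the design objective is
#' the target-count factor times \eqn{\lambda}.
#'
#' @param network a \code{gma_network}.
#' @param state a \code{gma_steady_state} (must be converged for grades to
#'   be meaningful; a non-converged state grades to all-zero).
#' @param sets an \code{objective_sets}.
#' @param specs membership specs from \code{\link{build_default_memberships}}.
#' @param n_targets number of selected targets for the count factor.
#' @return object of class \code{grade_report}: list with \code{grades}
#'   (named vector), \code{class} (one of \code{"T"}, \code{"A"},
#'   \code{"V"} per grade), \code{T}, \code{A}, \code{V} (class minima),
#'   \code{lambda}, \code{count_factor}, \code{overall}.
#' @export
grade_design <- function(network, state, sets, specs, n_targets = 0) {
  grades <- numeric(0); cls <- character(0)
  if (!isTRUE(state$converged)) {
    rep <- list(grades = grades, class = cls, T = 0, A = 0, V = 0,
                lambda = 0, count_factor = target_count_factor(n_targets, sets$Z_UB),
                overall = 0, feasible = FALSE)
    return(structure(rep, class = "grade_report"))
  }
  for (nm in sets$TE) {
    g <- membership_grade(state$x[[nm]], specs$species[[nm]])
    grades <- c(grades, stats::setNames(g, nm)); cls <- c(cls, "T")
  }
  for (nm in sets$AE) {
    g <- membership_grade(state$x[[nm]], specs$species[[nm]])
    grades <- c(grades, stats::setNames(g, nm)); cls <- c(cls, "A")
  }
  reg <- regulable_targets(network, sets)
  for (nm in reg$activities) {
    fold <- state$alpha[[nm]] / network$alpha_basal[[nm]]
    g <- membership_grade(fold, specs$activity_fold)
    grades <- c(grades, stats::setNames(g, nm)); cls <- c(cls, "V")
  }
  for (nm in reg$controls) {
    sp <- specs$control[[nm]]
    if (is.null(sp)) next
    g <- membership_grade(state$u[[nm]], sp)  # control specs are in absolute units
    grades <- c(grades, stats::setNames(g, nm)); cls <- c(cls, "V")
  }
  min_or_1 <- function(v) if (length(v)) min(v) else 1
  lam <- min_or_1(grades)
  cf <- target_count_factor(n_targets, sets$Z_UB)
  structure(list(grades = grades, class = cls,
                 T = min_or_1(grades[cls == "T"]),
                 A = min_or_1(grades[cls == "A"]),
                 V = min_or_1(grades[cls == "V"]),
                 lambda = lam, count_factor = cf, overall = cf * lam,
                 feasible = TRUE),
            class = "grade_report")
}

#' @export
print.grade_report <- function(x, ...) {
  cat(sprintf("grade report: T=%.3f A=%.3f V=%.3f lambda=%.3f overall=%.3f\n",
              x$T, x$A, x$V, x$lambda, x$overall))
  invisible(x)
}
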