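#' Describe a perturbation of a GMA network
#'
#' A perturbation collects absolute activity overrides, fold-multiplier
#' overrides, external-control overrides and disease restrictions. Disease
#' restrictions fix a reaction's activity (typically below basal) and remove
#' it from the regulable set of any downstream design problem.
#'
#' @param activity named numeric vector of absolute activities.
#' @param activity_fold named numeric vector of fold multipliers of basal
#'   activity.
#' @param controls named numeric vector of absolute control values.
#' @param disease named numeric vector of absolute activities for reactions
#'   under a disease restriction.
#' @return object of class \code{gma_perturbation}.
#' @export
perturbation <- function(activity = numeric(0), activity_fold = numeric(0),
                         controls = numeric(0), disease = numeric(0)) {
  chk <- function(v, what) {
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
      stop(what, " overrides must be named")
    if (anyDuplicated(names(v))) stop("duplicated ", what, " override")
    v
  }
  p <- structure(list(activity = chk(activity, "activity"),
                      activity_fold = chk(activity_fold, "activity fold"),
                      controls = chk(controls, "control"),
                      disease = chk(disease, "disease")), class = "gma_perturbation")
  both <- intersect(names(p$activity), names(p$activity_fold))
  if (length(both)) stop("reaction perturbed twice: ", paste(both, collapse = ", "))
  if (any(p$activity < 0) || any(p$activity_fold < 0) || any(p$disease < 0))
    stop("activities must be nonnegative (zero allowed for complete knockouts)")
  p
}

#' Combine two perturbations
#'
#' Later entries win on conflict, except disease restrictions, which may not
#' be overridden by treatment entries.
#' @param p1,p2 \code{gma_perturbation} objects.
#' @return combined \code{gma_perturbation}.
#' @export
combine_perturbations <- function(p1, p2) {
  merge_named <- function(a, b) {
    a <- a[setdiff(names(a), names(b))]
    c(a, b)
  }
  clash <- intersect(names(p1$disease),
                     c(names(p2$activity), names(p2$activity_fold)))
  if (length(clash))
    stop("diseased reactions cannot be regulated: ", paste(clash, collapse = ", "))
  perturbation(activity = merge_named(p1$activity, p2$activity),
               activity_fold = merge_named(p1$activity_fold, p2$activity_fold),
               controls = merge_named(p1$controls, p2$controls),
               disease = merge_named(p1$disease, p2$disease))
}

#' Build a deficiency perturbation
#'
#' Encodes a percentage enzyme deficiency as the disease restriction
#' \eqn{\alpha^{DS} = (1 - \delta/100)\,\alpha^{basal}}. The affected
#' reaction joins the disease set and is excluded from regulable targets.
#'
#' @param network a \code{gma_network}.
#' @param reaction reaction name.
#' @param delta_percent deficiency percentage in \code{[0, 100]};
#'   100 silences the reaction completely.
#' @return a \code{gma_perturbation} with a single disease entry.
#' @export
apply_deficiency <- function(network, reaction, delta_percent) {
  if (!reaction %in% network$reaction_names)
    stop("unknown reaction: ", reaction)
  if (delta_percent < 0 || delta_percent > 100)
    stop("delta_percent must lie in [0, 100]")
  a <- (1 - delta_percent / 100) * network$alpha_basal[[reaction]]
  perturbation(disease = stats::setNames(a, reaction))
}

# resolve a perturbation into concrete (alpha, u) vectors
apply_perturbation <- function(network, pert = NULL) {
  alpha <- network$alpha_basal
  u <- network$u_basal
  if (!is.null(pert)) {
    stopifnot(inherits(pert, "gma_perturbation"))
    for (nm in names(pert$disease)) {
      if (!nm %in% names(alpha)) stop("unknown reaction: ", nm)
      alpha[nm] <- pert$disease[[nm]]
    }
    for (nm in names(pert$activity)) {
      if (!nm %in% names(alpha)) stop("unknown reaction: ", nm)
      alpha[nm] <- pert$activity[[nm]]
    }
    for (nm in names(pert$activity_fold)) {
      if (!nm %in% names(alpha)) stop("unknown reaction: ", nm)
      alpha[nm] <- network$alpha_basal[[nm]] * pert$activity_fold[[nm]]
    }
    for (nm in names(pert$controls)) {
      if (!nm %in% names(u)) stop("unknown control: ", nm)
      u[nm] <- pert$controls[[nm]]
    }
  }
  list(alpha = alpha, u = u, disease_set = names(pert$disease))
}

#' Solver options for \code{solve_steady_state}
#'
#' @param tol relative residual tolerance; convergence requires the
#'   max-norm residual below \code{tol} times the basal flux scale.
#' @param max_iter Newton iteration cap.
#' @param x0 initial concentrations (default: basal state).
#' @param floor_eps concentration floor in relative units. Log-space
#'   variables cannot represent an exact zero; species pinned at the floor
#'   while their net balance still drains them are flagged
#'   \emph{effectively zero} (the regime where a pool collapses under a
#'   severe deficiency).
#' @param method \code{"auto"} (damped Newton with ODE-integration
#'   fallback), \code{"newton"}, or \code{"ode"}.
#' @param t_max horizon for the integration fallback.
#' @return list of options.
#' @export
steady_state_options <- function(tol = 1e-10, max_iter = 200, x0 = NULL,
                                 floor_eps = 1e-9, method = c("auto", "newton", "ode"),
                                 t_max = 1e6) {
  list(tol = tol, max_iter = max_iter, x0 = x0, floor_eps = floor_eps,
       method = match.arg(method), t_max = t_max)
}

#' Solve for a steady state of a GMA network
#'
#' Finds \eqn{x} with \eqn{N v(x,\alpha) + B u = 0} under an optional
#' perturbation. The primary path is a damped Newton iteration on
#' log-concentrations (the log transform keeps iterates positive and the
#' constraint geometry benign); if Newton stalls, the trajectory of the
#' material-balance ODE is integrated from the initial guess until the
#' time derivative vanishes, then polished by Newton. Species that collapse
#' toward zero are pinned at a small floor and flagged rather than breaking
#' the log transform.
#'
#' @param network a \code{gma_network}.
#' @param pert optional \code{gma_perturbation}.
#' @param options see \code{\link{steady_state_options}}.
#' @return object of class \code{gma_steady_state}: list with \code{x},
#'   \code{v}, \code{converged}, \code{residual_norm},
#'   \code{effectively_zero} (logical per species), \code{alpha}, \code{u},
#'   \code{method}.
#' @export
solve_steady_state <- function(network, pert = NULL, options = steady_state_options()) {
  opt <- utils::modifyList(steady_state_options(), options)
  au <- apply_perturbation(network, pert)
  alpha <- au$alpha; u <- au$u
  scale <- max(1, flux_scale(network))
  tol_abs <- opt$tol * scale
  x0 <- if (is.null(opt$x0)) network$x_basal else opt$x0
  y_floor <- log(opt$floor_eps)
  y0 <- log(pmax(x0, opt$floor_eps))

  out <- newton_log(network, y0, alpha, u, tol_abs, opt$max_iter, y_floor)
  method <- "newton"
  if (!out$converged && opt$method != "newton") {
    ode_y <- integrate_to_steady(network, y0, alpha, u, tol_abs, y_floor, opt$t_max)
    polished <- newton_log(network, ode_y, alpha, u, tol_abs, opt$max_iter, y_floor)
    if (polished$score < out$score) { out <- polished; method <- "ode+newton" }
    if (!out$converged) method <- "ode+newton"
  }
  x <- exp(out$y)
  eff_zero <- out$y <= y_floor + 1e-9
  x[eff_zero] <- exp(y_floor)
  v <- evaluate_rates(x, alpha, network$G)
  res <- steady_state_residual(network, x, alpha, u)
  structure(list(
    x = stats::setNames(x, network$species_names),
    v = v,
    converged = out$converged,
    residual_norm = max(abs(res[!eff_zero]), 0),
    effectively_zero = stats::setNames(eff_zero, network$species_names),
    alpha = alpha, u = u,
    method = method, iterations = out$iter
  ), class = "gma_steady_state")
}

#' @export
print.gma_steady_state <- function(x, ...) {
  cat(sprintf("GMA steady state (%s): %s, residual max-norm %.3g\n",
              x$method, if (x$converged) "converged" else "NOT converged",
              x$residual_norm))
  if (any(x$effectively_zero))
    cat("effectively zero:", paste(names(which(x$effectively_zero)), collapse = ", "), "\n")
  invisible(x)
}

# residual treating floored, draining species as balanced-at-zero
floored_score <- function(res, y, y_floor) {
  at_floor <- y <= y_floor + 1e-9
  ok_zero <- at_floor & res < 0
  max(abs(res[!ok_zero]), 0)
}

newton_log <- function(network, y, alpha, u, tol_abs, max_iter, y_floor) {
  N <- network$N; G <- network$G
  f_of <- function(y) {
    v <- alpha * exp(as.numeric(G %*% y))
    list(v = v, f = as.numeric(N %*% v) + as.numeric(network$B %*% u))
  }
  cur <- f_of(y)
  best <- list(y = y, score = floored_score(cur$f, y, y_floor), converged = FALSE, iter = 0)
  for (it in seq_len(max_iter)) {
    score <- floored_score(cur$f, y, y_floor)
    if (score < best$score) best <- list(y = y, score = score, converged = FALSE, iter = it)
    if (score <= tol_abs) {
      best <- list(y = y, score = score, converged = TRUE, iter = it)
      break
    }
    J <- N %*% (cur$v * G)                 # d(Nv)/dy = N diag(v) G
    # pinned coordinates: freeze species held at the floor that keep draining
    pin <- (y <= y_floor + 1e-9) & (cur$f < 0)
    d <- tryCatch({
      Jm <- J; fm <- cur$f
      if (any(pin)) {
        Jm[pin, ] <- 0; Jm[, pin] <- 0
        diag(Jm)[pin] <- 1; fm[pin] <- 0
      }
      solve(Jm, -fm)
    }, error = function(e) NULL)
    if (is.null(d)) break
    nd <- max(abs(d))
    if (nd > 5) d <- d * (5 / nd)          # trust region in log units
    t_step <- 1; improved <- FALSE
    for (h in 1:40) {
      y_new <- pmax(y + t_step * d, y_floor)
      cand <- f_of(y_new)
      if (floored_score(cand$f, y_new, y_floor) < score * (1 - 1e-4 * t_step) ||
          floored_score(cand$f, y_new, y_floor) <= tol_abs) {
        y <- y_new; cur <- cand; improved <- TRUE; break
      }
      t_step <- t_step / 2
    }
    if (!improved) break
  }
  sc <- floored_score(cur$f, y, y_floor)
  if (sc < best$score || sc <= tol_abs)
    best <- list(y = y, score = sc, converged = sc <= tol_abs, iter = max_iter)
  best
}

integrate_to_steady <- function(network, y0, alpha, u, tol_abs, y_floor, t_max) {
  N <- network$N; G <- network$G
  deriv <- function(t, y, parms) {
    y <- pmax(y, y_floor)
    v <- alpha * exp(as.numeric(G %*% y))
    f <- as.numeric(N %*% v) + as.numeric(network$B %*% u)
    list(f * exp(-y))                      # dy/dt = (dx/dt)/x
  }
  y <- y0
  t_end <- 1
  while (t_end <= t_max) {
    sol <- tryCatch(
      deSolve::lsoda(y, c(0, t_end), deriv, parms = NULL,
                     rtol = 1e-8, atol = 1e-10),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(sol) && nrow(sol) == 2) y <- pmax(as.numeric(sol[2, -1]), y_floor)
    v <- alpha * exp(as.numeric(G %*% y))
    f <- as.numeric(N %*% v) + as.numeric(network$B %*% u)
    if (floored_score(f, y, y_floor) <= tol_abs * 10) break
    t_end <- t_end * 10
  }
  y
}

#' Fold changes of a state relative to a reference
#'
#' Divides concentrations and fluxes by their values in a reference state
#' (typically the healthy basal steady state). Entries with a zero
#' reference are reported as \code{NA} with status \code{"undefined"}.
#'
#' @param state a \code{gma_steady_state}.
#' @param reference a \code{gma_steady_state} (or list with \code{x} and
#'   \code{v}).
#' @param zero_tol values below this (in reference units) count as zero.
#' @return list with data frames \code{species} (name, reference, value,
#'   fold, status) and \code{flux}.
#' @export
fold_changes <- function(state, reference, zero_tol = 1e-12) {
  fold_tab <- function(val, ref, nms) {
    fold <- ifelse(abs(ref) > zero_tol, val / ref, NA_real_)
    status <- ifelse(abs(ref) > zero_tol, "ok", "undefined")
    data.frame(name = nms, reference = as.numeric(ref), value = as.numeric(val),
               fold = as.numeric(fold), status = status,
               stringsAsFactors = FALSE)
  }
  list(species = fold_tab(state$x, reference$x, names(state$x)),
       flux = fold_tab(state$v, reference$v, names(state$v)))
}
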