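#' Configuration for the nested hybrid differential evolution search
#'
#' The outer search evolves integer-coded target subsets with differential
#' evolution augmented by two hybrid operators: \emph{migration} (the
#' population is re-seeded around the incumbent when diversity collapses)
#' and \emph{acceleration} (a one-swap hill climb on the incumbent each
#' generation). Every candidate subset is evaluated by the inner
#' continuous solve, and repeated subsets are served from a memo cache.
#'
#' @param pop_size population size (at least 4).
#' @param F mutation factor.
#' @param CR crossover rate in \code{(0, 1]}.
#' @param generations generation cap.
#' @param migration_threshold re-seed all but the incumbent when the
#'   fraction of distinct codes drops below this.
#' @param acceleration_steps number of one-swap trials on the incumbent
#'   per generation.
#' @param cardinality \code{"free"} (subset size varies up to
#'   \code{Z_UB}) or \code{"fixed"} (exactly \code{K} targets).
#' @param K subset size for \code{cardinality = "fixed"}.
#' @param seed RNG seed; the whole trajectory is reproducible.
#' @param inner options for \code{\link{solve_fixed_targets}}.
#' @return list of class \code{nhde_config}.
#' @export
nhde_config <- function(pop_size = 20, F = 0.5, CR = 0.8, generations = 200,
                        migration_threshold = 0.1, acceleration_steps = 4,
                        cardinality = c("free", "fixed"), K = NULL, seed = 1,
                        inner = list(n_starts = 4, maxit = 120)) {
  cardinality <- match.arg(cardinality)
  if (pop_size < 4) stop("pop_size must be at least 4")
  if (CR <= 0 || CR > 1) stop("CR must lie in (0, 1]")
  if (cardinality == "fixed" && is.null(K)) stop("fixed cardinality needs K")
  structure(list(pop_size = pop_size, F = F, CR = CR, generations = generations,
                 migration_threshold = migration_threshold,
                 acceleration_steps = acceleration_steps,
                 cardinality = cardinality, K = K, seed = seed, inner = inner),
            class = "nhde_config")
}

# order-independent integer hash of a subset, used to derive per-subset
# inner seeds so that evaluation order (or parallel scheduling) cannot
# change results
subset_hash <- function(idx, base_seed) {
  if (!length(idx)) return((base_seed * 2654435L) %% 2147483647L)
  h <- sum((sort(idx) * 2654435L) %% 2147483647L + sort(idx)^2)
  as.integer((base_seed + h) %% 2147483647L)
}

# decode a code vector (0 = empty slot) into a sorted unique subset
code_to_subset <- function(code) sort(unique(code[code > 0]))

# sample() without the scalar-x surprise
safe_sample <- function(x, k) {
  if (length(x) == 1) rep(x, k) else sample(x, k)
}

# repair duplicates / out-of-range entries in place, keeping determinism
repair_code <- function(code, m, lo) {
  code <- round(code)
  code[code < lo] <- lo
  code[code > m] <- m
  nz <- code > 0
  dup <- duplicated(code) & nz
  if (any(dup)) {
    unused <- setdiff(seq_len(m), code[nz & !dup])
    for (i in which(dup)) {
      if (length(unused)) {
        pick <- safe_sample(unused, 1)
        code[i] <- pick
        unused <- setdiff(unused, pick)
      } else code[i] <- if (lo == 0) 0 else code[i]
    }
  }
  code
}

#' Nested hybrid differential evolution over target subsets
#'
#' Searches subsets of regulable targets for the design maximizing the
#' target-count factor times the optimal \eqn{\lambda} of the inner
#' continuous problem. Selection is two-step: a one-to-one competition
#' between each parent and its trial (ties broken toward fewer targets,
#' then lexicographically), followed by an incumbent update. The best
#' fitness is non-decreasing across generations.
#'
#' @param problem a \code{decision_problem}.
#' @param config an \code{\link{nhde_config}}.
#' @param preset character vector of target names forced into every
#'   candidate (combination designs); counted in the target total.
#' @return list of class \code{nhde_result}: \code{best} (a
#'   \code{design_point} extended with \code{fitness}), \code{archive}
#'   (data frame: subset, n_targets, lambda, T, A, V, overall),
#'   \code{trace} (per-generation best fitness and diversity).
#' @export
nhde_search <- function(problem, config = nhde_config(), preset = character(0)) {
  sets <- problem$sets
  reg <- regulable_targets(problem$network, sets)
  pool <- setdiff(reg$all, preset)
  if (!length(reg$all)) stop("no regulable targets")
  bad <- setdiff(preset, reg$all)
  if (length(bad)) stop("preset targets not regulable: ", paste(bad, collapse = ", "))
  m <- length(pool)
  n_preset <- length(preset)
  L <- if (config$cardinality == "fixed") config$K - n_preset else sets$Z_UB - n_preset
  L <- min(L, m)
  if (L < 0) stop("preset already exceeds the target budget")
  lo <- if (config$cardinality == "fixed") 1L else 0L

  memo <- new.env(parent = emptyenv())
  archive <- list()
  evaluate <- function(idx) {
    subset <- c(preset, pool[idx])
    key <- paste(sort(subset), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (!length(subset)) {
      res <- list(fitness = -Inf, lambda = 0, design = NULL)
    } else {
      inner_opts <- utils::modifyList(config$inner,
                                      list(seed = subset_hash(match(subset, reg$all),
                                                              config$seed)))
      dp <- solve_fixed_targets(problem, subset, inner_opts)
      fit <- target_count_factor(length(subset), sets$Z_UB) * dp$lambda
      res <- list(fitness = fit, lambda = dp$lambda, design = dp)
      archive[[length(archive) + 1]] <<- data.frame(
        subset = key, n_targets = length(subset), lambda = dp$lambda,
        T = dp$report$T, A = dp$report$A, V = dp$report$V,
        overall = fit, stringsAsFactors = FALSE)
    }
    memo[[key]] <- res
    res
  }
  better <- function(a, ca, b, cb) {
    # TRUE if (a, code ca) beats (b, code cb)
    if (abs(a$fitness - b$fitness) > 1e-12) return(a$fitness > b$fitness)
    na <- length(code_to_subset(ca)); nb <- length(code_to_subset(cb))
    if (na != nb) return(na < nb)
    paste(sort(ca), collapse = ",") < paste(sort(cb), collapse = ",")
  }

  set.seed(config$seed)
  NP <- config$pop_size
  rand_code <- function() {
    k <- if (config$cardinality == "fixed") L else sample.int(max(L, 1), 1)
    code <- rep(0L, L)
    if (k > 0 && m > 0) code[seq_len(min(k, m))] <- sample.int(m, min(k, m))
    if (lo == 1L && any(code == 0L)) {
      unused <- setdiff(seq_len(m), code)
      code[code == 0L] <- safe_sample(unused, sum(code == 0L))
    }
    if (n_preset == 0 && all(code == 0L)) code[1] <- sample.int(m, 1)
    code
  }
  pop <- lapply(seq_len(NP), function(i) rand_code())
  fit <- lapply(pop, evaluate)
  bi <- 1
  for (i in seq_len(NP)) if (better(fit[[i]], pop[[i]], fit[[bi]], pop[[bi]])) bi <- i
  best <- list(code = pop[[bi]], res = fit[[bi]])
  trace <- data.frame(generation = 0, best_fitness = best$res$fitness,
                      diversity = length(unique(vapply(pop, paste, character(1),
                                                       collapse = ","))) / NP)

  for (gen in seq_len(config$generations)) {
    if (L > 0 && m > 1) {
      for (i in seq_len(NP)) {
        rs <- sample(setdiff(seq_len(NP), i), 3)
        mutant <- pop[[rs[1]]] + config$F * (pop[[rs[2]]] - pop[[rs[3]]])
        # reflect into [lo, m] by a triangle wave before rounding
        span <- m - lo
        if (span > 0) {
          r <- (mutant - lo) %% (2 * span)
          r[r > span] <- 2 * span - r[r > span]
          mutant <- lo + r
        } else mutant <- rep(lo, L)
        cross <- stats::runif(L) < config$CR
        cross[sample.int(L, 1)] <- TRUE
        trial <- ifelse(cross, mutant, pop[[i]])
        trial <- repair_code(trial, m, lo)
        if (n_preset == 0 && all(trial == 0L)) trial[sample.int(L, 1)] <- sample.int(m, 1)
        tf <- evaluate(trial)
        if (better(tf, trial, fit[[i]], pop[[i]])) {
          pop[[i]] <- trial; fit[[i]] <- tf
        }
        if (better(fit[[i]], pop[[i]], best$res, best$code))
          best <- list(code = pop[[i]], res = fit[[i]])
      }
      # acceleration: one-swap hill climb on the incumbent
      for (a in seq_len(config$acceleration_steps)) {
        if (L == 0) break
        cand <- best$code
        slot <- sample.int(L, 1)
        repl <- sample.int(m + ifelse(lo == 0, 1, 0), 1) - ifelse(lo == 0, 1, 0)
        cand[slot] <- repl
        cand <- repair_code(cand, m, lo)
        if (n_preset == 0 && all(cand == 0L)) next
        cf <- evaluate(cand)
        if (better(cf, cand, best$res, best$code)) best <- list(code = cand, res = cf)
      }
      # migration: re-seed all but the incumbent on diversity collapse
      div <- length(unique(vapply(pop, paste, character(1), collapse = ","))) / NP
      if (div < config$migration_threshold) {
        keep <- which.max(vapply(fit, function(f) f$fitness, numeric(1)))
        for (i in setdiff(seq_len(NP), keep)) {
          pop[[i]] <- rand_code()
          fit[[i]] <- evaluate(pop[[i]])
          if (better(fit[[i]], pop[[i]], best$res, best$code))
            best <- list(code = pop[[i]], res = fit[[i]])
        }
      }
    } else div <- 1
    trace <- rbind(trace, data.frame(generation = gen,
                                     best_fitness = best$res$fitness,
                                     diversity = div))
  }
  design <- best$res$design
  if (is.null(design)) {
    design <- structure(list(targets = character(0), values = numeric(0),
                             state = NULL, report = NULL, lambda = 0,
                             overall = 0, feasible = FALSE),
                        class = "design_point")
  }
  design$fitness <- best$res$fitness
  archive_df <- if (length(archive)) do.call(rbind, archive) else
    data.frame(subset = character(0), n_targets = integer(0), lambda = numeric(0),
               T = numeric(0), A = numeric(0), V = numeric(0), overall = numeric(0))
  structure(list(best = design, archive = archive_df, trace = trace,
                 config = config, preset = preset),
            class = "nhde_result")
}

#' @export
print.nhde_result <- function(x, ...) {
  cat(sprintf("NHDE result: best {%s} fitness=%.3f (%d subsets evaluated)\n",
              paste(x$best$targets, collapse = ", "), x$best$fitness,
              nrow(x$archive)))
  invisible(x)
}

#' Sweep the best design over fixed target-set sizes
#'
#' Runs one fixed-cardinality search per requested subset size and
#' tabulates the per-size optima, mirroring the comparison of design
#' quality against the number of regulated enzymes.
#'
#' @param problem a \code{decision_problem}.
#' @param K_list integer vector of subset sizes.
#' @param config base \code{\link{nhde_config}} (cardinality is overridden).
#' @return list with \code{designs} (per-K \code{design_point}s) and
#'   \code{table} (data frame: K, subset, lambda, T, A, V, overall).
#' @export
fixed_cardinality_sweep <- function(problem, K_list, config = nhde_config()) {
  designs <- list(); rows <- list()
  for (K in K_list) {
    cfg <- config; cfg$cardinality <- "fixed"; cfg$K <- K
    res <- nhde_search(problem, cfg)
    designs[[as.character(K)]] <- res$best
    rows[[length(rows) + 1]] <- data.frame(
      K = K, subset = paste(res$best$targets, collapse = "|"),
      lambda = res$best$lambda, T = res$best$report$T, A = res$best$report$A,
      V = res$best$report$V, overall = res$best$fitness,
      stringsAsFactors = FALSE)
  }
  list(designs = designs, table = do.call(rbind, rows))
}

#' Search for targets complementing a treatment preset
#'
#' Forces the preset targets (a drug class's known targets) into every
#' candidate and searches only the complementary targets; the preset
#' regulations are co-optimized by the inner solve. With an empty preset
#' this is identical to \code{\link{nhde_search}}; with nothing left free
#' it reduces to evaluating the preset itself.
#'
#' @inheritParams nhde_search
#' @param preset_targets character vector of forced target names.
#' @return an \code{nhde_result}.
#' @export
combination_search <- function(problem, preset_targets, config = nhde_config()) {
  nhde_search(problem, config, preset = preset_targets)
}
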