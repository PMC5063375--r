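#' Read a GMA model from JSON
#'
#' The model format lists \code{species} (name, basal), \code{reactions}
#' (name, alpha, \code{orders}: map species to kinetic order, \code{stoich}:
#' map species to stoichiometric coefficient), and \code{controls} (name,
#' basal, \code{stoich}: map species to connectivity coefficient). Optional
#' \code{independents} (constant quantities absorbed into the rate
#' constants) and \code{meta} blocks are carried through as metadata.
#'
#' @param path path to a model JSON file.
#' @param check verify basal-state consistency on load.
#' @return a \code{gma_network}.
#' @export
read_gma_model <- function(path, check = TRUE) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sp <- vapply(j$species, `[[`, character(1), "name")
  xb <- vapply(j$species, function(s) as.numeric(s$basal), numeric(1))
  rn <- vapply(j$reactions, `[[`, character(1), "name")
  alpha <- vapply(j$reactions, function(r) as.numeric(r$alpha), numeric(1))
  n <- length(sp); r <- length(rn)
  N <- matrix(0, n, r); G <- matrix(0, r, n)
  for (k in seq_len(r)) {
    rx <- j$reactions[[k]]
    for (nm in names(rx$stoich)) {
      i <- match(nm, sp)
      if (is.na(i)) stop("unknown species in stoich of ", rn[k], ": ", nm)
      N[i, k] <- as.numeric(rx$stoich[[nm]])
    }
    for (nm in names(rx$orders)) {
      i <- match(nm, sp)
      if (is.na(i)) stop("unknown species in orders of ", rn[k], ": ", nm)
      G[k, i] <- as.numeric(rx$orders[[nm]])
    }
  }
  cn <- character(0); ub <- numeric(0); B <- matrix(0, n, 0)
  if (!is.null(j$controls) && length(j$controls)) {
    cn <- vapply(j$controls, `[[`, character(1), "name")
    ub <- vapply(j$controls, function(cc) as.numeric(cc$basal), numeric(1))
    B <- matrix(0, n, length(cn))
    for (k in seq_along(cn)) {
      for (nm in names(j$controls[[k]]$stoich)) {
        i <- match(nm, sp)
        if (is.na(i)) stop("unknown species in control ", cn[k], ": ", nm)
        B[i, k] <- as.numeric(j$controls[[k]]$stoich[[nm]])
      }
    }
  }
  meta <- if (is.null(j$meta)) list() else j$meta
  if (!is.null(j$independents)) meta$independents <- j$independents
  gma_network(sp, rn, cn, N = N, B = B, G = G, alpha_basal = alpha,
              u_basal = ub, x_basal = xb, meta = meta, check = check)
}

#' Write a GMA model to JSON
#'
#' Inverse of \code{\link{read_gma_model}}; zero entries of the matrices
#' are omitted from the maps.
#'
#' @param network a \code{gma_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gma_model <- function(network, path) {
  sp <- network$species_names
  nz_map <- function(vals, nms) {
    keep <- which(vals != 0)
    if (!length(keep)) return(stats::setNames(list(), character(0)))
    as.list(stats::setNames(vals[keep], nms[keep]))
  }
  species <- lapply(seq_along(sp), function(i)
    list(name = sp[i], basal = network$x_basal[[i]]))
  reactions <- lapply(seq_along(network$reaction_names), function(k)
    list(name = network$reaction_names[k],
         alpha = network$alpha_basal[[k]],
         orders = nz_map(network$G[k, ], sp),
         stoich = nz_map(network$N[, k], sp)))
  controls <- lapply(seq_along(network$control_names), function(k)
    list(name = network$control_names[k],
         basal = network$u_basal[[k]],
         stoich = nz_map(network$B[, k], sp)))
  meta <- network$meta
  indep <- meta$independents
  meta$independents <- NULL
  out <- list(species = species, reactions = reactions, controls = controls)
  if (!is.null(indep)) out$independents <- indep
  if (length(meta)) out$meta <- meta
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export the N, B and G matrices as TSV files for audit
#'
#' @param network a \code{gma_network}.
#' @param dir output directory (created if missing); files are
#'   \code{N.tsv}, \code{B.tsv}, \code{G.tsv}.
#' @return the directory, invisibly.
#' @export
write_gma_matrices <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(mat, file) {
    df <- data.frame(name = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(network$N, "N.tsv"); wt(network$B, "B.tsv"); wt(network$G, "G.tsv")
  invisible(dir)
}

#' Read a scenario file (YAML or JSON)
#'
#' A scenario names disease restrictions (\code{disease}: list of
#' \code{reaction}/\code{delta_percent} pairs), optional fixed or
#' optimizable treatments (\code{treatment}: list of \code{target} with
#' \code{value} for a fixed level), optional objective sets
#' (\code{objectives}: \code{TE}/\code{AE}/\code{VE} lists) and
#' \code{Z_UB}.
#'
#' @param path YAML or JSON file path.
#' @return list with the parsed fields.
#' @export
read_scenario <- function(path) {
  s <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  s
}

# resolve a parsed scenario file into a perturbation for a given network
scenario_to_perturbation <- function(network, scenario) {
  pert <- perturbation()
  for (d in scenario$disease) {
    pert <- combine_perturbations(pert,
      apply_deficiency(network, d$reaction, d$delta_percent))
  }
  fixed <- numeric(0)
  for (tr in scenario$treatment) {
    if (!is.null(tr$value)) fixed <- c(fixed, stats::setNames(tr$value, tr$target))
  }
  if (length(fixed)) {
    af <- fixed[names(fixed) %in% network$reaction_names]
    cv <- fixed[names(fixed) %in% network$control_names]
    pert <- combine_perturbations(pert,
      perturbation(activity_fold = af, controls = cv))
  }
  pert
}

#' Write a steady state with fold changes as a TSV table
#'
#' @param state a \code{gma_steady_state}.
#' @param reference reference state for folds (typically healthy).
#' @param path output TSV path.
#' @return the fold-change species table, invisibly.
#' @export
write_state_table <- function(state, reference, path) {
  fc <- fold_changes(state, reference)
  tab <- fc$species
  tab$status <- ifelse(state$effectively_zero[tab$name], "effectively_zero",
                       tab$status)
  utils::write.table(format_numeric_df(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Write a grade report as a TSV table
#'
#' One row per graded objective: name, class (T/A/V), value basis and
#' grade, followed by summary rows for the class minima, \eqn{\lambda}
#' and the overall objective.
#'
#' @param report a \code{grade_report}.
#' @param path output TSV path.
#' @return the data frame written, invisibly.
#' @export
write_grade_report <- function(report, path) {
  df <- data.frame(name = names(report$grades), class = report$class,
                   grade = round(unname(report$grades), 3),
                   stringsAsFactors = FALSE)
  summary <- data.frame(name = c("T", "A", "V", "lambda", "overall"),
                        class = "summary",
                        grade = round(c(report$T, report$A, report$V,
                                        report$lambda, report$overall), 3),
                        stringsAsFactors = FALSE)
  out <- rbind(df, summary)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

format_numeric_df <- function(df, digits = 3) {
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- round(df[[nm]], digits)
  df
}
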