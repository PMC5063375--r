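#' Closed-form toy network
#'
#' Two species, three reactions: a constant influx \eqn{v_1 = \alpha_1}
#' (zero kinetic orders), a transfer
#' \eqn{v_2 = \alpha_2 x_1^{0.5}} and an efflux
#' \eqn{v_3 = \alpha_3 x_2^{0.5}}. The steady state has the closed form
#' \eqn{x_1 = (\alpha_1/\alpha_2)^2}, \eqn{x_2 = (\alpha_1/\alpha_3)^2},
#' which makes the network a convenient solver oracle.
#'
#' @param alpha rate constants, length 3; default \code{c(1, 1, 2)} giving
#'   steady state \code{c(1, 0.25)}.
#' @return a consistent \code{gma_network}.
#' @export
toy_network <- function(alpha = c(1, 1, 2)) {
  stopifnot(length(alpha) == 3, all(alpha > 0))
  x_star <- c((alpha[1] / alpha[2])^2, (alpha[1] / alpha[3])^2)
  gma_network(
    species_names = c("S1", "S2"),
    reaction_names = c("r_in", "r_tr", "r_out"),
    N = matrix(c(1, 0, -1, 1, 0, -1), nrow = 2,
               dimnames = list(NULL, NULL)),
    G = matrix(c(0, 0, 0.5, 0, 0, 0.5), nrow = 3, byrow = TRUE),
    alpha_basal = alpha,
    x_basal = x_star,
    meta = list(closed_form = "x1=(a1/a2)^2, x2=(a1/a3)^2")
  )
}

# Solve total species throughputs for a routed flux network.
# edges: data.frame(src, dst (list-col of integer vectors), weight); every
# species' outgoing weights sum to 1 (its last outgoing edge may be a pure
# efflux with empty dst). Source reactions have src = NA and carry a
# prescribed flux in `weight`; they only feed their destinations.
# ext: external (control) inflow per species. Throughput t of a species
# satisfies t = ext + sources + W^T t, where W_{s,d} sums edge weights
# from s to d.
route_fluxes <- function(n, edges, ext) {
  W <- matrix(0, n, n)
  for (i in seq_len(nrow(edges))) {
    s <- edges$src[i]
    if (is.na(s)) {
      for (d in edges$dst[[i]]) ext[d] <- ext[d] + edges$weight[i]
    } else {
      for (d in edges$dst[[i]]) W[s, d] <- W[s, d] + edges$weight[i]
    }
  }
  t_through <- solve(diag(n) - t(W), ext)
  if (any(t_through <= 0)) stop("flux routing produced a nonpositive throughput")
  flux <- ifelse(is.na(edges$src), edges$weight,
                 edges$weight * t_through[pmax(edges$src, 1L)])
  list(throughput = t_through, flux = flux)
}

# Assemble a consistent gma_network from routed fluxes: alpha is chosen as
# flux / prod(x^g) so the designated state balances exactly.
gma_from_fluxes <- function(species, x_basal, edges, flux, controls, meta = list()) {
  n <- length(species)
  r <- nrow(edges)
  N <- matrix(0, n, r)
  G <- matrix(0, r, n)
  for (i in seq_len(r)) {
    if (!is.na(edges$src[i])) {
      N[edges$src[i], i] <- N[edges$src[i], i] - 1
      G[i, edges$src[i]] <- edges$order[i]
    }
    for (d in edges$dst[[i]]) N[d, i] <- N[d, i] + 1
    mods <- edges$modifier[[i]]
    if (length(mods)) for (nm in names(mods)) {
      j <- match(nm, species)
      G[i, j] <- G[i, j] + mods[[nm]]
    }
  }
  denom <- vapply(seq_len(r), function(i) prod(x_basal^G[i, ]), numeric(1))
  alpha <- flux / denom
  m <- length(controls$names)
  B <- matrix(0, n, m)
  if (m) for (k in seq_len(m)) B[controls$into[k], k] <- 1
  gma_network(species, edges$name, controls$names, N = N, B = B, G = G,
              alpha_basal = alpha, u_basal = controls$basal,
              x_basal = x_basal, meta = meta)
}

#' Generate a random consistent GMA network
#'
#' Draws a layered pathway topology (a main chain with a downstream toxic
#' byproduct branch and random extra forward edges), a target steady state,
#' and kinetic orders, then back-solves each rate constant as the assigned
#' steady flux divided by the power-law product, so the designated state
#' balances to machine precision. The first external control carries the
#' pathway influx; any further controls are zero-basal dosing inputs wired
#' to random species.
#'
#' @param n_species number of species (at least 4). The last species is a
#'   toxic byproduct fed from the middle of the chain, so therapeutic and
#'   adverse objectives are both exercisable.
#' @param n_controls number of external controls (at least 1).
#' @param n_extra extra random forward transfer edges.
#' @param order_range magnitude range for substrate kinetic orders.
#' @param seed RNG seed; the same seed reproduces the same network.
#' @return a consistent \code{gma_network}. Metadata records the
#'   therapeutic species (end of the main chain) and the toxic byproduct.
#' @export
generate_random_gma <- function(n_species = 6, n_controls = 1, n_extra = 2,
                                order_range = c(0.3, 1), seed = 1) {
  stopifnot(n_species >= 4, n_controls >= 1)
  set.seed(seed)
  n <- n_species
  chain <- seq_len(n - 1)                      # main path
  toxin <- n
  branch_src <- max(2, floor((n - 1) / 2))
  species <- c(paste0("X", chain), "TOX")
  x_basal <- exp(stats::runif(n, log(0.5), log(2)))

  edges <- list()
  add_edge <- function(src, dst, weight) {
    edges[[length(edges) + 1]] <<- list(src = src, dst = dst, weight = weight)
  }
  # outgoing weights per species: transfers plus a terminal efflux
  for (s in chain) {
    dsts <- list()
    if (s < n - 1) dsts <- c(dsts, list(s + 1))
    if (s == branch_src) dsts <- c(dsts, list(toxin))
    k_extra <- 0
    if (n_extra > 0 && s < n - 1) {
      cand <- setdiff(seq(s + 1, n - 1), unlist(dsts))
      k_extra <- min(length(cand), stats::rbinom(1, 1, min(1, n_extra / (n - 2))))
      if (k_extra > 0) dsts <- c(dsts, as.list(sample(cand, k_extra)))
    }
    k <- length(dsts) + 1                      # + efflux
    w <- stats::runif(k, 0.5, 1.5)
    w[k] <- max(w[k], 0.25 * sum(w))           # efflux keeps >= ~20 % share
    w <- w / sum(w)
    for (j in seq_along(dsts)) add_edge(s, dsts[[j]], w[j])
    add_edge(s, integer(0), w[k])
  }
  add_edge(toxin, integer(0), 1)               # toxin cleared

  ed <- data.frame(src = vapply(edges, function(e) as.integer(e$src), integer(1)),
                   weight = vapply(edges, `[[`, numeric(1), "weight"))
  ed$dst <- lapply(edges, function(e) as.integer(e$dst))
  ed$order <- stats::runif(nrow(ed), order_range[1], order_range[2])
  ed$modifier <- rep(list(NULL), nrow(ed))
  ed$name <- paste0("a", seq_len(nrow(ed)))

  ext <- numeric(n); ext[1] <- 1               # influx via control 1
  routed <- route_fluxes(n, ed, ext)
  ctrl_names <- paste0("u", seq_len(n_controls))
  into <- c(1L, if (n_controls > 1) sample(seq_len(n - 1), n_controls - 1, replace = TRUE))
  controls <- list(names = ctrl_names, into = into,
                   basal = c(1, rep(0, n_controls - 1)))
  net <- gma_from_fluxes(species, x_basal, ed, routed$flux, controls,
                         meta = list(therapeutic = species[n - 1],
                                     toxic = "TOX", seed = seed))
  if (!net$consistent) stop("generated network failed its consistency check")
  net
}
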