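#' Construct a generalized mass-action (GMA) network
#'
#' A GMA network couples a stoichiometric description of a metabolic map to
#' power-law kinetics: every reaction rate is \eqn{v_k = \alpha_k \prod_l
#' x_l^{g_{kl}}}, where \eqn{\alpha_k} is the rate constant (enzyme activity)
#' and \eqn{g_{kl}} real-valued kinetic orders. External controls \code{u}
#' enter the material balance linearly through a connectivity matrix \code{B},
#' so that \eqn{dx/dt = N v(x, \alpha) + B u}.
#'
#' @param species_names character vector of n species identifiers.
#' @param reaction_names character vector of r reaction identifiers.
#' @param control_names character vector of m external-control identifiers
#'   (may be empty).
#' @param N n x r stoichiometric matrix.
#' @param B n x m connectivity matrix (n x 0 if there are no controls).
#' @param G r x n matrix of kinetic orders \eqn{g_{kl}}.
#' @param alpha_basal positive basal rate constants, length r.
#' @param u_basal nonnegative basal control values, length m.
#' @param x_basal positive basal (healthy-state) concentrations, length n.
#' @param meta optional list of free-form metadata (e.g. display labels,
#'   records of independent variables absorbed into the rate constants).
#' @param check if \code{TRUE}, verify that the basal state is a steady state
#'   (max-norm residual below \code{1e-8} times the basal flux scale) and tag
#'   the network as consistent.
#'
#' @return An object of class \code{gma_network}.
#' @export
gma_network <- function(species_names, reaction_names, control_names = character(0),
                        N, B = NULL, G, alpha_basal, u_basal = numeric(0),
                        x_basal, meta = list(), check = TRUE) {
  n <- length(species_names)
  r <- length(reaction_names)
  m <- length(control_names)
  N <- as.matrix(N)
  G <- as.matrix(G)
  if (is.null(B)) B <- matrix(0, n, 0)
  B <- as.matrix(B)
  stopifnot(nrow(N) == n, ncol(N) == r,
            nrow(G) == r, ncol(G) == n,
            nrow(B) == n, ncol(B) == m,
            length(alpha_basal) == r, length(u_basal) == m,
            length(x_basal) == n)
  if (any(alpha_basal <= 0)) stop("all basal rate constants must be positive")
  if (any(x_basal <= 0)) stop("all basal concentrations must be positive")
  if (any(u_basal < 0)) stop("basal control values must be nonnegative")
  dimnames(N) <- list(species_names, reaction_names)
  dimnames(G) <- list(reaction_names, species_names)
  dimnames(B) <- list(species_names, control_names)
  net <- structure(list(
    species_names = species_names,
    reaction_names = reaction_names,
    control_names = control_names,
    N = N, B = B, G = G,
    alpha_basal = stats::setNames(as.numeric(alpha_basal), reaction_names),
    u_basal = stats::setNames(as.numeric(u_basal), control_names),
    x_basal = stats::setNames(as.numeric(x_basal), species_names),
    meta = meta,
    consistent = FALSE
  ), class = "gma_network")
  if (check) {
    res <- steady_state_residual(net, net$x_basal, net$alpha_basal, net$u_basal)
    scale <- max(1, flux_scale(net))
    net$consistent <- max(abs(res)) <= 1e-8 * scale
  }
  net
}

# largest basal flux magnitude; used to put residual tolerances on a
# relative scale
flux_scale <- function(net) {
  v <- evaluate_rates(net$x_basal, net$alpha_basal, net$G)
  max(abs(v), abs(net$B %*% net$u_basal), 1e-12)
}

#' @export
print.gma_network <- function(x, ...) {
  cat(sprintf("GMA network: %d species, %d reactions, %d controls%s\n",
              length(x$species_names), length(x$reaction_names),
              length(x$control_names),
              if (isTRUE(x$consistent)) " (consistent at basal state)" else ""))
  invisible(x)
}

#' Evaluate power-law reaction rates
#'
#' Computes \eqn{v_k = \alpha_k \prod_l x_l^{g_{kl}}} for every reaction.
#' The convention \eqn{0^0 = 1} is used, so reactions with zero kinetic order
#' in a species are unaffected by that species even at zero concentration.
#' A zero rate constant silences a reaction (disease knockout).
#'
#' @param x nonnegative concentration vector (length n).
#' @param alpha nonnegative rate constants (length r); zeros are allowed only
#'   for knocked-out reactions.
#' @param G r x n kinetic-order matrix.
#' @return numeric rate vector of length r.
#' @export
evaluate_rates <- function(x, alpha, G) {
  G <- as.matrix(G)
  if (length(x) != ncol(G) || length(alpha) != nrow(G))
    stop("dimension mismatch between x, alpha and G")
  if (any(x < 0)) stop("negative concentration in rate evaluation")
  if (any(alpha < 0)) stop("negative rate constant in rate evaluation")
  v <- as.numeric(alpha)
  for (l in seq_along(x)) {
    g <- G[, l]
    nz <- which(g != 0)
    if (length(nz)) v[nz] <- v[nz] * x[l]^g[nz]  # 0^0 := 1 via skipping g == 0
  }
  stats::setNames(v, rownames(G))
}

#' Steady-state residual of a GMA network
#'
#' Returns the material-balance defect \eqn{N v(x, \alpha) + B u}, one entry
#' per species. At a steady state the residual is zero.
#'
#' @param network a \code{gma_network}.
#' @param x concentration vector.
#' @param alpha rate constants (defaults to basal).
#' @param u control values (defaults to basal).
#' @return named numeric vector of length n.
#' @export
steady_state_residual <- function(network, x, alpha = network$alpha_basal,
                                  u = network$u_basal) {
  v <- evaluate_rates(x, alpha, network$G)
  res <- as.numeric(network$N %*% v)
  if (length(u)) res <- res + as.numeric(network$B %*% u)
  stats::setNames(res, network$species_names)
}

#' Log-transformed kinetic constraints
#'
#' Evaluates the logarithmic form of the power law: with \eqn{y = \log x} and
#' \eqn{\hat\alpha = \log \alpha}, each log-rate is the affine expression
#' \eqn{w_j = \hat\alpha_j + \sum_k g_{jk} y_k} and \eqn{v_j = e^{w_j}},
#' \eqn{x_i = e^{y_i}}. This form avoids the numerical failure of the native
#' power law near zero concentrations and makes the equality constraints of
#' the target-design problem convex in \eqn{(y, \hat\alpha, w)}.
#'
#' @param network a \code{gma_network}.
#' @param y log-concentrations (length n, finite).
#' @param alpha_hat log rate constants (length r, finite).
#' @param u control values (length m).
#' @param exp_limit exponent clip guarding overflow; log-rates beyond the
#'   limit are clamped and reported via the \code{clipped} field.
#' @return list with \code{w} (log-rates), \code{v}, \code{x},
#'   \code{residual} (\eqn{N v + B u}) and \code{clipped} (logical, any
#'   exponent clamped).
#' @export
log_transform_constraints <- function(network, y, alpha_hat,
                                      u = network$u_basal, exp_limit = 500) {
  stopifnot(length(y) == length(network$species_names),
            length(alpha_hat) == length(network$reaction_names))
  w <- as.numeric(alpha_hat) + as.numeric(network$G %*% y)
  clipped <- any(abs(w) > exp_limit) || any(abs(y) > exp_limit)
  w_c <- pmin(pmax(w, -exp_limit), exp_limit)
  y_c <- pmin(pmax(y, -exp_limit), exp_limit)
  v <- exp(w_c)
  x <- exp(y_c)
  res <- as.numeric(network$N %*% v)
  if (length(u)) res <- res + as.numeric(network$B %*% u)
  list(w = stats::setNames(w, network$reaction_names),
       v = stats::setNames(v, network$reaction_names),
       x = stats::setNames(x, network$species_names),
       residual = stats::setNames(res, network$species_names),
       clipped = clipped)
}
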