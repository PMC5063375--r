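#' Membership specification for a fuzzy objective
#'
#' A fuzzy-\emph{equal} objective grades how close a quantity stays to its
#' basal (healthy) value: the grade is 0 at or beyond the outer bounds,
#' 1 on the basal plateau, and rises/falls monotonically in between. A
#' fuzzy-\emph{minimize} objective grades how well a quantity is kept low:
#' 1 at or below basal, falling monotonically to 0 at the upper bound.
#'
#' Five monotone branch shapes are supported (linear, exponential,
#' hyperbolic, inverse, piecewise-linear); all map the normalised position
#' within the branch through a monotone bijection of \code{[0, 1]}. The
#' linear shape is the default.
#'
#' @param kind \code{"equal"} or \code{"minimize"}.
#' @param x_LB lower zero-grade bound (equal only).
#' @param x_basal_LB,x_basal_UB plateau bounds; for \code{minimize},
#'   only the plateau end \code{x_basal_UB} is used (grade 1 at or below it)
#'   and \code{x_basal_LB} defaults to it.
#' @param x_UB upper zero-grade bound.
#' @param shape branch shape; one of \code{"linear"}, \code{"exponential"},
#'   \code{"hyperbolic"}, \code{"inverse"}, \code{"piecewise-linear"}.
#' @param shape_param positive curvature parameter for the non-linear
#'   shapes; for \code{"piecewise-linear"}, a two-column matrix of interior
#'   knots \code{(t, d)}.
#' @return object of class \code{membership_spec}.
#' @export
membership_spec <- function(kind = c("equal", "minimize"),
                            x_LB = NA_real_, x_basal_LB = NA_real_,
                            x_basal_UB, x_UB,
                            shape = c("linear", "exponential", "hyperbolic",
                                      "inverse", "piecewise-linear"),
                            shape_param = 2) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  if (kind == "minimize") {
    if (is.na(x_basal_LB)) x_basal_LB <- x_basal_UB
    if (is.na(x_LB)) x_LB <- -Inf
  }
  bp <- c(x_LB, x_basal_LB, x_basal_UB, x_UB)
  if (any(is.na(bp))) stop("breakpoints must all be given for kind = 'equal'")
  if (is.unsorted(bp)) stop("breakpoints must satisfy x_LB <= x_basal_LB <= x_basal_UB <= x_UB")
  structure(list(kind = kind, x_LB = x_LB, x_basal_LB = x_basal_LB,
                 x_basal_UB = x_basal_UB, x_UB = x_UB,
                 shape = shape, shape_param = shape_param),
            class = "membership_spec")
}

# monotone bijection of [0,1] used for membership branches
branch_shape <- function(t, shape, p) {
  t <- pmin(pmax(t, 0), 1)
  switch(shape,
    "linear" = t,
    "exponential" = (1 - exp(-p * t)) / (1 - exp(-p)),
    "hyperbolic" = (tanh(p * (t - 0.5)) + tanh(p / 2)) / (2 * tanh(p / 2)),
    "inverse" = t / (t + p * (1 - t)),
    "piecewise-linear" = {
      if (is.matrix(p)) {
        knots_t <- c(0, p[, 1], 1); knots_d <- c(0, p[, 2], 1)
        stats::approx(knots_t, knots_d, xout = t, rule = 2)$y
      } else t
    },
    stop("unknown shape: ", shape))
}

#' Satisfaction grade of a fuzzy-equal objective
#'
#' Grade 1 on the basal plateau, strictly monotone on the rising and
#' falling branches, 0 at or beyond the outer bounds.
#'
#' @param value numeric vector of graded quantities.
#' @param spec a \code{membership_spec} with \code{kind = "equal"}.
#' @return grades in \code{[0, 1]}, same length as \code{value}.
#' @export
fuzzy_equal_grade <- function(value, spec) {
  stopifnot(inherits(spec, "membership_spec"), spec$kind == "equal")
  g <- numeric(length(value))
  on_plateau <- value >= spec$x_basal_LB & value <= spec$x_basal_UB
  g[on_plateau] <- 1
  left <- value > spec$x_LB & value < spec$x_basal_LB
  if (any(left)) {
    t <- (value[left] - spec$x_LB) / (spec$x_basal_LB - spec$x_LB)
    g[left] <- branch_shape(t, spec$shape, spec$shape_param)
  }
  right <- value > spec$x_basal_UB & value < spec$x_UB
  if (any(right)) {
    t <- (spec$x_UB - value[right]) / (spec$x_UB - spec$x_basal_UB)
    g[right] <- branch_shape(t, spec$shape, spec$shape_param)
  }
  g
}

#' Satisfaction grade of a fuzzy-minimize objective
#'
#' Grade 1 at or below the basal value, strictly monotone decreasing up to
#' the upper bound, 0 at or beyond it.
#'
#' @inheritParams fuzzy_equal_grade
#' @param spec a \code{membership_spec} with \code{kind = "minimize"}.
#' @return grades in \code{[0, 1]}.
#' @export
fuzzy_min_grade <- function(value, spec) {
  stopifnot(inherits(spec, "membership_spec"), spec$kind == "minimize")
  g <- numeric(length(value))
  g[value <= spec$x_basal_UB] <- 1
  mid <- value > spec$x_basal_UB & value < spec$x_UB
  if (any(mid)) {
    t <- (spec$x_UB - value[mid]) / (spec$x_UB - spec$x_basal_UB)
    g[mid] <- branch_shape(t, spec$shape, spec$shape_param)
  }
  g
}

#' Grade a value under any membership specification
#' @inheritParams fuzzy_equal_grade
#' @return grades in \code{[0, 1]}.
#' @export
membership_grade <- function(value, spec) {
  if (spec$kind == "equal") fuzzy_equal_grade(value, spec)
  else fuzzy_min_grade(value, spec)
}
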