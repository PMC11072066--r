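# Triangular and percentile-anchored ("Trigen") triangular distributions.
# These are the uncertainty primitives of the sensitivity analyses; no
# installed package provides them, so density/CDF/quantile/sampler are
# implemented here and checked against closed forms and an independent
# numerical oracle in the test suite.

#' Triangular distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the triangular distribution with support `[min, max]` and mode `mode`.
#' Sampling is by inverse-CDF applied to a uniform draw, so a fixed RNG seed
#' reproduces draws exactly. The degenerate case `min == max` is treated as a
#' point mass (every draw returns the constant).
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param min,mode,max Distribution parameters, `min <= mode <= max`.
#' @return `dtri` the density, `ptri` the CDF, `qtri` the quantile function,
#'   `rtri` random draws.
#' @name triangular
NULL

check_tri_params <- function(min, mode, max) {
  stopifnot(length(min) == 1L, length(mode) == 1L, length(max) == 1L)
  if (is.na(min) || is.na(mode) || is.na(max) || min > mode || mode > max) {
    stop("triangular parameters must satisfy min <= mode <= max", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname triangular
#' @export
dtri <- function(x, min, mode, max) {
  check_tri_params(min, mode, max)
  if (min == max) return(ifelse(x == min, Inf, 0))
  out <- numeric(length(x))
  left <- x >= min & x < mode
  right <- x >= mode & x <= max
  if (mode > min) {
    out[left] <- 2 * (x[left] - min) / ((max - min) * (mode - min))
  }
  if (max > mode) {
    out[right] <- 2 * (max - x[right]) / ((max - min) * (max - mode))
  } else {
    out[x == mode] <- 2 / (max - min)
  }
  out
}

#' @rdname triangular
#' @export
ptri <- function(q, min, mode, max) {
  check_tri_params(min, mode, max)
  if (min == max) return(as.numeric(q >= min))
  out <- numeric(length(q))
  out[q >= max] <- 1
  left <- q > min & q <= mode
  right <- q > mode & q < max
  if (mode > min) {
    out[left] <- (q[left] - min)^2 / ((max - min) * (mode - min))
  } else {
    out[left] <- 0   # unreachable: q <= mode == min already handled
  }
  out[right] <- 1 - (max - q[right])^2 / ((max - min) * (max - mode))
  out
}

#' @rdname triangular
#' @export
qtri <- function(p, min, mode, max) {
  check_tri_params(min, mode, max)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (min == max) return(rep(min, length(p)))
  pm <- (mode - min) / (max - min)   # CDF at the mode
  out <- numeric(length(p))
  left <- p <= pm
  out[left] <- min + sqrt(p[left] * (max - min) * (mode - min))
  out[!left] <- max - sqrt((1 - p[!left]) * (max - min) * (max - mode))
  out
}

#' @rdname triangular
#' @export
rtri <- function(n, min, mode, max) {
  qtri(stats::runif(n), min, mode, max)
}

#' Triangular uncertainty specification
#'
#' @param minimum,mode,maximum Support and mode, `minimum <= mode <= maximum`.
#'   A fully degenerate spec (`minimum == maximum`) is allowed and denotes a
#'   point mass, used when collapsing a probabilistic analysis to its base
#'   case.
#' @return An object of class `vt_triangular`.
#' @export
triangular_spec <- function(minimum, mode, maximum) {
  check_tri_params(minimum, mode, maximum)
  if (minimum == maximum && minimum != mode) {
    stop("degenerate spec requires minimum == mode == maximum", call. = FALSE)
  }
  structure(list(minimum = as.numeric(minimum), mode = as.numeric(mode),
                 maximum = as.numeric(maximum)),
            class = c("vt_triangular", "vt_dist"))
}

#' Percentile-anchored triangular ("Trigen") specification
#'
#' Describes a triangular distribution by its most-likely value plus a lower
#' and an upper value anchored at stated percentiles (conventionally the 5th
#' and 95th), rather than by its support. This is the convention of the risk
#' analysis software used for published probabilistic sensitivity analyses;
#' recovering the actual support requires inverting the triangular CDF (see
#' [trigen_to_triangular()]).
#'
#' @param lower_anchor Value at `lower_percentile`.
#' @param mode Most-likely value, `lower_anchor <= mode <= upper_anchor`.
#' @param upper_anchor Value at `upper_percentile`.
#' @param lower_percentile,upper_percentile Percentiles in \[0, 100\],
#'   `lower_percentile < upper_percentile`. Defaults 5 and 95.
#' @return An object of class `vt_trigen`.
#' @export
trigen_spec <- function(lower_anchor, mode, upper_anchor,
                        lower_percentile = 5, upper_percentile = 95) {
  stopifnot(is.numeric(lower_anchor), is.numeric(mode), is.numeric(upper_anchor))
  if (lower_anchor > mode || mode > upper_anchor) {
    stop("trigen spec requires lower_anchor <= mode <= upper_anchor",
         call. = FALSE)
  }
  if (lower_percentile < 0 || upper_percentile > 100 ||
      lower_percentile >= upper_percentile) {
    stop("percentiles must satisfy 0 <= lower < upper <= 100", call. = FALSE)
  }
  structure(list(lower_anchor = as.numeric(lower_anchor),
                 mode = as.numeric(mode),
                 upper_anchor = as.numeric(upper_anchor),
                 lower_percentile = as.numeric(lower_percentile),
                 upper_percentile = as.numeric(upper_percentile)),
            class = c("vt_trigen", "vt_dist"))
}

#' Build a symmetric one-way sensitivity range
#'
#' Constructs the plus/minus `fraction` triangular range around a point
#' estimate used for one-way sensitivity analysis of unit costs (the
#' published analyses use 15 percent). Bounds are kept at full precision;
#' reports round them to the nearest integer currency unit.
#'
#' @param point_estimate Positive base-case value (e.g. a unit cost in QAR).
#' @param fraction Half-width as a proportion of the point estimate, in (0, 1).
#' @return A [triangular_spec()] with mode at the point estimate.
#' @examples
#' make_owsa_range(6678, 0.15)   # support 5676.3 .. 7679.7
#' @export
make_owsa_range <- function(point_estimate, fraction = 0.15) {
  if (!is.numeric(point_estimate) || length(point_estimate) != 1L ||
      is.na(point_estimate) || point_estimate <= 0) {
    stop("point estimate must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction < 1)
  triangular_spec(point_estimate * (1 - fraction), point_estimate,
                  point_estimate * (1 + fraction))
}

trigen_infeasible <- function(msg) {
  structure(class = c("vt_trigen_infeasible", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Recover the triangular support behind a Trigen specification
#'
#' Finds the unique triangular distribution with the given mode whose CDF
#' equals `lower_percentile/100` at `lower_anchor` and `upper_percentile/100`
#' at `upper_anchor`. Each support endpoint is located by root bisection
#' (nested: the upper endpoint is solved conditionally on a candidate lower
#' endpoint) to absolute tolerance `tol`; the returned support reproduces the
#' anchor CDF values to better than 1e-9. With percentiles 0 and 100 the
#' anchors are themselves the support.
#'
#' Note that for anchors near a natural boundary (e.g. a probability anchored
#' at 0 with 5 percent below it), the fitted support extends beyond the
#' boundary by construction; consumers sampling probabilities must handle
#' out-of-range draws (see [run_psa()]).
#'
#' @param spec A [trigen_spec()].
#' @param tol Bisection tolerance on the support endpoints.
#' @return A [triangular_spec()].
#' @examples
#' trigen_to_triangular(trigen_spec(0.3888, 0.5152, 0.6401))
#' @export
trigen_to_triangular <- function(spec, tol = 1e-10) {
  stopifnot(inherits(spec, "vt_trigen"))
  L <- spec$lower_anchor; m <- spec$mode; U <- spec$upper_anchor
  plo <- spec$lower_percentile / 100; phi <- spec$upper_percentile / 100
  if (L == U) return(triangular_spec(L, m, U))   # point mass

  solve_b <- function(a) {
    # F(U; a, m, b) is strictly decreasing in b from 1 (b -> U+) to 0
    h <- function(b) ptri(U, a, m, b) - phi
    lo <- max(U, m) + tol * max(1, abs(U))
    hi <- max(U, m) + (U - a) + 1
    it <- 0L
    while (h(hi) > 0) {
      hi <- max(U, m) + 2 * (hi - max(U, m)); it <- it + 1L
      if (it > 200L) stop(trigen_infeasible(
        "cannot bracket upper support; anchors inconsistent with mode"))
    }
    stats::uniroot(h, c(lo, hi), tol = tol)$root
  }
  solve_a_given_b <- function(b) {
    h <- function(a) ptri(L, a, m, b) - plo
    hi <- min(L, m) - tol * max(1, abs(L))
    lo <- min(L, m) - (U - L) - 1
    it <- 0L
    while (h(lo) < 0) {
      lo <- min(L, m) - 2 * (min(L, m) - lo); it <- it + 1L
      if (it > 200L) stop(trigen_infeasible(
        "cannot bracket lower support; anchors inconsistent with mode"))
    }
    stats::uniroot(h, c(lo, hi), tol = tol)$root
  }

  if (plo <= 0 && phi >= 1) {
    a <- L; b <- U
  } else if (plo <= 0) {
    a <- L; b <- solve_b(a)
  } else if (phi >= 1) {
    b <- U; a <- solve_a_given_b(b)
  } else {
    g <- function(a) ptri(L, a, m, solve_b(a)) - plo
    hi <- min(L, m) - tol * max(1, abs(L))
    lo <- min(L, m) - max(U - L, 1e-3)
    it <- 0L
    while (g(lo) < 0) {
      lo <- min(L, m) - 2 * (min(L, m) - lo); it <- it + 1L
      if (it > 200L) stop(trigen_infeasible(
        "cannot bracket lower support; anchors inconsistent with mode"))
    }
    a <- stats::uniroot(g, c(lo, hi), tol = tol)$root
    b <- solve_b(a)
  }
  fit <- triangular_spec(min(a, m), m, max(b, m))
  achieved <- c(ptri(L, fit$minimum, fit$mode, fit$maximum),
                ptri(U, fit$minimum, fit$mode, fit$maximum))
  if (max(abs(achieved - c(plo, phi))) > 1e-9) {
    stop(trigen_infeasible(sprintf(
      "fit does not reproduce anchor percentiles (achieved %.3g / %.3g)",
      achieved[1], achieved[2])))
  }
  fit
}

# Resolve any uncertainty spec to a plain triangular spec.
as_triangular <- function(spec) {
  if (inherits(spec, "vt_triangular")) return(spec)
  if (inherits(spec, "vt_trigen")) return(trigen_to_triangular(spec))
  stop("unknown distribution spec of class ",
       paste(class(spec), collapse = "/"), call. = FALSE)
}

#' Mean of a triangular specification
#'
#' `(min + mode + max) / 3`; Trigen specs are first converted to their
#' triangular support.
#'
#' @param spec A [triangular_spec()] or [trigen_spec()].
#' @return The distribution mean.
#' @export
tri_mean <- function(spec) {
  s <- as_triangular(spec)
  (s$minimum + s$mode + s$maximum) / 3
}
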