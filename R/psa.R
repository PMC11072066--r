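#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Draws every uncertain parameter independently from its triangular or
#' Trigen distribution, re-evaluates the model arms for each draw, and
#' records cost and effect differences and net monetary benefit for each
#' requested pairwise comparison. Sampling is inverse-CDF on seeded uniform
#' draws, so a fixed seed reproduces the whole sample set bit-for-bit.
#'
#' An iteration whose sampled parameters the model rejects (typically a
#' probability outside \[0, 1\] after renormalizing sibling branches -- which
#' percentile-anchored distributions with anchors at a boundary produce by
#' construction) is discarded and redrawn. Rejections are counted and the
#' run aborts with a diagnostic once they exceed `max_reject_frac * n`.
#'
#' @param model A model function: takes a named numeric vector of sampled
#'   parameter values (names matching `names(specs)`) and returns a data
#'   frame with columns `strategy`, `cost`, `effect` (one row per arm), or
#'   `NULL` to reject the sample. See [scd_psa_model()] for the packaged
#'   three-arm model.
#' @param specs Named list of [triangular_spec()] / [trigen_spec()] objects,
#'   one per sampled parameter.
#' @param n Number of Monte Carlo iterations (default 5000).
#' @param seed Integer seed; required, every run is reproducible from it.
#' @param wtp A [wtp_threshold()] used for the net-monetary-benefit output.
#' @param comparisons List of `c(comparator, reference)` strategy-name pairs.
#'   Default: every ordered pair produced by the first model evaluation,
#'   later arms compared against earlier ones.
#' @param max_reject_frac Abort once rejected iterations exceed this fraction
#'   of `n`. Default 0.5, sized for boundary-anchored Trigen inputs whose
#'   fitted supports unavoidably spill outside \[0, 1\].
#' @return An object of class `vt_psa`: list with `seed`, `n_iterations`,
#'   `input_matrix` (n x parameters), `arms` (n x arms cost and effect
#'   matrices), `comparisons` (named list of data frames with `delta_cost`,
#'   `delta_effect`, `nmb`), `rejections`, `wtp`.
#' @export
run_psa <- function(model, specs, n = 5000, seed, wtp = wtp_threshold(),
                    comparisons = NULL, max_reject_frac = 0.5) {
  stopifnot(is.function(model), is.list(specs), length(specs) >= 1L,
            !is.null(names(specs)), all(nzchar(names(specs))),
            is.numeric(n), length(n) == 1L, n >= 1,
            inherits(wtp, "vt_wtp"))
  if (missing(seed)) stop("run_psa requires an explicit seed", call. = FALSE)
  n <- as.integer(n)
  tri <- lapply(specs, as_triangular)
  pnames <- names(specs)
  set.seed(as.integer(seed))

  draw <- function() {
    u <- stats::runif(length(tri))
    vapply(seq_along(tri), function(j) {
      s <- tri[[j]]
      qtri(u[j], s$minimum, s$mode, s$maximum)
    }, numeric(1))
  }

  first <- NULL
  rejections <- 0L
  max_rej <- max_reject_frac * n
  inputs <- matrix(NA_real_, n, length(tri), dimnames = list(NULL, pnames))
  costs <- NULL; effects <- NULL
  for (i in seq_len(n)) {
    repeat {
      x <- draw(); names(x) <- pnames
      res <- model(x)
      if (!is.null(res)) break
      rejections <- rejections + 1L
      if (rejections > max_rej) {
        stop("PSA aborted: ", rejections, " rejected iterations exceed ",
             "max_reject_frac * n = ", format(max_rej), call. = FALSE)
      }
    }
    if (is.null(first)) {
      first <- res
      costs <- matrix(NA_real_, n, nrow(res), dimnames = list(NULL, res$strategy))
      effects <- costs
    }
    inputs[i, ] <- x
    costs[i, ] <- res$cost
    effects[i, ] <- res$effect
  }

  arms <- first$strategy
  if (is.null(comparisons)) {
    comparisons <- list()
    for (i in seq_along(arms)) for (j in seq_along(arms)) {
      if (j < i) comparisons[[length(comparisons) + 1L]] <- c(arms[i], arms[j])
    }
  }
  comp_out <- list()
  for (cp in comparisons) {
    stopifnot(length(cp) == 2L, all(cp %in% arms))
    dC <- costs[, cp[1]] - costs[, cp[2]]
    dE <- effects[, cp[1]] - effects[, cp[2]]
    comp_out[[paste0(cp[1], "_vs_", cp[2])]] <- data.frame(
      delta_cost = dC, delta_effect = dE, nmb = wtp$value * dE - dC)
  }
  structure(list(seed = as.integer(seed), n_iterations = n,
                 input_matrix = inputs,
                 arms = list(cost = costs, effect = effects),
                 comparisons = comp_out, rejections = rejections,
                 wtp = wtp),
            class = "vt_psa")
}

#' @export
print.vt_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_iterations, "iterations,",
      ncol(x$input_matrix), "parameters, seed", x$seed, "\n")
  cat("  rejected/redrawn iterations:", x$rejections, "\n")
  cat("  comparisons:", paste(names(x$comparisons), collapse = ", "), "\n")
  invisible(x)
}

#' Default willingness-to-pay grid
#'
#' 0 to 1,000,000 QAR in steps of 10,000, always including the 547,500 QAR
#' decision threshold (150,000 USD).
#'
#' @return Sorted numeric vector of thresholds.
#' @export
default_wtp_grid <- function() {
  sort(unique(c(seq(0, 1e6, by = 1e4), 547500)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the proportion of Monte Carlo
#' iterations in which the comparator has positive incremental net monetary
#' benefit (`lambda * dE - dC > 0`), and the proportion in which it strictly
#' dominates (`dE > 0` and `dC < 0`). The dominance proportion never exceeds
#' the cost-effectiveness proportion at any non-negative threshold.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Non-empty numeric vector of thresholds
#'   (default [default_wtp_grid()]).
#' @param comparison Name of the comparison (default: first).
#' @return Data frame with columns `wtp`, `probability_cost_effective`,
#'   `probability_dominant`.
#' @export
ceac <- function(psa, wtp_grid = default_wtp_grid(),
                 comparison = names(psa$comparisons)[1]) {
  stopifnot(inherits(psa, "vt_psa"))
  if (!is.numeric(wtp_grid) || length(wtp_grid) == 0L) {
    stop("wtp_grid must be a non-empty numeric vector", call. = FALSE)
  }
  cmp <- psa$comparisons[[comparison]]
  if (is.null(cmp)) stop("unknown comparison '", comparison, "'", call. = FALSE)
  p_dom <- mean(cmp$delta_effect > 0 & cmp$delta_cost < 0)
  data.frame(
    wtp = wtp_grid,
    probability_cost_effective = vapply(
      wtp_grid, function(l) mean(l * cmp$delta_effect - cmp$delta_cost > 0),
      numeric(1)),
    probability_dominant = p_dom)
}

#' Tornado analysis by standardized regression coefficients
#'
#' Regresses the standardized model output on all standardized sampled
#' inputs by ordinary least squares and ranks parameters by the magnitude of
#' their coefficients (largest first; ties broken alphabetically). Constant
#' input columns and columns dropped by the fit for collinearity are
#' reported with a warning and excluded from the ranking.
#'
#' @param psa A [run_psa()] result with more iterations than parameters + 1.
#' @param output Which output to explain: `"nmb"`, `"delta_cost"` or
#'   `"delta_effect"`.
#' @param comparison Name of the comparison (default: first).
#' @return Data frame with columns `parameter`, `standardized_coefficient`,
#'   `rank` (a permutation of `1..n` by descending magnitude).
#' @export
tornado_regression <- function(psa, output = c("nmb", "delta_cost", "delta_effect"),
                               comparison = names(psa$comparisons)[1]) {
  stopifnot(inherits(psa, "vt_psa"))
  output <- match.arg(output)
  cmp <- psa$comparisons[[comparison]]
  if (is.null(cmp)) stop("unknown comparison '", comparison, "'", call. = FALSE)
  X <- psa$input_matrix
  if (nrow(X) <= ncol(X) + 1L) {
    stop("tornado regression needs more iterations than parameters + 1",
         call. = FALSE)
  }
  y <- cmp[[output]]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant input column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (stats::sd(y) == 0) {
    stop("output '", output, "' is constant across iterations", call. = FALSE)
  }
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  fit <- stats::lm(ys ~ Xs)
  coefs <- stats::coef(fit)[-1]
  names(coefs) <- colnames(X)
  if (anyNA(coefs)) {
    warning("dropping collinear input column(s): ",
            paste(names(coefs)[is.na(coefs)], collapse = ", "))
    coefs <- coefs[!is.na(coefs)]
  }
  ord <- order(-abs(coefs), names(coefs))
  out <- data.frame(parameter = names(coefs)[ord],
                    standardized_coefficient = unname(coefs[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
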