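#' Strategy-level cost-effectiveness result
#'
#' @param strategy Strategy name.
#' @param cost Expected cost per patient per year (model currency).
#' @param effect Effectiveness: probability of avoiding a first pain crisis
#'   within the year, in \[0, 1\].
#' @param currency Currency code, default `"QAR"`.
#' @return An object of class `vt_arm`.
#' @export
arm_result <- function(strategy, cost, effect, currency = "QAR") {
  stopifnot(is.character(strategy), length(strategy) == 1L)
  if (!is.numeric(cost) || length(cost) != 1L || is.na(cost) || cost < 0) {
    stop("expected cost must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(effect) || length(effect) != 1L || is.na(effect) ||
      effect < 0 || effect > 1) {
    stop("effectiveness must lie in [0, 1]", call. = FALSE)
  }
  structure(list(strategy = strategy, cost = as.numeric(cost),
                 effect = as.numeric(effect), currency = currency),
            class = "vt_arm")
}

#' Willingness-to-pay threshold
#'
#' @param value Threshold in currency units per pain crisis averted; positive.
#' @param currency Currency code.
#' @return An object of class `vt_wtp`.
#' @export
wtp_threshold <- function(value = 547500, currency = "QAR") {
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  structure(list(value = as.numeric(value), currency = currency),
            class = "vt_wtp")
}

check_currency <- function(a, b) {
  if (!identical(a, b)) {
    stop("currency mismatch: '", a, "' vs '", b, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Net monetary benefit
#'
#' `NMB = lambda * effectiveness - cost` at willingness-to-pay `lambda`. The
#' strategy maximizing NMB is the cost-effective choice at that threshold.
#'
#' @param arm An [arm_result()].
#' @param wtp A [wtp_threshold()] in the same currency.
#' @return NMB in currency units.
#' @export
net_monetary_benefit <- function(arm, wtp) {
  stopifnot(inherits(arm, "vt_arm"), inherits(wtp, "vt_wtp"))
  check_currency(arm$currency, wtp$currency)
  wtp$value * arm$effect - arm$cost
}

#' Incremental cost-effectiveness of one strategy against another
#'
#' Computes cost and effect differences of `comparator` relative to
#' `reference` and classifies the comparison. The ratio is only formed when
#' both differences share a sign; otherwise the comparison is a dominance
#' (`dominant`: more effective and cheaper; `dominated`: less effective and
#' costlier) and no ratio is reported. When the effect difference is zero but
#' costs differ, the ratio is undefined and the comparison is classified by
#' cost alone. With a threshold supplied, ratio cases are classified by the
#' sign of the incremental net monetary benefit `lambda * dE - dC`.
#'
#' @param reference,comparator [arm_result()] objects with matching currency.
#' @param wtp Optional [wtp_threshold()]; required for the
#'   `cost_effective_vs_wtp` / `not_cost_effective_vs_wtp` classifications.
#' @param tol Absolute tolerance under which a difference counts as zero.
#' @return An object of class `vt_icer`: a list with `comparator`,
#'   `reference`, `delta_cost`, `delta_effect`, `icer` (`NA` when undefined),
#'   `classification`, and `cost_saving` (`-delta_cost` when positive, else 0).
#' @examples
#' g <- arm_result("glutamine", 200, 0.5)
#' c5 <- arm_result("criz", 100, 0.6)
#' icer(g, c5)$classification   # "dominant"
#' @export
icer <- function(reference, comparator, wtp = NULL, tol = 1e-12) {
  stopifnot(inherits(reference, "vt_arm"), inherits(comparator, "vt_arm"))
  check_currency(reference$currency, comparator$currency)
  if (!is.null(wtp)) {
    stopifnot(inherits(wtp, "vt_wtp"))
    check_currency(reference$currency, wtp$currency)
  }
  dC <- comparator$cost - reference$cost
  dE <- comparator$effect - reference$effect
  ratio <- NA_real_
  if (abs(dC) <= tol && abs(dE) <= tol) {
    cls <- "equal"
  } else if (dE > tol && dC < -tol) {
    cls <- "dominant"
  } else if (dE < -tol && dC > tol) {
    cls <- "dominated"
  } else if (abs(dE) <= tol) {
    # same effectiveness, different cost: ratio undefined, classify by cost
    cls <- if (is.null(wtp)) NA_character_ else
      if (dC < 0) "cost_effective_vs_wtp" else "not_cost_effective_vs_wtp"
  } else {
    ratio <- dC / dE
    cls <- if (is.null(wtp)) NA_character_ else
      if (wtp$value * dE - dC > 0) "cost_effective_vs_wtp" else
        "not_cost_effective_vs_wtp"
  }
  structure(list(
    comparator = comparator$strategy, reference = reference$strategy,
    delta_cost = dC, delta_effect = dE, icer = ratio, classification = cls,
    cost_saving = max(-dC, 0), currency = reference$currency),
    class = "vt_icer")
}

#' @export
print.vt_icer <- function(x, ...) {
  cat(x$comparator, "vs", x$reference, "\n")
  cat(sprintf("  delta cost:   %s %s\n", format(round(x$delta_cost)), x$currency))
  cat(sprintf("  delta effect: %.4f\n", x$delta_effect))
  if (!is.na(x$icer)) {
    cat(sprintf("  ICER:         %s %s per pain crisis averted\n",
                format(round(x$icer)), x$currency))
  } else {
    cat("  ICER:         undefined\n")
  }
  if (!is.na(x$classification)) cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' Incremental analysis across several strategies
#'
#' Sorts strategies by effectiveness, flags strict dominance (another strategy
#' at least as effective and strictly cheaper, or more effective and no more
#' expensive) and extended dominance (the strategy's ICER against the next
#' cheaper frontier member exceeds that of a more effective strategy), reports
#' ICERs along the efficient frontier, and identifies the optimal strategy at
#' the threshold by maximum net monetary benefit with ties broken toward
#' lower cost.
#'
#' @param arms List of [arm_result()] objects (at least two).
#' @param wtp A [wtp_threshold()].
#' @return A data frame of class `vt_frontier`, one row per strategy, sorted
#'   by effectiveness: columns `strategy`, `cost`, `effect`, `nmb`, `status`
#'   (`"on_frontier"`, `"dominated"`, `"extended_dominated"`), `icer` (vs the
#'   previous frontier strategy; `NA` for the cheapest), `optimal` (logical).
#' @export
incremental_frontier <- function(arms, wtp) {
  stopifnot(is.list(arms), length(arms) >= 2L,
            all(vapply(arms, inherits, logical(1), "vt_arm")),
            inherits(wtp, "vt_wtp"))
  for (a in arms) check_currency(a$currency, wtp$currency)
  df <- data.frame(
    strategy = vapply(arms, `[[`, character(1), "strategy"),
    cost = vapply(arms, `[[`, numeric(1), "cost"),
    effect = vapply(arms, `[[`, numeric(1), "effect"),
    stringsAsFactors = FALSE)
  df$nmb <- wtp$value * df$effect - df$cost
  df <- df[order(df$effect, df$cost), , drop = FALSE]
  n <- nrow(df)

  dominated <- vapply(seq_len(n), function(i) {
    any((df$effect >= df$effect[i] & df$cost < df$cost[i]) |
        (df$effect > df$effect[i] & df$cost <= df$cost[i]))
  }, logical(1))
  df$status <- ifelse(dominated, "dominated", "on_frontier")

  # extended dominance: repeatedly remove frontier members whose ICER vs the
  # previous member exceeds the ICER of the next member
  repeat {
    idx <- which(df$status == "on_frontier")
    if (length(idx) < 3L) break
    icers <- diff(df$cost[idx]) / diff(df$effect[idx])
    bad <- which(icers[-length(icers)] > icers[-1])
    if (!length(bad)) break
    df$status[idx[bad[1] + 1L]] <- "extended_dominated"
  }

  df$icer <- NA_real_
  idx <- which(df$status == "on_frontier")
  if (length(idx) > 1L) {
    df$icer[idx[-1]] <- diff(df$cost[idx]) / diff(df$effect[idx])
  }

  best <- which(df$nmb == max(df$nmb))
  if (length(best) > 1L) best <- best[which.min(df$cost[best])]
  df$optimal <- seq_len(n) == best
  rownames(df) <- NULL
  class(df) <- c("vt_frontier", "data.frame")
  df
}

#' Convert an amount between QAR and USD
#'
#' @param amount Amount(s) to convert.
#' @param rate Exchange rate in QAR per USD; positive. Default 3.641, the
#'   2021 rate implied by the model's published cost pairs.
#' @param direction `"qar_to_usd"` (divide) or `"usd_to_qar"` (multiply).
#' @return Converted amount(s).
#' @examples
#' convert_currency(79424, 3.6411, "qar_to_usd")   # ~21813 USD
#' @export
convert_currency <- function(amount, rate = 3.641,
                             direction = c("qar_to_usd", "usd_to_qar")) {
  direction <- match.arg(direction)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop("exchange rate must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(amount))
  if (direction == "qar_to_usd") amount / rate else amount * rate
}
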