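# The concrete three-arm model: crizanlizumab 5 mg/kg and 2.5 mg/kg versus
# l-glutamine for preventing the first vaso-occlusive pain crisis over one
# year, parameterized from the published base-case tables.

PATHWAY_LABELS <- c("success_ae", "success_no_ae", "first_second_additional",
                    "first_second_no_additional", "first_no_second",
                    "acs", "death", "other_failure")

#' Arm parameterization of the vaso-occlusive-crisis model
#'
#' Conditional clinical-event probabilities and per-pathway terminal costs
#' for one treatment strategy. The failure branch carries three published
#' sub-events (first pain crisis, acute chest syndrome, death); the residual
#' probability mass is assigned to an explicit `other_failure` branch whose
#' cost defaults to the arm's crisis-free (no-AE) cost -- a modelling choice
#' of this package, required because the published failure sub-events do not
#' complete a probability space.
#'
#' @param strategy Strategy name.
#' @param p_success Probability of no first pain crisis in the year.
#' @param p_ae_given_success Probability of adverse events given success.
#' @param p_first_crisis_given_failure,p_acs_given_failure,p_death_given_failure
#'   Conditional probabilities of the failure sub-events; their sum must not
#'   exceed 1 (the remainder goes to `other_failure`).
#' @param p_second_given_first Probability of a second crisis after the first.
#' @param p_additional_given_second Probability of an additional crisis after
#'   the second.
#' @param terminal_costs Named list/vector of non-negative pathway costs
#'   (QAR/patient/year) covering `success_ae`, `success_no_ae`,
#'   `first_second_additional`, `first_second_no_additional`,
#'   `first_no_second`, `acs`, `death`, `other_failure`.
#' @return An object of class `vt_arm_params`.
#' @export
arm_parameters <- function(strategy, p_success, p_ae_given_success,
                           p_first_crisis_given_failure, p_second_given_first,
                           p_additional_given_second, p_acs_given_failure,
                           p_death_given_failure, terminal_costs) {
  probs <- c(p_success = p_success, p_ae_given_success = p_ae_given_success,
             p_first_crisis_given_failure = p_first_crisis_given_failure,
             p_second_given_first = p_second_given_first,
             p_additional_given_second = p_additional_given_second,
             p_acs_given_failure = p_acs_given_failure,
             p_death_given_failure = p_death_given_failure)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("arm '", strategy, "': all probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  fail_sum <- p_first_crisis_given_failure + p_acs_given_failure +
    p_death_given_failure
  if (fail_sum > 1 + 1e-12) {
    stop("arm '", strategy, "': failure sub-event probabilities sum to ",
         format(fail_sum), " > 1", call. = FALSE)
  }
  terminal_costs <- as.list(terminal_costs)
  missing <- setdiff(PATHWAY_LABELS, names(terminal_costs))
  if (length(missing)) {
    stop("arm '", strategy, "': missing terminal cost(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  costs <- vapply(terminal_costs[PATHWAY_LABELS], as.numeric, numeric(1))
  if (anyNA(costs) || any(costs < 0)) {
    stop("arm '", strategy, "': terminal costs must be non-negative",
         call. = FALSE)
  }
  structure(c(list(strategy = strategy), as.list(probs),
              list(terminal_costs = as.list(costs))),
            class = "vt_arm_params")
}

#' Build the decision tree of one treatment arm
#'
#' Root chance node splits success / failure; success splits into with /
#' without adverse events (both effectiveness 1); failure splits into first
#' pain crisis, acute chest syndrome, death, and the residual `other_failure`
#' branch (all effectiveness 0); the first crisis may be followed by a
#' second, and the second by an additional crisis.
#'
#' @param params An [arm_parameters()] object.
#' @return A [decision_tree()] with eight terminal pathways.
#' @export
build_arm_tree <- function(params) {
  stopifnot(inherits(params, "vt_arm_params"))
  tc <- params$terminal_costs
  term <- function(label, effect) terminal_node(label, tc[[label]], effect)
  residual <- 1 - (params$p_first_crisis_given_failure +
                   params$p_acs_given_failure + params$p_death_given_failure)
  residual <- max(residual, 0)   # guard float round-off; sum<=1 checked upstream

  second_node <- chance_node("second_crisis", list(
    branch("additional_pain_crisis", params$p_additional_given_second,
           term("first_second_additional", 0)),
    branch("no_additional_pain_crisis", 1 - params$p_additional_given_second,
           term("first_second_no_additional", 0))))
  first_node <- chance_node("first_crisis", list(
    branch("second_pain_crisis", params$p_second_given_first, second_node),
    branch("no_second_pain_crisis", 1 - params$p_second_given_first,
           term("first_no_second", 0))))
  failure_node <- chance_node("failure", list(
    branch("first_pain_crisis", params$p_first_crisis_given_failure, first_node),
    branch("acs", params$p_acs_given_failure, term("acs", 0)),
    branch("death", params$p_death_given_failure, term("death", 0)),
    branch("other_failure", residual, term("other_failure", 0))))
  success_node <- chance_node("success", list(
    branch("with_aes", params$p_ae_given_success, term("success_ae", 1)),
    branch("without_aes", 1 - params$p_ae_given_success,
           term("success_no_ae", 1))))
  root <- chance_node(params$strategy, list(
    branch("success", params$p_success, success_node),
    branch("failure", 1 - params$p_success, failure_node)))
  decision_tree(root, name = params$strategy)
}

evaluate_arm <- function(params, currency = "QAR") {
  tree <- build_arm_tree(params)
  arm_result(params$strategy, expected_value(tree, "cost"),
             expected_value(tree, "effect"), currency = currency)
}

#' Load the packaged three-arm model parameterization
#'
#' Reads the shipped fixture file with the published conditional clinical
#' event probabilities, per-pathway terminal costs, Trigen uncertainty
#' ranges, medication unit costs, willingness-to-pay threshold and exchange
#' rate.
#'
#' @param path Optional path to an alternative fixtures file in the same
#'   schema; default is the file shipped with the package.
#' @return A list of class `vt_fixtures`: `arms` (named list of
#'   [arm_parameters()]), `printed_joints` (named list of published joint
#'   pathway probabilities), `trigen` / `trigen_complements` (published
#'   uncertainty ranges), `medication_unit_costs`, `cost_components`,
#'   `wtp_qar`, `wtp_usd`, `qar_per_usd`, `owsa_fraction`,
#'   `printed_headline`.
#' @export
scd_fixtures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scd_fixtures.yaml", package = "voctree")
  }
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "voctree-fixtures/1")) {
    stop("unsupported fixtures schema '", raw$schema, "'", call. = FALSE)
  }
  arms <- lapply(raw$arms, function(a) {
    arm_parameters(a$strategy, a$p_success, a$p_ae_given_success,
                   a$p_first_crisis_given_failure, a$p_second_given_first,
                   a$p_additional_given_second, a$p_acs_given_failure,
                   a$p_death_given_failure, a$terminal_costs)
  })
  printed <- lapply(raw$arms, function(a) {
    unlist(lapply(a$printed_joint_probabilities,
                  function(x) if (is.null(x)) NA_real_ else as.numeric(x)))
  })
  structure(list(
    arms = arms, printed_joints = printed,
    trigen = lapply(raw$arms, function(a) {
      lapply(a$trigen, function(r) as.numeric(unlist(r)))
    }),
    trigen_complements = lapply(raw$arms, function(a) {
      lapply(a$trigen_complements, function(r) as.numeric(unlist(r)))
    }),
    medication_unit_costs = raw$medication_unit_costs,
    cost_components = raw$cost_components,
    wtp_qar = raw$wtp_qar, wtp_usd = raw$wtp_usd,
    qar_per_usd = raw$qar_per_usd, owsa_fraction = raw$owsa_fraction,
    printed_headline = raw$printed_headline),
    class = "vt_fixtures")
}

#' Recompute the deterministic base case and check it against printed values
#'
#' Builds each arm's tree from the conditional inputs, enumerates pathways,
#' evaluates expected cost and effectiveness, forms all pairwise incremental
#' comparisons and the incremental frontier at the threshold, and reports
#' cell-by-cell agreement between the recomputed joint pathway probabilities
#' (rounded to 4 decimals, the published display precision) and the printed
#' joint values. The published headline ICERs are likewise compared against
#' the recomputed arithmetic and flagged: they are not derivable from the
#' published inputs, and this report documents that discrepancy rather than
#' reconciling it.
#'
#' @param fixtures A [scd_fixtures()] object.
#' @param wtp A [wtp_threshold()]; defaults to the fixtures' threshold.
#' @return A list of class `vt_base_case`: `arms` (data frame: strategy,
#'   expected cost, effectiveness, NMB), `pathways` (data frame with
#'   recomputed and printed joints, 4-dp agreement flag and discrepancy),
#'   `incrementals` (list of [icer()] results), `frontier`, and
#'   `headline_check` (data frame comparing printed headline ICERs with the
#'   recomputed values).
#' @export
reproduce_base_case <- function(fixtures = scd_fixtures(),
                                wtp = wtp_threshold(fixtures$wtp_qar)) {
  stopifnot(inherits(fixtures, "vt_fixtures"))
  arm_keys <- names(fixtures$arms)
  arms <- lapply(fixtures$arms, evaluate_arm)

  pathways <- do.call(rbind, lapply(arm_keys, function(k) {
    pw <- enumerate_pathways(build_arm_tree(fixtures$arms[[k]]))
    printed <- unname(fixtures$printed_joints[[k]][pw$terminal])
    rec4 <- round(pw$joint_probability, 4)
    data.frame(arm = k, pathway = pw$terminal,
               joint_probability = pw$joint_probability,
               recomputed_4dp = rec4,
               printed = as.numeric(printed),
               agree_4dp = !is.na(printed) & rec4 == as.numeric(printed),
               discrepancy = pw$joint_probability - as.numeric(printed),
               cost = pw$cost, effect = pw$effect,
               stringsAsFactors = FALSE)
  }))
  rownames(pathways) <- NULL

  inc <- list(
    criz5_vs_glutamine = icer(arms$glutamine, arms$criz5, wtp),
    criz25_vs_glutamine = icer(arms$glutamine, arms$criz25, wtp),
    criz25_vs_criz5 = icer(arms$criz5, arms$criz25, wtp))

  ph <- fixtures$printed_headline
  headline <- data.frame(
    quantity = c("icer_criz5_vs_glutamine_qar", "icer_criz25_vs_glutamine_qar",
                 "cost_saving_criz25_vs_criz5_qar"),
    printed = c(ph$icer_criz5_vs_glutamine_qar,
                ph$icer_criz25_vs_glutamine_qar,
                ph$cost_saving_criz25_vs_criz5_qar),
    recomputed = c(inc$criz5_vs_glutamine$icer, inc$criz25_vs_glutamine$icer,
                   inc$criz25_vs_criz5$cost_saving),
    stringsAsFactors = FALSE)
  headline$relative_discrepancy <-
    abs(headline$recomputed - headline$printed) / headline$printed
  headline$agree <- headline$relative_discrepancy <= 0.02

  arm_df <- data.frame(
    strategy = vapply(arms, `[[`, character(1), "strategy"),
    expected_cost = vapply(arms, `[[`, numeric(1), "cost"),
    effectiveness = vapply(arms, `[[`, numeric(1), "effect"),
    nmb = vapply(arms, net_monetary_benefit, numeric(1), wtp = wtp),
    stringsAsFactors = FALSE)
  rownames(arm_df) <- NULL

  structure(list(arms = arm_df, arm_results = arms, pathways = pathways,
                 incrementals = inc,
                 frontier = incremental_frontier(unname(arms), wtp),
                 headline_check = headline, wtp = wtp),
            class = "vt_base_case")
}

#' @export
print.vt_base_case <- function(x, ...) {
  cat("Base-case analysis (WTP", format(x$wtp$value), x$wtp$currency,
      "per pain crisis averted)\n\nArms:\n")
  df <- x$arms
  df$expected_cost <- round(df$expected_cost)
  df$effectiveness <- round(df$effectiveness, 4)
  df$nmb <- round(df$nmb)
  print(df, row.names = FALSE)
  cat("\nIncremental comparisons:\n")
  for (ic in x$incrementals) print(ic)
  n_dis <- sum(!x$pathways$agree_4dp & !is.na(x$pathways$printed))
  cat("\nPathway probabilities agreeing with printed values at 4 dp: ",
      sum(x$pathways$agree_4dp), "/", sum(!is.na(x$pathways$printed)),
      " (", n_dis, " discrepant)\n", sep = "")
  if (!all(x$headline_check$agree)) {
    cat("Printed headline ICERs NOT reproduced by the recomputed arithmetic:\n")
    print(within(x$headline_check, recomputed <- round(recomputed)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Packaged probabilistic-sensitivity-analysis model
#'
#' Builds the sampled-parameter specification (the published Trigen ranges of
#' the seven conditional clinical events per arm, 21 parameters in all) and a
#' model function for [run_psa()]. Complementary sibling branches are not
#' sampled separately: they are renormalized as the complements of the
#' sampled conditionals, keeping every chance node a probability space. A
#' When the three sampled failure sub-events (first crisis, acute chest
#' syndrome, death) jointly exceed probability 1, they are rescaled to sum
#' to 1 and the residual branch carries no mass -- the same renormalization
#' applied to the whole sibling set. A sampled set is rejected outright only
#' when an individual value falls outside \[0, 1\]; fitted supports of
#' boundary-anchored Trigen ranges extend below 0 by construction, so a few
#' percent of draws are rejected and redrawn.
#'
#' @param fixtures A [scd_fixtures()] object.
#' @return List with `model` (function for [run_psa()]) and `specs` (named
#'   list of [trigen_spec()], names `<arm>.<event>`).
#' @export
scd_psa_model <- function(fixtures = scd_fixtures()) {
  stopifnot(inherits(fixtures, "vt_fixtures"))
  arm_keys <- names(fixtures$arms)
  specs <- list()
  for (k in arm_keys) {
    for (ev in names(fixtures$trigen[[k]])) {
      r <- fixtures$trigen[[k]][[ev]]
      specs[[paste0(k, ".", ev)]] <- trigen_spec(r[1], r[2], r[3])
    }
  }
  base <- fixtures$arms
  model <- function(params) {
    rows <- vector("list", length(arm_keys))
    for (i in seq_along(arm_keys)) {
      k <- arm_keys[i]
      g <- function(ev) unname(params[[paste0(k, ".", ev)]])
      p <- c(g("success"), g("ae_given_success"),
             g("first_crisis_given_failure"), g("acs_given_failure"),
             g("death_given_failure"), g("second_given_first"),
             g("additional_given_second"))
      if (anyNA(p) || any(p < 0) || any(p > 1)) return(NULL)
      fail_sum <- p[3] + p[4] + p[5]
      if (fail_sum > 1) p[3:5] <- p[3:5] / fail_sum
      ap <- base[[k]]
      ap$p_success <- p[1]; ap$p_ae_given_success <- p[2]
      ap$p_first_crisis_given_failure <- p[3]
      ap$p_acs_given_failure <- p[4]; ap$p_death_given_failure <- p[5]
      ap$p_second_given_first <- p[6]; ap$p_additional_given_second <- p[7]
      tree <- build_arm_tree(ap)
      rows[[i]] <- data.frame(strategy = k,
                              cost = expected_value(tree, "cost"),
                              effect = expected_value(tree, "effect"),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  list(model = model, specs = specs)
}

#' One-way sensitivity analysis on medication unit costs
#'
#' Varies each medication's unit cost over a symmetric triangular range
#' (default plus/minus 15 percent of the point estimate) while holding all
#' clinical inputs at base case, and summarizes each pairwise incremental
#' result over Monte Carlo draws of the varied costs as a mean with a
#' 2.5/97.5 percentile interval. A change in unit cost rescales the arm's
#' annual medication cost, which enters every pathway of that arm equally;
#' by linearity of the expectation the arm's expected cost shifts by the
#' same amount (the identity is verified against full tree re-evaluation in
#' the package tests).
#'
#' @param fixtures A [scd_fixtures()] object.
#' @param fraction Half-width of the triangular range as a proportion of the
#'   point estimate; default the fixtures' published 0.15.
#' @param n Number of Monte Carlo draws (default 5000).
#' @param seed Integer seed; required.
#' @param wtp A [wtp_threshold()].
#' @return A list of class `vt_owsa`: `bounds` (data frame of point estimate
#'   and integer-rounded lower/upper bounds per medication), `results` (data
#'   frame per comparison: measure -- `icer` or `cost_saving` when the
#'   comparison is a dominance at base case -- mean, `ci_low`, `ci_high`),
#'   `fraction`, `n`, `seed`.
#' @export
run_owsa <- function(fixtures = scd_fixtures(), fraction = fixtures$owsa_fraction,
                     n = 5000, seed, wtp = wtp_threshold(fixtures$wtp_qar)) {
  stopifnot(inherits(fixtures, "vt_fixtures"), n >= 1)
  if (missing(seed)) stop("run_owsa requires an explicit seed", call. = FALSE)
  uc <- fixtures$medication_unit_costs
  spec_criz <- make_owsa_range(uc$crizanlizumab, fraction)
  spec_glu <- make_owsa_range(uc$l_glutamine, fraction)
  bounds <- data.frame(
    medication = c("crizanlizumab", "l_glutamine"),
    point_estimate = c(uc$crizanlizumab, uc$l_glutamine),
    lower = c(round(spec_criz$minimum), round(spec_glu$minimum)),
    upper = c(round(spec_criz$maximum), round(spec_glu$maximum)),
    stringsAsFactors = FALSE)

  arms <- lapply(fixtures$arms, evaluate_arm)
  med_annual <- fixtures$cost_components$medications   # criz5, criz25, glutamine
  base_cost <- vapply(arms, `[[`, numeric(1), "cost")
  eff <- vapply(arms, `[[`, numeric(1), "effect")

  set.seed(as.integer(seed))
  mult_criz <- rtri(n, spec_criz$minimum, spec_criz$mode, spec_criz$maximum) /
    uc$crizanlizumab
  mult_glu <- rtri(n, spec_glu$minimum, spec_glu$mode, spec_glu$maximum) /
    uc$l_glutamine
  # unit-cost multiplier shifts the arm's expected cost by med_annual*(m-1)
  cost <- cbind(
    criz5 = base_cost[["criz5"]] + med_annual$criz5 * (mult_criz - 1),
    criz25 = base_cost[["criz25"]] + med_annual$criz25 * (mult_criz - 1),
    glutamine = base_cost[["glutamine"]] + med_annual$glutamine * (mult_glu - 1))

  comparisons <- list(criz5_vs_glutamine = c("criz5", "glutamine"),
                      criz25_vs_glutamine = c("criz25", "glutamine"),
                      criz25_vs_criz5 = c("criz25", "criz5"))
  results <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cp <- comparisons[[nm]]
    dC <- cost[, cp[1]] - cost[, cp[2]]
    dE <- eff[[cp[1]]] - eff[[cp[2]]]
    if (dE > 0 && all(dC < 0)) {
      vals <- -dC; measure <- "cost_saving"
    } else {
      vals <- dC / dE; measure <- "icer"
    }
    data.frame(comparison = nm, measure = measure, mean = mean(vals),
               ci_low = unname(stats::quantile(vals, 0.025)),
               ci_high = unname(stats::quantile(vals, 0.975)),
               stringsAsFactors = FALSE)
  }))
  structure(list(bounds = bounds, results = results, fraction = fraction,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "vt_owsa")
}

#' @export
print.vt_owsa <- function(x, ...) {
  cat("One-way sensitivity analysis on medication unit costs (±",
      100 * x$fraction, "%, ", x$n, " draws, seed ", x$seed, ")\n", sep = "")
  print(x$bounds, row.names = FALSE)
  cat("\n")
  df <- x$results
  df$mean <- round(df$mean); df$ci_low <- round(df$ci_low)
  df$ci_high <- round(df$ci_high)
  print(df, row.names = FALSE)
  invisible(x)
}
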