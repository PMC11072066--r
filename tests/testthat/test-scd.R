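fixtures <- scd_fixtures()

test_that("fixture arms preserve the published effectiveness ordering", {
  eff <- vapply(fixtures$arms, function(a) {
    expected_value(build_arm_tree(a), "effect")
  }, numeric(1))
  expect_equal(unname(eff["glutamine"]), 0.4503)
  expect_equal(unname(eff["criz5"]), 0.5152)
  expect_equal(unname(eff["criz25"]), 0.5625)
  expect_true(eff["glutamine"] < eff["criz5"] && eff["criz5"] < eff["criz25"])
})

test_that("arm trees have the published pathway structure", {
  pw <- enumerate_pathways(build_arm_tree(fixtures$arms$criz5))
  expect_equal(nrow(pw), 8L)   # seven published pathways plus the residual
  expect_setequal(pw$terminal, c(
    "success_ae", "success_no_ae", "first_second_additional",
    "first_second_no_additional", "first_no_second", "acs", "death",
    "other_failure"))
  expect_true(validate_tree(build_arm_tree(fixtures$arms$criz5), 1e-9)$valid)
  # effectiveness indicator: 1 exactly on the success terminals
  expect_equal(pw$effect == 1, grepl("^success", pw$terminal))
})

test_that("degenerate arm with certain success puts all mass on success", {
  p <- fixtures$arms$criz5
  p$p_success <- 1
  pw <- enumerate_pathways(build_arm_tree(p))
  on_success <- grepl("^success", pw$terminal)
  expect_equal(sum(pw$joint_probability[on_success]), 1, tolerance = 1e-12)
  expect_equal(sum(pw$joint_probability[!on_success]), 0)
})

test_that("missing terminal costs are rejected", {
  tc <- fixtures$arms$criz5$terminal_costs
  tc$acs <- NULL
  expect_error(
    arm_parameters("x", 0.5, 0.5, 0.5, 0.5, 0.5, 0.1, 0.1, tc),
    "missing terminal cost")
  expect_error(
    arm_parameters("x", 0.5, 0.5, 0.8, 0.5, 0.5, 0.3, 0.3,
                   fixtures$arms$criz5$terminal_costs),
    "sum to")
})

test_that("base-case report agrees with printed joints where derivable", {
  bc <- reproduce_base_case(fixtures)
  cell <- function(arm, pathway, col) {
    bc$pathways[bc$pathways$arm == arm & bc$pathways$pathway == pathway, col]
  }
  expect_equal(cell("criz5", "success_ae", "recomputed_4dp"), 0.4431)
  expect_equal(cell("criz5", "first_no_second", "recomputed_4dp"), 0.2319)
  expect_true(cell("criz5", "success_ae", "agree_4dp"))

  # the printed l-glutamine success-with-AEs joint is NOT the product of the
  # printed conditionals (0.4503 x 0.98 = 0.4413 vs printed 0.4394); the
  # report must flag it rather than reconcile it
  expect_equal(cell("glutamine", "success_ae", "recomputed_4dp"), 0.4413)
  expect_false(cell("glutamine", "success_ae", "agree_4dp"))
  expect_equal(cell("glutamine", "success_ae", "discrepancy"),
               0.4503 * 0.98 - 0.4394, tolerance = 1e-9)

  # published headline ICERs are not derivable from the inputs: all flagged
  expect_false(any(bc$headline_check$agree))
})

test_that("expected costs equal the brute-force pathway sums", {
  arms <- generate_synthetic_params(n_arms = 5, seed = 37)
  for (a in arms) {
    tree <- build_arm_tree(a)
    pw <- enumerate_pathways(tree)
    expect_equal(expected_value(tree, "cost"),
                 sum(pw$joint_probability * pw$cost), tolerance = 1e-9)
  }
})

test_that("synthetic arms are valid by construction and seed-deterministic", {
  arms <- generate_synthetic_params(n_arms = 200, seed = 99)
  for (a in arms) {
    expect_true(validate_tree(build_arm_tree(a), tolerance = 1e-9)$valid)
  }
  again <- generate_synthetic_params(n_arms = 200, seed = 99)
  expect_identical(arms, again)
})

test_that("equal effectiveness with scaled costs yields no ratio", {
  a <- generate_synthetic_params(n_arms = 1, seed = 3)[[1]]
  b <- a
  b$strategy <- "arm_2"
  b$terminal_costs <- lapply(a$terminal_costs, function(x) 2 * x)
  as_arm <- function(p) {
    tree <- build_arm_tree(p)
    arm_result(p$strategy, expected_value(tree, "cost"),
               expected_value(tree, "effect"))
  }
  ra <- icer(as_arm(a), as_arm(b), wtp_threshold(547500))
  expect_equal(ra$delta_effect, 0)
  expect_true(is.na(ra$icer))
  expect_equal(ra$classification, "not_cost_effective_vs_wtp")
})

test_that("unit-cost variation shifts expected cost by the medication delta", {
  # the one-way analysis adds the medication-cost delta to every terminal of
  # an arm; by linearity the expectation shifts by exactly that delta
  a <- fixtures$arms$criz5
  delta <- 12345.6
  shifted <- a
  shifted$terminal_costs <- lapply(a$terminal_costs, function(x) x + delta)
  expect_equal(expected_value(build_arm_tree(shifted), "cost"),
               expected_value(build_arm_tree(a), "cost") + delta,
               tolerance = 1e-9)
})

test_that("one-way sensitivity analysis reports bounds and intervals", {
  ow <- run_owsa(fixtures, n = 500, seed = 11)
  expect_equal(ow$bounds$lower[ow$bounds$medication == "crizanlizumab"], 5676)
  expect_equal(ow$bounds$upper[ow$bounds$medication == "crizanlizumab"], 7680)
  expect_equal(ow$bounds$lower[ow$bounds$medication == "l_glutamine"], 82)
  expect_equal(ow$bounds$upper[ow$bounds$medication == "l_glutamine"], 110)
  res <- ow$results
  expect_true(all(res$ci_low <= res$mean & res$mean <= res$ci_high))
  # the dose comparison stays a dominance across the whole cost range
  expect_equal(res$measure[res$comparison == "criz25_vs_criz5"], "cost_saving")
  expect_identical(run_owsa(fixtures, n = 50, seed = 4),
                   run_owsa(fixtures, n = 50, seed = 4))
})

test_that("the packaged PSA model renormalizes siblings and rejects overflow", {
  pm <- scd_psa_model(fixtures)
  expect_length(pm$specs, 21L)   # seven sampled events per arm
  base_vals <- unlist(lapply(names(fixtures$arms), function(k) {
    a <- fixtures$arms[[k]]
    stats::setNames(
      c(a$p_success, a$p_ae_given_success, a$p_first_crisis_given_failure,
        a$p_acs_given_failure, a$p_death_given_failure,
        a$p_second_given_first, a$p_additional_given_second),
      paste0(k, ".", c("success", "ae_given_success",
                       "first_crisis_given_failure", "acs_given_failure",
                       "death_given_failure", "second_given_first",
                       "additional_given_second")))
  }))
  res <- pm$model(base_vals)
  bc <- reproduce_base_case(fixtures)
  expect_equal(res$cost, bc$arms$expected_cost, tolerance = 1e-12)
  expect_equal(res$effect, bc$arms$effectiveness, tolerance = 1e-12)

  # failure sub-events exceeding one are rescaled to a probability space,
  # leaving no residual mass
  over <- base_vals
  over["criz5.first_crisis_given_failure"] <- 0.95
  over["criz5.death_given_failure"] <- 0.25
  res_over <- pm$model(over)
  scaled <- fixtures$arms$criz5
  scaled$p_first_crisis_given_failure <- 0.95 / 1.2
  scaled$p_death_given_failure <- 0.25 / 1.2
  scaled$p_acs_given_failure <- 0
  expect_equal(res_over$cost[res_over$strategy == "criz5"],
               expected_value(build_arm_tree(scaled), "cost"),
               tolerance = 1e-9)
  expect_true(validate_tree(build_arm_tree(scaled), 1e-9)$valid)

  # individual out-of-range draws are rejected
  bad <- base_vals
  bad["criz5.acs_given_failure"] <- -0.01
  expect_null(pm$model(bad))
})
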