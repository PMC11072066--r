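# Synthetic model generators. These emulate the structure of the study
# inputs -- valid decision trees with branch probabilities summing to one and
# positive terminal costs -- so every engine code path is testable without
# the published fixtures.

#' Generate random valid arm parameterizations
#'
#' Branch probabilities are drawn uniformly; the four failure sub-branch
#' weights are drawn jointly and normalized so they always complete a
#' probability space (the residual mass is the implied `other_failure`
#' branch). Terminal costs are log-uniform on `[0.1, 10] * cost_scale`, with
#' the residual branch priced at the arm's crisis-free (no-AE) cost,
#' mirroring the packaged model. Fully deterministic under the seed.
#'
#' @param n_arms Number of arms to generate.
#' @param seed Integer seed; required.
#' @param cost_scale Cost scale in currency units; default 1e5, the order of
#'   magnitude of annual treatment costs in the packaged model.
#' @return List of [arm_parameters()] objects named `arm_1`, `arm_2`, ...
#' @export
generate_synthetic_params <- function(n_arms = 3, seed, cost_scale = 1e5) {
  stopifnot(n_arms >= 1, cost_scale > 0)
  if (missing(seed)) stop("generate_synthetic_params requires a seed", call. = FALSE)
  set.seed(as.integer(seed))
  lapply(stats::setNames(seq_len(n_arms), paste0("arm_", seq_len(n_arms))),
         function(i) {
    w <- stats::runif(4); w <- w / sum(w)   # first, acs, death, residual
    costs <- cost_scale * 10^stats::runif(7, -1, 1)
    names(costs) <- setdiff(PATHWAY_LABELS, "other_failure")
    costs <- c(costs, other_failure = unname(costs["success_no_ae"]))
    arm_parameters(
      strategy = paste0("arm_", i),
      p_success = stats::runif(1),
      p_ae_given_success = stats::runif(1),
      p_first_crisis_given_failure = w[1],
      p_second_given_first = stats::runif(1),
      p_additional_given_second = stats::runif(1),
      p_acs_given_failure = w[2],
      p_death_given_failure = w[3],
      terminal_costs = costs)
  })
}

#' Generate a random generic decision tree
#'
#' Builds a random tree of chance and terminal nodes for property testing:
#' each chance node's branch probabilities are drawn uniformly and normalized
#' to sum to one (so generated trees always validate at tolerance 1e-9),
#' terminal costs are log-uniform on `[0.1, 10] * cost_scale`, and terminal
#' effects are fair coin flips. Uses the current RNG state; seed with
#' `set.seed()` for reproducibility.
#'
#' @param depth Maximum tree depth (root at depth 0).
#' @param max_branches Maximum branches per chance node (at least 2).
#' @param p_terminal Probability that an internal position short-circuits to
#'   a terminal before reaching full depth.
#' @param cost_scale Cost scale for terminal costs.
#' @return A [decision_tree()].
#' @export
random_tree <- function(depth = 3, max_branches = 3, p_terminal = 0.3,
                        cost_scale = 1e5) {
  stopifnot(depth >= 1, max_branches >= 2)
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  next_name <- function(prefix) {
    counter$i <- counter$i + 1L
    paste0(prefix, "_", counter$i)
  }
  make_terminal <- function() {
    terminal_node(next_name("t"), cost_scale * 10^stats::runif(1, -1, 1),
                  stats::rbinom(1, 1, 0.5))
  }
  build <- function(d) {
    if (d <= 0 || (d < depth && stats::runif(1) < p_terminal)) {
      return(make_terminal())
    }
    k <- sample(2:max_branches, 1)
    p <- stats::runif(k); p <- p / sum(p)
    chance_node(next_name("c"), lapply(seq_len(k), function(j) {
      branch(next_name("b"), p[j], build(d - 1))
    }))
  }
  root <- build(depth)
  if (inherits(root, "vt_terminal")) {   # root must be a chance node
    p <- stats::runif(2); p <- p / sum(p)
    root <- chance_node(next_name("c"), list(
      branch(next_name("b"), p[1], root),
      branch(next_name("b"), p[2], make_terminal())))
  }
  decision_tree(root, name = "synthetic")
}
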