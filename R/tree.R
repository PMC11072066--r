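#' Build a terminal node
#'
#' A terminal (leaf) node of a decision tree carries the total cost accrued
#' along its pathway and a binary effectiveness indicator. In the
#' vaso-occlusive-crisis model the indicator is 1 when the patient reaches the
#' end of the year without a first pain crisis and 0 otherwise.
#'
#' @param name Node name (single string).
#' @param cost Total pathway cost, in model currency units per patient per
#'   year. Must be non-negative.
#' @param effect Binary effectiveness indicator, 0 or 1.
#' @return An object of class `vt_terminal`.
#' @examples
#' terminal_node("success_no_ae", cost = 390090, effect = 1)
#' @export
terminal_node <- function(name, cost, effect) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(cost) || length(cost) != 1L || is.na(cost) || cost < 0) {
    stop("terminal node '", name, "': cost must be a single non-negative number",
         call. = FALSE)
  }
  if (!is.numeric(effect) || length(effect) != 1L || !(effect %in% c(0, 1))) {
    stop("terminal node '", name, "': effect must be 0 or 1", call. = FALSE)
  }
  structure(
    list(name = name, cost = as.numeric(cost), effect = as.numeric(effect)),
    class = c("vt_terminal", "vt_node")
  )
}

#' Build a branch of a chance node
#'
#' @param label Branch label (single string), e.g. `"second_pain_crisis"`.
#' @param probability Conditional probability of taking this branch given that
#'   its parent chance node is reached; must lie in \[0, 1\].
#' @param child The node the branch leads to (`vt_terminal` or `vt_chance`).
#' @return An object of class `vt_branch`.
#' @export
branch <- function(label, probability, child) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(probability) || length(probability) != 1L ||
      is.na(probability) || probability < 0 || probability > 1) {
    stop("branch '", label, "': probability must lie in [0, 1]", call. = FALSE)
  }
  if (!inherits(child, "vt_node")) {
    stop("branch '", label, "': child must be a terminal or chance node",
         call. = FALSE)
  }
  structure(
    list(label = label, probability = as.numeric(probability), child = child),
    class = "vt_branch"
  )
}

#' Build a chance node
#'
#' A chance node holds an ordered list of at least two branches whose
#' conditional probabilities are expected to sum to one (checked by
#' [validate_tree()], not here, so that almost-complete probability spaces --
#' as printed in published model tables -- can still be represented and
#' flagged).
#'
#' @param name Node name (single string).
#' @param branches List of [branch()] objects, at least two.
#' @return An object of class `vt_chance`.
#' @export
chance_node <- function(name, branches) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.list(branches) || length(branches) < 2L ||
      !all(vapply(branches, inherits, logical(1), "vt_branch"))) {
    stop("chance node '", name, "' must have at least two branches",
         call. = FALSE)
  }
  structure(
    list(name = name, branches = branches),
    class = c("vt_chance", "vt_node")
  )
}

#' Build a decision tree
#'
#' @param root Root node, normally a [chance_node()]. A bare terminal is
#'   allowed (degenerate single-outcome tree).
#' @param name Tree name used in reports.
#' @return An object of class `vt_tree`.
#' @export
decision_tree <- function(root, name = "tree") {
  if (!inherits(root, "vt_node")) {
    stop("root must be a terminal or chance node", call. = FALSE)
  }
  structure(list(name = name, root = root), class = "vt_tree")
}

# Structural walk shared by validation and evaluation. Trees are nested lists,
# so cycles cannot arise in memory; depth is still bounded to catch corrupt
# structures built by hand.
check_structure <- function(node, depth = 0L, max_depth = 64L) {
  if (depth > max_depth) {
    stop(structural_error("tree exceeds maximum depth; cyclic or corrupt structure"))
  }
  if (inherits(node, "vt_terminal")) return(invisible(TRUE))
  if (!inherits(node, "vt_chance")) {
    stop(structural_error("node is neither terminal nor chance node"))
  }
  if (length(node$branches) < 2L) {
    stop(structural_error(paste0("chance node '", node$name,
                                 "' has fewer than two branches")))
  }
  for (b in node$branches) check_structure(b$child, depth + 1L, max_depth)
  invisible(TRUE)
}

structural_error <- function(msg) {
  structure(
    class = c("vt_structural_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

#' Validate a decision tree
#'
#' Checks that the tree is structurally sound (acyclic, every chance node has
#' at least two branches) and that the branch probabilities of every chance
#' node sum to one within `tolerance`. Structural defects raise an error of
#' class `vt_structural_error`; probability violations are reported, not
#' raised, because published model tables often print probabilities that do
#' not quite complete a probability space and those need to be surfaced
#' rather than hidden.
#'
#' @param tree A [decision_tree()].
#' @param tolerance Non-negative absolute tolerance on `|sum - 1|` per node.
#' @return A list of class `vt_validation` with elements `valid` (logical) and
#'   `violations` (data frame with columns `node`, `probability_sum`,
#'   `tolerance`). `valid` is `TRUE` iff `violations` has no rows.
#' @examples
#' t1 <- terminal_node("a", 0, 1); t2 <- terminal_node("b", 0, 0)
#' tr <- decision_tree(chance_node("root", list(
#'   branch("yes", 0.5, t1), branch("no", 0.5, t2))))
#' validate_tree(tr)$valid
#' @export
validate_tree <- function(tree, tolerance = 1e-9) {
  stopifnot(inherits(tree, "vt_tree"),
            is.numeric(tolerance), length(tolerance) == 1L, tolerance >= 0)
  check_structure(tree$root)
  viol <- list()
  walk <- function(node) {
    if (inherits(node, "vt_terminal")) return(invisible(NULL))
    s <- sum(vapply(node$branches, function(b) b$probability, numeric(1)))
    if (abs(s - 1) > tolerance) {
      viol[[length(viol) + 1L]] <<- data.frame(
        node = node$name, probability_sum = s, tolerance = tolerance,
        stringsAsFactors = FALSE)
    }
    for (b in node$branches) walk(b$child)
  }
  walk(tree$root)
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(node = character(), probability_sum = numeric(),
               tolerance = numeric(), stringsAsFactors = FALSE)
  structure(list(valid = nrow(violations) == 0L, violations = violations,
                 tolerance = tolerance),
            class = "vt_validation")
}

#' @export
print.vt_validation <- function(x, ...) {
  if (x$valid) {
    cat("Decision tree valid (tolerance ", format(x$tolerance), ")\n", sep = "")
  } else {
    cat("Decision tree INVALID; branch-probability violations:\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

#' Joint probability of a pathway
#'
#' Multiplies the conditional probabilities met along a root-to-terminal
#' route. Published pathway tables print these joint values; the product rule
#' is how they arise from the conditional inputs.
#'
#' @param conditionals Numeric vector of conditional probabilities, each in
#'   \[0, 1\]; must be non-empty.
#' @return The product, a probability in \[0, 1\].
#' @examples
#' pathway_probability(c(0.4848, 0.92, 0.48, 0.93))
#' @export
pathway_probability <- function(conditionals) {
  if (!is.numeric(conditionals) || length(conditionals) == 0L) {
    stop("conditionals must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(conditionals) || any(conditionals < 0) || any(conditionals > 1)) {
    stop("all conditional probabilities must lie in [0, 1]", call. = FALSE)
  }
  prod(conditionals)
}

#' Enumerate root-to-terminal pathways
#'
#' Walks the tree and returns one row per terminal node, with the pathway's
#' branch labels, its joint probability (product of the conditional
#' probabilities along the route), and the terminal payoffs.
#'
#' @param tree A [decision_tree()]; must be structurally valid.
#' @return A data frame with columns `pathway` (branch labels joined by
#'   `" > "`), `terminal`, `joint_probability`, `cost`, `effect`.
#' @export
enumerate_pathways <- function(tree) {
  stopifnot(inherits(tree, "vt_tree"))
  check_structure(tree$root)
  rows <- list()
  walk <- function(node, labels, probs) {
    if (inherits(node, "vt_terminal")) {
      rows[[length(rows) + 1L]] <<- data.frame(
        pathway = if (length(labels)) paste(labels, collapse = " > ") else node$name,
        terminal = node$name,
        joint_probability = if (length(probs)) pathway_probability(probs) else 1,
        cost = node$cost, effect = node$effect,
        stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    for (b in node$branches) {
      walk(b$child, c(labels, b$label), c(probs, b$probability))
    }
  }
  walk(tree$root, character(), numeric())
  do.call(rbind, rows)
}

#' Expected value of a decision tree
#'
#' Computes the probability-weighted expectation of a terminal payoff by
#' leaf-to-root rollback (the classical decision-tree evaluation). The result
#' equals the sum over enumerated pathways of joint probability times payoff;
#' the two routes agree to floating-point rollback error and the package's
#' test suite holds them to 1e-9 relative.
#'
#' @param tree A [decision_tree()].
#' @param payoff `"cost"` or `"effect"`.
#' @return The expected payoff (a scalar).
#' @examples
#' t1 <- terminal_node("a", 100, 1); t2 <- terminal_node("b", 200, 0)
#' tr <- decision_tree(chance_node("root", list(
#'   branch("yes", 0.3, t1), branch("no", 0.7, t2))))
#' expected_value(tr, "cost")   # 170
#' @export
expected_value <- function(tree, payoff = c("cost", "effect")) {
  stopifnot(inherits(tree, "vt_tree"))
  payoff <- match.arg(payoff)
  check_structure(tree$root)
  roll <- function(node) {
    if (inherits(node, "vt_terminal")) return(node[[payoff]])
    s <- 0
    for (b in node$branches) s <- s + b$probability * roll(b$child)
    s
  }
  roll(tree$root)
}
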