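# Small builders shared across tests.

two_branch_tree <- function(p = 0.5, c1 = 100, c2 = 200, e1 = 1, e2 = 0) {
  decision_tree(chance_node("root", list(
    branch("yes", p, terminal_node("t1", c1, e1)),
    branch("no", 1 - p, terminal_node("t2", c2, e2)))),
    name = "two_branch")
}

# Independent pathway oracle: walks routes explicitly on the raw list
# structure, accumulating probabilities without pathway_probability() or
# enumerate_pathways().
walk_paths <- function(node, prob = 1) {
  if (inherits(node, "vt_terminal")) {
    return(list(list(prob = prob, cost = node$cost, effect = node$effect)))
  }
  out <- list()
  for (b in node$branches) {
    out <- c(out, walk_paths(b$child, prob * b$probability))
  }
  out
}

brute_expected <- function(tree, payoff) {
  sum(vapply(walk_paths(tree$root),
             function(p) p$prob * p[[payoff]], numeric(1)))
}

# Independent frontier-walk chooser: start at the cheapest strategy and move
# along the non-dominated, non-extendedly-dominated frontier while the ICER
# of the step is within the threshold.
frontier_walk_choice <- function(cost, effect, lambda) {
  ord <- order(effect, cost)
  cost <- cost[ord]; effect <- effect[ord]; id <- seq_along(cost)[ord]
  keep <- !vapply(seq_along(cost), function(i) {
    any((effect >= effect[i] & cost < cost[i]) |
        (effect > effect[i] & cost <= cost[i]))
  }, logical(1))
  cost <- cost[keep]; effect <- effect[keep]; id <- id[keep]
  repeat {
    if (length(cost) < 3) break
    ic <- diff(cost) / diff(effect)
    bad <- which(ic[-length(ic)] > ic[-1])
    if (!length(bad)) break
    drop <- bad[1] + 1
    cost <- cost[-drop]; effect <- effect[-drop]; id <- id[-drop]
  }
  current <- 1
  while (current < length(cost)) {
    step_icer <- (cost[current + 1] - cost[current]) /
      (effect[current + 1] - effect[current])
    if (step_icer <= lambda) current <- current + 1 else break
  }
  id[current]
}
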