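test_that("validation accepts complete probability spaces and reports gaps", {
  expect_true(validate_tree(two_branch_tree(0.5), tolerance = 1e-9)$valid)

  # the published failure sub-events (first crisis / ACS / death) do not
  # complete a probability space: 0.92 + 0 + 0.016 = 0.936
  incomplete <- decision_tree(chance_node("failure", list(
    branch("first_pain_crisis", 0.92, terminal_node("t1", 1000, 0)),
    branch("acs", 0, terminal_node("t2", 2000, 0)),
    branch("death", 0.016, terminal_node("t3", 3000, 0)))))
  rep <- validate_tree(incomplete, tolerance = 1e-6)
  expect_false(rep$valid)
  expect_equal(rep$violations$node, "failure")
  expect_equal(rep$violations$probability_sum, 0.936)

  # normalized random nodes always validate
  set.seed(41)
  for (i in 1:20) {
    p <- runif(3); p <- p / sum(p)
    tr <- decision_tree(chance_node("r", lapply(1:3, function(j) {
      branch(paste0("b", j), p[j], terminal_node(paste0("t", j), j, 0))
    })))
    expect_true(validate_tree(tr, tolerance = 1e-9)$valid)
  }
})

test_that("structural defects raise errors distinct from probability gaps", {
  expect_error(chance_node("solo", list(branch("a", 1, terminal_node("t", 0, 0)))),
               "at least two branches")
  # a corrupt node built by hand, bypassing the constructor
  bad <- structure(list(name = "solo", branches = list(
    branch("a", 1, terminal_node("t", 0, 0)))), class = c("vt_chance", "vt_node"))
  expect_error(validate_tree(decision_tree(bad)), class = "vt_structural_error")
  expect_error(terminal_node("t", -1, 0), "non-negative")
  expect_error(branch("b", 1.2, terminal_node("t", 0, 0)), "\\[0, 1\\]")
})

test_that("pathway enumeration matches explicit route walking", {
  pw <- enumerate_pathways(two_branch_tree(0.3))
  expect_equal(nrow(pw), 2L)
  expect_equal(pw$joint_probability, c(0.3, 0.7))

  set.seed(7)
  for (i in 1:25) {
    tr <- random_tree(depth = 3, max_branches = 3)
    pw <- enumerate_pathways(tr)
    oracle <- walk_paths(tr$root)
    expect_equal(nrow(pw), length(oracle))
    expect_equal(pw$joint_probability,
                 vapply(oracle, `[[`, numeric(1), "prob"), tolerance = 1e-12)
  }
})

test_that("pathway probability is the product of conditionals", {
  expect_equal(round(pathway_probability(c(0.4848, 0.92, 0.48, 0.93)), 4), 0.1991)
  expect_equal(round(pathway_probability(c(0.4848, 0.92, 0.48, 0.07)), 4), 0.0150)
  expect_identical(pathway_probability(c(1, 1, 1)), 1)
  expect_error(pathway_probability(numeric()), "non-empty")
  expect_error(pathway_probability(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("expected value by rollback matches enumeration and hand sums", {
  single <- decision_tree(terminal_node("only", 100, 1))
  expect_equal(expected_value(single, "cost"), 100)
  expect_equal(expected_value(two_branch_tree(0.3), "cost"), 170)

  # flat tree over the printed l-glutamine pathway columns: the expectation
  # equals the sum of the seven printed probability x cost products
  p <- c(0.4394, 0.0109, 0.0072, 0.1724, 0.2657, 0.0852, 0.0131)
  cost <- c(156123, 148869, 493509, 317690, 149126, 174374, 148869)
  flat <- decision_tree(chance_node("glutamine", lapply(1:7, function(i) {
    branch(paste0("p", i), p[i], terminal_node(paste0("t", i), cost[i], 0))
  })))
  expect_equal(expected_value(flat, "cost"), sum(p * cost), tolerance = 1e-12)
  expect_equal(expected_value(flat, "cost"), 184976, tolerance = 1e-5)
})

test_that("rollback agrees with brute-force enumeration on random trees", {
  set.seed(11)
  for (i in 1:100) {
    tr <- random_tree(depth = sample(2:4, 1))
    for (payoff in c("cost", "effect")) {
      expect_equal(expected_value(tr, payoff), brute_expected(tr, payoff),
                   tolerance = 1e-9)
    }
  }
})

test_that("expected value is linear in payoffs and ignores null branches", {
  set.seed(13)
  tr <- random_tree(depth = 3)
  base <- expected_value(tr, "cost")
  scale_costs <- function(node, k) {
    if (inherits(node, "vt_terminal")) {
      return(terminal_node(node$name, node$cost * k, node$effect))
    }
    chance_node(node$name, lapply(node$branches, function(b) {
      branch(b$label, b$probability, scale_costs(b$child, k))
    }))
  }
  scaled <- decision_tree(scale_costs(tr$root, 2.5))
  expect_equal(expected_value(scaled, "cost"), 2.5 * base, tolerance = 1e-12)

  # adding a zero-probability branch changes nothing
  with_zero <- decision_tree(chance_node("root", c(
    tr$root$branches,
    list(branch("phantom", 0, terminal_node("ghost", 1e9, 1))))))
  expect_equal(expected_value(with_zero, "cost"), base, tolerance = 1e-12)
  expect_equal(expected_value(with_zero, "effect"),
               expected_value(tr, "effect"), tolerance = 1e-12)
})

test_that("pathway joint probabilities of validated trees sum to one", {
  set.seed(17)
  for (i in 1:50) {
    tr <- random_tree(depth = 3)
    expect_true(validate_tree(tr, tolerance = 1e-9)$valid)
    pw <- enumerate_pathways(tr)
    expect_equal(sum(pw$joint_probability), 1, tolerance = nrow(pw) * 1e-9)
  }
})

test_that("tree configs round-trip through YAML bit-exactly", {
  set.seed(19)
  tr <- random_tree(depth = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tree_config(tr, path)
  back <- read_tree_config(path)
  expect_identical(back, tr)   # includes every double, bit for bit

  # unknown keys and dangling references are hard errors
  cfg <- yaml::read_yaml(path)
  cfg$extra <- 1
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(cfg), path2)
  expect_error(read_tree_config(path2), "unknown key")

  cfg$extra <- NULL
  cfg$root <- "nowhere"
  writeLines(yaml::as.yaml(cfg), path2)
  expect_error(read_tree_config(path2), class = "vt_structural_error")
})

test_that("cyclic node references are rejected as structural errors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(
    schema = "voctree/1", name = "loop", root = "a",
    nodes = list(
      a = list(type = "chance", branches = list(
        list(label = "x", probability = 0.5, child = "b"),
        list(label = "y", probability = 0.5, child = "t"))),
      b = list(type = "chance", branches = list(
        list(label = "x", probability = 0.5, child = "a"),
        list(label = "y", probability = 0.5, child = "t"))),
      t = list(type = "terminal", cost = 1, effect = 0)))), path)
  expect_error(read_tree_config(path), class = "vt_structural_error")
})
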