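# Tree config I/O. One YAML dialect with a versioned schema key; unknown keys
# are hard errors so that fixture files cannot silently drift.

TREE_SCHEMA <- "voctree/1"

assert_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(allowed, names(x))
  if (length(missing)) {
    stop("missing key(s) in ", where, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a decision tree from a YAML config
#'
#' The config is a flat map of named nodes (`type: chance` with a list of
#' `(label, probability, child)` branches, or `type: terminal` with `cost` and
#' `effect`), plus `schema`, `name` and `root` keys. Node references are
#' resolved into a nested tree; dangling references and reference cycles are
#' structural errors. Writing with [write_tree_config()] and reading back
#' reproduces every number bit-exactly.
#'
#' @param path Path to a YAML file.
#' @return A [decision_tree()].
#' @seealso [write_tree_config()]
#' @export
read_tree_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  assert_keys(cfg, c("schema", "name", "root", "nodes"), "tree config")
  if (!identical(cfg$schema, TREE_SCHEMA)) {
    stop("unsupported schema '", cfg$schema, "' (expected '", TREE_SCHEMA, "')",
         call. = FALSE)
  }
  nodes <- cfg$nodes
  resolve <- function(name, path_names) {
    if (name %in% path_names) {
      stop(structural_error(paste0("cycle through node '", name, "'")))
    }
    nd <- nodes[[name]]
    if (is.null(nd)) {
      stop(structural_error(paste0("reference to undefined node '", name, "'")))
    }
    if (identical(nd$type, "terminal")) {
      assert_keys(nd, c("type", "cost", "effect"), paste0("terminal '", name, "'"))
      return(terminal_node(name, nd$cost, nd$effect))
    }
    if (identical(nd$type, "chance")) {
      assert_keys(nd, c("type", "branches"), paste0("chance node '", name, "'"))
      brs <- lapply(nd$branches, function(b) {
        assert_keys(b, c("label", "probability", "child"),
                    paste0("branch of '", name, "'"))
        branch(b$label, b$probability, resolve(b$child, c(path_names, name)))
      })
      return(chance_node(name, brs))
    }
    stop("node '", name, "': type must be 'chance' or 'terminal'", call. = FALSE)
  }
  decision_tree(resolve(cfg$root, character()), name = cfg$name)
}

#' Write a decision tree to a YAML config
#'
#' @param tree A [decision_tree()]. Node names must be unique.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_config <- function(tree, path) {
  stopifnot(inherits(tree, "vt_tree"))
  check_structure(tree$root)
  nodes <- list()
  collect <- function(node) {
    if (!is.null(nodes[[node$name]])) {
      stop("duplicate node name '", node$name, "'; config nodes must be unique",
           call. = FALSE)
    }
    if (inherits(node, "vt_terminal")) {
      nodes[[node$name]] <<- list(type = "terminal", cost = node$cost,
                                  effect = node$effect)
    } else {
      nodes[[node$name]] <<- list(
        type = "chance",
        branches = lapply(node$branches, function(b) {
          list(label = b$label, probability = b$probability,
               child = b$child$name)
        }))
      for (b in node$branches) collect(b$child)
    }
  }
  collect(tree$root)
  cfg <- list(schema = TREE_SCHEMA, name = tree$name,
              root = tree$root$name, nodes = nodes)
  # precision 17: enough decimal digits to round-trip any double bit-exactly
  writeLines(yaml::as.yaml(cfg, precision = 17L), path)
  invisible(path)
}
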