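# Run configuration, command dispatch and CSV/log artifacts. The package's
# functions are the primary interface; run_command() is the scripting surface
# behind the thin command-line wrapper in inst/cli/.

RUN_CONFIG_KEYS <- c("source", "seed", "n_iterations", "wtp", "currency_rate",
                     "owsa_fraction", "out_dir")

#' Assemble and validate a run configuration
#'
#' @param source `"fixtures"` for the packaged three-arm model, or a path to
#'   a tree config (accepted by the `validate` command only).
#' @param seed Integer seed used by every stochastic command.
#' @param n_iterations Monte Carlo iterations, at least 1.
#' @param wtp Willingness-to-pay threshold in QAR per pain crisis averted.
#' @param currency_rate Exchange rate, QAR per USD; positive.
#' @param owsa_fraction One-way sensitivity half-width, in (0, 1).
#' @param out_dir Output directory for artifacts (created if absent).
#' @return A list of class `vt_run_config`.
#' @export
run_config <- function(source = "fixtures", seed = 1L, n_iterations = 5000L,
                       wtp = 547500, currency_rate = 3.641,
                       owsa_fraction = 0.15, out_dir = ".") {
  stopifnot(is.character(source), length(source) == 1L)
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    stop("n_iterations must be at least 1", call. = FALSE)
  }
  if (!is.numeric(owsa_fraction) || owsa_fraction <= 0 || owsa_fraction >= 1) {
    stop("owsa_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(currency_rate) || currency_rate <= 0) {
    stop("currency_rate must be positive", call. = FALSE)
  }
  structure(list(source = source, seed = as.integer(seed),
                 n_iterations = as.integer(n_iterations), wtp = wtp,
                 currency_rate = currency_rate,
                 owsa_fraction = owsa_fraction, out_dir = out_dir),
            class = "vt_run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are errors, not warnings, to protect fixture integrity.
#'
#' @param path Path to a YAML file whose keys are the arguments of
#'   [run_config()].
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("unreadable config: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

write_report_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

fmt_qar <- function(x) round(x)
fmt_prob <- function(x) round(x, 4)

#' Run an analysis command and write its artifacts
#'
#' Dispatches one of the model commands, writes its CSV artifacts and a
#' `run.log` (inputs echoed, seed, iteration and rejection counts,
#' discrepancy flags) into `config$out_dir`, and returns the paths. Reported
#' numbers follow the published display conventions: QAR to the nearest
#' riyal, USD to the nearest dollar, probabilities to 4 decimals.
#'
#' @param command One of `"validate"`, `"base-case"`, `"owsa"`, `"psa"`,
#'   `"ceac"`, `"tornado"`.
#' @param config A [run_config()] object or path to a YAML config.
#' @return Invisibly, a list with `status` (0 on success) and `files`
#'   (character vector of written artifacts).
#' @export
run_command <- function(command = c("validate", "base-case", "owsa", "psa",
                                    "ceac", "tornado"),
                        config = run_config()) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "vt_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- c(
    paste0("command: ", command),
    paste0("source: ", config$source),
    paste0("seed: ", config$seed),
    paste0("n_iterations: ", config$n_iterations),
    paste0("wtp_qar: ", config$wtp),
    paste0("currency_rate: ", config$currency_rate),
    paste0("owsa_fraction: ", config$owsa_fraction))
  files <- character()
  wtp <- wtp_threshold(config$wtp)

  if (command == "validate" && config$source != "fixtures") {
    tree <- read_tree_config(config$source)
    rep <- validate_tree(tree)
    files <- write_report_csv(rep$violations, out("validation.csv"))
    log_lines <- c(log_lines, paste0("tree: ", tree$name),
                   paste0("valid: ", rep$valid))
  } else {
    fixtures <- if (config$source == "fixtures") scd_fixtures() else
      scd_fixtures(config$source)

    if (command == "validate") {
      rows <- do.call(rbind, lapply(names(fixtures$arms), function(k) {
        rep <- validate_tree(build_arm_tree(fixtures$arms[[k]]))
        data.frame(arm = k, valid = rep$valid,
                   violations = nrow(rep$violations))
      }))
      files <- write_report_csv(rows, out("validation.csv"))
      log_lines <- c(log_lines, paste0("all_valid: ", all(rows$valid)))
    } else if (command == "base-case") {
      bc <- reproduce_base_case(fixtures, wtp)
      arms <- bc$arms
      arms$expected_cost_qar <- fmt_qar(arms$expected_cost)
      arms$expected_cost_usd <-
        round(convert_currency(arms$expected_cost, config$currency_rate))
      arms$effectiveness <- fmt_prob(arms$effectiveness)
      arms$nmb_qar <- fmt_qar(arms$nmb)
      arms <- arms[c("strategy", "expected_cost_qar", "expected_cost_usd",
                     "effectiveness", "nmb_qar")]
      cmp <- do.call(rbind, lapply(bc$incrementals, function(ic) {
        data.frame(comparator = ic$comparator, reference = ic$reference,
                   delta_cost_qar = fmt_qar(ic$delta_cost),
                   delta_effect = fmt_prob(ic$delta_effect),
                   icer_qar = ifelse(is.na(ic$icer), NA, fmt_qar(ic$icer)),
                   classification = ic$classification)
      }))
      pw <- bc$pathways
      pw$joint_probability <- fmt_prob(pw$joint_probability)
      pw$discrepancy <- fmt_prob(pw$discrepancy)
      pw <- pw[c("arm", "pathway", "joint_probability", "printed",
                 "agree_4dp", "discrepancy", "cost")]
      files <- c(write_report_csv(arms, out("arms.csv")),
                 write_report_csv(cmp, out("comparisons.csv")),
                 write_report_csv(pw, out("pathways.csv")),
                 write_report_csv(bc$headline_check, out("headline_check.csv")))
      log_lines <- c(log_lines,
        paste0("pathway_cells_agreeing_4dp: ", sum(bc$pathways$agree_4dp),
               "/", sum(!is.na(bc$pathways$printed))),
        paste0("printed_headline_reproduced: ", all(bc$headline_check$agree)))
    } else if (command == "owsa") {
      ow <- run_owsa(fixtures, fraction = config$owsa_fraction,
                     n = config$n_iterations, seed = config$seed, wtp = wtp)
      res <- ow$results
      res$mean <- fmt_qar(res$mean); res$ci_low <- fmt_qar(res$ci_low)
      res$ci_high <- fmt_qar(res$ci_high)
      files <- c(write_report_csv(ow$bounds, out("owsa_bounds.csv")),
                 write_report_csv(res, out("owsa_results.csv")))
    } else {   # psa, ceac, tornado share the sampled model
      pm <- scd_psa_model(fixtures)
      psa <- run_psa(pm$model, pm$specs, n = config$n_iterations,
                     seed = config$seed, wtp = wtp)
      log_lines <- c(log_lines, paste0("rejections: ", psa$rejections))
      if (command == "psa") {
        flat <- cbind(
          as.data.frame(psa$input_matrix),
          do.call(cbind, lapply(names(psa$comparisons), function(nm) {
            d <- psa$comparisons[[nm]]
            stats::setNames(d, paste0(nm, ".", names(d)))
          })))
        files <- write_report_csv(flat, out("psa_samples.csv"))
      } else if (command == "ceac") {
        files <- unlist(lapply(names(psa$comparisons), function(nm) {
          cv <- ceac(psa, comparison = nm)
          cv$probability_cost_effective <- fmt_prob(cv$probability_cost_effective)
          cv$probability_dominant <- fmt_prob(cv$probability_dominant)
          write_report_csv(cv, out(paste0("ceac_", nm, ".csv")))
        }))
      } else {
        files <- unlist(lapply(names(psa$comparisons), function(nm) {
          write_report_csv(tornado_regression(psa, comparison = nm),
                           out(paste0("tornado_", nm, ".csv")))
        }))
      }
    }
  }
  log_path <- out("run.log")
  writeLines(log_lines, log_path)
  invisible(list(status = 0L, files = c(files, log_path)))
}
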