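# End-to-end experiments: replicate simulation under independent origins,
# the delta-AIC test in aligned and unaligned modes (the alignment-bias
# experiment), and the coestimation Bayes-factor test, with tabular
# summaries and figures.

#' Run the alignment-bias experiment
#'
#' For each replicate of an independent-origins scenario, runs the
#' delta-AIC test twice -- on the progressive alignment of all sequences and
#' on the raw unaligned stacking -- and aggregates the decisions. The
#' headline number is the aligned-mode false-positive rate: the fraction of
#' replicates whose aligned-mode delta AIC is positive (spuriously favoring
#' common ancestry) even though the data were simulated under independent
#' origins.
#'
#' @param config A [scenario_config()] (e.g. `scenario_preset("fig2-scaled")`).
#' @param modes Which modes to run (default both).
#' @param ... Passed to [run_uca_aic_test()].
#' @return An `experiment_summary`: `replicates` tibble (one row per
#'   replicate x mode with delta AIC, delta AIC/site, gap fraction,
#'   decision, or an error message), `summary` tibble of decision fractions
#'   per mode, `false_positive_rate` per mode, and the config.
#' @export
run_fig2_experiment <- function(config, modes = c("aligned", "unaligned"),
                                ...) {
  stopifnot(inherits(config, "scenario_config"))
  groups <- lapply(config$trees, function(t) t$tip.label)
  topologies <- c(config$trees,
                  list(joint = join_trees(config$trees[[1]],
                                          config$trees[[2]], 1)))
  reps <- generate_scenario(config)
  rows <- list()
  for (rep in reps) {
    for (mode in modes) {
      row <- tibble::tibble(
        replicate = rep$index, mode = mode, delta_aic = NA_real_,
        delta_aic_per_site = NA_real_, n_columns = NA_integer_,
        gap_fraction = NA_real_, decision = NA_character_,
        error = NA_character_)
      res <- tryCatch(
        run_uca_aic_test(rep$combined, groups, config$model, mode = mode,
                         topologies = topologies, ...),
        error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$delta_aic <- res$delta_aic
        row$delta_aic_per_site <- res$delta_aic_per_site
        row$n_columns <- res$n_columns
        row$gap_fraction <- gap_fraction(res$alignment)
        row$decision <- res$decision
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  replicates <- dplyr::bind_rows(rows)
  new_experiment_summary(replicates, config, test = "delta_aic")
}

#' Run the coestimation Bayes-factor experiment
#'
#' For each replicate of an independent-origins scenario, runs the three
#' MCMC chains (one per group and one joint), computes the harmonic-mean
#' Bayes factor, and aggregates the three-way decisions against the
#' 10-log-unit band.
#'
#' @param config A [scenario_config()] (e.g. `scenario_preset("fig3-scaled")`).
#' @param n_iter MCMC cycles per chain.
#' @param burn_in Burn-in fraction.
#' @param connecting_branch Length of the branch joining the group trees in
#'   the joint topology.
#' @param ... Passed to [run_mcmc()] via [run_delta_bf_test()].
#' @return An `experiment_summary` whose `replicates` tibble has one row per
#'   replicate with `delta_bf`, `delta_bf_per_site`, posterior medians and
#'   the decision.
#' @export
run_fig3_experiment <- function(config, n_iter = 5000L, burn_in = 0.25,
                                connecting_branch = 1, ...) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_iter < 1L) stop("zero-iteration MCMC configuration")
  groups <- lapply(config$trees, function(t) t$tip.label)
  topologies <- c(config$trees,
                  list(joint = join_trees(config$trees[[1]],
                                          config$trees[[2]],
                                          connecting_branch)))
  reps <- generate_scenario(config)
  rows <- list()
  for (rep in reps) {
    row <- tibble::tibble(
      replicate = rep$index, mode = "coestimation", delta_bf = NA_real_,
      delta_bf_per_site = NA_real_, alignment_length = NA_real_,
      tree_length = NA_real_, hme_unstable = NA, decision = NA_character_,
      error = NA_character_)
    res <- tryCatch(
      run_delta_bf_test(rep$combined, groups, topologies, config$model,
                        n_iter = n_iter, burn_in = burn_in,
                        seed = replicate_seed(config$seed, 10000L + rep$index),
                        ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$delta_bf <- res$delta_bf
      row$delta_bf_per_site <- res$delta_bf_per_site
      row$alignment_length <- res$posterior_median_alignment_length
      row$tree_length <- res$posterior_median_tree_length
      row$hme_unstable <- res$hme_unstable
      row$decision <- res$decision
    }
    rows[[length(rows) + 1L]] <- row
  }
  replicates <- dplyr::bind_rows(rows)
  new_experiment_summary(replicates, config, test = "delta_bf")
}

new_experiment_summary <- function(replicates, config, test) {
  ok <- replicates[is.na(replicates$error), ]
  summary <- ok |>
    dplyr::count(.data$mode, .data$decision) |>
    dplyr::group_by(.data$mode) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  fpr <- ok |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(false_positive_rate = mean(.data$decision == "UCA"),
                     .groups = "drop")
  structure(
    list(replicates = replicates, summary = summary,
         false_positive_rate = fpr, n_replicates = config$n_replicates,
         n_failed = sum(!is.na(replicates$error)) ,
         test = test,
         config = list(name = config$name, n_sites = config$n_sites,
                       n_replicates = config$n_replicates,
                       seed = config$seed,
                       model = config$model$name,
                       trees = vapply(config$trees, write_newick, ""))),
    class = "experiment_summary"
  )
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("experiment '%s' (%s): %d replicates (%d failed)\n",
              x$config$name, x$test, x$n_replicates, x$n_failed))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.experiment_summary <- function(x, ...) x$replicates

#' @export
glance.experiment_summary <- function(x, ...) {
  tidyr::pivot_wider(x$false_positive_rate, names_from = "mode",
                     values_from = "false_positive_rate",
                     names_prefix = "fpr_") |>
    dplyr::mutate(n_replicates = x$n_replicates, n_failed = x$n_failed,
                  test = x$test)
}

#' Write an experiment report to disk
#'
#' Writes `replicates.tsv`, `summary.tsv`, `summary.json`, and the figures
#' for the experiment type (delta AIC per site histograms by mode, or the
#' delta BF histogram and delta BF vs tree length scatter).
#'
#' @param summary An `experiment_summary`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(summary, dir) {
  stopifnot(inherits(summary, "experiment_summary"))
  if (nrow(summary$replicates) == 0) stop("empty summary")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(replicates = file.path(dir, "replicates.tsv"),
             summary = file.path(dir, "summary.tsv"),
             json = file.path(dir, "summary.json"))
  utils::write.table(summary$replicates, paths["replicates"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(summary$summary, paths["summary"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = summary$config,
         summary = summary$summary,
         false_positive_rate = summary$false_positive_rate),
    paths["json"], auto_unbox = TRUE, digits = NA)
  fig <- file.path(dir, paste0(summary$test, ".png"))
  grDevices::png(fig, width = 1400, height = 700, res = 150)
  print(ggplot2::autoplot(summary))
  grDevices::dev.off()
  paths <- c(paths, figure = fig)
  invisible(paths)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.experiment_summary <- function(object, ...) {
  ok <- object$replicates[is.na(object$replicates$error), ]
  if (object$test == "delta_aic") {
    ggplot2::ggplot(ok, ggplot2::aes(x = .data$delta_aic_per_site,
                                     fill = .data$mode)) +
      ggplot2::geom_histogram(bins = 30, alpha = 0.8,
                              position = "identity") +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::facet_wrap(~mode, scales = "free_x") +
      ggplot2::labs(x = expression(Delta * "AIC per site"),
                    y = "replicates",
                    title = "Independent-origins simulations: positive values favor common ancestry") +
      ggplot2::theme_minimal() +
      ggplot2::theme(legend.position = "none")
  } else {
    ggplot2::ggplot(ok, ggplot2::aes(x = .data$tree_length,
                                     y = .data$delta_bf,
                                     size = .data$alignment_length,
                                     colour = .data$decision)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_hline(yintercept = c(-10, 10), linetype = 2) +
      ggplot2::labs(x = "posterior median tree length (joint)",
                    y = expression(Delta * "BF"),
                    title = "Coestimation Bayes factors on independent-origins simulations") +
      ggplot2::theme_minimal()
  }
}
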