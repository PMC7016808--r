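## CSV + plain-text-manifest report layer.  The CSV files are the contract;
## plotting is left to the caller.

write_manifest <- function(out_dir, command, seed = NA, n = NA,
                           outputs = character()) {
  lines <- c(
    paste0("command=", command),
    paste0("package_version=", as.character(utils::packageVersion("mdtcea"))),
    paste0("seed=", seed),
    paste0("n_iterations=", n),
    paste0("timestamp=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("output=", outputs))
  writeLines(lines, file.path(out_dir, "MANIFEST.txt"))
}

warn_placeholders <- function(spec) {
  if (!is.null(spec$placeholders) && nrow(spec$placeholders) > 0L)
    message(sprintf("note: %d placeholder parameter value(s) active",
                    nrow(spec$placeholders)))
}

#' Deterministic base-case report
#'
#' Writes per-strategy discounted outcomes (`outcomes.csv`), all pairwise
#' incremental results (`icers.csv`), the per-cycle trace of each strategy
#' (`trace_<strategy>.csv`) and a run manifest.
#'
#' @param spec A valid `mdt_spec`.
#' @param out_dir Output directory (created if needed).
#' @return The outcomes data frame, invisibly.
#' @export
run_basecase_report <- function(spec, out_dir) {
  stop_if_invalid(spec)
  warn_placeholders(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outcomes <- run_all_strategies(spec)
  tab <- data.frame(
    strategy = names(outcomes),
    discounted_cost = vapply(outcomes, `[[`, numeric(1), "discounted_cost"),
    discounted_qaly = vapply(outcomes, `[[`, numeric(1), "discounted_qaly"),
    undiscounted_cost = vapply(outcomes, `[[`, numeric(1),
                               "undiscounted_cost"),
    undiscounted_qaly = vapply(outcomes, `[[`, numeric(1),
                               "undiscounted_qaly"),
    row.names = NULL)
  utils::write.csv(tab, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(icer_table(outcomes, spec$wtp),
                   file.path(out_dir, "icers.csv"), row.names = FALSE)
  files <- c("outcomes.csv", "icers.csv")
  for (s in spec$strategies) {
    f <- paste0("trace_", tolower(s), ".csv")
    utils::write.csv(trace_table(run_cohort(spec, s), spec),
                     file.path(out_dir, f), row.names = FALSE)
    files <- c(files, f)
  }
  write_manifest(out_dir, "basecase", outputs = files)
  invisible(tab)
}

#' Probabilistic sensitivity analysis report
#'
#' Writes per-iteration draws and outcomes (`psa_draws.csv`), CE-plane
#' coordinates and pairwise CEACs for every comparator of the first
#' strategy, the multi-strategy CEAC, a summary record and a manifest.
#'
#' @param spec A valid `mdt_spec`.
#' @param n Iterations.
#' @param seed RNG seed.
#' @param wtp_grid Thresholds for the acceptability curves.
#' @param out_dir Output directory.
#' @return The `mdt_psa` draw set, invisibly.
#' @export
run_psa_report <- function(spec, n = 10000, seed = 1,
                           wtp_grid = seq(0, 100000, by = 2000), out_dir) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  warn_placeholders(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  draws <- run_psa(spec, n = n, seed = seed)

  strategies <- colnames(draws$cost)
  out <- data.frame(iteration = seq_len(n), draws$params)
  for (s in strategies) {
    out[[paste0("cost_", tolower(s))]] <- draws$cost[, s]
    out[[paste0("qaly_", tolower(s))]] <- draws$qaly[, s]
  }
  utils::write.csv(out, file.path(out_dir, "psa_draws.csv"),
                   row.names = FALSE)
  files <- "psa_draws.csv"

  summaries <- list()
  for (cmp in strategies[-1L]) {
    pair <- c(strategies[1L], cmp)
    tag <- tolower(paste(pair, collapse = "_vs_"))
    utils::write.csv(ce_plane(draws, pair),
                     file.path(out_dir, paste0("ce_plane_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ceac(draws, pair, wtp_grid)),
                     file.path(out_dir, paste0("ceac_", tag, ".csv")),
                     row.names = FALSE)
    s <- psa_summary(draws, pair)
    summaries[[tag]] <- data.frame(
      pair = tag, n = s$n, wtp = s$wtp,
      mean_delta_cost = s$mean_delta_cost,
      mean_delta_qaly = s$mean_delta_qaly,
      icer_ratio_of_means = s$icer_ratio_of_means,
      icer_ne_mean = s$icer_ne_mean,
      prob_cost_effective = s$prob_cost_effective,
      frac_dominant = s$frac_dominant)
    files <- c(files, paste0("ce_plane_", tag, ".csv"),
               paste0("ceac_", tag, ".csv"))
  }
  utils::write.csv(do.call(rbind, summaries),
                   file.path(out_dir, "psa_summary.csv"), row.names = FALSE)
  if (length(strategies) >= 2L) {
    utils::write.csv(as.data.frame(multi_ceac(draws, wtp_grid)),
                     file.path(out_dir, "multi_ceac.csv"),
                     row.names = FALSE)
    files <- c(files, "multi_ceac.csv")
  }
  files <- c(files, "psa_summary.csv")
  write_manifest(out_dir, "psa", seed = seed, n = n, outputs = files)
  invisible(draws)
}

#' Scenario-analysis report
#'
#' Dispatches to the scenario engines and writes their tables: `"tornado"`
#' (one-way sensitivity), `"threshold"` (maximum cost-effective one-off
#' cost, for the total first-month MDT cost and the SBRT course),
#' `"effect"` (effect-size scaling) or `"se"` (standard-error scan).
#'
#' @param spec A valid `mdt_spec`.
#' @param which Scenario name.
#' @param out_dir Output directory.
#' @param pair Strategy pair for the scenario.
#' @param n,seed PSA size and seed (`which = "se"` only).
#' @return The scenario table, invisibly.
#' @export
run_scenario_report <- function(spec, which = c("tornado", "threshold",
                                                "effect", "se"),
                                out_dir, pair = c("MDT", "SURVEILLANCE"),
                                n = 1000, seed = 1) {
  which <- match.arg(which)
  warn_placeholders(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- switch(which,
    tornado = as.data.frame(one_way_tornado(spec, pair)),
    threshold = {
      rows <- lapply(c("first_month_mdt", "sbrt_course"), function(p) {
        r <- cost_threshold_search(spec, p, pair)
        data.frame(cost_parameter = p, feasible = r$feasible,
                   threshold = r$threshold, closed_form = r$closed_form,
                   wtp = r$wtp)
      })
      do.call(rbind, rows)
    },
    effect = effect_scaling_scan(spec, pair = pair),
    se = se_scenario_scan(spec, n = n, seed = seed, pair = pair))
  f <- paste0("scenario_", which, ".csv")
  utils::write.csv(tab, file.path(out_dir, f), row.names = FALSE)
  write_manifest(out_dir, paste0("scenario-", which), seed = seed, n = n,
                 outputs = f)
  invisible(tab)
}
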