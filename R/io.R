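# Result serialization (CSV mirroring the published table layouts, JSON at
# full precision) and figure generation (cost-effectiveness plane, CEAC).

.fmt_icer <- function(r) {
  if (is.na(r$icer_per_qaly)) {
    if (r$dominance == "undefined") return("NA(flag=zero_effect)")
    return(paste0("NA(flag=", r$dominance, ")"))
  }
  as.character(round(r$icer_per_qaly))
}

#' Write a comparison result as CSV and JSON files
#'
#' Produces `table2.csv` (per-strategy discounted life-years, QALYs, payer
#' and societal costs, and incremental ICERs; money rounded to whole CAD),
#' `table3.csv` (per-million event counts for each strategy and their
#' difference, reference minus alternative) and `results.json` (the full
#' result at full precision). An undefined ICER (zero effect difference) is
#' rendered as an explicit flag, never as infinity.
#'
#' @param result A `comparison_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("table2.csv", "table3.csv", "results.json"))

  strat_row <- function(tot, r) {
    data.frame(
      strategy = if (tot$strategy == "fh_based") "FH-based" else "Population",
      ly = round(tot$payer$ly, 2), qaly = round(tot$payer$qaly, 2),
      cost_payer = round(tot$payer$cost), cost_societal = round(tot$societal$cost),
      icer_payer_per_ly = if (is.null(r)) "NA" else
        if (is.na(r$payer$icer_per_ly)) .fmt_icer(r$payer) else
          as.character(round(r$payer$icer_per_ly)),
      icer_payer_per_qaly = if (is.null(r)) "NA" else .fmt_icer(r$payer),
      icer_societal_per_qaly = if (is.null(r)) "NA" else .fmt_icer(r$societal)
    )
  }
  t2 <- rbind(strat_row(result$reference, NULL),
              strat_row(result$alternative, result))
  write.csv(t2, paths[1], row.names = FALSE)

  pm <- result$per_million
  outcome_names <- c(bc_dx = "BC diagnoses", oc_dx = "OC diagnoses",
                     bc_deaths = "BC deaths", oc_deaths = "OC deaths",
                     chd_deaths = "Excess CHD deaths")
  t3 <- data.frame(
    outcome = outcome_names[names(pm$reference)],
    population = round(pm$alternative),
    fh_based = round(pm$reference),
    difference = round(pm$reference) - round(pm$alternative)
  )
  write.csv(t3, paths[2], row.names = FALSE)

  payload <- list(
    reference = unclass(result$reference),
    alternative = unclass(result$alternative),
    payer = result$payer, societal = result$societal,
    per_million = lapply(result$per_million, as.list)
  )
  jsonlite::write_json(payload, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a results JSON written by [write_results()]
#'
#' @param path Path to `results.json`.
#' @return The result payload as a list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Render the cost-effectiveness plane and acceptability curve
#'
#' Writes a scatter of the PSA draws on the incremental cost-effectiveness
#' plane (with willingness-to-pay lines) and the cost-effectiveness
#' acceptability curve with vertical reference lines at the two
#' willingness-to-pay thresholds, plus a small JSON sidecar describing the
#' exported plot data (including the reference-line positions).
#'
#' @param draws A `psa_draws` object.
#' @param ceac_curve A `ceac_curve` (from [ceac()]).
#' @param dir Output directory.
#' @param wtp Willingness-to-pay thresholds to mark.
#' @param perspective Perspective plotted on the CE plane.
#' @return Invisibly, the vector of file paths written.
#' @export
render_figures <- function(draws, ceac_curve, dir, wtp = c(50000, 100000),
                           perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  if (nrow(draws) == 0) stop("PSA draws are empty")
  if (nrow(ceac_curve) == 0) stop("CEAC lambda grid is empty")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("ce_plane.png", "ceac.png", "figure_data.json",
                            "ceac.csv"))

  dc <- draws[[paste0("delta_cost_", perspective)]]
  df <- data.frame(delta_qaly = draws$delta_qaly, delta_cost = dc)
  g1 <- ggplot2::ggplot(df, ggplot2::aes(x = delta_qaly, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs per woman",
                  y = "Incremental cost (CAD) per woman",
                  title = "Cost-effectiveness plane",
                  subtitle = paste0(perspective, " perspective")) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paths[1], g1, width = 6, height = 5, dpi = 150)

  g2 <- ggplot2::ggplot(ceac_curve,
                        ggplot2::aes(x = lambda, y = probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = wtp, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (CAD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paths[2], g2, width = 6, height = 4, dpi = 150)

  meta <- list(
    reference_lines = wtp,
    perspective = perspective,
    n_draws = nrow(draws),
    ceac_range = range(ceac_curve$lambda),
    ceac_probabilities_in_unit_interval =
      all(ceac_curve$probability >= 0 & ceac_curve$probability <= 1)
  )
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(ceac_curve), paths[4], row.names = FALSE)
  invisible(paths)
}
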