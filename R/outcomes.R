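# Aggregation of subgroup x intervention-profile results into per-strategy
# totals, incremental cost-effectiveness, and population impact per million.

#' Run one testing strategy over all decision-tree leaves
#'
#' Enumerates the subgroups of the strategy, expands each into its
#' intervention-profile distribution, runs (or reuses from cache) the Markov
#' cohort for every distinct hazard pathway, accrues costs and outcomes per
#' leaf and weight-averages them into strategy totals.
#'
#' @param strategy `"population"` or `"fh_based"`.
#' @param ps A `brca_params` object.
#' @param epi A `brca_epi` object.
#' @param cache Optional environment reused across calls to memoize cohort
#'   traces by hazard pathway. Traces depend only on hazards, so the cache
#'   stays valid when cost or utility parameters change between calls.
#' @param res_cache Optional environment memoizing accrued leaf results; only
#'   valid within a single parameter set (created fresh by default).
#' @return An object of class `strategy_totals`: list with `strategy`,
#'   `payer` and `societal` (`cost`, `ly`, `qaly` and undiscounted twins),
#'   `events` (per-woman probabilities) and `per_million` (events scaled by
#'   `cohort_scale`).
#' @export
run_strategy <- function(strategy, ps, epi, cache = NULL, res_cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(res_cache)) res_cache <- new.env(parent = emptyenv())
  subs <- enumerate_subgroups(strategy, ps)
  leaves <- list()
  for (i in seq_len(nrow(subs))) {
    sub <- subs[i, , drop = FALSE]
    profiles <- assign_interventions(sub, ps)
    for (j in seq_len(nrow(profiles))) {
      profile <- profiles[j, , drop = FALSE]
      w <- sub$weight * profile$prob
      if (w == 0) next
      mods <- hazard_modifiers(profile, ps)
      key <- .modifier_key(isTRUE(sub$carrier), mods)
      # accrued results are identical across FH strata and strategies for the
      # same (carrier, test result, profile) pathway; memoize both levels
      res_key <- paste("res", key, sub$tested, sub$result, profile$screening,
                       sep = "|")
      res <- res_cache[[res_key]]
      if (is.null(res)) {
        trace <- cache[[key]]
        if (is.null(trace)) {
          trace <- run_cohort(sub, profile, ps, epi)
          cache[[key]] <- trace
        }
        rules <- accrual_rules(sub, profile, ps, epi)
        res <- accrue(trace, rules, ps, epi)
        res_cache[[res_key]] <- res
      }
      leaves[[length(leaves) + 1]] <- list(weight = w, result = res)
    }
  }
  aggregate_strategy(strategy, leaves, ps$settings)
}

#' Aggregate weighted leaf results into strategy totals
#'
#' @param strategy Strategy label.
#' @param leaves List of `list(weight, result)` where `result` is the output
#'   of [accrue()]; weights must sum to 1.
#' @param settings A `brca_settings` (for `cohort_scale`).
#' @return A `strategy_totals` object.
#' @export
aggregate_strategy <- function(strategy, leaves, settings) {
  w <- vapply(leaves, function(l) l$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9)
    stop("leaf weights must sum to 1 (got ", format(sum(w)), ")")
  wavg <- function(f) sum(w * vapply(leaves, f, numeric(1)))
  persp <- function(p) {
    list(cost = wavg(function(l) l$result[[p]]$cost),
         ly = wavg(function(l) l$result[[p]]$ly),
         qaly = wavg(function(l) l$result[[p]]$qaly),
         cost_undiscounted = wavg(function(l) l$result[[p]]$cost_undiscounted),
         ly_undiscounted = wavg(function(l) l$result[[p]]$ly_undiscounted),
         qaly_undiscounted = wavg(function(l) l$result[[p]]$qaly_undiscounted))
  }
  ev_names <- names(leaves[[1]]$result$events)
  events <- vapply(ev_names, function(e)
    wavg(function(l) l$result$events[[e]]), numeric(1))
  structure(list(strategy = strategy, payer = persp("payer"),
                 societal = persp("societal"), events = events,
                 per_million = events * settings$cohort_scale),
            class = "strategy_totals")
}

#' Incremental cost-effectiveness of one strategy against a reference
#'
#' Computes incremental discounted cost and effect, the ICER per life-year
#' and per QALY for each perspective, a dominance classification
#' (`"dominant"` when the alternative saves money and gains health,
#' `"dominated"` for the reverse, `"undefined"` when the effect difference is
#' zero), and per-million event differences (reference minus alternative, so
#' positive numbers are events prevented by the alternative).
#'
#' @param ref `strategy_totals` of the reference strategy (family-history
#'   based testing).
#' @param alt `strategy_totals` of the alternative (population testing).
#' @param settings A `brca_settings`.
#' @return An object of class `comparison_result`.
#' @export
icer <- function(ref, alt, settings = NULL) {
  per <- function(p) {
    d_cost <- alt[[p]]$cost - ref[[p]]$cost
    d_ly <- alt[[p]]$ly - ref[[p]]$ly
    d_qaly <- alt[[p]]$qaly - ref[[p]]$qaly
    ratio <- function(dc, de) {
      if (de == 0) return(NA_real_)
      dc / de
    }
    dominance <- if (d_qaly > 0 && d_cost < 0) "dominant"
      else if (d_qaly < 0 && d_cost > 0) "dominated"
      else if (d_qaly == 0) "undefined"
      else "tradeoff"
    list(delta_cost = d_cost, delta_ly = d_ly, delta_qaly = d_qaly,
         icer_per_ly = ratio(d_cost, d_ly),
         icer_per_qaly = ratio(d_cost, d_qaly),
         dominance = dominance)
  }
  diffs <- ref$per_million - alt$per_million
  structure(list(
    reference = ref, alternative = alt,
    payer = per("payer"), societal = per("societal"),
    per_million = list(reference = ref$per_million,
                       alternative = alt$per_million,
                       difference = diffs),
    settings = settings
  ), class = "comparison_result")
}

#' Net monetary benefit of the alternative strategy
#'
#' @param result A `comparison_result`.
#' @param lambda Willingness-to-pay threshold (CAD per QALY), `>= 0`.
#' @param perspective `"payer"` or `"societal"`.
#' @return `lambda * delta_QALY - delta_cost` in CAD.
#' @export
net_benefit <- function(result, lambda, perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  stopifnot(lambda >= 0)
  p <- result[[perspective]]
  lambda * p$delta_qaly - p$delta_cost
}

#' Compare population-based against family-history-based testing
#'
#' Top-level model run: evaluates both strategies under identical parameters
#' and epidemiology and returns their incremental comparison, with
#' family-history-based testing as the reference.
#'
#' @param ps A `brca_params` object.
#' @param epi A `brca_epi` object.
#' @param cache Optional trace cache environment (reused across calls when
#'   only cost or utility parameters change).
#' @return A `comparison_result`.
#' @examples
#' \donttest{
#' ps <- load_parameters()
#' epi <- generate_inputs()
#' res <- compare_strategies(ps, epi)
#' res$payer$icer_per_qaly
#' }
#' @export
compare_strategies <- function(ps, epi, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  res_cache <- new.env(parent = emptyenv())  # valid for this ps only
  ref <- run_strategy("fh_based", ps, epi, cache, res_cache)
  alt <- run_strategy("population", ps, epi, cache, res_cache)
  icer(ref, alt, ps$settings)
}

#' @export
print.comparison_result <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 2, big.mark = " ")
  cat("<comparison_result> population-based vs FH-based BRCA1/2 testing\n")
  for (p in c("payer", "societal")) {
    r <- x[[p]]
    icer_txt <- if (r$dominance %in% c("dominant", "dominated", "undefined"))
      r$dominance else fmt(r$icer_per_qaly)
    cat(sprintf("  %-8s dC = %s, dQALY = %.5f, ICER = %s CAD/QALY\n",
                p, fmt(r$delta_cost), r$delta_qaly, icer_txt))
  }
  d <- x$per_million$difference
  cat(sprintf(paste0("  per million: %.0f BC and %.0f OC diagnoses prevented, ",
                     "%.0f BC and %.0f OC deaths averted, %.0f excess CHD deaths\n"),
              d[["bc_dx"]], d[["oc_dx"]], d[["bc_deaths"]], d[["oc_deaths"]],
              -d[["chd_deaths"]]))
  invisible(x)
}
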