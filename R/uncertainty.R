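# One-way (tornado) sensitivity analysis, probabilistic sensitivity analysis
# with cost-effectiveness acceptability curves, and threshold analyses on the
# testing cost and the pathogenic-variant prevalence.

#' One-way sensitivity analysis for a single parameter
#'
#' Runs the full dual-arm model twice with the named parameter at its lower
#' and upper bound (all other parameters at base) and reports the resulting
#' ICERs per QALY and their spread.
#'
#' @param ps A `brca_params` object.
#' @param epi A `brca_epi` object.
#' @param name Parameter name; must have a non-fixed variation rule.
#' @param perspective Perspective whose ICER defines the spread.
#' @return A one-row data.frame: `parameter`, `low`, `high` (input bounds),
#'   `icer_low`, `icer_high`, `spread`.
#' @export
one_way <- function(ps, epi, name, perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  if (ps$specs[[name]]$rule == "fixed")
    stop("parameter '", name, "' is fixed and cannot be varied")
  run_at <- function(direction) {
    ps2 <- vary_parameter(ps, name, direction)
    res <- compare_strategies(ps2, epi)
    list(value = parameter_value(ps2, name),
         icer = res[[perspective]]$icer_per_qaly)
  }
  lo <- run_at("low")
  hi <- run_at("high")
  data.frame(parameter = name, low = lo$value, high = hi$value,
             icer_low = lo$icer, icer_high = hi$icer,
             spread = abs(hi$icer - lo$icer))
}

#' Tornado table over all varying parameters
#'
#' @inheritParams one_way
#' @param names Parameters to vary; defaults to every parameter with a
#'   non-fixed variation rule.
#' @return A data.frame of [one_way()] rows sorted by descending spread,
#'   with class `tornado`.
#' @export
tornado <- function(ps, epi, names = varying_parameters(ps),
                    perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  rows <- lapply(names, function(nm) one_way(ps, epi, nm, perspective))
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint independent parameter samples from the fitted
#' distributions (beta for probabilities, gamma for costs, log-normal for
#' utilities; fixed parameters held at base), runs the full dual-arm model
#' for each draw, and records the incremental cost and effect per
#' perspective. One master seed spawns an independent substream per draw, so
#' results do not depend on execution order.
#'
#' @param ps A `brca_params` object.
#' @param epi A `brca_epi` object.
#' @param n_draws Number of draws (defaults to `settings$psa_draws`).
#' @param seed Master seed (defaults to `settings$seed`).
#' @return An object of class `psa_draws`: data.frame with one row per draw
#'   (`draw`, `delta_cost_payer`, `delta_cost_societal`, `delta_qaly`,
#'   `delta_ly`), with the seed as attribute.
#' @export
run_psa <- function(ps, epi, n_draws = NULL, seed = NULL) {
  n_draws <- n_draws %||% ps$settings$psa_draws
  seed <- seed %||% ps$settings$seed
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max - 1L, n_draws)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    psi <- sample_parameters(ps, substreams[i])
    res <- compare_strategies(psi, epi)
    rows[[i]] <- data.frame(
      draw = i,
      delta_cost_payer = res$payer$delta_cost,
      delta_cost_societal = res$societal$delta_cost,
      delta_qaly = res$payer$delta_qaly,
      delta_ly = res$payer$delta_ly
    )
  }
  out <- do.call(rbind, rows)
  if (any(!is.finite(as.matrix(out)))) stop("non-finite PSA draw encountered")
  attr(out, "seed") <- seed
  class(out) <- c("psa_draws", "data.frame")
  out
}

#' Probability that population testing is cost-effective at a threshold
#'
#' Fraction of PSA draws with nonnegative net monetary benefit
#' `lambda * delta_QALY - delta_cost`.
#'
#' @param draws A `psa_draws` object.
#' @param lambda Willingness-to-pay threshold (CAD per QALY).
#' @param perspective `"payer"` or `"societal"`.
#' @return Probability in [0, 1].
#' @export
prob_cost_effective <- function(draws, lambda,
                                perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  dc <- draws[[paste0("delta_cost_", perspective)]]
  mean(lambda * draws$delta_qaly - dc >= 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param draws A `psa_draws` object (nonempty).
#' @param lambda_grid Willingness-to-pay grid; defaults to 0 to 150 000 CAD
#'   per QALY in steps of 1 000.
#' @param perspective `"payer"` or `"societal"`.
#' @return A data.frame (`lambda`, `probability`) of class `ceac_curve`.
#' @export
ceac <- function(draws, lambda_grid = seq(0, 150000, by = 1000),
                 perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  if (nrow(draws) == 0) stop("PSA draws are empty")
  if (length(lambda_grid) == 0) stop("lambda grid is empty")
  probability <- vapply(lambda_grid, function(l)
    prob_cost_effective(draws, l, perspective), numeric(1))
  structure(data.frame(lambda = lambda_grid, probability = probability),
            class = c("ceac_curve", "data.frame"),
            perspective = perspective)
}

#' Threshold analysis on testing cost or carrier prevalence
#'
#' Finds, by bisection, the knob value at which the ICER of population-based
#' testing equals the willingness-to-pay threshold. For the testing-cost
#' knob the ICER increases with cost and the solution is the maximum cost at
#' which population testing remains cost-effective; for the prevalence knob
#' the ICER decreases as prevalence rises and the solution is the minimum
#' combined BRCA1/BRCA2 prevalence. The prevalence knob moves the overall
#' prevalence while holding P(carrier | FH) fixed and re-deriving
#' P(carrier | no FH) from the mixture identity. Monotonicity over the
#' bracket is asserted numerically before searching; if the ICER never
#' crosses `lambda` in the bracket the result is flagged not attainable.
#'
#' @param ps A `brca_params` object.
#' @param epi A `brca_epi` object.
#' @param knob `"test_cost"` or `"prevalence"`.
#' @param lambda Willingness-to-pay threshold (CAD per QALY).
#' @param perspective `"payer"` or `"societal"`.
#' @param bracket Numeric length-2 search interval; defaults to
#'   `c(0, 5000)` CAD for the cost knob and
#'   `c(1.05 * p_fh * prev_fh, 0.05)` for the prevalence knob.
#' @param tol_icer Bisection stops when the ICER at the midpoint is within
#'   this many CAD of `lambda` (default 0.25).
#' @return List with `knob`, `value`, `icer_at_value`, `lambda`,
#'   `perspective`, `direction` (`"maximum"` or `"minimum"`), `bracket`,
#'   `attainable`.
#' @export
threshold_search <- function(ps, epi, knob = c("test_cost", "prevalence"),
                             lambda, perspective = c("payer", "societal"),
                             bracket = NULL, tol_icer = 0.25) {
  knob <- match.arg(knob)
  perspective <- match.arg(perspective)
  cache <- new.env(parent = emptyenv())

  set_knob <- function(x) {
    if (knob == "test_cost") {
      set_parameter(ps, "cost_genetic_testing", x)
    } else {
      p_fh <- parameter_value(ps, "prevalence_fh")
      w_fh <- parameter_value(ps, "p_fh")
      prev_no_fh <- (x - w_fh * p_fh) / (1 - w_fh)
      if (prev_no_fh < 0 || prev_no_fh > 1)
        stop("prevalence knob value ", x, " outside the feasible mixture range")
      ps2 <- set_parameter(ps, "prevalence_overall", x)
      set_parameter(ps2, "prevalence_no_fh", prev_no_fh)
    }
  }
  icer_at <- function(x) {
    # only cost/weight inputs change for the cost knob, so traces are reused;
    # prevalence changes leaf weights only, so traces are reused there too
    res <- compare_strategies(set_knob(x), epi, cache = cache)
    res[[perspective]]$icer_per_qaly
  }

  if (is.null(bracket)) {
    bracket <- if (knob == "test_cost") c(0, 5000) else {
      lo <- 1.05 * parameter_value(ps, "p_fh") * parameter_value(ps, "prevalence_fh")
      c(lo, 0.05)
    }
  }
  f_lo <- icer_at(bracket[1])
  f_hi <- icer_at(bracket[2])
  f_mid <- icer_at(mean(bracket))
  increasing <- f_hi > f_lo
  direction <- if (knob == "test_cost") "maximum" else "minimum"
  mono_ok <- if (increasing) (f_mid >= f_lo && f_mid <= f_hi)
             else (f_mid <= f_lo && f_mid >= f_hi)
  if (!mono_ok)
    stop("ICER is not monotone over the bracket: f(lo) = ", f_lo,
         ", f(mid) = ", f_mid, ", f(hi) = ", f_hi)
  if ((lambda - f_lo) * (lambda - f_hi) > 0) {
    return(list(knob = knob, value = NA_real_, icer_at_value = NA_real_,
                lambda = lambda, perspective = perspective,
                direction = direction, bracket = bracket, attainable = FALSE))
  }

  lo <- bracket[1]; hi <- bracket[2]
  mid <- mean(bracket); f <- f_mid
  for (iter in 1:100) {
    if (abs(f - lambda) <= tol_icer) break
    if ((f > lambda) == increasing) hi <- mid else lo <- mid
    mid <- (lo + hi) / 2
    f <- icer_at(mid)
  }
  list(knob = knob, value = mid, icer_at_value = f, lambda = lambda,
       perspective = perspective, direction = direction, bracket = bracket,
       attainable = TRUE)
}
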