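# Annual-cycle Markov cohort engine. The public state space has 15 states;
# internally the five post-diagnosis years of each cancer/stage combination
# are expanded into one-year tunnel states so that cancer-specific mortality
# applies for exactly five cycles before remission, giving 31 engine states.

.engine_states <- c(
  "Well",
  paste0("BC_E", 1:5), paste0("BC_A", 1:5),
  "BC_Rem", "BC_Rec", "BC_Term", "DeathBC",
  paste0("OC_E", 1:5), paste0("OC_A", 1:5),
  "OC_Rem", "OC_Rec", "OC_Term", "DeathOC",
  "DeathCHD", "DeathOther"
)

.public_states <- c("Well", "EarlyBC", "AdvancedBC", "RemissionBC",
                    "RecurrenceBC", "TerminalBC", "DeathBC",
                    "EarlyOC", "AdvancedOC", "RemissionOC", "RecurrenceOC",
                    "TerminalOC", "DeathOC", "DeathCHD", "DeathOther")

.public_map <- list(
  Well = "Well",
  EarlyBC = paste0("BC_E", 1:5), AdvancedBC = paste0("BC_A", 1:5),
  RemissionBC = "BC_Rem", RecurrenceBC = "BC_Rec", TerminalBC = "BC_Term",
  DeathBC = "DeathBC",
  EarlyOC = paste0("OC_E", 1:5), AdvancedOC = paste0("OC_A", 1:5),
  RemissionOC = "OC_Rem", RecurrenceOC = "OC_Rec", TerminalOC = "OC_Term",
  DeathOC = "DeathOC",
  DeathCHD = "DeathCHD", DeathOther = "DeathOther"
)

.death_states <- c("DeathBC", "DeathOC", "DeathCHD", "DeathOther")

.alive_states <- setdiff(.engine_states, .death_states)

#' Model state space
#'
#' @param engine If `TRUE`, return the expanded engine states (with one-year
#'   tunnel states for the five post-diagnosis years); otherwise the 15
#'   public health states.
#' @return Character vector of state names; the absorbing death states carry
#'   the attribute `"absorbing"`.
#' @export
state_space <- function(engine = FALSE) {
  s <- if (engine) .engine_states else .public_states
  attr(s, "absorbing") <- .death_states
  s
}

.sidx <- function(name) match(name, .engine_states)

#' Combine competing within-cycle risks
#'
#' Converts each annual probability to a rate r = -ln(1 - p), computes the
#' total event probability 1 - exp(-sum(r)), and allocates it to causes in
#' proportion to their rates. If any input probability is 1, those causes
#' absorb the whole cycle (split equally among them).
#'
#' @param annual_probs Numeric vector of annual probabilities in [0, 1].
#' @return Numeric vector of adjusted probabilities (same length) whose sum
#'   is the combined event probability.
#' @examples
#' combine_competing_risks(c(0.02, 0.02))
#' @export
combine_competing_risks <- function(annual_probs) {
  stopifnot(all(annual_probs >= 0 & annual_probs <= 1))
  if (any(annual_probs == 1)) {
    out <- numeric(length(annual_probs))
    certain <- annual_probs == 1
    out[certain] <- 1 / sum(certain)
    return(out)
  }
  r <- -log1p(-annual_probs)
  tot <- sum(r)
  if (tot == 0) return(annual_probs)
  (r / tot) * (1 - exp(-tot))
}

# Vectorized competing-risk combination over cycles: `probs` is a list of
# equal-length vectors (one per cause); returns the list of adjusted vectors.
.compete_vec <- function(probs) {
  r <- lapply(probs, function(p) -log1p(-p))
  tot <- Reduce(`+`, r)
  comb <- 1 - exp(-tot)
  scale <- ifelse(tot > 0, comb / tot, 0)
  lapply(r, function(ri) ri * scale)
}

#' Build the per-age transition matrices for one pathway
#'
#' Constructs the row-stochastic annual transition matrix for every cycle of
#' the simulation, for a woman with the given carrier status under the given
#' hazard modifiers. From Well, breast-cancer incidence (carrier or general
#' population, times the intervention multiplier), ovarian-cancer incidence,
#' fatal excess CHD and all-cause background mortality compete within the
#' cycle; incident cancers split between early and advanced stage. During
#' the five post-diagnosis years the stage-specific annual cancer death
#' probability (derived from 5-year survival) competes with background
#' mortality; survivors enter remission, from which recurrence is possible.
#' Cancer deaths pass through a one-year terminal state. Death states are
#' absorbing. Every row sums to 1 within 1e-12 (verified, never clipped).
#'
#' @param carrier Logical: pathogenic-variant carrier hazards?
#' @param mods A `hazard_modifiers` object.
#' @param ps A `brca_params` object.
#' @param epi A `brca_epi` object.
#' @return 3-d array `[cycle, from, to]` with dimnames over engine states;
#'   cycle t maps ages `start_age + t - 1` to `start_age + t`.
#' @export
build_matrices <- function(carrier, mods, ps, epi) {
  start <- ps$settings$start_age
  horizon <- ps$settings$horizon_age
  ages <- start:(horizon - 1)
  n <- length(ages)
  S <- length(.engine_states)

  mv <- modifier_vectors(mods, ages)
  inc_bc <- .lookup(epi$incidence, if (carrier) "bc_carrier" else "bc_general", ages)
  inc_oc <- .lookup(epi$incidence, if (carrier) "oc_carrier" else "oc_general", ages)
  p_bc <- pmin(inc_bc * mv$bc, 1)
  p_oc <- pmin(inc_oc * mv$oc, 1)
  p_chd <- mv$chd_fatal
  q <- .lookup(epi$life, "qx", ages)
  if (any(c(p_bc, p_oc, p_chd, q) >= 1))
    stop("annual probability reached 1; competing-risk combination undefined")

  A <- array(0, dim = c(n, S, S),
             dimnames = list(NULL, .engine_states, .engine_states))
  set <- function(from, to, val) A[, .sidx(from), .sidx(to)] <<- val

  # Well row
  adj <- .compete_vec(list(bc = p_bc, oc = p_oc, chd = p_chd, oth = q))
  split <- epi$survival$stage_split_early
  set("Well", "BC_E1", adj$bc * split[["BC"]])
  set("Well", "BC_A1", adj$bc * (1 - split[["BC"]]))
  set("Well", "OC_E1", adj$oc * split[["OC"]])
  set("Well", "OC_A1", adj$oc * (1 - split[["OC"]]))
  set("Well", "DeathCHD", adj$chd)
  set("Well", "DeathOther", adj$oth)
  set("Well", "Well", 1 - (adj$bc + adj$oc + adj$chd + adj$oth))

  for (cc in c("BC", "OC")) {
    dth <- epi$survival$annual_death[[cc]]
    rec_p <- epi$survival$annual_recurrence[[cc]]
    for (stage in c("E", "A")) {
      d <- dth[[if (stage == "E") "early" else "advanced"]]
      for (k in 1:5) {
        from <- paste0(cc, "_", stage, k)
        a2 <- .compete_vec(list(ca = rep(d, n), oth = q))
        stay_to <- if (k < 5) paste0(cc, "_", stage, k + 1) else paste0(cc, "_Rem")
        set(from, paste0(cc, "_Term"), a2$ca)
        set(from, "DeathOther", a2$oth)
        set(from, stay_to, 1 - (a2$ca + a2$oth))
      }
    }
    a3 <- .compete_vec(list(rec = rep(rec_p, n), oth = q))
    set(paste0(cc, "_Rem"), paste0(cc, "_Rec"), a3$rec)
    set(paste0(cc, "_Rem"), "DeathOther", a3$oth)
    set(paste0(cc, "_Rem"), paste0(cc, "_Rem"), 1 - (a3$rec + a3$oth))
    a4 <- .compete_vec(list(ca = rep(dth[["advanced"]], n), oth = q))
    set(paste0(cc, "_Rec"), paste0(cc, "_Term"), a4$ca)
    set(paste0(cc, "_Rec"), "DeathOther", a4$oth)
    set(paste0(cc, "_Rec"), paste0(cc, "_Rec"), 1 - (a4$ca + a4$oth))
    set(paste0(cc, "_Term"), paste0("Death", cc), 1)
  }
  for (dd in .death_states) set(dd, dd, 1)

  rs <- rowSums(matrix(A, n * S, S))
  if (any(abs(rs - 1) > 1e-12))
    stop("transition matrix row sums deviate from 1 by more than 1e-12")
  if (any(A < 0) || any(A > 1))
    stop("transition probability outside [0, 1]")
  attr(A, "ages") <- ages
  A
}

#' Single-age transition matrix
#'
#' Convenience wrapper around [build_matrices()] returning the row-stochastic
#' transition matrix applying at one age for a given subgroup and
#' intervention profile.
#'
#' @param age Age (years) at the start of the cycle; must lie in
#'   `[start_age, horizon_age - 1]`.
#' @param sub One row of [enumerate_subgroups()].
#' @param profile One row of [assign_interventions()].
#' @param ps A `brca_params` object.
#' @param epi A `brca_epi` object.
#' @return A 31 x 31 row-stochastic matrix over engine states.
#' @export
build_matrix <- function(age, sub, profile, ps, epi) {
  start <- ps$settings$start_age
  if (age < start || age >= ps$settings$horizon_age)
    stop("age must lie within [start_age, horizon_age - 1]")
  mods <- hazard_modifiers(profile, ps)
  A <- build_matrices(isTRUE(sub$carrier), mods, ps, epi)
  A[age - start + 1, , ]
}

#' Discount a value to present value at the entry cycle
#'
#' @param value Amount (cost or QALY).
#' @param cycle Cycle index (0 = entry age; no discounting).
#' @param rate Annual discount rate.
#' @return `value / (1 + rate)^cycle`.
#' @examples
#' discount(100, 2, 0.015)
#' @export
discount <- function(value, cycle, rate) {
  stopifnot(rate >= 0)
  value / (1 + rate)^cycle
}

#' Propagate the cohort through the Markov model
#'
#' Starts the whole cohort in Well at the entry age and applies the annual
#' transition matrices until the horizon age, recording state occupancy at
#' every cycle and the incident flows into diagnosis, terminal and death
#' states (used for event counting and one-time costs).
#'
#' @inheritParams build_matrix
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (`(n_cycles + 1) x 31` matrix, rows summing to 1), `ages`, `flows` (per
#'   cycle: `dx_bc`, `dx_oc`, `term_bc`, `term_oc`, `death_bc`, `death_oc`,
#'   `death_chd`, `death_other`), `carrier` and the inputs' provenance.
#' @export
run_cohort <- function(sub, profile, ps, epi) {
  mods <- hazard_modifiers(profile, ps)
  A <- build_matrices(isTRUE(sub$carrier), mods, ps, epi)
  trace_from_matrices(A, carrier = isTRUE(sub$carrier),
                      start_age = ps$settings$start_age)
}

trace_from_matrices <- function(A, carrier, start_age) {
  n <- dim(A)[1]
  S <- dim(A)[2]
  occ <- matrix(0, n + 1, S, dimnames = list(NULL, .engine_states))
  occ[1, "Well"] <- 1
  for (t in seq_len(n)) occ[t + 1, ] <- occ[t, , drop = FALSE] %*% A[t, , ]
  tot <- rowSums(occ)
  if (any(abs(tot - 1) > 1e-9))
    stop("cohort occupancy not conserved within 1e-9")

  new_in <- function(state) occ[-1, state]
  newdx <- function(states) rowSums(occ[-1, states, drop = FALSE])
  flows <- list(
    dx_bc = newdx(c("BC_E1", "BC_A1")),
    dx_oc = newdx(c("OC_E1", "OC_A1")),
    term_bc = new_in("BC_Term"),
    term_oc = new_in("OC_Term"),
    death_bc = diff(occ[, "DeathBC"]),
    death_oc = diff(occ[, "DeathOC"]),
    death_chd = diff(occ[, "DeathCHD"]),
    death_other = diff(occ[, "DeathOther"])
  )
  structure(list(occupancy = occ, ages = start_age + 0:n, flows = flows,
                 carrier = carrier), class = "cohort_trace")
}

#' Aggregate a trace's occupancy to the 15 public health states
#'
#' @param trace A `cohort_trace`.
#' @return Matrix `(n_cycles + 1) x 15` over the public state space.
#' @export
public_occupancy <- function(trace) {
  out <- sapply(.public_map, function(cols)
    rowSums(trace$occupancy[, cols, drop = FALSE]))
  colnames(out) <- names(.public_map)
  out
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  cat("<cohort_trace> ", n, " annual cycles, ages ", x$ages[1], "-",
      x$ages[n + 1], ", carrier = ", x$carrier, "\n", sep = "")
  cat(sprintf("  cumulative: BC dx %.4f, OC dx %.4f, alive at end %.4f\n",
              sum(x$flows$dx_bc), sum(x$flows$dx_oc),
              1 - sum(x$occupancy[n + 1, .death_states])))
  invisible(x)
}

#' Individual-level microsimulation of the same transition matrices
#'
#' Simulates `n` women through the exact matrices the cohort engine uses, by
#' chained multinomial draws of state counts, and returns the occupancy
#' proportions. Used as an independent stochastic oracle for the
#' deterministic cohort propagation.
#'
#' @inheritParams build_matrix
#' @param n Number of simulated women.
#' @param seed Random seed.
#' @return Matrix `(n_cycles + 1) x 31` of occupancy proportions.
#' @export
microsimulate_cohort <- function(sub, profile, ps, epi, n = 200000, seed = 1L) {
  mods <- hazard_modifiers(profile, ps)
  A <- build_matrices(isTRUE(sub$carrier), mods, ps, epi)
  ncyc <- dim(A)[1]
  S <- dim(A)[2]
  set.seed(seed)
  counts <- matrix(0L, ncyc + 1, S, dimnames = list(NULL, .engine_states))
  counts[1, "Well"] <- n
  for (t in seq_len(ncyc)) {
    nxt <- numeric(S)
    occupied <- which(counts[t, ] > 0)
    for (s in occupied) {
      row <- A[t, s, ]
      nz <- which(row > 0)
      if (length(nz) == 1) {
        nxt[nz] <- nxt[nz] + counts[t, s]
      } else {
        draw <- stats::rmultinom(1, counts[t, s], row[nz])
        nxt[nz] <- nxt[nz] + draw[, 1]
      }
    }
    counts[t + 1, ] <- nxt
  }
  counts / n
}
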