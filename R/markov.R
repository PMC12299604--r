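# Cohort state-transition engine.
#
# Five mutually exclusive health states; hospital states are one-cycle
# tunnels (survivors return to HEALTHY after one year), both death states
# absorb. The vaccination decision sits upstream of the Markov layer: an arm
# is a matrix, and protection is constant over the horizon.

#' Health states of the cohort model
#'
#' In order: healthy, hospitalized community-acquired pneumonia (CAP),
#' hospitalized pneumococcal meningitis, pneumococcal-related death,
#' all-cause death. The two death states are absorbing; the hospital states
#' are one-cycle tunnels.
#'
#' @format Character vector of length 5.
#' @export
health_states <- c("HEALTHY", "HOSP_CAP", "HOSP_MENINGITIS",
                   "PNEUMO_DEATH", "ALL_CAUSE_DEATH")

#' Model arms
#'
#' @format Character vector: `"VACCINATED"`, `"UNVACCINATED"`.
#' @export
arms <- c("VACCINATED", "UNVACCINATED")

.cfr <- function(mortality, incidence, disease) {
  if (incidence == 0) {
    if (mortality == 0) return(0)
    stop(disease, ": mortality rate positive with zero incidence",
         call. = FALSE)
  }
  cfr <- mortality / incidence
  if (cfr > 1) {
    stop(disease, ": case fatality ratio ", signif(cfr, 4),
         " exceeds 1 (mortality rate exceeds incidence rate)", call. = FALSE)
  }
  cfr
}

#' Build the annual transition matrix for one arm
#'
#' From HEALTHY the cohort can be hospitalized for CAP or meningitis, die of
#' any cause, or stay healthy (residual). Disease entry probabilities are the
#' per-100,000 incidence rates converted per person and, in the vaccinated
#' arm, reduced by the single-dose efficacy (optionally scaled by serotype
#' coverage when `settings$serotype_switch` is `TRUE`). From a hospital state
#' the case either dies (case fatality = mortality rate / incidence rate) or
#' returns to HEALTHY. Death rows are unit vectors onto themselves.
#'
#' Competing exits from HEALTHY are applied as independent probabilities with
#' the residual to HEALTHY; their sum is about 7e-3 at base case, so no
#' normalization is applied.
#'
#' @param p A validated [load_parameters()] set.
#' @param arm `"VACCINATED"` or `"UNVACCINATED"`.
#' @return A `ppv_transition_matrix`: 5x5 row-stochastic matrix with
#'   dimnames `health_states` and attribute `arm`.
#' @examples
#' m <- build_transition_matrix(load_parameters(), "UNVACCINATED")
#' rowSums(m)
#' @export
build_transition_matrix <- function(p, arm = c("UNVACCINATED", "VACCINATED")) {
  arm <- match.arg(arm)
  conv <- p$settings$rate_conversion
  epi <- p$epidemiology

  s <- if (isTRUE(p$settings$serotype_switch)) epi$serotype_coverage$base else 1
  red_cap <- if (arm == "VACCINATED") 1 - p$vaccine$ve_pneumonia$base * s else 1
  red_men <- if (arm == "VACCINATED") 1 - p$vaccine$ve_meningitis$base * s else 1

  p_cap <- per_capita_rate(epi$cap_incidence$base, 1e5, conv) * red_cap
  p_men <- per_capita_rate(epi$men_incidence$base, 1e5, conv) * red_men
  p_nat <- per_capita_rate(epi$natural_mortality$base, 1e3, conv)

  cfr_cap <- .cfr(epi$cap_mortality$base, epi$cap_incidence$base, "pneumonia")
  cfr_men <- .cfr(epi$men_mortality$base, epi$men_incidence$base, "meningitis")

  exit <- p_cap + p_men + p_nat
  if (exit > 1) {
    stop("exit probabilities from HEALTHY sum to ", signif(exit, 4),
         " > 1; rates incompatible with a 1-year cycle", call. = FALSE)
  }

  m <- matrix(0, 5, 5, dimnames = list(health_states, health_states))
  m["HEALTHY", "HOSP_CAP"] <- p_cap
  m["HEALTHY", "HOSP_MENINGITIS"] <- p_men
  m["HEALTHY", "ALL_CAUSE_DEATH"] <- p_nat
  m["HEALTHY", "HEALTHY"] <- 1 - exit
  m["HOSP_CAP", "PNEUMO_DEATH"] <- cfr_cap
  m["HOSP_CAP", "HEALTHY"] <- 1 - cfr_cap
  m["HOSP_MENINGITIS", "PNEUMO_DEATH"] <- cfr_men
  m["HOSP_MENINGITIS", "HEALTHY"] <- 1 - cfr_men
  m["PNEUMO_DEATH", "PNEUMO_DEATH"] <- 1
  m["ALL_CAUSE_DEATH", "ALL_CAUSE_DEATH"] <- 1

  structure(m, arm = arm, class = c("ppv_transition_matrix", "matrix", "array"))
}

#' Run a closed cohort through the transition matrix
#'
#' All members start in HEALTHY. Occupancy is propagated by
#' `occupancy[c + 1, ] = occupancy[c, ] %*% m` for `c = 0..cycles - 1`
#' (expected values, no sampling, no half-cycle correction). Incident cases
#' for a cycle are the inflow into each state excluding self-transitions, so
#' for the tunnel hospital states they equal the new hospitalizations that
#' year.
#'
#' @param m A [build_transition_matrix()] result (any row-stochastic 5x5
#'   matrix over `health_states` is accepted).
#' @param n0 Initial cohort size (>= 0; fractional allowed).
#' @param cycles Number of annual cycles (>= 1).
#' @return A `ppv_cohort_trace`: list with `occupancy`
#'   ((cycles + 1) x 5 matrix, row 1 = cycle 0), `incident`
#'   (cycles x 5 inflow matrix), `n0`, `cycles`, `arm`.
#' @examples
#' p <- load_parameters()
#' tr <- run_cohort(build_transition_matrix(p, "UNVACCINATED"), 1e5, 5)
#' head(as.data.frame(tr))
#' @export
run_cohort <- function(m, n0, cycles = 5) {
  if (n0 < 0) stop("cohort size must be non-negative", call. = FALSE)
  if (cycles < 1) stop("cycles must be >= 1", call. = FALSE)
  stopifnot(is.matrix(m), nrow(m) == 5, ncol(m) == 5)

  occ <- matrix(0, cycles + 1, 5,
                dimnames = list(0:cycles, health_states))
  inc <- matrix(0, cycles, 5, dimnames = list(1:cycles, health_states))
  occ[1, "HEALTHY"] <- n0
  for (c in seq_len(cycles)) {
    occ[c + 1, ] <- occ[c, , drop = FALSE] %*% m
    # inflow excluding self-loops
    inc[c, ] <- occ[c + 1, ] - occ[c, ] * diag(m)
  }
  structure(
    list(occupancy = occ, incident = inc, n0 = n0, cycles = cycles,
         arm = attr(m, "arm")),
    class = "ppv_cohort_trace"
  )
}

#' @export
print.ppv_cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace: n0 = %g, %d cycles%s\n", x$n0, x$cycles,
              if (is.null(x$arm)) "" else paste0(" (", x$arm, ")")))
  print(round(x$occupancy, 3))
  invisible(x)
}

#' Tidy export of a cohort trace
#'
#' @param x A `ppv_cohort_trace`.
#' @param ... Unused.
#' @return Long data frame with columns `cycle`, `state`, `count`,
#'   `incident_cases` (NA at cycle 0).
#' @export
as.data.frame.ppv_cohort_trace <- function(x, ...) {
  cycles <- 0:x$cycles
  out <- expand.grid(cycle = cycles, state = health_states,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- as.vector(x$occupancy)
  inc <- rbind(NA_real_, x$incident)
  out$incident_cases <- as.vector(inc)
  out[order(out$cycle, match(out$state, health_states)), c(
    "cycle", "state", "count", "incident_cases")]
}

#' Per-cycle incident hospitalized cases for one disease
#'
#' @param trace A [run_cohort()] trace.
#' @param disease `"CAP"` or `"MENINGITIS"`.
#' @return Numeric vector (length `cycles`) of expected new hospitalizations
#'   per cycle; fractional values are expected counts.
#' @export
annual_cases <- function(trace, disease = c("CAP", "MENINGITIS")) {
  disease <- match.arg(disease)
  state <- if (disease == "CAP") "HOSP_CAP" else "HOSP_MENINGITIS"
  unname(trace$incident[, state])
}
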