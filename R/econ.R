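# Cost and benefit accounting, discounting, and strategy comparison.
#
# Accounting conventions: all internal arithmetic in CNY, converted to USD
# only at reporting time. Programme costs are booked at t = 0 undiscounted
# (a single-dose campaign at programme start); benefits -- pneumococcal
# disease costs averted -- accrue in years 1..n and are discounted at rate r.
# Deaths are not monetized; the benefit is purely disease cost averted.

#' Present-value annuity factor
#'
#' Sum of discount factors \eqn{\sum_{t=1}^{n} (1+r)^{-t}}; converts a
#' constant annual amount into its present value at the start of year 1.
#'
#' @param r Annual discount rate (>= 0).
#' @param n Horizon in years (>= 1).
#' @return The annuity factor; equals `n` when `r = 0`.
#' @examples
#' annuity_factor(0.03, 5) # 4.579707
#' @export
annuity_factor <- function(r, n) {
  stopifnot(r >= 0, n >= 1)
  if (r == 0) return(as.numeric(n))
  (1 - (1 + r)^(-n)) / r
}

#' Doses administered under a coverage assumption
#'
#' @param population Target population size.
#' @param coverage Uptake proportion on [0, 1].
#' @param rounded Round to whole doses? Default `FALSE`: downstream
#'   accounting keeps the unrounded expectation.
#' @return Number of doses.
#' @examples
#' doses_administered(1367900, 0.1343)        # 183708.97
#' doses_administered(1367900, 0.1343, TRUE)  # 183709
#' @export
doses_administered <- function(population, coverage, rounded = FALSE) {
  stopifnot(coverage >= 0, coverage <= 1, population >= 0)
  d <- population * coverage
  if (rounded) round(d) else d
}

.breakdown <- function(components, class, currency = "CNY") {
  structure(c(components, list(total = sum(unlist(components)),
                               currency = currency)),
            class = class)
}

#' Programme cost of administering a number of doses
#'
#' Components, all incurred at t = 0 and undiscounted: vaccine procurement
#' (`doses x (1 + wastage) x price`), cold chain and consumables, delivery
#' service, and expected severe adverse-event treatment
#' (`doses x ae_incidence / 1e5 x ae_cost`).
#'
#' @param doses Doses administered (>= 0).
#' @param p Parameter set.
#' @return A `ppv_cost_breakdown`: list with `procurement`, `consumables`,
#'   `service`, `adverse_events`, `total`, `currency` (CNY).
#' @export
program_cost <- function(doses, p) {
  stopifnot(doses >= 0)
  co <- p$costs
  .breakdown(list(
    procurement = doses * (1 + p$vaccine$wastage$base) * co$vaccine_price$base,
    consumables = doses * co$consumables_per_dose$base,
    service = doses * co$service_per_dose$base,
    adverse_events = doses * p$vaccine$ae_incidence$base / 1e5 * co$ae_cost$base
  ), "ppv_cost_breakdown")
}

#' Expected annual cases averted by vaccinating `doses` people
#'
#' Closed form `doses x incidence / 1e5 x efficacy` (times serotype coverage
#' when the serotype switch is on). Identical, by construction, to the
#' first-cycle difference in incident cases between equal-sized unvaccinated
#' and vaccinated cohorts from the Markov engine; the test suite asserts the
#' cross-check.
#'
#' @param p Parameter set.
#' @param doses Doses administered.
#' @param disease `"CAP"` or `"MENINGITIS"`.
#' @return Expected cases averted per year (fractional).
#' @export
averted_annual_cases <- function(p, doses, disease = c("CAP", "MENINGITIS")) {
  disease <- match.arg(disease)
  conv <- p$settings$rate_conversion
  s <- if (isTRUE(p$settings$serotype_switch))
    p$epidemiology$serotype_coverage$base else 1
  if (disease == "CAP") {
    doses * per_capita_rate(p$epidemiology$cap_incidence$base, 1e5, conv) *
      p$vaccine$ve_pneumonia$base * s
  } else {
    doses * per_capita_rate(p$epidemiology$men_incidence$base, 1e5, conv) *
      p$vaccine$ve_meningitis$base * s
  }
}

#' Present value of disease costs averted
#'
#' Each averted case avoids its hospitalization cost plus caregiver income
#' loss (`caregiver_daily x caregiver_days`). The constant annual amount is
#' discounted over years 1..n via [annuity_factor()].
#'
#' @param p Parameter set.
#' @param averted Named list or vector with elements `cap` and `meningitis`:
#'   annual averted case counts.
#' @return A `ppv_benefit_breakdown`: list with `averted_cap_medical`,
#'   `averted_men_medical`, `averted_caregiver`, `total`, `currency` (CNY).
#' @export
benefit_present_value <- function(p, averted) {
  cap <- averted[["cap"]]
  men <- averted[["meningitis"]]
  stopifnot(cap >= 0, men >= 0)
  af <- annuity_factor(p$settings$discount_rate$base, p$settings$horizon_years)
  care_per_case <- p$costs$caregiver_daily$base * p$costs$caregiver_days$base
  .breakdown(list(
    averted_cap_medical = cap * p$costs$cap_hospitalization$base * af,
    averted_men_medical = men * p$costs$men_hospitalization$base * af,
    averted_caregiver = (cap + men) * care_per_case * af
  ), "ppv_benefit_breakdown")
}

#' @export
print.ppv_cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "Programme cost (%s): total %.2f\n  procurement %.2f | consumables %.2f | service %.2f | adverse events %.2f\n",
    x$currency, x$total, x$procurement, x$consumables, x$service,
    x$adverse_events))
  invisible(x)
}

#' @export
print.ppv_benefit_breakdown <- function(x, ...) {
  cat(sprintf(
    "Discounted benefit (%s): total %.2f\n  CAP medical %.2f | meningitis medical %.2f | caregiver %.2f\n",
    x$currency, x$total, x$averted_cap_medical, x$averted_men_medical,
    x$averted_caregiver))
  invisible(x)
}

#' Net benefit
#'
#' @param benefit,cost Discounted totals in the same currency.
#' @return `benefit - cost`.
#' @export
net_benefit <- function(benefit, cost) benefit - cost

#' Benefit-cost ratio
#'
#' @param benefit,cost Discounted totals in the same currency; `cost` must be
#'   strictly positive.
#' @return `benefit / cost`; values above 1 are conventionally favorable.
#' @export
benefit_cost_ratio <- function(benefit, cost) {
  if (cost <= 0) stop("benefit-cost ratio undefined for cost <= 0",
                      call. = FALSE)
  benefit / cost
}

#' Convert a cost or benefit breakdown between CNY and USD
#'
#' @param x A `ppv_cost_breakdown` or `ppv_benefit_breakdown`.
#' @param to Target currency, `"CNY"` or `"USD"`.
#' @param rate CNY per USD.
#' @return The breakdown in the target currency.
#' @export
convert_currency <- function(x, to = c("USD", "CNY"), rate) {
  to <- match.arg(to)
  stopifnot(rate > 0)
  if (x$currency == to) return(x)
  f <- if (to == "USD") 1 / rate else rate
  for (nm in setdiff(names(x), "currency")) {
    if (is.numeric(x[[nm]])) x[[nm]] <- x[[nm]] * f
  }
  x$currency <- to
  x
}

#' Evaluate one vaccination strategy end to end
#'
#' Computes doses from coverage, programme cost, annual averted cases (CAP
#' and meningitis), discounted benefit, net benefit and BCR, in CNY with a
#' USD view attached.
#'
#' @param p Parameter set.
#' @param strategy `"free"` (government-funded), `"self"` (self-paid) or
#'   `"none"`.
#' @param doses Override the dose count (e.g. to use a published head count
#'   instead of `population x coverage`); default computes from coverage.
#' @return A `ppv_strategy_result`: list with `strategy`, `doses`,
#'   `doses_rounded`, `cost`, `benefit` (CNY breakdowns), `net_benefit`,
#'   `bcr` (NA for a costless strategy), `averted` (annual counts), and the
#'   exchange rate used for USD views.
#' @examples
#' res <- evaluate_strategy(load_parameters(), "free")
#' res$bcr
#' @export
evaluate_strategy <- function(p, strategy = c("free", "self", "none"),
                              doses = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(doses)) {
    cov <- switch(strategy,
                  free = p$vaccine$coverage_free$base,
                  self = p$vaccine$coverage_self$base,
                  none = 0)
    doses <- doses_administered(p$settings$population, cov)
  }
  cost <- program_cost(doses, p)
  averted <- list(cap = averted_annual_cases(p, doses, "CAP"),
                  meningitis = averted_annual_cases(p, doses, "MENINGITIS"))
  benefit <- benefit_present_value(p, averted)
  structure(list(
    strategy = strategy,
    doses = doses,
    doses_rounded = round(doses),
    cost = cost,
    benefit = benefit,
    net_benefit = net_benefit(benefit$total, cost$total),
    bcr = if (cost$total > 0) benefit_cost_ratio(benefit$total, cost$total)
          else NA_real_,
    averted = averted,
    cny_per_usd = p$costs$cny_per_usd$base
  ), class = "ppv_strategy_result")
}

#' @export
print.ppv_strategy_result <- function(x, ...) {
  rate <- x$cny_per_usd
  cat(sprintf("Strategy '%s': %s doses\n", x$strategy,
              format(x$doses_rounded, big.mark = ",")))
  cat(sprintf("  cost    %14.2f CNY (%12.2f USD)\n", x$cost$total,
              x$cost$total / rate))
  cat(sprintf("  benefit %14.2f CNY (%12.2f USD)\n", x$benefit$total,
              x$benefit$total / rate))
  cat(sprintf("  net benefit %10.2f CNY (%12.2f USD)\n", x$net_benefit,
              x$net_benefit / rate))
  cat(sprintf("  BCR %.4f | averted/yr: CAP %.2f, meningitis %.3f\n",
              x$bcr, x$averted$cap, x$averted$meningitis))
  invisible(x)
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' Monetary-on-monetary ICER: incremental programme cost per incremental
#' unit of disease cost averted, `(cost_a - cost_b) / (benefit_a -
#' benefit_b)`. Currency-invariant (both numerator and denominator scale by
#' the exchange rate).
#'
#' @param a,b `ppv_strategy_result` objects (a is the more intensive
#'   strategy).
#' @return The ICER.
#' @export
icer <- function(a, b) {
  db <- a$benefit$total - b$benefit$total
  if (db == 0) stop("ICER undefined: zero benefit difference", call. = FALSE)
  (a$cost$total - b$cost$total) / db
}

#' Table-style comparison of vaccination strategies
#'
#' @param p Parameter set.
#' @param strategies Strategies to evaluate (default free, self, none).
#' @return Data frame with one row per strategy: doses, cost, benefit, net
#'   benefit in both currencies, BCR, annual averted cases, and the ICER of
#'   free vs self-paid on the free row (NA elsewhere). Strategy results are
#'   attached as attribute `"results"`.
#' @export
compare_strategies <- function(p, strategies = c("free", "self", "none")) {
  res <- lapply(strategies, function(s) evaluate_strategy(p, s))
  names(res) <- strategies
  rate <- p$costs$cny_per_usd$base
  tab <- do.call(rbind, lapply(res, function(r) {
    data.frame(
      strategy = r$strategy,
      doses = r$doses_rounded,
      cost_cny = r$cost$total,
      benefit_cny = r$benefit$total,
      net_benefit_cny = r$net_benefit,
      cost_usd = r$cost$total / rate,
      benefit_usd = r$benefit$total / rate,
      net_benefit_usd = r$net_benefit / rate,
      bcr = r$bcr,
      averted_cap_per_year = r$averted$cap,
      averted_meningitis_per_year = r$averted$meningitis,
      stringsAsFactors = FALSE
    )
  }))
  tab$icer_vs_self_paid <- NA_real_
  if (all(c("free", "self") %in% strategies)) {
    tab$icer_vs_self_paid[tab$strategy == "free"] <-
      icer(res[["free"]], res[["self"]])
  }
  rownames(tab) <- NULL
  attr(tab, "results") <- res
  tab
}
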