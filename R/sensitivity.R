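# One-way sensitivity analysis over parameter ranges.
#
# Endpoints are always recomputed through the full strategy pipeline -- no
# linear interpolation -- so near-insensitivity (e.g. of the meningitis
# parameters) is an emergent result, not an assumption.

#' Dotted paths of all parameters with a non-degenerate range
#'
#' @param p Parameter set.
#' @return Character vector of `group.field` paths with `low < high`.
#' @export
ranged_parameters <- function(p) {
  out <- character(0)
  for (g in names(.ranged_fields)) {
    for (f in .ranged_fields[[g]]) {
      r <- p[[g]][[f]]
      if (inherits(r, "ranged") && r$low < r$high) {
        out <- c(out, paste(g, f, sep = "."))
      }
    }
  }
  out
}

#' Default key-parameter set for the tornado analysis
#'
#' The parameters the reported sensitivity analysis varies: vaccine efficacy
#' and hospitalization cost for both diseases, plus the discount rate. Pass
#' `parameters = "all"` to [tornado()] to cover every ranged parameter
#' instead (which adds, notably, the disease incidence ranges).
#'
#' @return Character vector of dotted parameter paths.
#' @export
key_parameters <- function() {
  c("vaccine.ve_pneumonia", "vaccine.ve_meningitis",
    "costs.cap_hospitalization", "costs.men_hospitalization",
    "settings.discount_rate")
}

.pipeline_metric <- function(p, metric, strategy, currency) {
  r <- evaluate_strategy(p, strategy)
  val <- if (metric == "BCR") r$bcr else r$net_benefit
  if (metric == "NB" && currency == "USD") val <- val / r$cny_per_usd
  val
}

#' One-way sensitivity of a strategy metric to one parameter
#'
#' Re-runs the full pipeline twice with the parameter at its low and high
#' bound (all other parameters at base) and reports both outcomes. The input
#' parameter set is never modified. A degenerate range (`low == high`)
#' returns `NULL` as a skip signal rather than an error.
#'
#' @param p Parameter set (bases used for everything else).
#' @param parameter Dotted path, e.g. `"vaccine.ve_pneumonia"`.
#' @param metric `"BCR"` or `"NB"` (net benefit).
#' @param strategy Strategy to evaluate (default `"free"`).
#' @param currency Currency for NB outcomes (`"USD"` default; BCR is
#'   dimensionless).
#' @return A one-row data frame (`ppv_tornado_entry`) with columns
#'   `parameter`, `low_input`, `high_input`, `outcome_low`, `outcome_high`,
#'   `spread`; or `NULL` for a degenerate range.
#' @examples
#' one_way(load_parameters(), "vaccine.ve_pneumonia", "BCR", "free")
#' @export
one_way <- function(p, parameter, metric = c("BCR", "NB"),
                    strategy = c("free", "self"),
                    currency = c("USD", "CNY")) {
  metric <- match.arg(metric)
  strategy <- match.arg(strategy)
  currency <- match.arg(currency)
  r <- param_value(p, parameter, "ranged")
  if (!inherits(r, "ranged")) {
    stop("'", parameter, "' is not a ranged parameter", call. = FALSE)
  }
  if (r$low == r$high) return(NULL)
  lo <- .pipeline_metric(set_param(p, parameter, ranged(r$low, r$low, r$high)),
                         metric, strategy, currency)
  hi <- .pipeline_metric(set_param(p, parameter, ranged(r$high, r$low, r$high)),
                         metric, strategy, currency)
  out <- data.frame(parameter = parameter, low_input = r$low,
                    high_input = r$high, outcome_low = lo, outcome_high = hi,
                    spread = abs(hi - lo), stringsAsFactors = FALSE)
  class(out) <- c("ppv_tornado_entry", "data.frame")
  out
}

#' Tornado table: one-way sensitivity across a parameter list
#'
#' One [one_way()] entry per ranged parameter, sorted by spread descending
#' (ties broken alphabetically by parameter path). Parameters with a
#' degenerate range are skipped.
#'
#' @inheritParams one_way
#' @param parameters Dotted paths to vary; default [key_parameters()], or
#'   `"all"` for every ranged parameter in `p`.
#' @return A `ppv_tornado` data frame (possibly zero rows) with the
#'   [one_way()] columns, plus attributes `metric` and `strategy`.
#' @examples
#' tornado(load_parameters(), "BCR", "free")
#' @export
tornado <- function(p, metric = c("BCR", "NB"), strategy = c("free", "self"),
                    parameters = key_parameters(),
                    currency = c("USD", "CNY")) {
  metric <- match.arg(metric)
  strategy <- match.arg(strategy)
  currency <- match.arg(currency)
  if (identical(parameters, "all")) parameters <- ranged_parameters(p)
  rows <- lapply(parameters, function(pp)
    one_way(p, pp, metric, strategy, currency))
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) == 0) {
    data.frame(parameter = character(0), low_input = numeric(0),
               high_input = numeric(0), outcome_low = numeric(0),
               outcome_high = numeric(0), spread = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(-out$spread, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppv_tornado", "data.frame")
  attr(out, "metric") <- metric
  attr(out, "strategy") <- strategy
  out
}

#' Horizontal bar rendering of a tornado table
#'
#' @param x A [tornado()] result.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.ppv_tornado <- function(x, ...) {
  if (nrow(x) == 0) {
    warning("empty tornado table; nothing to plot")
    return(invisible(x))
  }
  o <- rev(seq_len(nrow(x)))
  base <- (min(x$outcome_low, x$outcome_high) +
             max(x$outcome_low, x$outcome_high)) / 2
  graphics::barplot(
    rbind(pmin(x$outcome_low, x$outcome_high)[o] - base,
          abs(x$outcome_high - x$outcome_low)[o]),
    horiz = TRUE, names.arg = x$parameter[o], las = 1,
    col = c(NA, "steelblue"), border = c(NA, "black"), offset = base,
    main = sprintf("One-way sensitivity: %s (%s arm)",
                   attr(x, "metric"), attr(x, "strategy")), ...)
  invisible(x)
}
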