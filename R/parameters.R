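# Parameter schema, validation and config I/O for the PPV23 cohort model.
#
# A parameter set has four groups (epidemiology, vaccine, costs, settings).
# Every numeric model input is stored as a "ranged" value {base, low, high};
# low = high = base when no plausible range is given. Units follow the field
# conventions: incidence/mortality per 100,000 person-years (natural
# mortality per 1,000), proportions on [0, 1], money in CNY.

.ranged_fields <- list(
  epidemiology = c(
    "cap_incidence", "cap_mortality", "men_incidence", "men_mortality",
    "natural_mortality", "serotype_coverage"
  ),
  vaccine = c(
    "ve_pneumonia", "ve_meningitis", "coverage_free", "coverage_self",
    "wastage", "ae_incidence"
  ),
  costs = c(
    "cap_hospitalization", "men_hospitalization", "caregiver_daily",
    "caregiver_days", "ae_cost", "vaccine_price", "consumables_per_dose",
    "service_per_dose", "cny_per_usd"
  ),
  settings = "discount_rate"
)

.plain_settings <- c(
  "horizon_years", "cycle_years", "population", "currency_out",
  "serotype_switch", "rate_conversion"
)

.proportion_fields <- c(
  "serotype_coverage", "ve_pneumonia", "ve_meningitis", "coverage_free",
  "coverage_self", "wastage", "discount_rate"
)

#' Create a ranged parameter value
#'
#' A ranged value carries a base (point) estimate together with the low and
#' high ends of its plausible range, as used by one-way sensitivity analysis
#' and the scenario sampler. When no range is known, `low` and `high`
#' default to `base`.
#'
#' @param base Point estimate.
#' @param low,high Range bounds; default to `base`.
#' @return An object of class `ranged`: a list with elements `base`, `low`,
#'   `high`.
#' @examples
#' ranged(38, 25, 45)
#' ranged(0.0625) # degenerate range
#' @export
ranged <- function(base, low = base, high = base) {
  stopifnot(is.numeric(base), is.numeric(low), is.numeric(high),
            length(base) == 1, length(low) == 1, length(high) == 1)
  structure(list(base = base, low = low, high = high), class = "ranged")
}

#' @export
print.ranged <- function(x, ...) {
  if (x$low == x$high) {
    cat(sprintf("%g\n", x$base))
  } else {
    cat(sprintf("%g [%g, %g]\n", x$base, x$low, x$high))
  }
  invisible(x)
}

.as_ranged <- function(x, field) {
  if (inherits(x, "ranged")) return(x)
  if (is.list(x)) {
    if (is.null(x$base) || !is.numeric(x$base)) {
      stop("non-numeric or missing 'base' for parameter '", field, "'",
           call. = FALSE)
    }
    lo <- if (is.null(x$low)) x$base else x$low
    hi <- if (is.null(x$high)) x$base else x$high
    if (!is.numeric(lo) || !is.numeric(hi)) {
      stop("non-numeric range bound for parameter '", field, "'",
           call. = FALSE)
    }
    return(ranged(x$base, lo, hi))
  }
  if (!is.numeric(x) || length(x) != 1) {
    stop("non-numeric value for parameter '", field, "'", call. = FALSE)
  }
  ranged(x)
}

#' Path to the packaged base-case configuration
#'
#' @param format `"yaml"` (default) or `"json"`.
#' @return Filesystem path to the shipped base-case config.
#' @export
base_case_path <- function(format = c("yaml", "json")) {
  format <- match.arg(format)
  system.file("extdata", paste0("base_case.", format), package = "ppv23cba",
              mustWork = TRUE)
}

.read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Load a model parameter set
#'
#' Reads a YAML or JSON configuration (dispatch on file extension), fills any
#' field missing from the file with the packaged base-case value, then applies
#' `overrides`. With `path = NULL` the packaged base case itself is loaded.
#'
#' A user-supplied file must contain all four parameter groups
#' (`epidemiology`, `vaccine`, `costs`, `settings`); individual fields within
#' a group are optional. Overrides are named by dotted path
#' (e.g. `"settings.discount_rate"`) or by bare field name when unambiguous; a
#' numeric override replaces the base value and keeps the range, a
#' `ranged()` override replaces the whole entry.
#'
#' Structural problems (missing group, non-numeric value) are errors;
#' semantic problems are left to [validate_parameters()], which is run at the
#' end and reports warnings (never errors) so that deliberately invalid sets
#' can still be constructed and inspected.
#'
#' @param path Config file path, or `NULL` for the packaged base case.
#' @param overrides Named list of overrides (see Details).
#' @param quiet Suppress validation warnings.
#' @return A `ppv_parameters` object.
#' @examples
#' p <- load_parameters()
#' p$epidemiology$cap_incidence
#' p5 <- load_parameters(overrides = list(discount_rate = 0.05))
#' @export
load_parameters <- function(path = NULL, overrides = NULL, quiet = FALSE) {
  defaults <- .read_config_file(base_case_path())
  groups <- names(.ranged_fields)
  if (is.null(path)) {
    raw <- defaults
  } else {
    raw <- .read_config_file(path)
    if (is.null(raw) || length(raw) == 0) {
      stop("empty config: required groups missing: ",
           paste(groups, collapse = ", "), call. = FALSE)
    }
    missing_groups <- setdiff(groups, names(raw))
    if (length(missing_groups) > 0) {
      stop("config missing required group(s): ",
           paste(missing_groups, collapse = ", "), call. = FALSE)
    }
  }

  p <- list()
  for (g in groups) {
    p[[g]] <- list()
    for (f in .ranged_fields[[g]]) {
      val <- raw[[g]][[f]]
      if (is.null(val)) val <- defaults[[g]][[f]]
      if (is.null(val)) {
        stop("missing required field '", g, ".", f, "'", call. = FALSE)
      }
      p[[g]][[f]] <- .as_ranged(val, paste(g, f, sep = "."))
    }
  }
  for (f in .plain_settings) {
    val <- raw$settings[[f]]
    if (is.null(val)) val <- defaults$settings[[f]]
    if (is.null(val)) {
      stop("missing required field 'settings.", f, "'", call. = FALSE)
    }
    p$settings[[f]] <- val
  }
  class(p) <- "ppv_parameters"

  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      p <- set_param(p, nm, overrides[[nm]])
    }
  }

  if (!quiet) {
    v <- validate_parameters(p)
    w <- v[v$severity == "warning", , drop = FALSE]
    for (i in seq_len(nrow(w))) {
      warning(w$field[i], ": ", w$message[i], call. = FALSE)
    }
  }
  p
}

#' @export
print.ppv_parameters <- function(x, ...) {
  cat("PPV23 cohort model parameters\n")
  for (g in names(.ranged_fields)) {
    cat("$", g, "\n", sep = "")
    for (f in names(x[[g]])) {
      r <- x[[g]][[f]]
      if (inherits(r, "ranged")) {
        if (r$low == r$high) {
          cat(sprintf("  %-22s %g\n", f, r$base))
        } else {
          cat(sprintf("  %-22s %g [%g, %g]\n", f, r$base, r$low, r$high))
        }
      } else {
        cat(sprintf("  %-22s %s\n", f, format(r)))
      }
    }
  }
  invisible(x)
}

.resolve_path <- function(p, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2) return(parts)
  if (length(parts) == 1) {
    hits <- character(0)
    for (g in names(.ranged_fields)) {
      if (parts %in% names(p[[g]])) hits <- c(hits, g)
    }
    if (length(hits) == 1) return(c(hits, parts))
    if (length(hits) == 0) stop("unknown parameter '", path, "'", call. = FALSE)
    stop("ambiguous parameter name '", path, "'; use group.field",
         call. = FALSE)
  }
  stop("malformed parameter path '", path, "'", call. = FALSE)
}

#' Get a parameter by dotted path
#'
#' @param p A `ppv_parameters` object.
#' @param path Dotted path such as `"vaccine.ve_pneumonia"`, or a bare field
#'   name when unambiguous.
#' @param what `"base"`, `"low"`, `"high"`, or `"ranged"` for the whole entry.
#' @return Numeric value, or the `ranged` object.
#' @export
param_value <- function(p, path, what = c("base", "low", "high", "ranged")) {
  what <- match.arg(what)
  loc <- .resolve_path(p, path)
  val <- p[[loc[1]]][[loc[2]]]
  if (!inherits(val, "ranged")) return(val)
  if (what == "ranged") val else val[[what]]
}

#' Set a parameter by dotted path
#'
#' A numeric value replaces the base estimate (range kept); a [ranged()]
#' value replaces the whole entry; plain settings (e.g. `horizon_years`) are
#' assigned directly.
#'
#' @inheritParams param_value
#' @param value Replacement value.
#' @return The modified `ppv_parameters` object.
#' @export
set_param <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1 && parts %in% .plain_settings) {
    p$settings[[parts]] <- value
    return(p)
  }
  if (length(parts) == 2 && parts[1] == "settings" &&
      parts[2] %in% .plain_settings) {
    p$settings[[parts[2]]] <- value
    return(p)
  }
  loc <- .resolve_path(p, path)
  cur <- p[[loc[1]]][[loc[2]]]
  if (inherits(value, "ranged")) {
    p[[loc[1]]][[loc[2]]] <- value
  } else if (is.numeric(value) && length(value) == 1) {
    p[[loc[1]]][[loc[2]]] <- ranged(value, cur$low, cur$high)
  } else {
    stop("override for '", path, "' must be numeric or ranged()",
         call. = FALSE)
  }
  p
}

#' Write a parameter set to YAML or JSON
#'
#' Round-trips with [load_parameters()]: writing and re-loading yields a
#' field-by-field identical set.
#'
#' @param p A `ppv_parameters` object.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  out <- list()
  for (g in names(.ranged_fields)) {
    out[[g]] <- lapply(p[[g]], function(r) {
      if (inherits(r, "ranged")) list(base = r$base, low = r$low, high = r$high)
      else r
    })
  }
  for (f in .plain_settings) out$settings[[f]] <- p$settings[[f]]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

.violation <- function(field, message, severity = "error") {
  data.frame(field = field, message = message, severity = severity,
             stringsAsFactors = FALSE)
}

#' Validate a parameter set
#'
#' Checks every structural and semantic invariant of the model inputs and
#' returns the violations as data, not exceptions: rates and money
#' non-negative, proportions on [0, 1], disease mortality not exceeding
#' incidence (case fatality <= 1), range bounds ordered, settings sane. A
#' base value lying outside its own plausible range is reported with severity
#' `"warning"` (the shipped wastage entry is the known instance); everything
#' else is severity `"error"`.
#'
#' @param p A `ppv_parameters` object.
#' @return A data frame with columns `field`, `message`, `severity`; zero
#'   rows when all invariants hold.
#' @seealso [is_valid_parameters()]
#' @export
validate_parameters <- function(p) {
  v <- .violation(character(0), character(0), character(0))[0, ]

  for (g in names(.ranged_fields)) {
    for (f in .ranged_fields[[g]]) {
      r <- p[[g]][[f]]
      path <- paste(g, f, sep = ".")
      if (!inherits(r, "ranged")) {
        v <- rbind(v, .violation(path, "not a ranged value"))
        next
      }
      if (r$low > r$high) {
        v <- rbind(v, .violation(path, sprintf(
          "range inverted: low %g > high %g", r$low, r$high)))
      } else if (r$base < r$low || r$base > r$high) {
        v <- rbind(v, .violation(path, sprintf(
          "base %g outside plausible range [%g, %g]", r$base, r$low, r$high),
          "warning"))
      }
      for (b in c("base", "low", "high")) {
        x <- r[[b]]
        if (f %in% .proportion_fields) {
          if (x < 0 || x > 1) {
            v <- rbind(v, .violation(path, sprintf(
              "%s %g: proportion out of [0,1]", b, x)))
          }
        } else if (x < 0) {
          v <- rbind(v, .violation(path, sprintf("%s %g is negative", b, x)))
        }
      }
    }
  }

  cfr_check <- function(mort, inc, disease) {
    if (mort$base > inc$base) {
      .violation(paste0("epidemiology.", disease),
                 sprintf("%s case fatality > 1 (mortality %g > incidence %g)",
                         disease, mort$base, inc$base))
    } else NULL
  }
  v <- rbind(v, cfr_check(p$epidemiology$cap_mortality,
                          p$epidemiology$cap_incidence, "cap"))
  v <- rbind(v, cfr_check(p$epidemiology$men_mortality,
                          p$epidemiology$men_incidence, "men"))

  if (p$costs$cny_per_usd$base <= 0) {
    v <- rbind(v, .violation("costs.cny_per_usd", "exchange rate must be > 0"))
  }
  s <- p$settings
  if (!is.numeric(s$horizon_years) || s$horizon_years < 1 ||
      s$horizon_years != round(s$horizon_years)) {
    v <- rbind(v, .violation("settings.horizon_years",
                             "horizon must be an integer >= 1"))
  }
  if (!identical(as.numeric(s$cycle_years), 1)) {
    v <- rbind(v, .violation("settings.cycle_years",
                             "cycle length is fixed at 1 year"))
  }
  if (!is.numeric(s$population) || s$population <= 0) {
    v <- rbind(v, .violation("settings.population", "population must be > 0"))
  }
  if (!s$currency_out %in% c("CNY", "USD")) {
    v <- rbind(v, .violation("settings.currency_out",
                             "currency_out must be CNY or USD"))
  }
  if (!s$rate_conversion %in% c("linear", "exponential")) {
    v <- rbind(v, .violation("settings.rate_conversion",
                             "rate_conversion must be linear or exponential"))
  }
  if (p$settings$discount_rate$base >= 1) {
    v <- rbind(v, .violation("settings.discount_rate",
                             "discount rate must be < 1"))
  }
  rownames(v) <- NULL
  v
}

#' Does a parameter set pass validation?
#'
#' @inheritParams validate_parameters
#' @return `TRUE` when [validate_parameters()] reports no error-severity
#'   violation (warnings allowed).
#' @export
is_valid_parameters <- function(p) {
  v <- validate_parameters(p)
  !any(v$severity == "error")
}

#' Convert a reported rate to an annual per-person probability
#'
#' Model inputs are quoted per 100,000 (disease rates) or per 1,000 (natural
#' mortality) person-years. The default conversion is direct scaling
#' `rate / per`; with `method = "exponential"` the competing-risks form
#' `1 - exp(-rate / per)` is used instead. For the annual rates involved here
#' (all below 7 per 1,000) the two agree to well under 0.02%.
#'
#' @param rate Non-negative rate, vectorized.
#' @param per Denominator of the quoted rate (default 100,000).
#' @param method `"linear"` (default) or `"exponential"`.
#' @return Annual probability (same length as `rate`).
#' @examples
#' per_capita_rate(38)          # 3.8e-4
#' per_capita_rate(6.25, 1e3)   # natural mortality, per mille
#' @export
per_capita_rate <- function(rate, per = 1e5,
                            method = c("linear", "exponential")) {
  method <- match.arg(method)
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  if (method == "linear") rate / per else 1 - exp(-rate / per)
}
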