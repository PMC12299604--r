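# Seeded generator of synthetic parameter sets and deterministic stress
# cases, so every pipeline stage is testable without external data. Ranges
# come from the base-case configuration; the printed ranges are ranges, not
# distributions, so uniform sampling is the honest default and the sampling
# scheme is explicit in the spec object.

#' Specification of a scenario batch
#'
#' @param seed Integer seed fixing the whole output stream.
#' @param n_scenarios Number of parameter sets to draw.
#' @param sampling `"uniform"` (independent uniform within each `[low,
#'   high]`) or `"jitter"` (multiplicative jitter around base, clamped to the
#'   range).
#' @param jitter_fraction Half-width of the relative jitter (only for
#'   `sampling = "jitter"`).
#' @return A `ppv_scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1L, n_scenarios = 100L,
                          sampling = c("uniform", "jitter"),
                          jitter_fraction = 0.1) {
  sampling <- match.arg(sampling)
  stopifnot(n_scenarios >= 0, jitter_fraction >= 0)
  structure(list(seed = as.integer(seed),
                 n_scenarios = as.integer(n_scenarios),
                 sampling = sampling, jitter_fraction = jitter_fraction),
            class = "ppv_scenario_spec")
}

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw synthetic parameter sets within the published ranges
#'
#' Every ranged parameter with `low < high` is drawn independently (uniform
#' within its range, or jittered around base); degenerate ranges stay at
#' base. Identical spec and template give bit-identical output. A jittered
#' proportion falling outside [0, 1] is clamped and the clamp recorded in the
#' attribute `"clamp_warnings"` of the affected set.
#'
#' @param spec A [scenario_spec()].
#' @param template A valid parameter set supplying bases and ranges
#'   (default: packaged base case).
#' @return List of `n_scenarios` parameter sets; each carries attributes
#'   `scenario_id` and `seed`.
#' @export
sample_parameter_sets <- function(spec, template = load_parameters()) {
  stopifnot(inherits(spec, "ppv_scenario_spec"))
  if (spec$n_scenarios == 0) return(list())
  paths <- ranged_parameters(template)
  .with_seed(spec$seed, {
    lapply(seq_len(spec$n_scenarios), function(i) {
      p <- template
      clamps <- character(0)
      for (pp in paths) {
        r <- param_value(p, pp, "ranged")
        if (spec$sampling == "uniform") {
          x <- stats::runif(1, r$low, r$high)
        } else {
          x <- r$base * (1 + stats::runif(1, -spec$jitter_fraction,
                                          spec$jitter_fraction))
          x <- min(max(x, r$low), r$high)
        }
        field <- sub("^[^.]+\\.", "", pp)
        if (field %in% .proportion_fields && (x < 0 || x > 1)) {
          x <- min(max(x, 0), 1)
          clamps <- c(clamps, sprintf("%s clamped to [0,1]", pp))
        }
        p <- set_param(p, pp, ranged(x, r$low, r$high))
      }
      attr(p, "scenario_id") <- i
      attr(p, "seed") <- spec$seed
      if (length(clamps) > 0) attr(p, "clamp_warnings") <- clamps
      p
    })
  })
}

#' Deterministic stress-case parameter sets
#'
#' Labeled edge scenarios exercising the pipeline's boundary behaviour:
#' zero and full vaccine efficacy, zero disease incidence, zero discounting,
#' zero and full coverage, and a case-fatality-of-one boundary.
#'
#' @param template A valid parameter set (default: packaged base case).
#' @return Named list of parameter sets.
#' @export
stress_cases <- function(template = load_parameters()) {
  tweak <- function(...) {
    p <- template
    mods <- list(...)
    for (nm in names(mods)) p <- set_param(p, nm, ranged(mods[[nm]]))
    p
  }
  list(
    zero_efficacy = tweak(vaccine.ve_pneumonia = 0, vaccine.ve_meningitis = 0),
    full_efficacy = tweak(vaccine.ve_pneumonia = 1, vaccine.ve_meningitis = 1),
    zero_incidence = tweak(epidemiology.cap_incidence = 0,
                           epidemiology.cap_mortality = 0,
                           epidemiology.men_incidence = 0,
                           epidemiology.men_mortality = 0),
    zero_discount = tweak(settings.discount_rate = 0),
    coverage_zero = tweak(vaccine.coverage_free = 0, vaccine.coverage_self = 0),
    coverage_full = tweak(vaccine.coverage_free = 1, vaccine.coverage_self = 1),
    cfr_one = tweak(epidemiology.cap_mortality =
                      template$epidemiology$cap_incidence$base,
                    epidemiology.men_mortality =
                      template$epidemiology$men_incidence$base)
  )
}

#' Write a scenario batch to disk
#'
#' One YAML config per scenario plus a `manifest.csv` recording scenario id,
#' seed, and every sampled value.
#'
#' @param sets List of parameter sets from [sample_parameter_sets()].
#' @param dir Output directory (created if missing).
#' @return Path to the manifest, invisibly.
#' @export
write_scenario_batch <- function(sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- if (length(sets) > 0) ranged_parameters(sets[[1]]) else character(0)
  rows <- lapply(seq_along(sets), function(i) {
    p <- sets[[i]]
    f <- file.path(dir, sprintf("scenario_%03d.yaml", i))
    write_parameters(p, f)
    vals <- vapply(paths, function(pp) param_value(p, pp), numeric(1))
    cbind(data.frame(scenario_id = i,
                     seed = attr(p, "seed") %||% NA_integer_,
                     config = basename(f), stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), check.names = FALSE))
  })
  manifest <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(scenario_id = integer(0), seed = integer(0),
               config = character(0))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
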