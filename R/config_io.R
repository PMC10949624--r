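#' Load and validate a model configuration
#'
#' Reads the JSON configuration (national inputs, utilisation fractions,
#' strategy mix, transition rows and model settings) together with its CSV
#' cost-schedule side files, applies defaults for omitted optional fields,
#' validates every invariant, and attaches a deterministic content
#' fingerprint for provenance logging.
#'
#' @param path Path to a JSON configuration file. Cost-schedule CSVs named in
#'   `cost_schedule_files` are resolved relative to its directory.
#' @return A validated list of class `perio_config` with the combined
#'   `cost_schedule` attached and a `fingerprint` attribute.
#' @seealso [base_config()] for the packaged base case, [validate_config()]
#'   for the issue report, [write_config()] for persisting.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  config <- apply_config_defaults(raw)

  if (!is.null(config$cost_schedule_files)) {
    parts <- lapply(config$cost_schedule_files, function(f) {
      read_cost_schedule(file.path(dirname(path), f))
    })
    config$cost_schedule <- cost_schedule(do.call(rbind, unname(parts)))
  } else if (!is.null(config$cost_schedule)) {
    config$cost_schedule <- cost_schedule(
      as.data.frame(lapply(purrr_transpose(config$cost_schedule), unlist),
                    stringsAsFactors = FALSE))
  }

  class(config) <- c("perio_config", "list")
  issues <- validate_config(config)
  errors <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0) {
    stop_validation("invalid configuration:\n",
                    paste0("  - ", errors$field, ": ", errors$rule,
                           " (got ", errors$value, ")", collapse = "\n"))
  }
  warningsdf <- issues[issues$severity == "warning", , drop = FALSE]
  for (i in seq_len(nrow(warningsdf))) {
    warning(warningsdf$field[i], ": ", warningsdf$rule[i], call. = FALSE)
  }
  attr(config, "fingerprint") <- config_fingerprint(config)
  config
}

# rows-of-lists -> list-of-columns, without importing purrr
purrr_transpose <- function(rows) {
  nm <- names(rows[[1]])
  stats::setNames(lapply(nm, function(k) lapply(rows, `[[`, k)), nm)
}

apply_config_defaults <- function(config) {
  config$cycle_length_months <- config$cycle_length_months %||% 3L
  config$n_cycles <- config$n_cycles %||% 4L
  config$exchange_rate_usd_per_myr <- config$exchange_rate_usd_per_myr %||% 0.2382
  config$price_year <- config$price_year %||% 2020L
  config$strategy_mix <- config$strategy_mix %||%
    as.list(strategy_mix())
  config
}

#' The packaged base-case configuration
#'
#' Loads the configuration shipped with the package: 2020 adult census
#' (24,692,460), 2010 national survey prevalences (48.5% / 30.3% / 18.2% with
#' 95% CIs), 2019 utilisation fractions (8.7% reported problems, 23.0% sought
#' treatment, 17.0% severe-periodontitis share), per-capita visit rates
#' (0.23 public / 0.06 private), the published per-visit cost schedules for
#' both sectors, the default strategy mix, and a documented synthetic
#' placeholder transition-row set (the originally used matrices are not
#' published in machine-readable form; see the vignette).
#'
#' @return A `perio_config`.
#' @examples
#' cfg <- base_config()
#' cfg$census_adults
#' @export
base_config <- function() {
  load_config(system.file("extdata", "base_config.json",
                          package = "perioburden", mustWork = TRUE))
}

#' Validate a configuration, returning issues as data
#'
#' Unlike [load_config()], this never throws for content problems: every
#' violated invariant is reported as one row, so a caller sees all problems
#' at once rather than just the first.
#'
#' @param config A structurally parsed configuration list.
#' @return Data frame with columns `field` (path of the offending value),
#'   `value` (observed, formatted), `rule` (violated invariant) and
#'   `severity` ("error" or "warning"). Zero rows for a valid configuration.
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(field, value, rule, severity = "error") {
    issues[[length(issues) + 1]] <<- data.frame(
      field = field, value = paste(format(value), collapse = ","),
      rule = rule, severity = severity, stringsAsFactors = FALSE)
  }
  check_fraction <- function(x, field) {
    e <- tryCatch(as_est(x, field), error = function(err) NULL)
    if (is.null(e)) {
      add(field, NA, "must be a point-with-bounds fraction"); return()
    }
    v <- unclass(e)
    if (any(v < 0 | v > 1)) add(field, v, "fractions must lie in [0, 1]")
  }
  check_ci_order <- function(x, field) {
    e <- tryCatch(as_est(x, field), error = function(err) NULL)
    if (is.null(e)) return()
    if (!(e[["lower"]] <= e[["point"]] && e[["point"]] <= e[["upper"]])) {
      add(field, unclass(e), "interval must satisfy lower <= point <= upper")
    }
  }

  if (is.null(config$census_adults) || !is.numeric(config$census_adults) ||
      config$census_adults <= 0) {
    add("census_adults", config$census_adults, "must be a positive count")
  }
  for (g in names(config$prevalence)) {
    f <- paste0("prevalence$", g)
    check_fraction(config$prevalence[[g]], f)
    check_ci_order(config$prevalence[[g]], f)
  }
  u <- config$utilisation
  for (k in intersect(c("b", "f", "perio_share", "d", "e"), names(u))) {
    check_fraction(u[[k]], paste0("utilisation$", k))
    check_ci_order(u[[k]], paste0("utilisation$", k))
  }
  if (is.null(u$perio_share) && (is.null(u$d) || is.null(u$e))) {
    add("utilisation", NA,
        "needs either perio_share or both d and e prevalences")
  }
  rates <- c(public = 0, private = 0)
  for (k in c("visit_rate_public", "visit_rate_private")) {
    e <- tryCatch(as_est(u[[k]], k), error = function(err) NULL)
    if (is.null(e) || any(unclass(e) < 0)) {
      add(paste0("utilisation$", k), u[[k]], "visit rate must be >= 0")
    } else {
      rates[[sub("visit_rate_", "", k)]] <- e[["point"]]
    }
  }
  if (sum(rates) == 0) {
    add("utilisation", rates, "visit rates cannot both be zero")
  }

  mix <- tryCatch(strategy_mix(config$strategy_mix), error = function(e) NULL)
  if (is.null(mix)) {
    add("strategy_mix", unlist(config$strategy_mix),
        "weights must be non-negative over known strategies and sum to 1")
  }

  if (!is.null(config$cycle_length_months) && !is.null(config$n_cycles) &&
      config$cycle_length_months * config$n_cycles != 12) {
    add("cycle_length_months", config$cycle_length_months * config$n_cycles,
        "cycle_length_months x n_cycles != 12: horizon is not one year",
        severity = "warning")
  }
  if (!is.null(config$exchange_rate_usd_per_myr) &&
      config$exchange_rate_usd_per_myr <= 0) {
    add("exchange_rate_usd_per_myr", config$exchange_rate_usd_per_myr,
        "exchange rate must be positive")
  }

  sched <- config$cost_schedule
  if (is.null(sched)) {
    add("cost_schedule", NA, "a cost schedule is required")
  } else {
    for (sec in c("public", "private")) {
      for (strat in PERIO_STRATEGIES) {
        for (st in PERIO_STATES) {
          n <- sum(sched$sector == sec & sched$visit == 0 &
                     sched$state == st & !is.na(sched$strategy) &
                     sched$strategy == strat)
          if (n != 1) {
            add(paste0("cost_schedule(", sec, ", visit 0, ", st, ", ", strat, ")"),
                n, "cell must be present exactly once")
          }
        }
      }
      for (v in 1:4) {
        for (st in PERIO_STATES) {
          n <- sum(sched$sector == sec & sched$visit == v & sched$state == st)
          if (n != 1) {
            add(paste0("cost_schedule(", sec, ", visit ", v, ", ", st, ")"),
                n, "cell must be present exactly once")
          }
        }
      }
    }
    if (any(sched$cost_base < 0 | sched$cost_low < 0 | sched$cost_high < 0)) {
      add("cost_schedule", NA, "cost cells must be non-negative")
    }
    bad <- sched$cost_low > sched$cost_base | sched$cost_base > sched$cost_high
    if (any(bad)) {
      add("cost_schedule", which(bad),
          "cells must satisfy cost_low <= cost_base <= cost_high")
    }
  }

  ts <- config$transition_spec
  if (!is.null(ts)) {
    mode <- ts$mode %||% "rows"
    if (mode == "rows") {
      rows <- c(list(stable_row_annual = ts$stable_row_annual,
                     remission_row_annual = ts$remission_row_annual,
                     unstable_maintenance_row = ts$unstable_maintenance_row),
                stats::setNames(
                  ts$unstable_cycle1_rows,
                  paste0("unstable_cycle1_rows$",
                         names(ts$unstable_cycle1_rows))))
      for (nm in names(rows)) {
        r <- rows[[nm]]
        if (is.null(r)) next
        r <- unlist(r)
        if (length(r) != 3 || any(r < 0 | r > 1) || abs(sum(r) - 1) > 1e-9) {
          add(paste0("transition_spec$", nm), r,
              "row must be 3 probabilities summing to 1")
        }
      }
      if (is.null(ts$unstable_cycle1_rows)) {
        add("transition_spec$unstable_cycle1_rows", NA,
            "per-strategy first-cycle unstable rows are required")
      }
    } else if (mode == "matrices") {
      for (strat in names(ts$matrices)) {
        for (k in seq_along(ts$matrices[[strat]])) {
          m <- matrix(unlist(ts$matrices[[strat]][[k]]), nrow = 3, byrow = TRUE)
          ok <- tryCatch({transition_matrix(m); TRUE},
                         error = function(e) FALSE)
          if (!ok) {
            add(paste0("transition_spec$matrices$", strat, "[[", k, "]]"),
                m, "must be a row-stochastic 3x3 matrix")
          }
        }
      }
    } else {
      add("transition_spec$mode", mode, "must be 'rows' or 'matrices'")
    }
  } else if (is.null(config$per_patient_costs)) {
    add("transition_spec", NA,
        "required unless per_patient_costs calibration values are supplied")
  }
  if (!is.null(config$per_patient_costs) &&
      any(unlist(config$per_patient_costs) < 0)) {
    add("per_patient_costs", unlist(config$per_patient_costs),
        "must be non-negative")
  }

  if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(field = character(), value = character(), rule = character(),
               severity = character(), stringsAsFactors = FALSE)
  }
}

#' Deterministic content fingerprint of a configuration
#'
#' MD5 of the canonicalised (name-sorted, full-precision) JSON rendering of
#' the configuration content; used for provenance logging in reports.
#'
#' @param config A `perio_config`.
#' @return Hex string.
#' @export
config_fingerprint <- function(config) {
  content <- unclass(config)
  attr(content, "fingerprint") <- NULL
  # hash content, not file layout: the side-file pointers and data-frame row
  # names are presentation details
  content$cost_schedule_files <- NULL
  if (!is.null(content$cost_schedule)) {
    content$cost_schedule <- as.data.frame(content$cost_schedule)
    rownames(content$cost_schedule) <- NULL
  }
  canonical <- jsonlite::toJSON(sort_names_rec(content), auto_unbox = TRUE,
                                digits = NA, dataframe = "rows")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(canonical), tmp)
  unname(tools::md5sum(tmp))
}

sort_names_rec <- function(x) {
  if (is.data.frame(x)) return(x[, sort(names(x)), drop = FALSE])
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    return(lapply(x, sort_names_rec))
  }
  x
}

#' Persist a configuration
#'
#' Writes the JSON configuration and its cost-schedule CSV side file so that
#' [load_config()] on the result reproduces the configuration exactly.
#'
#' @param config A `perio_config`.
#' @param path Output JSON path; the cost schedule CSV is written alongside.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  attr(out, "fingerprint") <- NULL
  if (!is.null(out$cost_schedule)) {
    csv <- paste0(tools::file_path_sans_ext(basename(path)),
                  "_cost_schedule.csv")
    write_tables(as.data.frame(out$cost_schedule), file.path(dirname(path), csv))
    out$cost_schedule_files <- list(all = csv)
    out$cost_schedule <- NULL
  }
  ok <- tryCatch({
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write config to ", path)
  invisible(path)
}

#' Write a tabular stage output as CSV
#'
#' Writes any of the pipeline's tabular objects (data frames, cohort traces,
#' burden reports) with full-precision floats so that re-reading round-trips
#' the numbers exactly.
#'
#' @param x A data frame, matrix, [run_cohort()] trace or
#'   [blend_and_scale()] `burden_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(x, path) {
  df <- as_output_table(x)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_io("output directory does not exist: ", dir)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write table to ", path)
  invisible(path)
}

as_output_table <- function(x) {
  if (inherits(x, "burden_report")) {
    sectors <- names(x$counts)
    return(data.frame(
      sector = c(sectors, "total"),
      treated = c(as.numeric(x$counts), sum(x$counts)),
      per_patient_myr = c(as.numeric(x$per_patient), NA),
      burden_myr = c(as.numeric(x$sector_burden_myr), x$total_myr),
      burden_usd = c(as.numeric(x$sector_burden_myr) *
                       x$exchange_rate_usd_per_myr, x$total_usd),
      stringsAsFactors = FALSE))
  }
  if (inherits(x, "cohort_trace") || is.matrix(x)) {
    df <- as.data.frame(unclass(x))
    df <- cbind(cycle = seq_len(nrow(df)) - 1L, df)
    rownames(df) <- NULL
    return(df)
  }
  as.data.frame(x)
}
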