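#' Define a one-way sensitivity scenario
#'
#' Each scenario perturbs exactly one parameter group of the base
#' configuration (one-way discipline). Supported kinds:
#' \describe{
#'   \item{`none`}{No perturbation; must reproduce the base burden
#'     bit-for-bit.}
#'   \item{`strategy_mix_override`}{Replace the strategy mix;
#'     `params$weights` as for [strategy_mix()]. A mix of
#'     `c(NSPT_only = 1)` excludes antibiotic adjuncts entirely, which also
#'     switches every patient to the NSPT-only first-cycle dynamics.}
#'   \item{`counts_bound`}{Use the interval-substituted treated counts;
#'     `params$which` is "lower" or "upper".}
#'   \item{`fee_bound`}{Use the low or high cost schedule via
#'     [cost_range_variant()]; `params$which` is "low" or "high".}
#'   \item{`cell_override`}{Replace individual cost cells; `params$cells` is
#'     a list of `list(sector, visit, state, strategy = NULL, cost_base)`.}
#' }
#'
#' @param id Short unique identifier.
#' @param label Human-readable description.
#' @param kind Perturbation kind, see above.
#' @param params Kind-specific parameter list.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(id, label, kind, params = list()) {
  kinds <- c("none", "strategy_mix_override", "counts_bound", "fee_bound",
             "cell_override")
  if (!is.character(id) || length(id) != 1 || !nzchar(id)) {
    stop_validation("scenario id must be a non-empty string")
  }
  if (!kind %in% kinds) {
    stop_validation("scenario '", id, "': unknown perturbation kind '", kind,
                    "' (expected one of ", paste(kinds, collapse = ", "), ")")
  }
  if (kind == "counts_bound" &&
      !identical(params$which, "lower") && !identical(params$which, "upper")) {
    stop_validation("scenario '", id, "': counts_bound needs which = ",
                    "'lower' or 'upper'")
  }
  if (kind == "fee_bound" &&
      !identical(params$which, "low") && !identical(params$which, "high")) {
    stop_validation("scenario '", id, "': fee_bound needs which = ",
                    "'low' or 'high'")
  }
  if (kind == "strategy_mix_override") strategy_mix(params$weights)
  if (kind == "cell_override" && !length(params$cells)) {
    stop_validation("scenario '", id, "': cell_override needs cells")
  }
  structure(list(id = id, label = label, kind = kind, params = params),
            class = "scenario_spec")
}

apply_scenario <- function(config, spec) {
  out <- config
  switch(spec$kind,
    none = out,
    strategy_mix_override = {
      out$strategy_mix <- as.list(strategy_mix(spec$params$weights))
      out
    },
    counts_bound = {
      out$counts_bound <- spec$params$which
      out
    },
    fee_bound = {
      out$cost_schedule <- cost_range_variant(out$cost_schedule,
                                              spec$params$which)
      out
    },
    cell_override = {
      for (cell in spec$params$cells) {
        sel <- out$cost_schedule$sector == cell$sector &
          out$cost_schedule$visit == cell$visit &
          out$cost_schedule$state == cell$state
        if (!is.null(cell$strategy)) {
          sel <- sel & !is.na(out$cost_schedule$strategy) &
            out$cost_schedule$strategy == cell$strategy
        }
        if (sum(sel) != 1) {
          stop_validation("scenario '", spec$id, "': cell override matches ",
                          sum(sel), " schedule rows")
        }
        out$cost_schedule$cost_base[sel] <- cell$cost_base
        out$cost_schedule$cost_low[sel] <-
          pmin(out$cost_schedule$cost_low[sel], cell$cost_base)
        out$cost_schedule$cost_high[sel] <-
          pmax(out$cost_schedule$cost_high[sel], cell$cost_base)
      }
      out
    }
  )
}

#' Run one sensitivity scenario
#'
#' Applies the scenario's single perturbation to the base configuration,
#' reruns the full pipeline, and reports the burden together with the percent
#' difference against the base case.
#'
#' @param base A validated `perio_config`.
#' @param spec A [scenario_spec()].
#' @param base_result Optional precomputed [burden_pipeline()] result for
#'   `base`, to avoid rerunning it.
#' @return List with `spec`, `result` (the scenario's pipeline output),
#'   `report`, and `pct_diff` (`100 * (scenario/base - 1)` on the total MYR
#'   burden).
#' @export
run_scenario <- function(base, spec, base_result = NULL) {
  if (!inherits(spec, "scenario_spec")) {
    spec <- do.call(scenario_spec, spec)
  }
  base_result <- base_result %||% burden_pipeline(base)
  res <- burden_pipeline(apply_scenario(base, spec))
  list(spec = spec,
       result = res,
       report = res$report,
       pct_diff = 100 * (res$report$total_myr /
                           base_result$report$total_myr - 1))
}

#' One-way sensitivity table
#'
#' Runs every scenario against the base configuration and assembles the
#' published-table layout: one row per scenario plus the base row, with
#' treated counts, sector burdens, the total, and the percent difference
#' (reported to two decimals at print time).
#'
#' @param base A validated `perio_config`.
#' @param specs Non-empty list of [scenario_spec()]s with unique ids.
#' @return Data frame with columns `id`, `label`, `treated_public`,
#'   `treated_private`, `burden_public_myr`, `burden_private_myr`,
#'   `burden_total_myr`, `pct_diff`.
#' @export
one_way_table <- function(base, specs) {
  if (!length(specs)) stop_validation("scenario list must be non-empty")
  specs <- lapply(specs, function(s) {
    if (inherits(s, "scenario_spec")) s else do.call(scenario_spec, s)
  })
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_validation("duplicated scenario id(s): ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  base_result <- burden_pipeline(base)
  row_of <- function(id, label, report, pct) {
    data.frame(id = id, label = label,
               treated_public = unname(report$counts[["public"]]),
               treated_private = unname(report$counts[["private"]]),
               burden_public_myr = unname(report$sector_burden_myr[["public"]]),
               burden_private_myr = unname(report$sector_burden_myr[["private"]]),
               burden_total_myr = report$total_myr,
               pct_diff = pct, stringsAsFactors = FALSE)
  }
  rows <- lapply(specs, function(s) {
    r <- run_scenario(base, s, base_result = base_result)
    row_of(s$id, s$label, r$report, r$pct_diff)
  })
  out <- rbind(row_of("base", "Base case", base_result$report, 0),
               do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("one_way_table", "data.frame")
  out
}

#' @export
print.one_way_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$pct_diff <- sprintf("%+.2f%%", y$pct_diff)
  for (col in grep("burden_", names(y))) {
    y[[col]] <- formatC(round_cents(y[[col]]), format = "f", digits = 2,
                        big.mark = ",")
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' The packaged one-way scenario set
#'
#' The five scenarios of the base analysis: (a) exclude antibiotic adjuncts,
#' (b)/(c) lower/upper interval limits of the treated-count cascade,
#' (d)/(e) lower/upper treatment-fee schedules.
#'
#' @return List of five [scenario_spec()]s.
#' @export
base_scenarios <- function() {
  list(
    scenario_spec("a", "Exclude the use of adjuncts", "strategy_mix_override",
                  list(weights = c(NSPT_only = 1))),
    scenario_spec("b", "Lower limit of the proportion who received treatment",
                  "counts_bound", list(which = "lower")),
    scenario_spec("c", "Upper limit of the proportion who received treatment",
                  "counts_bound", list(which = "upper")),
    scenario_spec("d", "Lower limit of the treatment fee",
                  "fee_bound", list(which = "low")),
    scenario_spec("e", "Upper limit of the treatment fee",
                  "fee_bound", list(which = "high"))
  )
}
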