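#' Construct and validate a per-visit cost schedule
#'
#' A cost schedule holds the average direct medical cost per patient for each
#' (sector, visit, periodontal state) cell, in MYR at the model's price year.
#' Visit 0 is the initial assessment plus cause-related therapy and is
#' additionally broken down by treatment strategy; visits 1-4 are the recall
#' visits. `cost_low`/`cost_high` carry the sensitivity bounds: in the
#' packaged base case the public bounds are +/-20% of the average and the
#' private bounds are independently elicited fee ranges.
#'
#' @param df Data frame with columns `sector` ("public"/"private"), `visit`
#'   (integer 0-4), `state` (one of [PERIO_STATES]), `strategy` (one of
#'   [PERIO_STRATEGIES] for visit 0, `NA` otherwise), `cost_base`,
#'   `cost_low`, `cost_high` (money, MYR).
#' @return The validated data frame with class `cost_schedule`.
#' @export
cost_schedule <- function(df) {
  needed <- c("sector", "visit", "state", "strategy",
              "cost_base", "cost_low", "cost_high")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_validation("cost schedule lacks columns: ",
                    paste(missing_cols, collapse = ", "))
  }
  df$visit <- as.integer(df$visit)
  df$strategy <- as.character(df$strategy)
  bad_state <- setdiff(unique(df$state), PERIO_STATES)
  if (length(bad_state)) {
    stop_validation("unknown periodontal state(s): ",
                    paste(bad_state, collapse = ", "))
  }
  if (any(df$cost_base < 0 | df$cost_low < 0 | df$cost_high < 0, na.rm = TRUE)) {
    stop_validation("cost cells must be non-negative")
  }
  class(df) <- c("cost_schedule", "data.frame")
  df
}

#' Read a cost schedule from its CSV dialect
#'
#' Columns: `sector, visit, state, strategy, cost_base, cost_low, cost_high`;
#' `strategy` is blank for the recall visits.
#'
#' @param path Path to the CSV file.
#' @return A [cost_schedule()].
#' @export
read_cost_schedule <- function(path) {
  if (!file.exists(path)) stop_io("cost schedule file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(strategy = "character"))
  df$strategy[!nzchar(df$strategy) | is.na(df$strategy)] <- NA_character_
  cost_schedule(df)
}

#' Look up one cost cell
#'
#' @param schedule A [cost_schedule()].
#' @param sector "public" or "private".
#' @param visit Visit index 0-4.
#' @param state Periodontal state.
#' @param strategy Strategy label, required for visit 0.
#' @param which Which variant column: "base", "low" or "high".
#' @return Money (MYR), length 1.
#' @export
schedule_cell <- function(schedule, sector, visit, state, strategy = NULL,
                          which = "base") {
  col <- paste0("cost_", match.arg(which, c("base", "low", "high")))
  sel <- schedule$sector == sector & schedule$visit == visit &
    schedule$state == state
  if (visit == 0) {
    if (is.null(strategy)) {
      stop_validation("visit-0 cells are strategy-specific; supply a strategy")
    }
    sel <- sel & !is.na(schedule$strategy) & schedule$strategy == strategy
  }
  hit <- schedule[sel, col]
  if (length(hit) != 1) {
    stop_validation("cost schedule cell (", sector, ", visit ", visit, ", ",
                    state, if (!is.null(strategy)) paste0(", ", strategy),
                    ") is ", if (length(hit)) "duplicated" else "missing")
  }
  hit
}

#' Restate a unit cost at another price year via GDP deflators
#'
#' @param cost Money at the base price year.
#' @param base_year_deflator GDP deflator index of the cost's base year.
#' @param target_year_deflator GDP deflator index of the target year.
#' @return `cost * target_year_deflator / base_year_deflator`.
#' @examples
#' deflate_cost(2511.30, 98.4, 100)
#' @export
deflate_cost <- function(cost, base_year_deflator, target_year_deflator) {
  if (any(base_year_deflator <= 0) || any(target_year_deflator <= 0)) {
    stop_domain("GDP deflators must be positive")
  }
  cost * target_year_deflator / base_year_deflator
}

#' Average visit cost weighted by procedure receipt proportions
#'
#' For one (sector, visit, state) cell, sums each procedure's unit cost
#' (optionally restated to the target price year) weighted by the fraction of
#' patients receiving it.
#'
#' @param procedures Data frame with columns `unit_cost`,
#'   `receipt_proportion`, and optionally `base_year_deflator`.
#' @param target_year_deflator Deflator of the reporting year; if supplied
#'   together with per-procedure `base_year_deflator`, each unit cost is
#'   deflated first.
#' @return The weighted average direct medical cost (MYR).
#' @examples
#' weighted_visit_cost(data.frame(unit_cost = c(100, 200),
#'                                receipt_proportion = c(0.5, 0.25)))
#' @export
weighted_visit_cost <- function(procedures, target_year_deflator = NULL) {
  if (!is.data.frame(procedures) || nrow(procedures) == 0) {
    stop_domain("procedures must be a non-empty data frame")
  }
  assert_probability(procedures$receipt_proportion, "receipt_proportion")
  if (any(procedures$unit_cost < 0)) stop_domain("unit costs must be >= 0")
  cost <- procedures$unit_cost
  if (!is.null(target_year_deflator) &&
      !is.null(procedures$base_year_deflator)) {
    cost <- deflate_cost(cost, procedures$base_year_deflator,
                         target_year_deflator)
  }
  sum(cost * procedures$receipt_proportion)
}

#' Strategy-blended cost of the initial visit
#'
#' Patients enter the model unstable and receive one of the treatment
#' strategies at visit 0; the expected entry cost is the mix-weighted average
#' of the strategy-specific unstable visit-0 cells.
#'
#' @param schedule A [cost_schedule()].
#' @param mix Named strategy weights summing to 1 (see [strategy_mix()]).
#' @param sector "public" or "private".
#' @return Blended initial-visit cost (MYR).
#' @examples
#' sched <- base_config()$cost_schedule
#' blend_initial_cost(sched, strategy_mix(), "public")
#' @export
blend_initial_cost <- function(schedule, mix, sector) {
  mix <- strategy_mix(mix)
  cells <- vapply(names(mix), function(s) {
    schedule_cell(schedule, sector, 0L, "unstable", s)
  }, numeric(1))
  sum(mix * cells)
}

#' Normalise and validate a strategy mix
#'
#' @param weights Named numeric vector or list of weights over
#'   [PERIO_STRATEGIES]. The default mix reflects 20% of patients receiving
#'   antibiotic adjuncts, 80% of those amoxycillin+metronidazole and 20%
#'   azithromycin.
#' @return Named numeric vector over all strategies, summing to 1.
#' @export
strategy_mix <- function(weights = c(NSPT_only = 0.80,
                                     NSPT_AMOX_MET = 0.16,
                                     NSPT_AZ = 0.04)) {
  w <- unlist(weights)
  unknown <- setdiff(names(w), PERIO_STRATEGIES)
  if (length(unknown)) {
    stop_validation("unknown strategy in mix: ", paste(unknown, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(PERIO_STRATEGIES)), PERIO_STRATEGIES)
  full[names(w)] <- w
  if (any(full < 0) || abs(sum(full) - 1) > 1e-9) {
    stop_validation("strategy_mix weights must be non-negative and sum to 1 ",
                    "(got sum ", format(sum(full)), ")")
  }
  full
}

#' Sensitivity variant of a cost schedule
#'
#' Produces the low or high cost schedule used by the one-way sensitivity
#' analysis. Public cells are scaled by 0.8 (low) or 1.2 (high) and rounded to
#' the cent; private cells are replaced by their independently elicited fee
#' bounds (`cost_low`/`cost_high`), which are not a fixed multiple of the
#' average.
#'
#' @param schedule A [cost_schedule()].
#' @param which "low" or "high".
#' @return A [cost_schedule()] whose `cost_base` holds the variant costs.
#' @export
cost_range_variant <- function(schedule, which = c("low", "high")) {
  which <- match.arg(which)
  factor <- if (which == "low") 0.8 else 1.2
  out <- schedule
  pub <- out$sector == "public"
  out$cost_base[pub] <- round_cents(schedule$cost_base[pub] * factor)
  bound_col <- paste0("cost_", which)
  out$cost_base[!pub] <- schedule[[bound_col]][!pub]
  cost_schedule(as.data.frame(out))
}
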