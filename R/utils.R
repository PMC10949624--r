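#' Periodontal health states used throughout the model
#'
#' Ordered state labels for the 3-state transition structure:
#' stable (PPD <= 4 mm, BOP < 10%), in remission (PPD <= 4 mm, BOP >= 10%),
#' unstable (PPD >= 5 mm).
#'
#' @format Character vector of length 3.
#' @export
PERIO_STATES <- c("stable", "remission", "unstable")

#' First-visit treatment strategies
#'
#' Subgingival instrumentation alone or with one of the two systemic
#' antibiotic adjuncts in routine specialist use: amoxycillin plus
#' metronidazole, or azithromycin.
#'
#' @format Character vector of length 3.
#' @export
PERIO_STRATEGIES <- c("NSPT_only", "NSPT_AMOX_MET", "NSPT_AZ")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when converting fractional person
#' counts and money to whole units. Base R's `round()` rounds half to even,
#' which does not reproduce conventional published tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.5)     # 1, where round(0.5) is 0
#' round_half_up(2.345, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round money to the cent
#'
#' @param x Numeric vector of money values.
#' @return `x` rounded half-up to 2 decimal places.
#' @export
round_cents <- function(x) round_half_up(x, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("perioburden_domain_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("perioburden_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("perioburden_io_error", "error")))
}

is_probability <- function(x) is.numeric(x) && !anyNA(x) && all(x >= 0 & x <= 1)

assert_probability <- function(x, what) {
  if (!is_probability(x)) {
    stop_domain(what, " must be a fraction in [0, 1], got ",
                paste(format(x), collapse = ", "))
  }
  invisible(x)
}
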