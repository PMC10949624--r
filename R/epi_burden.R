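#' Point estimate with confidence bounds
#'
#' Lightweight container for a quantity carried through the pipeline together
#' with its lower and upper 95% interval limits. Interval propagation is
#' stage-wise: every downstream quantity's bounds are obtained by substituting
#' all inputs' lower (resp. upper) limits simultaneously, so a "lower" bound
#' labels the bound-substituted run, not necessarily the smaller value (the
#' public sector share, for instance, is larger when both visit rates sit at
#' their lower limits).
#'
#' @param point Point estimate.
#' @param lower,upper Interval limits; default to `point`.
#' @return Named numeric vector `c(point, lower, upper)` of class `perio_est`.
#' @examples
#' est(0.485, 0.460, 0.512)
#' @export
est <- function(point, lower = point, upper = point) {
  x <- c(point = point, lower = lower, upper = upper)
  structure(x, class = "perio_est")
}

as_est <- function(x, what = "estimate") {
  if (inherits(x, "perio_est")) return(x)
  if (is.numeric(x) && length(x) == 1) return(est(x))
  if (is.list(x)) {
    if (is.null(x$point)) stop_validation(what, " needs a 'point' value")
    return(est(x$point, x$lower %||% x$point, x$upper %||% x$point))
  }
  if (is.numeric(x) && length(x) == 3) return(est(x[[1]], x[[2]], x[[3]]))
  stop_validation(what, " cannot be interpreted as a point-with-bounds estimate")
}

# Apply f to each of point/lower/upper of one or more perio_est inputs.
est_map <- function(f, ...) {
  args <- lapply(list(...), as_est)
  vals <- vapply(c("point", "lower", "upper"), function(k) {
    do.call(f, lapply(args, function(a) unname(a[k])))
  }, numeric(1))
  est(vals[["point"]], vals[["lower"]], vals[["upper"]])
}

#' Estimate national disease counts from census and prevalence
#'
#' Multiplies the adult census count with prevalence fractions (overall,
#' moderate and severe periodontitis), rounding half-up to whole persons.
#' Interval bounds are propagated by substituting the prevalence interval
#' limits.
#'
#' @param census Number of adults in the reference population.
#' @param prevalences Named list of prevalence estimates (each a [est()] or a
#'   `list(point=, lower=, upper=)`), conventionally named
#'   `all`, `moderate`, `severe`.
#' @return A `data.frame` of class `disease_burden` with one row per
#'   prevalence and columns `group`, `prevalence`, `count`, `count_lower`,
#'   `count_upper`.
#' @examples
#' estimate_disease_counts(24692460, list(all = est(0.485, 0.460, 0.512)))
#' @export
estimate_disease_counts <- function(census, prevalences) {
  if (!is.numeric(census) || length(census) != 1 || census <= 0) {
    stop_domain("census must be a single positive count")
  }
  prevalences <- lapply(prevalences, as_est, what = "prevalence")
  for (p in prevalences) assert_probability(unclass(p), "prevalence")
  rows <- lapply(names(prevalences), function(g) {
    p <- prevalences[[g]]
    n <- est_map(function(q) round_half_up(census * q), p)
    data.frame(group = g,
               prevalence = unname(p["point"]),
               count = unname(n["point"]),
               count_lower = unname(n["lower"]),
               count_upper = unname(n["upper"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("disease_burden", "data.frame")
  out
}

#' Care-seeking cascade for adults with periodontitis
#'
#' Chains the published survey fractions into the number of adults with
#' (severe) periodontitis who reported a recent oral health problem and sought
#' treatment:
#' reporters `a = b x c`, treatment seekers `a x f`, and finally the
#' periodontitis share of seekers, taken either directly from the configured
#' split or derived as `d / (d + e)` from the severe-periodontitis and caries
#' prevalences (symptom-driven reporting assumption). Each stage is rounded
#' half-up to whole persons before the next stage, which is what makes the
#' published tables reproducible; interval bounds substitute all limits
#' simultaneously.
#'
#' @param u Utilisation inputs: a list with elements
#'   `b` (fraction of adults reporting recent oral health problems),
#'   `c` (adult census count),
#'   `f` (fraction of reporters who sought treatment), and either
#'   `perio_share` (fraction of seekers attributable to severe periodontitis)
#'   or both `d` (severe periodontitis prevalence) and `e` (caries
#'   prevalence). `b`, `f`, `d`, `e`, `perio_share` may carry bounds via
#'   [est()].
#' @return List of class `perio_cascade` with `perio_est` elements
#'   `a` (reporters), `sought_any` (reporters who sought treatment),
#'   `perio_share`, and `sought_total` (seekers with severe periodontitis).
#' @examples
#' cascade(list(b = 0.087, c = 24692460, f = 0.23, perio_share = 0.17))
#' @export
cascade <- function(u) {
  b <- as_est(u$b, "b"); f <- as_est(u$f, "f")
  assert_probability(unclass(b), "b"); assert_probability(unclass(f), "f")
  cc <- u$c
  if (!is.numeric(cc) || length(cc) != 1 || cc <= 0) {
    stop_domain("c (census) must be a single positive count")
  }
  if (!is.null(u$perio_share)) {
    share <- as_est(u$perio_share, "perio_share")
  } else {
    d <- as_est(u$d, "d"); e <- as_est(u$e, "e")
    assert_probability(unclass(d), "d"); assert_probability(unclass(e), "e")
    if (unname(d["point"] + e["point"]) <= 0) {
      stop_domain("d + e must be positive to form the periodontitis share")
    }
    share <- est_map(function(di, ei) di / (di + ei), d, e)
  }
  assert_probability(unclass(share), "perio_share")

  a <- est_map(function(bi) round_half_up(bi * cc), b)
  sought_any <- est_map(function(ai, fi) round_half_up(ai * fi), a, f)
  sought_total <- est_map(function(si, pi) round_half_up(si * pi),
                          sought_any, share)
  structure(list(a = a, sought_any = sought_any, perio_share = share,
                 sought_total = sought_total),
            class = "perio_cascade")
}

#' Split treatment seekers between public and private sectors
#'
#' Allocates the treated cohort to sectors in proportion to the annual mean
#' number of dental visits per capita in each sector. The sector composition
#' is rounded to three decimal places (one decimal in percent) before
#' multiplying, matching how such shares are published; the two sector counts
#' are then reconciled to sum to the total within one person.
#'
#' @param sought_total Treated count, a scalar or [est()].
#' @param visit_rate_public,visit_rate_private Annual mean visits per capita
#'   by sector, scalars or [est()] with bounds.
#' @return A `data.frame` of class `sector_counts` with rows
#'   `point`, `lower`, `upper` and columns `composition_public`,
#'   `composition_private`, `treated_public`, `treated_private`,
#'   `treated_total`.
#' @examples
#' split_by_sector(83996, 0.23, 0.06)
#' @export
split_by_sector <- function(sought_total, visit_rate_public, visit_rate_private) {
  total <- as_est(sought_total, "sought_total")
  rp <- as_est(visit_rate_public, "visit_rate_public")
  rq <- as_est(visit_rate_private, "visit_rate_private")
  if (any(unclass(rp) < 0) || any(unclass(rq) < 0)) {
    stop_domain("visit rates must be non-negative")
  }
  if (any(unclass(rp) + unclass(rq) == 0)) {
    stop_domain("visit rates cannot both be zero")
  }
  comp_pub <- est_map(function(p, q) round_half_up(p / (p + q), 3), rp, rq)
  comp_priv <- est_map(function(p, q) round_half_up(q / (p + q), 3), rp, rq)
  t_pub <- est_map(function(n, w) round_half_up(n * w), total, comp_pub)
  t_priv <- est_map(function(n, w) round_half_up(n * w), total, comp_priv)
  # Reconcile independent roundings: the sectors must tile the total.
  for (k in c("point", "lower", "upper")) {
    if (abs(t_pub[k] + t_priv[k] - total[k]) > 1) {
      t_priv[k] <- total[k] - t_pub[k]
    }
  }
  out <- data.frame(
    bound = c("point", "lower", "upper"),
    composition_public = unclass(comp_pub),
    composition_private = unclass(comp_priv),
    treated_public = unclass(t_pub),
    treated_private = unclass(t_priv),
    treated_total = unclass(total),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("sector_counts", "data.frame")
  out
}

#' Run the full epidemiological stage of the pipeline
#'
#' Convenience wrapper computing disease counts, the care-seeking cascade and
#' the sector split from a validated model configuration.
#'
#' @param config A `perio_config`, e.g. from [load_config()] or
#'   [base_config()].
#' @return List with elements `disease` ([estimate_disease_counts()] output),
#'   `cascade` ([cascade()] output) and `sectors` ([split_by_sector()]
#'   output).
#' @export
epi_pipeline <- function(config) {
  disease <- estimate_disease_counts(config$census_adults, config$prevalence)
  casc <- cascade(c(config$utilisation, list(c = config$census_adults)))
  sectors <- split_by_sector(casc$sought_total,
                             config$utilisation$visit_rate_public,
                             config$utilisation$visit_rate_private)
  list(disease = disease, cascade = casc, sectors = sectors)
}
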