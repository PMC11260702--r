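# Synthetic external fixtures: a Gompertz-Makeham life table, a unimodal
# age-at-diagnosis incidence mix and an age-declining baseline utility
# curve. These emulate the statistical structure of the national registry
# inputs (age-specific all-cause mortality, rectal-cancer incidence by age,
# population EQ-5D-5L norms) so the full pipeline runs with no download;
# they are synthetic stand-ins, not transcriptions of any registry.

#' Generate a Gompertz-Makeham life table
#'
#' Annual probability of death
#' `qx(age) = 1 - exp(-(makeham + gompertz_a * exp(gompertz_b * age)))`,
#' clipped to `[0, 1]`, for ages 0-100. Defaults give a remaining life
#' expectancy at 70 of roughly 15 years, in the range of a contemporary
#' Western European population. Setting `makeham = 0, gompertz_a = 0`
#' yields the immortal cohort used by zero-mortality analyses.
#'
#' @param makeham Age-independent hazard component (>= 0).
#' @param gompertz_a Gompertz level (>= 0).
#' @param gompertz_b Gompertz slope (> 0 when `gompertz_a > 0`).
#' @param ages Integer ages (default 0-100).
#' @return Data frame with columns `age`, `qx`.
#' @export
make_life_table <- function(makeham = 5e-4, gompertz_a = 2e-5,
                            gompertz_b = 0.095, ages = 0:100) {
  stopifnot(makeham >= 0, gompertz_a >= 0)
  hazard <- makeham + gompertz_a * exp(gompertz_b * ages)
  qx <- pmin(pmax(1 - exp(-hazard), 0), 1)
  if (any(qx[ages < 60] >= 1))
    warning("life-table parameters produce qx = 1 before age 60")
  data.frame(age = ages, qx = qx)
}

#' Generate a unimodal age-at-diagnosis incidence mix
#'
#' Discretized normal density over the diagnosis ages, peaked in late
#' adulthood, normalized to sum to 1. A degenerate `spread` places all mass
#' at the mode. Optional multiplicative lognormal jitter (seeded) roughens
#' the curve the way registry counts are rough.
#'
#' @param mode Modal age (default 70).
#' @param spread Standard deviation of the age distribution (years).
#' @param ages Ages covered (default 25-99).
#' @param jitter_sd Standard deviation of lognormal weight jitter
#'   (default 0, deterministic output).
#' @param seed Seed used when `jitter_sd > 0`.
#' @return Data frame with columns `age`, `weight`; weights sum to 1.
#' @export
make_incidence_mix <- function(mode = 70, spread = 12, ages = 25:99,
                               jitter_sd = 0, seed = NULL) {
  stopifnot(mode >= min(ages), mode <= max(ages), spread >= 0)
  if (spread < 1e-8) {
    w <- as.numeric(ages == ages[which.min(abs(ages - mode))])
  } else {
    w <- stats::dnorm(ages, mean = mode, sd = spread)
  }
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    w <- w * stats::rlnorm(length(w), -jitter_sd^2 / 2, jitter_sd)
  }
  data.frame(age = ages, weight = w / sum(w))
}

#' Generate a baseline utility curve declining in age
#'
#' Linear (default) or logistic decline from `u_young` at the youngest age
#' to `u_old` at the oldest; values stay within `[u_old, u_young]` and are
#' non-increasing in age.
#'
#' @param u_young Utility at the youngest age, in `[0, 1]`.
#' @param u_old Utility at the oldest age, `u_old <= u_young`.
#' @param ages Ages covered (default 25-100).
#' @param shape `"linear"` or `"logistic"`.
#' @param midpoint,steepness Logistic parameters (ignored for linear).
#' @return Data frame with columns `age`, `utility`.
#' @export
make_utility_curve <- function(u_young = 0.92, u_old = 0.74, ages = 25:100,
                               shape = c("linear", "logistic"),
                               midpoint = 70, steepness = 0.08) {
  shape <- match.arg(shape)
  if (u_old > u_young) stop("u_old must not exceed u_young")
  stopifnot(u_young <= 1, u_old >= 0)
  frac <- switch(shape,
    linear = (ages - min(ages)) / max(max(ages) - min(ages), 1),
    logistic = stats::plogis(steepness * (ages - midpoint)))
  data.frame(age = ages, utility = u_young - (u_young - u_old) * frac)
}

#' Interpolate a utility curve at (possibly fractional) ages
#'
#' @param curve Data frame with columns `age`, `utility`.
#' @param age Numeric vector of ages; must lie within the curve's range.
#' @return Interpolated utilities.
#' @export
utility_at <- function(curve, age) {
  stopifnot(all(c("age", "utility") %in% names(curve)))
  if (any(age < min(curve$age) | age > max(curve$age)))
    stop("age outside the utility curve's range [", min(curve$age), ", ",
         max(curve$age), "]")
  stats::approx(curve$age, curve$utility, xout = age)$y
}

#' Write the synthetic fixture files
#'
#' Writes `life_table.csv`, `incidence.csv` and `utilities.csv` to a
#' directory, in the same schema the readers expect, so real registry
#' extracts with identical columns can be dropped in unchanged.
#'
#' @param dir Output directory (created if needed).
#' @param life_table,incidence,utilities Fixture data frames; defaults are
#'   the package defaults.
#' @return Named character vector of the file paths, invisibly.
#' @export
write_fixtures <- function(dir, life_table = make_life_table(),
                           incidence = make_incidence_mix(),
                           utilities = make_utility_curve()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(life_table = file.path(dir, "life_table.csv"),
             incidence = file.path(dir, "incidence.csv"),
             utilities = file.path(dir, "utilities.csv"))
  utils::write.csv(life_table, paths[["life_table"]], row.names = FALSE)
  utils::write.csv(incidence, paths[["incidence"]], row.names = FALSE)
  utils::write.csv(utilities, paths[["utilities"]], row.names = FALSE)
  invisible(paths)
}

.read_fixture <- function(path, cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(cols %in% names(df)))
    stop(what, " file ", path, " must have columns ",
         paste(cols, collapse = ", "))
  df
}

#' Read a life table CSV (`age`, `qx`)
#' @param path File path.
#' @return Validated data frame.
#' @export
read_life_table <- function(path) {
  df <- .read_fixture(path, c("age", "qx"), "life table")
  .check_life_table(df)
  df
}

#' Read an incidence-mix CSV (`age`, `weight`)
#' @param path File path.
#' @return Validated data frame.
#' @export
read_incidence <- function(path) {
  df <- .read_fixture(path, c("age", "weight"), "incidence")
  if (any(df$weight < 0) || abs(sum(df$weight) - 1) > 1e-6)
    stop("incidence weights must be non-negative and sum to 1")
  df
}

#' Read a utility-curve CSV (`age`, `utility`)
#' @param path File path.
#' @return Validated data frame.
#' @export
read_utilities <- function(path) {
  df <- .read_fixture(path, c("age", "utility"), "utility curve")
  if (any(df$utility < 0 | df$utility > 1))
    stop("utilities must lie in [0, 1]")
  df
}
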