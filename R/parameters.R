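# Parameter table: every model quantity with base-case value, uncertainty
# distribution, units and provenance. Values are stored exactly as printed in
# the source table (probabilities on the percent scale); `param_value()` is
# the single conversion point to the unit scale used in computation.

.prob_groups <- c("transition", "treatment", "recurrence", "mortality")

.required_ids <- c(
  paste0("p_tox_grade", 1:4),
  "ntcp_imrt_igrt", "ntcp_imrt", "ntcp_3dcrt",
  "p_loperamide_success", "p_second_line_ab", "p_second_line_bas",
  "p_ab_success", "p_bas_success",
  "p_surgery", "p_supportive",
  "p_surgery_survival", "p_surgery_death",
  "p_supportive_survival", "p_supportive_death",
  paste0("p_rec", rep(1:4, each = 2), c("_surgery", "_supportive")),
  "cost_loperamide_unit", "cost_ab_unit", "cost_bas_unit",
  "cost_hosp_surgery", "cost_hosp_supportive",
  "activity_rate", "wage_daily", "wage_annual",
  "sickdays_event", "sickdays_management", "sickleave_hosp_factor",
  "disutility_pharma", "disutility_supportive", "disutility_surgery")

#' Model settings and their defaults
#'
#' Returns the base-case configuration of the model: half-yearly cycles, a
#' lifetime horizon to age 100, discount rates of 3.0% (costs) and 1.5%
#' (utilities), a toxicity-hazard plateau of 5 years followed by a 25% annual
#' decline, one-way sensitivity bounds of 70%/130%, and 1,000 probabilistic
#' draws. Resource-use knobs (drug course length and daily doses) and
#' structural switches (half-cycle discounting, recurrence-risk proxy for
#' pharmaceutically managed patients, hazard decay on recurrence risk,
#' within-cycle escalation of failed pharmaceutical management) are exposed
#' here as well.
#'
#' @param ... named overrides of individual settings.
#' @return A named list of settings.
#' @export
default_settings <- function(...) {
  s <- list(
    cycle_length_years = 0.5,
    horizon_age = 100,
    cost_discount = 0.030,
    utility_discount = 0.015,
    decay_onset_years = 5,
    decay_per_year = 0.25,
    dsa_low = 0.70,
    dsa_high = 1.30,
    psa_draws = 1000,
    retirement_age = 65,
    ntcp_reference = 0.180,
    course_days = 90,
    units_per_day = c(loperamide = 2, ab = 3, bas = 4),
    psa_mode = "calibrated",
    beta_ess = 100,
    sigma_log = 0.25,
    half_cycle = TRUE,
    pharma_recurrence_source = "supportive",
    decay_on_recurrence = FALSE,
    pharma_failure_escalates = FALSE)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(s))
    if (length(bad)) stop("unknown setting(s): ", paste(bad, collapse = ", "))
    s[names(dots)] <- dots
  }
  s
}

#' Path to the packaged parameter table
#'
#' @return File path of the CSV transcription of the model's parameter table.
#' @export
sbtox_parameter_file <- function() {
  system.file("extdata", "parameters.csv", package = "sbtoxecon",
              mustWork = TRUE)
}

#' Radiotherapy technique identifiers
#'
#' @return Character vector `c("imrt_igrt", "imrt", "3dcrt")`, ordered from
#'   most to least conformal technique.
#' @export
sbtox_techniques <- function() c("imrt_igrt", "imrt", "3dcrt")

.parse_dist_params <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}

.validate_row <- function(row) {
  id <- row$id
  v <- row$base_value
  if (!is.finite(v)) stop("parameter '", id, "' has a non-numeric base value")
  if (row$unit == "%" && row$group %in% .prob_groups &&
      (v < 0 || v > 100))
    stop("parameter '", id, "' out of range: probabilities must lie in ",
         "[0, 100] percent, got ", v)
  if (row$group == "utility" && (v < -100 || v > 0))
    stop("parameter '", id, "' out of range: relative disutilities must lie ",
         "in [-100, 0] percent, got ", v)
  if (row$unit == "fraction" && (v <= 0 || v > 1))
    stop("parameter '", id, "' out of range: NTCP fractions must lie in ",
         "(0, 1], got ", v)
  if (row$unit %in% c("EUR", "days", "factor") && v < 0)
    stop("parameter '", id, "' out of range: must be non-negative, got ", v)
  dp <- .parse_dist_params(row$dist_params)
  switch(row$family,
    beta = {
      if (length(dp) && (dp[["alpha"]] <= 0 || dp[["beta"]] <= 0))
        stop("parameter '", id, "': beta shapes must be positive")
    },
    gamma = {
      if (length(dp) && (dp[["shape"]] <= 0 || dp[["scale"]] <= 0))
        stop("parameter '", id, "': gamma shape/scale must be positive")
    },
    lognormal = NULL,
    degenerate = NULL,
    stop("parameter '", id, "': unknown distribution family '",
         row$family, "'"))
  invisible(TRUE)
}

#' Load and validate the model parameter set
#'
#' Reads a delimited parameter table (columns `id`, `group`, `base_value`,
#' `unit`, `family`, `dist_params`, `source`), checks completeness against
#' the set of required identifiers, validates ranges and distribution
#' parameters, and attaches the model settings.
#'
#' @param path Path to the parameter CSV; defaults to the packaged table.
#' @param settings Named list of setting overrides (see [default_settings()]).
#' @return An object of class `parameter_set`.
#' @export
load_parameter_set <- function(path = sbtox_parameter_file(),
                               settings = list()) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(dist_params = "character"))
  need <- c("id", "group", "base_value", "unit", "family", "dist_params",
            "source")
  if (!all(need %in% names(tab)))
    stop("parameter file lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicated parameter id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  unknown <- setdiff(tab$id, .required_ids)
  if (length(unknown))
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.required_ids, tab$id)
  if (length(missing))
    stop("incomplete parameter set; missing id(s): ",
         paste(missing, collapse = ", "))
  for (i in seq_len(nrow(tab))) .validate_row(tab[i, ])
  ps <- structure(
    list(table = tab,
         settings = do.call(default_settings, settings),
         log = character()),
    class = "parameter_set")
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>", nrow(x$table), "parameters\n")
  cat("  groups:", paste(sort(unique(x$table$group)), collapse = ", "), "\n")
  cat("  NTCP: ", paste(sprintf("%s=%.3f", names(ntcp(x)), ntcp(x)),
                        collapse = ", "), "\n")
  invisible(x)
}

.param_row <- function(ps, id) {
  i <- match(id, ps$table$id)
  if (is.na(i)) stop("unknown parameter id: '", id, "'")
  ps$table[i, ]
}

#' Access a parameter value
#'
#' @param ps A `parameter_set`.
#' @param id Parameter identifier.
#' @param scale `"unit"` (default) converts percent-scale entries to the
#'   `[0, 1]` scale used in computation; `"printed"` returns the value as
#'   stored in the table.
#' @return A numeric scalar.
#' @export
param_value <- function(ps, id, scale = c("unit", "printed")) {
  scale <- match.arg(scale)
  row <- .param_row(ps, id)
  v <- row$base_value
  if (scale == "unit" && row$unit == "%") v <- v / 100
  v
}

#' NTCP fractions by technique
#'
#' @param ps A `parameter_set`.
#' @return Named numeric vector of small-bowel NTCP fractions for
#'   `imrt_igrt`, `imrt` and `3dcrt`.
#' @export
ntcp <- function(ps) {
  c(imrt_igrt = param_value(ps, "ntcp_imrt_igrt"),
    imrt = param_value(ps, "ntcp_imrt"),
    `3dcrt` = param_value(ps, "ntcp_3dcrt"))
}

#' Multiply one parameter's base value by a factor
#'
#' Used by the one-way deterministic sensitivity analysis. Probabilities are
#' capped at 100% (unit scale 1.0) and relative disutilities at -100%; any
#' cap is recorded in the parameter set's log and messaged.
#'
#' @param ps A `parameter_set`.
#' @param id Parameter identifier.
#' @param factor Positive multiplier.
#' @return A modified copy of `ps`.
#' @export
perturb <- function(ps, id, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  i <- match(id, ps$table$id)
  if (is.na(i)) stop("unknown parameter id: '", id, "'")
  row <- ps$table[i, ]
  v <- row$base_value * factor
  capped <- FALSE
  if (row$unit == "%" && row$group %in% .prob_groups && v > 100) {
    v <- 100; capped <- TRUE
  }
  if (row$unit == "fraction" && v > 1) {
    v <- 1; capped <- TRUE
  }
  if (row$group == "utility" && v < -100) {
    v <- -100; capped <- TRUE
  }
  if (capped) {
    msg <- sprintf("perturb('%s', %.4g): value capped at %g", id, factor, v)
    ps$log <- c(ps$log, msg)
    message(msg)
  }
  ps$table$base_value[i] <- v
  ps
}

#' Write a parameter set back to CSV
#'
#' Inverse of [load_parameter_set()]; `load(write(ps))` round-trips exactly.
#'
#' @param ps A `parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(ps, path) {
  utils::write.csv(ps$table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.beta_mom <- function(mean, ess) {
  stopifnot(mean > 0, mean < 1)
  c(alpha = mean * ess, beta = (1 - mean) * ess)
}

.draw_one <- function(row, mode, settings) {
  fam <- row$family
  if (fam == "degenerate" || mode == "degenerate") return(row$base_value)
  pct <- row$unit == "%"
  base <- if (pct) row$base_value / 100 else row$base_value
  dp <- .parse_dist_params(row$dist_params)
  draw <- switch(fam,
    beta = {
      if (mode == "verbatim" && length(dp)) {
        stats::rbeta(1, dp[["alpha"]], dp[["beta"]])
      } else {
        sh <- .beta_mom(base, settings$beta_ess)
        stats::rbeta(1, sh[["alpha"]], sh[["beta"]])
      }
    },
    gamma = {
      shape <- if (length(dp)) dp[["shape"]] else 100
      scale <- if (mode == "verbatim" && length(dp)) dp[["scale"]]
               else base / shape
      stats::rgamma(1, shape = shape, scale = scale)
    },
    lognormal = {
      sdlog <- settings$sigma_log
      meanlog <- if (mode == "verbatim" && length(dp)) dp[["meanlog"]]
                 else log(base) - sdlog^2 / 2
      stats::rlnorm(1, meanlog = meanlog, sdlog = sdlog)
    },
    stop("cannot sample family '", fam, "'"))
  if (pct) draw * 100 else draw
}

#' Draw one joint parameter sample for probabilistic analysis
#'
#' Produces one independent joint draw of all non-degenerate parameters.
#' In the default `"calibrated"` mode beta parameters are re-derived by the
#' method of moments around the base-case mean with effective sample size
#' `beta_ess`, gamma scales are set to `base/shape`, and lognormal locations
#' to `log(base) - sigma^2/2`, so that every sampled parameter has its
#' base-case value as (approximate) mean. `"verbatim"` uses the printed
#' distribution parameters unchanged; `"degenerate"` returns the base case.
#'
#' @param ps A `parameter_set`.
#' @param seed Optional integer seed; when supplied the draw is a pure
#'   function of `(ps, seed)`.
#' @param mode One of `"calibrated"`, `"verbatim"`, `"degenerate"`; defaults
#'   to the `psa_mode` setting.
#' @return A `parameter_set` whose base values are replaced by the draw.
#' @export
draw_parameter_set <- function(ps, seed = NULL,
                               mode = ps$settings$psa_mode) {
  mode <- match.arg(mode, c("calibrated", "verbatim", "degenerate"))
  if (!is.null(seed)) set.seed(seed)
  out <- ps
  for (i in seq_len(nrow(ps$table))) {
    out$table$base_value[i] <- .draw_one(ps$table[i, ], mode, ps$settings)
  }
  out
}
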