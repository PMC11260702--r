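# Orchestration of the four analyses: lifetime base case on the age-mixed
# cohort, age-cohort hospitalization scenario, one-way deterministic
# sensitivity analysis (tornado), and probabilistic sensitivity analysis
# (Monte Carlo, cost-effectiveness plane).

.econ_by_technique <- function(ps, life_table, incidence, utilities,
                               techniques = sbtox_techniques()) {
  w <- incidence$weight
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("incidence weights must be non-negative and sum to 1")
  keep <- w > 0
  ages <- incidence$age[keep]
  if (max(ages) + 0.01 > max(utilities$age) || min(ages) < min(utilities$age))
    stop("utility curve does not cover the incidence ages")
  w <- w[keep]
  res <- list()
  for (tech in techniques) {
    per_age <- lapply(ages, function(a) {
      tr <- run_cohort(ps, tech, a, life_table)
      list(full = value_cohort(tr, ps, utilities, include_indirect = TRUE),
           direct = value_cohort(tr, ps, utilities,
                                 include_indirect = FALSE))
    })
    res[[tech]] <- list(
      full = .combine_econ(lapply(per_age, `[[`, "full"), w, tech),
      direct = .combine_econ(lapply(per_age, `[[`, "direct"), w, tech))
  }
  res
}

.incrementals <- function(res, ref = "3dcrt") {
  comps <- setdiff(names(res), ref)
  do.call(rbind, lapply(comps, function(tech) {
    data.frame(
      comparator = paste0(tech, "_vs_", ref),
      dcost_discounted = res[[tech]]$full$cost_discounted -
        res[[ref]]$full$cost_discounted,
      dcost_undiscounted = res[[tech]]$full$cost_undiscounted -
        res[[ref]]$full$cost_undiscounted,
      dcost_direct_discounted = res[[tech]]$direct$cost_discounted -
        res[[ref]]$direct$cost_discounted,
      dqaly_discounted = res[[tech]]$full$qaly_discounted -
        res[[ref]]$full$qaly_discounted,
      dqaly_undiscounted = res[[tech]]$full$qaly_undiscounted -
        res[[ref]]$full$qaly_undiscounted)
  }))
}

#' Run the lifetime base-case analysis
#'
#' Runs the age-mixed cohort once per technique on identical fixtures and
#' reports absolute and incremental (vs 3D-CRT) discounted and undiscounted
#' costs and QALYs, with and without indirect (productivity) costs.
#'
#' @param ps A `parameter_set`.
#' @param life_table Life table data frame (`age`, `qx`).
#' @param incidence Incidence mix data frame (`age`, `weight`).
#' @param utilities Utility curve data frame (`age`, `utility`).
#' @return An object of class `sbtox_base_case`: per-technique
#'   `econ_result`s (`$results`), direct-cost-only variants
#'   (`$results_direct`), the incremental table (`$incremental`) and a
#'   wide summary table (`$table`).
#' @export
run_base_case <- function(ps, life_table, incidence, utilities) {
  res <- .econ_by_technique(ps, life_table, incidence, utilities)
  inc <- .incrementals(res)
  tab <- do.call(rbind, lapply(names(res), function(tech) {
    r <- res[[tech]]$full
    data.frame(technique = tech,
               cost_discounted = r$cost_discounted,
               qaly_discounted = r$qaly_discounted,
               cost_undiscounted = r$cost_undiscounted,
               qaly_undiscounted = r$qaly_undiscounted)
  }))
  structure(list(results = lapply(res, `[[`, "full"),
                 results_direct = lapply(res, `[[`, "direct"),
                 incremental = inc, table = tab),
            class = "sbtox_base_case")
}

#' @export
print.sbtox_base_case <- function(x, ...) {
  cat("<sbtox_base_case>\n")
  print(x$table, row.names = FALSE, digits = 6)
  cat("incremental (vs 3D-CRT):\n")
  print(x$incremental, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Cumulative hospitalizations per 100 patients by age cohort
#'
#' Deterministic scenario: homogeneous cohorts (default ages 30, 50, 70,
#' 90) are run per technique and the expected admissions (grade 3-4 first
#' events plus all recurrent events) are accumulated at 10-year horizons.
#' Cells whose horizon would extend past age 100 are `NA`.
#'
#' @param ps A `parameter_set`.
#' @param life_table Life table data frame (`age`, `qx`).
#' @param cohort_ages Ages at diagnosis (default `c(30, 50, 70, 90)`).
#' @param horizons Horizons in years after treatment (default 10-70 by 10).
#' @param per Cohort size the counts are scaled to (default 100).
#' @return Object of class `sbtox_scenario`: long data frame `$counts`
#'   with columns `age`, `technique`, `horizon`, `hospitalizations`
#'   (expected) and `rounded`.
#' @export
run_hospitalization_scenario <- function(ps, life_table,
                                         cohort_ages = c(30, 50, 70, 90),
                                         horizons = seq(10, 70, by = 10),
                                         per = 100) {
  cl <- ps$settings$cycle_length_years
  horizon_age <- ps$settings$horizon_age
  out <- list()
  for (age in cohort_ages) {
    for (tech in sbtox_techniques()) {
      tr <- run_cohort(ps, tech, age, life_table)
      cum <- cumsum(tr$flows$hospitalizations)
      for (h in horizons) {
        val <- if (age + h > horizon_age) NA_real_ else {
          n <- min(round(h / cl), length(cum))
          per * cum[n]
        }
        out[[length(out) + 1L]] <- data.frame(
          age = age, technique = tech, horizon = h,
          hospitalizations = val)
      }
    }
  }
  counts <- do.call(rbind, out)
  counts$rounded <- round(counts$hospitalizations)
  structure(list(counts = counts, per = per), class = "sbtox_scenario")
}

#' @export
print.sbtox_scenario <- function(x, ...) {
  cat("<sbtox_scenario> cumulative admissions per", x$per, "patients\n")
  wide <- stats::reshape(
    x$counts[c("age", "technique", "horizon", "rounded")],
    idvar = c("age", "technique"), timevar = "horizon",
    direction = "wide")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full base case with each parameter set to `dsa_low` (70%)
#' and `dsa_high` (130%) of its base value, everything else held at base,
#' and reports the incremental cost and QALY at both ends, per comparator,
#' sorted by spread.
#'
#' @inheritParams run_base_case
#' @param param_ids Parameter identifiers to vary (default: all).
#' @return Data frame with columns `comparator`, `outcome`, `param`,
#'   `low`, `high`, `base`, `spread`, sorted by decreasing `|spread|`
#'   within comparator and outcome.
#' @export
run_owsa <- function(ps, life_table, incidence, utilities,
                     param_ids = ps$table$id) {
  bad <- setdiff(param_ids, ps$table$id)
  if (length(bad)) stop("unknown parameter id(s): ",
                        paste(bad, collapse = ", "))
  base <- run_base_case(ps, life_table, incidence, utilities)$incremental
  rows <- list()
  for (id in param_ids) {
    ends <- lapply(c(ps$settings$dsa_low, ps$settings$dsa_high),
                   function(f) {
      run_base_case(perturb(ps, id, f), life_table, incidence,
                    utilities)$incremental
    })
    for (i in seq_len(nrow(base))) {
      for (oc in c("dcost_discounted", "dqaly_discounted")) {
        rows[[length(rows) + 1L]] <- data.frame(
          comparator = base$comparator[i],
          outcome = oc, param = id,
          low = ends[[1]][[oc]][i], high = ends[[2]][[oc]][i],
          base = base[[oc]][i],
          spread = abs(ends[[2]][[oc]][i] - ends[[1]][[oc]][i]))
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$comparator, out$outcome, -out$spread), ]
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Draws `n_draws` independent joint parameter samples from the assigned
#' distributions, re-runs the full model per draw, and summarizes the
#' incremental cost/QALY clouds (means, 2.5/97.5 percentiles, and the
#' share of draws in the dominant south-east quadrant: cheaper and more
#' effective).
#'
#' @inheritParams run_base_case
#' @param n_draws Number of Monte Carlo draws (default from settings).
#' @param seed Integer seed; the draw sequence is reproducible.
#' @param mode Sampling mode passed to [draw_parameter_set()].
#' @return Object of class `sbtox_psa`: `$draws` (one row per draw and
#'   comparator) and `$summary`.
#' @export
run_psa <- function(ps, life_table, incidence, utilities,
                    n_draws = ps$settings$psa_draws, seed = 1,
                    mode = ps$settings$psa_mode) {
  stopifnot(n_draws >= 1)
  mode <- match.arg(mode, c("calibrated", "verbatim", "degenerate"))
  set.seed(seed)
  draws <- list()
  for (i in seq_len(n_draws)) {
    psi <- draw_parameter_set(ps, mode = mode)
    inc <- .incrementals(.econ_by_technique(psi, life_table, incidence,
                                            utilities))
    inc$draw <- i
    draws[[i]] <- inc
  }
  draws <- do.call(rbind, draws)
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  summ <- do.call(rbind, lapply(split(draws, draws$comparator),
                                function(d) {
    data.frame(comparator = d$comparator[1],
               mean_dcost = mean(d$dcost_discounted),
               dcost_lo = qs(d$dcost_discounted)[1],
               dcost_hi = qs(d$dcost_discounted)[2],
               mean_dqaly = mean(d$dqaly_discounted),
               dqaly_lo = qs(d$dqaly_discounted)[1],
               dqaly_hi = qs(d$dqaly_discounted)[2],
               share_southeast = mean(d$dcost_discounted < 0 &
                                      d$dqaly_discounted > 0))
  }))
  structure(list(draws = draws, summary = summ, seed = seed, mode = mode),
            class = "sbtox_psa")
}

#' @export
print.sbtox_psa <- function(x, ...) {
  cat("<sbtox_psa>", max(x$draws$draw), "draws | seed", x$seed, "| mode",
      x$mode, "\n")
  print(x$summary, row.names = FALSE, digits = 5)
  invisible(x)
}
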