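# Valuation: converts a cohort trace into per-cycle cost streams (drugs,
# admissions, productivity losses from morbidity and premature mortality)
# and QALY streams, raw and discounted, and sums them into an economic
# result.

#' Discount factor at a point in time
#'
#' @param t_years Time from model entry, years (>= 0).
#' @param rate Annual discount rate (>= 0).
#' @return `(1 + rate)^(-t_years)`.
#' @export
discount_factor <- function(t_years, rate) {
  if (any(t_years < 0)) stop("t_years must be non-negative")
  if (rate < 0) stop("rate must be non-negative")
  (1 + rate)^(-t_years)
}

# Present value, at the moment of death, of one monetary unit per year over
# W remaining working years (continuous approximation).
.annuity <- function(W, rate) {
  W <- pmax(W, 0)
  if (rate == 0) return(W)
  (1 - (1 + rate)^(-W)) / log(1 + rate)
}

.cycle_times <- function(trace, settings) {
  k <- trace$flows$cycle
  half <- if (isTRUE(settings$half_cycle)) 0.5 else 0
  (k + half) * trace$cycle_length
}

#' Accrue per-cycle cost streams from a cohort trace
#'
#' Micro-costing by event flows: drug and admission costs are the collapsed
#' cycle-tree expectations per event; morbidity productivity cost is
#' sick-leave days times daily wage times the work-activity rate, restricted
#' to working age; mortality productivity cost values each small-bowel
#' toxicity death by the (human-capital) remaining earnings to retirement
#' age, discounted at the cost rate within the annuity.
#'
#' @param trace A single-age `cohort_trace` (its `age` column must be
#'   populated).
#' @param ps A `parameter_set`.
#' @param include_indirect Include productivity costs (default `TRUE`).
#' @return Data frame with one row per cycle: components `drugs`,
#'   `hospitalizations`, `productivity_morbidity`, `productivity_mortality`,
#'   their sum `total`, and discounted counterparts suffixed `_disc`.
#' @export
accrue_costs <- function(trace, ps, include_indirect = TRUE) {
  s <- ps$settings
  fl <- trace$flows
  if (anyNA(fl$age))
    stop("accrue_costs() needs a single-age trace with a populated age ",
         "column; value mixed cohorts per starting age instead")
  ph <- trace$context$pharma_out
  ho <- trace$context$hosp_out
  act <- param_value(ps, "activity_rate")
  wage_d <- param_value(ps, "wage_daily")
  wage_a <- param_value(ps, "wage_annual")
  working <- as.numeric(fl$age < s$retirement_age)
  drugs <- fl$pharma_events * ph$expected_cost_drug +
    fl$hosp_first * ho$expected_cost_drug +
    fl$recurrences * ho$expected_cost_drug
  hosp <- fl$pharma_events * ph$expected_cost_hosp +
    (fl$hosp_first + fl$recurrences) * ho$expected_cost_hosp
  sick_days <- fl$pharma_events * ph$expected_sick_days +
    (fl$hosp_first + fl$recurrences) * ho$expected_sick_days
  morb <- if (include_indirect) working * sick_days * wage_d * act
          else numeric(nrow(fl))
  W <- pmax(s$retirement_age - fl$age, 0)
  mort_raw <- if (include_indirect) fl$sb_deaths * wage_a * act * W
              else numeric(nrow(fl))
  mort_pv <- if (include_indirect)
    fl$sb_deaths * wage_a * act * .annuity(W, s$cost_discount)
  else numeric(nrow(fl))
  t <- .cycle_times(trace, s)
  df <- discount_factor(t, s$cost_discount)
  out <- data.frame(
    cycle = fl$cycle, t = t,
    drugs = drugs, hospitalizations = hosp,
    productivity_morbidity = morb, productivity_mortality = mort_raw,
    drugs_disc = drugs * df, hospitalizations_disc = hosp * df,
    productivity_morbidity_disc = morb * df,
    productivity_mortality_disc = mort_pv * df)
  out$total <- out$drugs + out$hospitalizations +
    out$productivity_morbidity + out$productivity_mortality
  out$total_disc <- out$drugs_disc + out$hospitalizations_disc +
    out$productivity_morbidity_disc + out$productivity_mortality_disc
  out
}

#' Accrue per-cycle QALY streams from a cohort trace
#'
#' Each half-year cycle contributes `0.5 * U(age)` per surviving patient;
#' patients transitioning through an event lose the pathway-specific
#' relative disutility for that one cycle (applied multiplicatively to the
#' baseline utility, for the surviving event flow). Dead states contribute
#' nothing.
#'
#' @param trace A single-age `cohort_trace`.
#' @param ps A `parameter_set`.
#' @param curve Utility curve data frame (`age`, `utility`) covering the
#'   ages reached by the cohort.
#' @return Data frame with per-cycle `qaly` and `qaly_disc`, plus the
#'   undiscounted life-years `ly` for reference.
#' @export
accrue_qalys <- function(trace, ps, curve) {
  s <- ps$settings
  fl <- trace$flows
  if (anyNA(fl$age))
    stop("accrue_qalys() needs a single-age trace")
  ph <- trace$context$pharma_out
  ho <- trace$context$hosp_out
  U <- utility_at(curve, fl$age)
  cl <- trace$cycle_length
  d_ph <- if (ph$dest_probs[["death_sb"]] < 1)
    ph$disutility_surviving / (1 - ph$death_prob) else 0
  d_ho <- ho$disutility_surviving / (1 - ho$death_prob)
  loss <- fl$pharma_surviving * d_ph +
    (fl$hosp_surviving + fl$recurrences * (1 - ho$death_prob)) * d_ho
  qaly <- cl * U * (fl$alive_end - loss)
  ly <- cl * fl$alive_end
  t <- .cycle_times(trace, s)
  data.frame(cycle = fl$cycle, t = t, ly = ly, qaly = qaly,
             qaly_disc = qaly * discount_factor(t, s$utility_discount))
}

#' Sum cost and QALY streams into an economic result
#'
#' @param costs Output of [accrue_costs()].
#' @param qalys Output of [accrue_qalys()].
#' @param technique Technique label carried into the result.
#' @return An object of class `econ_result` with discounted and
#'   undiscounted totals and a component breakdown.
#' @export
summarize_economics <- function(costs, qalys, technique = NA_character_) {
  stopifnot(nrow(costs) == nrow(qalys))
  comp <- c("drugs", "hospitalizations", "productivity_morbidity",
            "productivity_mortality")
  breakdown <- data.frame(
    component = comp,
    undiscounted = vapply(comp, function(c) sum(costs[[c]]), numeric(1)),
    discounted = vapply(comp, function(c) sum(costs[[paste0(c, "_disc")]]),
                        numeric(1)))
  structure(list(
    technique = technique,
    cost_discounted = sum(costs$total_disc),
    cost_undiscounted = sum(costs$total),
    qaly_discounted = sum(qalys$qaly_disc),
    qaly_undiscounted = sum(qalys$qaly),
    ly_undiscounted = sum(qalys$ly),
    breakdown = breakdown), class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat("<econ_result>", x$technique, "\n")
  cat(sprintf("  cost  discounted %10.2f | undiscounted %10.2f EUR\n",
              x$cost_discounted, x$cost_undiscounted))
  cat(sprintf("  QALY  discounted %10.4f | undiscounted %10.4f\n",
              x$qaly_discounted, x$qaly_undiscounted))
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Value a single-age cohort trace
#'
#' Convenience wrapper: [accrue_costs()] + [accrue_qalys()] +
#' [summarize_economics()].
#'
#' @inheritParams accrue_costs
#' @inheritParams accrue_qalys
#' @return An `econ_result`.
#' @export
value_cohort <- function(trace, ps, curve, include_indirect = TRUE) {
  summarize_economics(accrue_costs(trace, ps, include_indirect),
                      accrue_qalys(trace, ps, curve),
                      technique = trace$technique)
}

# weight-average a list of econ_results (all totals are linear in the trace)
.combine_econ <- function(results, weights, technique) {
  stopifnot(length(results) == length(weights))
  agg <- results[[1]]
  num <- c("cost_discounted", "cost_undiscounted", "qaly_discounted",
           "qaly_undiscounted", "ly_undiscounted")
  for (f in num) agg[[f]] <- sum(vapply(seq_along(results), function(j)
    results[[j]][[f]] * weights[j], numeric(1)))
  bk <- agg$breakdown
  for (col in c("undiscounted", "discounted")) {
    bk[[col]] <- Reduce(`+`, lapply(seq_along(results), function(j)
      results[[j]]$breakdown[[col]] * weights[j]))
  }
  agg$breakdown <- bk
  agg$technique <- technique
  agg
}
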