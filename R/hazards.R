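# Probability/rate transformations: rate <-> probability conversion on the
# constant-hazard assumption, NTCP-ratio scaling across radiotherapy
# techniques, and the post-plateau hazard decay schedule.

#' Convert a per-period probability to a constant yearly rate
#'
#' @param p Event probability over duration `t`, in `[0, 1)`.
#' @param t Duration in years over which `p` applies (> 0).
#' @return Rate per year, `-log(1 - p) / t`.
#' @export
prob_to_rate <- function(p, t) {
  stopifnot(t > 0)
  if (any(p < 0 | p >= 1))
    stop("probabilities must lie in [0, 1); p = 1 implies an infinite rate")
  -log(1 - p) / t
}

#' Convert a constant yearly rate to a per-period probability
#'
#' Inverse of [prob_to_rate()].
#'
#' @param r Rate per year (>= 0).
#' @param t Duration in years (> 0).
#' @return Probability `1 - exp(-r * t)`.
#' @export
rate_to_prob <- function(r, t) {
  stopifnot(t > 0)
  if (any(r < 0)) stop("rates must be non-negative")
  1 - exp(-r * t)
}

#' Scale grade-specific toxicity probabilities by an NTCP ratio
#'
#' Technique comparison works through the ratio of small-bowel NTCP values:
#' the reference technique's grade-specific half-yearly probabilities are
#' multiplied directly on the probability scale by
#' `ntcp_target / ntcp_ref`. Direct multiplicative scaling (rather than
#' scaling the underlying rates) is what reproduces the published
#' technique-specific transition probabilities to three decimals.
#'
#' @param p Numeric vector of probabilities on the unit scale.
#' @param ntcp_target NTCP fraction of the target technique.
#' @param ntcp_ref NTCP fraction of the reference technique.
#' @return Scaled probability vector.
#' @export
scale_by_ntcp <- function(p, ntcp_target, ntcp_ref) {
  stopifnot(ntcp_target > 0, ntcp_ref > 0)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  out <- p * (ntcp_target / ntcp_ref)
  if (any(out > 1))
    stop("NTCP scaling pushed a probability above 1; ratio = ",
         format(ntcp_target / ntcp_ref))
  out
}

#' Apply the post-plateau hazard decay to an event probability
#'
#' The toxicity hazard is held constant for the first `onset_years` after
#' treatment and thereafter declines by `annual_decline` in a stepwise
#' fashion for each whole elapsed year: the underlying rate is multiplied by
#' `(1 - annual_decline)^floor(years - onset)` and converted back to a
#' probability, so decay acts on the rate scale, not directly on the
#' probability.
#'
#' @param p0 Baseline per-cycle probability in `[0, 1)`.
#' @param years_since_treatment Non-negative time since treatment, years.
#' @param onset_years Plateau length in years (default 5).
#' @param annual_decline Fractional decline per year after the plateau
#'   (default 0.25).
#' @param cycle_length Cycle length in years (default 0.5).
#' @return Decayed per-cycle probability.
#' @export
decayed_probability <- function(p0, years_since_treatment,
                                onset_years = 5, annual_decline = 0.25,
                                cycle_length = 0.5) {
  stopifnot(years_since_treatment >= 0, onset_years >= 0,
            annual_decline >= 0, annual_decline < 1)
  if (any(p0 < 0 | p0 >= 1)) stop("p0 must lie in [0, 1)")
  w <- floor(max(0, years_since_treatment - onset_years))
  m <- (1 - annual_decline)^w
  # equivalent to rate_to_prob(m * prob_to_rate(p0, cycle_length), cycle_length)
  1 - (1 - p0)^m
}

#' Technique-specific half-yearly toxicity probabilities
#'
#' Combines the reference grade probabilities, the NTCP ratio for the
#' requested technique and the hazard decay schedule into the four
#' grade-specific per-cycle probabilities in force at a given time since
#' treatment.
#'
#' @param ps A `parameter_set`.
#' @param technique One of [sbtox_techniques()].
#' @param years_since_treatment Time since treatment, years (default 0).
#' @return Numeric vector of length 4 (grades 1-4), unit scale.
#' @export
grade_probabilities <- function(ps, technique, years_since_treatment = 0) {
  technique <- match.arg(technique, sbtox_techniques())
  base <- vapply(paste0("p_tox_grade", 1:4), function(id)
    param_value(ps, id), numeric(1))
  scaled <- scale_by_ntcp(base, ntcp(ps)[[technique]],
                          ps$settings$ntcp_reference)
  decayed_probability(scaled, years_since_treatment,
                      onset_years = ps$settings$decay_onset_years,
                      annual_decline = ps$settings$decay_per_year,
                      cycle_length = ps$settings$cycle_length_years)
}
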