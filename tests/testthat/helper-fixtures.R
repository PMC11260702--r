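# Shared fixtures, built in code at test time.

test_ps <- function(...) load_parameter_set(settings = list(...))

zero_lt <- function() make_life_table(makeham = 0, gompertz_a = 0)

# overwrite one printed base value in place (bypasses perturb's capping)
set_param <- function(ps, id, value) {
  i <- match(id, ps$table$id)
  stopifnot(!is.na(i))
  ps$table$base_value[i] <- value
  ps
}

# parameter set with all toxicity and recurrence risk switched off
zero_tox_ps <- function(...) {
  ps <- test_ps(...)
  for (id in c(paste0("p_tox_grade", 1:4),
               paste0("p_rec", rep(1:4, each = 2),
                      c("_surgery", "_supportive"))))
    ps <- set_param(ps, id, 0)
  ps
}

# a hand-built single-age cohort trace with prescribed event flows, for
# unit-testing the valuation layer in isolation
mk_trace <- function(ps, n_cycles, start_age = 40, technique = "3dcrt",
                     alive_end = 1) {
  flow_names <- c("ev_g1", "ev_g2", "ev_g3", "ev_g4", "pharma_events",
                  "hosp_first", "recurrences", "rec_resolved",
                  "hospitalizations", "sb_deaths", "other_deaths",
                  "pharma_surviving", "hosp_surviving", "alive_end")
  fl <- as.data.frame(matrix(0, n_cycles, length(flow_names),
                             dimnames = list(NULL, flow_names)))
  fl$alive_end <- alive_end
  fl <- cbind(cycle = seq_len(n_cycles) - 1L,
              age = start_age + (seq_len(n_cycles) - 1L) * 0.5, fl)
  structure(list(technique = technique, start_age = start_age,
                 cycle_length = ps$settings$cycle_length_years,
                 flows = fl,
                 context = list(
                   pharma_out = collapse_tree(build_pharma_tree(ps)),
                   hosp_out = collapse_tree(build_hospital_tree(ps)))),
            class = "cohort_trace")
}
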