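# Half-yearly Markov cohort engine. State space: a symptom-free
# post-treatment state; symptom-management states indexed by treatment
# pathway (pharmaceutical / supportive / surgical) and by number of prior
# recurrences (0-4); one-cycle tunnel states for recurrent events 1-4; and
# two absorbing death states (small-bowel toxicity, other causes).

.N_STATES <- 22L
.I_PT <- 1L
.I_DEATH_SB <- 21L
.I_DEATH_OTHER <- 22L
.PATHWAYS <- c("pharma", "supportive", "surgery")

.mgmt_idx <- function(pathway, level) {
  p <- match(pathway, .PATHWAYS)
  1L + (p - 1L) * 5L + level + 1L
}
.tunnel_idx <- function(level) 16L + level

#' The model's state space
#'
#' @return A data frame with one row per state: `name`, `type`
#'   (`post_treatment`, `management`, `tunnel`, `death`), `pathway` and
#'   recurrence `level` where applicable, in the fixed state order used by
#'   all occupancy matrices.
#' @export
state_space <- function() {
  rows <- list(data.frame(name = "post_treatment", type = "post_treatment",
                          pathway = NA, level = NA))
  for (p in .PATHWAYS) {
    for (v in 0:4) {
      rows <- c(rows, list(data.frame(
        name = sprintf("mgmt_%s_%d", p, v), type = "management",
        pathway = p, level = v)))
    }
  }
  for (v in 1:4) {
    rows <- c(rows, list(data.frame(
      name = sprintf("recurrent_%d", v), type = "tunnel",
      pathway = NA, level = v)))
  }
  rows <- c(rows, list(
    data.frame(name = "death_sb", type = "death", pathway = NA, level = NA),
    data.frame(name = "death_other", type = "death", pathway = NA,
               level = NA)))
  do.call(rbind, rows)
}

.check_life_table <- function(life_table) {
  stopifnot(is.data.frame(life_table),
            all(c("age", "qx") %in% names(life_table)))
  if (!all(0:100 %in% life_table$age))
    stop("life table must cover ages 0-100")
  if (any(life_table$qx < 0 | life_table$qx > 1))
    stop("life-table qx values must lie in [0, 1]")
  q <- life_table$qx[match(0:100, life_table$age)]
  names(q) <- 0:100
  q
}

# Pre-extract everything the per-cycle update needs.
.model_context <- function(ps, technique, life_table) {
  technique <- match.arg(technique, sbtox_techniques())
  s <- ps$settings
  base <- vapply(paste0("p_tox_grade", 1:4), function(id)
    param_value(ps, id), numeric(1))
  grades0 <- scale_by_ntcp(base, ntcp(ps)[[technique]], s$ntcp_reference)
  rec <- matrix(0, nrow = 4, ncol = 3,
                dimnames = list(NULL, .PATHWAYS))
  for (lev in 1:4) {
    rec[lev, "surgery"] <- param_value(ps, sprintf("p_rec%d_surgery", lev))
    rec[lev, "supportive"] <-
      param_value(ps, sprintf("p_rec%d_supportive", lev))
  }
  rec[, "pharma"] <- rec[, s$pharma_recurrence_source]
  pharma_out <- collapse_tree(build_pharma_tree(ps))
  hosp_out <- collapse_tree(build_hospital_tree(ps))
  list(technique = technique, settings = s, grades0 = grades0, rec = rec,
       pharma_out = pharma_out, hosp_out = hosp_out,
       q_annual = .check_life_table(life_table))
}

.decay_multiplier <- function(s, years) {
  (1 - s$decay_per_year)^floor(max(0, years - s$decay_onset_years))
}

# Per-cycle probability pieces: half-yearly background mortality and the
# decayed grade probabilities at the start of cycle `k` (0-based).
.cycle_pieces <- function(ctx, cycle_index, age) {
  s <- ctx$settings
  a <- floor(age)
  if (a < 0 || a > 100) stop("age ", age, " outside the life table")
  qh <- 1 - (1 - ctx$q_annual[[as.character(min(a, 100L))]])^
    s$cycle_length_years
  m <- .decay_multiplier(s, cycle_index * s$cycle_length_years)
  gk <- 1 - (1 - ctx$grades0)^m
  rec <- ctx$rec
  if (isTRUE(s$decay_on_recurrence)) rec <- 1 - (1 - rec)^m
  list(qh = qh, gk = gk, rec = rec)
}

.dest_to_idx <- function(dest_probs, level) {
  v <- numeric(.N_STATES)
  v[.mgmt_idx("pharma", level)] <- dest_probs[["mgmt_pharma"]]
  v[.mgmt_idx("supportive", level)] <- dest_probs[["mgmt_supportive"]]
  v[.mgmt_idx("surgery", level)] <- dest_probs[["mgmt_surgery"]]
  v[.I_DEATH_SB] <- dest_probs[["death_sb"]]
  v
}

.transition_matrix <- function(ctx, cycle_index, age) {
  pc <- .cycle_pieces(ctx, cycle_index, age)
  qh <- pc$qh
  g12 <- pc$gk[1] + pc$gk[2]
  g34 <- pc$gk[3] + pc$gk[4]
  if (1 - g12 - g34 < 0)
    stop("negative residual self-probability in post-treatment row; ",
         "event probabilities sum above 1")
  tm <- matrix(0, .N_STATES, .N_STATES,
               dimnames = list(state_space()$name, state_space()$name))
  surv <- 1 - qh
  # post-treatment: background death first, events among survivors
  pt_row <- surv * (g12 * .dest_to_idx(ctx$pharma_out$dest_probs, 0L) +
                    g34 * .dest_to_idx(ctx$hosp_out$dest_probs, 0L))
  pt_row[.I_PT] <- surv * (1 - g12 - g34)
  pt_row[.I_DEATH_OTHER] <- qh
  tm[.I_PT, ] <- pt_row
  # management states: recurrence risk by pathway and level
  for (p in .PATHWAYS) {
    for (v in 0:4) {
      i <- .mgmt_idx(p, v)
      nxt <- min(v + 1L, 4L)
      r <- pc$rec[nxt, p]
      tm[i, i] <- surv * (1 - r)
      tm[i, .tunnel_idx(nxt)] <- surv * r
      tm[i, .I_DEATH_OTHER] <- qh
    }
  }
  # tunnel states resolve through the hospitalization tree
  for (v in 1:4) {
    i <- .tunnel_idx(v)
    row <- surv * .dest_to_idx(ctx$hosp_out$dest_probs, v)
    row[.I_DEATH_OTHER] <- qh
    tm[i, ] <- row
  }
  tm[.I_DEATH_SB, .I_DEATH_SB] <- 1
  tm[.I_DEATH_OTHER, .I_DEATH_OTHER] <- 1
  tm
}

#' Build the one-cycle transition matrix
#'
#' Rows and columns follow [state_space()]. Background mortality (annual
#' life-table probability converted to the half-year by
#' `1 - (1 - q)^0.5`) is applied first; toxicity dynamics apply to
#' survivors. First events leave the post-treatment state permanently and
#' resolve through the collapsed cycle trees; management states carry
#' pathway- and level-specific recurrence risk into one-cycle tunnel states;
#' tunnels resolve through the hospitalization tree.
#'
#' @param ps A `parameter_set`.
#' @param technique One of [sbtox_techniques()].
#' @param cycle_index 0-based cycle number (drives the decay clock).
#' @param age Cohort age at the start of the cycle.
#' @param life_table Data frame with columns `age` (0-100) and `qx`.
#' @return A 22 x 22 row-stochastic matrix.
#' @export
build_transition_matrix <- function(ps, technique, cycle_index, age,
                                    life_table) {
  ctx <- .model_context(ps, technique, life_table)
  .transition_matrix(ctx, cycle_index, age)
}

#' Run the cohort model for a single starting age
#'
#' Iterates cohort occupancy from full mass in the post-treatment state over
#' half-yearly cycles until `horizon_age`, recording per-cycle occupancy and
#' event flows (first events by grade, recurrences, admissions, deaths).
#' Deterministic: no sampling is involved.
#'
#' @param ps A `parameter_set`.
#' @param technique One of [sbtox_techniques()].
#' @param start_age Age at model entry, in `[25, 99]`.
#' @param life_table Data frame with columns `age` (0-100) and `qx`.
#' @param horizon_age Age at which the model stops (default from settings).
#' @return An object of class `cohort_trace`: `occupancy` (one row per
#'   cycle boundary), `flows` (one row per cycle) and run metadata.
#' @export
run_cohort <- function(ps, technique, start_age, life_table,
                       horizon_age = ps$settings$horizon_age) {
  if (start_age < 25 || start_age > 99)
    stop("start_age must lie in [25, 99]")
  if (horizon_age <= start_age)
    stop("horizon_age must exceed start_age")
  ctx <- .model_context(ps, technique, life_table)
  s <- ctx$settings
  cl <- s$cycle_length_years
  n_cycles <- ceiling((horizon_age - start_age) / cl)
  occ <- matrix(0, n_cycles + 1L, .N_STATES,
                dimnames = list(NULL, state_space()$name))
  occ[1L, .I_PT] <- 1
  flow_names <- c("ev_g1", "ev_g2", "ev_g3", "ev_g4", "pharma_events",
                  "hosp_first", "recurrences", "rec_resolved",
                  "hospitalizations", "sb_deaths", "other_deaths",
                  "pharma_surviving", "hosp_surviving", "alive_end")
  fl <- matrix(0, n_cycles, length(flow_names),
               dimnames = list(NULL, flow_names))
  mgmt_i <- as.integer(mapply(.mgmt_idx, rep(.PATHWAYS, each = 5),
                              rep(0:4, 3)))
  nxt_lev <- pmin(rep(0:4, 3) + 1L, 4L)
  mgmt_pathway <- rep(.PATHWAYS, each = 5)
  tun_i <- .tunnel_idx(1:4)
  ph <- ctx$pharma_out
  ho <- ctx$hosp_out
  for (k in seq_len(n_cycles) - 1L) {
    age <- start_age + k * cl
    pc <- .cycle_pieces(ctx, k, age)
    qh <- pc$qh
    s_now <- occ[k + 1L, ]
    alive <- s_now[1:20]
    od <- sum(alive) * qh
    sv <- alive * (1 - qh)
    new <- numeric(.N_STATES)
    # first events out of post-treatment
    g12 <- pc$gk[1] + pc$gk[2]
    g34 <- pc$gk[3] + pc$gk[4]
    if (1 - g12 - g34 < 0)
      stop("event probabilities sum above 1 at cycle ", k)
    pt <- sv[.I_PT]
    ev12 <- pt * g12
    ev34 <- pt * g34
    new[.I_PT] <- pt * (1 - g12 - g34)
    new <- new + ev12 * .dest_to_idx(ph$dest_probs, 0L) +
      ev34 * .dest_to_idx(ho$dest_probs, 0L)
    # management -> tunnels
    rvec <- pc$rec[cbind(nxt_lev, match(mgmt_pathway, .PATHWAYS))]
    m_occ <- sv[mgmt_i]
    new[mgmt_i] <- new[mgmt_i] + m_occ * (1 - rvec)
    rec_flow <- m_occ * rvec
    for (lev in 1:4) {
      new[tun_i[lev]] <- sum(rec_flow[nxt_lev == lev])
    }
    # tunnel resolution (recurrence that occurred last cycle)
    t_occ <- sv[tun_i]
    for (lev in 1:4) {
      new <- new + t_occ[lev] * .dest_to_idx(ho$dest_probs, lev)
    }
    sb_first <- ev12 * ph$death_prob + ev34 * ho$death_prob
    sb_tunnel <- sum(t_occ) * ho$death_prob
    new[.I_DEATH_SB] <- new[.I_DEATH_SB] + s_now[.I_DEATH_SB]
    new[.I_DEATH_OTHER] <- s_now[.I_DEATH_OTHER] + od
    occ[k + 2L, ] <- new
    recs <- sum(rec_flow)
    fl[k + 1L, ] <- c(
      pt * pc$gk, ev12, ev34, recs, sum(t_occ),
      ev12 * ph$expected_hospitalizations +
        ev34 * ho$expected_hospitalizations + recs,
      sb_first + sb_tunnel, od,
      ev12 * (1 - ph$death_prob), ev34 * (1 - ho$death_prob),
      sum(new[1:20]))
  }
  flows <- as.data.frame(fl)
  flows <- cbind(cycle = seq_len(n_cycles) - 1L,
                 age = start_age + (seq_len(n_cycles) - 1L) * cl, flows)
  structure(list(technique = ctx$technique, start_age = start_age,
                 horizon_age = horizon_age, cycle_length = cl,
                 states = state_space(), occupancy = occ, flows = flows,
                 context = ctx),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$flows)
  cat("<cohort_trace>", x$technique, "| start age", x$start_age, "|",
      n, "half-year cycles\n")
  last <- x$occupancy[n + 1L, ]
  cat(sprintf("  final: alive %.4f, SB deaths %.4f, other deaths %.4f\n",
              sum(last[1:20]), last[.I_DEATH_SB], last[.I_DEATH_OTHER]))
  cat(sprintf("  cumulative admissions per patient: %.4f\n",
              sum(x$flows$hospitalizations)))
  invisible(x)
}

#' Run an age-mixed cohort
#'
#' Runs [run_cohort()] for every starting age in the incidence mix and
#' returns the weight-averaged occupancy and flows. Shorter runs (older
#' cohorts reaching the horizon age earlier) are padded with their frozen
#' final occupancy and zero flows before averaging.
#'
#' @param ps A `parameter_set`.
#' @param technique One of [sbtox_techniques()].
#' @param incidence Data frame with columns `age` and `weight`; weights must
#'   be non-negative and sum to 1 within 1e-9.
#' @param life_table Data frame with columns `age` (0-100) and `qx`.
#' @return A `cohort_trace` whose occupancy and flows are weight-averaged;
#'   individual runs are kept in `$by_age`.
#' @export
run_mixed_cohort <- function(ps, technique, incidence, life_table) {
  stopifnot(is.data.frame(incidence),
            all(c("age", "weight") %in% names(incidence)))
  w <- incidence$weight
  if (any(w < 0)) stop("incidence weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9)
    stop("incidence weights must sum to 1 (got ",
         format(sum(w), digits = 10), ")")
  keep <- w > 0
  ages <- incidence$age[keep]
  w <- w[keep]
  runs <- lapply(ages, function(a)
    run_cohort(ps, technique, a, life_table))
  n_max <- max(vapply(runs, function(r) nrow(r$flows), integer(1)))
  occ <- matrix(0, n_max + 1L, .N_STATES,
                dimnames = dimnames(runs[[1]]$occupancy))
  flow_cols <- setdiff(names(runs[[1]]$flows), c("cycle", "age"))
  fl <- matrix(0, n_max, length(flow_cols),
               dimnames = list(NULL, flow_cols))
  for (j in seq_along(runs)) {
    r <- runs[[j]]
    n <- nrow(r$flows)
    o <- r$occupancy
    if (n < n_max) {
      o <- rbind(o, matrix(rep(o[n + 1L, ], n_max - n),
                           ncol = .N_STATES, byrow = TRUE))
    }
    occ <- occ + w[j] * o
    f <- as.matrix(r$flows[flow_cols])
    fl[seq_len(n), ] <- fl[seq_len(n), ] + w[j] * f
  }
  flows <- as.data.frame(fl)
  flows <- cbind(cycle = seq_len(n_max) - 1L,
                 age = NA_real_, flows)
  structure(list(technique = match.arg(technique, sbtox_techniques()),
                 start_age = stats::weighted.mean(ages, w),
                 horizon_age = ps$settings$horizon_age,
                 cycle_length = ps$settings$cycle_length_years,
                 states = state_space(), occupancy = occ, flows = flows,
                 weights = stats::setNames(w, ages), by_age = runs),
            class = "cohort_trace")
}
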