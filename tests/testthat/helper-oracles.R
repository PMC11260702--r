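# Independent oracles: a Monte-Carlo random walk through a cycle tree and
# an individual-level microsimulation of the cohort model. Both re-derive
# their probabilities from the parameter table directly and share no code
# with collapse_tree() or run_cohort().

# Random walks through a tree by recursive multinomial splitting: payloads
# are accumulated along each sampled path. Returns per-terminal-path counts
# and path payloads, from which means and Monte-Carlo SEs follow.
walk_tree <- function(tree, n_walks, seed) {
  set.seed(seed)
  acc0 <- list(cost = 0, sick = 0, disutility = 0, hosp = 0)
  rec <- function(node, n, acc) {
    pl <- node$payload
    acc$cost <- acc$cost + pl$cost_drug + pl$cost_hosp
    acc$sick <- acc$sick + pl$sick_days
    acc$disutility <- acc$disutility + pl$disutility
    acc$hosp <- acc$hosp + pl$hospitalization
    if (node$type == "terminal")
      return(list(list(n = n, dest = node$dest, acc = acc)))
    if (n == 0) return(list())
    probs <- vapply(node$branches, `[[`, numeric(1), "prob")
    counts <- as.vector(stats::rmultinom(1, n, probs))
    out <- list()
    for (i in seq_along(node$branches))
      out <- c(out, rec(node$branches[[i]]$node, counts[i], acc))
    out
  }
  paths <- rec(tree, n_walks, acc0)
  n <- vapply(paths, `[[`, numeric(1), "n")
  list(n_walks = n_walks, n = n,
       dest = vapply(paths, `[[`, character(1), "dest"),
       cost = vapply(paths, function(p) p$acc$cost, numeric(1)),
       death = as.numeric(vapply(paths, `[[`, character(1),
                                 "dest") == "death_sb"))
}

walk_mean_se <- function(w, values) {
  m <- sum(w$n * values) / w$n_walks
  v <- sum(w$n * (values - m)^2) / w$n_walks
  list(mean = m, se = sqrt(v / w$n_walks))
}

# Individual-level microsimulation. State coding matches state_space():
# 1 post-treatment; 2-16 management (pharma/supportive/surgery x level
# 0-4); 17-20 recurrent-event tunnels; 21 SB death; 22 other death.
# Probabilities are recomputed here from the parameter table.
microsim_occupancy <- function(ps, technique, start_age, life_table,
                               n_patients, n_cycles, seed) {
  set.seed(seed)
  pv <- function(id) {
    i <- match(id, ps$table$id)
    r <- ps$table[i, ]
    if (r$unit == "%") r$base_value / 100 else r$base_value
  }
  ntcps <- c(imrt_igrt = pv("ntcp_imrt_igrt"), imrt = pv("ntcp_imrt"),
             `3dcrt` = pv("ntcp_3dcrt"))
  g0 <- vapply(paste0("p_tox_grade", 1:4), pv, numeric(1)) *
    ntcps[[technique]] / 0.180
  p_surg <- pv("p_surgery")
  p_surg_death <- pv("p_surgery_death")
  p_sup_death <- pv("p_supportive_death")
  # recurrence probability and destination tunnel for each management state
  rec_p <- numeric(22)
  tun_target <- integer(22)
  for (p_i in 1:3) {          # 1 pharma, 2 supportive, 3 surgery
    for (lev in 0:4) {
      st <- 1 + (p_i - 1) * 5 + lev + 1
      nxt <- min(lev + 1, 4)
      src <- if (p_i == 3) "surgery" else "supportive"  # pharma proxy
      rec_p[st] <- pv(sprintf("p_rec%d_%s", nxt, src))
      tun_target[st] <- 16 + nxt
    }
  }
  qx <- life_table$qx[match(0:100, life_table$age)]
  state <- rep(1L, n_patients)
  occ <- matrix(0, n_cycles + 1, 22)
  occ[1, 1] <- 1
  for (k in 0:(n_cycles - 1)) {
    age <- start_age + k * 0.5
    qh <- 1 - (1 - qx[floor(age) + 1])^0.5
    m <- 0.75^floor(max(0, k * 0.5 - 5))
    gk <- 1 - (1 - g0)^m
    old <- state
    alive <- old <= 20
    # background death first
    dies <- alive & stats::runif(n_patients) < qh
    state[dies] <- 22L
    live <- alive & !dies
    # first events out of post-treatment
    in_pt <- live & old == 1L
    u <- stats::runif(n_patients)
    grade <- findInterval(u, cumsum(gk)) + 1L   # 5 = no event
    ev <- in_pt & grade <= 4
    state[ev & grade <= 2] <- 2L                # mgmt_pharma_0
    h <- which(ev & grade >= 3)
    if (length(h)) {
      surg <- stats::runif(length(h)) < p_surg
      die <- ifelse(surg, stats::runif(length(h)) < p_surg_death,
                    stats::runif(length(h)) < p_sup_death)
      state[h] <- ifelse(die, 21L, ifelse(surg, 12L, 7L))
    }
    # recurrences out of management
    in_m <- live & old >= 2L & old <= 16L
    r <- stats::runif(n_patients)
    recur <- in_m & r < rec_p[old]
    state[recur] <- tun_target[old[recur]]
    # tunnel resolution through the hospitalization pathway
    tn <- which(live & old >= 17L & old <= 20L)
    if (length(tn)) {
      lev <- old[tn] - 16L
      surg <- stats::runif(length(tn)) < p_surg
      die <- ifelse(surg, stats::runif(length(tn)) < p_surg_death,
                    stats::runif(length(tn)) < p_sup_death)
      state[tn] <- ifelse(die, 21L,
                          ifelse(surg, 11L + lev + 1L, 6L + lev + 1L))
    }
    occ[k + 2, ] <- tabulate(state, 22) / n_patients
  }
  occ
}
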