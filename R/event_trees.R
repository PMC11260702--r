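# Markov cycle trees: within-cycle treatment pathways triggered by a first
# or recurrent small-bowel toxicity event. A tree is a nesting of chance
# nodes (branch probabilities) and terminal nodes (destination states);
# every node may carry incremental one-time payloads (drug cost,
# hospitalization cost, sick-leave days, disutility exposure,
# hospitalization count) that accumulate along the path.

.tree_dests <- c("mgmt_pharma", "mgmt_supportive", "mgmt_surgery", "death_sb")

.payload <- function(cost_drug = 0, cost_hosp = 0, sick_days = 0,
                     disutility = 0, hospitalization = 0) {
  list(cost_drug = cost_drug, cost_hosp = cost_hosp, sick_days = sick_days,
       disutility = disutility, hospitalization = hospitalization)
}

#' @rdname build_pharma_tree
#' @param name Node label used in error messages and outlines.
#' @param branches List of branches created by [tree_branch()].
#' @param payload Incremental payload from [tree_payload()].
#' @export
chance_node <- function(name, branches, payload = tree_payload()) {
  structure(list(type = "chance", name = name, branches = branches,
                 payload = payload), class = "event_tree_node")
}

#' @rdname build_pharma_tree
#' @param prob Branch probability (may be an expression already resolved to a
#'   number).
#' @param node Child node.
#' @param label Optional branch label.
#' @export
tree_branch <- function(prob, node, label = NULL) {
  list(prob = prob, node = node, label = label)
}

#' @rdname build_pharma_tree
#' @param dest Destination state: one of `"mgmt_pharma"`,
#'   `"mgmt_supportive"`, `"mgmt_surgery"`, `"death_sb"`.
#' @export
terminal_node <- function(dest, payload = tree_payload()) {
  dest <- match.arg(dest, .tree_dests)
  structure(list(type = "terminal", dest = dest, payload = payload),
            class = "event_tree_node")
}

#' @rdname build_pharma_tree
#' @param cost_drug,cost_hosp One-time drug / hospitalization cost, EUR.
#' @param sick_days Sick-leave days.
#' @param disutility Fraction of one cycle's utility lost (>= 0).
#' @param hospitalization Admission count contributed by this node.
#' @export
tree_payload <- function(cost_drug = 0, cost_hosp = 0, sick_days = 0,
                         disutility = 0, hospitalization = 0) {
  .payload(cost_drug, cost_hosp, sick_days, disutility, hospitalization)
}

.course_cost <- function(ps, drug) {
  s <- ps$settings
  unit <- param_value(ps, paste0("cost_", drug, "_unit"))
  unit * s$units_per_day[[drug]] * s$course_days
}

#' Build the pharmaceutical-management cycle tree
#'
#' First-line loperamide controls symptoms in most patients; failures split
#' between antibiotics and bile acid sequestrants. Regardless of second-line
#' success, grade 1-2 events resolve to symptom management within the cycle
#' (recovery is assumed; escalation happens only through later recurrence),
#' unless the `pharma_failure_escalates` setting routes persistent failures
#' through the hospitalization tree instead. Drug costs follow the
#' configured course (days times daily dose times unit cost); every event
#' carries the per-event sick leave, entry into management adds the
#' management sick leave, and the pharmaceutical relative disutility applies
#' for one cycle.
#'
#' @param ps A `parameter_set`.
#' @return An `event_tree_node` (the tree root).
#' @export
build_pharma_tree <- function(ps) {
  p_lop <- param_value(ps, "p_loperamide_success")
  p_ab <- param_value(ps, "p_second_line_ab")
  p_ab_ok <- param_value(ps, "p_ab_success")
  p_bas_ok <- param_value(ps, "p_bas_success")
  d <- abs(param_value(ps, "disutility_pharma"))
  sick_ev <- param_value(ps, "sickdays_event")
  sick_mgmt <- param_value(ps, "sickdays_management")
  managed <- function(extra_cost = 0)
    terminal_node("mgmt_pharma",
                  tree_payload(cost_drug = extra_cost, sick_days = sick_mgmt))
  unresolved <- function(extra_cost = 0) {
    if (isTRUE(ps$settings$pharma_failure_escalates)) {
      esc <- build_hospital_tree(ps)
      esc$payload$cost_drug <- esc$payload$cost_drug + extra_cost
      esc
    } else managed(extra_cost)
  }
  second_line <- chance_node("second_line", list(
    tree_branch(p_ab, chance_node("antibiotics", list(
      tree_branch(p_ab_ok, managed(), "ab_success"),
      tree_branch(1 - p_ab_ok, unresolved(), "ab_failure")),
      tree_payload(cost_drug = .course_cost(ps, "ab"))), "ab"),
    tree_branch(1 - p_ab, chance_node("bile_acid_sequestrant", list(
      tree_branch(p_bas_ok, managed(), "bas_success"),
      tree_branch(1 - p_bas_ok, unresolved(), "bas_failure")),
      tree_payload(cost_drug = .course_cost(ps, "bas"))), "bas")))
  chance_node("loperamide", list(
    tree_branch(p_lop, managed(), "loperamide_success"),
    tree_branch(1 - p_lop, second_line, "loperamide_failure")),
    tree_payload(cost_drug = .course_cost(ps, "loperamide"),
                 sick_days = sick_ev, disutility = d))
}

#' Build the hospitalization cycle tree
#'
#' Grade 3-4 events and all recurrent events lead to admission, split
#' between surgery and supportive (non-operative) treatment, each with its
#' own unit cost, relative disutility and case fatality; survivors enter the
#' corresponding symptom-management state. Event sick leave is inflated by
#' the additional-sick-leave factor for hospitalized patients.
#'
#' @param ps A `parameter_set`.
#' @return An `event_tree_node` (the tree root).
#' @export
build_hospital_tree <- function(ps) {
  p_surg <- param_value(ps, "p_surgery")
  p_surg_death <- param_value(ps, "p_surgery_death")
  p_sup_death <- param_value(ps, "p_supportive_death")
  d_surg <- abs(param_value(ps, "disutility_surgery"))
  d_sup <- abs(param_value(ps, "disutility_supportive"))
  sick_ev <- param_value(ps, "sickdays_event") *
    (1 + param_value(ps, "sickleave_hosp_factor"))
  sick_mgmt <- param_value(ps, "sickdays_management")
  chance_node("hospitalization", list(
    tree_branch(p_surg, chance_node("surgery", list(
      tree_branch(p_surg_death, terminal_node("death_sb"), "surgery_death"),
      tree_branch(1 - p_surg_death,
                  terminal_node("mgmt_surgery",
                                tree_payload(sick_days = sick_mgmt)),
                  "surgery_survival")),
      tree_payload(cost_hosp = param_value(ps, "cost_hosp_surgery"),
                   disutility = d_surg)), "surgery"),
    tree_branch(1 - p_surg, chance_node("supportive", list(
      tree_branch(p_sup_death, terminal_node("death_sb"), "supportive_death"),
      tree_branch(1 - p_sup_death,
                  terminal_node("mgmt_supportive",
                                tree_payload(sick_days = sick_mgmt)),
                  "supportive_survival")),
      tree_payload(cost_hosp = param_value(ps, "cost_hosp_supportive"),
                   disutility = d_sup)), "supportive")),
    tree_payload(sick_days = sick_ev, hospitalization = 1))
}

.enumerate_paths <- function(node, prob = 1, acc = .payload(),
                             label = character(0)) {
  pl <- node$payload
  acc <- Map(`+`, acc, pl)
  if (node$type == "terminal") {
    return(list(list(prob = prob, dest = node$dest, payload = acc,
                     label = paste(label, collapse = "/"))))
  }
  probs <- vapply(node$branches, function(b) b$prob, numeric(1))
  if (any(probs < 0 | probs > 1))
    stop("chance node '", node$name, "' has a branch probability outside ",
         "[0, 1]")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("chance node '", node$name, "' is not normalized: branch ",
         "probabilities sum to ", format(sum(probs), digits = 12))
  out <- list()
  for (b in node$branches) {
    lab <- if (is.null(b$label)) node$name else b$label
    out <- c(out, .enumerate_paths(b$node, prob * b$prob, acc,
                                   c(label, lab)))
  }
  out
}

#' Collapse a cycle tree to its expected pathway outcome
#'
#' Exact expectation by path enumeration: branch probabilities are
#' multiplied along each root-to-terminal path, payloads are summed along
#' the path, and path outcomes are combined weighted by path probability.
#' No sampling is involved.
#'
#' @param tree An `event_tree_node` built by [build_pharma_tree()] or
#'   [build_hospital_tree()].
#' @return An object of class `pathway_outcome`: destination-state
#'   probabilities, death probability, expected one-time costs (drug and
#'   hospitalization components), expected sick-leave days, expected
#'   disutility weight (all paths, and conditional on surviving paths),
#'   expected admissions, and a per-path detail table.
#' @export
collapse_tree <- function(tree) {
  paths <- .enumerate_paths(tree)
  probs <- vapply(paths, `[[`, numeric(1), "prob")
  dests <- vapply(paths, `[[`, character(1), "dest")
  get <- function(f) vapply(paths, function(p) p$payload[[f]], numeric(1))
  dest_probs <- vapply(.tree_dests, function(d) sum(probs[dests == d]),
                       numeric(1))
  surviving <- dests != "death_sb"
  disut <- get("disutility")
  out <- structure(list(
    dest_probs = dest_probs,
    death_prob = dest_probs[["death_sb"]],
    expected_cost = sum(probs * (get("cost_drug") + get("cost_hosp"))),
    expected_cost_drug = sum(probs * get("cost_drug")),
    expected_cost_hosp = sum(probs * get("cost_hosp")),
    expected_sick_days = sum(probs * get("sick_days")),
    expected_disutility_weight = sum(probs * disut),
    disutility_surviving = sum(probs[surviving] * disut[surviving]),
    expected_hospitalizations = sum(probs * get("hospitalization")),
    paths = data.frame(
      label = vapply(paths, `[[`, character(1), "label"),
      prob = probs, dest = dests,
      cost_drug = get("cost_drug"), cost_hosp = get("cost_hosp"),
      sick_days = get("sick_days"), disutility = disut,
      hospitalization = get("hospitalization"))),
    class = "pathway_outcome")
  stopifnot(abs(sum(out$dest_probs) - 1) < 1e-9)
  out
}

#' @export
print.pathway_outcome <- function(x, ...) {
  cat("<pathway_outcome>\n")
  cat(sprintf("  death probability    %.6f\n", x$death_prob))
  cat(sprintf("  expected cost        %.2f EUR (drugs %.2f, hosp %.2f)\n",
              x$expected_cost, x$expected_cost_drug, x$expected_cost_hosp))
  cat(sprintf("  expected sick days   %.3f\n", x$expected_sick_days))
  cat(sprintf("  expected disutility  %.4f\n", x$expected_disutility_weight))
  cat(sprintf("  expected admissions  %.3f\n", x$expected_hospitalizations))
  invisible(x)
}

#' Render a cycle tree as an indented text outline
#'
#' Debug export: each node on one line with its resolved branch probability
#' and non-zero payload entries.
#'
#' @param tree An `event_tree_node`.
#' @param prob Probability of the branch leading to `tree` (internal).
#' @param indent Indentation level (internal).
#' @return Character vector of lines, invisibly; printed as a side effect.
#' @export
tree_outline <- function(tree, prob = NA, indent = 0) {
  pad <- strrep("  ", indent)
  pl <- tree$payload
  extras <- pl[vapply(pl, function(v) v != 0, logical(1))]
  extra_txt <- if (length(extras))
    paste0(" [", paste(sprintf("%s=%.4g", names(extras),
                               unlist(extras)), collapse = ", "), "]")
  else ""
  head <- if (tree$type == "terminal")
    paste0(pad, "-> ", tree$dest) else paste0(pad, tree$name)
  if (!is.na(prob)) head <- paste0(head, sprintf(" (p=%.5f)", prob))
  lines <- paste0(head, extra_txt)
  if (tree$type == "chance") {
    for (b in tree$branches) {
      lines <- c(lines, tree_outline(b$node, b$prob, indent + 1))
    }
  }
  if (indent == 0) cat(lines, sep = "\n")
  invisible(lines)
}
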