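# 1:1 matching of treated subjects to distinct controls on the propensity
# score: exact optimal (minimum total distance) assignment, greedy
# nearest-neighbour, and tiered variants, with caliper / exact-stratum /
# common-support options.

#' Matching specification
#'
#' @param method `"optimal"` (exact minimum-cost 1:1 assignment) or
#'   `"nearest"` (greedy without replacement).
#' @param distance_scale distance measured on the `"logit"` (linear
#'   predictor, the standard recommendation) or `"probability"` scale.
#' @param caliper_sd optional caliper width as a positive multiple of the
#'   pooled SD of the logit scores; pairs farther apart are inadmissible.
#' @param exact_vars optional categorical columns on which pairs must agree
#'   exactly (matching is solved independently within each stratum).
#' @param common_support if `TRUE`, treated subjects whose logit lies
#'   outside the control group's logit range are discarded before matching.
#' @param discard_unmatchable if `TRUE`, treated subjects with no admissible
#'   control are discarded (with a reason) instead of raising an error.
#' @param tie_break ties are broken lexicographically by subject id
#'   (currently the only policy).
#' @return a `match_spec` list.
#' @export
match_spec <- function(method = c("optimal", "nearest"),
                       distance_scale = c("logit", "probability"),
                       caliper_sd = NULL, exact_vars = NULL,
                       common_support = FALSE,
                       discard_unmatchable = FALSE,
                       tie_break = "subject_id") {
  method <- match.arg(method)
  distance_scale <- match.arg(distance_scale)
  if (!is.null(caliper_sd) && (!is_scalar_number(caliper_sd) || caliper_sd <= 0))
    qc_stop("qcmatch_config_error", "caliper_sd must be a positive number")
  structure(list(method = method, distance_scale = distance_scale,
                 caliper_sd = caliper_sd, exact_vars = exact_vars,
                 common_support = common_support,
                 discard_unmatchable = discard_unmatchable,
                 tie_break = tie_break),
            class = "match_spec")
}

# Internal: shared preparation of a matching problem.
match_problem <- function(scores, groups, spec, table = NULL) {
  if (!nrow(scores)) qc_stop("qcmatch_validation_error", "empty scores")
  if (is.null(groups)) groups <- attr(scores, "group")
  if (is.null(groups) || length(groups) != nrow(scores))
    qc_stop("qcmatch_validation_error", "groups must align with scores")
  tlab <- attr(scores, "treated_label") %||% unique(groups)[1]
  d <- if (spec$distance_scale == "logit") scores$linear_predictor else scores$probability
  logit <- scores$linear_predictor
  treated <- groups == tlab
  if (!any(treated) || all(treated))
    qc_stop("qcmatch_validation_error", "both groups must be nonempty")
  # the smaller group is the 'from' side; pairs are always reported as
  # (treated_id, control_id)
  from_treated <- sum(treated) <= sum(!treated)
  stratum <- rep("", nrow(scores))
  if (!is.null(spec$exact_vars)) {
    if (is.null(table))
      qc_stop("qcmatch_schema_error", "exact_vars requires the cohort table")
    missing_cols <- setdiff(spec$exact_vars, names(table))
    if (length(missing_cols))
      qc_stop("qcmatch_schema_error", "exact column(s) not in table: ",
              paste(missing_cols, collapse = ", "))
    stratum <- do.call(paste, c(lapply(spec$exact_vars,
                                       function(v) as.character(table[[v]])),
                                sep = "\r"))
  }
  caliper <- if (!is.null(spec$caliper_sd))
    spec$caliper_sd * pooled_sd(logit[treated], logit[!treated]) else Inf
  list(id = scores$subject_id, d = d, logit = logit, treated = treated,
       from_treated = from_treated, stratum = stratum, caliper = caliper)
}

# Lexicographic normalization of equal-cost pairings within one exact
# stratum: if swapping two pairs' partners leaves total cost unchanged,
# keeps both inside the caliper, and lowers the pairing order, swap.
# Fixes the tie-break deterministically.
normalize_ties <- function(pairs, caliper = Inf) {
  if (nrow(pairs) < 2) return(pairs)
  pairs <- pairs[order(pairs$treated_id), , drop = FALSE]
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(pairs) - 1L)) {
      for (b in seq(a + 1L, nrow(pairs))) {
        cur <- pairs$distance[a] + pairs$distance[b]
        d_ab <- abs(pairs$dt[a] - pairs$dc[b])
        d_ba <- abs(pairs$dt[b] - pairs$dc[a])
        alt1 <- d_ab + d_ba
        if (abs(alt1 - cur) < 1e-12 && d_ab <= caliper && d_ba <= caliper &&
            pairs$control_id[b] < pairs$control_id[a]) {
          tmp <- pairs[a, c("control_id", "dc")]
          pairs[a, c("control_id", "dc")] <- pairs[b, c("control_id", "dc")]
          pairs[b, c("control_id", "dc")] <- tmp
          pairs$distance[a] <- abs(pairs$dt[a] - pairs$dc[a])
          pairs$distance[b] <- abs(pairs$dt[b] - pairs$dc[b])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  pairs
}

#' Optimal 1:1 propensity matching
#'
#' Among all 1:1 assignments of treated subjects to distinct controls that
#' respect the caliper and exact strata, returns one minimizing the total
#' absolute propensity distance, solved exactly as a minimum-cost bipartite
#' assignment (Hungarian algorithm with potentials). Ties are resolved
#' lexicographically by subject id.
#'
#' @param scores a `propensity_scores` from [compute_scores()].
#' @param groups group labels aligned to `scores` (defaults to the scores'
#'   `group` attribute).
#' @param spec a [match_spec()].
#' @param table cohort table, required when `spec$exact_vars` is set.
#' @return a `match_result`: `pairs` (data frame `treated_id`, `control_id`,
#'   `distance`), `discarded` (data frame `subject_id`, `reason`),
#'   `total_distance`, `spec`.
#' @export
optimal_match <- function(scores, groups = NULL, spec = match_spec(),
                          table = NULL) {
  run_match(scores, groups, spec, table, engine = "optimal")
}

#' Greedy nearest-neighbour matching
#'
#' Processes treated subjects in descending logit order; each takes the
#' closest remaining admissible control (ties to the lexicographically
#' smallest control id). Generally suboptimal relative to [optimal_match()]
#' but never better.
#'
#' @inheritParams optimal_match
#' @return a `match_result`.
#' @export
nearest_match <- function(scores, groups = NULL, spec = match_spec(method = "nearest"),
                          table = NULL) {
  run_match(scores, groups, spec, table, engine = "nearest")
}

run_match <- function(scores, groups, spec, table, engine) {
  pr <- match_problem(scores, groups, spec, table)
  discarded <- data.frame(subject_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  add_discard <- function(ids, reason) {
    if (length(ids))
      discarded <<- rbind(discarded,
                          data.frame(subject_id = ids, reason = reason,
                                     stringsAsFactors = FALSE))
  }
  t_idx_all <- which(pr$treated)
  c_idx_all <- which(!pr$treated)
  if (!pr$from_treated) { tmp <- t_idx_all; t_idx_all <- c_idx_all; c_idx_all <- tmp }

  if (spec$common_support) {
    rng <- range(pr$logit[c_idx_all])
    out <- t_idx_all[pr$logit[t_idx_all] < rng[1] | pr$logit[t_idx_all] > rng[2]]
    if (length(out) && !spec$discard_unmatchable)
      qc_stop("qcmatch_capacity_error",
              "treated subject(s) outside common support; set discard_unmatchable")
    add_discard(pr$id[out], "outside_common_support")
    t_idx_all <- setdiff(t_idx_all, out)
  }

  pairs_list <- list()
  for (s in unique(pr$stratum[c(t_idx_all, c_idx_all)])) {
    ti <- t_idx_all[pr$stratum[t_idx_all] == s]
    ci <- c_idx_all[pr$stratum[c_idx_all] == s]
    if (!length(ti)) next
    if (!length(ci)) {
      if (!spec$discard_unmatchable)
        qc_stop("qcmatch_capacity_error", "exact stratum with no controls")
      add_discard(pr$id[ti], "empty_exact_stratum")
      next
    }
    # caliper feasibility per treated
    feas <- lapply(ti, function(i) ci[abs(pr$d[i] - pr$d[ci]) <= pr$caliper])
    infeasible <- ti[lengths(feas) == 0L]
    if (length(infeasible)) {
      if (!spec$discard_unmatchable)
        qc_stop("qcmatch_capacity_error",
                "treated subject(s) with no control inside the caliper")
      add_discard(pr$id[infeasible], "no_candidate_in_caliper")
      ti <- setdiff(ti, infeasible)
      if (!length(ti)) next
    }
    if (length(ti) > length(ci)) {
      if (!spec$discard_unmatchable)
        qc_stop("qcmatch_capacity_error", "insufficient controls (",
                length(ci), " for ", length(ti), " treated)")
    }
    res <- if (engine == "optimal")
      solve_stratum_optimal(pr, ti, ci, spec, add_discard)
    else
      solve_stratum_nearest(pr, ti, ci, spec, add_discard)
    if (engine == "optimal") res <- normalize_ties(res, pr$caliper)
    pairs_list[[length(pairs_list) + 1L]] <- res
  }
  pairs <- if (length(pairs_list)) do.call(rbind, pairs_list) else
    data.frame(treated_id = character(0), control_id = character(0),
               dt = numeric(0), dc = numeric(0), distance = numeric(0),
               stringsAsFactors = FALSE)
  if (!pr$from_treated && nrow(pairs)) {
    # 'from' side was the control group: swap columns back
    pairs <- data.frame(treated_id = pairs$control_id,
                        control_id = pairs$treated_id,
                        dt = pairs$dc, dc = pairs$dt,
                        distance = pairs$distance, stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$treated_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs[, c("treated_id", "control_id", "distance")],
                 discarded = discarded,
                 total_distance = sum(pairs$distance),
                 spec = spec),
            class = "match_result")
}

BIG_COST <- 1e9

solve_stratum_optimal <- function(pr, ti, ci, spec, add_discard) {
  # deterministic input order: sort both sides by subject id
  ti <- ti[order(pr$id[ti])]
  ci <- ci[order(pr$id[ci])]
  repeat {
    cost <- abs(outer(pr$d[ti], pr$d[ci], "-"))
    cost[cost > pr$caliper] <- BIG_COST
    if (length(ti) > length(ci)) {
      # more treated than controls: assign controls to treated; unassigned
      # treated are discarded as insufficient_controls
      assign_c <- solve_assignment_cpp(t(cost))
      matched_t <- assign_c            # index into ti per control
      keep_t <- sort(unique(matched_t))
      dropped <- setdiff(seq_along(ti), keep_t)
      add_discard(pr$id[ti[dropped]], "insufficient_controls")
      sel_t <- ti[matched_t]
      sel_c <- ci
    } else {
      assign_t <- solve_assignment_cpp(cost)
      sel_t <- ti
      sel_c <- ci[assign_t]
    }
    dist <- abs(pr$d[sel_t] - pr$d[sel_c])
    over <- dist > pr$caliper
    if (!any(over)) {
      return(data.frame(treated_id = pr$id[sel_t], control_id = pr$id[sel_c],
                        dt = pr$d[sel_t], dc = pr$d[sel_c], distance = dist,
                        stringsAsFactors = FALSE))
    }
    # assignment was forced through inadmissible edges: those treated have
    # admissible controls individually but not jointly
    if (!spec$discard_unmatchable)
      qc_stop("qcmatch_capacity_error",
              "caliper leaves too few controls for a feasible 1:1 matching")
    add_discard(pr$id[sel_t[over]], "no_candidate_in_caliper")
    ti <- setdiff(ti, sel_t[over])
    if (!length(ti))
      return(data.frame(treated_id = character(0), control_id = character(0),
                        dt = numeric(0), dc = numeric(0), distance = numeric(0),
                        stringsAsFactors = FALSE))
  }
}

solve_stratum_nearest <- function(pr, ti, ci, spec, add_discard) {
  # descending logit order; id order breaks exact ties
  ti <- ti[order(-pr$logit[ti], pr$id[ti])]
  avail <- ci[order(pr$id[ci])]
  out_t <- integer(0); out_c <- integer(0)
  for (i in ti) {
    if (!length(avail)) {
      if (!spec$discard_unmatchable)
        qc_stop("qcmatch_capacity_error", "insufficient controls")
      add_discard(pr$id[i], "insufficient_controls")
      next
    }
    dist <- abs(pr$d[i] - pr$d[avail])
    ok <- dist <= pr$caliper
    if (!any(ok)) {
      if (!spec$discard_unmatchable)
        qc_stop("qcmatch_capacity_error",
                "treated subject with no control inside the caliper")
      add_discard(pr$id[i], "no_candidate_in_caliper")
      next
    }
    j <- avail[ok][which.min(dist[ok])]
    out_t <- c(out_t, i); out_c <- c(out_c, j)
    avail <- setdiff(avail, j)
  }
  data.frame(treated_id = pr$id[out_t], control_id = pr$id[out_c],
             dt = pr$d[out_t], dc = pr$d[out_c],
             distance = abs(pr$d[out_t] - pr$d[out_c]),
             stringsAsFactors = FALSE)
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result:", nrow(x$pairs), "pairs, total distance",
      format(x$total_distance, digits = 6), ";", nrow(x$discarded),
      "discarded\n")
  if (nrow(x$discarded))
    print(table(x$discarded$reason))
  invisible(x)
}

#' Tiered matching
#'
#' Matches on the most important covariates first, then re-fits the
#' propensity model on the next tier within the matched sample and
#' re-matches, iterating through the tiers. Useful when a single propensity
#' model over all metrics cannot reach balance.
#'
#' @param table a [cohort_table()].
#' @param tiers ordered list of character vectors of covariate names
#'   (non-overlapping).
#' @param spec a [match_spec()].
#' @return a `match_result` whose `tier_balance` attribute holds a
#'   [balance_report()] snapshot per tier.
#' @export
tiered_match <- function(table, tiers, spec = match_spec()) {
  if (!length(tiers)) qc_stop("qcmatch_config_error", "need at least one tier")
  if (anyDuplicated(unlist(tiers)))
    qc_stop("qcmatch_config_error", "tiers must not overlap")
  current <- table
  result <- NULL
  snapshots <- list()
  for (k in seq_along(tiers)) {
    covs <- tiers[[k]]
    missing_cols <- setdiff(covs, names(current))
    if (length(missing_cols))
      qc_stop("qcmatch_schema_error", "tier ", k, " references missing column(s): ",
              paste(missing_cols, collapse = ", "))
    model <- fit_propensity(current, covs)
    scores <- compute_scores(model, current)
    result <- run_match(scores, current$group, spec, current,
                        engine = spec$method)
    if (!nrow(result$pairs))
      qc_stop("qcmatch_tier_error", "tier ", k, " emptied the sample")
    snapshots[[k]] <- balance_report(current, result, covs, scores)
    current <- apply_match(current, result)
    if (!all(c(treated_label(table), control_label(table)) %in% current$group))
      qc_stop("qcmatch_tier_error", "tier ", k, " emptied a group")
  }
  attr(result, "tier_balance") <- snapshots
  result
}

#' Subset a cohort to the matched subjects
#'
#' Returns the paired subjects only: the treated block (pair order) followed
#' by the control block (same order), so row `i` of each block forms pair
#' `i`.
#'
#' @param table a [cohort_table()].
#' @param result a `match_result`.
#' @return a [cohort_table()] with `2 * nrow(result$pairs)` records.
#' @export
apply_match <- function(table, result) {
  ids <- c(result$pairs$treated_id, result$pairs$control_id)
  idx <- match(ids, table$subject_id)
  if (anyNA(idx))
    qc_stop("qcmatch_consistency_error", "pair id(s) absent from table: ",
            paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  cohort_table(as.data.frame(out), treated_label = treated_label(table),
               control_label = control_label(table),
               name = paste0(attr(table, "name"), ":matched"))
}

#' Write match pairs and discards to TSV
#'
#' @param result a `match_result`.
#' @param pairs_path,discards_path output paths (`NULL` to skip).
#' @export
write_match_result <- function(result, pairs_path, discards_path = NULL) {
  utils::write.table(result$pairs, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(discards_path))
    utils::write.table(result$discarded, discards_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
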