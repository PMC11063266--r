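#' Weight breakdowns for every path in a topology
#'
#' @param labelmap A [label_map()].
#' @param landmarks A [landmark_set()] resolving all topology landmarks.
#' @param topology A [load_topology()] result.
#' @param coeffs Risk coefficients.
#' @return Named list of [path_weight()] breakdowns, one per path.
#' @export
compute_all_weights <- function(labelmap, landmarks, topology,
                                coeffs = default_risk_coefficients()) {
  missing <- setdiff(topology$landmarks, rownames(landmarks))
  if (length(missing)) {
    affected <- names(topology$paths)[vapply(topology$paths, function(p)
      any(p$landmarks %in% missing), NA)]
    stop("landmark(s) ", paste(missing, collapse = ", "),
         " are missing; unresolvable path(s): ",
         paste(affected, collapse = ", "))
  }
  out <- lapply(names(topology$paths), function(pid)
    path_weight(labelmap, landmarks, topology$paths[[pid]], coeffs,
                path_id = pid))
  stats::setNames(out, names(topology$paths))
}

# Extract a named numeric weight vector from breakdowns (or pass through a
# plain named numeric vector, used heavily in tests).
weight_vector <- function(weights) {
  if (is.numeric(weights)) return(weights)
  stats::setNames(vapply(weights, function(w) w$weight, 0), names(weights))
}

# Topological order of windows under the path graph (Kahn's algorithm).
window_topo_order <- function(topology) {
  wins <- names(topology$windows)
  indeg <- stats::setNames(integer(length(wins)), wins)
  for (p in topology$paths)
    indeg[p$exit_window] <- indeg[p$exit_window] + 1L
  succ <- split(names(topology$paths),
                vapply(topology$paths, function(p) p$entry_window, ""))
  queue <- sort(wins[indeg == 0L])
  order <- character()
  while (length(queue)) {
    w <- queue[1]; queue <- queue[-1]
    order <- c(order, w)
    for (pid in succ[[w]]) {
      tgt <- topology$paths[[pid]]$exit_window
      indeg[tgt] <- indeg[tgt] - 1L
      if (indeg[tgt] == 0L) queue <- sort(c(queue, tgt))
    }
  }
  if (length(order) < length(wins))
    stop("cyclic path graph: windows ",
         paste(setdiff(wins, order), collapse = ", "))
  order
}

#' Minimum-total-weight plan by shortest path on the corridor DAG
#'
#' Single-source shortest path over the window-node / path-edge DAG, relaxed
#' in topological order. Path weights are frequently negative (surgical
#' freedom can exceed injury risk), so classic Dijkstra is inapplicable;
#' topological-order relaxation is exact for any edge weights on a DAG and
#' always equals the exhaustive minimum over [enumerate_plans()]. Exact ties
#' are broken by the lexicographically smallest plan id.
#'
#' @param topology A [load_topology()] result.
#' @param weights Named list of [path_weight()] breakdowns or a named numeric
#'   vector of path weights covering every topology path.
#' @return A `plan_result` list: `plan_id`, `approach_label` (declared label
#'   or `NA`), `path_ids`, `total_weight`, `breakdowns` (when available),
#'   `rank = 1`.
#' @export
optimal_plan <- function(topology, weights) {
  wv <- weight_vector(weights)
  missing <- setdiff(names(topology$paths), names(wv))
  if (length(missing))
    stop("weights missing for path(s): ", paste(missing, collapse = ", "))

  order <- window_topo_order(topology)
  dist <- stats::setNames(rep(Inf, length(order)), order)
  back <- stats::setNames(rep(NA_character_, length(order)), order)
  dist[topology$start_window] <- 0
  succ <- split(names(topology$paths),
                vapply(topology$paths, function(p) p$entry_window, ""))
  for (w in order) {
    if (!is.finite(dist[w])) next
    for (pid in succ[[w]]) {
      tgt <- topology$paths[[pid]]$exit_window
      cand <- dist[w] + wv[pid]
      if (cand < dist[tgt]) {
        dist[tgt] <- cand
        back[tgt] <- pid
      }
    }
  }
  if (!is.finite(dist[topology$end_window]))
    stop("no plan: start window '", topology$start_window,
         "' and end window '", topology$end_window, "' are disconnected")
  best <- unname(dist[topology$end_window])

  # gather exact ties over the declared/enumerated plans; lexicographically
  # smallest plan id wins (the DAG minimum is authoritative for the value)
  plans <- enumerate_plans(topology)
  totals <- vapply(plans, function(seqp) sum(wv[seqp]), 0)
  hit <- which(totals <= best + 1e-12 * max(1, abs(best)))
  if (!length(hit)) hit <- which.min(totals)   # defensive; cannot happen on a DAG
  ids <- vapply(plans[hit], function(seqp) {
    m <- match_plan_id(topology, seqp)
    if (is.na(m)) paste(seqp, collapse = "+") else m
  }, "")
  pick <- hit[order(ids)][1]
  seqp <- plans[[pick]]
  pid <- sort(ids)[1]
  plan_result(pid, topology, seqp, wv, weights, rank = 1L)
}

plan_result <- function(plan_id, topology, path_seq, wv, weights, rank) {
  label <- if (!is.na(plan_id) && plan_id %in% names(topology$plans))
    topology$plans[[plan_id]]$label else NA_character_
  structure(
    list(plan_id = plan_id,
         approach_label = label,
         path_ids = path_seq,
         total_weight = sum(wv[path_seq]),
         breakdowns = if (is.list(weights)) weights[path_seq] else NULL,
         rank = as.integer(rank)),
    class = "plan_result"
  )
}

#' @export
print.plan_result <- function(x, ...) {
  cat("<plan_result> rank ", x$rank, ": ", x$plan_id,
      if (!is.na(x$approach_label)) paste0(" [", x$approach_label, "]"),
      ", total weight ", format(x$total_weight),
      " (", paste(x$path_ids, collapse = " > "), ")\n", sep = "")
  invisible(x)
}

#' Classify a plan as ITA, TTA or STA
#'
#' Compares the superior (z) coordinate of each path-tetrahedron centroid
#' with the jugular-tubercle landmark: all centroids below `tubercle - delta`
#' give ITA (infra-tubercle), all above `tubercle + delta` give STA
#' (supra-tubercle), anything straddling or within the band gives TTA
#' (trans-tubercle).
#'
#' @param plan A plan id, a `plan_result`, or a character vector of path ids.
#' @param topology A [load_topology()] result with a `tubercle_landmark`.
#' @param landmarks A [landmark_set()].
#' @param delta Height of the trans-tubercle band, mm (default 2).
#' @return `"ITA"`, `"TTA"` or `"STA"`.
#' @export
classify_approach <- function(plan, topology, landmarks, delta = 2) {
  path_seq <- if (inherits(plan, "plan_result")) plan$path_ids
    else if (length(plan) == 1L && plan %in% names(topology$plans))
      topology$plans[[plan]]$paths
    else as.character(plan)
  if (is.na(topology$tubercle_landmark) ||
      !topology$tubercle_landmark %in% rownames(landmarks))
    stop("cannot resolve tubercle landmark '", topology$tubercle_landmark, "'")
  tz <- unclass(landmarks)[topology$tubercle_landmark, 3]
  cz <- vapply(path_seq, function(pid) {
    verts <- resolve_tetra(landmarks, topology$paths[[pid]]$landmarks)
    mean(verts[, 3])
  }, 0)
  if (all(cz < tz - delta)) "ITA"
  else if (all(cz > tz + delta)) "STA"
  else "TTA"
}

#' Rank all plans by total weight
#'
#' All declared plans ordered by ascending total weight (exact ties broken by
#' plan id); rank 1 always agrees with [optimal_plan()]. Each result carries
#' the geometric approach classification of [classify_approach()].
#'
#' @inheritParams optimal_plan
#' @param landmarks A [landmark_set()] (used for classification).
#' @param delta Trans-tubercle band for [classify_approach()].
#' @return List of `plan_result`, ranks 1..n.
#' @export
rank_plans <- function(topology, weights, landmarks, delta = 2) {
  wv <- weight_vector(weights)
  ids <- names(topology$plans)
  totals <- vapply(ids, function(id) sum(wv[topology$plans[[id]]$paths]), 0)
  ord <- order(totals, ids)
  out <- lapply(seq_along(ord), function(r) {
    id <- ids[ord[r]]
    res <- plan_result(id, topology, topology$plans[[id]]$paths, wv, weights,
                       rank = r)
    res$approach_label <- classify_approach(id, topology, landmarks, delta)
    res
  })
  out
}
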