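#' Load and validate a corridor topology
#'
#' A corridor topology is the combinatorial object behind planning: *windows*
#' (triangular apertures given by landmark triples), *paths* (tetrahedral
#' corridor segments given by landmark quadruples, bounded by an entry and an
#' exit window that are faces of the tetrahedron), and *plans* (face-adjacent
#' path sequences from the start window to the end window). Topology is data,
#' not code: it is loaded from a YAML/JSON config (`schema: 1`) so alternative
#' corridor systems can be dropped in.
#'
#' Validation is total: any malformed config is rejected with an error naming
#' the offending element, never a crash downstream.
#'
#' @param config Path to a YAML or JSON config file, or an already-parsed
#'   list with the same structure.
#' @return An object of class `corridor_topology` with elements `landmarks`,
#'   `windows` (named list of sorted landmark triples), `paths` (named list
#'   with `landmarks`, `entry_window`, `exit_window`), `plans` (named list
#'   with `label`, `paths`), `start_window`, `end_window`,
#'   `tubercle_landmark`.
#' @export
load_topology <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("topology config not found: ", config)
    if (tolower(tools::file_ext(config)) == "json")
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  } else config
  for (field in c("landmarks", "windows", "paths", "plans",
                  "start_window", "end_window"))
    if (is.null(cfg[[field]])) stop("topology config is missing '", field, "'")

  lms <- as.character(unlist(cfg$landmarks))
  if (anyDuplicated(lms)) stop("duplicate landmark ids in topology")

  windows <- list()
  for (w in cfg$windows) {
    id <- as.character(w$id)
    tri <- as.character(unlist(w$landmarks))
    if (is.null(w$id) || !nzchar(id)) stop("window without id in topology config")
    if (id %in% names(windows)) stop("duplicate window id: ", id)
    if (length(tri) != 3L || anyDuplicated(tri))
      stop("window ", id, " must have three distinct landmarks")
    bad <- setdiff(tri, lms)
    if (length(bad))
      stop("window ", id, " references undeclared landmark(s): ",
           paste(bad, collapse = ", "))
    windows[[id]] <- sort(tri)
  }

  paths <- list()
  for (p in cfg$paths) {
    id <- as.character(p$id)
    quad <- as.character(unlist(p$landmarks))
    if (is.null(p$id) || !nzchar(id)) stop("path without id in topology config")
    if (id %in% names(paths)) stop("duplicate path id: ", id)
    if (length(quad) != 4L || anyDuplicated(quad))
      stop("path ", id, " must have four distinct landmarks")
    bad <- setdiff(quad, lms)
    if (length(bad))
      stop("path ", id, " references undeclared landmark(s): ",
           paste(bad, collapse = ", "))
    for (side in c("entry_window", "exit_window")) {
      wid <- as.character(p[[side]])
      if (is.null(p[[side]]) || !wid %in% names(windows))
        stop("path ", id, " references unknown ", side, ": ", wid)
      if (!all(windows[[wid]] %in% quad))
        stop("path ", id, ": ", side, " '", wid,
             "' is not a face of the path tetrahedron")
    }
    if (identical(p$entry_window, p$exit_window))
      stop("path ", id, ": entry and exit windows must differ")
    paths[[id]] <- list(landmarks = sort(quad),
                        entry_window = as.character(p$entry_window),
                        exit_window = as.character(p$exit_window))
  }
  quads <- vapply(paths, function(p) paste(p$landmarks, collapse = ""), "")
  if (anyDuplicated(quads))
    stop("two paths share the same landmark quadruple: ",
         paste(unique(quads[duplicated(quads)]), collapse = ", "))

  for (side in c("start_window", "end_window"))
    if (!cfg[[side]] %in% names(windows))
      stop(side, " '", cfg[[side]], "' is not a declared window")

  plans <- list()
  for (pl in cfg$plans) {
    id <- as.character(pl$id)
    if (is.null(pl$id) || !nzchar(id)) stop("plan without id in topology config")
    if (id %in% names(plans)) stop("duplicate plan id: ", id)
    seqp <- as.character(unlist(pl$paths))
    if (!length(seqp)) stop("plan ", id, " has no paths")
    bad <- setdiff(seqp, names(paths))
    if (length(bad))
      stop("plan ", id, " references unknown path(s): ", paste(bad, collapse = ", "))
    if (paths[[seqp[1]]]$entry_window != cfg$start_window)
      stop("plan ", id, ": first path '", seqp[1],
           "' does not start at the start window")
    if (paths[[seqp[length(seqp)]]]$exit_window != cfg$end_window)
      stop("plan ", id, ": last path '", seqp[length(seqp)],
           "' does not end at the end window")
    if (length(seqp) > 1L)
      for (t in seq_len(length(seqp) - 1L))
        if (paths[[seqp[t]]]$exit_window != paths[[seqp[t + 1L]]]$entry_window)
          stop("plan ", id, ": paths '", seqp[t], "' and '", seqp[t + 1L],
               "' are not face-adjacent (break at position ", t, ")")
    plans[[id]] <- list(label = if (is.null(pl$label)) NA_character_
                                else as.character(pl$label),
                        paths = seqp)
  }

  topo <- structure(
    list(landmarks = lms, windows = windows, paths = paths, plans = plans,
         start_window = as.character(cfg$start_window),
         end_window = as.character(cfg$end_window),
         tubercle_landmark = if (is.null(cfg$tubercle_landmark)) NA_character_
                             else as.character(cfg$tubercle_landmark)),
    class = "corridor_topology"
  )
  check_topology_acyclic(topo)
  topo
}

# Reject cycles in the window/path graph reachable from the start window, so
# plan enumeration always terminates.
check_topology_acyclic <- function(topo) {
  succ <- split(names(topo$paths),
                vapply(topo$paths, function(p) p$entry_window, ""))
  state <- new.env(parent = emptyenv())
  visit <- function(win, stack) {
    if (win %in% stack)
      stop("cyclic path graph detected at window '", win, "'")
    key <- paste0("w_", win)
    if (isTRUE(state[[key]])) return(invisible())
    for (pid in succ[[win]])
      visit(topo$paths[[pid]]$exit_window, c(stack, win))
    assign(key, TRUE, envir = state)
    invisible()
  }
  visit(topo$start_window, character())
  invisible(TRUE)
}

#' @export
print.corridor_topology <- function(x, ...) {
  cat("<corridor_topology> ", length(x$landmarks), " landmarks, ",
      length(x$windows), " windows, ", length(x$paths), " paths, ",
      length(x$plans), " plans; ", x$start_window, " -> ", x$end_window, "\n",
      sep = "")
  invisible(x)
}

#' The bundled default corridor topology
#'
#' Eleven landmarks, seventeen windows, twelve tetrahedral paths and seven
#' plans spanning the retro-condylar route to the inferior clivus, with the
#' three canonical approaches pre-labelled: ITA (infra-tubercle), TTA
#' (trans-tubercle) and STA (supra-tubercle), named for passing under,
#' through and above the jugular tubercle.
#'
#' @return A `corridor_topology`.
#' @export
#' @examples
#' topo <- default_topology()
#' lengths(topo[c("landmarks", "windows", "paths", "plans")])
default_topology <- function() {
  load_topology(system.file("extdata", "default_topology.yaml",
                            package = "cliviplan", mustWork = TRUE))
}

#' Enumerate every plan from the start window to the end window
#'
#' Depth-first traversal of the window/path DAG. Returns every face-adjacent
#' path sequence from start to end, in lexicographic order of the path-id
#' sequence. On the default topology this reproduces exactly the seven
#' declared plans.
#'
#' @param topology A [load_topology()] result.
#' @return A list of character vectors (path-id sequences); empty if start
#'   and end are disconnected.
#' @export
enumerate_plans <- function(topology) {
  succ <- split(names(topology$paths),
                vapply(topology$paths, function(p) p$entry_window, ""))
  succ <- lapply(succ, sort)
  out <- list()
  walk <- function(win, trail) {
    if (win == topology$end_window && length(trail)) {
      out[[length(out) + 1L]] <<- trail
      # the end window is terminal for a route, but continue only through
      # declared paths (fall through) in case further routes pass beyond it
    }
    for (pid in succ[[win]])
      walk(topology$paths[[pid]]$exit_window, c(trail, pid))
    invisible()
  }
  walk(topology$start_window, character())
  keys <- vapply(out, paste, "", collapse = "\r")
  out[order(keys)]
}

# Match an enumerated path sequence to a declared plan id, if any.
match_plan_id <- function(topology, path_seq) {
  for (id in names(topology$plans))
    if (identical(topology$plans[[id]]$paths, path_seq)) return(id)
  NA_character_
}
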