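test_that("the default topology has the canonical combinatorics", {
  topo <- default_topology()
  expect_length(topo$landmarks, 11)
  expect_length(topo$windows, 17)
  expect_length(topo$paths, 12)
  expect_length(topo$plans, 7)
  # the three named approaches are declared and pairwise distinct
  labels <- vapply(topo$plans, `[[`, "", "label")
  expect_setequal(stats::na.omit(labels), c("ITA", "TTA", "STA"))
  labelled <- topo$plans[!is.na(labels)]
  seqs <- vapply(labelled, function(p) paste(p$paths, collapse = "|"), "")
  expect_equal(anyDuplicated(seqs), 0L)
  # every path id is the sorted concatenation of its landmark letters
  for (pid in names(topo$paths))
    expect_identical(pid, paste(sort(topo$paths[[pid]]$landmarks), collapse = ""))
})

test_that("enumerating the default topology reproduces the declared plans exactly", {
  topo <- default_topology()
  enumerated <- enumerate_plans(topo)
  expect_length(enumerated, 7)
  declared <- lapply(topo$plans, function(p) p$paths)
  expect_setequal(vapply(enumerated, paste, "", collapse = "|"),
                  vapply(declared, paste, "", collapse = "|"))
  # deterministic lexicographic order
  keys <- vapply(enumerated, paste, "", collapse = "|")
  expect_identical(keys, sort(keys))
})

test_that("the minimal one-tetrahedron topology is valid and has one plan", {
  topo <- load_topology(minimal_topology_config())
  expect_length(topo$paths, 1)
  plans <- enumerate_plans(topo)
  expect_length(plans, 1)
  expect_identical(plans[[1]], "pqrs")
})

test_that("malformed configs are rejected with located errors", {
  base <- minimal_topology_config()

  cfg <- base; cfg$windows[[1]]$landmarks <- list("p", "q", "zz")
  expect_error(load_topology(cfg), "undeclared landmark.*zz")

  cfg <- base; cfg$paths[[1]]$entry_window <- "nope"
  expect_error(load_topology(cfg), "unknown entry_window: nope")

  cfg <- base; cfg$windows[[2]]$landmarks <- list("p", "q", "q")
  expect_error(load_topology(cfg), "three distinct landmarks")

  # entry window not a face of the tetrahedron
  cfg <- base
  cfg$landmarks <- c(base$landmarks, "t")
  cfg$windows[[3]] <- list(id = "w3", landmarks = list("p", "q", "t"))
  cfg$paths[[1]]$entry_window <- "w3"
  expect_error(load_topology(cfg), "not a face")

  # plan with non-adjacent consecutive paths names the break position
  cfg <- minimal_topology_config()
  cfg$landmarks <- list("p", "q", "r", "s", "t")
  cfg$windows[[3]] <- list(id = "mid2", landmarks = list("r", "s", "t"))
  cfg$windows[[4]] <- list(id = "alt", landmarks = list("q", "s", "t"))
  cfg$paths[[2]] <- list(id = "qrst", landmarks = list("q", "r", "s", "t"),
                         entry_window = "out", exit_window = "mid2")
  cfg$end_window <- "mid2"
  cfg$plans <- list(list(id = "bad", paths = list("pqrs", "qrst")))
  expect_no_error(load_topology(cfg))   # adjacent: fine
  cfg$paths[[2]]$entry_window <- "alt"  # still a face, but breaks adjacency
  expect_error(load_topology(cfg), "bad.*not face-adjacent.*position 1")
})

test_that("cyclic path graphs are rejected", {
  # three windows sharing the q-r edge form a 3-cycle of valid tetrahedra
  cfg <- list(
    schema = 1,
    landmarks = list("p", "q", "r", "s", "t"),
    start_window = "w1", end_window = "w2",
    windows = list(list(id = "w1", landmarks = list("p", "q", "r")),
                   list(id = "w2", landmarks = list("q", "r", "s")),
                   list(id = "w3", landmarks = list("q", "r", "t"))),
    paths = list(
      list(id = "pqrs", landmarks = list("p", "q", "r", "s"),
           entry_window = "w1", exit_window = "w2"),
      list(id = "qrst", landmarks = list("q", "r", "s", "t"),
           entry_window = "w2", exit_window = "w3"),
      list(id = "pqrt", landmarks = list("p", "q", "r", "t"),
           entry_window = "w3", exit_window = "w1")),
    plans = list()
  )
  expect_error(load_topology(cfg), "cyclic")
})

test_that("plan enumeration matches an adjacency-matrix path-count oracle", {
  # random layered strip DAGs; count start-to-end routes via powers of the
  # window adjacency matrix (independent of the DFS in enumerate_plans)
  set.seed(42)
  for (rep in 1:10) {
    n_layers <- sample(2:6, 1)
    lm_pool <- letters[1:14]
    layers <- list(list(sort(sample(lm_pool, 3))))
    paths <- list()
    seen_quads <- character()
    seen_windows <- list(layers[[1]][[1]])
    win_id <- function(tri) paste(tri, collapse = "")
    for (l in seq_len(n_layers)) {
      prev <- layers[[l]]
      prev_ids <- vapply(seen_windows, win_id, "")
      nxt <- list()
      for (w in prev) {
        for (k in seq_len(sample(2:3, 1))) {
          drop_i <- sample(3, 1)
          add <- sample(setdiff(lm_pool, w), 1)
          tri <- sort(c(w[-drop_i], add))
          quad <- paste(sort(unique(c(w, tri))), collapse = "")
          # forward edges only: the exit window must not belong to this or
          # any earlier layer, so the graph stays a layered DAG (merges into
          # the next layer are allowed and create multi-route counts)
          if (nchar(quad) != 4 || quad %in% seen_quads) next
          if (win_id(tri) %in% prev_ids) next
          seen_quads <- c(seen_quads, quad)
          if (!win_id(tri) %in% vapply(nxt, win_id, "")) nxt <- c(nxt, list(tri))
          paths[[quad]] <- list(landmarks = sort(unique(c(w, tri))),
                                entry = win_id(w), exit = win_id(tri))
        }
      }
      if (!length(nxt)) break
      layers[[l + 1]] <- nxt
      seen_windows <- c(seen_windows, nxt)
    }
    if (length(layers) < 2) next
    end_tri <- layers[[length(layers)]][[1]]
    cfg <- list(
      schema = 1,
      landmarks = as.list(lm_pool),
      start_window = win_id(layers[[1]][[1]]),
      end_window = win_id(end_tri),
      windows = lapply(seen_windows, function(w)
        list(id = win_id(w), landmarks = as.list(w))),
      paths = lapply(names(paths), function(q)
        list(id = q, landmarks = as.list(paths[[q]]$landmarks),
             entry_window = paths[[q]]$entry, exit_window = paths[[q]]$exit)),
      plans = list()
    )
    topo <- load_topology(cfg)
    got <- length(enumerate_plans(topo))

    # oracle: sum over path lengths of (A^m)[start, end]
    wins <- vapply(seen_windows, win_id, "")
    A <- matrix(0, length(wins), length(wins), dimnames = list(wins, wins))
    for (p in paths) A[p$entry, p$exit] <- A[p$entry, p$exit] + 1
    total <- 0; P <- diag(length(wins)); dimnames(P) <- dimnames(A)
    for (m in seq_along(paths)) {
      P <- P %*% A
      total <- total + P[cfg$start_window, cfg$end_window]
    }
    expect_equal(got, total, info = paste("rep", rep))
  }
})
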