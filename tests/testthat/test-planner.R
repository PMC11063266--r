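random_weights <- function(topo, sd = 300) {
  stats::setNames(stats::rnorm(length(topo$paths), sd = sd), names(topo$paths))
}

brute_force_min <- function(topo, wv) {
  plans <- enumerate_plans(topo)
  totals <- vapply(plans, function(s) sum(wv[s]), 0)
  plans[[which.min(totals)]]
}

test_that("compute_all_weights returns one deterministic breakdown per path", {
  ph <- small_phantom()
  topo <- default_topology()
  w1 <- compute_all_weights(ph$labels, ph$landmarks, topo)
  expect_length(w1, 12)
  expect_setequal(names(w1), names(topo$paths))
  w2 <- compute_all_weights(ph$labels, ph$landmarks, topo)
  expect_identical(cliviplan:::weight_vector(w1), cliviplan:::weight_vector(w2))
})

test_that("a missing landmark is reported with every affected path", {
  ph <- small_phantom()
  topo <- default_topology()
  lm <- ph$landmarks[rownames(ph$landmarks) != "g", ]
  class(lm) <- c("landmark_set", class(lm))
  err <- tryCatch(compute_all_weights(ph$labels, lm, topo), error = identity)
  expect_s3_class(err, "error")
  for (pid in c("abcg", "bcgh", "bcgi", "cghi", "cgij", "ghij", "gijk"))
    expect_match(conditionMessage(err), pid)
})

test_that("DAG shortest path equals the exhaustive minimum, negative weights included", {
  topo <- default_topology()
  set.seed(99)
  for (rep in 1:200) {
    wv <- random_weights(topo)
    best <- optimal_plan(topo, wv)
    oracle <- brute_force_min(topo, wv)
    expect_identical(best$path_ids, oracle, info = paste("rep", rep))
    expect_equal(best$total_weight, sum(wv[oracle]))
  }
})

test_that("exact ties go to the lexicographically smallest plan id", {
  topo <- default_topology()
  # zero weights: every plan ties at 0; ids sort ita < sta < sta_return < tta...
  wv <- stats::setNames(rep(0, 12), names(topo$paths))
  best <- optimal_plan(topo, wv)
  expect_identical(best$plan_id, sort(names(topo$plans))[1])
  expect_identical(best$total_weight, 0)
})

test_that("a one-plan topology returns that plan with its single path weight", {
  topo <- load_topology(minimal_topology_config())
  best <- optimal_plan(topo, c(pqrs = -12.5))
  expect_identical(best$plan_id, "only")
  expect_identical(best$total_weight, -12.5)
  expect_identical(best$rank, 1L)
})

test_that("disconnected topologies raise a no-plan error", {
  cfg <- minimal_topology_config()
  cfg$landmarks <- list("p", "q", "r", "s", "u")
  cfg$windows[[3]] <- list(id = "island", landmarks = list("q", "r", "u"))
  cfg$end_window <- "island"
  cfg$plans <- list()
  topo <- load_topology(cfg)
  expect_error(optimal_plan(topo, c(pqrs = 1)), "disconnected")
})

test_that("rank_plans orders all plans by total weight with rank 1 optimal", {
  ph <- small_phantom()
  topo <- default_topology()
  weights <- compute_all_weights(ph$labels, ph$landmarks, topo)
  ranked <- rank_plans(topo, weights, ph$landmarks)
  expect_length(ranked, 7)
  totals <- vapply(ranked, `[[`, 0, "total_weight")
  expect_true(all(diff(totals) >= 0))
  expect_identical(vapply(ranked, `[[`, 0L, "rank"), 1:7)
  expect_identical(ranked[[1]]$path_ids, optimal_plan(topo, weights)$path_ids)
  # total weight equals the sum of its per-path breakdowns
  for (r in ranked)
    expect_equal(r$total_weight,
                 sum(vapply(r$breakdowns, `[[`, 0, "weight")))
})

test_that("rank-1 agrees with the oracle across random weight vectors", {
  topo <- default_topology()
  ph <- small_phantom()
  set.seed(7)
  for (rep in 1:100) {
    wv <- random_weights(topo)
    ranked <- rank_plans(topo, wv, ph$landmarks)
    expect_identical(ranked[[1]]$path_ids, brute_force_min(topo, wv))
  }
})

test_that("classify_approach separates infra, trans and supra corridors", {
  topo <- default_topology()
  ph <- generate_phantom(small_params(jitter_mm = 0))

  # the pre-declared approach labels agree with the geometric classification
  for (id in names(topo$plans)) {
    declared <- topo$plans[[id]]$label
    if (!is.na(declared))
      expect_identical(classify_approach(id, topo, ph$landmarks), declared)
  }

  # synthetic control: translate all landmarks far below/above the tubercle
  lm <- unclass(ph$landmarks)
  tz <- lm["f", 3]
  low <- lm; low[setdiff(rownames(lm), "f"), 3] <- tz - 30
  expect_identical(
    classify_approach("sta", topo, landmark_set(low)), "ITA")
  high <- lm; high[setdiff(rownames(lm), "f"), 3] <- tz + 30
  expect_identical(
    classify_approach("ita", topo, landmark_set(high)), "STA")
  # straddling centroids give TTA by construction
  expect_identical(classify_approach("tta", topo, ph$landmarks), "TTA")
})

test_that("plan reports are schema-valid, complete and byte-reproducible", {
  ph <- small_phantom()
  topo <- default_topology()
  coeffs <- default_risk_coefficients()
  weights <- compute_all_weights(ph$labels, ph$landmarks, topo, coeffs)
  ranked <- rank_plans(topo, weights, ph$landmarks)
  report <- plan_report(ranked, coeffs, provenance = list(seed = 0))
  expect_true(validate_plan_report(report))

  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2, csv)))
  write_plan_report(report, f1, csv)
  write_plan_report(plan_report(ranked, coeffs, provenance = list(seed = 0)), f2)
  expect_identical(readLines(f1), readLines(f2))

  tab <- utils::read.csv(csv)
  expect_identical(nrow(tab), 7L)
  expect_identical(names(tab), c("plan_id", "label", "total_weight",
                                 "injury_risk_sum", "freedom_sum", "rank"))
  expect_error(validate_plan_report(list(tool = NULL)), "missing required")
})
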