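#' Anatomical variation distribution for cohort simulation
#'
#' Per-parameter samplers for [phantom_params()]: vertebral-artery caliber
#' (lognormal body with a hypoplasia mass point, truncated), sinus dominance
#' (Beta), CN XI root height and tubercle/condyle sizes (truncated normal),
#' plus the landmark jitter scale. Every sampled parameter set satisfies the
#' [phantom_params()] invariants by construction.
#'
#' @param config Path to a variation YAML (defaults to the bundled
#'   `default_variation.yaml`) or an equivalent list.
#' @return A list of class `variation_distribution`.
#' @export
variation_distribution <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "default_variation.yaml",
                          package = "cliviplan", mustWork = TRUE)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (f in c("va_radius_mm", "sinus_dominance", "cn11_height_mm",
              "tubercle_size_mm", "condyle_size_mm"))
    if (is.null(cfg[[f]])) stop("variation config is missing '", f, "'")
  structure(cfg, class = "variation_distribution")
}

rtrunc_norm <- function(n, spec) {
  pmin(pmax(stats::rnorm(n, spec$mean, spec$sd), spec$min), spec$max)
}

# Draw one phantom_params from the distribution (RNG state of the caller).
sample_phantom_params <- function(dist, seed,
                                  grid_shape = c(96L, 96L, 96L),
                                  spacing_mm = c(1, 1, 1)) {
  va <- dist$va_radius_mm
  u <- stats::runif(1)
  ect <- if (is.null(va$ectasia_prob)) 0 else va$ectasia_prob
  r <- if (u < va$hypoplasia_prob) va$hypoplasia_radius
       else if (u < va$hypoplasia_prob + ect) va$ectasia_radius
       else pmin(pmax(stats::rlnorm(1, va$meanlog, va$sdlog), va$min), va$max)
  phantom_params(
    grid_shape = grid_shape, spacing_mm = spacing_mm,
    va_radius_mm = r,
    sinus_dominance = stats::rbeta(1, dist$sinus_dominance$shape1,
                                   dist$sinus_dominance$shape2),
    cn11_height_mm = rtrunc_norm(1, dist$cn11_height_mm),
    tubercle_size_mm = rtrunc_norm(1, dist$tubercle_size_mm),
    condyle_size_mm = rtrunc_norm(1, dist$condyle_size_mm),
    jitter_mm = if (is.null(dist$jitter_mm)) 0.5 else dist$jitter_mm,
    seed = seed)
}

# Subject-indexed derived seed, below 2^31 so it stays a valid R integer.
subject_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) * 48271 + i * 16807) %% 2147483647)
}

#' Simulate a cohort of synthetic subjects and tabulate optimal approaches
#'
#' Draws `n` independent phantoms from the variation distribution, plans each
#' end-to-end (weights, ranking, geometric approach classification of the
#' rank-1 plan), and tabulates winner frequencies. Per-subject RNG streams
#' are derived from the master seed by subject index, so extending the cohort
#' never reshuffles earlier subjects; the whole result is a pure function of
#' `(dist, n, topology, coeffs, seed)`.
#'
#' @param dist A [variation_distribution()].
#' @param n Number of subjects (>= 1).
#' @param topology A [load_topology()] result.
#' @param coeffs Risk coefficients.
#' @param seed Master seed (non-negative integer).
#' @param grid_shape,spacing_mm Phantom grid geometry (smaller grids make
#'   large sweeps cheap).
#' @return A list of class `cohort_result`: `n`, `subjects` (per-subject
#'   parameters, winner plan id/label and total weight), and `frequency`
#'   (data frame label / count / percent, counts summing to `n`).
#' @export
simulate_cohort <- function(dist, n, topology = default_topology(),
                            coeffs = default_risk_coefficients(),
                            seed = 0L,
                            grid_shape = c(96L, 96L, 96L),
                            spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(dist, "variation_distribution"), n >= 1)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    si <- subject_seed(seed, i)
    params <- with_seed(si, sample_phantom_params(dist, seed = si,
                                                  grid_shape = grid_shape,
                                                  spacing_mm = spacing_mm))
    ph <- tryCatch(generate_phantom(params),
                   error = function(e) stop("subject ", i, ": ",
                                            conditionMessage(e)))
    weights <- tryCatch(
      compute_all_weights(ph$labels, ph$landmarks, topology, coeffs),
      error = function(e) stop("subject ", i, ": ", conditionMessage(e)))
    ranked <- rank_plans(topology, weights, ph$landmarks)
    win <- ranked[[1]]
    subjects[[i]] <- list(index = i, seed = si, params = unclass(params),
                          winner_plan = win$plan_id,
                          winner_label = win$approach_label,
                          winner_weight = win$total_weight)
  }
  labels <- vapply(subjects, `[[`, "", "winner_label")
  counts <- table(factor(labels, levels = c("ITA", "TTA", "STA")))
  freq <- data.frame(label = names(counts),
                     count = as.integer(counts),
                     percent = 100 * as.integer(counts) / n)
  structure(list(n = n, seed = seed, subjects = subjects, frequency = freq),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> n = ", x$n, ", master seed ", x$seed, "\n", sep = "")
  print(x$frequency, row.names = FALSE)
  invisible(x)
}

#' Sensitivity sweep over one phantom parameter
#'
#' Replans a fixed phantom while one parameter moves along a grid, everything
#' else (including the seed) held constant. Used to show how anatomical
#' variation flips the optimal plan, e.g. a vertebral artery growing from
#' hypoplastic to grossly dilated driving the winner away from the
#' infra-tubercle approach.
#'
#' @param base_params A [phantom_params()] to perturb.
#' @param parameter Name of the swept parameter (a [phantom_params()] field).
#' @param grid Sorted numeric vector of values.
#' @param topology A [load_topology()] result.
#' @param coeffs Risk coefficients.
#' @param delta Trans-tubercle classification band, mm.
#' @return A data frame with one row per grid value: the value, winner plan
#'   id/label, and one `weight_<plan>` column per declared plan.
#' @export
sensitivity_sweep <- function(base_params, parameter, grid,
                              topology = default_topology(),
                              coeffs = default_risk_coefficients(),
                              delta = 2) {
  stopifnot(inherits(base_params, "phantom_params"))
  if (!parameter %in% setdiff(names(base_params), c("grid_shape", "spacing_mm")))
    stop("unknown sweep parameter: ", parameter)
  if (is.unsorted(grid)) stop("sweep grid must be sorted")
  rows <- lapply(grid, function(v) {
    p <- unclass(base_params)
    p[[parameter]] <- v
    p <- do.call(phantom_params, p)
    ph <- generate_phantom(p)
    weights <- compute_all_weights(ph$labels, ph$landmarks, topology, coeffs)
    ranked <- rank_plans(topology, weights, ph$landmarks, delta)
    totals <- stats::setNames(
      vapply(ranked, `[[`, 0, "total_weight"),
      paste0("weight_", vapply(ranked, `[[`, "", "plan_id")))
    c(list(value = v,
           winner_plan = ranked[[1]]$plan_id,
           winner_label = ranked[[1]]$approach_label),
      as.list(totals[sort(names(totals))]))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
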