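#' Risk coefficients per tissue class
#'
#' Non-negative dimensionless multipliers converting tissue volume (mm^3)
#' inside a corridor into injury risk (coefficient-weighted mm^3). Free space
#' always has coefficient 0. Defaults are bundled
#' (`inst/extdata/default_coefficients.yaml`) and can be overridden by a user
#' YAML with the same class-name -> value structure.
#'
#' @param path Optional path to a YAML file of class name -> coefficient.
#' @return Named numeric vector over all eight tissue classes.
#' @export
default_risk_coefficients <- function() {
  load_risk_coefficients(system.file("extdata", "default_coefficients.yaml",
                                     package = "cliviplan", mustWork = TRUE))
}

#' @rdname default_risk_coefficients
#' @export
load_risk_coefficients <- function(path) {
  if (!file.exists(path)) stop("risk coefficient file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_risk_coefficients(unlist(raw))
}

validate_risk_coefficients <- function(coeffs) {
  coeffs <- stats::setNames(as.numeric(coeffs), names(coeffs))
  unknown <- setdiff(names(coeffs), tissue_names())
  if (length(unknown))
    stop("unknown tissue class in risk coefficients: ",
         paste(unknown, collapse = ", "))
  bad <- !is.na(coeffs) & (!is.finite(coeffs) | coeffs < 0)
  if (any(bad))
    stop("risk coefficients must be finite and non-negative")
  if (!is.na(coeffs["space"]) && coeffs["space"] != 0)
    stop("the 'space' coefficient is fixed at 0")
  coeffs["space"] <- 0
  coeffs[setdiff(tissue_names(), names(coeffs))] <- NA_real_
  coeffs[tissue_names()]
}

#' Injury risk of a corridor segment
#'
#' The sum over non-space tissue classes of tissue volume times its risk
#' coefficient. Errors if a class with positive volume has no coefficient.
#'
#' @param volumes Named per-class volumes (mm^3), as returned by
#'   [tissue_volumes_in_tetra()].
#' @param coeffs Named risk coefficients, see [default_risk_coefficients()].
#' @return Injury risk in coefficient-weighted mm^3 (>= 0).
#' @export
injury_risk <- function(volumes, coeffs = default_risk_coefficients()) {
  coeffs <- validate_risk_coefficients(coeffs)
  classes <- setdiff(tissue_names(), "space")
  v <- volumes[classes]
  v[is.na(v)] <- 0
  undefined <- classes[v > 0 & is.na(coeffs[classes])]
  if (length(undefined))
    stop("no risk coefficient for tissue class(es) with positive volume: ",
         paste(undefined, collapse = ", "))
  k <- coeffs[classes]
  k[is.na(k)] <- 0
  sum(v * k)
}

#' Surgical freedom of a corridor segment
#'
#' The volume of free operative space (class `space`) inside the segment.
#'
#' @inheritParams injury_risk
#' @return Free-space volume in mm^3 (>= 0).
#' @export
surgical_freedom <- function(volumes) {
  v <- volumes["space"]
  if (is.na(v)) 0 else unname(v)
}

#' Full weight breakdown of one corridor path
#'
#' Resolves the path's four landmarks to a tetrahedron, measures per-class
#' tissue volumes inside it, and computes
#' `weight = injury_risk - surgical_freedom`. Weights may be negative
#' (freedom can exceed risk) and are never clamped.
#'
#' @param labelmap A [label_map()].
#' @param landmarks A [landmark_set()].
#' @param path A path entry from a `corridor_topology` (list with
#'   `landmarks`), or a character vector of four landmark ids.
#' @param coeffs Risk coefficients.
#' @param path_id Optional id recorded in the breakdown.
#' @return A list of class `weight_breakdown`: `path_id`, `tissue_volumes`,
#'   `injury_risk`, `surgical_freedom`, `weight`.
#' @export
path_weight <- function(labelmap, landmarks, path,
                        coeffs = default_risk_coefficients(),
                        path_id = NULL) {
  ids <- if (is.list(path)) path$landmarks else as.character(path)
  if (is.null(path_id))
    path_id <- paste(sort(ids), collapse = "")
  verts <- resolve_tetra(landmarks, ids)
  vols <- tissue_volumes_in_tetra(labelmap, verts)
  risk <- injury_risk(vols, coeffs)
  freedom <- surgical_freedom(vols)
  structure(
    list(path_id = path_id, tissue_volumes = vols,
         injury_risk = risk, surgical_freedom = freedom,
         weight = risk - freedom),
    class = "weight_breakdown"
  )
}

#' @export
print.weight_breakdown <- function(x, ...) {
  cat("<weight_breakdown> path ", x$path_id,
      ": risk ", format(x$injury_risk), ", freedom ",
      format(x$surgical_freedom), ", weight ", format(x$weight), "\n", sep = "")
  invisible(x)
}
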