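#' Construct a landmark set
#'
#' Named 3-D points in the same RAS millimetre frame as the label map. The
#' default corridor topology uses single letters `a`..`k`, but any unique
#' string ids are allowed.
#'
#' @param coords Numeric matrix with one row per landmark and 3 columns
#'   (x, y, z in mm), or a named list of length-3 numeric vectors.
#' @param ids Character vector of ids (required when `coords` has no
#'   rownames).
#' @return A `landmark_set`: a numeric matrix with rownames, columns x/y/z.
#' @export
landmark_set <- function(coords, ids = NULL) {
  if (is.list(coords)) {
    ids <- names(coords)
    coords <- do.call(rbind, lapply(coords, as.numeric))
  }
  coords <- as.matrix(coords)
  if (!is.null(ids)) rownames(coords) <- ids
  if (is.null(rownames(coords)) || any(rownames(coords) == ""))
    stop("every landmark needs an id")
  if (ncol(coords) != 3L) stop("landmark coordinates must be 3-D")
  if (anyDuplicated(rownames(coords)))
    stop("duplicate landmark id: ",
         paste(unique(rownames(coords)[duplicated(rownames(coords))]), collapse = ", "))
  if (any(!is.finite(coords))) stop("non-finite landmark coordinates")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  class(coords) <- c("landmark_set", class(coords))
  coords
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", nrow(x), " landmarks (mm)\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Read / write landmarks (JSON or CSV)
#'
#' JSON dialect: an object mapping id to `[x, y, z]`. CSV dialect: columns
#' `id,x,y,z` with a header row. The format is chosen by file extension.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @param landmarks A [landmark_set()].
#' @param required Optional character vector of ids that must be present
#'   (e.g. `topology$landmarks`); an informative error is raised if any are
#'   missing.
#' @return `read_landmarks()` returns a [landmark_set()].
#' @export
read_landmarks <- function(path, required = NULL) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(raw)) raw <- as.list(as.data.frame(t(raw)))
    lm <- landmark_set(lapply(raw, as.numeric))
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("landmark CSV must have columns id,x,y,z: ", path)
    if (anyDuplicated(df$id))
      stop("duplicate landmark id: ",
           paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
    lm <- landmark_set(as.matrix(df[, c("x", "y", "z")]), ids = df$id)
  } else {
    stop("unsupported landmark format: .", ext, " (use .json or .csv)")
  }
  if (!is.null(required)) {
    missing <- setdiff(required, rownames(lm))
    if (length(missing))
      stop("landmark file ", path, " is missing required ids: ",
           paste(missing, collapse = ", "))
  }
  lm
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- lapply(seq_len(nrow(landmarks)), function(i) unname(landmarks[i, ]))
    names(obj) <- rownames(landmarks)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  } else if (ext == "csv") {
    df <- data.frame(id = rownames(landmarks),
                     x = landmarks[, 1], y = landmarks[, 2], z = landmarks[, 3])
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("unsupported landmark format: .", ext, " (use .json or .csv)")
  }
  invisible(path)
}

#' Check that landmarks lie inside a label map's physical bounds
#'
#' @param landmarks A [landmark_set()].
#' @param labelmap A [label_map()].
#' @return `TRUE` invisibly, or an error naming the offending landmarks.
#' @export
check_landmarks_in_bounds <- function(landmarks, labelmap) {
  b <- labelmap_bounds(labelmap)
  out <- rownames(landmarks)[apply(landmarks, 1, function(p)
    any(p < b["lower", ] | p > b["upper", ]))]
  if (length(out))
    stop("landmarks outside label map bounds: ", paste(out, collapse = ", "))
  invisible(TRUE)
}
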