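#' Tissue classes of the skull-base label map
#'
#' The label map uses eight integer codes: free operative space plus the seven
#' anatomical items weighed in surgical planning (bone, cerebellum, brainstem,
#' artery, vein, cranial nerve) and a catch-all "other" class. Code 0 is
#' always free space; the remaining codes are arbitrary but fixed.
#'
#' @return A data frame with columns `code` (integer) and `name` (character).
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() {
  data.frame(
    code = 0:7,
    name = c("space", "bone", "cerebellum", "brainstem",
             "artery", "vein", "cranial_nerve", "other"),
    stringsAsFactors = FALSE
  )
}

#' @rdname tissue_classes
#' @format NULL
TISSUE_CODES <- c(
  space = 0L, bone = 1L, cerebellum = 2L, brainstem = 3L,
  artery = 4L, vein = 5L, cranial_nerve = 6L, other = 7L
)

tissue_names <- function() names(TISSUE_CODES)

#' Look up a tissue code by name
#'
#' @param name Tissue class name, e.g. `"artery"`.
#' @return Integer code.
#' @export
tissue_code <- function(name) {
  if (!all(name %in% names(TISSUE_CODES)))
    stop("unknown tissue class: ", paste(setdiff(name, names(TISSUE_CODES)), collapse = ", "))
  unname(TISSUE_CODES[name])
}
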