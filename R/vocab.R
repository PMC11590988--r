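#' Behavior class vocabulary
#'
#' The closed four-state ethogram used throughout the package: `lying`,
#' `stand`, `drink`, `eat`. Annotation sources spell these inconsistently
#' ("standing", "lying down", "feeding", ...), so [normalize_class()] maps
#' common synonyms onto the canonical labels.
#'
#' @return Character vector of the four canonical class names, in the fixed
#'   order used for YOLO class indices (0-based: lying = 0, stand = 1,
#'   drink = 2, eat = 3).
#' @export
#' @examples
#' behavior_classes()
#' normalize_class(c("Lying Down", "FEEDING", "stand"))
behavior_classes <- function() c("lying", "stand", "drink", "eat")

.class_synonyms <- c(
  lying = "lying", lie = "lying", "lying down" = "lying", lyingdown = "lying",
  lying_down = "lying",
  stand = "stand", standing = "stand",
  drink = "drink", drinking = "drink",
  eat = "eat", eating = "eat", feed = "eat", feeding = "eat"
)

#' @rdname behavior_classes
#' @param x character vector of raw class names.
#' @export
normalize_class <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.class_synonyms[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop("unknown behavior class(es): ", paste(bad, collapse = ", "),
         "; allowed classes are: ", paste(behavior_classes(), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname behavior_classes
#' @export
class_index <- function(x) match(normalize_class(x), behavior_classes()) - 1L
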