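# Structured conditions used across the package.

mh_error <- function(message, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "mh_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

mh_parse_error <- function(message, ...) {
  mh_error(message, "mh_parse_error", call = sys.call(-1), ...)
}

mh_structural_error <- function(message, ...) {
  mh_error(message, "mh_structural_error", call = sys.call(-1), ...)
}

mh_precondition_error <- function(message, ...) {
  mh_error(message, "mh_precondition_error", call = sys.call(-1), ...)
}

#' Signal that an RDM center assignment search is intractable
#'
#' Raised by [derive_pair_mapping()] when the number of reaction-center
#' assignment combinations exceeds the configured cap.  The condition carries
#' the offending `count` so callers can report it.
#'
#' @param count Number of combinations that would have to be enumerated.
#' @param limit The configured cap.
#' @keywords internal
mh_combinatorial_limit <- function(count, limit) {
  mh_error(
    sprintf(
      "combinatorial explosion: %.4g center-assignment combinations exceed the cap of %.4g",
      count, limit
    ),
    "mh_combinatorial_limit",
    call = sys.call(-1), count = count, limit = limit
  )
}
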