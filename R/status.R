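#' Status label coding
#'
#' Worker status is coded on a four-level scale: `0` = safe, `1` = fall
#' (fall from height), `2` = stumble (trip-and-fall at ground level),
#' `3` = coma (prolonged stillness after a collapse).  All functions in the
#' package pass labels around as integer codes; these helpers convert
#' between codes and names and validate label vectors.
#'
#' @return `status_levels()` returns a named integer vector mapping names to
#'   codes.  `status_name()` returns a character vector, `status_code()` an
#'   integer vector, `status_factor()` a factor with all four levels.
#' @examples
#' status_levels()
#' status_name(c(0L, 3L))
#' status_code(c("fall", "safe"))
#' @export
status_levels <- function() {
  c(safe = 0L, fall = 1L, stumble = 2L, coma = 3L)
}

#' @rdname status_levels
#' @param code integer label codes in `0:3`.
#' @export
status_name <- function(code) {
  validate_labels(code)
  names(status_levels())[as.integer(code) + 1L]
}

#' @rdname status_levels
#' @param name character label names (`"safe"`, `"fall"`, `"stumble"`, `"coma"`).
#' @export
status_code <- function(name) {
  lv <- status_levels()
  bad <- !(name %in% names(lv))
  if (any(bad)) {
    stop_imufall(sprintf("unknown status name(s): %s",
                         paste(unique(name[bad]), collapse = ", ")),
                 "imufall_validation_error")
  }
  unname(lv[name])
}

#' @rdname status_levels
#' @export
status_factor <- function(code) {
  validate_labels(code)
  factor(status_name(code), levels = names(status_levels()))
}

# Validate a vector of integer label codes; `where` annotates error messages
# with e.g. a line number.
validate_labels <- function(code, where = NULL) {
  codes <- suppressWarnings(as.integer(code))
  bad <- which(is.na(codes) | !(codes %in% 0:3))
  if (length(bad)) {
    loc <- if (is.null(where)) sprintf("position %d", bad[1L])
           else sprintf("%s %d", where, bad[1L])
    stop_imufall(
      sprintf("invalid status label code '%s' at %s (must be 0, 1, 2 or 3)",
              as.character(code[bad[1L]]), loc),
      "imufall_validation_error")
  }
  invisible(codes)
}

# Typed conditions --------------------------------------------------------

stop_imufall <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "imufall_error", "error", "condition"),
    list(message = message, call = call)))
}
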