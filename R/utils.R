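`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a brapifed condition
#'
#' All errors raised by the package carry a specific class under the common
#' `brapifed_error` class so callers (and the server layer) can map them to
#' response statuses.
#'
#' @param class condition subclass, e.g. `"brapifed_config_error"`.
#' @param message human-readable message.
#' @param ... additional condition fields (e.g. `status`, `backend`).
#' @keywords internal
#' @noRd
stop_brapifed <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "brapifed_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, positive = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x) &&
    (if (positive) x >= 1 else x >= 0)
}

#' Stable cache key for a named parameter list
#' @noRd
params_key <- function(params) {
  if (length(params) == 0L) return("")
  ord <- order(names(params))
  paste(
    vapply(ord, function(i) {
      paste0(names(params)[i], "=", paste(as.character(params[[i]]), collapse = ","))
    }, character(1)),
    collapse = "&"
  )
}

#' BrAPI status message entry
#' @noRd
status_message <- function(message, type = "INFO") {
  list(message = message, messageType = type)
}

compact <- function(x) x[!vapply(x, is.null, logical(1))]
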