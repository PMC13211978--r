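#' Number of pages needed to hold a list
#'
#' BrAPI pagination is 0-based: pages `0 .. totalPages - 1` carry data, and
#' `totalPages == ceiling(totalCount / pageSize)` (0 when the list is empty).
#'
#' @param totalCount non-negative number of items.
#' @param pageSize positive page capacity.
#' @return integer page count.
#' @examples
#' total_pages(0, 10)   # 0
#' total_pages(11, 10)  # 2
#' @export
total_pages <- function(totalCount, pageSize) {
  stopifnot(all(totalCount >= 0), all(pageSize >= 1))
  as.integer(ceiling(totalCount / pageSize))
}

#' Pagination metadata for a BrAPI list response
#'
#' @param currentPage 0-based page index.
#' @param pageSize positive items-per-page.
#' @param totalCount non-negative total item count across all pages.
#' @return a `pagination_meta` list with fields `currentPage`, `pageSize`,
#'   `totalCount`, `totalPages`.
#' @export
pagination_meta <- function(currentPage, pageSize, totalCount) {
  if (!is_count(currentPage)) stop_brapifed("brapifed_validation_error", "currentPage must be a non-negative integer")
  if (!is_count(pageSize, positive = TRUE)) stop_brapifed("brapifed_validation_error", "pageSize must be a positive integer")
  if (!is_count(totalCount)) stop_brapifed("brapifed_validation_error", "totalCount must be a non-negative integer")
  structure(
    list(
      currentPage = as.integer(currentPage),
      pageSize = as.integer(pageSize),
      totalCount = as.integer(totalCount),
      totalPages = total_pages(totalCount, pageSize)
    ),
    class = "pagination_meta"
  )
}

#' Pagination metadata for one axis of an allele-matrix response
#'
#' Allele-matrix responses are paged in two dimensions; each response carries
#' exactly two of these entries, one for the `VARIANTS` axis and one for the
#' `CALLSETS` axis.
#'
#' @param dimension `"VARIANTS"` or `"CALLSETS"`.
#' @param page 0-based page index along this axis.
#' @param pageSize positive page capacity along this axis.
#' @param totalCount non-negative axis length.
#' @return a `matrix_pagination` list.
#' @export
matrix_pagination <- function(dimension, page, pageSize, totalCount) {
  dimension <- match.arg(dimension, c("VARIANTS", "CALLSETS"))
  if (!is_count(page)) stop_brapifed("brapifed_validation_error", "page must be a non-negative integer")
  if (!is_count(pageSize, positive = TRUE)) stop_brapifed("brapifed_validation_error", "pageSize must be a positive integer")
  if (!is_count(totalCount)) stop_brapifed("brapifed_validation_error", "totalCount must be a non-negative integer")
  structure(
    list(
      dimension = dimension,
      page = as.integer(page),
      pageSize = as.integer(pageSize),
      totalCount = as.integer(totalCount),
      totalPages = total_pages(totalCount, pageSize)
    ),
    class = "matrix_pagination"
  )
}

#' Validate a raw pagination block from a backend response
#' @noRd
validate_pagination_block <- function(p, backend = "?") {
  need <- c("currentPage", "pageSize", "totalCount", "totalPages")
  if (is.null(p) || !all(need %in% names(p))) {
    stop_brapifed(
      "brapifed_malformed_body",
      sprintf("backend '%s': response lacks a complete pagination block", backend),
      backend = backend
    )
  }
  vals <- vapply(need, function(f) as.numeric(p[[f]] %||% NA_real_), numeric(1))
  if (anyNA(vals) || vals[["pageSize"]] < 1 || vals[["totalCount"]] < 0 ||
      vals[["totalPages"]] != total_pages(vals[["totalCount"]], vals[["pageSize"]])) {
    stop_brapifed(
      "brapifed_malformed_body",
      sprintf("backend '%s': inconsistent pagination metadata", backend),
      backend = backend
    )
  }
  lapply(p[need], as.integer)
}
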