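#' Probe each backend's total count for a filtered query
#'
#' A federated page needs every backend's `totalCount` before any slice can
#' be located.  Totals are read from the pagination metadata of a minimal
#' probe request (`page = 0`, `pageSize = 1`) against each routed backend.
#' Skipped backends (filter routing) and backends not serving the endpoint
#' contribute 0 without any HTTP call.  An unreachable backend either fails
#' the federated request (`onBackendError = "fail"`, the default) or is
#' excluded with a warning status (`"degrade"`).
#'
#' @param endpoint endpoint name.
#' @param routing per-backend routing from [route_filters()].
#' @param client a `brapi_client`.
#' @param config a [federation_config()].
#' @return list with `totals` (integer per backend; 0 for skipped or
#'   excluded), `skipped`, `excluded` (logical per backend), `status`
#'   (warning statuses collected during probing).
#' @export
probe_totals <- function(endpoint, routing, client, config) {
  n <- length(config$backends)
  totals <- integer(n)
  skipped <- logical(n)
  excluded <- logical(n)
  status <- list()
  for (i in seq_len(n)) {
    b <- config$backends[[i]]
    r <- routing[[b$name]]
    if (isTRUE(r$skip) || !(endpoint %in% b$endpoints)) {
      skipped[i] <- TRUE
      next
    }
    probe <- tryCatch(
      fetch_page(client, b, endpoint, r$params, page = 0L, pageSize = 1L),
      brapifed_error = function(c) c
    )
    if (inherits(probe, "condition")) {
      if (identical(config$onBackendError, "degrade")) {
        excluded[i] <- TRUE
        status <- c(status, list(status_message(
          sprintf("backend '%s' excluded: %s", b$name, conditionMessage(probe)),
          "WARNING"
        )))
      } else {
        stop_brapifed(
          "brapifed_federation_error",
          sprintf("backend '%s' failed while probing '%s': %s",
                  b$name, endpoint, conditionMessage(probe)),
          backend = b$name, status = 502
        )
      }
      next
    }
    totals[i] <- probe$pagination$totalCount
  }
  list(totals = totals, skipped = skipped, excluded = excluded, status = status)
}

#' Plan the backend fetches realizing one global page
#'
#' The federated list is the virtual concatenation of the backend lists in
#' configuration order.  Page `page` at size `pageSize` is the half-open
#' global item window `[page*pageSize, min(page*pageSize + pageSize,
#' sum(totals)))`.  For each backend whose item range overlaps the window,
#' the plan records the local half-open slice and the backend page indices
#' (at the same `pageSize`) covering that slice -- never more than two,
#' because a window no longer than `pageSize` spans at most one local page
#' boundary.
#'
#' @param page 0-based global page index.
#' @param pageSize positive page size.
#' @param totals integer vector of per-backend total counts, in backend
#'   order.
#' @return a `fetch_plan`: `list(page, pageSize, window = c(start, end),
#'   subrequests)` where each subrequest is
#'   `list(backend_index, pages, slice)` with `slice` a local half-open
#'   `[lo, hi)` interval.
#' @export
compute_fetch_plan <- function(page, pageSize, totals) {
  stopifnot(is_count(page), is_count(pageSize, positive = TRUE), all(totals >= 0))
  totals <- as.integer(totals)
  total <- sum(totals)
  start <- as.integer(page) * as.integer(pageSize)
  end <- min(start + as.integer(pageSize), total)
  subrequests <- list()
  if (end > start) {
    offset <- 0L
    for (i in seq_along(totals)) {
      lo <- max(start - offset, 0L)
      hi <- min(end - offset, totals[i])
      if (hi > lo) {
        pages <- seq.int(lo %/% pageSize, (hi - 1L) %/% pageSize)
        subrequests[[length(subrequests) + 1L]] <- list(
          backend_index = i, pages = pages, slice = c(lo, hi)
        )
      }
      offset <- offset + totals[i]
    }
  }
  structure(
    list(
      page = as.integer(page), pageSize = as.integer(pageSize),
      window = c(start, end), subrequests = subrequests
    ),
    class = "fetch_plan"
  )
}

#' @export
print.fetch_plan <- function(x, ...) {
  cat(sprintf(
    "<fetch_plan> page %d (size %d), window [%d,%d), %d subrequest(s)\n",
    x$page, x$pageSize, x$window[1], x$window[2], length(x$subrequests)
  ))
  for (s in x$subrequests) {
    cat(sprintf(
      "  backend #%d: pages {%s}, slice [%d,%d)\n",
      s$backend_index, paste(s$pages, collapse = ","), s$slice[1], s$slice[2]
    ))
  }
  invisible(x)
}

#' Execute a fetch plan and merge the slices into one federated page
#'
#' Fetches each planned backend page, cuts out the planned local slice,
#' namespaces every record with the owning backend's prefix, and
#' concatenates in backend order.  The merged pagination reports
#' `totalCount = sum(totals)` and `currentPage = page` -- the federated
#' paging scheme, not any backend's.  If a backend yields fewer items than
#' its probed total promised (the list shrank between probe and fetch), a
#' `brapifed_stale_total` condition is raised so the caller can re-probe
#' and replan once; with `truncate = TRUE` the shortfall instead yields a
#' truncated page plus a warning status (the documented
#' eventual-consistency contract).
#'
#' @param plan a `fetch_plan` from [compute_fetch_plan()] (same
#'   `pageSize`).
#' @param endpoint endpoint name.
#' @param routing per-backend routing from [route_filters()].
#' @param client a `brapi_client`.
#' @param config a [federation_config()].
#' @param totals the probed totals the plan was computed from.
#' @param status statuses to carry into the merged response.
#' @param truncate tolerate backend shortfalls (see above).
#' @return an entity page: `list(pagination, records, status)`.
#' @export
execute_plan <- function(plan, endpoint, routing, client, config, totals,
                         status = list(), truncate = FALSE) {
  stopifnot(inherits(plan, "fetch_plan"))
  records <- list()
  for (s in plan$subrequests) {
    b <- config$backends[[s$backend_index]]
    r <- routing[[b$name]]
    got <- list()
    for (p in s$pages) {
      pg <- fetch_page(client, b, endpoint, r$params, page = p, pageSize = plan$pageSize)
      got <- c(got, pg$records)
      if (length(pg$status)) {
        status <- c(status, lapply(pg$status, function(st) {
          st$message <- paste0("[", b$name, "] ", st$message %||% "")
          st
        }))
      }
    }
    base <- s$pages[1] * plan$pageSize
    idx <- seq.int(s$slice[1] - base + 1L, s$slice[2] - base)
    if (max(idx) > length(got)) {
      if (!truncate) {
        stop_brapifed(
          "brapifed_stale_total",
          sprintf("backend '%s' returned fewer '%s' items than probed", b$name, endpoint),
          backend = b$name
        )
      }
      idx <- idx[idx <= length(got)]
      status <- c(status, list(status_message(
        sprintf("backend '%s': page truncated, fewer items than probed totalCount", b$name),
        "WARNING"
      )))
    }
    slice <- got[idx]
    records <- c(records, lapply(slice, namespace_record, backend = b, separator = config$separator))
  }
  list(
    pagination = pagination_meta(plan$page, plan$pageSize, sum(totals)),
    records = records,
    status = status
  )
}

#' Create a fresh probe-total cache
#'
#' Backend totals are a best-effort snapshot; the proxy caches them per
#' `(endpoint, params)` with a short TTL so that iterating many federated
#' pages of one query costs a single probe round per backend.
#' @return an environment usable as the `cache` argument of
#'   [federated_list_page()].
#' @export
new_probe_cache <- function() new.env(parent = emptyenv())

cached_probe <- function(cache, key, ttl, refresh, fun) {
  if (is.null(cache)) return(fun())
  hit <- cache[[key]]
  now <- as.numeric(Sys.time())
  if (!refresh && !is.null(hit) && (now - hit$time) <= ttl) return(hit$value)
  value <- fun()
  cache[[key]] <- list(time = now, value = value)
  value
}

#' Serve one federated list page (probe, plan, fetch, merge)
#'
#' The full list pipeline: [route_filters()] -> [probe_totals()] ->
#' [compute_fetch_plan()] -> [execute_plan()].  On a stale-total shortfall
#' the probe is refreshed and the plan recomputed once; a second
#' inconsistency yields a truncated page with a warning status.
#'
#' @param endpoint endpoint name.
#' @param params query filters (no `page`/`pageSize`).
#' @param page,pageSize requested global page.
#' @param client a `brapi_client`.
#' @param config a [federation_config()].
#' @param cache optional probe cache environment (see
#'   [new_probe_cache()]); totals are cached per `(endpoint, params)`.
#' @param cache_ttl cache lifetime in seconds (default 30).
#' @return an entity page: `list(pagination, records, status)`.
#' @export
federated_list_page <- function(endpoint, params, page, pageSize, client, config,
                                cache = NULL, cache_ttl = 30) {
  routing <- route_filters(params, config, endpoint)
  key <- paste0(endpoint, "?", params_key(params))
  probe <- cached_probe(cache, key, cache_ttl, refresh = FALSE, function() {
    probe_totals(endpoint, routing, client, config)
  })
  plan <- compute_fetch_plan(page, pageSize, probe$totals)
  tryCatch(
    execute_plan(plan, endpoint, routing, client, config, probe$totals, probe$status),
    brapifed_stale_total = function(c) {
      probe2 <- cached_probe(cache, key, cache_ttl, refresh = TRUE, function() {
        probe_totals(endpoint, routing, client, config)
      })
      plan2 <- compute_fetch_plan(page, pageSize, probe2$totals)
      execute_plan(plan2, endpoint, routing, client, config, probe2$totals,
                   probe2$status, truncate = TRUE)
    }
  )
}
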