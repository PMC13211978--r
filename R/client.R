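#' Backend clients
#'
#' A client owns the HTTP contract to the underlying BrAPI endpoints:
#' request construction, per-backend bearer auth, bounded retries with
#' exponential backoff, an error taxonomy, and a call log that tests use to
#' assert minimal fetching.  Two transports exist: an in-process mock
#' transport (a named list of handler functions, one per backend) and a
#' plain HTTP transport built on base R's libcurl connections.
#'
#' @param config a [federation_config()].
#' @param handlers named list, backend name -> `function(endpoint, params)`
#'   returning a parsed BrAPI response body (a list).  Handlers signal
#'   `brapifed_network_error` / `brapifed_http_error` conditions to emulate
#'   failures.
#' @param retries attempts per call (default 3); retried only on network
#'   errors and HTTP 5xx -- 4xx are terminal, the requests are idempotent
#'   GETs.
#' @param retry_delay base backoff in seconds (doubled per attempt, with
#'   multiplicative jitter).
#' @return a `brapi_client` object.
#' @name brapi_client
NULL

new_client <- function(config, handlers, retries, retry_delay) {
  stopifnot(inherits(config, "federation_config"))
  missing <- setdiff(names(config$backends), names(handlers))
  if (length(missing)) {
    stop_brapifed(
      "brapifed_config_error",
      sprintf("no transport handler for backend(s): %s", paste(missing, collapse = ", "))
    )
  }
  env <- new.env(parent = emptyenv())
  env$config <- config
  env$handlers <- handlers
  env$retries <- as.integer(retries)
  env$retry_delay <- as.numeric(retry_delay)
  env$log <- list()
  class(env) <- "brapi_client"
  env
}

#' @rdname brapi_client
#' @export
mock_client <- function(config, handlers, retries = 3, retry_delay = 0) {
  new_client(config, handlers, retries, retry_delay)
}

#' @rdname brapi_client
#' @export
http_client <- function(config, retries = 3, retry_delay = 0.2) {
  handlers <- lapply(config$backends, function(b) http_backend_handler(b))
  names(handlers) <- names(config$backends)
  new_client(config, handlers, retries, retry_delay)
}

#' @export
print.brapi_client <- function(x, ...) {
  cat(sprintf(
    "<brapi_client> %d backend(s), %d call(s) logged, retries=%d\n",
    length(x$handlers), length(x$log), x$retries
  ))
  invisible(x)
}

#' Inspect or reset the backend call log
#'
#' Every outbound backend call is appended to the client's log as
#' `list(backend, endpoint, params, attempts, outcome)`; `outcome` is one
#' of `"ok"`, `"http-error"`, `"network-error"`, `"malformed-body"`.
#'
#' @param client a `brapi_client`.
#' @return `client_log()`: list of call records. `clear_client_log()`:
#'   the client, invisibly.
#' @export
client_log <- function(client) client$log

#' @rdname client_log
#' @export
clear_client_log <- function(client) {
  client$log <- list()
  invisible(client)
}

retryable <- function(cond) {
  inherits(cond, "brapifed_network_error") ||
    (inherits(cond, "brapifed_http_error") && (cond$status %||% 500) >= 500)
}

#' Perform one logical backend call with retries, appending to the log
#' @noRd
client_request <- function(client, backend, endpoint, params = list()) {
  handler <- client$handlers[[backend$name]]
  if (is.null(handler)) {
    stop_brapifed("brapifed_config_error", sprintf("no handler for backend '%s'", backend$name))
  }
  attempts <- 0L
  outcome <- "ok"
  res <- NULL
  last <- NULL
  repeat {
    attempts <- attempts + 1L
    res <- tryCatch(handler(endpoint, params), brapifed_error = function(c) c)
    if (!inherits(res, "condition")) break
    last <- res
    if (retryable(res) && attempts < client$retries) {
      if (client$retry_delay > 0) {
        Sys.sleep(client$retry_delay * 2^(attempts - 1L) * runif(1, 0.5, 1.5))
      }
      next
    }
    outcome <- if (inherits(res, "brapifed_network_error")) "network-error"
      else if (inherits(res, "brapifed_http_error")) "http-error"
      else "malformed-body"
    break
  }
  client$log <- c(client$log, list(list(
    backend = backend$name, endpoint = endpoint, params = params,
    attempts = attempts, outcome = outcome
  )))
  if (inherits(res, "condition")) stop(res)
  res
}

#' Fetch one raw (un-namespaced) page of a backend list endpoint
#'
#' @param client a `brapi_client`.
#' @param backend the target [backend_config()]; must serve `endpoint`.
#' @param endpoint endpoint name, e.g. `"germplasm"`.
#' @param params localized query parameters (no `page`/`pageSize`).
#' @param page,pageSize 0-based page request.
#' @return list with `pagination` (validated), `records` (list), `status`.
#' @export
fetch_page <- function(client, backend, endpoint, params = list(),
                       page = 0L, pageSize = 1000L) {
  if (!(endpoint %in% backend$endpoints)) {
    stop_brapifed(
      "brapifed_capability_error",
      sprintf("backend '%s' does not serve endpoint '%s'", backend$name, endpoint),
      backend = backend$name, endpoint = endpoint
    )
  }
  body <- client_request(
    client, backend, endpoint,
    c(params, list(page = as.integer(page), pageSize = as.integer(pageSize)))
  )
  pagination <- validate_pagination_block(body$metadata$pagination, backend$name)
  records <- body$result$data
  if (is.null(records)) records <- list()
  if (!is.list(records)) {
    stop_brapifed(
      "brapifed_malformed_body",
      sprintf("backend '%s': result.data is not a list", backend$name),
      backend = backend$name
    )
  }
  if (length(records) > pagination$pageSize) {
    stop_brapifed(
      "brapifed_malformed_body",
      sprintf("backend '%s': page holds more records than pageSize", backend$name),
      backend = backend$name
    )
  }
  list(pagination = pagination, records = records, status = body$metadata$status %||% list())
}

rows_to_matrix <- function(rows, nrow, ncol, backend = "?") {
  m <- matrix(character(0), nrow = nrow, ncol = ncol)
  if (nrow == 0L || ncol == 0L) return(m)
  if (length(rows) != nrow) {
    stop_brapifed(
      "brapifed_malformed_body",
      sprintf("backend '%s': dataMatrix row count does not match variantDbIds", backend),
      backend = backend
    )
  }
  for (i in seq_len(nrow)) {
    row <- unlist(rows[[i]], use.names = FALSE)
    if (length(row) != ncol) {
      stop_brapifed(
        "brapifed_malformed_body",
        sprintf("backend '%s': dataMatrix row width does not match callSetDbIds", backend),
        backend = backend
      )
    }
    m[i, ] <- as.character(row)
  }
  m
}

#' Fetch one raw 2D page of a backend allele matrix
#'
#' @param client a `brapi_client`.
#' @param backend the target [backend_config()]; must serve `allelematrix`.
#' @param params localized filter parameters.
#' @param variantPage,variantPageSize,callSetPage,callSetPageSize 2D page.
#' @return an allele-matrix block: `variantDbIds`, `callSetDbIds`
#'   (character vectors), `dataMatrices` (list of
#'   `list(dataMatrixName, dataType, values)` with `values` a character
#'   matrix variants x callsets), and per-axis `pagination`.
#' @export
fetch_matrix <- function(client, backend, params = list(),
                         variantPage = 0L, variantPageSize = 100L,
                         callSetPage = 0L, callSetPageSize = 100L) {
  if (!("allelematrix" %in% backend$endpoints)) {
    stop_brapifed(
      "brapifed_capability_error",
      sprintf("backend '%s' does not serve the allele matrix", backend$name),
      backend = backend$name, endpoint = "allelematrix"
    )
  }
  body <- client_request(
    client, backend, "allelematrix",
    c(params, list(
      dimensionVariantPage = as.integer(variantPage),
      dimensionVariantPageSize = as.integer(variantPageSize),
      dimensionCallSetPage = as.integer(callSetPage),
      dimensionCallSetPageSize = as.integer(callSetPageSize)
    ))
  )
  res <- body$result
  if (is.null(res) || is.null(res$pagination) || length(res$pagination) != 2L) {
    stop_brapifed(
      "brapifed_malformed_body",
      sprintf("backend '%s': allele matrix response lacks 2D pagination", backend$name),
      backend = backend$name
    )
  }
  pag <- list()
  for (p in res$pagination) {
    dim <- toupper(p$dimension %||% "")
    if (!dim %in% c("VARIANTS", "CALLSETS")) {
      stop_brapifed(
        "brapifed_malformed_body",
        sprintf("backend '%s': unknown matrix pagination dimension", backend$name),
        backend = backend$name
      )
    }
    pag[[dim]] <- matrix_pagination(dim, p$page %||% 0, p$pageSize %||% 1, p$totalCount %||% 0)
  }
  if (length(pag) != 2L) {
    stop_brapifed(
      "brapifed_malformed_body",
      sprintf("backend '%s': allele matrix must carry one pagination entry per dimension", backend$name),
      backend = backend$name
    )
  }
  variants <- as.character(unlist(res$variantDbIds %||% list(), use.names = FALSE))
  callsets <- as.character(unlist(res$callSetDbIds %||% list(), use.names = FALSE))
  mats <- lapply(res$dataMatrices %||% list(), function(dm) {
    list(
      dataMatrixName = dm$dataMatrixName %||% "genotype",
      dataType = dm$dataType %||% "string",
      values = rows_to_matrix(dm$dataMatrix %||% list(), length(variants), length(callsets), backend$name)
    )
  })
  list(
    variantDbIds = variants, callSetDbIds = callsets,
    dataMatrices = mats, pagination = pag
  )
}

#' HTTP transport handler for one backend (base libcurl connections)
#' @noRd
http_backend_handler <- function(backend) {
  force(backend)
  function(endpoint, params) {
    qs <- ""
    if (length(params)) {
      parts <- unlist(lapply(names(params), function(n) {
        vapply(as.character(params[[n]]), function(v) {
          paste0(URLencode(n, reserved = TRUE), "=", URLencode(v, reserved = TRUE))
        }, character(1))
      }), use.names = FALSE)
      qs <- paste0("?", paste(parts, collapse = "&"))
    }
    target <- paste0(backend$baseUrl, "/", endpoint, qs)
    headers <- c(Accept = "application/json")
    if (!is.null(backend$authToken)) {
      headers <- c(headers, Authorization = paste("Bearer", backend$authToken))
    }
    old <- options(timeout = backend$timeout)
    on.exit(options(old), add = TRUE)
    # libcurl reports the HTTP status via a warning and then fails the
    # open with a generic message; collect both to classify the failure
    warn_txt <- character(0)
    txt <- tryCatch(
      withCallingHandlers(
        {
          con <- url(target, open = "rb", headers = headers)
          on.exit(close(con), add = TRUE)
          rawToChar(readBin(con, what = "raw", n = 50e6))
        },
        warning = function(w) {
          warn_txt <<- c(warn_txt, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) {
        msg <- paste(c(conditionMessage(e), warn_txt), collapse = " | ")
        st <- regmatches(msg, regexpr("HTTP status was '[0-9]{3}", msg))
        st <- sub("HTTP status was '", "", st)
        if (length(st) && as.integer(st) >= 400) {
          stop_brapifed(
            "brapifed_http_error",
            sprintf("backend '%s': HTTP %s for %s", backend$name, st, target),
            status = as.integer(st), backend = backend$name
          )
        }
        stop_brapifed(
          "brapifed_network_error",
          sprintf("backend '%s': %s", backend$name, msg),
          backend = backend$name
        )
      }
    )
    tryCatch(
      jsonlite::fromJSON(txt, simplifyVector = FALSE),
      error = function(e) stop_brapifed(
        "brapifed_malformed_body",
        sprintf("backend '%s': response is not valid JSON", backend$name),
        backend = backend$name
      )
    )
  }
}
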