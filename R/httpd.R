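http_reason <- function(status) {
  switch(as.character(status),
    "200" = "OK", "400" = "Bad Request", "401" = "Unauthorized",
    "404" = "Not Found", "405" = "Method Not Allowed",
    "500" = "Internal Server Error", "502" = "Bad Gateway", "OK"
  )
}

#' Parse an HTTP query string into a named list
#'
#' Repeated keys and comma-separated values both become multi-valued
#' parameters, matching how BrAPI clients pass identifier lists.
#' @noRd
parse_query <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  out <- list()
  for (pair in strsplit(qs, "&", fixed = TRUE)[[1]]) {
    kv <- strsplit(pair, "=", fixed = TRUE)[[1]]
    if (length(kv) == 0L || !nzchar(kv[1])) next
    key <- URLdecode(kv[1])
    val <- if (length(kv) >= 2L) URLdecode(paste(kv[-1], collapse = "=")) else ""
    val <- strsplit(val, ",", fixed = TRUE)[[1]]
    out[[key]] <- c(out[[key]], val)
  }
  out
}

write_http_response <- function(con, status, body_json) {
  resp <- paste0(
    "HTTP/1.1 ", status, " ", http_reason(status), "\r\n",
    "Content-Type: application/json\r\n",
    "Content-Length: ", nchar(body_json, type = "bytes"), "\r\n",
    "Connection: close\r\n\r\n",
    body_json
  )
  writeChar(resp, con, eos = NULL)
  flush(con)
}

#' Serve a request handler over plain HTTP (single-threaded)
#'
#' A minimal HTTP/1.1 front end on base R server sockets: one connection
#' at a time, GET only, JSON out.  This is deliberately simple -- the
#' proxy's work is merging, not connection handling -- and is the
#' transport behind [serve_federation()] and [serve_backend()].
#'
#' @param handler `function(method, path, query, headers)` returning
#'   `list(status, body)`.
#' @param port TCP port to bind.
#' @param host bind address.
#' @param max_requests stop after this many requests (default unlimited;
#'   finite values are handy in tests).
#' @param quiet suppress the per-request log line.
#' @return number of requests served, invisibly.
#' @export
serve_http <- function(handler, port, host = "127.0.0.1",
                       max_requests = Inf, quiet = FALSE) {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  if (!quiet) message(sprintf("listening on http://%s:%d", host, port))
  served <- 0L
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+")
    served <- served + 1L
    t0 <- Sys.time()
    req <- tryCatch(readLines(con, n = 1L, warn = FALSE), error = function(e) character(0))
    if (length(req) == 0L) {
      close(con)
      next
    }
    parts <- strsplit(req, " ", fixed = TRUE)[[1]]
    method <- parts[1] %||% "GET"
    target <- if (length(parts) >= 2L) parts[2] else "/"
    headers <- character(0)
    repeat {
      line <- tryCatch(readLines(con, n = 1L, warn = FALSE), error = function(e) character(0))
      if (length(line) == 0L || !nzchar(line)) break
      sep <- regexpr(":", line, fixed = TRUE)
      if (sep > 0L) {
        nm <- trimws(substr(line, 1L, sep - 1L))
        headers[nm] <- trimws(substr(line, sep + 1L, nchar(line)))
      }
    }
    qpos <- regexpr("?", target, fixed = TRUE)
    path <- if (qpos > 0L) substr(target, 1L, qpos - 1L) else target
    query <- if (qpos > 0L) parse_query(substr(target, qpos + 1L, nchar(target))) else list()
    resp <- tryCatch(
      handler(method, path, query, headers),
      error = function(e) list(status = 500L, body = error_body(conditionMessage(e)))
    )
    json <- jsonlite::toJSON(resp$body, auto_unbox = TRUE, null = "null", digits = NA)
    tryCatch(write_http_response(con, resp$status, json), error = function(e) NULL)
    close(con)
    if (!quiet) {
      message(sprintf("%s %s -> %d (%.0f ms)", method, target, resp$status,
                      as.numeric(Sys.time() - t0, units = "secs") * 1000))
    }
  }
  invisible(served)
}

#' Serve the federated proxy over HTTP
#'
#' Binds the merged public BrAPI endpoint: all routes of
#' [proxy_handle()] plus the OpenAPI document at `/openapi.json`.
#'
#' @param config a [federation_config()] or path to a config file.
#' @param port TCP port (default: the configured server port).
#' @param client optional `brapi_client` (defaults to HTTP transport).
#' @param host,max_requests,quiet see [serve_http()].
#' @return number of requests served, invisibly.
#' @export
serve_federation <- function(config, port = NULL, client = NULL,
                             host = "127.0.0.1", max_requests = Inf,
                             quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  proxy <- brapi_proxy(config, client)
  serve_http(
    function(method, path, query, headers) {
      if (path %in% c("/openapi.json", "/brapi/v2/openapi.json")) {
        return(list(status = 200L, body = openapi_document(proxy)))
      }
      proxy_handle(proxy, method, path, query, headers)
    },
    port = port %||% config$port, host = host,
    max_requests = max_requests, quiet = quiet
  )
}

#' Serve one synthetic backend store over HTTP
#'
#' Exposes a [world_stores()] store as a private BrAPI endpoint -- the
#' HTTP test double for a relational phenotype database or a variant
#' browser.  One process serves one store; start several (one per source)
#' to emulate a distributed federation end to end.
#'
#' @param store one store from [world_stores()].
#' @param port TCP port.
#' @param host,max_requests,quiet see [serve_http()].
#' @return number of requests served, invisibly.
#' @export
serve_backend <- function(store, port, host = "127.0.0.1",
                          max_requests = Inf, quiet = FALSE) {
  handler <- backend_handler(store)
  serve_http(
    function(method, path, query, headers) {
      endpoint <- sub("^/brapi/v2(\\.[0-9]+)?", "", path)
      endpoint <- sub("^/", "", sub("/$", "", endpoint))
      body <- tryCatch(
        handler(endpoint, query),
        brapifed_error = function(c) c
      )
      if (inherits(body, "condition")) {
        status <- if (!is.null(body$status)) as.integer(body$status) else 500L
        return(list(status = status, body = error_body(conditionMessage(body))))
      }
      list(status = 200L, body = body)
    },
    port = port, host = host, max_requests = max_requests, quiet = quiet
  )
}
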