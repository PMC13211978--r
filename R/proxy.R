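LIST_ENDPOINTS <- c("germplasm", "samples", "studies", "observations",
                    "variants", "callsets")

endpoint_id_field <- function(endpoint) {
  switch(endpoint,
    germplasm = "germplasmDbId", samples = "sampleDbId", studies = "studyDbId",
    observations = "observationDbId", variants = "variantDbId",
    callsets = "callSetDbId", NA_character_
  )
}

#' Create a federated BrAPI proxy
#'
#' The proxy is the public face of the federation: it owns the
#' configuration, a backend client and a probe cache, and answers BrAPI
#' requests through [proxy_handle()] (in process) or [serve_federation()]
#' (over HTTP).
#'
#' @param config a [federation_config()].
#' @param client a `brapi_client`; defaults to an [http_client()] over the
#'   configured base URLs.
#' @return a `brapi_proxy` object.
#' @export
brapi_proxy <- function(config, client = NULL) {
  stopifnot(inherits(config, "federation_config"))
  env <- new.env(parent = emptyenv())
  env$config <- config
  env$client <- client %||% http_client(config)
  env$cache <- new_probe_cache()
  class(env) <- "brapi_proxy"
  env
}

#' @export
print.brapi_proxy <- function(x, ...) {
  cat(sprintf(
    "<brapi_proxy> %d backend(s); endpoints: %s\n",
    length(x$config$backends), paste(proxy_endpoints(x), collapse = ", ")
  ))
  invisible(x)
}

#' Endpoints the proxy advertises and routes
#'
#' An entity endpoint is offered exactly when at least one configured
#' backend serves it; `serverinfo` is always offered.  This single
#' function backs the live routing table, the `serverinfo` payload and the
#' OpenAPI document, so the three can never disagree.
#'
#' @param proxy a `brapi_proxy`.
#' @return character vector of endpoint names.
#' @export
proxy_endpoints <- function(proxy) {
  served <- unique(unlist(lapply(proxy$config$backends, `[[`, "endpoints")))
  c("serverinfo", intersect(KNOWN_ENDPOINTS, served))
}

error_body <- function(message) {
  list(
    metadata = list(
      pagination = list(currentPage = 0L, pageSize = 0L, totalCount = 0L, totalPages = 0L),
      status = list(status_message(message, "ERROR")), datafiles = list()
    ),
    result = NULL
  )
}

authorized <- function(proxy, headers) {
  tokens <- proxy$config$serverTokens
  if (length(tokens) == 0L) return(TRUE)
  nm <- tolower(names(headers) %||% character())
  auth <- headers[nm == "authorization"]
  if (length(auth) == 0L) return(FALSE)
  tok <- sub("^[Bb]earer +", "", auth[[1]])
  tok %in% tokens
}

matrix_page_body <- function(page, fill = ".") {
  grid_rows <- function(values) {
    lapply(seq_len(nrow(values)), function(i) as.list(unname(values[i, ])))
  }
  list(
    metadata = list(status = page$status, datafiles = list()),
    result = list(
      variantDbIds = as.list(page$variantDbIds),
      callSetDbIds = as.list(page$callSetDbIds),
      dataMatrices = lapply(page$dataMatrices, function(dm) {
        list(dataMatrixName = dm$dataMatrixName, dataType = dm$dataType,
             dataMatrix = grid_rows(dm$values))
      }),
      expandHomozygotes = TRUE, sepUnphased = "/",
      unknownString = fill,
      pagination = lapply(page$pagination, function(p) {
        list(dimension = p$dimension, page = p$page, pageSize = p$pageSize,
             totalCount = p$totalCount, totalPages = p$totalPages)
      })
    )
  )
}

list_page_body <- function(page) {
  list(
    metadata = list(
      pagination = unclass(page$pagination),
      status = page$status, datafiles = list()
    ),
    result = list(data = page$records)
  )
}

#' Answer one BrAPI request against the federation
#'
#' The in-process request entry point used both by tests and by the HTTP
#' front end.  Routing: `serverinfo` (open), `commoncropnames` (union of
#' backend crops), the entity list endpoints (probe/plan/fetch/merge
#' pipeline of [federated_list_page()]), their single-record `/{id}` forms
#' (resolved to one backend via [resolve_id()], no merging), and
#' `allelematrix` ([filtered_matrix()]).  When proxy tokens are
#' configured every data route demands a valid bearer token (401
#' otherwise); federation failures map to 502 with the backend named in
#' the status; unresolvable ids map to 404.
#'
#' @param proxy a `brapi_proxy`.
#' @param method HTTP method (only `GET` is routed).
#' @param path request path, with or without a `/brapi/v2*` base.
#' @param query named list of query parameters (values may be vectors).
#' @param headers named character vector of request headers.
#' @return `list(status = <int>, body = <list>)`; the body is a BrAPI
#'   response envelope ready for JSON serialisation.
#' @export
proxy_handle <- function(proxy, method = "GET", path = "/", query = list(),
                         headers = character()) {
  stopifnot(inherits(proxy, "brapi_proxy"))
  path <- sub("^/brapi/v2(\\.[0-9]+)?", "", path)
  path <- sub("[?].*$", "", path)
  segs <- strsplit(sub("^/", "", sub("/$", "", path)), "/", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs)]
  if (!identical(toupper(method), "GET")) {
    return(list(status = 405L, body = error_body("only GET is supported")))
  }
  if (length(segs) == 0L) {
    return(list(status = 404L, body = error_body("no such endpoint")))
  }
  endpoint <- segs[[1]]
  offered <- proxy_endpoints(proxy)
  if (identical(endpoint, "serverinfo")) {
    return(list(status = 200L, body = serverinfo_payload(proxy)))
  }
  if (identical(endpoint, "openapi.json")) {
    return(list(status = 200L, body = openapi_document(proxy)))
  }
  if (!(endpoint %in% offered) || length(segs) > 2L) {
    return(list(status = 404L, body = error_body(sprintf("no such endpoint: %s", path))))
  }
  if (!authorized(proxy, headers)) {
    return(list(status = 401L, body = error_body("missing or invalid bearer token")))
  }

  handle <- function() {
    if (identical(endpoint, "commoncropnames")) {
      return(list(status = 200L, body = commoncropnames_body(proxy, query)))
    }
    if (identical(endpoint, "allelematrix")) {
      page <- filtered_matrix(query, proxy$client, proxy$config)
      return(list(status = 200L,
                  body = matrix_page_body(page, proxy$config$missingGenotype)))
    }
    if (length(segs) == 2L) {
      return(single_record_response(proxy, endpoint, segs[[2]]))
    }
    page_no <- as.integer(query[["page"]] %||% 0L)
    pageSize <- as.integer(query[["pageSize"]] %||% 1000L)
    filters <- query[setdiff(names(query), c("page", "pageSize"))]
    page <- federated_list_page(endpoint, filters, page_no, pageSize,
                                proxy$client, proxy$config, cache = proxy$cache)
    list(status = 200L, body = list_page_body(page))
  }

  tryCatch(
    handle(),
    brapifed_unresolvable_id = function(c) {
      list(status = 404L, body = error_body(conditionMessage(c)))
    },
    brapifed_error = function(c) {
      status <- if (!is.null(c$status) && c$status >= 400 && c$status < 600) 502L else 502L
      list(status = status, body = error_body(conditionMessage(c)))
    }
  )
}

commoncropnames_body <- function(proxy, query) {
  crops <- character(0)
  for (b in proxy$config$backends) {
    if (!("commoncropnames" %in% b$endpoints)) next
    pg <- fetch_page(proxy$client, b, "commoncropnames", list(), 0L, 100L)
    crops <- c(crops, unlist(pg$records, use.names = FALSE))
  }
  crops <- unique(crops)
  page <- as.integer(query[["page"]] %||% 0L)
  pageSize <- as.integer(query[["pageSize"]] %||% 1000L)
  lo <- page * pageSize
  sel <- if (lo >= length(crops)) character(0) else
    crops[seq.int(lo + 1L, min(lo + pageSize, length(crops)))]
  brapi_envelope(as.list(sel), page, pageSize, length(crops))
}

single_record_response <- function(proxy, endpoint, id) {
  res <- resolve_id(id, proxy$config)
  b <- res$backend
  if (!(endpoint %in% b$endpoints)) {
    return(list(status = 404L, body = error_body(
      sprintf("backend '%s' owning '%s' does not serve '%s'", b$name, id, endpoint)
    )))
  }
  field <- endpoint_id_field(endpoint)
  pg <- fetch_page(proxy$client, b, endpoint, setNames(list(res$localId), field), 0L, 2L)
  if (length(pg$records) == 0L) {
    return(list(status = 404L, body = error_body(sprintf("%s '%s' not found", endpoint, id))))
  }
  record <- namespace_record(pg$records[[1]], b, proxy$config$separator)
  list(status = 200L, body = list(
    metadata = list(
      pagination = list(currentPage = 0L, pageSize = 1L, totalCount = 1L, totalPages = 1L),
      status = list(), datafiles = list()
    ),
    result = record
  ))
}

#' The aggregated serverinfo payload
#'
#' Advertises exactly the endpoints the proxy routes (see
#' [proxy_endpoints()]), each as a GET call with JSON content, tagged
#' BrAPI v2.1.
#'
#' @param proxy a `brapi_proxy`.
#' @return a BrAPI serverinfo envelope (list).
#' @export
serverinfo_payload <- function(proxy) {
  calls <- lapply(proxy_endpoints(proxy), function(e) {
    list(
      service = e,
      methods = list("GET"),
      versions = list("2.1"),
      contentTypes = list("application/json"),
      dataTypes = list("application/json")
    )
  })
  list(
    metadata = list(
      pagination = list(currentPage = 0L, pageSize = length(calls),
                        totalCount = length(calls), totalPages = 1L),
      status = list(), datafiles = list()
    ),
    result = list(
      serverName = "brapifed",
      serverDescription = "federated BrAPI proxy",
      organizationName = "brapifed",
      contactEmail = "author@example.org",
      documentationURL = "",
      location = "",
      calls = calls
    )
  )
}

openapi_parameter <- function(name, where = "query", type = "integer",
                              required = NULL, description = "") {
  compact(list(
    name = name, `in` = where,
    required = if (identical(where, "path")) TRUE else required,
    description = description,
    schema = list(type = type)
  ))
}

paging_parameters <- function() {
  list(
    openapi_parameter("page", description = "0-based federated page index"),
    openapi_parameter("pageSize", description = "items per federated page")
  )
}

#' Generate the OpenAPI description of the federated interface
#'
#' The document enumerates exactly the endpoints [proxy_endpoints()]
#' advertises -- list endpoints with federated paging and their
#' identifier filters, single-record paths, and the allele matrix with its
#' four 2D-paging parameters -- so Swagger-style middleware can be built
#' against the proxy.  A `bearerAuth` security scheme is declared when
#' proxy tokens are configured.
#'
#' @param proxy a `brapi_proxy`.
#' @return the OpenAPI 3.0 document as a nested list (serialise with
#'   `jsonlite::toJSON(doc, auto_unbox = TRUE)`).
#' @export
openapi_document <- function(proxy) {
  eps <- proxy_endpoints(proxy)
  paths <- list()
  op <- function(summary, parameters = list(), secured = TRUE) {
    o <- list(
      summary = summary,
      parameters = parameters,
      responses = list(
        "200" = list(description = "BrAPI response envelope"),
        "401" = list(description = "missing or invalid bearer token"),
        "404" = list(description = "unknown endpoint or identifier"),
        "502" = list(description = "backend federation failure")
      )
    )
    if (secured && length(proxy$config$serverTokens)) {
      o$security <- list(list(bearerAuth = list()))
    }
    o
  }
  for (e in eps) {
    if (e == "serverinfo") {
      paths[["/serverinfo"]] <- list(get = op("aggregated service description", secured = FALSE))
    } else if (e == "commoncropnames") {
      paths[["/commoncropnames"]] <- list(get = op("union of backend crop names", paging_parameters()))
    } else if (e == "allelematrix") {
      params <- c(
        lapply(c("dimensionVariantPage", "dimensionVariantPageSize",
                 "dimensionCallSetPage", "dimensionCallSetPageSize"),
               openapi_parameter),
        lapply(c("variantDbId", "callSetDbId", "sampleDbId", "germplasmDbId"),
               openapi_parameter, type = "string")
      )
      paths[["/allelematrix"]] <- list(get = op("merged 2D-paged allele matrix", params))
    } else {
      idf <- endpoint_id_field(e)
      params <- c(paging_parameters(), list(openapi_parameter(idf, type = "string")))
      if (e == "observations") {
        params <- c(params, list(
          openapi_parameter("germplasmDbId", type = "string"),
          openapi_parameter("observationVariableName", type = "string")
        ))
      }
      if (e %in% c("samples", "callsets")) {
        params <- c(params, list(openapi_parameter(
          if (e == "samples") "germplasmDbId" else "sampleDbId", type = "string"
        )))
      }
      paths[[paste0("/", e)]] <- list(get = op(paste("federated", e, "list"), params))
      paths[[paste0("/", e, "/{", idf, "}")]] <- list(
        get = op(paste("single", e, "record by namespaced id"),
                 list(openapi_parameter(idf, where = "path", type = "string")))
      )
    }
  }
  doc <- list(
    openapi = "3.0.3",
    info = list(
      title = "brapifed federated BrAPI endpoint",
      version = "2.1",
      description = "Merged view over the configured backend BrAPI endpoints."
    ),
    paths = paths
  )
  if (length(proxy$config$serverTokens)) {
    doc$components <- list(securitySchemes = list(
      bearerAuth = list(type = "http", scheme = "bearer")
    ))
  }
  doc
}

#' Structurally validate an OpenAPI 3.x document
#'
#' Checks the constraints the OpenAPI 3.0 schema imposes on the parts of
#' the language the proxy emits: version string, `info` with title and
#' version, non-empty `paths` keyed by `/`-prefixed templates, operations
#' restricted to HTTP methods with non-empty `responses`, parameters with
#' `name`/`in`/`schema` (path parameters required and declared in the
#' template).
#'
#' @param doc an OpenAPI document as a nested list.
#' @return `TRUE` when valid, otherwise `FALSE` with the problems in
#'   `attr(, "errors")`.
#' @export
validate_openapi <- function(doc) {
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)
  if (!is_string(doc$openapi %||% "") || !grepl("^3\\.", doc$openapi)) {
    note("openapi version must be a '3.x' string")
  }
  if (!is_string(doc$info$title %||% "") || !nzchar(doc$info$title %||% "")) {
    note("info.title is required")
  }
  if (!is_string(doc$info$version %||% "")) note("info.version is required")
  paths <- doc$paths
  if (!is.list(paths) || length(paths) == 0L) {
    note("paths must be a non-empty object")
    paths <- list()
  }
  methods <- c("get", "put", "post", "delete", "options", "head", "patch", "trace")
  for (p in names(paths)) {
    if (!startsWith(p, "/")) note(sprintf("path '%s' must start with '/'", p))
    tmpl_params <- regmatches(p, gregexpr("\\{[^}]+\\}", p))[[1]]
    tmpl_params <- gsub("[{}]", "", tmpl_params)
    ops <- paths[[p]][names(paths[[p]]) %in% methods]
    if (length(ops) == 0L) note(sprintf("path '%s' has no operations", p))
    for (m in names(ops)) {
      o <- ops[[m]]
      if (!is.list(o$responses) || length(o$responses) == 0L) {
        note(sprintf("%s %s: responses must be non-empty", toupper(m), p))
      }
      declared_path_params <- character(0)
      for (par in o$parameters %||% list()) {
        if (!is_string(par$name %||% "")) note(sprintf("%s %s: parameter without name", toupper(m), p))
        if (!(par$`in` %||% "") %in% c("query", "path", "header", "cookie")) {
          note(sprintf("%s %s: parameter '%s' has invalid 'in'", toupper(m), p, par$name %||% "?"))
        }
        if (identical(par$`in`, "path")) {
          if (!isTRUE(par$required)) {
            note(sprintf("%s %s: path parameter '%s' must be required", toupper(m), p, par$name))
          }
          declared_path_params <- c(declared_path_params, par$name)
        }
        if (is.null(par$schema) && is.null(par$content)) {
          note(sprintf("%s %s: parameter '%s' needs a schema", toupper(m), p, par$name %||% "?"))
        }
      }
      for (tp in tmpl_params) {
        if (!(tp %in% declared_path_params)) {
          note(sprintf("%s %s: template parameter '%s' not declared", toupper(m), p, tp))
        }
      }
    }
  }
  ok <- length(errs) == 0L
  if (!ok) attr(ok, "errors") <- errs
  ok
}
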