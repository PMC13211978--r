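#' Endpoints the proxy knows how to federate
#'
#' The federated surface covers the BrAPI v2.1 core entity endpoints plus
#' the allele matrix and the service descriptors.
#' @keywords internal
KNOWN_ENDPOINTS <- c(
  "commoncropnames", "germplasm", "samples", "studies", "observations",
  "variants", "callsets", "allelematrix"
)

#' Describe one backend BrAPI endpoint
#'
#' @param name short label, unique within the federation.
#' @param baseUrl base URL of the backend BrAPI root (e.g.
#'   `"https://host/brapi/v2"`). For purely in-process mock federations a
#'   placeholder such as `"mock://pheno"` is fine.
#' @param prefix identifier prefix (possibly `""`). All `DbId` values owned
#'   by this backend are exposed as `prefix + separator + localId`; the
#'   empty prefix designates the fallback backend for unprefixed ids.
#' @param authToken optional bearer token forwarded to the backend.
#'   `"${VAR}"` is interpolated from the environment at load time.
#' @param endpoints character vector of endpoint names this backend serves
#'   (subset of `KNOWN_ENDPOINTS`).
#' @param timeout request timeout in seconds (default 30; allele-matrix
#'   pages from array-store backends can be slow).
#' @return a `backend_config` object.
#' @export
backend_config <- function(name, baseUrl, prefix = "", authToken = NULL,
                           endpoints = KNOWN_ENDPOINTS, timeout = 30) {
  if (!is_string(name) || !nzchar(name)) {
    stop_brapifed("brapifed_config_error", "backend name must be a non-empty string")
  }
  if (!is_string(baseUrl)) stop_brapifed("brapifed_config_error", "baseUrl must be a string")
  if (!is.character(prefix) || length(prefix) != 1L || is.na(prefix)) {
    stop_brapifed("brapifed_config_error", "prefix must be a single string (possibly empty)")
  }
  endpoints <- unique(as.character(endpoints))
  unknown <- setdiff(endpoints, KNOWN_ENDPOINTS)
  if (length(unknown)) {
    stop_brapifed(
      "brapifed_config_error",
      sprintf("backend '%s': unknown endpoint(s): %s", name, paste(unknown, collapse = ", "))
    )
  }
  structure(
    list(
      name = name, baseUrl = sub("/+$", "", baseUrl), prefix = prefix,
      authToken = if (is.null(authToken)) NULL else as.character(authToken),
      endpoints = endpoints, timeout = as.numeric(timeout)
    ),
    class = "backend_config"
  )
}

#' Assemble and validate a federation configuration
#'
#' The order of `backends` is load-bearing: it defines the concatenation
#' order of merged lists and matrix axes, so it must be stable across
#' requests.  Prefix validity is enforced here, at configuration time, so
#' identifier resolution can never be ambiguous at request time:
#' non-empty prefixes must be pairwise distinct and prefix-free (none a
#' leading substring of another), and at most one backend may carry the
#' empty prefix (the fallback for unprefixed identifiers).
#'
#' @param backends list of [backend_config()] objects (non-empty).
#' @param serverTokens character vector of accepted proxy bearer tokens;
#'   empty means the proxy is open (public phase).
#' @param separator string placed between prefix and local id (default
#'   `"-"`). It may also occur inside local ids: resolution matches the
#'   longest configured `prefix + separator` head, it never splits on the
#'   separator.
#' @param missingGenotype fill string for allele-matrix cells that pair a
#'   variant and a callset from different backends (default `"."`, the VCF
#'   missing-call convention).
#' @param onBackendError `"fail"` (default) to fail a federated request
#'   when a backend is unreachable, or `"degrade"` to exclude the backend
#'   and attach a warning status.
#' @param port port for the HTTP front end (used by [serve_federation()]).
#' @return a `federation_config` object.
#' @export
federation_config <- function(backends, serverTokens = character(),
                              separator = "-", missingGenotype = ".",
                              onBackendError = c("fail", "degrade"),
                              port = 8080L) {
  onBackendError <- match.arg(onBackendError)
  if (!is.list(backends) || length(backends) == 0L) {
    stop_brapifed("brapifed_config_error", "a federation needs at least one backend")
  }
  if (!all(vapply(backends, inherits, logical(1), "backend_config"))) {
    stop_brapifed("brapifed_config_error", "backends must be backend_config objects")
  }
  nms <- vapply(backends, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_brapifed("brapifed_config_error", "backend names must be unique")
  }
  prefixes <- vapply(backends, `[[`, character(1), "prefix")
  if (sum(prefixes == "") > 1L) {
    stop_brapifed(
      "brapifed_config_error",
      "at most one backend may have an empty prefix (the fallback backend)"
    )
  }
  nonempty <- prefixes[prefixes != ""]
  if (anyDuplicated(nonempty)) {
    stop_brapifed("brapifed_config_error", "non-empty prefixes must be pairwise distinct")
  }
  for (a in nonempty) {
    for (b in nonempty) {
      if (a != b && startsWith(b, a)) {
        stop_brapifed(
          "brapifed_config_error",
          sprintf("prefix '%s' is a leading substring of prefix '%s'; prefixes must be prefix-free", a, b)
        )
      }
    }
  }
  if (!is_string(separator)) {
    stop_brapifed("brapifed_config_error", "separator must be a single string")
  }
  if (nzchar(separator) == FALSE && length(nonempty)) {
    stop_brapifed("brapifed_config_error", "separator must be non-empty when prefixes are used")
  }
  names(backends) <- nms
  structure(
    list(
      backends = backends,
      serverTokens = as.character(serverTokens),
      separator = separator,
      missingGenotype = as.character(missingGenotype),
      onBackendError = onBackendError,
      port = as.integer(port)
    ),
    class = "federation_config"
  )
}

#' @export
print.federation_config <- function(x, ...) {
  cat(sprintf(
    "<federation_config> %d backend(s), separator '%s', fill '%s', %s\n",
    length(x$backends), x$separator, x$missingGenotype,
    if (length(x$serverTokens)) "token-protected" else "open access"
  ))
  for (b in x$backends) {
    cat(sprintf(
      "  %-12s prefix='%s'  %s  [%s]\n",
      b$name, b$prefix, b$baseUrl, paste(b$endpoints, collapse = ", ")
    ))
  }
  invisible(x)
}

interpolate_env <- function(x) {
  if (is.null(x) || !is.character(x)) return(x)
  m <- regmatches(x, gregexpr("\\$\\{[A-Za-z_][A-Za-z0-9_]*\\}", x))[[1]]
  for (tok in unique(m)) {
    var <- substr(tok, 3, nchar(tok) - 1L)
    x <- gsub(tok, Sys.getenv(var, unset = ""), x, fixed = TRUE)
  }
  x
}

#' Load a federation configuration file
#'
#' Reads the YAML configuration dialect: top-level `server` (port, tokens),
#' `federation` (separator, missingGenotype, onBackendError) and `backends`
#' (list of `{name, baseUrl, prefix, authToken, endpoints}`).  `${VAR}`
#' occurrences in token strings are interpolated from environment
#' variables, so secrets need not live in the file.  Structural problems --
#' duplicate or nested prefixes, more than one empty prefix, zero backends,
#' unknown endpoint names -- are rejected here rather than surfacing as
#' request-time ambiguity.
#'
#' @param path path to a YAML configuration file.
#' @return a validated [federation_config()] object.
#' @seealso [save_config()] for the inverse; the two round-trip.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_brapifed("brapifed_config_error", sprintf("config file not found: %s", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_brapifed(
      "brapifed_config_error",
      sprintf("cannot parse config file %s: %s", path, conditionMessage(e))
    )
  )
  if (!is.list(raw) || is.null(raw$backends)) {
    stop_brapifed("brapifed_config_error", "config must contain a 'backends' list")
  }
  backends <- lapply(raw$backends, function(b) {
    backend_config(
      name = b$name %||% stop_brapifed("brapifed_config_error", "every backend needs a name"),
      baseUrl = b$baseUrl %||% "",
      prefix = b$prefix %||% "",
      authToken = {
        tok <- interpolate_env(b$authToken)
        if (is.null(tok) || !nzchar(tok)) NULL else tok
      },
      endpoints = b$endpoints %||% KNOWN_ENDPOINTS,
      timeout = b$timeout %||% 30
    )
  })
  fed <- raw$federation %||% list()
  srv <- raw$server %||% list()
  tokens <- unlist(lapply(srv$tokens %||% character(), interpolate_env))
  tokens <- tokens[nzchar(tokens)]
  federation_config(
    backends = backends,
    serverTokens = tokens,
    separator = fed$separator %||% "-",
    missingGenotype = fed$missingGenotype %||% ".",
    onBackendError = fed$onBackendError %||% "fail",
    port = srv$port %||% 8080L
  )
}

#' Write a federation configuration back to YAML
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg` (tokens are
#' written literally, so configurations that used environment interpolation
#' round-trip to their interpolated form).
#'
#' @param config a [federation_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "federation_config"))
  out <- list(
    server = list(
      port = config$port,
      tokens = as.list(config$serverTokens)
    ),
    federation = list(
      separator = config$separator,
      missingGenotype = config$missingGenotype,
      onBackendError = config$onBackendError
    ),
    backends = lapply(unname(config$backends), function(b) {
      compact(list(
        name = b$name, baseUrl = b$baseUrl, prefix = b$prefix,
        authToken = b$authToken, endpoints = as.list(b$endpoints),
        timeout = b$timeout
      ))
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
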