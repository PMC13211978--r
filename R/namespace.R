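#' Map a DbId attribute name to the endpoint that owns the entity
#'
#' BrAPI links entities through `...DbId` attributes (its foreign keys).
#' The attribute stem tells which entity -- and therefore which endpoint --
#' an identifier refers to.  Stems outside this table (e.g. `referenceDbId`)
#' are treated as backend-internal.
#' @return endpoint name, or `NA_character_` for an unknown stem.
#' @keywords internal
#' @noRd
dbid_entity <- function(field) {
  stem <- sub("DbIds?$", "", field)
  switch(stem,
    germplasm = "germplasm",
    sample = "samples",
    study = "studies",
    observation = "observations",
    variant = "variants",
    callSet = "callsets",
    NA_character_
  )
}

is_dbid_field <- function(field) grepl("DbIds?$", field)

#' Render a namespaced identifier
#'
#' @param prefix backend prefix (possibly `""`).
#' @param localId backend-local identifier(s).
#' @param separator separator between prefix and local id.
#' @return character vector: `prefix + separator + localId`, or `localId`
#'   unchanged when the prefix is empty.
#' @export
render_id <- function(prefix, localId, separator = "-") {
  if (!nzchar(prefix)) return(as.character(localId))
  ifelse(is.na(localId), NA_character_, paste0(prefix, separator, localId))
}

#' Resolve a namespaced identifier to its owning backend
#'
#' Resolution matches the longest configured `prefix + separator` head of
#' the rendered id (never splitting on the separator, which may legally
#' occur inside local ids).  When no prefixed backend matches and a
#' fallback backend (empty prefix) is configured, the id is attributed to
#' the fallback unchanged.
#'
#' @param renderedId a single namespaced identifier.
#' @param config a [federation_config()].
#' @return list with elements `backend` (a `backend_config`) and `localId`.
#' @export
resolve_id <- function(renderedId, config) {
  stopifnot(inherits(config, "federation_config"), is_string(renderedId))
  best <- NULL
  best_len <- -1L
  fallback <- NULL
  for (b in config$backends) {
    if (!nzchar(b$prefix)) {
      fallback <- b
      next
    }
    head <- paste0(b$prefix, config$separator)
    if (startsWith(renderedId, head) && nchar(b$prefix) > best_len) {
      best <- b
      best_len <- nchar(b$prefix)
    }
  }
  if (!is.null(best)) {
    return(list(
      backend = best,
      localId = substr(renderedId, nchar(best$prefix) + nchar(config$separator) + 1L, nchar(renderedId))
    ))
  }
  if (!is.null(fallback)) {
    return(list(backend = fallback, localId = renderedId))
  }
  stop_brapifed(
    "brapifed_unresolvable_id",
    sprintf("identifier '%s' matches no configured prefix and no fallback backend exists", renderedId),
    id = renderedId
  )
}

#' Vectorised resolution: backend name per id (NA when unresolvable)
#' @noRd
resolve_ids <- function(ids, config) {
  n <- length(ids)
  owner <- rep(NA_character_, n)
  local <- as.character(ids)
  prefixed <- Filter(function(b) nzchar(b$prefix), config$backends)
  if (length(prefixed)) {
    ord <- order(vapply(prefixed, function(b) nchar(b$prefix), integer(1)), decreasing = TRUE)
    for (b in prefixed[ord]) {
      head <- paste0(b$prefix, config$separator)
      hit <- is.na(owner) & startsWith(local, head)
      if (any(hit)) {
        owner[hit] <- b$name
        local[hit] <- substr(ids[hit], nchar(head) + 1L, nchar(ids[hit]))
      }
    }
  }
  fallback <- Filter(function(b) !nzchar(b$prefix), config$backends)
  if (length(fallback)) {
    owner[is.na(owner)] <- fallback[[1]]$name
  }
  data.frame(id = as.character(ids), owner = owner, localId = local, stringsAsFactors = FALSE)
}

prefix_id_values <- function(value, prefix, separator) {
  if (is.character(value)) {
    return(render_id(prefix, value, separator))
  }
  if (is.list(value)) {
    return(lapply(value, prefix_id_values, prefix = prefix, separator = separator))
  }
  value
}

#' Namespace every owned identifier in an entity record
#'
#' Walks a raw backend record (arbitrarily nested lists) and prepends
#' `prefix + separator` to every attribute whose name ends in `DbId` or
#' `DbIds` -- including elements of list-valued identifier attributes --
#' provided the backend owns the referenced entity.  A backend owns an
#' identifier when the entity's endpoint is among the backend's served
#' endpoints, or when the attribute stem is not a cross-endpoint link (such
#' identifiers are backend-internal).  Identifiers of entities served
#' elsewhere in the federation are passed through untouched: backends store
#' such cross-backend references already in their global form.  All
#' non-identifier attributes are returned byte-identical; with an empty
#' prefix the record is unchanged.
#'
#' @param record a named list (one BrAPI entity record).
#' @param backend the [backend_config()] the record came from.
#' @param separator the federation separator.
#' @return the namespaced record.
#' @export
namespace_record <- function(record, backend, separator = "-") {
  if (!nzchar(backend$prefix) || !is.list(record)) return(record)
  nms <- names(record)
  if (is.null(nms)) {
    # unnamed container (e.g. a list of sub-records): recurse into elements
    return(lapply(record, namespace_record, backend = backend, separator = separator))
  }
  for (i in seq_along(record)) {
    nm <- nms[[i]]
    v <- record[[i]]
    if (nzchar(nm) && is_dbid_field(nm)) {
      entity <- dbid_entity(nm)
      owned <- is.na(entity) || entity %in% backend$endpoints
      if (owned) {
        record[[i]] <- prefix_id_values(v, backend$prefix, separator)
      }
    } else if (is.list(v)) {
      record[[i]] <- namespace_record(v, backend = backend, separator = separator)
    }
  }
  record
}

#' Route identifier filters to the backends that own them
#'
#' Partitions a query-parameter map into per-backend localized parameter
#' maps.  Identifier filters (attribute names ending `DbId`/`DbIds`, scalar
#' or list-valued) are resolved value by value: a value owned by the
#' backend is localized (prefix stripped); a value referring to an entity
#' the backend does not serve is forwarded verbatim (backends store
#' cross-backend references in global form); a value owned by a different
#' backend for an entity this backend does serve is dropped.  Unresolvable
#' values are dropped rather than raised -- BrAPI filters are match-based,
#' so they simply match nothing.  A backend left with no values for some
#' identifier filter is marked `skip` and must receive no call.
#' Non-identifier filters are forwarded verbatim to every non-skipped
#' backend.
#'
#' @param params named list of query parameters (values may be vectors).
#' @param config a [federation_config()].
#' @param endpoint optional endpoint name; backends not serving it are
#'   marked `skip` outright.
#' @return named list (one entry per backend) of
#'   `list(skip = logical, params = named list)`.
#' @export
route_filters <- function(params, config, endpoint = NULL) {
  stopifnot(inherits(config, "federation_config"))
  params <- params %||% list()
  id_fields <- names(params)[vapply(names(params) %||% character(), is_dbid_field, logical(1))]
  plain <- params[setdiff(names(params), id_fields)]
  resolved <- lapply(params[id_fields], function(v) resolve_ids(unlist(v, use.names = FALSE), config))

  out <- lapply(config$backends, function(b) {
    if (!is.null(endpoint) && !(endpoint %in% b$endpoints)) {
      return(list(skip = TRUE, params = list()))
    }
    localized <- plain
    for (f in id_fields) {
      rs <- resolved[[f]]
      entity <- dbid_entity(f)
      foreign_link <- !is.na(entity) && !(entity %in% b$endpoints)
      if (foreign_link) {
        keep <- rs$id
      } else {
        keep <- rs$localId[!is.na(rs$owner) & rs$owner == b$name]
      }
      if (length(keep) == 0L) {
        return(list(skip = TRUE, params = list()))
      }
      localized[[f]] <- keep
    }
    list(skip = FALSE, params = localized)
  })
  names(out) <- names(config$backends)
  out
}
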