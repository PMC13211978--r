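axis_windows <- function(page, pageSize, totals) {
  totals <- as.integer(totals)
  start <- as.integer(page) * as.integer(pageSize)
  end <- min(start + as.integer(pageSize), sum(totals))
  per_backend <- vector("list", length(totals))
  offset <- 0L
  if (end > start) {
    for (i in seq_along(totals)) {
      lo <- max(start - offset, 0L)
      hi <- min(end - offset, totals[i])
      if (hi > lo) {
        per_backend[[i]] <- list(
          slice = c(lo, hi),
          pages = seq.int(lo %/% pageSize, (hi - 1L) %/% pageSize)
        )
      }
      offset <- offset + totals[i]
    }
  }
  list(window = c(start, end), per_backend = per_backend)
}

#' Plan the backend fetches realizing one 2D allele-matrix page
#'
#' The merged matrix axes are the concatenations of the backend axes in
#' configuration order, so the requested `(variantPage, callSetPage)`
#' window intersects each backend in an axis-aligned sub-rectangle.  For
#' each axis the plan records the backend-local slice and the local page
#' indices covering it (at most two per axis, as for lists).  A backend
#' intersecting only one axis still contributes labels for that axis: its
#' rows or columns exist in the window even though all its cells pair with
#' another backend's axis and therefore take the fill value.
#'
#' @param variantPage,variantPageSize,callSetPage,callSetPageSize requested
#'   2D page (0-based, sizes >= 1).
#' @param variantTotals,callSetTotals per-backend axis totals, in backend
#'   order (0 for skipped backends).
#' @return a `matrix_plan`: per-backend variant/callset subplans plus the
#'   global windows and the totals.
#' @export
plan_matrix_window <- function(variantPage, variantPageSize,
                               callSetPage, callSetPageSize,
                               variantTotals, callSetTotals) {
  stopifnot(
    is_count(variantPage), is_count(variantPageSize, positive = TRUE),
    is_count(callSetPage), is_count(callSetPageSize, positive = TRUE),
    length(variantTotals) == length(callSetTotals)
  )
  v <- axis_windows(variantPage, variantPageSize, variantTotals)
  c_ <- axis_windows(callSetPage, callSetPageSize, callSetTotals)
  structure(
    list(
      variantPage = as.integer(variantPage),
      variantPageSize = as.integer(variantPageSize),
      callSetPage = as.integer(callSetPage),
      callSetPageSize = as.integer(callSetPageSize),
      variantTotals = as.integer(variantTotals),
      callSetTotals = as.integer(callSetTotals),
      variantWindow = v$window, callSetWindow = c_$window,
      subplans = lapply(seq_along(variantTotals), function(i) {
        list(backend_index = i, variants = v$per_backend[[i]], callsets = c_$per_backend[[i]])
      })
    ),
    class = "matrix_plan"
  )
}

slice_fetched_axis <- function(labels, sub, pageSize) {
  base <- sub$pages[1] * pageSize
  idx <- seq.int(sub$slice[1] - base + 1L, sub$slice[2] - base)
  if (max(idx) > length(labels)) {
    stop_brapifed(
      "brapifed_stale_total",
      "allele-matrix axis shorter than probed total"
    )
  }
  list(labels = labels[idx], idx = idx)
}

#' Fetch one backend's contribution to a planned matrix window
#'
#' Issues one allele-matrix call per (local variant page x local callset
#' page) tile, stitches the tiles, and cuts the planned local slices.  A
#' backend intersecting only one axis is fetched with the other dimension
#' at size 1 purely to read the axis labels.
#' @return `list(variantDbIds, callSetDbIds, matrices)` (local ids;
#'   `matrices` named list of character grids), or axis labels with
#'   `matrices = NULL` when only one axis intersects.
#' @noRd
fetch_backend_block <- function(client, backend, params, sub, plan) {
  vsub <- sub$variants
  csub <- sub$callsets
  vps <- plan$variantPageSize
  cps <- plan$callSetPageSize
  blk_names <- function(blk) {
    vapply(blk$dataMatrices, `[[`, character(1), "dataMatrixName")
  }
  if (is.null(vsub) && is.null(csub)) {
    return(list(variantDbIds = character(0), callSetDbIds = character(0),
                matrices = NULL, matrix_names = character(0)))
  }
  if (is.null(csub)) {
    labels <- character(0)
    nms <- character(0)
    for (vp in vsub$pages) {
      blk <- fetch_matrix(client, backend, params, vp, vps, 0L, 1L)
      labels <- c(labels, blk$variantDbIds)
      nms <- union(nms, blk_names(blk))
    }
    v <- slice_fetched_axis(labels, vsub, vps)
    return(list(variantDbIds = v$labels, callSetDbIds = character(0),
                matrices = NULL, matrix_names = nms))
  }
  if (is.null(vsub)) {
    labels <- character(0)
    nms <- character(0)
    for (cp in csub$pages) {
      blk <- fetch_matrix(client, backend, params, 0L, 1L, cp, cps)
      labels <- c(labels, blk$callSetDbIds)
      nms <- union(nms, blk_names(blk))
    }
    c_ <- slice_fetched_axis(labels, csub, cps)
    return(list(variantDbIds = character(0), callSetDbIds = c_$labels,
                matrices = NULL, matrix_names = nms))
  }
  vlabels <- character(0)
  clabels <- character(0)
  mats <- list()   # name -> list of row-strips
  row_strips <- list()
  for (vp in vsub$pages) {
    strip <- NULL
    strip_names <- NULL
    for (cp in csub$pages) {
      blk <- fetch_matrix(client, backend, params, vp, vps, cp, cps)
      if (cp == csub$pages[1]) {
        vlabels <- c(vlabels, blk$variantDbIds)
      }
      if (vp == vsub$pages[1]) {
        clabels <- c(clabels, blk$callSetDbIds)
      }
      tile_by_name <- setNames(
        lapply(blk$dataMatrices, `[[`, "values"),
        vapply(blk$dataMatrices, `[[`, character(1), "dataMatrixName")
      )
      if (is.null(strip)) {
        strip <- tile_by_name
        strip_names <- vapply(blk$dataMatrices, function(m) m$dataType, character(1))
        names(strip_names) <- names(tile_by_name)
      } else {
        for (nm in names(strip)) {
          strip[[nm]] <- cbind(strip[[nm]], tile_by_name[[nm]])
        }
      }
    }
    row_strips[[length(row_strips) + 1L]] <- strip
    if (vp == vsub$pages[1]) mats$types <- strip_names
  }
  full <- list()
  for (nm in names(row_strips[[1]])) {
    full[[nm]] <- do.call(rbind, lapply(row_strips, `[[`, nm))
  }
  v <- slice_fetched_axis(vlabels, vsub, vps)
  c_ <- slice_fetched_axis(clabels, csub, cps)
  list(
    variantDbIds = v$labels, callSetDbIds = c_$labels,
    matrices = lapply(full, function(m) m[v$idx, c_$idx, drop = FALSE]),
    dataTypes = mats$types, matrix_names = names(full)
  )
}

namespace_axis <- function(ids, backend, entity, separator) {
  if (!nzchar(backend$prefix) || !(entity %in% backend$endpoints)) return(ids)
  render_id(backend$prefix, ids, separator)
}

#' Assemble fetched backend blocks into one merged 2D matrix page
#'
#' The merged axes are the window slices of the concatenated, namespaced
#' backend axes.  Each cell pairing a variant and a callset from the same
#' backend is copied byte-for-byte from that backend's grid; every
#' cross-backend cell takes the configured missing-genotype fill -- no
#' backend can genotype another backend's samples, so the merged matrix is
#' block-diagonal.  Data matrices are matched across backends by
#' `dataMatrixName`; a name served by only some backends is still emitted,
#' with fill over the others' blocks.
#'
#' @param plan a `matrix_plan` from [plan_matrix_window()].
#' @param blocks per-backend fetched blocks (internal layout; produced by
#'   [filtered_matrix()]'s fetch stage).
#' @param fill the missing-genotype fill string.
#' @param config a [federation_config()].
#' @param status statuses to carry through.
#' @return a merged matrix page: `list(variantDbIds, callSetDbIds,
#'   dataMatrices, pagination, status)` with `pagination` carrying one
#'   [matrix_pagination()] entry per dimension.
#' @export
assemble_matrix <- function(plan, blocks, fill, config, status = list()) {
  stopifnot(inherits(plan, "matrix_plan"))
  variants <- character(0)
  callsets <- character(0)
  spans <- list()
  for (i in seq_along(blocks)) {
    b <- config$backends[[plan$subplans[[i]]$backend_index]]
    blk <- blocks[[i]]
    v_ids <- namespace_axis(blk$variantDbIds, b, "variants", config$separator)
    c_ids <- namespace_axis(blk$callSetDbIds, b, "callsets", config$separator)
    spans[[i]] <- list(
      rows = if (length(v_ids)) seq.int(length(variants) + 1L, length(variants) + length(v_ids)) else integer(0),
      cols = if (length(c_ids)) seq.int(length(callsets) + 1L, length(callsets) + length(c_ids)) else integer(0)
    )
    variants <- c(variants, v_ids)
    callsets <- c(callsets, c_ids)
  }
  mat_names <- unique(unlist(lapply(blocks, function(blk) {
    blk$matrix_names %||% names(blk$matrices)
  })))
  grids <- lapply(mat_names, function(nm) {
    matrix(fill, nrow = length(variants), ncol = length(callsets))
  })
  names(grids) <- mat_names
  types <- setNames(rep("string", length(mat_names)), mat_names)
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    if (is.null(blk$matrices)) next
    for (nm in names(blk$matrices)) {
      grids[[nm]][spans[[i]]$rows, spans[[i]]$cols] <- blk$matrices[[nm]]
      if (!is.null(blk$dataTypes) && !is.na(blk$dataTypes[nm])) {
        types[nm] <- blk$dataTypes[nm]
      }
    }
  }
  list(
    variantDbIds = variants,
    callSetDbIds = callsets,
    dataMatrices = lapply(mat_names, function(nm) {
      list(dataMatrixName = nm, dataType = unname(types[nm]), values = grids[[nm]])
    }),
    pagination = list(
      VARIANTS = matrix_pagination("VARIANTS", plan$variantPage,
                                   plan$variantPageSize, sum(plan$variantTotals)),
      CALLSETS = matrix_pagination("CALLSETS", plan$callSetPage,
                                   plan$callSetPageSize, sum(plan$callSetTotals))
    ),
    status = status
  )
}

probe_matrix_totals <- function(routing, client, config) {
  n <- length(config$backends)
  v <- integer(n)
  c_ <- integer(n)
  excluded <- logical(n)
  status <- list()
  for (i in seq_len(n)) {
    b <- config$backends[[i]]
    r <- routing[[b$name]]
    if (isTRUE(r$skip) || !("allelematrix" %in% b$endpoints)) next
    probe <- tryCatch(
      fetch_matrix(client, b, r$params, 0L, 1L, 0L, 1L),
      brapifed_error = function(c) c
    )
    if (inherits(probe, "condition")) {
      if (identical(config$onBackendError, "degrade")) {
        excluded[i] <- TRUE
        status <- c(status, list(status_message(
          sprintf("backend '%s' excluded: %s", b$name, conditionMessage(probe)),
          "WARNING"
        )))
        next
      }
      stop_brapifed(
        "brapifed_federation_error",
        sprintf("backend '%s' failed while probing the allele matrix: %s",
                b$name, conditionMessage(probe)),
        backend = b$name, status = 502
      )
    }
    v[i] <- probe$pagination$VARIANTS$totalCount
    c_[i] <- probe$pagination$CALLSETS$totalCount
  }
  list(variantTotals = v, callSetTotals = c_, excluded = excluded, status = status)
}

#' Serve one federated allele-matrix page, with filter routing
#'
#' The full matrix pipeline: identifier filters (`variantDbId`,
#' `callSetDbId`, `sampleDbId`, `germplasmDbId`) are routed per
#' [route_filters()]; backends with no matching identifiers are skipped;
#' per-backend filtered axis totals are probed; the 2D window is planned
#' ([plan_matrix_window()]), fetched, and assembled
#' ([assemble_matrix()]).
#'
#' @param params named list: optional identifier filters plus the 2D page
#'   parameters `dimensionVariantPage`, `dimensionVariantPageSize`,
#'   `dimensionCallSetPage`, `dimensionCallSetPageSize` (defaults 0 and
#'   1000).
#' @param client a `brapi_client`.
#' @param config a [federation_config()].
#' @return a merged matrix page (see [assemble_matrix()]).
#' @export
filtered_matrix <- function(params, client, config) {
  params <- params %||% list()
  dim_names <- c("dimensionVariantPage", "dimensionVariantPageSize",
                 "dimensionCallSetPage", "dimensionCallSetPageSize")
  vPage <- as.integer(params[["dimensionVariantPage"]] %||% 0L)
  vSize <- as.integer(params[["dimensionVariantPageSize"]] %||% 1000L)
  cPage <- as.integer(params[["dimensionCallSetPage"]] %||% 0L)
  cSize <- as.integer(params[["dimensionCallSetPageSize"]] %||% 1000L)
  filters <- params[setdiff(names(params), dim_names)]
  routing <- route_filters(filters, config, "allelematrix")
  probe <- probe_matrix_totals(routing, client, config)
  plan <- plan_matrix_window(vPage, vSize, cPage, cSize,
                             probe$variantTotals, probe$callSetTotals)
  blocks <- lapply(plan$subplans, function(sub) {
    b <- config$backends[[sub$backend_index]]
    fetch_backend_block(client, b, routing[[b$name]]$params, sub, plan)
  })
  assemble_matrix(plan, blocks, config$missingGenotype, config, probe$status)
}
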