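#' Connections: how the pipeline talks to a BrAPI endpoint
#'
#' The validation pipeline only needs `function(endpoint, query) ->
#' parsed BrAPI body`, so it runs unchanged against an in-process proxy
#' ([proxy_connection()]) or any live BrAPI base URL
#' ([http_connection()]).
#'
#' @param proxy a `brapi_proxy`.
#' @param token bearer token presented to the endpoint (when required).
#' @return a connection function.
#' @export
proxy_connection <- function(proxy, token = NULL) {
  headers <- if (is.null(token)) character(0) else c(Authorization = paste("Bearer", token))
  function(endpoint, query = list()) {
    resp <- proxy_handle(proxy, "GET", paste0("/", endpoint), query, headers)
    if (resp$status != 200L) {
      stop_brapifed(
        "brapifed_http_error",
        sprintf("endpoint '%s' answered %d", endpoint, resp$status),
        status = resp$status
      )
    }
    resp$body
  }
}

#' @rdname proxy_connection
#' @param baseUrl BrAPI root URL of the endpoint.
#' @export
http_connection <- function(baseUrl, token = NULL) {
  backend <- backend_config("remote", baseUrl, prefix = "", authToken = token)
  handler <- http_backend_handler(backend)
  function(endpoint, query = list()) handler(endpoint, query)
}

#' Describe the marker neighbourhood and trait to validate
#'
#' @param chromosome chromosome label (e.g. `"6H"`).
#' @param position 1-based marker position in bp.
#' @param windowHalfWidth half-width of the selection window in bp
#'   (default 5 kb, wide enough that a confirming variant a few kb from
#'   the literature marker is captured).
#' @param traitName observation-variable label of the trait.
#' @return a `marker_query` object.
#' @export
marker_query <- function(chromosome, position, windowHalfWidth = 5000,
                         traitName = "Plant height") {
  if (!is_count(position, positive = TRUE)) {
    stop_brapifed("brapifed_validation_error", "position must be a positive 1-based integer")
  }
  if (!is.numeric(windowHalfWidth) || windowHalfWidth < 0) {
    stop_brapifed("brapifed_validation_error", "windowHalfWidth must be >= 0")
  }
  structure(
    list(chromosome = as.character(chromosome), position = as.integer(position),
         windowHalfWidth = as.numeric(windowHalfWidth), traitName = as.character(traitName)),
    class = "marker_query"
  )
}

fetch_all_pages <- function(conn, endpoint, params = list(), pageSize = 1000L) {
  records <- list()
  page <- 0L
  repeat {
    body <- conn(endpoint, c(params, list(page = page, pageSize = pageSize)))
    records <- c(records, body$result$data %||% list())
    pg <- body$metadata$pagination
    if (is.null(pg) || page + 1L >= (pg$totalPages %||% 1L)) break
    page <- page + 1L
  }
  records
}

batched <- function(ids, size = 100L) {
  if (length(ids) == 0L) return(list())
  split(ids, ceiling(seq_along(ids) / size))
}

#' Select variants near a genomic position
#'
#' Iterates all pages of the endpoint's `/variants` list and keeps the
#' variants on the query chromosome within
#' `|position - query$position| <= windowHalfWidth`.
#'
#' @param conn a connection (see [proxy_connection()]).
#' @param query a [marker_query()].
#' @param pageSize backend page size used while iterating.
#' @return list of variant records (ids as served, i.e. namespaced when
#'   `conn` is a federated endpoint).
#' @export
find_variants_near <- function(conn, query, pageSize = 1000L) {
  stopifnot(inherits(query, "marker_query"))
  records <- fetch_all_pages(conn, "variants", pageSize = pageSize)
  hit <- vapply(records, function(r) {
    chrom <- as.character(r$referenceName %||% r$chromosome %||% "")
    pos <- suppressWarnings(as.numeric(r$start %||% r$position %||% NA))
    !is.na(pos) && identical(chrom, query$chromosome) &&
      abs(pos - query$position) <= query$windowHalfWidth
  }, logical(1))
  records[hit]
}

normalize_genotype <- function(g) {
  vapply(g, function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.", "")) return(".")
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(".")
    paste(sort(alleles), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

fetch_matrix_by_variants <- function(conn, variant_ids, callset_pageSize = 500L) {
  geno <- NULL
  callsets <- character(0)
  page <- 0L
  repeat {
    body <- conn("allelematrix", list(
      variantDbId = variant_ids,
      dimensionVariantPage = 0L, dimensionVariantPageSize = length(variant_ids),
      dimensionCallSetPage = page, dimensionCallSetPageSize = callset_pageSize
    ))
    res <- body$result
    vids <- as.character(unlist(res$variantDbIds, use.names = FALSE))
    cids <- as.character(unlist(res$callSetDbIds, use.names = FALSE))
    dm <- NULL
    for (m in res$dataMatrices %||% list()) {
      if (identical(m$dataMatrixName %||% "genotype", "genotype")) dm <- m
    }
    tile <- matrix(NA_character_, nrow = length(vids), ncol = length(cids),
                   dimnames = list(vids, cids))
    if (!is.null(dm) && length(vids) && length(cids)) {
      for (i in seq_along(vids)) {
        tile[i, ] <- as.character(unlist(dm$dataMatrix[[i]], use.names = FALSE))
      }
    }
    geno <- if (is.null(geno)) tile else cbind(geno, tile[rownames(geno), , drop = FALSE])
    callsets <- c(callsets, cids)
    cpag <- NULL
    for (p in res$pagination %||% list()) {
      if (toupper(p$dimension %||% "") == "CALLSETS") cpag <- p
    }
    if (is.null(cpag) || page + 1L >= (cpag$totalPages %||% 1L)) break
    page <- page + 1L
  }
  geno
}

#' Link trait observations to per-variant genotype classes
#'
#' Walks the federated linkage chain of the BrAPI model: allele matrix ->
#' callsets -> samples -> germplasm -> observations of the named trait.
#' For each variant the trait values are grouped by normalized genotype
#' class (`1/0` folds to `0/1`; unphased semantics).  Observations of
#' germplasm without any genotyped callset are counted separately rather
#' than grouped, and missing matrix cells (`.`) contribute no group
#' membership.  A dangling identifier anywhere along the chain -- a
#' callset naming an unknown sample, a sample naming an unknown germplasm
#' -- is recorded as a data-integrity warning naming the offending id, not
#' an error: surfacing isolated components is part of what the linkage
#' walk is for.
#'
#' @param conn a connection.
#' @param variants variant records from [find_variants_near()] (or a
#'   character vector of variant ids).
#' @param traitName observation-variable label.
#' @param callset_pageSize callset-axis page size for matrix retrieval.
#' @return a `grouped_trait` object: per-variant genotype classes with
#'   trait values and germplasm members, integrity warnings, and the
#'   observation accounting (`total_observations`, per-variant
#'   `excluded_missing`, `ungenotyped`).
#' @export
link_trait_to_genotypes <- function(conn, variants, traitName,
                                    callset_pageSize = 500L) {
  if (is.character(variants)) {
    variants <- lapply(variants, function(id) list(variantDbId = id))
  }
  variant_ids <- vapply(variants, function(r) as.character(r$variantDbId), character(1))
  vmeta <- lapply(variants, function(r) {
    list(
      variantDbId = as.character(r$variantDbId),
      chromosome = as.character(r$referenceName %||% NA_character_),
      position = suppressWarnings(as.numeric(r$start %||% NA))
    )
  })
  names(vmeta) <- variant_ids
  warnings <- character(0)

  geno <- fetch_matrix_by_variants(conn, variant_ids, callset_pageSize)
  callset_ids <- colnames(geno) %||% character(0)

  # callset -> sample
  callset_sample <- setNames(rep(NA_character_, length(callset_ids)), callset_ids)
  for (batch in batched(callset_ids)) {
    recs <- fetch_all_pages(conn, "callsets", list(callSetDbId = batch),
                            pageSize = length(batch))
    for (r in recs) {
      callset_sample[[as.character(r$callSetDbId)]] <- as.character(r$sampleDbId %||% NA)
    }
  }
  dangling_cs <- callset_ids[is.na(callset_sample)]
  warnings <- c(warnings, sprintf("callset '%s' not resolvable to a record", dangling_cs))

  # sample -> germplasm
  sample_ids <- unique(callset_sample[!is.na(callset_sample)])
  sample_germplasm <- setNames(rep(NA_character_, length(sample_ids)), sample_ids)
  for (batch in batched(sample_ids)) {
    recs <- fetch_all_pages(conn, "samples", list(sampleDbId = batch),
                            pageSize = length(batch))
    for (r in recs) {
      sample_germplasm[[as.character(r$sampleDbId)]] <- as.character(r$germplasmDbId %||% NA)
    }
  }
  dangling_s <- sample_ids[is.na(sample_germplasm)]
  warnings <- c(warnings, sprintf("sample '%s' not resolvable to a record", dangling_s))

  callset_germplasm <- sample_germplasm[callset_sample[callset_ids]]
  names(callset_germplasm) <- callset_ids

  # germplasm -> trait observations
  obs <- fetch_all_pages(conn, "observations", list(observationVariableName = traitName))
  obs_germplasm <- vapply(obs, function(r) as.character(r$germplasmDbId %||% NA), character(1))
  obs_value <- vapply(obs, function(r) suppressWarnings(as.numeric(r$value %||% NA)), numeric(1))
  keep <- !is.na(obs_germplasm) & !is.na(obs_value)
  values_by_germplasm <- split(obs_value[keep], obs_germplasm[keep])

  genotyped_germplasm <- unique(callset_germplasm[!is.na(callset_germplasm)])
  ungenotyped <- sum(!(obs_germplasm[keep] %in% genotyped_germplasm))

  per_variant <- lapply(variant_ids, function(vid) {
    cells <- normalize_genotype(geno[vid, callset_ids])
    classes <- list()
    members <- list()
    excluded_missing <- 0L
    for (j in seq_along(callset_ids)) {
      g <- callset_germplasm[[callset_ids[j]]]
      if (is.na(g)) next
      vals <- values_by_germplasm[[g]]
      if (is.null(vals)) next
      if (cells[j] == ".") {
        excluded_missing <- excluded_missing + length(vals)
        next
      }
      cls <- cells[j]
      classes[[cls]] <- c(classes[[cls]], vals)
      members[[cls]] <- c(members[[cls]], g)
    }
    meta <- vmeta[[vid]]
    list(
      variantDbId = vid, chromosome = meta$chromosome, position = meta$position,
      classes = classes, members = lapply(members, unique),
      excluded_missing = excluded_missing
    )
  })
  names(per_variant) <- variant_ids

  structure(
    list(
      traitName = traitName,
      variants = per_variant,
      total_observations = sum(keep),
      ungenotyped = ungenotyped,
      warnings = warnings
    ),
    class = "grouped_trait"
  )
}

#' @export
print.grouped_trait <- function(x, ...) {
  cat(sprintf(
    "<grouped_trait> '%s': %d variant(s), %d observation(s) (%d from ungenotyped germplasm), %d warning(s)\n",
    x$traitName, length(x$variants), x$total_observations, x$ungenotyped,
    length(x$warnings)
  ))
  invisible(x)
}

#' Two-sided rank-sum comparison of two samples
#'
#' The Wilcoxon--Mann--Whitney rank-sum statistic with midranks for ties.
#' Below a combined sample size of `exact_max` the null distribution is
#' enumerated exhaustively over all assignments of the pooled values to
#' the two groups, so the p-value is exact even under heavy ties (where
#' the classical exact distribution is unavailable); above it, the normal
#' approximation with tie-corrected variance and continuity correction is
#' used.  The two-sided p-value uses the symmetry of the subset-sum
#' distribution around `n1 (n+1) / 2` (the midrank multiset is invariant
#' under rank reflection).
#'
#' @param x,y numeric samples.
#' @param exact_max combined size at or below which enumeration is used
#'   (default 20; `choose(20, 10)` = 184756 assignments).
#' @return list with `statistic` (rank sum of `x`), `p.value`, `n1`,
#'   `n2`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 20L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) {
    stop_brapifed("brapifed_validation_error", "both samples must be non-empty")
  }
  n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= exact_max) {
    dev <- abs(W - mu)
    idx <- utils::combn(n, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    p <- mean(abs(sums - mu) >= dev - 1e-9)
    return(list(statistic = W, p.value = p, n1 = n1, n2 = n2,
                method = "exact enumeration"))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = W, p.value = 1, n1 = n1, n2 = n2,
                method = "normal approximation"))
  }
  dev <- abs(W - mu)
  z <- max(dev - 0.5, 0) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-z))
  list(statistic = W, p.value = p, n1 = n1, n2 = n2,
       method = "normal approximation")
}

#' Compare per-genotype trait distributions variant by variant
#'
#' For each variant whose homozygous-reference class and pooled
#' alternate-carrying classes both reach `minGroupSize`, performs the
#' two-sided rank-sum comparison of [rank_sum_test()]; when all three
#' diploid classes are individually eligible a Kruskal--Wallis 3-class
#' rank test is reported alongside.  Raw p-values are accompanied by a
#' Bonferroni adjustment across the tested variants.
#'
#' @param groups a `grouped_trait` from [link_trait_to_genotypes()].
#' @param minGroupSize minimum observations per compared group (default
#'   5).
#' @return data frame sorted by ascending p-value: `variantDbId`,
#'   `chromosome`, `position`, `statistic`, `p_value`, `p_bonferroni`,
#'   `kruskal_p`, `n_ref`, `n_alt`, `n_classes`.  Zero rows (with a
#'   `status` attribute) when no variant is testable.
#' @export
test_marker_trait <- function(groups, minGroupSize = 5L) {
  stopifnot(inherits(groups, "grouped_trait"))
  rows <- list()
  for (v in groups$variants) {
    classes <- v$classes
    if (length(classes) == 0L) next
    ref <- classes[["0/0"]] %||% numeric(0)
    alt_classes <- classes[setdiff(names(classes), "0/0")]
    alt <- unlist(alt_classes, use.names = FALSE) %||% numeric(0)
    if (length(ref) < minGroupSize || length(alt) < minGroupSize) next
    rs <- rank_sum_test(ref, alt)
    kp <- NA_real_
    eligible <- names(classes)[vapply(classes, length, integer(1)) >= minGroupSize]
    if (all(c("0/0", "0/1", "1/1") %in% eligible)) {
      kp <- kruskal.test(classes[c("0/0", "0/1", "1/1")])$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variantDbId = v$variantDbId, chromosome = v$chromosome,
      position = v$position, statistic = rs$statistic, p_value = rs$p.value,
      kruskal_p = kp, n_ref = length(ref), n_alt = length(alt),
      n_classes = length(classes), stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    out <- data.frame(
      variantDbId = character(0), chromosome = character(0), position = numeric(0),
      statistic = numeric(0), p_value = numeric(0), kruskal_p = numeric(0),
      n_ref = integer(0), n_alt = integer(0), n_classes = integer(0),
      stringsAsFactors = FALSE
    )
    attr(out, "status") <- "no variant reached the minimum group sizes"
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out <- out[order(out$p_value), c(
    "variantDbId", "chromosome", "position", "statistic", "p_value",
    "p_bonferroni", "kruskal_p", "n_ref", "n_alt", "n_classes"
  )]
  rownames(out) <- NULL
  out
}

tab_or_unknown <- function(values) {
  values[is.na(values) | !nzchar(values)] <- "unknown"
  tab <- table(values)
  setNames(as.integer(tab), names(tab))
}

#' Passport and study-year breakdown of alternate-allele carriers
#'
#' For the germplasm carrying at least one alternate allele at a variant,
#' tabulates the collecting institute and country of origin from the
#' germplasm passport attributes, and the year of observation via the
#' observation -> study link.  Missing passport fields are counted under
#' `"unknown"`.
#'
#' @param conn a connection.
#' @param germplasmDbIds carrier germplasm identifiers.
#' @param traitName trait whose observations define the study years.
#' @return list with `institutes`, `countries`, `years` (named integer
#'   counts) and `n_carriers`.
#' @export
passport_breakdown <- function(conn, germplasmDbIds, traitName = NULL) {
  germplasmDbIds <- unique(germplasmDbIds)
  recs <- list()
  for (batch in batched(germplasmDbIds)) {
    recs <- c(recs, fetch_all_pages(conn, "germplasm", list(germplasmDbId = batch),
                                    pageSize = length(batch)))
  }
  institutes <- tab_or_unknown(vapply(recs, function(r) {
    as.character(r$instituteName %||% NA_character_)
  }, character(1)))
  countries <- tab_or_unknown(vapply(recs, function(r) {
    as.character(r$countryOfOriginCode %||% NA_character_)
  }, character(1)))

  years <- integer(0)
  if (length(germplasmDbIds)) {
    params <- list(germplasmDbId = germplasmDbIds)
    if (!is.null(traitName)) params$observationVariableName <- traitName
    obs <- list()
    for (batch in batched(germplasmDbIds)) {
      p <- params
      p$germplasmDbId <- batch
      obs <- c(obs, fetch_all_pages(conn, "observations", p))
    }
    study_ids <- unique(vapply(obs, function(r) as.character(r$studyDbId %||% NA), character(1)))
    study_ids <- study_ids[!is.na(study_ids)]
    study_year <- setNames(rep(NA_character_, length(study_ids)), study_ids)
    for (batch in batched(study_ids)) {
      srecs <- fetch_all_pages(conn, "studies", list(studyDbId = batch),
                               pageSize = length(batch))
      for (r in srecs) {
        study_year[[as.character(r$studyDbId)]] <-
          as.character(r$year %||% r$seasons[[1]] %||% NA)
      }
    }
    years <- tab_or_unknown(vapply(obs, function(r) {
      sid <- as.character(r$studyDbId %||% NA)
      if (is.na(sid) || !(sid %in% names(study_year))) NA_character_ else study_year[[sid]]
    }, character(1)))
  }
  list(
    institutes = institutes, countries = countries, years = years,
    n_carriers = length(germplasmDbIds)
  )
}

#' Validate a marker--trait relationship through a BrAPI endpoint
#'
#' The end-to-end workflow: select variants in the query window, walk the
#' allele-matrix linkage chain to trait observations, compare
#' per-genotype trait distributions, and break down the carriers of the
#' top-ranked variant by passport attributes and study year.
#'
#' @param conn a connection ([proxy_connection()] or
#'   [http_connection()]).
#' @param query a [marker_query()].
#' @param minGroupSize minimum observations per compared group.
#' @return a `marker_validation` object: `query`, `variants` (selected
#'   records), `groups`, `results` (the test table), `breakdown` (for the
#'   top variant's carriers; `NULL` when nothing is testable), and
#'   `warnings`.
#' @export
run_marker_validation <- function(conn, query, minGroupSize = 5L) {
  variants <- find_variants_near(conn, query)
  if (length(variants) == 0L) {
    return(structure(
      list(query = query, variants = list(), groups = NULL,
           results = test_marker_trait(structure(list(variants = list()),
                                                 class = "grouped_trait")),
           breakdown = NULL, warnings = character(0)),
      class = "marker_validation"
    ))
  }
  groups <- link_trait_to_genotypes(conn, variants, query$traitName)
  results <- test_marker_trait(groups, minGroupSize)
  breakdown <- NULL
  if (nrow(results)) {
    top <- results$variantDbId[1]
    members <- groups$variants[[top]]$members
    carriers <- unique(unlist(members[setdiff(names(members), "0/0")], use.names = FALSE))
    if (length(carriers)) {
      breakdown <- passport_breakdown(conn, carriers, query$traitName)
    }
  }
  structure(
    list(query = query, variants = variants, groups = groups,
         results = results, breakdown = breakdown,
         warnings = groups$warnings),
    class = "marker_validation"
  )
}

#' @export
print.marker_validation <- function(x, ...) {
  q <- x$query
  cat(sprintf(
    "<marker_validation> %s:%d +/- %g bp, trait '%s'\n",
    q$chromosome, q$position, q$windowHalfWidth, q$traitName
  ))
  cat(sprintf("  %d variant(s) in window, %d tested\n",
              length(x$variants), nrow(x$results)))
  if (nrow(x$results)) {
    top <- x$results[1, ]
    cat(sprintf(
      "  top variant: %s (%s:%d), rank-sum p = %.3g (Bonferroni %.3g), n = %d ref / %d alt\n",
      top$variantDbId, top$chromosome, top$position, top$p_value,
      top$p_bonferroni, top$n_ref, top$n_alt
    ))
  }
  if (!is.null(x$breakdown)) {
    cat(sprintf("  carriers: %d germplasm; institutes: %s\n",
                x$breakdown$n_carriers,
                paste(names(x$breakdown$institutes), x$breakdown$institutes,
                      sep = "=", collapse = ", ")))
  }
  if (length(x$warnings)) {
    cat(sprintf("  %d data-integrity warning(s)\n", length(x$warnings)))
  }
  invisible(x)
}
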