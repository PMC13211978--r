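#' Generate a synthetic multi-backend federation with a planted
#' marker--trait effect
#'
#' Emulates the data landscape the proxy is built for: one relational
#' passport/phenotype source holding germplasm, samples, studies and
#' observations for every crop, plus one genotype source per crop holding
#' variants, callsets and the allele matrix (the shape of a genebank
#' project with a phenotype database and per-crop variant browsers).  The
#' linkage chain variant -> callset -> sample -> germplasm -> observation
#' is closed by construction.
#'
#' Genotypes are unphased VCF-style strings (`0/0`, `0/1`, `1/1`, missing
#' `.`).  Each variant draws an alternate-allele frequency from
#' Uniform(0.1, 0.9) and genotypes follow Hardy--Weinberg proportions at
#' that frequency.  Exactly one planted variant carries a trait effect:
#' the trait value of a germplasm is `mu + beta * dosage + N(0, sigma)`,
#' where `dosage` is the germplasm's alternate-allele count at the planted
#' variant (0 for crops without the planted variant).  Missingness is
#' applied only to the served matrix, after trait simulation, as in real
#' genotyping where the phenotype does not depend on call success.
#'
#' @param crops crop labels; the first crop hosts the planted variant.
#' @param n_germplasm germplasm (= samples = callsets) per crop, recycled.
#' @param n_variants variants per crop, recycled.
#' @param chromosomes chromosome label per crop, recycled.
#' @param pos_range 1-based bp range variants are placed in (uniform,
#'   distinct positions).
#' @param n_studies number of studies (field trials across years).
#' @param obs_per_germplasm observations of the trait per germplasm.
#' @param trait_name observation-variable label.
#' @param missing_rate per-cell probability of a missing genotype call in
#'   the served matrix (in `[0, 1)`).
#' @param effect list with `position` (bp of the planted variant, placed on
#'   the first crop's chromosome), `beta` (trait units per alternate
#'   allele), `mu` (baseline), `sigma` (observation noise SD), and `maf`
#'   (the planted variant's alternate-allele frequency; fixed at 0.3
#'   rather than drawn, so that a marker worth validating -- one whose
#'   genotype classes are all observable in a panel of this size -- is
#'   planted every time).
#' @param seed RNG seed; worlds are byte-identical given the same inputs.
#' @return a `synthetic_world` list; see Details for components.
#' @details Components: `germplasm`, `samples`, `studies`, `observations`
#'   (data frames, passport/phenotype source), and per crop in `genotype`:
#'   `variants`, `callsets` (data frames), `matrix` (served genotype grid
#'   with missingness), `dosage` (true alternate-allele counts), `maf`
#'   (alternate-allele frequency per variant).  `effect` records the
#'   planted variant (crop, local id, chromosome, position, beta, mu,
#'   sigma).
#' @export
generate_world <- function(crops = c("barley", "wheat"),
                           n_germplasm = c(100, 40),
                           n_variants = c(30, 20),
                           chromosomes = c("6H", "6A"),
                           pos_range = c(17000000, 17015000),
                           n_studies = 4,
                           obs_per_germplasm = 2,
                           trait_name = "Plant height",
                           missing_rate = 0.02,
                           effect = list(position = 17009885, beta = 30, mu = 100, sigma = 10),
                           seed = 1) {
  if (length(crops) < 1L) stop_brapifed("brapifed_validation_error", "need at least one crop")
  n_germplasm <- rep_len(as.integer(n_germplasm), length(crops))
  n_variants <- rep_len(as.integer(n_variants), length(crops))
  chromosomes <- rep_len(as.character(chromosomes), length(crops))
  if (any(n_germplasm < 1) || any(n_variants < 1) || n_studies < 1 || obs_per_germplasm < 1) {
    stop_brapifed("brapifed_validation_error", "entity counts must be positive")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_brapifed("brapifed_validation_error", "missing_rate must be in [0, 1)")
  }
  eff <- modifyList(
    list(position = 17009885, beta = 30, mu = 100, sigma = 10, maf = 0.3),
    effect %||% list()
  )
  set.seed(as.integer(seed))

  institutes <- c("IPK Gatersleben", "CGN Wageningen", "NordGen", "ICARDA", "INRAE URGI")
  countries <- c("DEU", "NLD", "SWE", "SYR", "FRA", "ETH", "TUR")

  total_g <- sum(n_germplasm)
  crop_of <- rep(crops, n_germplasm)
  germplasm <- data.frame(
    germplasmDbId = paste0("g", seq_len(total_g)),
    germplasmName = paste0(toupper(substr(crop_of, 1, 3)), "-", sprintf("%04d", seq_len(total_g))),
    commonCropName = crop_of,
    instituteName = ifelse(runif(total_g) < 0.05, NA_character_,
                           sample(institutes, total_g, replace = TRUE, prob = c(4, 3, 2, 2, 1))),
    countryOfOriginCode = sample(countries, total_g, replace = TRUE, prob = c(5, 3, 2, 2, 2, 1, 1)),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sampleDbId = paste0("s", seq_len(total_g)),
    sampleName = paste0("sample-", seq_len(total_g)),
    germplasmDbId = germplasm$germplasmDbId,
    stringsAsFactors = FALSE
  )
  years <- seq(2019, length.out = n_studies)
  studies <- data.frame(
    studyDbId = paste0("st", seq_len(n_studies)),
    studyName = paste0("Field trial ", years),
    year = years,
    stringsAsFactors = FALSE
  )

  genotype <- list()
  dosage_of_germplasm <- setNames(numeric(total_g), germplasm$germplasmDbId)
  for (ci in seq_along(crops)) {
    crop <- crops[ci]
    nv <- n_variants[ci]
    ng <- n_germplasm[ci]
    pos <- sort(sample(seq(pos_range[1], pos_range[2]), nv))
    if (ci == 1L) {
      # the planted variant sits at the configured position on crop 1
      planted_idx <- which.min(abs(pos - eff$position))
      pos[planted_idx] <- as.integer(eff$position)
      pos <- sort(pos)
      planted_idx <- match(as.integer(eff$position), pos)
    }
    variants <- data.frame(
      variantDbId = paste0("v", seq_len(nv)),
      referenceName = chromosomes[ci],
      start = pos,
      end = pos,
      variantType = "SNP",
      stringsAsFactors = FALSE
    )
    g_ids <- germplasm$germplasmDbId[crop_of == crop]
    s_ids <- samples$sampleDbId[match(g_ids, samples$germplasmDbId)]
    callsets <- data.frame(
      callSetDbId = paste0("c", seq_len(ng)),
      callSetName = paste0(crop, "-callset-", seq_len(ng)),
      sampleDbId = s_ids,
      stringsAsFactors = FALSE
    )
    maf <- runif(nv, 0.1, 0.9)
    if (ci == 1L) maf[planted_idx] <- eff$maf
    dosage <- matrix(0L, nrow = nv, ncol = ng)
    for (vi in seq_len(nv)) {
      p <- maf[vi]
      dosage[vi, ] <- sample(0:2, ng, replace = TRUE,
                             prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    }
    geno <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], nrow = nv, ncol = ng)
    if (missing_rate > 0) {
      geno[runif(nv * ng) < missing_rate] <- "."
    }
    rownames(geno) <- variants$variantDbId
    colnames(geno) <- callsets$callSetDbId
    genotype[[crop]] <- list(
      crop = crop, variants = variants, callsets = callsets,
      matrix = geno, dosage = dosage, maf = maf,
      germplasmDbId = g_ids
    )
    if (ci == 1L) {
      dosage_of_germplasm[g_ids] <- dosage[planted_idx, ]
      planted <- list(
        crop = crop, variantDbId = variants$variantDbId[planted_idx],
        chromosome = chromosomes[ci], position = pos[planted_idx],
        beta = eff$beta, mu = eff$mu, sigma = eff$sigma
      )
    }
  }

  n_obs <- total_g * obs_per_germplasm
  obs_germplasm <- rep(germplasm$germplasmDbId, each = obs_per_germplasm)
  observations <- data.frame(
    observationDbId = paste0("o", seq_len(n_obs)),
    germplasmDbId = obs_germplasm,
    studyDbId = sample(studies$studyDbId, n_obs, replace = TRUE),
    observationVariableName = trait_name,
    value = eff$mu + eff$beta * dosage_of_germplasm[obs_germplasm] +
      rnorm(n_obs, 0, eff$sigma),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      crops = crops, trait_name = trait_name, seed = as.integer(seed),
      germplasm = germplasm, samples = samples, studies = studies,
      observations = observations, genotype = genotype, effect = planted
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> crops: %s; %d germplasm, %d observations of '%s'\n",
    paste(x$crops, collapse = ", "), nrow(x$germplasm), nrow(x$observations),
    x$trait_name
  ))
  cat(sprintf(
    "  planted effect: %s %s:%d, beta=%g, mu=%g, sigma=%g\n",
    x$effect$crop, x$effect$chromosome, x$effect$position,
    x$effect$beta, x$effect$mu, x$effect$sigma
  ))
  invisible(x)
}

df_to_records <- function(df) {
  recs <- vector("list", nrow(df))
  nms <- names(df)
  for (i in seq_len(nrow(df))) {
    rec <- as.list(df[i, , drop = FALSE])
    names(rec) <- nms
    rec <- rec[!vapply(rec, function(v) is.na(v)[1], logical(1))]
    recs[[i]] <- rec
  }
  recs
}

#' Build the per-source data stores of a synthetic world
#'
#' One store per private data source: `pheno` (germplasm, samples,
#' studies, observations for all crops) and one genotype store per crop
#' (variants, callsets, allele matrix).  Stores are what
#' [backend_handler()] serves.
#'
#' @param world a `synthetic_world`.
#' @return named list of stores.
#' @export
world_stores <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  stores <- list(
    pheno = list(
      name = "pheno", crops = world$crops,
      endpoints = c("commoncropnames", "germplasm", "samples", "studies", "observations"),
      tables = list(
        germplasm = df_to_records(world$germplasm),
        samples = df_to_records(world$samples),
        studies = df_to_records(world$studies),
        observations = df_to_records(world$observations)
      )
    )
  )
  for (crop in world$crops) {
    g <- world$genotype[[crop]]
    stores[[crop]] <- list(
      name = crop, crops = crop,
      endpoints = c("commoncropnames", "variants", "callsets", "allelematrix"),
      tables = list(
        variants = df_to_records(g$variants),
        callsets = df_to_records(g$callsets)
      ),
      matrix = g$matrix,
      variant_ids = g$variants$variantDbId,
      callset_ids = g$callsets$callSetDbId,
      callset_sample = setNames(g$callsets$sampleDbId, g$callsets$callSetDbId),
      callset_germplasm = setNames(g$germplasmDbId, g$callsets$callSetDbId)
    )
  }
  stores
}

brapi_envelope <- function(records, page, pageSize, totalCount, status = list()) {
  list(
    metadata = list(
      pagination = list(
        currentPage = as.integer(page), pageSize = as.integer(pageSize),
        totalCount = as.integer(totalCount),
        totalPages = total_pages(totalCount, pageSize)
      ),
      status = status, datafiles = list()
    ),
    result = list(data = records)
  )
}

match_filter <- function(records, field, values) {
  keep <- vapply(records, function(r) {
    v <- r[[field]]
    !is.null(v) && any(as.character(v) %in% values)
  }, logical(1))
  records[keep]
}

#' An in-process BrAPI request handler over a synthetic store
#'
#' Returns a `function(endpoint, params)` implementing the backend side of
#' the federation contract -- list endpoints with local 0-based pagination
#' and match-based filters, `commoncropnames`, and the 2D-paged
#' `allelematrix` -- exactly as a private BrAPI endpoint would.  Usable
#' directly as a [mock_client()] handler or served over HTTP with
#' [serve_backend()].
#'
#' @param store one store from [world_stores()].
#' @return a handler function.
#' @export
backend_handler <- function(store) {
  force(store)
  function(endpoint, params) {
    params <- params %||% list()
    page <- as.integer(params[["page"]] %||% 0L)
    pageSize <- as.integer(params[["pageSize"]] %||% 1000L)
    if (endpoint == "commoncropnames") {
      ids <- as.list(store$crops)
      lo <- page * pageSize
      sel <- ids[seq_along(ids) > lo & seq_along(ids) <= lo + pageSize]
      return(brapi_envelope(sel, page, pageSize, length(ids)))
    }
    if (endpoint == "allelematrix") {
      return(allelematrix_response(store, params))
    }
    records <- store$tables[[endpoint]]
    if (is.null(records)) {
      stop_brapifed(
        "brapifed_http_error",
        sprintf("endpoint '%s' not found on backend '%s'", endpoint, store$name),
        status = 404L
      )
    }
    for (f in setdiff(names(params), c("page", "pageSize"))) {
      values <- as.character(unlist(params[[f]], use.names = FALSE))
      field <- sub("DbIds$", "DbId", f)
      records <- match_filter(records, field, values)
    }
    total <- length(records)
    lo <- page * pageSize
    sel <- if (lo >= total) list() else records[seq.int(lo + 1L, min(lo + pageSize, total))]
    brapi_envelope(sel, page, pageSize, total)
  }
}

allelematrix_response <- function(store, params) {
  v_keep <- seq_along(store$variant_ids)
  c_keep <- seq_along(store$callset_ids)
  if (!is.null(params[["variantDbId"]])) {
    v_keep <- v_keep[store$variant_ids %in% as.character(unlist(params[["variantDbId"]]))]
  }
  if (!is.null(params[["callSetDbId"]])) {
    c_keep <- c_keep[store$callset_ids %in% as.character(unlist(params[["callSetDbId"]]))]
  }
  if (!is.null(params[["sampleDbId"]])) {
    c_keep <- c_keep[store$callset_sample[store$callset_ids[c_keep]] %in%
                       as.character(unlist(params[["sampleDbId"]]))]
  }
  if (!is.null(params[["germplasmDbId"]])) {
    c_keep <- c_keep[store$callset_germplasm[store$callset_ids[c_keep]] %in%
                       as.character(unlist(params[["germplasmDbId"]]))]
  }
  vPage <- as.integer(params[["dimensionVariantPage"]] %||% 0L)
  vSize <- as.integer(params[["dimensionVariantPageSize"]] %||% 1000L)
  cPage <- as.integer(params[["dimensionCallSetPage"]] %||% 0L)
  cSize <- as.integer(params[["dimensionCallSetPageSize"]] %||% 1000L)
  v_tot <- length(v_keep)
  c_tot <- length(c_keep)
  v_lo <- vPage * vSize
  c_lo <- cPage * cSize
  v_sel <- if (v_lo >= v_tot) integer(0) else v_keep[seq.int(v_lo + 1L, min(v_lo + vSize, v_tot))]
  c_sel <- if (c_lo >= c_tot) integer(0) else c_keep[seq.int(c_lo + 1L, min(c_lo + cSize, c_tot))]
  grid <- store$matrix[v_sel, c_sel, drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) as.list(unname(grid[i, ])))
  list(
    metadata = list(status = list(), datafiles = list()),
    result = list(
      variantDbIds = as.list(store$variant_ids[v_sel]),
      callSetDbIds = as.list(store$callset_ids[c_sel]),
      dataMatrices = list(list(
        dataMatrixName = "genotype", dataType = "string", dataMatrix = rows
      )),
      expandHomozygotes = TRUE, sepUnphased = "/", unknownString = ".",
      pagination = list(
        list(dimension = "VARIANTS", page = vPage, pageSize = vSize,
             totalCount = v_tot, totalPages = total_pages(v_tot, vSize)),
        list(dimension = "CALLSETS", page = cPage, pageSize = cSize,
             totalCount = c_tot, totalPages = total_pages(c_tot, cSize))
      )
    )
  )
}

#' Wire a synthetic world into a ready federation (config, client, proxy)
#'
#' Builds the configuration (fallback passport backend with an empty
#' prefix; one prefixed genotype backend per crop, prefix = first three
#' letters of the crop name), a [mock_client()] over the world's stores,
#' and a [brapi_proxy()].
#'
#' @param world a `synthetic_world`.
#' @param serverTokens accepted proxy tokens (default: open access).
#' @param separator identifier separator.
#' @return list with `config`, `client`, `proxy`, `stores`.
#' @export
world_federation <- function(world, serverTokens = character(), separator = "-") {
  stores <- world_stores(world)
  backends <- list(backend_config(
    name = "pheno", baseUrl = "mock://pheno", prefix = "",
    endpoints = stores$pheno$endpoints
  ))
  for (crop in world$crops) {
    backends <- c(backends, list(backend_config(
      name = crop, baseUrl = paste0("mock://", crop),
      prefix = substr(crop, 1, 3),
      endpoints = stores[[crop]]$endpoints
    )))
  }
  config <- federation_config(backends, serverTokens = serverTokens, separator = separator)
  client <- mock_client(config, lapply(stores, backend_handler))
  list(config = config, client = client, proxy = brapi_proxy(config, client), stores = stores)
}

#' Wrap a handler so its first calls fail (fault injection for tests)
#'
#' @param handler a backend handler function.
#' @param times number of leading calls that fail.
#' @param class condition class to signal (`"brapifed_network_error"` or
#'   `"brapifed_http_error"`).
#' @param status HTTP status for `brapifed_http_error`.
#' @return a handler with the same signature.
#' @export
flaky_handler <- function(handler, times, class = "brapifed_network_error", status = 503L) {
  count <- 0L
  function(endpoint, params) {
    if (count < times) {
      count <<- count + 1L
      stop_brapifed(class, sprintf("injected failure %d", count), status = status)
    }
    handler(endpoint, params)
  }
}

#' Dump a synthetic world to plain JSON fixture files
#'
#' Writes one JSON file per entity table plus the genotype matrices, for
#' offline inspection or for feeding other BrAPI tooling.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
dump_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(world$germplasm, file.path(dir, "germplasm.json"), dataframe = "rows")
  jsonlite::write_json(world$samples, file.path(dir, "samples.json"), dataframe = "rows")
  jsonlite::write_json(world$studies, file.path(dir, "studies.json"), dataframe = "rows")
  jsonlite::write_json(world$observations, file.path(dir, "observations.json"), dataframe = "rows")
  for (crop in world$crops) {
    g <- world$genotype[[crop]]
    jsonlite::write_json(
      list(
        variants = g$variants, callsets = g$callsets,
        matrix = apply(g$matrix, 1, as.list)
      ),
      file.path(dir, paste0("genotype-", crop, ".json")),
      dataframe = "rows", auto_unbox = TRUE
    )
  }
  invisible(dir)
}
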