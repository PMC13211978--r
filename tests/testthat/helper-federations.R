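# Fixture builders and independent oracles shared across the suite.
# All fixtures are constructed in code; nothing is read from disk.

# A list-endpoint store: n records of one entity, ids local to the backend.
make_list_store <- function(name, n, endpoint = "germplasm", crop = name) {
  field <- switch(endpoint,
    germplasm = "germplasmDbId", samples = "sampleDbId", studies = "studyDbId",
    observations = "observationDbId", variants = "variantDbId",
    callsets = "callSetDbId"
  )
  records <- lapply(seq_len(n), function(i) {
    rec <- list()
    rec[[field]] <- paste0("r", i)
    rec$name <- paste0(name, "-item-", i)
    rec
  })
  tables <- list()
  tables[[endpoint]] <- records
  list(name = name, crops = crop,
       endpoints = c("commoncropnames", endpoint), tables = tables)
}

# Assemble config + mock client + proxy over a set of stores.
stores_federation <- function(stores, prefixes, serverTokens = character(),
                              separator = "-") {
  backends <- lapply(seq_along(stores), function(i) {
    backend_config(
      name = stores[[i]]$name, baseUrl = paste0("mock://", stores[[i]]$name),
      prefix = prefixes[[i]], endpoints = stores[[i]]$endpoints
    )
  })
  config <- federation_config(backends, serverTokens = serverTokens,
                              separator = separator)
  handlers <- lapply(stores, backend_handler)
  names(handlers) <- vapply(stores, `[[`, character(1), "name")
  client <- mock_client(config, handlers)
  list(config = config, client = client, proxy = brapi_proxy(config, client),
       stores = stores)
}

# Oracle: the namespaced concatenation of all backend lists, in backend order.
oracle_concatenation <- function(fed, endpoint = "germplasm") {
  out <- list()
  for (i in seq_along(fed$stores)) {
    b <- fed$config$backends[[i]]
    recs <- fed$stores[[i]]$tables[[endpoint]] %||% list()
    out <- c(out, lapply(recs, namespace_record, backend = b,
                         separator = fed$config$separator))
  }
  out
}

# Random list federation: 1-4 backends, 0-200 records each, distinct
# prefix-free prefixes (possibly one empty fallback).
random_list_federation <- function(seed) {
  set.seed(seed)
  nb <- sample(1:4, 1)
  pool <- c("bar", "whe", "oat", "rye")
  prefixes <- sample(pool, nb)
  if (runif(1) < 0.5) prefixes[1] <- ""
  counts <- sample(0:200, nb, replace = TRUE)
  stores <- lapply(seq_len(nb), function(i) {
    make_list_store(paste0("b", i), counts[i])
  })
  fed <- stores_federation(stores, prefixes)
  fed$counts <- counts
  fed
}

# A genotype store with synthetic, per-cell-unique genotype strings, so
# tests can verify byte-for-byte placement.
make_matrix_store <- function(name, nv, nc) {
  geno <- matrix(character(0), nrow = nv, ncol = nc)
  if (nv > 0 && nc > 0) {
    geno <- outer(seq_len(nv), seq_len(nc),
                  function(i, j) paste0(name, ":", i, ",", j))
  }
  store <- list(
    name = name, crops = name,
    endpoints = c("commoncropnames", "variants", "callsets", "allelematrix"),
    tables = list(
      variants = lapply(seq_len(nv), function(i) {
        list(variantDbId = paste0("v", i), referenceName = "1", start = i)
      }),
      callsets = lapply(seq_len(nc), function(j) {
        list(callSetDbId = paste0("c", j), sampleDbId = paste0("s", j))
      })
    ),
    matrix = geno,
    variant_ids = sprintf("v%d", seq_len(nv)),
    callset_ids = sprintf("c%d", seq_len(nc)),
    callset_sample = setNames(sprintf("s%d", seq_len(nc)), sprintf("c%d", seq_len(nc))),
    callset_germplasm = setNames(sprintf("g%d", seq_len(nc)), sprintf("c%d", seq_len(nc)))
  )
  store
}

# Oracle: explicit block-diagonal assembly of a 2-store matrix federation.
oracle_block_diagonal <- function(fed, fill) {
  stores <- fed$stores
  config <- fed$config
  v_ids <- character(0)
  c_ids <- character(0)
  blocks <- list()
  for (i in seq_along(stores)) {
    b <- config$backends[[i]]
    s <- stores[[i]]
    blocks[[i]] <- list(
      rows = length(v_ids) + seq_along(s$variant_ids),
      cols = length(c_ids) + seq_along(s$callset_ids),
      values = s$matrix
    )
    v_ids <- c(v_ids, render_id(b$prefix, s$variant_ids, config$separator))
    c_ids <- c(c_ids, render_id(b$prefix, s$callset_ids, config$separator))
  }
  grid <- matrix(fill, nrow = length(v_ids), ncol = length(c_ids),
                 dimnames = list(v_ids, c_ids))
  for (blk in blocks) grid[blk$rows, blk$cols] <- blk$values
  grid
}

# Oracle for the rank-sum p-value: exhaustive enumeration over group
# assignments, written independently of rank_sum_test().
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  r <- rank(pooled)
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0L
  combos <- utils::combn(n, n1)
  for (k in seq_len(ncol(combos))) {
    if (abs(sum(r[combos[, k]]) - mu) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / ncol(combos)
}

# Count backend page-requests per backend from a client log slice.
log_requests_per_backend <- function(log, endpoint) {
  tab <- table(vapply(
    Filter(function(e) identical(e$endpoint, endpoint), log),
    `[[`, character(1), "backend"
  ))
  setNames(as.integer(tab), names(tab))
}

small_world_federation <- function(seed = 7, ...) {
  w <- generate_world(
    n_germplasm = c(20, 10), n_variants = c(8, 5),
    obs_per_germplasm = 2, seed = seed, ...
  )
  fed <- world_federation(w)
  fed$world <- w
  fed
}
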