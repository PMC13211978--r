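test_that("data routes demand a valid bearer token when tokens are configured", {
  fed <- small_world_federation()
  secured <- stores_federation(fed$stores,
                               prefixes = c("", substr(fed$world$crops, 1, 3)),
                               serverTokens = "sesame")
  data_routes <- setdiff(proxy_endpoints(secured$proxy), "serverinfo")
  for (e in data_routes) {
    r <- proxy_handle(secured$proxy, "GET", paste0("/", e))
    expect_identical(r$status, 401L)
    r2 <- proxy_handle(secured$proxy, "GET", paste0("/", e),
                       headers = c(Authorization = "Bearer wrong"))
    expect_identical(r2$status, 401L)
    r3 <- proxy_handle(secured$proxy, "GET", paste0("/", e),
                       headers = c(Authorization = "Bearer sesame"))
    expect_identical(r3$status, 200L)
  }
  # serverinfo stays open; with no tokens configured all routes are open
  expect_identical(proxy_handle(secured$proxy, "GET", "/serverinfo")$status, 200L)
  open <- stores_federation(fed$stores,
                            prefixes = c("", substr(fed$world$crops, 1, 3)))
  expect_identical(proxy_handle(open$proxy, "GET", "/germplasm")$status, 200L)
})

test_that("list endpoints serve merged pages and single records route directly", {
  fed <- stores_federation(
    list(make_list_store("pheno", 3), make_list_store("barley", 5)),
    prefixes = c("", "bar")
  )
  r <- proxy_handle(fed$proxy, "GET", "/germplasm",
                    query = list(page = 1, pageSize = 4))
  expect_identical(r$status, 200L)
  expect_identical(r$body$result$data, oracle_concatenation(fed)[5:8])
  expect_identical(r$body$metadata$pagination$totalCount, 8L)

  # single-record fetch bypasses merging and namespaces the record
  clear_client_log(fed$client)
  r2 <- proxy_handle(fed$proxy, "GET", "/germplasm/bar-r2")
  expect_identical(r2$status, 200L)
  expect_identical(r2$body$result$germplasmDbId, "bar-r2")
  expect_identical(unique(vapply(client_log(fed$client), `[[`, character(1), "backend")),
                   "barley")

  # unknown id and unknown endpoint map to 404; non-GET to 405
  expect_identical(proxy_handle(fed$proxy, "GET", "/germplasm/zzz-r1")$status, 404L)
  expect_identical(proxy_handle(fed$proxy, "GET", "/germplasm/bar-r99")$status, 404L)
  expect_identical(proxy_handle(fed$proxy, "GET", "/trials")$status, 404L)
  expect_identical(proxy_handle(fed$proxy, "POST", "/germplasm")$status, 405L)

  # a BrAPI base path prefix is accepted
  r3 <- proxy_handle(fed$proxy, "GET", "/brapi/v2/germplasm")
  expect_identical(r3$status, 200L)
})

test_that("federation failures surface as 502 with the backend named", {
  store <- make_list_store("ok", 2)
  config <- federation_config(list(
    backend_config("ok", "mock://ok", prefix = "a", endpoints = store$endpoints),
    backend_config("broken", "mock://broken", prefix = "b", endpoints = store$endpoints)
  ))
  client <- mock_client(config, list(
    ok = backend_handler(store),
    broken = function(endpoint, params) stop_brapifed("brapifed_network_error", "refused")
  ))
  proxy <- brapi_proxy(config, client)
  r <- proxy_handle(proxy, "GET", "/germplasm")
  expect_identical(r$status, 502L)
  expect_match(r$body$metadata$status[[1]]$message, "broken")
})

test_that("serverinfo, the OpenAPI document and live routing agree", {
  fed <- small_world_federation()
  proxy <- fed$proxy

  advertised <- vapply(serverinfo_payload(proxy)$result$calls, `[[`,
                       character(1), "service")
  expect_setequal(advertised, proxy_endpoints(proxy))

  doc <- openapi_document(proxy)
  doc_endpoints <- unique(sub("/.*$", "", sub("^/", "", names(doc$paths))))
  expect_setequal(doc_endpoints, proxy_endpoints(proxy))

  # every advertised endpoint answers; an unadvertised one does not
  for (e in setdiff(advertised, "serverinfo")) {
    expect_identical(proxy_handle(proxy, "GET", paste0("/", e))$status, 200L,
                     info = e)
  }
  expect_identical(proxy_handle(proxy, "GET", "/serverinfo")$status, 200L)

  # capability rule: with no genotype backends, genotype endpoints vanish
  pheno_only <- stores_federation(fed$stores["pheno"], prefixes = "")
  eps <- proxy_endpoints(pheno_only$proxy)
  expect_false(any(c("variants", "callsets", "allelematrix") %in% eps))
  expect_true(all(c("serverinfo", "germplasm") %in% eps))
  expect_identical(proxy_handle(pheno_only$proxy, "GET", "/variants")$status, 404L)
  doc2 <- openapi_document(pheno_only$proxy)
  expect_false("/allelematrix" %in% names(doc2$paths))
})

test_that("the OpenAPI document is structurally valid and the validator bites", {
  fed <- small_world_federation()
  secured <- stores_federation(fed$stores,
                               prefixes = c("", substr(fed$world$crops, 1, 3)),
                               serverTokens = "tok")
  doc <- openapi_document(secured$proxy)
  expect_true(validate_openapi(doc))
  expect_true("/allelematrix" %in% names(doc$paths))
  am_params <- vapply(doc$paths$`/allelematrix`$get$parameters, `[[`,
                      character(1), "name")
  expect_true(all(c("dimensionVariantPage", "dimensionVariantPageSize",
                    "dimensionCallSetPage", "dimensionCallSetPageSize") %in% am_params))

  # the validator rejects structural damage
  broken <- doc
  broken$paths$`/germplasm/{germplasmDbId}`$get$parameters[[1]]$required <- NULL
  expect_false(validate_openapi(broken))
  broken2 <- doc
  broken2$paths <- list()
  expect_false(validate_openapi(broken2))
  broken3 <- doc
  broken3$openapi <- "2.0"
  expect_false(validate_openapi(broken3))
})

test_that("the allelematrix route and commoncropnames work through the proxy", {
  fed <- small_world_federation()
  r <- proxy_handle(fed$proxy, "GET", "/commoncropnames")
  expect_identical(r$status, 200L)
  expect_setequal(unlist(r$body$result$data), fed$world$crops)

  r2 <- proxy_handle(fed$proxy, "GET", "/allelematrix",
                     query = list(dimensionVariantPageSize = 5,
                                  dimensionCallSetPageSize = 5))
  expect_identical(r2$status, 200L)
  expect_length(r2$body$result$pagination, 2)
  expect_length(r2$body$result$variantDbIds, 5)
  expect_length(r2$body$result$dataMatrices[[1]]$dataMatrix, 5)

  # malformed backend grid maps to 502 naming the backend
  crop1 <- fed$world$crops[1]
  bad_stores <- fed$stores
  bad_handler <- function(endpoint, params) {
    body <- backend_handler(bad_stores[[crop1]])(endpoint, params)
    if (endpoint == "allelematrix" && length(body$result$dataMatrices[[1]]$dataMatrix)) {
      body$result$dataMatrices[[1]]$dataMatrix[[1]] <- list("broken")
    }
    body
  }
  handlers <- lapply(bad_stores, backend_handler)
  handlers[[crop1]] <- bad_handler
  client <- mock_client(fed$config, handlers)
  proxy <- brapi_proxy(fed$config, client)
  r3 <- proxy_handle(proxy, "GET", "/allelematrix",
                     query = list(dimensionVariantPageSize = 500,
                                  dimensionCallSetPageSize = 500))
  expect_identical(r3$status, 502L)
  expect_match(r3$body$metadata$status[[1]]$message, crop1)
})
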