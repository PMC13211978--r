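three_source_config <- function() {
  federation_config(list(
    backend_config("pheno", "mock://pheno", prefix = "",
                   endpoints = c("commoncropnames", "germplasm", "samples",
                                 "studies", "observations")),
    backend_config("barley", "mock://barley", prefix = "bar",
                   endpoints = c("commoncropnames", "variants", "callsets", "allelematrix")),
    backend_config("wheat", "mock://wheat", prefix = "whe",
                   endpoints = c("commoncropnames", "variants", "callsets", "allelematrix"))
  ))
}

test_that("namespace_record prefixes owned DbId fields and nothing else", {
  bar <- backend_config("barley", "mock://b", prefix = "bar",
                        endpoints = c("germplasm", "variants", "callsets"))
  rec <- namespace_record(
    list(germplasmDbId = "G1", germplasmName = "Alpha"), bar, "-"
  )
  expect_identical(rec, list(germplasmDbId = "bar-G1", germplasmName = "Alpha"))

  # list-valued identifier attributes are prefixed element-wise
  rec2 <- namespace_record(
    list(variantDbId = "V9", callSetDbIds = list("C1", "C2")),
    backend_config("wheat", "mock://w", prefix = "whe",
                   endpoints = c("variants", "callsets")),
    "-"
  )
  expect_identical(rec2$variantDbId, "whe-V9")
  expect_identical(rec2$callSetDbIds, list("whe-C1", "whe-C2"))

  # empty prefix: identity
  rec3 <- list(germplasmDbId = "G1", x = list(sampleDbId = "S1"))
  expect_identical(
    namespace_record(rec3, backend_config("pheno", "mock://p", prefix = ""), "-"),
    rec3
  )

  # nested records are walked; unknown DbId stems count as backend-internal
  rec4 <- namespace_record(
    list(variantDbId = "V1", referenceDbId = "chr1",
         info = list(callSetDbId = "C1")),
    backend_config("barley", "mock://b", prefix = "bar",
                   endpoints = c("variants", "callsets")), "-"
  )
  expect_identical(rec4$referenceDbId, "bar-chr1")
  expect_identical(rec4$info$callSetDbId, "bar-C1")

  # cross-backend references (entity served elsewhere) pass through
  rec5 <- namespace_record(
    list(callSetDbId = "C1", sampleDbId = "s17"),
    backend_config("barley", "mock://b", prefix = "bar",
                   endpoints = c("variants", "callsets", "allelematrix")), "-"
  )
  expect_identical(rec5$callSetDbId, "bar-C1")
  expect_identical(rec5$sampleDbId, "s17")
})

test_that("resolve_id uses longest-prefix match with fallback", {
  cfg <- three_source_config()
  r <- resolve_id("bar-G1", cfg)
  expect_identical(r$backend$name, "barley")
  expect_identical(r$localId, "G1")

  r2 <- resolve_id("G1", cfg)
  expect_identical(r2$backend$name, "pheno")
  expect_identical(r2$localId, "G1")

  # separator inside the local id survives resolution
  r3 <- resolve_id("bar-G-1-a", cfg)
  expect_identical(r3$localId, "G-1-a")

  no_fallback <- federation_config(list(
    backend_config("barley", "mock://b", prefix = "bar"),
    backend_config("wheat", "mock://w", prefix = "whe")
  ))
  expect_error(resolve_id("xyz-G1", no_fallback),
               class = "brapifed_unresolvable_id")
})

test_that("namespace round-trip is the identity for every configured backend", {
  set.seed(11)
  pool <- c("", "bar", "whe", "oat", "hv", "ta")
  for (rep in 1:40) {
    prefixes <- sample(pool, sample(2:5, 1))
    cfg <- try(federation_config(lapply(seq_along(prefixes), function(i) {
      backend_config(paste0("b", i), "mock://x", prefix = prefixes[[i]])
    })), silent = TRUE)
    if (inherits(cfg, "try-error")) next  # random draw violated prefix rules
    for (i in seq_along(cfg$backends)) {
      b <- cfg$backends[[i]]
      local <- paste0("id", sample(1e6, 1))
      rendered <- render_id(b$prefix, local, cfg$separator)
      r <- resolve_id(rendered, cfg)
      if (nzchar(b$prefix)) {
        expect_identical(r$backend$name, b$name)
        expect_identical(r$localId, local)
      } else {
        expect_identical(r$localId, rendered)
      }
    }
    # injectivity: distinct (backend, localId) pairs render distinctly
    rendered <- unlist(lapply(cfg$backends, function(b) {
      render_id(b$prefix, c("a", "b", "c"), cfg$separator)
    }))
    expect_identical(anyDuplicated(rendered), 0L)
  }
})

test_that("route_filters localizes, forwards or skips per backend", {
  cfg3 <- federation_config(list(
    backend_config("pheno", "mock://p", prefix = ""),
    backend_config("barley", "mock://b", prefix = "bar"),
    backend_config("wheat", "mock://w", prefix = "whe")
  ))

  # single-owner routing
  r <- route_filters(list(germplasmDbId = "bar-G1"), cfg3)
  expect_true(r$pheno$skip)
  expect_false(r$barley$skip)
  expect_identical(r$barley$params$germplasmDbId, "G1")
  expect_true(r$wheat$skip)

  # non-identifier filters broadcast to everyone
  r2 <- route_filters(list(studyType = "trial"), cfg3)
  expect_false(any(vapply(r2, `[[`, logical(1), "skip")))
  expect_identical(r2$wheat$params$studyType, "trial")

  # list-valued filter partitioned by owner (oracle: resolve_id per value)
  values <- c("bar-V1", "whe-V2")
  r3 <- route_filters(list(variantDbId = values), cfg3)
  oracle <- split(
    vapply(values, function(v) resolve_id(v, cfg3)$localId, character(1)),
    vapply(values, function(v) resolve_id(v, cfg3)$backend$name, character(1))
  )
  expect_identical(r3$barley$params$variantDbId, unname(oracle$barley))
  expect_identical(r3$wheat$params$variantDbId, unname(oracle$wheat))
  expect_true(r3$pheno$skip)

  # mixed resolvable/unresolvable values: unresolvable ones are dropped
  no_fallback <- federation_config(list(
    backend_config("barley", "mock://b", prefix = "bar"),
    backend_config("wheat", "mock://w", prefix = "whe")
  ))
  r4 <- route_filters(list(variantDbId = c("bar-V1", "zzz-V9")), no_fallback)
  expect_identical(r4$barley$params$variantDbId, "V1")
  expect_true(r4$wheat$skip)

  # filters on entities a backend does not serve are forwarded globally
  fed3 <- three_source_config()
  r5 <- route_filters(list(sampleDbId = "s17"), fed3, endpoint = "allelematrix")
  expect_true(r5$pheno$skip)                      # no allelematrix capability
  expect_identical(r5$barley$params$sampleDbId, "s17")
  expect_identical(r5$wheat$params$sampleDbId, "s17")
})

test_that("namespacing is applied exactly once along the response path", {
  fed <- stores_federation(
    list(make_list_store("b1", 3), make_list_store("b2", 3)),
    prefixes = c("bar", "whe")
  )
  for (pg in 0:1) {
    page <- federated_list_page("germplasm", list(), pg, 4, fed$client, fed$config)
    ids <- vapply(page$records, `[[`, character(1), "germplasmDbId")
    expect_true(all(grepl("^(bar|whe)-r[0-9]+$", ids)))
    expect_false(any(grepl("(bar|whe)-(bar|whe)-", ids)))
  }
})
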