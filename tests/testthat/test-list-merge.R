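# Oracle: slice the explicit concatenation of labeled items.
oracle_window <- function(totals, page, pageSize) {
  items <- unlist(lapply(seq_along(totals), function(i) {
    if (totals[i] == 0) character(0) else paste0("b", i, ":", seq_len(totals[i]) - 1L)
  }))
  lo <- page * pageSize
  if (lo >= length(items)) return(character(0))
  items[seq.int(lo + 1L, min(lo + pageSize, length(items)))]
}

plan_items <- function(plan) {
  unlist(lapply(plan$subrequests, function(s) {
    paste0("b", s$backend_index, ":", seq.int(s$slice[1], s$slice[2] - 1L))
  })) %||% character(0)
}

test_that("fetch plans select exactly the requested global window", {
  # single-backend passthrough
  p <- compute_fetch_plan(0, 5, 10)
  expect_length(p$subrequests, 1)
  expect_identical(p$subrequests[[1]]$pages, 0L)
  expect_identical(p$subrequests[[1]]$slice, c(0L, 5L))

  # window straddling a backend boundary and a local page boundary
  p2 <- compute_fetch_plan(1, 4, c(3, 5))
  expect_identical(p2$window, c(4L, 8L))
  expect_length(p2$subrequests, 1)
  expect_identical(p2$subrequests[[1]]$backend_index, 2L)
  expect_identical(p2$subrequests[[1]]$pages, c(0L, 1L))
  expect_identical(p2$subrequests[[1]]$slice, c(1L, 5L))

  # window beyond the data: empty plan
  p3 <- compute_fetch_plan(2, 2, c(2, 2))
  expect_length(p3$subrequests, 0)
  expect_identical(p3$window, c(4L, 4L))

  # randomized agreement with the concatenation oracle
  set.seed(21)
  for (i in 1:300) {
    nb <- sample(1:4, 1)
    totals <- sample(0:40, nb, replace = TRUE)
    pageSize <- sample(1:25, 1)
    page <- sample(0:ceiling(sum(totals) / pageSize + 1), 1)
    plan <- compute_fetch_plan(page, pageSize, totals)
    expect_identical(plan_items(plan), oracle_window(totals, page, pageSize))
    for (s in plan$subrequests) {
      expect_lte(length(s$pages), 2L)
    }
  }
})

test_that("probe_totals reads backend totals and honours skip and capability", {
  fed <- stores_federation(
    list(make_list_store("b1", 3), make_list_store("b2", 5)),
    prefixes = c("bar", "whe")
  )
  routing <- route_filters(list(), fed$config, "germplasm")
  probe <- probe_totals("germplasm", routing, fed$client, fed$config)
  expect_identical(probe$totals, c(3L, 5L))

  # a skipped backend contributes 0 with no HTTP call
  clear_client_log(fed$client)
  routing2 <- route_filters(list(germplasmDbId = "bar-r1"), fed$config, "germplasm")
  probe2 <- probe_totals("germplasm", routing2, fed$client, fed$config)
  expect_identical(probe2$totals[2], 0L)
  expect_false("b2" %in% vapply(client_log(fed$client), `[[`, character(1), "backend"))
})

test_that("unreachable backends fail or degrade according to policy", {
  stores <- list(make_list_store("up", 3), make_list_store("down", 5))
  mk <- function(policy) {
    backends <- list(
      backend_config("up", "mock://up", prefix = "bar",
                     endpoints = stores[[1]]$endpoints),
      backend_config("down", "mock://down", prefix = "whe",
                     endpoints = stores[[2]]$endpoints)
    )
    config <- federation_config(backends, onBackendError = policy)
    handlers <- list(
      up = backend_handler(stores[[1]]),
      down = function(endpoint, params) {
        stop_brapifed("brapifed_network_error", "connection refused")
      }
    )
    mock_client(config, handlers)
  }
  client <- mk("fail")
  routing <- route_filters(list(), client$config, "germplasm")
  expect_error(
    probe_totals("germplasm", routing, client, client$config),
    class = "brapifed_federation_error"
  )

  client2 <- mk("degrade")
  probe <- probe_totals("germplasm", routing, client2, client2$config)
  expect_identical(probe$totals, c(3L, 0L))
  expect_true(probe$excluded[2])
  expect_match(probe$status[[1]]$message, "down")
  # the degraded page serves the live backend and carries the warning
  page <- federated_list_page("germplasm", list(), 0, 10, client2, client2$config)
  expect_length(page$records, 3)
  expect_identical(page$status[[1]]$messageType, "WARNING")
})

test_that("executed pages equal the namespaced concatenation oracle", {
  fed <- stores_federation(
    list(make_list_store("pheno", 3), make_list_store("barley", 5)),
    prefixes = c("", "bar")
  )
  oracle <- oracle_concatenation(fed)
  page <- federated_list_page("germplasm", list(), 1, 4, fed$client, fed$config)
  expect_identical(page$records, oracle[5:8])
  expect_identical(page$pagination$totalCount, 8L)
  expect_identical(page$pagination$totalPages, 2L)

  # empty page beyond the data still reports full metadata
  empty <- federated_list_page("germplasm", list(), 5, 4, fed$client, fed$config)
  expect_length(empty$records, 0)
  expect_identical(empty$pagination$totalCount, 8L)
})

test_that("a backend shrinking between probe and fetch yields a truncated page with warning", {
  store <- make_list_store("shrink", 4)
  lying <- function(endpoint, params) {
    body <- backend_handler(store)(endpoint, params)
    body$metadata$pagination$totalCount <- 6L
    body$metadata$pagination$totalPages <- total_pages(6L, body$metadata$pagination$pageSize)
    body
  }
  config <- federation_config(list(
    backend_config("shrink", "mock://s", prefix = "sh",
                   endpoints = store$endpoints)
  ))
  client <- mock_client(config, list(shrink = lying))
  page <- federated_list_page("germplasm", list(), 0, 6, client, config)
  expect_length(page$records, 4)
  expect_identical(page$pagination$totalCount, 6L)
  expect_true(any(vapply(page$status, function(s) s$messageType == "WARNING", logical(1))))
})

test_that("iterating all federated pages reproduces the oracle for random federations", {
  set.seed(31)
  for (rep in 1:25) {
    fed <- random_list_federation(1000 + rep)
    oracle <- oracle_concatenation(fed)
    pageSize <- sample(1:25, 1)
    got <- list()
    n_pages <- max(1L, total_pages(length(oracle), pageSize))
    seen_pages <- list()
    for (pg in seq_len(n_pages) - 1L) {
      page <- federated_list_page("germplasm", list(), pg, pageSize,
                                  fed$client, fed$config, cache = fed$proxy$cache)
      expect_lte(length(page$records), pageSize)
      seen_pages[[pg + 1L]] <- page$records
      got <- c(got, page$records)
    }
    expect_identical(got, oracle)
    # page disjointness: no record appears on two pages
    ids <- unlist(lapply(seen_pages, function(rs) {
      vapply(rs, `[[`, character(1), "germplasmDbId")
    }))
    expect_identical(anyDuplicated(ids), 0L)
  }
})
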