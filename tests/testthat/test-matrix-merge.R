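matrix_federation <- function(nv1, nc1, nv2, nc2, fill = ".") {
  stores <- list(make_matrix_store("m1", nv1, nc1), make_matrix_store("m2", nv2, nc2))
  backends <- lapply(seq_along(stores), function(i) {
    backend_config(stores[[i]]$name, paste0("mock://", stores[[i]]$name),
                   prefix = c("a", "b")[i], endpoints = stores[[i]]$endpoints)
  })
  config <- federation_config(backends, missingGenotype = fill)
  handlers <- lapply(stores, backend_handler)
  names(handlers) <- c("m1", "m2")
  list(config = config, client = mock_client(config, handlers), stores = stores)
}

merged_as_grid <- function(page) {
  g <- page$dataMatrices[[1]]$values
  dimnames(g) <- list(page$variantDbIds, page$callSetDbIds)
  g
}

test_that("matrix windows are planned per backend with at most two pages per axis", {
  plan <- plan_matrix_window(0, 4, 0, 4, c(2, 3), c(2, 2))
  expect_identical(plan$variantWindow, c(0L, 4L))
  expect_identical(plan$subplans[[1]]$variants$slice, c(0L, 2L))
  expect_identical(plan$subplans[[1]]$callsets$slice, c(0L, 2L))
  expect_identical(plan$subplans[[2]]$variants$slice, c(0L, 2L))
  expect_identical(plan$subplans[[2]]$callsets$slice, c(0L, 2L))

  # window entirely inside backend 2
  plan2 <- plan_matrix_window(1, 2, 1, 2, c(2, 3), c(2, 2))
  expect_null(plan2$subplans[[1]]$variants)
  expect_null(plan2$subplans[[1]]$callsets)
  expect_identical(plan2$subplans[[2]]$variants$slice, c(0L, 2L))
  expect_identical(plan2$subplans[[2]]$callsets$slice, c(0L, 2L))

  # out-of-range windows are empty
  plan3 <- plan_matrix_window(9, 5, 0, 5, c(2, 3), c(2, 2))
  expect_true(all(vapply(plan3$subplans, function(s) is.null(s$variants), logical(1))))

  set.seed(41)
  for (i in 1:100) {
    vt <- sample(0:12, 2, replace = TRUE)
    ct <- sample(0:12, 2, replace = TRUE)
    ps <- sample(1:7, 2)
    pl <- plan_matrix_window(sample(0:3, 1), ps[1], sample(0:3, 1), ps[2], vt, ct)
    for (s in pl$subplans) {
      if (!is.null(s$variants)) expect_lte(length(s$variants$pages), 2L)
      if (!is.null(s$callsets)) expect_lte(length(s$callsets$pages), 2L)
    }
  }
})

test_that("two 1x1 backends merge into the block-diagonal 2x2 grid", {
  stores <- list(make_matrix_store("m1", 1, 1), make_matrix_store("m2", 1, 1))
  stores[[1]]$matrix[1, 1] <- "0/0"
  stores[[2]]$matrix[1, 1] <- "1/1"
  backends <- lapply(seq_along(stores), function(i) {
    backend_config(stores[[i]]$name, "mock://x", prefix = c("a", "b")[i],
                   endpoints = stores[[i]]$endpoints)
  })
  config <- federation_config(backends, missingGenotype = ".")
  handlers <- lapply(stores, backend_handler)
  names(handlers) <- c("m1", "m2")
  client <- mock_client(config, handlers)
  page <- filtered_matrix(list(dimensionVariantPageSize = 2,
                               dimensionCallSetPageSize = 2), client, config)
  expect_identical(page$variantDbIds, c("a-v1", "b-v1"))
  expect_identical(page$callSetDbIds, c("a-c1", "b-c1"))
  expect_identical(page$dataMatrices[[1]]$values,
                   matrix(c("0/0", ".", ".", "1/1"), 2, 2, byrow = TRUE))
  expect_identical(page$pagination$VARIANTS$totalCount, 2L)
  expect_identical(page$pagination$CALLSETS$totalCount, 2L)
})

test_that("a single backend merges to itself with namespaced axes", {
  fed <- matrix_federation(3, 2, 0, 0)
  page <- filtered_matrix(list(), fed$client, fed$config)
  expect_identical(page$variantDbIds, paste0("a-v", 1:3))
  expect_identical(page$callSetDbIds, paste0("a-c", 1:2))
  expect_identical(unname(page$dataMatrices[[1]]$values),
                   unname(fed$stores[[1]]$matrix))
})

test_that("tiling all 2D pages reconstructs the block-diagonal matrix exactly once", {
  set.seed(51)
  for (rep in 1:12) {
    dims <- sample(1:9, 4, replace = TRUE)
    fed <- matrix_federation(dims[1], dims[2], dims[3], dims[4])
    oracle <- oracle_block_diagonal(fed, ".")
    vps <- sample(1:5, 1)
    cps <- sample(1:5, 1)
    nvp <- max(1L, total_pages(nrow(oracle), vps))
    ncp <- max(1L, total_pages(ncol(oracle), cps))
    seen <- matrix(0L, nrow(oracle), ncol(oracle), dimnames = dimnames(oracle))
    for (vp in seq_len(nvp) - 1L) {
      for (cp in seq_len(ncp) - 1L) {
        page <- filtered_matrix(list(
          dimensionVariantPage = vp, dimensionVariantPageSize = vps,
          dimensionCallSetPage = cp, dimensionCallSetPageSize = cps
        ), fed$client, fed$config)
        g <- merged_as_grid(page)
        if (length(g) == 0) next
        expect_identical(g, oracle[rownames(g), colnames(g), drop = FALSE])
        seen[rownames(g), colnames(g)] <- seen[rownames(g), colnames(g)] + 1L
      }
    }
    expect_true(all(seen == 1L))
    # conservation: axis totals are the sums over backends
    page <- filtered_matrix(list(), fed$client, fed$config)
    expect_identical(page$pagination$VARIANTS$totalCount, as.integer(dims[1] + dims[3]))
    expect_identical(page$pagination$CALLSETS$totalCount, as.integer(dims[2] + dims[4]))
  }
})

test_that("matrix filters route to owning backends and fill cross cells", {
  fed <- matrix_federation(4, 3, 5, 2)
  clear_client_log(fed$client)
  page <- filtered_matrix(list(variantDbId = "a-v2"), fed$client, fed$config)
  expect_identical(page$variantDbIds, "a-v2")
  expect_identical(page$callSetDbIds, paste0("a-c", 1:3))
  called <- unique(vapply(client_log(fed$client), `[[`, character(1), "backend"))
  expect_identical(called, "m1")

  # filters spanning both crops: both called, cross cells filled
  page2 <- filtered_matrix(list(variantDbId = c("a-v1", "b-v1")),
                           fed$client, fed$config)
  g <- merged_as_grid(page2)
  expect_identical(g["a-v1", "b-c1"], ".")
  expect_identical(g["b-v1", "a-c1"], ".")
  expect_identical(g["a-v1", "a-c2"], fed$stores[[1]]$matrix[1, 2])

  # unresolvable filter values give an empty result
  page3 <- filtered_matrix(list(variantDbId = "zzz-v1"), fed$client, fed$config)
  expect_length(page3$variantDbIds, 0)
  expect_identical(page3$pagination$VARIANTS$totalCount, 0L)
})

test_that("data matrices are matched by name; absent blocks are filled", {
  plan <- plan_matrix_window(0, 4, 0, 4, c(1, 1), c(1, 1))
  blocks <- list(
    list(variantDbIds = "v1", callSetDbIds = "c1",
         matrices = list(genotype = matrix("0/1", 1, 1)),
         dataTypes = c(genotype = "string")),
    list(variantDbIds = "v1", callSetDbIds = "c1",
         matrices = list(genotype = matrix("1/1", 1, 1),
                         depth = matrix("7", 1, 1)),
         dataTypes = c(genotype = "string", depth = "integer"))
  )
  config <- federation_config(list(
    backend_config("m1", "mock://1", prefix = "a",
                   endpoints = c("variants", "callsets", "allelematrix")),
    backend_config("m2", "mock://2", prefix = "b",
                   endpoints = c("variants", "callsets", "allelematrix"))
  ))
  page <- assemble_matrix(plan, blocks, ".", config)
  names(page$dataMatrices) <- vapply(page$dataMatrices, `[[`, character(1), "dataMatrixName")
  expect_setequal(names(page$dataMatrices), c("genotype", "depth"))
  expect_identical(page$dataMatrices$depth$values,
                   matrix(c(".", ".", ".", "7"), 2, 2, byrow = TRUE))
  expect_identical(page$dataMatrices$depth$dataType, "integer")
  expect_identical(page$dataMatrices$genotype$values[1, 1], "0/1")
})
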