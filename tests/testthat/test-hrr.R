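test_that("pearson_profile reproduces closed-form correlations", {
  expr <- tibble::tibble(
    gene_id = c("q", "lin", "anti", "perm"),
    s1 = c(1, 2, 3, 1), s2 = c(2, 4, 2, 3), s3 = c(3, 6, 1, 2)
  )
  p <- pearson_profile(expr, "q")
  pcc <- setNames(p$pcc, p$partner)
  expect_equal(pcc[["lin"]], 1.0)
  expect_equal(pcc[["anti"]], -1.0)
  # deviations (-1,0,1) . (-1,1,0) / 2 = 0.5
  expect_equal(pcc[["perm"]], 0.5)
  expect_error(pearson_profile(expr, "nope"), "nope",
               class = "hrrnet_lookup_error")
})

test_that("pearson_profile refuses zero-variance genes", {
  expr <- tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 5), s2 = c(2, 5),
                         s3 = c(3, 5))
  expect_error(pearson_profile(expr, "a"), "b",
               class = "hrrnet_validation_error")
})

test_that("directed ranks sort by PCC descending with lexicographic tie-break", {
  prof <- tibble::tibble(query = "A", partner = c("B", "C", "D"),
                         pcc = c(0.9, 0.5, 0.1))
  rk <- directed_ranks(prof)
  expect_equal(setNames(rk$rank, rk$partner), c(B = 1L, C = 2L, D = 3L))

  tied <- tibble::tibble(query = "A", partner = c("D", "B", "C"),
                         pcc = c(0.9, 0.9, 0.5))
  rk2 <- directed_ranks(tied)
  expect_equal(setNames(rk2$rank, rk2$partner), c(B = 1L, D = 2L, C = 3L))

  single <- tibble::tibble(query = "A", partner = "B", pcc = 0.0)
  expect_equal(directed_ranks(single)$rank, 1L)
})

test_that("hrr_value is the max of the two directed ranks and symmetric", {
  expect_equal(hrr_value(3L, 7L), 7L)
  expect_equal(hrr_value(1L, 1L), 1L)
  expect_equal(hrr_value(7L, 3L), hrr_value(3L, 7L))
  withr::with_seed(5, {
    a <- sample(1000L, 100, replace = TRUE)
    b <- sample(1000L, 100, replace = TRUE)
    expect_identical(hrr_value(a, b), hrr_value(b, a))
  })
  expect_error(hrr_value(0L, 3L), class = "hrrnet_validation_error")
  expect_error(hrr_value(1.5, 3), class = "hrrnet_validation_error")
})

test_that("toy-matrix neighborhoods match the hand computation", {
  expr <- toy_matrix()
  p <- pearson_profile(expr, "A")
  expect_equal(p$pcc[p$partner == "D"], 0.8)

  nb1 <- hrr_neighborhood(expr, "A", cutoff = 1)
  expect_equal(nb1$partner, "B")
  expect_equal(nb1$pcc, 1.0)
  expect_equal(nb1$hrr, 1L)

  nb2 <- hrr_neighborhood(expr, "A", cutoff = 2)
  expect_equal(nb2$partner, c("B", "D"))
  expect_equal(nb2$hrr, c(1L, 2L))

  # exclusive cutoff drops edges at the boundary
  nb2x <- hrr_neighborhood(expr, "A", cutoff = 2, inclusive = FALSE)
  expect_equal(nb2x$partner, "B")
})

test_that("a cutoff below the minimum attainable HRR yields an empty neighborhood", {
  expr <- random_matrix(20, 8, seed = 9)
  nb <- hrr_neighborhood(expr, expr$gene_id[1], cutoff = 1)
  full <- hrr_neighborhood(expr, expr$gene_id[1], cutoff = 19)
  if (min(full$hrr) > 1) expect_equal(nrow(nb), 0)
  expect_true(all(c("query", "partner", "pcc", "hrr") %in% names(nb)))
})

test_that("the all-pairs table covers each unordered pair once with symmetric HRR", {
  expr <- toy_matrix()
  edges <- hrr_all_pairs(expr)
  expect_equal(nrow(edges), 6)
  expect_true(all(edges$gene_a < edges$gene_b))
  expect_equal(edges$hrr[edges$gene_a == "A" & edges$gene_b == "B"], 1L)
  expect_equal(edges$hrr, pmax(edges$rank_ab, edges$rank_ba))

  two <- random_matrix(2, 5, seed = 2)
  e2 <- hrr_all_pairs(two)
  expect_equal(nrow(e2), 1)
  expect_equal(c(e2$rank_ab, e2$rank_ba, e2$hrr), c(1L, 1L, 1L))

  big <- tibble::tibble(gene_id = sprintf("g%d", 1:2001),
                        s1 = 1:2001, s2 = (1:2001)^2, s3 = sqrt(1:2001))
  expect_error(hrr_all_pairs(big), class = "hrrnet_size_error")
})

test_that("per-query neighborhoods equal the all-pairs oracle for all queries and cutoffs", {
  expr <- random_matrix(50, 10, seed = 7)
  edges <- hrr_all_pairs(expr)
  for (q in expr$gene_id[c(1, 13, 50)]) {
    for (cutoff in c(1, 5, 25, 49)) {
      nb <- hrr_neighborhood(expr, q, cutoff = cutoff)
      ref <- oracle_neighborhood(edges, q, cutoff)
      expect_equal(nb$partner, ref$partner)
      expect_equal(nb$hrr, ref$hrr)
      expect_equal(nb$rank_query_to_partner, ref$rank_query_to_partner)
      expect_equal(nb$rank_partner_to_query, ref$rank_partner_to_query)
      expect_equal(nb$pcc, ref$pcc, tolerance = 1e-12)
    }
  }
})

test_that("rank tables are permutations of 1..G-1", {
  expr <- random_matrix(30, 12, seed = 21)
  for (q in expr$gene_id[c(1, 15, 30)]) {
    rk <- directed_ranks(pearson_profile(expr, q))
    expect_setequal(rk$rank, 1:29)
  }
})

test_that("neighborhoods nest monotonically in the cutoff", {
  expr <- random_matrix(40, 15, seed = 31)
  q <- expr$gene_id[5]
  prev <- character(0)
  for (cutoff in c(2, 5, 10, 20, 39)) {
    nb <- hrr_neighborhood(expr, q, cutoff = cutoff)
    expect_true(all(prev %in% nb$partner))
    expect_true(all(nb$hrr <= cutoff))
    prev <- nb$partner
  }
})

test_that("PCC ranks and HRR are invariant under positive per-gene affine transforms", {
  expr <- random_matrix(25, 10, seed = 17)
  scaled <- expr
  withr::with_seed(18, {
    slopes <- runif(25, 0.5, 4)
    offsets <- runif(25, 0, 10)
  })
  scaled[, -1] <- scaled[, -1] * slopes + offsets
  q <- expr$gene_id[3]
  nb1 <- hrr_neighborhood(expr, q, cutoff = 24)
  nb2 <- hrr_neighborhood(scaled, q, cutoff = 24)
  expect_equal(nb1$partner, nb2$partner)
  expect_equal(nb1$hrr, nb2$hrr)
  expect_equal(nb1$pcc, nb2$pcc, tolerance = 1e-10)
})

test_that("neighborhood TSV output round-trips through readr", {
  expr <- random_matrix(20, 8, seed = 4)
  nb <- hrr_neighborhood(expr, expr$gene_id[2], cutoff = 10)
  path <- tempfile(fileext = ".tsv")
  write_neighborhood_tsv(nb, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$partner, nb$partner)
  expect_equal(back$hrr, as.numeric(nb$hrr))
  unlink(path)
  g <- glance(nb)
  expect_equal(g$n_partners, nrow(nb))
  expect_equal(g$cutoff, 10)
})
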