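test_that("the generator is a pure function of its spec and seed", {
  sim1 <- simulate_expression(n_genes = 80, n_samples = 40,
                              modules = list(c(size = 10, loading = 2)),
                              seed = 42)
  sim2 <- simulate_expression(n_genes = 80, n_samples = 40,
                              modules = list(c(size = 10, loading = 2)),
                              seed = 42)
  expect_identical(sim1$expression, sim2$expression)
  sim3 <- simulate_expression(n_genes = 80, n_samples = 40,
                              modules = list(c(size = 10, loading = 2)),
                              seed = 43)
  expect_false(identical(sim1$expression, sim3$expression))
})

test_that("adding a module does not perturb earlier background genes' draws", {
  one <- simulate_expression(n_genes = 100, n_samples = 20,
                             modules = list(c(size = 10, loading = 2)),
                             seed = 5)
  two <- simulate_expression(n_genes = 100, n_samples = 20,
                             modules = list(c(size = 10, loading = 2),
                                            c(size = 10, loading = 1)),
                             seed = 5)
  # genes 21..100 are background in both runs; their noise streams are
  # per-gene, so values agree up to the global non-negativity shift
  a <- as.matrix(one$expression[21:100, -1])
  b <- as.matrix(two$expression[21:100, -1])
  shift <- a[1, 1] - b[1, 1]
  expect_equal(a - shift, b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("matrix is non-negative with the planted layout and TPM-like shape", {
  sim <- simulate_expression(n_genes = 120, n_samples = 30,
                             modules = list(c(size = 15, loading = 2),
                                            c(size = 20, loading = 3)),
                             seed = 8)
  x <- as.matrix(sim$expression[-1])
  expect_true(all(x >= 0))
  expect_equal(min(x), 0)
  expect_equal(sim$truth$module_of$module[1:15], rep(1L, 15))
  expect_equal(sim$truth$module_of$module[16:35], rep(2L, 20))
  expect_true(all(is.na(sim$truth$module_of$module[36:120])))
})

test_that("within-module correlation matches the closed form beta^2/(beta^2+sigma^2)", {
  sim <- simulate_expression(n_genes = 200, n_samples = 100,
                             modules = list(c(size = 50, loading = 2)),
                             noise_sd = 1, seed = 42)
  x <- as.matrix(sim$expression[1:50, -1])
  cc <- stats::cor(t(x))
  mean_pcc <- mean(cc[upper.tri(cc)])
  expect_lt(abs(mean_pcc - 0.8), 0.05)
})

test_that("zero loading gives uncorrelated module genes", {
  sim <- simulate_expression(n_genes = 60, n_samples = 100,
                             modules = list(c(size = 20, loading = 0)),
                             noise_sd = 1, seed = 9)
  x <- as.matrix(sim$expression[1:20, -1])
  cc <- stats::cor(t(x))
  expect_lt(abs(mean(cc[upper.tri(cc)])), 4 / sqrt(100))
})

test_that("generator specs are validated", {
  expect_error(simulate_expression(n_genes = 10, modules = list(c(size = 50, loading = 1))),
               class = "hrrnet_validation_error")
  expect_error(simulate_expression(modules = list(c(size = 1, loading = 1))),
               class = "hrrnet_validation_error")
  expect_error(simulate_expression(noise_sd = 0), class = "hrrnet_validation_error")
})

test_that("planted annotations cover modules at the requested rate", {
  sim <- simulate_expression(n_genes = 150, n_samples = 20,
                             modules = list(c(size = 50, loading = 2)),
                             seed = 3)
  full <- simulate_annotations(sim$truth, module_coverage = 1.0,
                               background_rate = 0.05, seed = 3)
  planted <- attr(full, "planted_terms")$term[1]
  expect_gte(sum(full$term == planted), 50)

  none <- simulate_annotations(sim$truth, module_coverage = 1.0,
                               background_rate = 0, n_terms = 0, seed = 3)
  expect_true(all(none$term == planted))
  expect_true(all(none$aspect == "biological_process"))

  part1 <- simulate_annotations(sim$truth, module_coverage = 0.8, seed = 11)
  part2 <- simulate_annotations(sim$truth, module_coverage = 0.8, seed = 11)
  expect_identical(part1, part2)
  k <- sum(part1$term == planted)
  expect_true(k >= 25 && k <= 50) # binomial draw around 40

  expect_error(simulate_annotations(sim$truth, module_coverage = 1.2),
               class = "hrrnet_validation_error")
})

test_that("ortholog maps realise the requested one-to-one and duplicated structure", {
  gx <- sprintf("x%03d", 1:50)
  gy <- sprintf("y%03d", 1:60)
  bij <- simulate_orthologs(gx, gy, one_to_one = 1.0, duplicated = 0, seed = 2)
  expect_equal(nrow(bij), 50)
  expect_equal(anyDuplicated(bij$gene_x), 0L)
  expect_equal(anyDuplicated(bij$gene_y), 0L)

  empty <- simulate_orthologs(gx, gy, one_to_one = 0, duplicated = 0, seed = 2)
  expect_equal(nrow(empty), 0)

  mixed <- simulate_orthologs(gx, gy, one_to_one = 0.6, duplicated = 0.2, seed = 7)
  per_x <- table(mixed$gene_x)
  expect_equal(sum(per_x == 1), 30)
  expect_equal(sum(per_x == 2), 10)
  expect_identical(mixed, simulate_orthologs(gx, gy, one_to_one = 0.6,
                                             duplicated = 0.2, seed = 7))

  expect_error(simulate_orthologs(gx, gy[1:3], one_to_one = 1.0),
               class = "hrrnet_validation_error")
})

test_that("module recovery: HRR neighborhood of a module gene is precise against truth", {
  sim <- simulate_expression(n_genes = 300, n_samples = 100,
                             modules = list(c(size = 30, loading = 2)),
                             noise_sd = 1, seed = 77)
  truth_members <- sim$truth$module_of$gene_id[!is.na(sim$truth$module_of$module)]
  q <- truth_members[1]
  nb <- hrr_neighborhood(sim$expression, q, cutoff = 29)
  precision <- mean(nb$partner %in% truth_members)
  expect_gte(precision, 0.9)
})
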