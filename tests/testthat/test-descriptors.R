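test_that("the default panel has 208 named descriptors and computes known values", {
  provider <- ob_descriptor_provider()
  expect_length(provider$descriptor_names, 208)
  expect_false(anyDuplicated(provider$descriptor_names) > 0)

  records <- data.frame(compound_id = "benzene", smiles = "c1ccccc1")
  m <- compute_descriptors(records, provider)
  expect_identical(dim(m), c(1L, 208L))
  expect_equal(unname(m[1, "ob_MW"]), 78.11, tolerance = 1e-3)
  expect_equal(unname(m[1, "elem_C"]), 6)
  expect_equal(unname(m[1, "elem_N"]), 0)
})

test_that("descriptor computation is deterministic and rejects bad structures", {
  records <- data.frame(compound_id = c("a", "b", "c"),
                        smiles = c("CCO", "C1CC", "c1ccncc1"))
  expect_warning(m1 <- compute_descriptors(records), "rejected")
  expect_identical(rownames(m1), c("a", "c"))
  expect_identical(attr(m1, "rejects")$compound_id, "b")
  m2 <- suppressWarnings(compute_descriptors(records))
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])
})

test_that("an empty record list yields an empty matrix with the full name list", {
  empty <- data.frame(compound_id = character(), smiles = character())
  m <- compute_descriptors(empty, ob_descriptor_provider())
  expect_identical(nrow(m), 0L)
  expect_identical(colnames(m), ob_descriptor_provider()$descriptor_names)
})

test_that("the file-backed provider serves precomputed rows and reports missing ids", {
  d <- tiny_qsar()
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(compound_id = rownames(d$descriptors),
                   as.data.frame(unclass(d$descriptors)), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  provider <- file_descriptor_provider(path)
  sub <- data.frame(compound_id = c(rownames(d$descriptors)[3:5], "ghost"),
                    smiles = "CC")
  m <- suppressWarnings(compute_descriptors(sub, provider))
  expect_identical(rownames(m), rownames(d$descriptors)[3:5])
  expect_equal(unclass(m)[, ], unclass(d$descriptors)[3:5, ])
  expect_identical(attr(m, "rejects")$compound_id, "ghost")
})

test_that("standardization centres and scales the training matrix exactly", {
  d <- tiny_qsar()
  m <- d$descriptors
  std <- fit_standardizer(m)
  z <- apply_standardizer(std, m)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  nonconst <- apply(unclass(m), 2, sd) > 0
  expect_equal(unname(apply(unclass(z)[, nonconst], 2, sd)),
               rep(1, sum(nonconst)), tolerance = 1e-12)
  # constant columns map to exactly 0 via unit scale
  expect_true(all(unclass(z)[, !nonconst] == 0))
  expect_true(all(std$scale[!nonconst] == 1))
})

test_that("held-out data standardized with training parameters stays near zero mean", {
  train <- tiny_qsar(seed = 5)
  test <- tiny_qsar(seed = 6)
  std <- fit_standardizer(train$descriptors)
  z <- apply_standardizer(std, test$descriptors)
  nonconst <- apply(unclass(train$descriptors), 2, sd) > 0
  # sampling error at n = 240 is ~1/sqrt(240); allow 4 sigma
  expect_lt(max(abs(colMeans(unclass(z)[, nonconst]))), 4 / sqrt(240))
})

test_that("standardizer refuses mismatched descriptor panels", {
  d <- tiny_qsar()
  std <- fit_standardizer(d$descriptors)
  wrong <- unclass(d$descriptors)
  colnames(wrong)[1] <- "unseen_descriptor"
  expect_error(apply_standardizer(std, wrong), "unseen_descriptor|do not match")
})

test_that("chemical-space PCA satisfies its structural invariants", {
  d <- tiny_qsar()
  z <- apply_standardizer(fit_standardizer(d$descriptors), d$descriptors)
  cs <- fit_chemspace(z, n_components = 3)
  expect_true(all(diff(cs$ev_ratio) <= 1e-12))
  expect_lte(sum(cs$ev_ratio), 1 + 1e-12)
  gram <- t(cs$loadings) %*% cs$loadings
  expect_equal(gram, diag(3), ignore_attr = TRUE, tolerance = 1e-10)
  # projecting the training centroid lands at the origin
  centroid <- matrix(colMeans(unclass(z)), 1,
                     dimnames = list("centroid", colnames(z)))
  proj <- project_chemspace(cs, centroid)
  expect_lt(max(abs(unlist(proj[, -1]))), 1e-9)
  # per-component score variance reproduces the explained-variance ratios
  scores <- project_chemspace(cs, z)
  total_var <- sum(apply(unclass(z), 2, var))
  got <- apply(scores[, -1], 2, var) / total_var
  expect_equal(unname(got), unname(cs$ev_ratio), tolerance = 1e-8)
  expect_error(fit_chemspace(z, n_components = ncol(z) + 1), "n_components")
})

test_that("isotropic Gaussian data spreads variance evenly over components", {
  set.seed(42)
  m <- matrix(rnorm(4000), 500, 8, dimnames = list(NULL, paste0("g", 1:8)))
  cs <- fit_chemspace(m, n_components = 8)
  # under isotropy each ratio is 1/8 within sampling error
  expect_lt(max(abs(cs$ev_ratio - 1 / 8)), 0.03)
})

test_that("applicability domain covers training data and flags outliers", {
  d <- tiny_qsar()
  z <- apply_standardizer(fit_standardizer(d$descriptors), d$descriptors)
  cs <- fit_chemspace(z, n_components = 2)
  ad <- applicability_domain(cs, z, margin = 0)
  expect_identical(ad$overlap_fraction, 1)
  far <- unclass(z)[1, , drop = FALSE] * 0 +
    10 * matrix(cs$ranges[2, 1] * cs$loadings[, 1], 1)
  colnames(far) <- colnames(z)
  expect_false(applicability_domain(cs, far)$flags$in_domain)
})

test_that("applicability overlap is monotone in the margin and high for in-distribution data", {
  train <- tiny_qsar(seed = 5)
  lib <- tiny_qsar(seed = 9)
  std <- fit_standardizer(train$descriptors)
  cs <- fit_chemspace(apply_standardizer(std, train$descriptors), 2)
  zlib <- apply_standardizer(std, lib$descriptors)
  overlaps <- vapply(c(0, 0.05, 0.1, 0.2),
                     function(mg) applicability_domain(cs, zlib, mg)$overlap_fraction,
                     numeric(1))
  expect_true(all(diff(overlaps) >= 0))
  expect_gt(overlaps[1], 0.9)
})
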