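test_that("acat_combine matches independently computed reference values", {
  # frozen values from a 40-digit arbitrary-precision evaluation of the
  # weighted Cauchy combination formula
  expect_equal(acat_combine(c(0.01, 0.5)), 0.019980299664053647,
               tolerance = 1e-14)
  expect_equal(acat_combine(c(0.01, 0.5, 0.2), weights = c(1, 2, 3)),
               0.05264073149758981, tolerance = 1e-14)
  expect_equal(acat_combine(c(0.001, 0.9, 0.9, 0.9)), 0.004119275966025263,
               tolerance = 1e-14)
  expect_equal(acat_combine(0.3), 0.3)
})

test_that("combining identical P values is a fixed point to 12+ digits", {
  for (p0 in c(1e-8, 0.001, 0.025, 0.3, 0.5, 0.77, 0.999)) {
    got <- acat_combine(rep(p0, 7))
    expect_equal(got, p0, tolerance = 1e-13)
  }
})

test_that("combined P is strictly decreasing in any single input", {
  base <- c(0.2, 0.4, 0.6)
  ref <- acat_combine(base)
  for (i in seq_along(base)) {
    lower <- base; lower[i] <- base[i] / 2
    expect_lt(acat_combine(lower), ref)
  }
})

test_that("weights are scale-invariant and inputs permutation-invariant", {
  p <- c(0.01, 0.3, 0.8)
  w <- c(1, 2, 5)
  expect_identical(acat_combine(p, w), acat_combine(p, w * 137.5))
  set.seed(1)
  for (i in 1:5) {
    ord <- sample(3)
    expect_equal(acat_combine(p[ord], w[ord]), acat_combine(p, w),
                 tolerance = 1e-15)
  }
})

test_that("invalid inputs to acat_combine raise structured errors", {
  expect_error(acat_combine(numeric(0)), class = "arch_config_error")
  expect_error(acat_combine(c(0.1, 0)), class = "arch_input_error")
  expect_error(acat_combine(c(0.1, 1)), class = "arch_input_error")
  expect_error(acat_combine(0.5, weights = -1), class = "arch_config_error")
  expect_error(acat_combine(c(0.1, 0.2), weights = 1), class = "arch_config_error")
  # sub-clamp values are clamped with a warning, not rejected
  expect_warning(acat_combine(c(1e-20, 0.5)), "clamped")
})

test_that("annotation_matrix validates shape, missingness and weights", {
  m <- annotation_matrix(matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2),
                         variant_ids = c("a", "b"),
                         layer_names = c("L1", "L2"))
  expect_s3_class(m, "annotation_matrix")
  expect_error(annotation_matrix(matrix(c(0.1, NA), 1, 2)),
               class = "arch_input_error")
  imp <- annotation_matrix(matrix(c(0.1, 0.3, NA, 0.2, 0.4, 0.6), 3, 2),
                           impute = "layer_mean")
  expect_equal(imp$p[3, 1], 0.2)  # layer mean of the observed cells
  expect_error(annotation_matrix(matrix(0.5, 1, 2), weights = c(1, -1)),
               class = "arch_config_error")
})

test_that("layer means equal brute-force column means", {
  m1 <- annotation_matrix(matrix(c(0.1, 0.4), 1, 2),
                          variant_ids = "a", layer_names = c("L1", "L2"))
  expect_equal(unname(layer_means(m1)), c(0.1, 0.4))
  mc <- annotation_matrix(matrix(0.2, 5, 3))
  expect_equal(unname(layer_means(mc)), rep(0.2, 3))

  m <- simulate_annotations(sprintf("v%02d", 1:40), n_layers = 4, seed = 2)
  lm <- layer_means(m)
  for (j in seq_len(ncol(m$p))) {
    expect_equal(unname(lm[j]), oracle_mean(m$p[, j]))
  }
})

test_that("variant spread returns per-row min and max", {
  m1 <- annotation_matrix(matrix(c(0.3, 0.6), 2, 1))
  sp1 <- variant_spread(m1)
  expect_equal(sp1$p_min, sp1$p_max)
  m <- annotation_matrix(matrix(c(0.1, 0.4, 0.2, 0.3), 1, 4))
  sp <- variant_spread(m)
  expect_equal(sp$p_min, 0.1)
  expect_equal(sp$p_max, 0.4)
  sim <- simulate_annotations(sprintf("v%02d", 1:30), n_layers = 5, seed = 3)
  got <- variant_spread(sim)
  for (i in seq_len(nrow(sim$p))) {
    expect_equal(got$p_min[i], min(sim$p[i, ]))
    expect_equal(got$p_max[i], max(sim$p[i, ]))
    expect_lte(got$p_min[i], got$p_max[i])
  }
})

test_that("layer correlation is computed on -log10 p with unit diagonal", {
  p <- matrix(runif(200, 0.01, 0.99), 100, 2)
  ident <- annotation_matrix(cbind(p[, 1], p[, 1]))
  cc <- layer_correlation(ident)
  expect_equal(unname(cc[1, 2]), 1)
  expect_equal(unname(diag(cc)), c(1, 1))

  # analytic anti-linear construction: -log10 p2 = c - (-log10 p1)
  y1 <- runif(100, 0.5, 2)
  p_anti <- cbind(10^(-y1), 10^(-(3 - y1)))
  cc2 <- layer_correlation(annotation_matrix(p_anti))
  expect_equal(unname(cc2[1, 2]), -1, tolerance = 1e-10)

  const <- annotation_matrix(cbind(p[, 1], rep(0.5, 100)))
  expect_warning(cc3 <- layer_correlation(const), "zero variance")
  expect_true(is.na(cc3[1, 2]))
  expect_equal(unname(diag(cc3)), c(1, 1))
})

test_that("simulated layers recover the target correlation at n = 1000", {
  m0 <- simulate_annotations(sprintf("v%04d", 1:1000), n_layers = 3,
                             rho = 0, seed = 7)
  cc0 <- layer_correlation(m0)
  expect_true(all(abs(cc0[upper.tri(cc0)]) < 0.12))

  m5 <- simulate_annotations(sprintf("v%04d", 1:1000), n_layers = 4,
                             rho = 0.5, seed = 8)
  cc5 <- layer_correlation(m5)
  expect_true(all(abs(cc5[upper.tri(cc5)] - 0.5) < 0.12))
  expect_true(all(cc5 >= -1 & cc5 <= 1))
})

test_that("annotation matrices round-trip through TSV with optional weights", {
  m <- simulate_annotations(sprintf("v%02d", 1:6), n_layers = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    cbind(data.frame(variant_id = rownames(m$p)), as.data.frame(m$p)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- read_annotation_matrix(path)
  expect_equal(dim(rt$p), dim(m$p))
  expect_equal(rt$p, m$p, tolerance = 1e-14)

  wpath <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(layer = colnames(m$p), weight = c(1, 2, 3)),
                     wpath, sep = "\t", quote = FALSE, row.names = FALSE)
  rtw <- read_annotation_matrix(path, weights_path = wpath)
  expect_equal(rtw$weights, c(1, 2, 3))
  bad <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(layer = "other", weight = 1), bad,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation_matrix(path, weights_path = bad),
               class = "arch_config_error")
})
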