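soft_specs <- build_component_specs("soft")
bone_specs <- build_component_specs("bone")

test_that("pure-tissue sampling honours the reference moments", {
  set.seed(101)
  raw <- sample_pure(soft_specs$adipose, 1e5, renormalize = FALSE)
  # all fractions non-negative (rejection post-condition)
  expect_true(all(as.matrix(raw[, c("wH", "wC", "wN", "wO", "wCa")]) >= 0))
  # Monte-Carlo mean of H within 3 standard errors of the 11.4% reference
  se <- 0.002 / sqrt(1e5)
  expect_lt(abs(mean(raw$wH) - 0.114), 3 * se)
  # SD of H close to the worked 0.2% value
  expect_equal(sd(raw$wH), 0.002, tolerance = 0.02)
  # soft tissue carries no calcium
  expect_true(all(raw$wCa == 0))

  set.seed(102)
  cort <- sample_pure(bone_specs$cortical_bone, 1e5, renormalize = FALSE)
  expect_true(all(cort$wH >= 0.0335 & cort$wH <= 0.0345))
  # red-marrow Ca: precision range truncated at zero by rejection
  set.seed(103)
  rm_ <- sample_pure(bone_specs$red_marrow, 2e4, renormalize = FALSE)
  expect_true(all(rm_$wCa >= 0 & rm_$wCa <= 0.0005))
})

test_that("renormalized compositions lie on the unit simplex", {
  set.seed(104)
  for (sp in list(soft_specs$adipose, bone_specs$cortical_bone)) {
    s <- sample_pure(sp, 500)
    sums <- rowSums(s[, c("wH", "wC", "wN", "wO", "wCa")])
    expect_equal(sums, rep(1, 500), tolerance = 1e-12)
  }
  m <- sample_mixture(soft_specs$adipose, soft_specs$muscle, 500)
  expect_equal(rowSums(m[, c("wH", "wC", "wN", "wO", "wCa")]),
               rep(1, 500), tolerance = 1e-12)
})

test_that("mixtures blend fractions convexly and densities harmonically", {
  set.seed(21)
  # fixed mixing ratio: fractions are convex combinations of the
  # component ranges, density between the component densities
  m <- sample_mixture(bone_specs$cortical_bone, bone_specs$red_marrow,
                      2000, w1 = 0.5)
  expect_true(all(m$mixing_ratio == 0.5))
  expect_true(all(m$component_label == "mixture"))
  # H always between the two (renormalized) component H ranges
  a_rng <- range(sample_pure(bone_specs$cortical_bone, 2000)$wH)
  b_rng <- range(sample_pure(bone_specs$red_marrow, 2000)$wH)
  expect_true(all(m$wH >= min(a_rng) - 1e-9 & m$wH <= max(b_rng) + 1e-9))
  expect_true(all(m$rho > 1025 - 1 & m$rho < 1925 + 1))
  # degenerate mixture equals a pure draw in distribution
  m1 <- sample_mixture(soft_specs$adipose, soft_specs$muscle, 5000, w1 = 1)
  p1 <- sample_pure(soft_specs$adipose, 5000)
  expect_equal(mean(m1$wH), mean(p1$wH), tolerance = 0.005)
  expect_equal(mean(m1$rho), mean(p1$rho), tolerance = 0.005)
  expect_error(sample_mixture(soft_specs$adipose, soft_specs$muscle,
                              2, w1 = 1.5), "\\[0, 1\\]")
})

test_that("category population is one third per component, shuffled", {
  g <- generate_category("soft", 10000, seed = 0)
  expect_equal(unname(table(g$component_label)[c("adipose", "muscle", "mixture")]),
               c(3334, 3333, 3333), ignore_attr = TRUE)
  g3 <- generate_category("bone", 3, seed = 0)
  expect_setequal(g3$component_label,
                  c("cortical_bone", "red_marrow", "mixture"))
  # different seeds permute differently but keep the label multiset
  a <- generate_category("soft", 300, seed = 0)
  b <- generate_category("soft", 300, seed = 1)
  expect_false(identical(a$component_label, b$component_label))
  expect_equal(sort(a$component_label), sort(b$component_label))
  expect_error(generate_category("soft", 2), "at least 3")
})

test_that("noise injection realizes the SNR definition", {
  mu <- rep(30, 1e5)
  expect_identical(add_noise(mu, Inf), mu)
  set.seed(31)
  noisy <- add_noise(mu, 10)
  sigma <- 30 / 10
  # empirical SD within 3 standard errors (SE of SD ~ sigma / sqrt(2n))
  expect_lt(abs(sd(noisy - mu) - sigma), 3 * sigma / sqrt(2 * 1e5))
  # zero-mean: empirical mean within 3 standard errors
  expect_lt(abs(mean(noisy) - 30), 3 * sigma / sqrt(1e5))
  set.seed(32)
  noisy5 <- add_noise(mu, 5)
  expect_lt(abs(sd(noisy5 - mu) - 6), 3 * 6 / sqrt(2 * 1e5))
  expect_error(add_noise(mu, 0), "positive")
  expect_error(add_noise(mu, -2), "positive")
})

test_that("standardization gives zero-mean unit-SD training features", {
  set.seed(41)
  x <- cbind(rnorm(500, 40, 5), rnorm(500, 25, 2))
  st <- compute_stats(x)
  xs <- standardize(x, st)
  expect_equal(colMeans(xs), c(0, 0), tolerance = 1e-6)
  expect_equal(apply(xs, 2, sd), c(1, 1), tolerance = 1e-6)
  # applying the same statistics twice is not the identity
  expect_false(isTRUE(all.equal(standardize(xs, st), xs)))
  expect_error(compute_stats(cbind(x[, 1], 7)), "constant")
})

test_that("9:1 split with 20% validation holdout partitions all samples", {
  idx <- split_dataset(10000, seed = 0)
  expect_equal(lengths(idx), c(train = 7200, val = 1800, test = 1000))
  expect_equal(sort(c(idx$train, idx$val, idx$test)), 1:10000)
  idx2 <- split_dataset(10000, seed = 1)
  expect_false(identical(idx, idx2))
  expect_equal(lengths(idx2), lengths(idx))
  expect_error(split_dataset(5), "at least 10")
})

test_that("dataset assembly is deterministic and physically ordered", {
  d1 <- build_dataset("soft", Inf, n = 400, seed = 3)
  d1b <- build_dataset("soft", Inf, n = 400, seed = 3)
  expect_identical(d1, d1b)  # bit-identical per seed
  expect_true(all(d1$mu50_raw > d1$mu88_raw))
  # noise-free: noisy channels equal the raw ones
  expect_identical(d1$mu50_noisy, d1$mu50_raw)
  d4 <- build_dataset("bone", Inf, n = 400, seed = 3)
  expect_gt(mean(d4$mu50_raw), mean(d1$mu50_raw))
  # training features standardized with training statistics
  xtr <- dataset_features(d1, "train")
  expect_equal(colMeans(xtr), c(0, 0), tolerance = 1e-6)
  expect_equal(apply(xtr, 2, sd), c(1, 1), tolerance = 1e-6)
  # targets cover the category element set
  expect_equal(colnames(dataset_targets(d4, "test")),
               c("H", "C", "N", "O", "Ca"))
  # noisy dataset differs from raw in features only
  d3 <- build_dataset("soft", 5, n = 400, seed = 3)
  expect_identical(d3$wH, d1$wH)
  expect_false(identical(d3$mu50_noisy, d3$mu50_raw))
})

test_that("the six study variants cover both categories and noise levels", {
  ds <- build_all_datasets(seed = 0, n = 60)
  expect_named(ds, paste0("D", 1:6))
  expect_equal(vapply(ds, attr, "", "category"),
               c(D1 = "soft", D2 = "soft", D3 = "soft",
                 D4 = "bone", D5 = "bone", D6 = "bone"))
  expect_equal(unname(vapply(ds, attr, 1, "snr")), c(Inf, 10, 5, Inf, 10, 5))
})

test_that("dataset CSV round-trips exactly with its sidecar", {
  d <- build_dataset("bone", 10, n = 60, seed = 7)
  path <- file.path(withr::local_tempdir(), "d5.csv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(d))
  expect_equal(attr(back, "stats"), attr(d, "stats"), ignore_attr = TRUE)
  expect_equal(attr(back, "snr"), 10)
  expect_equal(attr(back, "category"), "bone")

  # header mismatch is a parse error
  bad <- file.path(dirname(path), "bad.csv")
  lines <- readLines(path)
  lines[1] <- sub("sample_id", "id", lines[1])
  writeLines(lines, bad)
  file.copy(paste0(path, ".json"), paste0(bad, ".json"))
  expect_error(read_dataset(bad), "header mismatch")

  empty <- file.path(dirname(path), "empty.csv")
  file.create(empty)
  expect_error(read_dataset(empty), "empty")
  expect_error(read_dataset(file.path(dirname(path), "nope.csv")), "no such")
})
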