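test_that("two-way ANOVA conserves the total sum of squares", {
  set.seed(51)
  for (rep in 1:20) {
    m <- matrix(rnorm(10 * 9, 50, 10), 10, 9)
    ms <- two_way_anova(m)
    SS_tot <- sum((m - mean(m))^2)
    SS_sum <- ms$MSR * ms$df_rows + ms$MSC * ms$df_cols + ms$MSE * ms$df_err
    expect_equal(SS_sum, SS_tot, tolerance = 1e-9)
  }
})

test_that("ANOVA components match direct cell-by-cell summation", {
  set.seed(52)
  m <- matrix(rnorm(90), 10, 9)
  ms <- two_way_anova(m)
  n <- 10; k <- 9
  g <- mean(m)
  MSR <- 0; for (i in 1:n) MSR <- MSR + k * (mean(m[i, ]) - g)^2 / (n - 1)
  MSC <- 0; for (j in 1:k) MSC <- MSC + n * (mean(m[, j]) - g)^2 / (k - 1)
  MSE <- 0
  for (i in 1:n) for (j in 1:k)
    MSE <- MSE + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + g)^2 / ((n - 1) * (k - 1))
  expect_equal(ms$MSR, MSR)
  expect_equal(ms$MSC, MSC)
  expect_equal(ms$MSE, MSE)
})

test_that("identical columns give MSC = MSE = 0 and ICC = 1", {
  y <- rnorm(8, 10, 4)
  m <- matrix(rep(y, 5), 8, 5)
  ms <- two_way_anova(m)
  expect_equal(ms$MSC, 0)
  expect_equal(ms$MSE, 0)
  r <- icc_absolute_agreement(m)
  expect_false(r$degenerate)
  expect_equal(r$icc, 1)
  expect_equal(r$lower, 1)
  expect_equal(r$upper, 1)
})

test_that("a constant matrix is flagged degenerate, not scored", {
  r <- icc_absolute_agreement(matrix(7, 6, 4))
  expect_true(r$degenerate)
  expect_true(is.na(r$icc))
})

test_that("ICC(A,1) point and bounds match the aov-based oracle to 1e-8", {
  set.seed(53)
  for (rep in 1:50) {
    n <- sample(5:12, 1); k <- sample(2:9, 1)
    m <- matrix(rnorm(n * k, 100, 15) + rep(rnorm(n, 0, 10), k), n, k)
    r <- icc_absolute_agreement(m)
    ref <- oracle_icc_a1(m)
    expect_equal(r$icc, ref$icc, tolerance = 1e-8)
    expect_equal(r$lower, ref$lower, tolerance = 1e-8)
    expect_equal(r$upper, ref$upper, tolerance = 1e-8)
    expect_lte(r$lower, r$icc + 1e-12)
    expect_gte(r$upper, r$icc - 1e-12)
  }
})

test_that("ICC(A,1) agrees with an external reference implementation", {
  # reference values computed with pingouin 0.6.1 (ICC(A,1) row of
  # intraclass_corr) on the identical seeded matrix; its CI is printed
  # rounded to 2 decimals
  set.seed(42)
  m <- matrix(round(rnorm(90, 50, 10), 4), 10, 9)
  r <- icc_absolute_agreement(m)
  expect_equal(r$icc, -0.037159775686, tolerance = 1e-9)
  expect_equal(round(r$lower, 2), -0.09)
  expect_equal(round(r$upper, 2), 0.13)
  set.seed(7)
  m2 <- matrix(round(rnorm(12, 0, 1) + rep(rnorm(4, 0, 2), 3), 4), 4, 3)
  r2 <- icc_absolute_agreement(m2)
  expect_equal(r2$icc, 0.574738088124, tolerance = 1e-9)
  expect_equal(round(r2$lower, 2), 0.00)
  expect_equal(round(r2$upper, 2), 0.96)
})

test_that("ICC is invariant to common affine maps and negative values survive", {
  set.seed(54)
  m <- matrix(rnorm(60, 10, 3), 10, 6)
  r0 <- icc_absolute_agreement(m)
  r1 <- icc_absolute_agreement(3.7 * m - 212)
  expect_equal(r0$icc, r1$icc, tolerance = 1e-12)
  expect_equal(r0$lower, r1$lower, tolerance = 1e-10)
  expect_equal(r0$upper, r1$upper, tolerance = 1e-10)
  # pure column noise with no subject effect drifts negative at times
  found_neg <- FALSE
  for (s in 1:20) {
    mm <- matrix(rnorm(40), 10, 4)
    rr <- icc_absolute_agreement(mm)
    if (!rr$degenerate && rr$icc < 0) found_neg <- TRUE
  }
  expect_true(found_neg)
})

test_that("systematic rater offsets depress absolute-agreement ICC", {
  set.seed(55)
  subj <- rnorm(10, 0, 5)
  base <- matrix(rep(subj, 4), 10, 4) + matrix(rnorm(40, 0, 0.5), 10, 4)
  shifted <- base + matrix(rep(c(0, 4, 8, 12), each = 10), 10, 4)
  expect_lt(icc_absolute_agreement(shifted)$icc,
            icc_absolute_agreement(base)$icc)
})

test_that("estimator tracks the planted variance ratio in simulation", {
  # y_ij = subject_i + noise: expected ICC = s2b / (s2b + s2w)
  set.seed(56)
  s2b <- 4; s2w <- 1
  target <- s2b / (s2b + s2w)
  est <- replicate(200, {
    m <- matrix(rep(rnorm(10, 0, sqrt(s2b)), 9), 10, 9) +
      matrix(rnorm(90, 0, sqrt(s2w)), 10, 9)
    icc_absolute_agreement(m)$icc
  })
  expect_lt(abs(mean(est) - target), 3 * sd(est) / sqrt(length(est)) + 0.02)
})

test_that("icc_star and pairwise_icc wire the feature table correctly", {
  set.seed(57)
  tumors <- paste0("t", 1:6)
  segs <- paste0("s", 1:4)
  vals <- rnorm(24, 50, 8)
  tab <- expand.grid(tumor_id = tumors, segmentation_id = segs,
                     stringsAsFactors = FALSE)
  tab$image_type <- "original"; tab$feature_class <- "firstorder"
  tab$feature_name <- "Mean"; tab$value <- vals
  fid <- data.frame(image_type = "original", feature_class = "firstorder",
                    feature_name = "Mean")
  m <- feature_matrix(tab, fid)
  expect_equal(dim(m), c(6L, 4L))
  expect_equal(icc_star(tab, fid)$icc, icc_absolute_agreement(m)$icc)

  pw <- pairwise_icc(tab, fid)
  expect_equal(nrow(pw$pairs), 6L)  # C(4,2)
  expect_true(all(pw$pairs$seg_i < pw$pairs$seg_j))
  ok <- !pw$pairs$degenerate
  expect_equal(pw$icc_average, mean(pw$pairs$icc[ok]))
  expect_equal(pw$icc_min, min(pw$pairs$icc[ok]))

  # missing cell -> completeness error naming the cell
  tab2 <- tab[-5, ]
  expect_error(feature_matrix(tab2, fid), "completeness error")

  # identical raters across a cohort give icc_star 1
  tab$value <- rep(rnorm(6, 0, 5), length(segs))
  expect_equal(icc_star(tab, fid)$icc, 1)
})
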