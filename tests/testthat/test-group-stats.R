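test_that("exact Mann-Whitney p equals brute-force enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")$p_one_sided,
               0.05)
  set.seed(83)
  for (na in 1:6) {
    for (nb in 1:6) {
      a <- stats::runif(na)
      b <- stats::runif(nb)
      p_pkg <- mann_whitney_u(a, b, "less")$p_one_sided
      expect_equal(p_pkg, enum_u_p_less(a, b), tolerance = 1e-12,
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  }
})

test_that("U statistics partition n_a * n_b and symmetric cases give p = 1", {
  set.seed(84)
  for (i in 1:20) {
    a <- sample(1:8, 7, replace = TRUE) # ties on purpose
    b <- sample(1:8, 5, replace = TRUE)
    ua <- mann_whitney_u(a, b)$statistic
    ub <- mann_whitney_u(b, a)$statistic
    expect_equal(unname(ua + ub), length(a) * length(b))
  }
  x <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney_u(x, sample(x), "two_sided")$p_two_sided, 1)
})

test_that("one-sided p-values obey the swap identity in the exact case", {
  set.seed(85)
  a <- stats::runif(5); b <- stats::runif(6)
  p <- mann_whitney_u(a, b, "less")$p_one_sided
  p_swap <- mann_whitney_u(b, a, "less")$p_one_sided
  ua <- unname(mann_whitney_u(a, b)$statistic)
  point <- stats::dwilcox(ua, 5, 6)
  expect_equal(p_swap, 1 - p + point, tolerance = 1e-12)
})

test_that("the large-sample branch matches the standard rank-sum approximation", {
  set.seed(86)
  for (i in 1:10) {
    a <- stats::rnorm(15 + i)
    b <- stats::rnorm(20)
    m <- mann_whitney_u(a, b, "less")
    w <- stats::wilcox.test(a, b, alternative = "less", exact = FALSE,
                            correct = TRUE)
    expect_equal(m$p_one_sided, w$p.value, tolerance = 1e-12)
    w2 <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(m$p_two_sided, w2$p.value, tolerance = 1e-12)
  }
  # ties engage the tie-corrected variance
  x <- c(1, 2, 2, 3, 5, 5, 5, 7, 8, 9, 9, 10, 11)
  y <- c(2, 3, 3, 4, 5, 6, 6, 8, 8, 12, 13)
  expect_equal(mann_whitney_u(x, y, "less")$p_one_sided,
               stats::wilcox.test(x, y, alternative = "less", exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Pearson chi-square matches the closed form and is symmetric", {
  t1 <- matrix(c(10, 0, 0, 10), 2)
  r1 <- pearson_chi_square(t1)
  expect_equal(unname(r1$statistic), 20)
  expect_equal(pearson_chi_square(matrix(c(30, 20, 15, 10), 2))$p_two_sided, 1,
               tolerance = 1e-12)
  set.seed(87)
  for (i in 1:10) {
    tb <- matrix(stats::rpois(4, 20) + 1, 2)
    mine <- pearson_chi_square(tb)
    ref <- stats::chisq.test(tb, correct = FALSE)
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(pearson_chi_square(t(tb))$statistic),
                 unname(mine$statistic), tolerance = 1e-12)
    expect_equal(unname(pearson_chi_square(tb[2:1, 2:1])$statistic),
                 unname(mine$statistic), tolerance = 1e-12)
  }
  expect_error(pearson_chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("Fisher's exact test enumerates the hypergeometric tail", {
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2))$p_two_sided, 0.1)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_two_sided, 1)
  set.seed(88)
  for (i in 1:10) {
    tb <- matrix(stats::rpois(4, 15) + 1, 2)
    mine <- fisher_exact(tb)$p_two_sided
    ref <- stats::fisher.test(tb)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
    # p at least the point probability of the observed table
    r <- rowSums(tb); cl <- colSums(tb)
    point <- stats::dhyper(tb[1, 1], r[1], r[2], cl[1])
    expect_gte(mine + 1e-12, point)
  }
  # with all cells >= 20 and a real association, Fisher and Pearson agree
  # in the decision-relevant (small p) region
  checked <- 0L
  for (i in 1:40) {
    tb <- matrix(c(stats::rpois(2, c(60, 35)), stats::rpois(2, c(35, 60))),
                 2) + 20
    pf <- fisher_exact(tb)$p_two_sided
    if (pf < 0.3) {
      expect_lt(abs(pf - pearson_chi_square(tb)$p_two_sided), 0.05)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5)
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "margin")
  expect_equal(p0$p_two_sided, 1)
})

test_that("two-sample t handles the degenerate and standard cases", {
  x <- c(1.2, 3.4, 2.2, 4.8)
  expect_equal(two_sample_t(x, x)$p_two_sided, 1, tolerance = 1e-12)
  expect_equal(unname(two_sample_t(x, x)$statistic), 0, tolerance = 1e-12)
  expect_error(two_sample_t(c(0, 0), c(1, 1)), "zero variance")
  set.seed(89)
  a <- stats::rnorm(12, 1); b <- stats::rnorm(15)
  w <- two_sample_t(a, b, "welch")
  # independent recomputation of the Welch statistic
  se <- sqrt(stats::var(a) / 12 + stats::var(b) / 15)
  expect_equal(unname(w$statistic), (mean(a) - mean(b)) / se,
               tolerance = 1e-12)
})

test_that("compare_groups is pure, direction-faithful and stratum-aware", {
  set.seed(90)
  n <- 20
  ft <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:(2 * n)),
    group = rep(c("control", "music"), each = n),
    sex = "female",
    channel = "femg_zygomaticus", anchor = "start",
    value = c(stats::rnorm(n, 8, 2), stats::rnorm(n, 4, 2)),
    unit = "uV", qc = "kept"
  )
  ct <- compare_groups(ft)
  all_row <- ct[ct$stratum == "all", ]
  expect_lt(all_row$p_one_sided, 0.05)
  expect_identical(all_row$direction, "less")
  # single-sex cohort: male stratum not computable, "all" intact
  male_row <- ct[ct$stratum == "male", ]
  expect_false(male_row$computable)
  expect_true(all_row$computable)
  # purity
  expect_equal(as.data.frame(compare_groups(ft)), as.data.frame(ct))
  # flipping the direction makes the same data non-significant
  ct_gr <- compare_groups(ft, plan = list(femg_zygomaticus = "greater"))
  expect_gt(ct_gr$p_one_sided[ct_gr$stratum == "all"], 0.9)
})

test_that("tidiers expose test results as one-row tibbles", {
  tt <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")
  td <- generics::tidy(tt)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$p_one_sided, 0.05)
  expect_equal(td$n_a, 3)
  expect_identical(generics::glance(tt), td)
})
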