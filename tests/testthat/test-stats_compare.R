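test_that("ROUT leaves a tight sample alone and pulls out a gross contaminant", {
  expect_false(any(rout_outliers(c(1, 2, 3))))
  expect_warning(m <- rout_outliers(c(1, 2)), "n < 3")
  expect_false(any(m))

  withr::with_seed(101, {
    hits <- logical(50); exact <- logical(50)
    for (i in 1:50) {
      x <- rnorm(20)
      x[7] <- 100
      m <- rout_outliers(x, q = 1)
      hits[i] <- m[7]
      exact[i] <- identical(which(m), 7L)
    }
    expect_true(all(hits))        # the contaminant is always flagged
    expect_gte(mean(exact), 0.9)  # and almost always exclusively
  })
})

test_that("ROUT is permutation-invariant and equivariant under affine maps", {
  withr::with_seed(7, {
    x <- c(rnorm(12), 9)
    m <- rout_outliers(x)
    perm <- sample(length(x))
    expect_identical(as.logical(m)[perm], as.logical(rout_outliers(x[perm])))
    expect_identical(as.logical(m), as.logical(rout_outliers(3 * x - 10)))
    expect_identical(as.logical(m), as.logical(rout_outliers(-x)))
  })
})

test_that("paired comparisons gate on the normality of differences", {
  # identical samples: degenerate route with p ~ 1
  x <- c(1, 2, 3, 4, 5)
  r <- compare_paired(x, x)
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0)

  withr::with_seed(33, {
    # clean shift: t route, significant
    x <- rnorm(8); y <- x + 3 + rnorm(8, 0, 0.5)
    r <- compare_paired(x, y)
    expect_equal(r$test_name, "paired t-test")
    expect_lt(r$p_value, 0.01)
    expect_equal(r$effect$estimate, mean(y - x))
    # route is reproducible from the recorded normality p
    expect_true(r$normality_p >= 0.05)

    # heavy-tailed differences select Wilcoxon in the majority of seeds
    # (n = 30 pairs: the normality gate needs a workable sample size to
    # resolve t2 tails)
    routes <- replicate(200, {
      d <- rt(30, df = 2)
      compare_paired(rep(0, 30), d)$test_name
    })
    expect_gt(mean(routes == "Wilcoxon signed-rank"), 0.5)
  })
  expect_error(compare_paired(1:3, 1:4), class = "urodyn_validation_error")
  expect_error(compare_paired(1:2, 1:2), class = "urodyn_validation_error")
})

test_that("unpaired comparisons gate per sample and match the Welch/MW routes", {
  withr::with_seed(44, {
    x <- rnorm(8); y <- rnorm(8)
    r <- compare_unpaired(x, x)
    expect_gt(r$p_value, 0.99)
    r2 <- compare_unpaired(x, y)
    expect_true(r2$test_name %in% c("Welch t-test", "Mann-Whitney"))
    expect_length(r2$normality_p, 2L)

    # exponential samples route to Mann-Whitney in the majority of seeds
    routes <- replicate(200, {
      compare_unpaired(rexp(8), rexp(8))$test_name
    })
    expect_gt(mean(routes == "Mann-Whitney"), 0.5)

    # power sanity: a 2-SD shift at n = 8 is mostly detected
    pow <- mean(replicate(200, compare_unpaired(rnorm(8), rnorm(8, 2))$p_value < 0.05))
    expect_gt(pow, 0.8)
  })
})

test_that("paired gated power matches a brute-force reimplementation of the
           same routine", {
  # oracle: an independent inline rebuild of the gate + tests
  oracle <- function(x, y, alpha = 0.05) {
    d <- y - x
    if (shapiro.test(d)$p.value >= alpha) t.test(d)$p.value else
      suppressWarnings(wilcox.test(d))$p.value
  }
  withr::with_seed(55, {
    n_rep <- 400
    mine <- theirs <- logical(n_rep)
    for (i in seq_len(n_rep)) {
      x <- rnorm(8)
      y <- x + 1.5 + rnorm(8)   # 1.5 SD shift
      mine[i] <- compare_paired(x, y)$p_value < 0.05
      theirs[i] <- oracle(x, y) < 0.05
    }
    expect_identical(mine, theirs)   # decision-identical, not just close
  })
})

test_that("three-group comparison routes, pairwise follow-up and guards", {
  # three identical samples -> omnibus p ~ 1
  s <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5), c = c(1, 2, 3, 4, 5))
  r <- compare_three_groups(s)
  expect_gt(r$p_value, 0.99)

  withr::with_seed(66, {
    # separated third group: only that pair significant in most seeds
    wins <- replicate(60, {
      r <- compare_three_groups(list(a = rnorm(8), b = rnorm(8),
                                     c = rnorm(5, 2)))
      pw <- r$pairwise
      sig <- pw$p_adj < 0.05
      sep <- grepl("c", pw$comparison)
      all(sig[sep]) || (any(sig[sep]) && !any(sig[!sep]))
    })
    expect_gt(mean(wins), 0.5)

    # non-normal group routes to Kruskal-Wallis + Dunn
    r2 <- compare_three_groups(list(a = rexp(10)^3, b = rexp(10)^3,
                                    c = rexp(10)^3))
    expect_true(r2$test_name %in% c("Kruskal-Wallis",
                                    "Brown-Forsythe and Welch ANOVA"))
    routes <- replicate(100, compare_three_groups(
      list(a = rexp(8)^2, b = rexp(8)^2, c = rexp(8)^2))$test_name)
    expect_gt(mean(routes == "Kruskal-Wallis"), 0.5)
  })
  expect_error(compare_three_groups(list(1:5, 1:5)),
               class = "urodyn_validation_error")
  expect_error(compare_three_groups(list(a = 1:5, b = 1:5, c = 1:2)),
               class = "urodyn_validation_error")
})

test_that("Brown-Forsythe F* agrees with a direct formula evaluation", {
  withr::with_seed(9, {
    s <- list(rnorm(8, 0, 1), rnorm(8, 0.5, 2), rnorm(5, 1, 0.5))
    bf <- brown_forsythe_anova(s)
    n <- lengths(s); N <- sum(n)
    means <- vapply(s, mean, numeric(1)); vars <- vapply(s, var, numeric(1))
    grand <- sum(n * means) / N
    Fstar <- sum(n * (means - grand)^2) / sum((1 - n / N) * vars)
    expect_equal(bf$statistic, Fstar)
    expect_true(bf$p.value >= 0 && bf$p.value <= 1)
  })
})

test_that("the SMM distribution reduces to the two-sided t at one contrast and
           orders correctly in the contrast count", {
  for (q in c(0.5, 1.5, 2.5)) {
    expect_equal(urodyn:::psmm(q, 1, 10), 1 - 2 * pt(q, 10, lower.tail = FALSE),
                 tolerance = 1e-7)
  }
  # more simultaneous contrasts -> smaller coverage at fixed quantile
  expect_gt(urodyn:::psmm(2, 1, 12), urodyn:::psmm(2, 3, 12))
  # adjusted pairwise p is never smaller than the unadjusted Welch p
  withr::with_seed(12, {
    s <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(5))
    pw <- dunnett_t3(s)
    raw <- 2 * pt(pw$statistic, pw$df, lower.tail = FALSE)
    expect_true(all(pw$p_adj >= raw - 1e-12))
  })
})

test_that("Dunn pairwise z statistics match a direct rank computation", {
  s <- list(a = c(1, 5, 8, 11), b = c(2, 9, 13, 15), c = c(20, 25, 30, 35))
  pw <- dunn_test(s)
  values <- unlist(s); r <- rank(values)
  rbar <- tapply(r, rep(1:3, each = 4), mean)
  N <- 12
  se <- sqrt((N * (N + 1) / 12) * (1 / 4 + 1 / 4))
  z_ab <- abs(rbar[1] - rbar[2]) / se
  expect_equal(pw$statistic[pw$comparison == "a vs b"], unname(z_ab))
  expect_true(all(pw$p_adj <= 1))
})

test_that("significance stars follow the reporting scheme with the 0.005 tier", {
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.009), "**")
  expect_equal(significance_stars(0.004), "***")
  expect_equal(significance_stars(5e-5), "****")
  expect_equal(significance_stars(0.5), "")
  expect_equal(significance_stars(0.05), "")
  expect_error(significance_stars(1.5), class = "urodyn_validation_error")
})

test_that("outlier exclusion integrates with the comparison wrappers", {
  withr::with_seed(77, {
    x <- rnorm(10); y <- x + rnorm(10, 0, 0.3)
    y[4] <- 50  # one wrecked pair
    r <- compare_paired(x, y, rout_q = 1)
    expect_equal(r$outliers_removed, 4L)
    expect_equal(r$n_per_group, 9L)
    rx <- c(rnorm(10), 30)
    r2 <- compare_unpaired(rx, rnorm(10), rout_q = 1)
    expect_equal(r2$outliers_removed$x, 11L)
  })
})
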