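# Normality-gated statistical workflow: ROUT outlier exclusion,
# Shapiro-Wilk gate at alpha, then paired t / Wilcoxon signed-rank
# (within-group), Welch t / Mann-Whitney (between two groups), or
# Brown-Forsythe and Welch ANOVA with Dunnett T3 / Kruskal-Wallis with
# Dunn's test (three groups).  All tests two-tailed; effects reported as
# mean difference +/- SEM.

#' ROUT outlier detection for a univariate sample
#'
#' The ROUT procedure (robust regression followed by FDR-controlled outlier
#' testing) specialised to a univariate sample, i.e. to robustly fitting a
#' constant: location by iteratively reweighted Tukey-biweight fit, robust
#' scale as the 68.27th percentile of absolute residuals times
#' `N / (N - K)` (the RSDR, with K = 1 fitted parameter), per-point
#' t statistics `|residual| / RSDR` on `N - K` degrees of freedom, and
#' outliers called from the extremes inward by Benjamini-Hochberg step-up
#' at FDR `Q` percent.
#'
#' @param x Numeric sample (n >= 3; smaller samples return no outliers with
#'   a warning).
#' @param q FDR rate in percent (default 1, i.e. Q = 1).
#' @return A logical mask, `TRUE` for flagged points, with attributes
#'   `location` (robust fit) and `rsdr` (robust scale).
#' @export
rout_outliers <- function(x, q = 1) {
  n <- length(x)
  mask <- rep(FALSE, n)
  if (n < 3L) {
    warning("rout_outliers: n < 3, no exclusion performed")
    return(mask)
  }
  fit <- biweight_location(x)
  res <- x - fit
  k_par <- 1L
  rsdr <- as.numeric(quantile(abs(res), 0.6827, type = 7)) * n / (n - k_par)
  attr(mask, "location") <- fit
  attr(mask, "rsdr") <- rsdr
  if (rsdr <= 0) return(mask)
  tstat <- abs(res) / rsdr
  p <- 2 * pt(tstat, df = n - k_par, lower.tail = FALSE)
  ord <- order(p)                       # most extreme first
  thresh <- (q / 100) * seq_len(n) / n  # BH step-up from the extremes inward
  passed <- which(p[ord] <= thresh)
  if (length(passed)) mask[ord[seq_len(max(passed))]] <- TRUE
  attributes(mask) <- c(attributes(mask),
                        list(location = fit, rsdr = rsdr))
  mask
}

# Tukey biweight M-estimate of location (c = 4.685 on an MAD scale),
# starting from the median.
biweight_location <- function(x, max_iter = 50L, tol = 1e-10) {
  m <- median(x)
  s <- mad(x)
  if (s <= 0) return(m)
  for (i in seq_len(max_iter)) {
    u <- (x - m) / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) <= 0) break
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) {
      m <- m_new
      break
    }
    m <- m_new
  }
  m
}

shapiro_p <- function(x) {
  if (length(unique(x)) < 3L || sd(x) == 0) return(NA_real_)
  shapiro.test(x)$p.value
}

stars_or_empty <- function(p) significance_stars(p)

new_comparison <- function(test_name, statistic, p_value, n_per_group,
                           normality_p, outliers_removed, effect,
                           extra = list()) {
  structure(c(list(
    test_name = test_name,
    statistic = as.numeric(statistic),
    p_value = as.numeric(p_value),
    n_per_group = n_per_group,
    normality_p = normality_p,
    outliers_removed = outliers_removed,
    effect = effect,
    stars = significance_stars(p_value)
  ), extra), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: statistic = %.4g, p = %.4g %s (n = %s)\n",
              x$test_name, x$statistic, x$p_value, x$stars,
              paste(x$n_per_group, collapse = "/")))
  if (!is.null(x$effect$estimate) && !is.na(x$effect$estimate)) {
    cat(sprintf("  effect: %.4g +/- %.4g (mean difference +/- SEM)\n",
                x$effect$estimate, x$effect$sem))
  }
  invisible(x)
}

#' Paired two-sample comparison with normality gate
#'
#' Shapiro-Wilk on the paired differences: p >= `alpha` routes to a
#' two-tailed paired t test, otherwise to the Wilcoxon signed-rank test.
#' All-zero differences short-circuit to a degenerate result with p = 1.
#' Optional ROUT exclusion (`rout_q`) removes flagged difference pairs
#' before testing.
#'
#' @param x,y Paired samples (same length, paired by subject).
#' @param alpha Normality-gate significance level.
#' @param rout_q ROUT Q in percent, or `NULL` for no outlier exclusion.
#' @return A `comparison_result`.
#' @export
compare_paired <- function(x, y, alpha = 0.05, rout_q = NULL) {
  if (length(x) != length(y)) abort_validation("paired samples must have equal length")
  if (length(x) < 3L) abort_validation("paired comparison needs n >= 3")
  d <- y - x
  removed <- integer()
  if (!is.null(rout_q)) {
    mask <- rout_outliers(d, rout_q)
    removed <- which(mask)
    if (length(removed)) d <- d[!mask]
    if (length(d) < 3L) abort_validation("fewer than 3 pairs left after outlier exclusion")
  }
  if (all(d == 0)) {
    return(new_comparison("degenerate (no differences)", 0, 1,
                          length(d), NA_real_, removed,
                          list(estimate = 0, sem = 0)))
  }
  sw <- shapiro_p(d)
  eff <- list(estimate = mean(d), sem = sd(d) / sqrt(length(d)))
  if (!is.na(sw) && sw >= alpha) {
    tt <- t.test(d)
    new_comparison("paired t-test", tt$statistic, tt$p.value, length(d),
                   sw, removed, eff)
  } else {
    wt <- suppressWarnings(wilcox.test(d, mu = 0))
    new_comparison("Wilcoxon signed-rank", wt$statistic, wt$p.value,
                   length(d), sw, removed, eff)
  }
}

#' Unpaired two-sample comparison with normality gate
#'
#' Shapiro-Wilk on each sample: both normal routes to Welch's two-tailed
#' t test, otherwise to the Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param x,y Samples (n >= 3 each).
#' @inheritParams compare_paired
#' @return A `comparison_result`.
#' @export
compare_unpaired <- function(x, y, alpha = 0.05, rout_q = NULL) {
  if (length(x) < 3L || length(y) < 3L) {
    abort_validation("unpaired comparison needs n >= 3 in each group")
  }
  removed <- list(x = integer(), y = integer())
  if (!is.null(rout_q)) {
    mx <- rout_outliers(x, rout_q); removed$x <- which(mx); x <- x[!mx]
    my <- rout_outliers(y, rout_q); removed$y <- which(my); y <- y[!my]
    if (length(x) < 3L || length(y) < 3L) {
      abort_validation("fewer than 3 values left after outlier exclusion")
    }
  }
  sw <- c(shapiro_p(x), shapiro_p(y))
  eff <- list(estimate = mean(y) - mean(x),
              sem = sqrt(sd(x)^2 / length(x) + sd(y)^2 / length(y)))
  normal <- all(!is.na(sw)) && all(sw >= alpha)
  if (normal) {
    tt <- t.test(x, y, var.equal = FALSE)
    new_comparison("Welch t-test", tt$statistic, tt$p.value,
                   c(length(x), length(y)), sw, removed, eff)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y))
    new_comparison("Mann-Whitney", wt$statistic, wt$p.value,
                   c(length(x), length(y)), sw, removed, eff)
  }
}

#' Three-group comparison with normality gate and pairwise follow-up
#'
#' Shapiro-Wilk on each group: all normal routes to the Brown-Forsythe and
#' Welch one-way ANOVA pair (heteroscedasticity-robust; the reported
#' omnibus p is Welch's, with the Brown-Forsythe F* and p recorded
#' alongside) followed by Dunnett's T3 pairwise comparisons (Welch t
#' statistics referred to the Studentized Maximum Modulus distribution).
#' Any non-normal group routes to Kruskal-Wallis followed by Dunn's
#' pairwise z tests with Bonferroni adjustment.
#'
#' @param samples A list of three numeric samples (named, or names are
#'   generated).
#' @param pairwise Set `FALSE` to skip the pairwise follow-up and report
#'   only the omnibus test (cheaper in large simulations).
#' @inheritParams compare_paired
#' @return A `comparison_result` with a `pairwise` tibble
#'   (`comparison`, `statistic`, `p_adj`, `stars`).
#' @export
compare_three_groups <- function(samples, alpha = 0.05, rout_q = NULL,
                                 pairwise = TRUE) {
  if (length(samples) != 3L) abort_validation("exactly three groups required")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("g", seq_along(samples))
  }
  if (any(lengths(samples) < 3L)) {
    abort_validation("each group needs n >= 3")
  }
  removed <- lapply(samples, function(v) integer())
  if (!is.null(rout_q)) {
    for (i in seq_along(samples)) {
      m <- rout_outliers(samples[[i]], rout_q)
      removed[[i]] <- which(m)
      samples[[i]] <- samples[[i]][!m]
    }
    if (any(lengths(samples) < 3L)) {
      abort_validation("fewer than 3 values left in a group after outlier exclusion")
    }
  }
  sw <- vapply(samples, shapiro_p, numeric(1))
  normal <- all(!is.na(sw)) && all(sw >= alpha)
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(names(samples), lengths(samples)),
                   levels = names(samples))
  if (normal) {
    welch <- oneway.test(values ~ groups, var.equal = FALSE)
    bf <- brown_forsythe_anova(samples)
    pw <- if (pairwise) dunnett_t3(samples) else NULL
    new_comparison(
      "Brown-Forsythe and Welch ANOVA", welch$statistic, welch$p.value,
      lengths(samples), sw, removed,
      list(estimate = NA_real_, sem = NA_real_),
      extra = list(pairwise = pw, brown_forsythe = bf,
                   pairwise_method = "Dunnett T3")
    )
  } else {
    kw <- kruskal.test(values, groups)
    pw <- if (pairwise) dunn_test(samples) else NULL
    new_comparison(
      "Kruskal-Wallis", kw$statistic, kw$p.value,
      lengths(samples), sw, removed,
      list(estimate = NA_real_, sem = NA_real_),
      extra = list(pairwise = pw, pairwise_method = "Dunn")
    )
  }
}

#' Brown-Forsythe one-way ANOVA (F* on means)
#'
#' The Brown-Forsythe modification of the one-way F test for unequal
#' variances: `F* = sum n_i (xbar_i - xbar)^2 / sum (1 - n_i/N) s_i^2`
#' with Satterthwaite denominator degrees of freedom.  (Not the
#' Levene-type test on spreads that shares the name.)
#'
#' @param samples List of numeric samples.
#' @return A list with `statistic`, `df1`, `df2`, `p.value`.
#' @export
brown_forsythe_anova <- function(samples) {
  k <- length(samples)
  n <- lengths(samples)
  N <- sum(n)
  means <- vapply(samples, mean, numeric(1))
  vars <- vapply(samples, function(v) sd(v)^2, numeric(1))
  grand <- sum(n * means) / N
  num <- sum(n * (means - grand)^2)
  denom_terms <- (1 - n / N) * vars
  denom <- sum(denom_terms)
  Fstar <- num / denom
  c_i <- denom_terms / denom
  df2 <- 1 / sum(c_i^2 / (n - 1))
  list(statistic = Fstar, df1 = k - 1, df2 = df2,
       p.value = pf(Fstar, k - 1, df2, lower.tail = FALSE))
}

# P(max_i |T_i| <= q) for c independent t-like contrasts sharing a
# chi-distributed scale on df degrees of freedom: the Studentized Maximum
# Modulus distribution, by numerical integration over the scale.
psmm <- function(q, c_comp, df) {
  if (q <= 0) return(0)
  dens <- function(u) {
    exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(u) - df * u^2 / 2)
  }
  f <- function(u) (2 * pnorm(q * u) - 1)^c_comp * dens(u)
  integrate(f, 0, Inf, rel.tol = 1e-9)$value
}

#' Dunnett's T3 pairwise comparisons
#'
#' All pairwise Welch t statistics with Welch-Satterthwaite degrees of
#' freedom, referred to the Studentized Maximum Modulus distribution with
#' as many contrasts as pairs (multiplicity-adjusted p-values).
#'
#' @param samples Named list of numeric samples.
#' @return A tibble: `comparison`, `statistic`, `df`, `p_adj`, `stars`.
#' @export
dunnett_t3 <- function(samples) {
  nm <- names(samples)
  pairs <- utils::combn(seq_along(samples), 2)
  n_comp <- ncol(pairs)
  rows <- lapply(seq_len(n_comp), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x <- samples[[i1]]; y <- samples[[i2]]
    v1 <- sd(x)^2 / length(x); v2 <- sd(y)^2 / length(y)
    tt <- abs(mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    p_adj <- min(1, max(0, 1 - psmm(tt, n_comp, df)))
    tibble::tibble(
      comparison = paste(nm[i1], "vs", nm[i2]),
      statistic = tt, df = df, p_adj = p_adj,
      stars = significance_stars(p_adj)
    )
  })
  dplyr::bind_rows(rows)
}

#' Dunn's pairwise comparisons after Kruskal-Wallis
#'
#' Rank-based z statistics with tie correction; p-values Bonferroni-
#' adjusted for the number of pairs.
#'
#' @param samples Named list of numeric samples.
#' @return A tibble: `comparison`, `statistic`, `p_adj`, `stars`.
#' @export
dunn_test <- function(samples) {
  nm <- names(samples)
  values <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- lengths(samples)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(samples), 2)
  n_comp <- ncol(pairs)
  rows <- lapply(seq_len(n_comp), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i1] + 1 / n[i2]))
    z <- abs(rbar[i1] - rbar[i2]) / se
    p_adj <- min(1, 2 * pnorm(z, lower.tail = FALSE) * n_comp)
    tibble::tibble(
      comparison = paste(nm[i1], "vs", nm[i2]),
      statistic = as.numeric(z), p_adj = p_adj,
      stars = significance_stars(p_adj)
    )
  })
  dplyr::bind_rows(rows)
}

#' Significance stars
#'
#' Maps a p-value to the reporting scheme `* p < 0.05`, `** p < 0.01`,
#' `*** p < 0.005` (note the 0.005 third tier), `**** p < 0.0001`; empty
#' string otherwise.
#'
#' @param p A p-value in `[0, 1]`.
#' @return A string of 0-4 asterisks.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0 || p > 1) abort_validation("p must lie in [0, 1]")
  if (p < 0.0001) "****"
  else if (p < 0.005) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else ""
}
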