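#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. The U statistic is
#' computed from mid-ranks, so `U_a + U_b = n_a * n_b` with ties counting
#' one half. P-values are exact (from the Wilcoxon rank-sum distribution)
#' when `n_a + n_b <= 12` and there are no ties, and otherwise use the
#' normal approximation with tie correction and a 0.5 continuity
#' correction. `alternative = "less"` tests whether `a` is stochastically
#' smaller than `b`.
#'
#' @param a,b Numeric vectors, each with at least one value; `NA`s dropped.
#' @param alternative `"less"`, `"greater"` or `"two_sided"`.
#' @param exact_max Largest combined n for the exact branch (default 12).
#' @return A `bst_test` result; see [tidy.bst_test()].
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less") # exact p = 0.05
#' @export
mann_whitney_u <- function(a, b, alternative = c("less", "greater",
                                                 "two_sided"),
                           exact_max = 12) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("both groups need at least one value.", call. = FALSE)
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (!has_ties && (na + nb) <= exact_max) {
    p_less <- stats::pwilcox(ua, na, nb)
    p_greater <- stats::pwilcox(ub, na, nb)
    p_two <- min(1, 2 * min(p_less, p_greater))
    method <- "Mann-Whitney U (exact)"
  } else {
    N <- na + nb
    mu <- na * nb / 2
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p_less <- p_greater <- p_two <- 1
    } else {
      sigma <- sqrt(sigma2)
      z_less <- (ua - mu + 0.5) / sigma
      z_greater <- (ua - mu - 0.5) / sigma
      p_less <- stats::pnorm(z_less)
      p_greater <- stats::pnorm(z_greater, lower.tail = FALSE)
      z_two <- max(0, abs(ua - mu) - 0.5) / sigma
      p_two <- 2 * stats::pnorm(-z_two)
    }
    method <- "Mann-Whitney U (normal approximation)"
  }
  p_one <- switch(alternative, less = p_less, greater = p_greater,
                  two_sided = NA_real_)
  new_bst_test(
    statistic = c(U = ua), p_one_sided = p_one, p_two_sided = min(1, p_two),
    method = method, alternative = alternative, n = c(n_a = na, n_b = nb)
  )
}

#' Pearson chi-square test for a 2x2 table
#'
#' Plain Pearson statistic without continuity correction,
#' `X^2 = N (ad - bc)^2 / (r1 r2 c1 c2)`, referred to the chi-square
#' distribution with one degree of freedom. Used for the cohort's
#' categorical baseline characteristics.
#'
#' @param tab A 2x2 matrix of non-negative counts.
#' @return A `bst_test`.
#' @examples
#' pearson_chi_square(matrix(c(51, 47, 50, 48), 2)) # p = 0.886
#' @export
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0)) {
    stop("`tab` must be a 2x2 matrix of non-negative counts.", call. = FALSE)
  }
  n <- sum(tab)
  if (n == 0) stop("table total must be positive.", call. = FALSE)
  r <- rowSums(tab); cl <- colSums(tab)
  if (any(r == 0) || any(cl == 0)) {
    stop("chi-square undefined: a row or column margin is zero.", call. = FALSE)
  }
  x2 <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (r[1] * r[2] * cl[1] * cl[2])
  p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  new_bst_test(statistic = c(X2 = unname(x2)), p_one_sided = NA_real_,
               p_two_sided = p, method = "Pearson chi-square (no correction)",
               alternative = "two_sided", n = c(n = n))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities (margins
#' fixed) of all tables no more probable than the observed one. A zero
#' margin leaves only one attainable table; p = 1 with a warning.
#'
#' @param tab A 2x2 matrix of non-negative counts.
#' @return A `bst_test`.
#' @examples
#' fisher_exact(matrix(c(3, 0, 0, 3), 2)) # p = 0.1
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0)) {
    stop("`tab` must be a 2x2 matrix of non-negative counts.", call. = FALSE)
  }
  r <- rowSums(tab); cl <- colSums(tab)
  if (any(r == 0) || any(cl == 0)) {
    warning("zero margin: only one table attainable; p = 1.", call. = FALSE)
    return(new_bst_test(statistic = c(odds_ratio = NA_real_),
                        p_one_sided = NA_real_, p_two_sided = 1,
                        method = "Fisher exact", alternative = "two_sided",
                        n = c(n = sum(tab))))
  }
  x <- tab[1, 1]
  support <- max(0, cl[1] - r[2]):min(r[1], cl[1])
  probs <- stats::dhyper(support, r[1], r[2], cl[1])
  p_obs <- stats::dhyper(x, r[1], r[2], cl[1])
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  new_bst_test(statistic = c(odds_ratio = unname(or)), p_one_sided = NA_real_,
               p_two_sided = min(1, p), method = "Fisher exact",
               alternative = "two_sided", n = c(n = sum(tab)))
}

#' Two-sample t test
#'
#' Student's (pooled) or Welch's t test, one- and two-sided p-values; a thin
#' wrapper over [stats::t.test()] returning the package's common test
#' container. Requires at least two values per group and nonzero variance
#' in at least one group.
#'
#' @param a,b Numeric vectors.
#' @param variant `"pooled"` (classic Student) or `"welch"`.
#' @param alternative Direction for the one-sided p (`a` vs `b`).
#' @return A `bst_test`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch"),
                         alternative = c("less", "greater")) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least two values.", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both groups have zero variance; t statistic undefined.",
         call. = FALSE)
  }
  ht2 <- stats::t.test(a, b, var.equal = variant == "pooled")
  ht1 <- stats::t.test(a, b, var.equal = variant == "pooled",
                       alternative = sub("_.*", "", alternative))
  new_bst_test(statistic = c(t = unname(ht2$statistic)),
               p_one_sided = ht1$p.value, p_two_sided = ht2$p.value,
               method = sprintf("two-sample t (%s)", variant),
               alternative = alternative,
               n = c(n_a = length(a), n_b = length(b)))
}

new_bst_test <- function(statistic, p_one_sided, p_two_sided, method,
                         alternative, n) {
  structure(
    list(statistic = statistic, p_one_sided = p_one_sided,
         p_two_sided = p_two_sided, method = method,
         alternative = alternative, n = n),
    class = "bst_test"
  )
}

#' @export
print.bst_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g", x$method, names(x$statistic), x$statistic))
  if (!is.na(x$p_one_sided)) {
    cat(sprintf(", one-sided p (%s) = %.4g", x$alternative, x$p_one_sided))
  }
  cat(sprintf(", two-sided p = %.4g [n: %s]\n", x$p_two_sided,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Broom-style tidiers for test results
#'
#' `tidy()` returns a one-row tibble (statistic, p-values, method, group
#' sizes); `glance()` is an alias for `tidy()` for these one-row results.
#'
#' @param x A `bst_test`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @importFrom generics tidy glance
#' @exportS3Method generics::tidy
tidy.bst_test <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$statistic[1]),
    statistic_name = names(x$statistic)[1],
    p_one_sided = x$p_one_sided,
    p_two_sided = x$p_two_sided,
    method = x$method,
    alternative = x$alternative,
    n_a = unname(x$n[1]),
    n_b = if (length(x$n) > 1) unname(x$n[2]) else NA_integer_
  )
}

#' @rdname tidy.bst_test
#' @exportS3Method generics::glance
glance.bst_test <- function(x, ...) tidy(x)
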