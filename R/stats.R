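#' Mean, SEM and n of one group
#'
#' SEM is the sample standard deviation over the square root of n; it is
#' undefined (\code{NA}) for a single observation.
#'
#' @param values Numeric vector, length >= 1.
#' @return List with elements \code{mean}, \code{sem}, \code{n}.
#' @examples
#' summarizeGroup(c(2, 4, 6)) # mean 4, sem 2/sqrt(3)
#' @export
summarizeGroup <- function(values) {
  if (length(values) == 0L) stop("empty input")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

.testResult <- function(test, statistic, p, comparison, method = NA_character_,
                        alpha = 0.05) {
  p <- min(max(p, 0), 1)
  methods::new("TestResult", test = test, statistic = as.numeric(statistic),
               pValue = p, comparison = comparison, alpha = alpha,
               significant = p < alpha, method = method)
}

#' Coerce a list of test results to a data.frame
#'
#' @param results A [TestResult] or list of them.
#' @return \code{data.frame} with one row per test.
#' @export
testResultsToDf <- function(results) {
  if (methods::is(results, "TestResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(test = r@test, comparison = r@comparison,
               statistic = r@statistic, p_value = r@pValue,
               significant = r@significant, method = r@method,
               stringsAsFactors = FALSE)))
}

#' Fisher's exact test on a 2 x 2 incidence table
#'
#' Two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins that
#' are no more probable than the observed one (the classical reading of
#' "Fisher's exact test", as implemented by \code{stats::fisher.test}).
#'
#' @param table2x2 2 x 2 matrix of non-negative integer counts (e.g. groups
#'   in rows, incidence yes/no in columns).
#' @return A [TestResult]; the statistic is the conditional MLE odds ratio.
#' @examples
#' fisherExact(matrix(c(3, 0, 0, 3), 2))
#' @export
fisherExact <- function(table2x2) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == c(2L, 2L))) stop("a 2 x 2 table is required")
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  ft <- stats::fisher.test(m, alternative = "two.sided")
  .testResult("Fisher exact", unname(ft$estimate), ft$p.value,
              "incidence x group", method = "point-probability two-sided")
}

# Midrank U statistic of x against y.
.ustat <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' U is computed with midranks for ties. For combined sample sizes up to
#' \code{exactMax} the two-sided p-value is exact: all assignments of the
#' pooled values into the two groups are enumerated and tables at least as
#' far from the null mean U = n1 n2 / 2 as the observed one are counted
#' (valid with ties). Larger samples use the normal approximation with tie
#' correction and continuity correction. The method used is recorded.
#'
#' @param x,y Non-empty numeric samples.
#' @param exactMax Combined-size cutoff for the exact path (default 12).
#' @return A [TestResult] with the U statistic of \code{x}.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mannWhitney <- function(x, y, exactMax = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (N <= exactMax) {
    sel <- utils::combn(N, n1)
    us <- apply(sel, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1; method <- "normal approximation (degenerate)"
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "normal approximation, tie + continuity correction"
    }
  }
  .testResult("Mann-Whitney U", U, p, "x vs y", method = method)
}

#' Two-way ANOVA with Bonferroni post-tests
#'
#' Crossed two-factor ANOVA (group x condition) on per-animal values. A
#' balanced design is fitted with \code{stats::aov} (where type I and type II
#' sums of squares coincide); unbalanced input triggers a warning and type-II
#' sums of squares via \code{car::Anova}. Post-tests are the four pairwise
#' pooled-variance t comparisons between groups within each condition and
#' between conditions within each group, using the ANOVA residual mean
#' square, Bonferroni-adjusted with multiplier 4 (capped at 1).
#'
#' A fully degenerate input (all values identical) is reported as F = 0,
#' p = 1 for every effect.
#'
#' @param table \code{data.frame} with columns \code{group},
#'   \code{condition} (two levels each) and \code{value}; one row per animal.
#' @return List of [TestResult]: three main/interaction effects followed by
#'   the four adjusted post-tests.
#' @export
twoWayAnovaBonferroni <- function(table) {
  need <- c("group", "condition", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns group, condition, value")
  df <- data.frame(group = factor(table$group),
                   condition = factor(table$condition),
                   value = as.numeric(table$value))
  if (nlevels(df$group) != 2L || nlevels(df$condition) != 2L)
    stop("exactly two levels of group and of condition are required")
  cells <- table(df$group, df$condition)
  if (any(cells == 0)) stop("empty design cell: every group x condition cell needs data")
  gl <- levels(df$group); cl <- levels(df$condition)

  if (stats::var(df$value) == 0) {
    effects <- lapply(c("group", "condition", "group:condition"), function(e)
      .testResult("Two-way ANOVA", 0, 1, e, method = "degenerate (constant data)"))
    posts <- lapply(c(paste0(gl[1], " vs ", gl[2], " | ", cl),
                      paste0(cl[1], " vs ", cl[2], " | ", gl)), function(cmp)
      .testResult("Bonferroni post-test", 0, 1, cmp,
                  method = "degenerate (constant data)"))
    return(c(effects, posts))
  }

  balanced <- length(unique(as.vector(cells))) == 1L
  fit <- stats::lm(value ~ group * condition, data = df)
  if (balanced) {
    a <- stats::anova(fit)
    rows <- c("group", "condition", "group:condition")
    Fv <- a[rows, "F value"]; pv <- a[rows, "Pr(>F)"]
    method <- "type I (balanced)"
  } else {
    warning("unbalanced design: using type-II sums of squares", call. = FALSE)
    a <- car::Anova(fit, type = 2)
    rows <- c("group", "condition", "group:condition")
    Fv <- a[rows, "F value"]; pv <- a[rows, "Pr(>F)"]
    method <- "type II (unbalanced)"
  }
  effects <- Map(function(e, f, p)
    .testResult("Two-way ANOVA", f, p, e, method = method),
    c("group", "condition", "group:condition"), Fv, pv)

  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  dfres <- fit$df.residual
  cellMean <- tapply(df$value, list(df$group, df$condition), mean)
  cellN <- cells
  postT <- function(m1, m2, n1, n2, cmp) {
    tstat <- (m1 - m2) / sqrt(mse * (1 / n1 + 1 / n2))
    praw <- 2 * stats::pt(-abs(tstat), dfres)
    .testResult("Bonferroni post-test", tstat, min(1, 4 * praw), cmp,
                method = "pooled-MSE t, adjusted x4")
  }
  posts <- list()
  for (cc in cl)
    posts[[length(posts) + 1]] <-
      postT(cellMean[gl[1], cc], cellMean[gl[2], cc],
            cellN[gl[1], cc], cellN[gl[2], cc],
            paste0(gl[1], " vs ", gl[2], " | ", cc))
  for (gg in gl)
    posts[[length(posts) + 1]] <-
      postT(cellMean[gg, cl[1]], cellMean[gg, cl[2]],
            cellN[gg, cl[1]], cellN[gg, cl[2]],
            paste0(cl[1], " vs ", cl[2], " | ", gg))
  c(effects, posts)
}
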