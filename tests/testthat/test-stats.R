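test_that("group summaries give mean, SEM and n with SEM undefined at n = 1", {
  s <- summarizeGroup(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 2 / sqrt(3))
  expect_identical(s$n, 3L)
  s1 <- summarizeGroup(5)
  expect_true(is.na(s1$sem))
  expect_equal(summarizeGroup(rep(3, 4))$sem, 0)
  expect_error(summarizeGroup(numeric(0)), "empty")
})

test_that("Fisher's exact test matches hand values and rejects bad counts", {
  expect_equal(fisherExact(matrix(c(5, 5, 5, 5), 2))@pValue, 1)
  expect_equal(fisherExact(matrix(c(3, 0, 0, 3), 2))@pValue, 0.1)
  expect_error(fisherExact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisherExact(matrix(c(1.5, 2, 3, 4), 2)), "non-negative")
})

test_that("Fisher p equals the hypergeometric enumeration oracle", {
  set.seed(12)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    expect_equal(fisherExact(tab)@pValue, oracleFisherP(tab),
                 tolerance = 1e-10, info = paste(tab, collapse = ","))
  }
})

test_that("Mann-Whitney exact path matches hand values and the oracle", {
  r <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(r@statistic, 0)
  expect_equal(r@pValue, 2 / 6)
  expect_match(r@method, "exact")

  same <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same@statistic, 8)  # n^2 / 2
  expect_equal(same@pValue, 1)

  set.seed(13)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(1:5, n1 + n2, replace = TRUE)  # heavy ties
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    expect_equal(mannWhitney(x, y)@pValue, oracleMannWhitneyP(x, y),
                 tolerance = 1e-12, info = paste("case", i))
  }
})

test_that("the large-sample path uses the tie-corrected normal approximation", {
  set.seed(14)
  x <- round(rnorm(13, 10, 2)); y <- round(rnorm(13, 11, 2))
  r <- mannWhitney(x, y)
  expect_match(r@method, "normal approximation")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r@pValue, ref$p.value, tolerance = 1e-10)
  expect_equal(r@statistic, unname(ref$statistic))
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("two-way ANOVA handles the degenerate constant case as F = 0", {
  df <- expand.grid(group = c("N", "IHH"), condition = c("control", "ischemia"),
                    rep = 1:3)
  df$value <- 5
  res <- twoWayAnovaBonferroni(df)
  expect_length(res, 7)
  for (r in res) {
    expect_equal(r@statistic, 0)
    expect_equal(r@pValue, 1)
  }
})

test_that("post-test p-values are the raw t p times four, capped at one", {
  set.seed(15)
  df <- expand.grid(group = c("N", "IHH"), condition = c("control", "ischemia"),
                    rep = 1:6)
  df$value <- rnorm(nrow(df)) + ifelse(df$group == "IHH", 2, 0)
  res <- twoWayAnovaBonferroni(df)
  posts <- res[4:7]
  # recompute one comparison by hand from the pooled residual MS
  fit <- lm(value ~ group * condition, data = df)
  mse <- sum(residuals(fit)^2) / fit$df.residual
  sub <- df[df$condition == "control", ]
  mIHH <- mean(sub$value[sub$group == "IHH"])
  mN <- mean(sub$value[sub$group == "N"])
  tstat <- (mIHH - mN) / sqrt(mse * (1 / 6 + 1 / 6))
  praw <- 2 * pt(-abs(tstat), fit$df.residual)
  got <- posts[[1]]  # IHH vs N | control (factor levels sort IHH first)
  expect_equal(abs(got@statistic), abs(tstat), tolerance = 1e-10)
  expect_equal(got@pValue, min(1, 4 * praw), tolerance = 1e-10)
  for (p in posts) expect_lte(p@pValue, 1)
})

test_that("a strong group main effect is detected and the interaction is null-calibrated", {
  set.seed(16)
  nSim <- 500
  sigGroup <- sigInter <- 0
  for (i in seq_len(nSim)) {
    df <- expand.grid(group = c("N", "IHH"),
                      condition = c("control", "ischemia"), rep = 1:6)
    df$value <- rnorm(nrow(df)) + ifelse(df$group == "IHH", 3, 0)
    res <- twoWayAnovaBonferroni(df)
    sigGroup <- sigGroup + res[[1]]@significant
    sigInter <- sigInter + res[[3]]@significant
  }
  expect_gte(sigGroup / nSim, 0.95)
  expect_lte(sigInter / nSim, 0.07)
})

test_that("design validation: levels, empty cells, unbalanced warning", {
  df <- expand.grid(group = c("a", "b", "c"), condition = c("x", "y"), rep = 1:3)
  df$value <- rnorm(nrow(df))
  expect_error(twoWayAnovaBonferroni(df), "two levels")

  df2 <- expand.grid(group = c("a", "b"), condition = c("x", "y"), rep = 1:3)
  df2$value <- rnorm(nrow(df2))
  expect_error(twoWayAnovaBonferroni(df2[!(df2$group == "a" & df2$condition == "x"), ]),
               "empty design cell")
  expect_warning(twoWayAnovaBonferroni(df2[-1, ]), "unbalanced")
})
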