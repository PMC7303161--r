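## Brute-force oracles, kept deliberately naive and separate from the
## implementations they check.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
oracle_H <- function(groups) {
  x <- unlist(groups); N <- length(x); rk <- rank(x)
  ri <- split(rk, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (N * (N + 1)) * sum(vapply(ri, function(r) length(r) * mean(r)^2, 0)) -
    3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

test_that("Spearman correlation handles monotone and hand-ranked cases", {
  expect_equal(spearman_rank(1:10, (1:10)^3)$r, 1)
  expect_equal(spearman_rank(1:10, -(1:10))$r, -1)
  ## x = 1..5, y = (2,1,4,3,5): sum d^2 = 4 -> r = 1 - 24/120 = 0.8
  expect_equal(spearman_rank(1:5, c(2, 1, 4, 3, 5))$r, 0.8)
  expect_error(spearman_rank(1:5, rep(2, 5)), "constant")
})

test_that("Spearman agrees with the brute-force rank oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:30, 1L)
    x <- sample(1:10, n, replace = TRUE)   # ties exercised via mid-ranks
    y <- x + rnorm(n, sd = 3)
    got <- spearman_rank(x, y)
    expect_equal(got$r, oracle_spearman(x, y), tolerance = 1e-10)
    tt <- got$r * sqrt((n - 2) / (1 - got$r^2))
    expect_equal(got$p, 2 * pt(-abs(tt), n - 2), tolerance = 1e-10)
  }
})

test_that("the pooled t-test matches the textbook formula and its edge cases", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  z <- ttest_independent(a, b)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_lt(ttest_independent(rnorm(10, 0, 0.1), rnorm(10, 100, 0.1))$p, 1e-10)
  expect_error(ttest_independent(c(1, 1), c(1, 1)), "zero pooled variance")
  set.seed(202)
  for (i in 1:50) {
    a <- rnorm(sample(3:12, 1L)); b <- rnorm(sample(3:12, 1L), mean = 0.5)
    got <- ttest_independent(a, b)
    expect_equal(got$t, oracle_t(a, b), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis/Dunn matches the tie-corrected oracle and annotates letters", {
  kd <- kruskal_dunn(list(a = 1:8, b = 11:18, c = 21:28))
  expect_equal(kd$H, oracle_H(list(1:8, 11:18, 21:28)), tolerance = 1e-12)
  expect_true(all(kd$pairwise$p < 0.05))
  expect_equal(unname(kd$letters), c("b,c", "a,c", "a,b"))
  ## identical groups: H ~ 0, no letters
  same <- kruskal_dunn(list(a = c(1, 2), b = c(1, 2), c = c(2, 1)))
  expect_lt(same$H, 1e-9)
  expect_true(all(same$letters == ""))
  ## all observations equal: degenerate zero H
  flat <- kruskal_dunn(list(a = c(3, 3), b = c(3, 3), c = c(3, 3)))
  expect_equal(flat$H, 0)
  set.seed(303)
  for (i in 1:30) {
    g <- lapply(1:3, function(k) sample(1:6, sample(3:8, 1L), replace = TRUE))
    if (var(unlist(g)) == 0) next
    expect_equal(kruskal_dunn(g)$H, oracle_H(g), tolerance = 1e-10)
  }
})

test_that("Dunn z statistics match the mean-rank formula on a hand case", {
  g <- list(a = c(1, 3, 5), b = c(2, 4, 6), c = c(10, 11, 12))
  kd <- kruskal_dunn(g)
  x <- unlist(g); N <- 9; rk <- rank(x)
  rb <- tapply(rk, rep(names(g), each = 3L), mean)
  se <- sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 3))
  expect_equal(kd$pairwise$z[1L], unname((rb["a"] - rb["b"]) / se), tolerance = 1e-12)
  expect_equal(kd$pairwise$z[3L], unname((rb["b"] - rb["c"]) / se), tolerance = 1e-12)
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(404)
  x <- rnorm(40); y <- x + rnorm(40)
  expect_equal(spearman_rank(exp(x), y)$r, spearman_rank(x, y)$r, tolerance = 1e-12)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  expect_equal(kruskal_dunn(lapply(g, exp))$H, kruskal_dunn(g)$H, tolerance = 1e-12)
})

test_that("forward-conditional selection recovers constructed truth", {
  set.seed(505)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, sd = 0.5)
  fit <- forward_conditional_regression(data.frame(x1 = x1, x2 = x2), y)
  expect_equal(fit$selected, "x1")
  expect_equal(fit$table$beta[1L], 2, tolerance = 0.15)
  ## independent response: empty model
  fit0 <- forward_conditional_regression(data.frame(x1 = x1, x2 = x2), rnorm(n))
  expect_length(fit0$selected, 0L)
  expect_equal(nrow(fit0$table), 0L)
  ## collinear true predictors: exactly one retained
  x3 <- x1 + rnorm(n, sd = 1e-4)
  fitc <- forward_conditional_regression(data.frame(x1 = x1, x3 = x3),
                                         2 * x1 + rnorm(n, sd = 0.5))
  expect_length(fitc$selected, 1L)
})

test_that("Lin's concordance decomposes into precision and accuracy", {
  x <- as.numeric(1:10)
  z <- concordance(x, x)
  expect_equal(z$ccc, 1); expect_equal(z$precision, 1); expect_equal(z$accuracy, 1)
  sh <- concordance(x, x + 3)
  expect_equal(sh$precision, 1)
  expect_lt(sh$ccc, 1)
  expect_equal(sh$accuracy, sh$ccc)
  set.seed(606)
  for (i in 1:50) {
    a <- rnorm(sample(4:20, 1L)); b <- a * runif(1, 0.5, 2) + rnorm(length(a))
    z <- concordance(a, b)
    expect_equal(z$ccc, oracle_ccc(a, b), tolerance = 1e-12)
    expect_lte(abs(z$ccc), abs(z$precision) + 1e-12)   # CCC never exceeds |r|
  }
  expect_error(concordance(rep(1, 5), 1:5), "zero variance")
})

test_that("variability and bias follow their paired-difference definitions", {
  x <- seq(10, 20, length.out = 12)
  z <- variability_and_bias(x, x)
  expect_equal(z$bias_pct, 0); expect_equal(z$cov_pct, 0)
  ## y = 1.07 x: bias = 100 * (-0.07) / 1.035 = -6.76%
  z2 <- variability_and_bias(x, 1.07 * x)
  expect_equal(z2$bias_pct, 100 * mean(x - 1.07 * x) / mean((x + 1.07 * x) / 2),
               tolerance = 1e-12)
  expect_equal(z2$bias_pct, -6.76, tolerance = 0.01)
  set.seed(707)
  a <- rnorm(15, 50, 5); b <- a + rnorm(15)
  z3 <- variability_and_bias(a, b)
  expect_equal(z3$cov_pct, 100 * sd(a - b) / mean((a + b) / 2), tolerance = 1e-12)
})

test_that("the cohort report reproduces explicit age-group partitions", {
  g <- make_cohort(cohort_spec(seed = 21L))$cohort
  a <- sort(g$age)
  breaks <- c(-Inf, (a[12] + a[13]) / 2, (a[21] + a[22]) / 2,
              (a[32] + a[33]) / 2, (a[42] + a[43]) / 2, Inf)
  rep <- build_report(g, age_breaks = breaks)
  expect_equal(as.integer(rep$age_groups$sizes), c(12L, 9L, 11L, 10L, 11L))
  expect_true(all(c("descriptives", "correlations", "regression") %in% names(rep)))
  expect_true(all(rep$correlations$p >= 0, rep$correlations$p <= 1))
  ## multivariate model only draws from univariately significant metrics
  expect_true(all(rep$regression$selected %in%
                    rep$regression$univariate$metric[rep$regression$univariate$p < 0.05]))
})

test_that("an all-null cohort produces only small correlations", {
  et <- default_effect_table()
  et$rho_age <- 0
  g <- make_cohort(cohort_spec(effect_table = et, seed = 31L))$cohort
  rep <- build_report(g)
  expect_lt(max(abs(rep$correlations$r)), 0.45)
})
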