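#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using mid-ranks for ties; the two-sided p-value uses
#' the t approximation `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @return list with `r`, `p`, `n`
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant series")
  r <- stats::cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Independent two-sample t-test (pooled variance)
#'
#' @param a,b numeric vectors, each n >= 2
#' @return list with `t`, `p`, `df`
#' @export
ttest_independent <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero pooled variance: t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Kruskal-Wallis H test with Dunn post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) plus Dunn's
#' pairwise z statistics on mean ranks, with the usual tie correction.
#' Per-group significance letters mark, for each group, the letters of the
#' other groups it differs from at `alpha` (the annotation style of
#' age-group tables: a group labelled `a` annotated `d,e` differs from
#' groups `d` and `e`).
#'
#' @param groups list of numeric vectors (>= 3 groups, each n >= 2)
#' @param alpha pairwise significance level for the letters
#' @param adjust `"none"` (default) or `"bonferroni"` for the Dunn p-values
#' @return list with `H`, `p`, `pairwise` (data.frame: `group1`, `group2`,
#'   `z`, `p`, `p_adjusted`), `letters` (named character vector)
#' @export
kruskal_dunn <- function(groups, alpha = 0.05, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 3L,
            all(vapply(groups, length, 0L) >= 2L))
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- letters[seq_len(k)]
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  if (stats::var(x) == 0) {
    pair <- t(utils::combn(names(groups), 2L))
    pw <- data.frame(group1 = pair[, 1L], group2 = pair[, 2L],
                     z = 0, p = 1, p_adjusted = 1, stringsAsFactors = FALSE)
    return(list(H = 0, p = 1, pairwise = pw,
                letters = stats::setNames(rep("", k), names(groups))))
  }
  kw <- stats::kruskal.test(x, g)
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  ni <- tapply(rk, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pair <- t(utils::combn(names(groups), 2L))
  z <- p <- numeric(nrow(pair))
  for (i in seq_len(nrow(pair))) {
    g1 <- pair[i, 1L]; g2 <- pair[i, 2L]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ni[[g1]] + 1 / ni[[g2]]))
    z[i] <- (rbar[[g1]] - rbar[[g2]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  p_adj <- if (adjust == "bonferroni") pmin(1, p * nrow(pair)) else p
  sig <- p_adj < alpha
  lets <- vapply(names(groups), function(gn) {
    others <- c(pair[sig & pair[, 1L] == gn, 2L], pair[sig & pair[, 2L] == gn, 1L])
    paste(sort(others), collapse = ",")
  }, "")
  list(H = unname(kw$statistic), p = kw$p.value,
       pairwise = data.frame(group1 = pair[, 1L], group2 = pair[, 2L],
                             z = z, p = p, p_adjusted = p_adj,
                             stringsAsFactors = FALSE),
       letters = lets)
}

#' Forward-conditional stepwise linear regression
#'
#' Iteratively adds the candidate with the smallest entry p-value below
#' `p_enter`, then re-tests the included terms and removes any whose
#' p-value exceeds `p_remove`, until the model is stable. Candidates should
#' be pre-filtered to univariate significance. Returns the final model's
#' coefficient table.
#'
#' @param candidates data.frame or matrix of candidate predictors
#' @param y response vector
#' @param p_enter entry threshold (default 0.05)
#' @param p_remove removal threshold (default 0.10)
#' @return list with `selected` (character), `table` (data.frame:
#'   `variable`, `beta`, `se`, `p`), `steps` (log of entries/removals)
#' @export
forward_conditional_regression <- function(candidates, y,
                                           p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(candidates)
  stopifnot(nrow(X) == length(y), nrow(X) > ncol(X) + 2L)
  vars <- names(X)
  included <- character(0L)
  steps <- character(0L)
  coef_p <- function(terms) {
    df <- cbind(data.frame(.y = y), X[terms])
    fit <- stats::lm(.y ~ ., data = df)
    sm <- summary(fit)$coefficients
    sm[match(terms, rownames(sm)), , drop = FALSE]
  }
  repeat {
    remaining <- setdiff(vars, included)
    if (!length(remaining)) break
    entry_p <- vapply(remaining, function(v) {
      sm <- coef_p(c(included, v))
      sm[nrow(sm), 4L]
    }, 0)
    best <- names(which.min(entry_p))
    if (!length(best) || min(entry_p) >= p_enter) break
    included <- c(included, best)
    steps <- c(steps, paste0("+", best))
    ## conditional removal pass
    repeat {
      if (length(included) < 2L) break
      sm <- coef_p(included)
      worst <- which.max(sm[, 4L])
      if (sm[worst, 4L] > p_remove) {
        steps <- c(steps, paste0("-", included[worst]))
        included <- included[-worst]
      } else break
    }
  }
  if (!length(included)) {
    return(list(selected = character(0L),
                table = data.frame(variable = character(0L), beta = numeric(0L),
                                   se = numeric(0L), p = numeric(0L)),
                steps = steps))
  }
  sm <- coef_p(included)
  list(selected = included,
       table = data.frame(variable = included, beta = sm[, 1L],
                          se = sm[, 2L], p = sm[, 4L],
                          row.names = NULL, stringsAsFactors = FALSE),
       steps = steps)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var x + var y + (mean x - mean y)^2)`, decomposed
#' into precision (the Pearson correlation) and accuracy (the
#' bias-correction factor `CCC / r`). Population (n) variances are used, as
#' in Lin's definition.
#'
#' @param x,y paired measurements, n >= 3
#' @return list with `ccc`, `precision`, `accuracy`
#' @export
concordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  sx2 <- stats::var(x) * (n - 1) / n
  sy2 <- stats::var(y) * (n - 1) / n
  if (sx2 == 0 || sy2 == 0) stop("concordance undefined for zero variance")
  sxy <- stats::cov(x, y) * (n - 1) / n
  ccc <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
  r <- stats::cor(x, y)
  list(ccc = ccc, precision = r, accuracy = ccc / r)
}

#' Coefficient of variability and percentage bias of paired measurements
#'
#' `bias_pct = 100 mean(x - y) / mean((x + y)/2)` and
#' `cov_pct = 100 sd(x - y) / mean((x + y)/2)`.
#'
#' @param x,y paired measurements, n >= 3
#' @return list with `cov_pct`, `bias_pct`
#' @export
variability_and_bias <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  level <- mean((x + y) / 2)
  if (abs(level) < .Machine$double.eps * 100)
    stop("zero mean level: percentage metrics undefined")
  list(cov_pct = 100 * stats::sd(x - y) / level,
       bias_pct = 100 * mean(x - y) / level)
}

#' Cohort report: descriptives, age associations, regression, age groups
#'
#' Produces the standard cohort-analysis tables from a per-subject metric
#' table: (1) mean +/- SD overall and by sex with pooled t-test p-values;
#' (2) Spearman correlation of every metric with age; (3) univariate linear
#' regression of age on each metric plus a forward-conditional multivariate
#' model over the univariately significant metrics; (4) median +/- IQR
#' across age groups with Kruskal-Wallis p and Dunn pairwise letters.
#'
#' @param cohort data.frame with columns `age`, `sex` and metric columns
#' @param metrics metric column names (default: all numeric except
#'   `age`/`bsa`)
#' @param age_breaks explicit age-bin edges, or `NULL` for `n_groups`
#'   equal-count (quantile) groups
#' @param n_groups number of age groups when `age_breaks` is `NULL`
#' @param p_enter,p_remove stepwise thresholds
#' @param dunn_adjust Dunn p adjustment for the letters
#' @return object of class `cohort_result` with elements `descriptives`,
#'   `correlations`, `regression` (`univariate`, `multivariate`,
#'   `selected`), `age_groups` (`sizes`, `summary`, one row set per metric)
#' @export
build_report <- function(cohort, metrics = NULL, age_breaks = NULL,
                         n_groups = 5L, p_enter = 0.05, p_remove = 0.10,
                         dunn_adjust = c("none", "bonferroni")) {
  dunn_adjust <- match.arg(dunn_adjust)
  stopifnot(is.data.frame(cohort), "age" %in% names(cohort),
            nrow(cohort) >= 3L)
  if (is.null(metrics)) {
    num <- vapply(cohort, is.numeric, TRUE)
    metrics <- setdiff(names(cohort)[num], c("age", "bsa"))
  }
  ## 1. descriptives by sex
  has_sex <- "sex" %in% names(cohort) && length(unique(cohort$sex)) == 2L
  desc <- do.call(rbind, lapply(c("age", metrics), function(m) {
    row <- data.frame(metric = m,
                      mean = mean(cohort[[m]]), sd = stats::sd(cohort[[m]]),
                      stringsAsFactors = FALSE)
    if (has_sex) {
      f <- cohort[[m]][cohort$sex == "F"]; ml <- cohort[[m]][cohort$sex == "M"]
      row$mean_f <- mean(f); row$sd_f <- stats::sd(f)
      row$mean_m <- mean(ml); row$sd_m <- stats::sd(ml)
      row$p_sex <- tryCatch(ttest_independent(f, ml)$p, error = function(e) NA_real_)
    }
    row
  }))
  ## 2. Spearman vs age
  corr <- do.call(rbind, lapply(metrics, function(m) {
    s <- tryCatch(spearman_rank(cohort$age, cohort[[m]]),
                  error = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(metric = m, r = s$r, p = s$p, stringsAsFactors = FALSE)
  }))
  ## 3. regression: univariate age ~ metric, then forward-conditional
  uni <- do.call(rbind, lapply(metrics, function(m) {
    sm <- summary(stats::lm(cohort$age ~ cohort[[m]]))$coefficients
    data.frame(metric = m, beta = sm[2L, 1L], se = sm[2L, 2L], p = sm[2L, 4L],
               stringsAsFactors = FALSE)
  }))
  sig <- uni$metric[uni$p < p_enter]
  multi <- if (length(sig) >= 1L && nrow(cohort) > length(sig) + 2L) {
    forward_conditional_regression(cohort[sig], cohort$age, p_enter, p_remove)
  } else list(selected = character(0L),
              table = data.frame(variable = character(0L), beta = numeric(0L),
                                 se = numeric(0L), p = numeric(0L)))
  ## 4. age groups
  if (is.null(age_breaks)) {
    qs <- stats::quantile(cohort$age, probs = seq(0, 1, length.out = n_groups + 1L))
    qs[1L] <- -Inf; qs[length(qs)] <- Inf
    age_breaks <- qs
  }
  grp <- cut(cohort$age, breaks = age_breaks, include.lowest = TRUE,
             labels = letters[seq_len(length(age_breaks) - 1L)])
  sizes <- table(grp)
  group_tabs <- lapply(c("age", metrics), function(m) {
    gl <- split(cohort[[m]], grp)
    med <- vapply(gl, stats::median, 0)
    iqr <- vapply(gl, stats::IQR, 0)
    res <- if (m == "age" || length(gl) < 3L || any(lengths(gl) < 2L)) {
      NULL
    } else tryCatch(kruskal_dunn(gl, adjust = dunn_adjust),
                    error = function(e) NULL)
    data.frame(metric = m, group = names(gl), n = as.integer(lengths(gl)),
               median = med, iqr = iqr,
               letters = if (is.null(res)) "" else res$letters[names(gl)],
               p_kw = if (is.null(res)) NA_real_ else res$p,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(list(descriptives = desc,
                 correlations = corr,
                 regression = list(univariate = uni,
                                   multivariate = multi$table,
                                   selected = multi$selected),
                 age_groups = list(sizes = sizes,
                                   summary = do.call(rbind, group_tabs),
                                   breaks = age_breaks),
                 n = nrow(cohort)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> n = %d\n", x$n))
  cat("Strongest age associations (Spearman):\n")
  co <- x$correlations[order(abs(x$correlations$r), decreasing = TRUE), ]
  print(utils::head(co, 5L), row.names = FALSE, digits = 3L)
  if (length(x$regression$selected))
    cat("Multivariate model retains:", paste(x$regression$selected, collapse = ", "), "\n")
  invisible(x)
}
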