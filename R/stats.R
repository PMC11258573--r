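#' Shapiro-Wilk normality test with explicit degenerate handling
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list of class `normality_test`: `W`, `p`, `n`, `degenerate`
#'   (TRUE when the sample has zero variance, in which case W and p are NA).
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) {
    stop(sprintf("sample size %d outside the supported range 3..5000", n))
  }
  if (stats::var(x) == 0) {
    return(structure(list(W = NA_real_, p = NA_real_, n = n, degenerate = TRUE),
                     class = "normality_test"))
  }
  t <- stats::shapiro.test(x)
  structure(list(W = unname(t$statistic), p = t$p.value, n = n,
                 degenerate = FALSE), class = "normality_test")
}

#' @export
print.normality_test <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Shapiro-Wilk: degenerate sample (zero variance), n = %d\n", x$n))
  } else {
    cat(sprintf("Shapiro-Wilk: W = %.4f, p = %.4g, n = %d\n", x$W, x$p, x$n))
  }
  invisible(x)
}

new_anova_result <- function(effects, residual, design) {
  structure(list(effects = effects, residual = residual, design = design),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, digits = 4, ...) {
  tab <- rbind(
    data.frame(term = x$effects$term, df = x$effects$df,
               sumsq = x$effects$sumsq, meansq = x$effects$meansq,
               F = x$effects$statistic, p = x$effects$p_value),
    data.frame(term = "Residuals", df = x$residual$df,
               sumsq = x$residual$sumsq, meansq = x$residual$meansq,
               F = NA, p = NA))
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA via the standard linear-model fit. When every
#' observation is identical the test is reported as F = 0, p = 1 rather
#' than 0/0.
#'
#' @param groups either a list of numeric samples (each n >= 2) or a numeric
#'   vector when `g` is given.
#' @param g optional grouping factor matching `groups` as a vector.
#' @return an `anova_result` with one effect row (`group`) and a residual
#'   row; `design` echoes group sizes.
#' @export
one_way_anova <- function(groups, g = NULL) {
  if (is.null(g)) {
    stopifnot(is.list(groups))
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  } else {
    y <- groups
    g <- factor(g)
  }
  if (nlevels(g) < 2L) stop("at least two groups are required")
  if (any(base::table(g) < 2L)) stop("every group needs n >= 2")
  design <- list(factors = "group", levels = levels(g),
                 n_per_group = as.integer(base::table(g)))
  if (stats::var(y) == 0) {
    k <- nlevels(g); N <- length(y)
    return(new_anova_result(
      data.frame(term = "group", df = k - 1L, sumsq = 0, meansq = 0,
                 statistic = 0, p_value = 1),
      list(df = N - k, sumsq = 0, meansq = 0), design))
  }
  fit <- stats::lm(y ~ g)
  # a perfect fit triggers an "unreliable F" warning; that case is
  # re-derived explicitly below
  a <- suppressWarnings(stats::anova(fit))
  eff <- data.frame(term = "group", df = a$Df[1], sumsq = a$`Sum Sq`[1],
                    meansq = a$`Mean Sq`[1], statistic = a$`F value`[1],
                    p_value = a$`Pr(>F)`[1])
  if (a$`Sum Sq`[2] <= 1e-12 * sum(a$`Sum Sq`)) {
    # perfect separation: groups differ, no within-group noise
    eff$statistic <- Inf
    eff$p_value <- 0
  }
  new_anova_result(eff, list(df = a$Df[2], sumsq = a$`Sum Sq`[2],
                             meansq = a$`Mean Sq`[2]), design)
}

#' Two-way analysis of variance (balanced designs)
#'
#' Main effects and interaction for a balanced full-factorial design with
#' replication. Unbalanced or incomplete designs are an explicit error
#' naming the offending cells, rather than a silently chosen
#' sums-of-squares type (in a balanced design all types coincide).
#'
#' @param values numeric response.
#' @param factorA,factorB factors (or coercible) of the same length.
#' @return an `anova_result` with rows for A, B and A:B.
#' @export
two_way_anova <- function(values, factorA, factorB) {
  a <- factor(factorA)
  b <- factor(factorB)
  stopifnot(length(values) == length(a), length(values) == length(b))
  tab <- base::table(a, b)
  if (any(tab == 0L) || length(unique(as.vector(tab))) != 1L) {
    bad <- which(tab == 0L | tab != as.vector(tab)[1], arr.ind = TRUE)
    cells <- apply(bad, 1, function(ij) {
      sprintf("%s:%s (n=%d)", levels(a)[ij[1]], levels(b)[ij[2]],
              tab[ij[1], ij[2]])
    })
    stop(sprintf("unbalanced design; offending cell(s): %s",
                 paste(cells, collapse = ", ")))
  }
  if (as.vector(tab)[1] < 2L) {
    stop("the design needs replication (n >= 2 per cell) for the interaction")
  }
  design <- list(factors = c("A", "B"),
                 levels = list(A = levels(a), B = levels(b)),
                 n_per_cell = as.vector(tab)[1])
  terms <- c("A", "B", "A:B")
  if (stats::var(values) == 0) {
    dfA <- nlevels(a) - 1L; dfB <- nlevels(b) - 1L
    dfs <- c(dfA, dfB, dfA * dfB)
    return(new_anova_result(
      data.frame(term = terms, df = dfs, sumsq = 0, meansq = 0,
                 statistic = 0, p_value = 1),
      list(df = length(values) - 1L - sum(dfs), sumsq = 0, meansq = 0),
      design))
  }
  fit <- stats::aov(values ~ a * b)
  # a perfect fit triggers an "unreliable F" warning; that case is
  # re-derived explicitly below
  s <- suppressWarnings(summary(fit))[[1]]
  eff <- data.frame(term = terms, df = s$Df[1:3], sumsq = s$`Sum Sq`[1:3],
                    meansq = s$`Mean Sq`[1:3], statistic = s$`F value`[1:3],
                    p_value = s$`Pr(>F)`[1:3])
  tot <- sum(s$`Sum Sq`)
  if (s$`Sum Sq`[4] <= 1e-12 * tot) {  # perfect fit: define F by the effect SS
    zero <- eff$sumsq <= 1e-12 * tot
    eff$statistic <- ifelse(zero, 0, Inf)
    eff$p_value <- ifelse(zero, 1, 0)
  }
  new_anova_result(eff, list(df = s$Df[4], sumsq = s$`Sum Sq`[4],
                             meansq = s$`Mean Sq`[4]), design)
}

#' Tukey honestly-significant-difference post hoc test
#'
#' Studentized-range adjusted p-values and simultaneous confidence
#' intervals for all pairwise group contrasts of a one-way layout.
#'
#' @param groups list of numeric samples (each n >= 2) or a numeric vector
#'   with `g`.
#' @param g optional grouping factor.
#' @param conf_level familywise confidence level.
#' @return data frame of class `tukey_result`: pair, diff, lwr, upr,
#'   p_adj.
#' @export
tukey_hsd <- function(groups, g = NULL, conf_level = 0.95) {
  if (is.null(g)) {
    stopifnot(is.list(groups))
    if (length(groups) < 2L) stop("at least two groups are required")
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  } else {
    y <- groups
    g <- factor(g)
  }
  if (nlevels(g) < 2L) stop("at least two groups are required")
  if (any(base::table(g) < 2L)) stop("every group needs n >= 2")
  if (stats::var(y) == 0) {
    prs <- utils::combn(levels(g), 2L)
    out <- data.frame(pair = paste(prs[2, ], prs[1, ], sep = "-"),
                      diff = 0, lwr = 0, upr = 0, p_adj = 1)
    return(structure(out, class = c("tukey_result", "data.frame")))
  }
  t <- stats::TukeyHSD(stats::aov(y ~ g), conf.level = conf_level)$g
  out <- data.frame(pair = rownames(t), diff = t[, "diff"],
                    lwr = t[, "lwr"], upr = t[, "upr"],
                    p_adj = pmin(pmax(t[, "p adj"], 0), 1))
  rownames(out) <- NULL
  structure(out, class = c("tukey_result", "data.frame"))
}

#' Pearson correlation with p-value
#'
#' @param x,y numeric vectors of equal length, n >= 3, both with non-zero
#'   variance (a zero-variance input is reported as undefined, not an
#'   error).
#' @return list of class `pearson_test`: `r`, `p` (t transform, n - 2 df),
#'   `n`, and `reason` (NULL, or why r is undefined).
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          reason = "zero variance"),
                     class = "pearson_test"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 reason = NULL), class = "pearson_test")
}

#' @export
print.pearson_test <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("Pearson correlation undefined (%s), n = %d\n", x$reason, x$n))
  } else {
    cat(sprintf("Pearson r = %.4f, p = %.4g, n = %d\n", x$r, x$p, x$n))
  }
  invisible(x)
}
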