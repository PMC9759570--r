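#' One-way analysis of variance
#'
#' Ordinary (equal-variance) one-way ANOVA across dietary groups: the
#' standard between/within sum-of-squares decomposition with the p-value
#' from the F distribution. No Welch correction is applied.
#'
#' @param groups A named or unnamed list of numeric vectors, one per
#'   group; at least 2 groups with at least 2 values each.
#' @return An object of class \code{anova_result}: list with
#'   \code{f_stat}, \code{df_between}, \code{df_within}, \code{p_value}.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every group needs at least 2 values")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(list(
    f_stat = unname(fit$statistic),
    df_between = as.integer(unname(fit$parameter[1])),
    df_within = as.integer(unname(fit$parameter[2])),
    p_value = unname(fit$p.value)
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' Tukey's honestly-significant-difference multiple comparisons
#'
#' All pairwise group-mean differences with studentized-range-adjusted
#' p-values; a pair is called significant when its adjusted p is below
#' \code{alpha}.
#'
#' @inheritParams one_way_anova
#' @param alpha Familywise significance level.
#' @return A data.frame with columns \code{comparison}, \code{diff},
#'   \code{lwr}, \code{upr}, \code{p_adj}, \code{significant}.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every group needs at least 2 values")
  }
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nms, vapply(groups, length, 1L)), levels = nms)
  tk <- stats::TukeyHSD(stats::aov(y ~ g), conf.level = 1 - alpha)$g
  data.frame(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    row.names = NULL
  )
}

#' Pearson correlation with confidence interval and strength class
#'
#' Pearson's r with the Fisher-z 95\% confidence interval and two-tailed
#' p-value (t distribution on n - 2 degrees of freedom), plus the
#' magnitude-based strength label of \code{\link{classify_r}}.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @param conf_level Confidence level for the interval.
#' @return An object of class \code{correlation_result}: list with
#'   \code{r}, \code{ci95}, \code{p_two_tailed}, \code{n},
#'   \code{strength_label}.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        conf.level = conf_level)
  r <- unname(ct$estimate)
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else {
    c(NA_real_, NA_real_)
  }
  structure(list(
    r = r,
    ci95 = ci,
    p_two_tailed = ct$p.value,
    n = length(x),
    strength_label = classify_r(r)
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f [%.3f, %.3f], p = %.3g (%s), n = %d\n",
              x$r, x$ci95[1], x$ci95[2], x$p_two_tailed,
              x$strength_label, x$n))
  invisible(x)
}

#' Correlation strength classification
#'
#' Classifies the magnitude of a correlation coefficient irrespective of
#' sign: strong for |r| >= 0.7, moderate for |r| in \[0.5, 0.7), fair for
#' |r| in \[0.3, 0.5), negligible for |r| < 0.3.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\]. Vectorized.
#' @return Character vector of labels.
#' @export
classify_r <- function(r) {
  stopifnot(is.numeric(r))
  if (any(abs(r) > 1 + 1e-12)) stop("|r| > 1 is not a correlation")
  a <- pmin(abs(r), 1)
  ifelse(a >= 0.7, "strong",
         ifelse(a >= 0.5, "moderate",
                ifelse(a >= 0.3, "fair", "negligible")))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise Pearson correlation matrix with BH-adjusted significance
#'
#' Computes Pearson's r for every feature pair, adjusts the off-diagonal
#' p-values jointly with Benjamini-Hochberg, and annotates significance
#' stars at 0.05 (*), 0.01 (**) and 0.001 (***). Constant (zero-variance)
#' features are excluded with a warning.
#'
#' @param features A data.frame of numeric feature columns (non-numeric
#'   columns such as identifiers are dropped), >= 3 complete rows.
#' @return An object of class \code{correlation_matrix_result}: list with
#'   \code{features} (names used), \code{r}, \code{p_raw}, \code{p_adj}
#'   (symmetric matrices), and \code{stars} (character matrix).
#' @export
correlation_matrix <- function(features) {
  stopifnot(is.data.frame(features))
  num <- features[vapply(features, is.numeric, TRUE)]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  if (nrow(num) < 3) stop("need at least 3 complete rows")
  constant <- vapply(num, function(col) stats::var(col) == 0, TRUE)
  if (any(constant)) {
    warning("excluding zero-variance features: ",
            paste(names(num)[constant], collapse = ", "))
    num <- num[!constant]
  }
  nm <- names(num)
  k <- length(nm)
  if (k < 2) stop("need at least 2 usable features")
  r <- diag(1, k); p_raw <- matrix(0, k, k)
  dimnames(r) <- dimnames(p_raw) <- list(nm, nm)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- pearson_with_ci(num[[i]], num[[j]])
      r[i, j] <- r[j, i] <- ct$r
      p_raw[i, j] <- p_raw[j, i] <- ct$p_two_tailed
    }
  }
  upper <- upper.tri(p_raw)
  p_adj <- matrix(0, k, k, dimnames = dimnames(p_raw))
  p_adj[upper] <- bh_adjust(p_raw[upper])
  p_adj <- p_adj + t(p_adj)
  stars <- matrix("", k, k, dimnames = dimnames(p_raw))
  stars[p_adj < 0.05] <- "*"
  stars[p_adj < 0.01] <- "**"
  stars[p_adj < 0.001] <- "***"
  diag(stars) <- ""
  structure(list(features = nm, r = r, p_raw = p_raw, p_adj = p_adj,
                 stars = stars),
            class = "correlation_matrix_result")
}

#' @export
print.correlation_matrix_result <- function(x, ...) {
  cat(sprintf("Pearson correlation matrix over %d features (BH-adjusted)\n",
              length(x$features)))
  out <- matrix(sprintf("%.2f%s", x$r, x$stars),
                nrow(x$r), dimnames = dimnames(x$r))
  diag(out) <- "1"
  print(out, quote = FALSE)
  invisible(x)
}
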