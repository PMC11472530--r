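#' Construct an agreement result
#'
#' Common container for kappa, weighted kappa, percentage agreement and
#' ICC estimates.  Degenerate inputs (one or both sides constant) are a
#' typed `status`, never an exception or numeric sentinel, mirroring the
#' footnote convention of published reliability tables.
#'
#' @param statistic `"kappa"`, `"weighted_kappa"`, `"percent_agreement"`
#'   or `"icc"`.
#' @param estimate point estimate (`NA` when undefined).
#' @param se standard error (`NA` where not defined).
#' @param ci_low,ci_high 95% confidence limits.
#' @param p_value one-sided p against the zero null.
#' @param n number of pairs (or rows for ICC).
#' @param status `"ok"`, `"undefined_constant_one_side"`,
#'   `"undefined_constant_both_sides"` or `"undefined"`.
#' @return object of class `agreement_result`; `interpretation` is filled
#'   from [interpret_landis_koch()] when the estimate is defined.
#' @export
agreement_result <- function(statistic, estimate, se = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             p_value = NA_real_, n = NA_integer_,
                             status = "ok") {
  interp <- if (status == "ok" && is.finite(estimate) &&
                statistic != "percent_agreement")
    interpret_landis_koch(estimate) else NA_character_
  structure(list(statistic = statistic, estimate = estimate, se = se,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 interpretation = interp, n = as.integer(n),
                 status = status),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<%s> not estimable (%s), n = %d\n", x$statistic,
                x$status, x$n))
    return(invisible(x))
  }
  ci <- if (is.finite(x$ci_low))
    sprintf(" (95%% CI %.3f-%.3f)", x$ci_low, x$ci_high) else ""
  p <- if (is.finite(x$p_value)) paste0(", p ", format_p(x$p_value)) else ""
  interp <- if (is.na(x$interpretation)) "" else
    paste0(" [", gsub("_", " ", x$interpretation), "]")
  cat(sprintf("<%s> %.3f%s%s, n = %d%s\n", x$statistic, x$estimate, ci,
              p, x$n, interp))
  invisible(x)
}

as_table <- function(table) {
  m <- unclass(as.matrix(table))
  if (nrow(m) != ncol(m) || nrow(m) < 2)
    stop("contingency table must be square, k >= 2", call. = FALSE)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Percentage agreement
#'
#' The percentage of pairs where both sides selected the same response:
#' `100 * trace / n`.  Values above 70% are conventionally called high
#' (strictly greater).
#'
#' @param table a square contingency table ([tabulate_pairs()] output or
#'   any k x k count matrix, side A in rows).
#' @return numeric in `[0, 100]`, with attribute `high` (`TRUE` iff
#'   strictly above 70).
#' @examples
#' percent_agreement(matrix(c(1, 0, 1, 1), 2))  # 66.7%
#' @export
percent_agreement <- function(table) {
  m <- as_table(table)
  n <- sum(m)
  if (n < 1) stop("empty contingency table", call. = FALSE)
  pa <- 100 * sum(diag(m)) / n
  attr(pa, "high") <- pa > 70
  pa
}

# linear agreement weights w_ij = 1 - |i - j| / (k - 1); identity weights
# for unweighted kappa
linear_weights <- function(k) {
  idx <- seq_len(k)
  1 - abs(outer(idx, idx, "-")) / (k - 1)
}
identity_weights <- function(k) diag(k)

table_degeneracy <- function(m) {
  a_const <- sum(rowSums(m) > 0) < 2
  b_const <- sum(colSums(m) > 0) < 2
  if (a_const && b_const) "undefined_constant_both_sides"
  else if (a_const || b_const) "undefined_constant_one_side"
  else "ok"
}

# shared kappa machinery: point estimate, Fleiss-Cohen-Everitt asymptotic
# SE, null SE, one-sided p, Wald CI truncated to [-1, 1]
kappa_engine <- function(m, w, statistic) {
  n <- sum(m)
  if (n < 1) stop("empty contingency table", call. = FALSE)
  status <- table_degeneracy(m)
  if (status != "ok")
    return(agreement_result(statistic, NA_real_, n = n, status = status))
  p <- m / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (abs(1 - pe) < 1e-15)
    return(agreement_result(statistic, NA_real_, n = n,
                            status = "undefined"))
  kap <- (po - pe) / (1 - pe)
  # row/column expected weights
  wr <- as.vector(w %*% pc)        # wbar_{i.} = sum_j p_.j w_ij
  wc <- as.vector(t(w) %*% pr)     # wbar_{.j} = sum_i p_i. w_ij
  wsum <- outer(wr, wc, "+")
  v <- (sum(p * (w - wsum * (1 - kap))^2) -
          (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  v0 <- (sum(outer(pr, pc) * (w - wsum)^2) - pe^2) / (n * (1 - pe)^2)
  se0 <- sqrt(max(v0, 0))
  pval <- if (se0 > 0)
    stats::pnorm(kap / se0, lower.tail = FALSE) else NA_real_
  agreement_result(statistic, kap, se = se,
                   ci_low = max(kap - 1.96 * se, -1),
                   ci_high = min(kap + 1.96 * se, 1),
                   p_value = pval, n = n, status = "ok")
}

#' Cohen's kappa
#'
#' Chance-corrected agreement for nominal categories,
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed and `p_e` the
#' chance proportion of agreement.  The standard error uses the
#' Fleiss-Cohen-Everitt large-sample variance; the 95% CI is the Wald
#' interval truncated to `[-1, 1]`; the one-sided p-value tests
#' `kappa = 0` using the null-hypothesis SE.  When one (or both) side's
#' ratings are constant the estimate is undefined and only the status is
#' set — percentage agreement remains reportable.
#'
#' @inheritParams percent_agreement
#' @return an [agreement_result()].
#' @examples
#' cohens_kappa(matrix(c(20, 10, 5, 15), 2))  # kappa = 0.4
#' @export
cohens_kappa <- function(table) {
  m <- as_table(table)
  kappa_engine(m, identity_weights(nrow(m)), "kappa")
}

#' Linearly weighted kappa
#'
#' Kappa for ordinal categories with linear agreement weights
#' `w_ij = 1 - |i - j| / (k - 1)` (responses assumed equally spaced), so
#' near-miss disagreements receive partial credit.  Reduces exactly to
#' unweighted kappa for two categories.  Category order is taken from the
#' table's row/column order, which [tabulate_pairs()] sets to schema label
#' order.
#'
#' @inheritParams percent_agreement
#' @return an [agreement_result()].
#' @export
weighted_kappa <- function(table) {
  m <- as_table(table)
  kappa_engine(m, linear_weights(nrow(m)), "weighted_kappa")
}

#' Intraclass correlation from a units x raters score matrix
#'
#' Single-rater two-way random-effects ICC from the two-way ANOVA
#' decomposition (mean squares for rows/units `MSR`, columns/raters
#' `MSC`, residual `MSE`):
#' consistency `ICC(C,1) = (MSR - MSE) / (MSR + (c-1) MSE)`;
#' absolute agreement
#' `ICC(A,1) = (MSR - MSE) / (MSR + (c-1) MSE + (c/n)(MSC - MSE))`.
#' 95% confidence intervals use the exact F interval for consistency and
#' the McGraw-Wong Satterthwaite interval for absolute agreement; the
#' p-value is the one-sided F test of zero between-unit correlation
#' (`F = MSR / MSE`).  Rows with any missing value are dropped listwise
#' (count recorded as attribute `n_dropped`).
#'
#' @param scores numeric matrix, rows = units, columns = raters/passes
#'   (>= 2 of each after listwise deletion).
#' @param definition `"consistency"` (default) or `"agreement"`.
#' @return an [agreement_result()] with `statistic = "icc"`; zero
#'   between-row variance yields status `"undefined"`.
#' @export
icc <- function(scores, definition = c("consistency", "agreement")) {
  definition <- match.arg(definition)
  x <- as.matrix(scores)
  keep <- stats::complete.cases(x)
  dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (k < 2) stop("ICC needs at least 2 raters/passes", call. = FALSE)
  if (n < 2) stop("ICC needs at least 2 complete units", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (ssr < 1e-14 * max(sst, 1)) {
    res <- agreement_result("icc", NA_real_, n = n, status = "undefined")
    attr(res, "n_dropped") <- dropped
    return(res)
  }
  est <- if (definition == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fobs <- msr / mse
  pval <- stats::pf(fobs, df1, df2, lower.tail = FALSE)
  if (definition == "consistency") {
    fl <- fobs / stats::qf(0.975, df1, df2)
    fu <- fobs * stats::qf(0.975, df2, df1)
    ci_low <- (fl - 1) / (fl + k - 1)
    ci_high <- (fu - 1) / (fu + k - 1)
  } else {
    # McGraw & Wong interval with Satterthwaite degrees of freedom
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / df2)
    f1 <- stats::qf(0.975, df1, v)
    f2 <- stats::qf(0.975, v, df1)
    ci_low <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  }
  res <- agreement_result("icc", est, ci_low = ci_low, ci_high = ci_high,
                          p_value = pval, n = n, status = "ok")
  attr(res, "n_dropped") <- dropped
  attr(res, "mean_squares") <- c(MSR = msr, MSC = msc, MSE = mse)
  res
}

#' Landis-Koch interpretation of an agreement statistic
#'
#' Verbal bands for kappa-type statistics and ICCs: below 0.00 poor,
#' 0.00-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial, 0.81-1.00 almost perfect.  The printed band edges are
#' two-decimal and exhaustive after rounding, so values are rounded to
#' two decimals before banding (0.205 rounds to 0.2, slight).
#'
#' @param value numeric (vectorised), at most 1.
#' @return character vector of band labels (underscore style, e.g.
#'   `"almost_perfect"`).
#' @export
interpret_landis_koch <- function(value) {
  if (any(value > 1 + 1e-12, na.rm = TRUE))
    stop("agreement statistics cannot exceed 1", call. = FALSE)
  r <- round(value, 2)
  out <- ifelse(r < 0, "poor",
         ifelse(r <= 0.20, "slight",
         ifelse(r <= 0.40, "fair",
         ifelse(r <= 0.60, "moderate",
         ifelse(r <= 0.80, "substantial", "almost_perfect")))))
  out[is.na(value)] <- NA_character_
  out
}

format_p <- function(p) ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))
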