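# Between-subject statistics: the median +/- 3 SD outlier rule, the
# single-option block and >95% high-effort subject exclusions, Pearson
# correlations, Steiger's test for two dependent overlapping correlations,
# and the pairwise correlation heatmap with significance stars.

#' Outlier inclusion mask
#'
#' A subject enters an analysis only if, for every variable in that analysis,
#' their value is non-missing and within `k` standard deviations of that
#' variable's median. The SD is the sample SD of the full non-missing sample
#' (outlier candidates included) and the rule is applied per analysis, not
#' globally, which is why downstream Ns vary between analyses.
#'
#' @param data A data frame of subject-level measures.
#' @param vars Variables entering the analysis; defaults to all numeric
#'   columns.
#' @param k Number of SDs from the median beyond which a value is an outlier
#'   (default 3).
#' @return A logical inclusion mask, one entry per row of `data`.
#' @examples
#' d <- data.frame(x = c(1:10, 1000))
#' outlier_filter(d)   # excludes only the 1000
#' @export
outlier_filter <- function(data, vars = NULL, k = 3) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  stopifnot(length(vars) >= 1)
  mask <- rep(TRUE, nrow(data))
  for (v in vars) {
    x <- data[[v]]
    if (is.null(x)) stop("variable not found: ", v)
    nm <- !is.na(x)
    if (sum(nm) == 0) stop("variable is all-missing: ", v)
    if (sum(nm) < 4) stop("need at least 4 non-missing values for: ", v)
    s <- stats::sd(x[nm])
    m <- stats::median(x[nm])
    ok <- nm & (s == 0 | abs(x - m) <= k * s)
    ok[is.na(ok)] <- FALSE
    mask <- mask & ok
  }
  mask
}

#' Single-option block exclusion
#'
#' A block is excluded when the subject picked one option (either the high-
#' or the low-effort one) on strictly more than 94% of its trials; 94%
#' exactly is retained.
#'
#' @param records A choice-record data frame with `block_index` and `chosen`.
#' @return Integer vector of excluded block indices (possibly empty).
#' @export
block_exclusion <- function(records) {
  r <- records[!records$missed, , drop = FALSE]
  excluded <- integer(0)
  for (b in unique(r$block_index)) {
    ch <- r$chosen[r$block_index == b]
    if (max(mean(ch == "HE"), mean(ch == "LE")) > 0.94) {
      excluded <- c(excluded, b)
    }
  }
  excluded
}

#' Near-exclusive high-effort subject exclusion
#'
#' A subject is excluded when they chose the high-effort option on strictly
#' more than 95% of the trials of either task, pooling that task's blocks
#' (such subjects' preferences cannot be fitted). The rule is high-effort
#' specific, as stated: an all-low-effort subject is retained by this rule.
#'
#' @param choices A named list of per-subject choice-record tables.
#' @param threshold Exclusion threshold on the pooled high-effort proportion
#'   (default 0.95, strict inequality).
#' @return Character vector of excluded subject ids.
#' @export
subject_exclusion <- function(choices, threshold = 0.95) {
  excluded <- character(0)
  for (id in names(choices)) {
    rec <- choices[[id]]
    rec <- rec[!rec$missed, , drop = FALSE]
    for (dom in unique(rec$domain)) {
      he <- mean(rec$chosen[rec$domain == dom] == "HE")
      if (he > threshold) {
        excluded <- c(excluded, id)
        break
      }
    }
  }
  excluded
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#' @param variables Length-2 character vector naming the pair.
#' @return A list of class `correlation_result` with `r`, `p` (two-sided,
#'   t-distributed), `n` and `variables`.
#' @export
pearson <- function(x, y, variables = c("x", "y")) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("zero variance in one of the variables")
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 variables = variables),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%s, %s) = %.3f, p = %.4g, n = %d\n",
              x$variables[1], x$variables[2], x$r, x$p, x$n))
  invisible(x)
}

#' Steiger's test for two dependent overlapping correlations
#'
#' Compares `r12` and `r13` — two correlations sharing variable 1 and
#' measured on the same `n` subjects — with Steiger's (1980) modified Z: the
#' Fisher-z difference is scaled by the asymptotic covariance of the two
#' z-transforms, evaluated at the pooled correlation
#' `rbar = (r12 + r13) / 2`:
#' \deqn{Z = (z_{12} - z_{13}) \sqrt{(n-3) / (2 - 2 \bar s)},}
#' where `sbar = psi / (1 - rbar^2)^2` and
#' `psi = r23 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r23^2) / 2`.
#'
#' The alternative's direction must be supplied explicitly: `"greater"`
#' tests r12 > r13, `"less"` tests r12 < r13.
#'
#' @param r12,r13 The two correlations being compared (share variable 1).
#' @param r23 Correlation between the two non-shared variables.
#' @param n Number of subjects (> 3) on which all three correlations were
#'   computed.
#' @param tail One-tailed direction, `"greater"` or `"less"` (no default).
#' @return A list of class `steiger_result` with `z`, `p` (one-tailed), `n`,
#'   `r12`, `r13`, `r23`, `tail`.
#' @examples
#' steiger_test(0.5, 0.3, 0.2, n = 50, tail = "greater")
#' @export
steiger_test <- function(r12, r13, r23, n, tail) {
  if (missing(tail)) {
    stop("`tail` must be supplied explicitly (\"greater\" or \"less\")")
  }
  tail <- match.arg(tail, c("greater", "less"))
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must have |r| < 1")
  if (n <= 3) stop("n must exceed 3")
  R <- matrix(c(1, r12, r13,
                r12, 1, r23,
                r13, r23, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("the implied 3x3 correlation matrix is not positive semi-definite")
  }
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - rbar^2 * (1 - 2 * rbar^2 - r23^2) / 2
  sbar <- psi / (1 - rbar^2)^2
  z <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 - 2 * sbar))
  p <- if (tail == "greater") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    stats::pnorm(z)
  }
  structure(list(z = z, p = p, n = n, r12 = r12, r13 = r13, r23 = r23,
                 tail = tail),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger test (r12 = %.3f vs r13 = %.3f, r23 = %.3f, n = %d)\n",
              x$r12, x$r13, x$r23, x$n))
  cat(sprintf("  z = %.3f, one-tailed p (%s) = %.4g\n", x$z, x$tail, x$p))
  invisible(x)
}

#' Steiger's test with correlations recomputed on the common subset
#'
#' Printed correlation coefficients usually come from per-analysis subsets,
#' so a Steiger test fed printed r-values is not reproducible from them
#' alone. This entry point instead restricts the data to the subjects with
#' complete, non-outlier values on all three variables, recomputes the three
#' correlations there, and then applies [steiger_test()].
#'
#' @param data A data frame of subject-level measures.
#' @param shared Name of the variable shared by both correlations.
#' @param v1,v2 Names of the two variables compared against `shared`.
#' @param tail One-tailed direction, `"greater"` or `"less"` (no default).
#' @param k Outlier rule width in SDs (default 3); set `filter_outliers =
#'   FALSE` to skip the rule.
#' @param filter_outliers Apply [outlier_filter()] on the three variables
#'   before recomputing the correlations (default TRUE).
#' @return A `steiger_result` (see [steiger_test()]).
#' @export
steiger_from_data <- function(data, shared, v1, v2, tail, k = 3,
                              filter_outliers = TRUE) {
  d <- data[, c(shared, v1, v2)]
  keep <- stats::complete.cases(d)
  if (filter_outliers) keep <- keep & outlier_filter(d, k = k)
  d <- d[keep, , drop = FALSE]
  r12 <- stats::cor(d[[shared]], d[[v1]])
  r13 <- stats::cor(d[[shared]], d[[v2]])
  r23 <- stats::cor(d[[v1]], d[[v2]])
  steiger_test(r12, r13, r23, n = nrow(d), tail = tail)
}

#' Pairwise correlation table with significance stars
#'
#' Computes every pairwise Pearson correlation between `rows` and `cols`
#' variables, applying the per-analysis outlier rule to each pair
#' separately, and attaches significance stars at the conventional 0.05,
#' 0.01 and 0.001 thresholds.
#'
#' @param data A data frame of subject-level measures.
#' @param rows,cols Character vectors of variable names; `cols` defaults to
#'   `rows`.
#' @param k Outlier rule width in SDs (default 3).
#' @return A data frame of class `correlation_heatmap` with columns `var1`,
#'   `var2`, `r`, `p`, `n`, `stars`. `as.matrix()` returns the r matrix.
#' @export
correlation_heatmap <- function(data, rows, cols = rows, k = 3) {
  out <- expand.grid(var1 = rows, var2 = cols, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$r <- out$p <- NA_real_
  out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    v1 <- out$var1[i]
    v2 <- out$var2[i]
    if (v1 == v2) {
      keep <- !is.na(data[[v1]])
      out$r[i] <- 1
      out$p[i] <- 0
      out$n[i] <- sum(keep)
      next
    }
    keep <- outlier_filter(data, vars = c(v1, v2), k = k)
    res <- pearson(data[[v1]][keep], data[[v2]][keep], variables = c(v1, v2))
    out$r[i] <- res$r
    out$p[i] <- res$p
    out$n[i] <- res$n
  }
  out$stars <- as.character(cut(out$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                                labels = c("***", "**", "*", "")))
  class(out) <- c("correlation_heatmap", "data.frame")
  out
}

#' @export
as.matrix.correlation_heatmap <- function(x, ...) {
  rows <- unique(x$var1)
  cols <- unique(x$var2)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (i in seq_len(nrow(x))) m[x$var1[i], x$var2[i]] <- x$r[i]
  m
}
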