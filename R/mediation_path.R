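# Mediation with the joint-significance rule and the just-identified serial
# path model (estimated by sequential least squares, which is exact for a
# recursive model with no latent variables).

.standardise <- function(x) as.numeric(scale(x))

#' Simple mediation analysis
#'
#' Tests whether `m` statistically mediates the relation between `x` and `y`
#' on standardised complete cases: path `a` from `m ~ x`, paths `b` and `c'`
#' from `y ~ x + m`, and the total path `c` from `y ~ x`. The mediation
#' p-value is the joint-significance rule `max(p(a), p(b))`, and the verdict
#' is significant when that value is below `alpha` AND the direct path
#' shrinks in absolute value once the mediator is accounted for
#' (`|c'| < |c|`; absolute values, since mediated paths can be negative).
#'
#' On standardised complete data the decomposition `c = c' + a * b` holds
#' exactly.
#'
#' @param x,m,y Numeric vectors: independent variable, mediator, outcome.
#'   Incomplete cases are dropped (filter outliers upstream with
#'   [outlier_filter()]).
#' @param alpha Significance level for the joint rule (default 0.05).
#' @return An object of class `mediation_result`: standardised `a`, `b`,
#'   `c`, `c_prime` with p-values, `mediation_p`, `significant`, `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(100); m <- 0.6 * x + rnorm(100); y <- 0.6 * m + rnorm(100)
#' simple_mediation(x, m, y)
#' @export
simple_mediation <- function(x, m, y, alpha = 0.05) {
  cc <- stats::complete.cases(x, m, y)
  n <- sum(cc)
  if (n < 10) stop("need at least 10 complete cases")
  xs <- .standardise(x[cc])
  ms <- .standardise(m[cc])
  ys <- .standardise(y[cc])
  if (abs(stats::cor(xs, ms)) > 0.999) {
    stop("x and m are (nearly) collinear; mediation is not estimable")
  }
  fa <- summary(stats::lm(ms ~ xs))$coefficients
  fb <- summary(stats::lm(ys ~ xs + ms))$coefficients
  fc <- summary(stats::lm(ys ~ xs))$coefficients
  a <- fa["xs", 1]; p_a <- fa["xs", 4]
  c_prime <- fb["xs", 1]; p_c_prime <- fb["xs", 4]
  b <- fb["ms", 1]; p_b <- fb["ms", 4]
  cval <- fc["xs", 1]; p_c <- fc["xs", 4]
  mediation_p <- max(p_a, p_b)
  structure(list(
    a = a, b = b, c = cval, c_prime = c_prime,
    p_a = p_a, p_b = p_b, p_c = p_c, p_c_prime = p_c_prime,
    mediation_p = mediation_p,
    significant = mediation_p < alpha && abs(c_prime) < abs(cval),
    alpha = alpha, n = n
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  star <- function(p) if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  cat(sprintf("Mediation (n = %d)\n", x$n))
  cat(sprintf("  a  (X -> M)        = %+0.3f (p = %.4g)%s\n", x$a, x$p_a, star(x$p_a)))
  cat(sprintf("  b  (M -> Y | X)    = %+0.3f (p = %.4g)%s\n", x$b, x$p_b, star(x$p_b)))
  cat(sprintf("  c  (X -> Y)        = %+0.3f (p = %.4g)%s\n", x$c, x$p_c, star(x$p_c)))
  cat(sprintf("  c' (X -> Y | M)    = %+0.3f (p = %.4g)%s\n", x$c_prime,
              x$p_c_prime, star(x$p_c_prime)))
  cat(sprintf("  mediation p = max(p(a), p(b)) = %.4g -> %s\n", x$mediation_p,
              if (x$significant) "mediation" else "no mediation"))
  invisible(x)
}

#' Serial (recursive) path model
#'
#' Estimates the chain `X1 -> X2 -> X3 -> Y` as the just-identified
#' recursive system of regressions on standardised complete cases:
#' `X2 ~ X1`, `X3 ~ X1 + X2`, `Y ~ X1 + X2 + X3`. For such a model
#' sequential least squares coincides with maximum-likelihood SEM, so no
#' latent-variable machinery is needed. Explained variance is reported per
#' endogenous node.
#'
#' @param x1,x2,x3,y Numeric vectors along the chain (e.g. plasma lactate,
#'   dmPFC/dACC lactate, neural effort sensitivity, choice behaviour).
#' @param names Variable labels used in the output edges.
#' @return An object of class `path_model_result`: `edges` (data frame with
#'   `from`, `to`, `coef`, `p`), `r_squared` (named, per endogenous node),
#'   `n`.
#' @export
serial_path_model <- function(x1, x2, x3, y,
                              names = c("X1", "X2", "X3", "Y")) {
  stopifnot(length(names) == 4)
  cc <- stats::complete.cases(x1, x2, x3, y)
  n <- sum(cc)
  if (n < 10) stop("need at least 10 complete cases")
  Z <- vapply(list(x1[cc], x2[cc], x3[cc], y[cc]), .standardise, numeric(n))
  colnames(Z) <- names
  if (qr(Z)$rank < 4) stop("rank-deficient inputs; path model not estimable")
  d <- as.data.frame(Z)
  fits <- list(
    stats::lm(stats::reformulate(names[1], names[2]), data = d),
    stats::lm(stats::reformulate(names[1:2], names[3]), data = d),
    stats::lm(stats::reformulate(names[1:3], names[4]), data = d)
  )
  edges <- do.call(rbind, lapply(fits, function(f) {
    cf <- summary(f)$coefficients
    terms <- setdiff(rownames(cf), "(Intercept)")
    data.frame(from = terms,
               to = all.vars(stats::formula(f))[1],
               coef = cf[terms, 1], p = cf[terms, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  r2 <- vapply(fits, function(f) summary(f)$r.squared, numeric(1))
  names(r2) <- names[2:4]
  structure(list(edges = edges, r_squared = r2, n = n),
            class = "path_model_result")
}

#' @export
print.path_model_result <- function(x, ...) {
  cat(sprintf("Serial path model (n = %d)\n", x$n))
  e <- x$edges
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %s -> %s: %+0.3f (p = %.4g)\n",
                e$from[i], e$to[i], e$coef[i], e$p[i]))
  }
  cat("  R-squared:", paste(sprintf("%s %.3f", names(x$r_squared),
                                    x$r_squared), collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap confidence interval for the indirect effect
#'
#' Percentile CI for the indirect effect `a * b` over seeded case
#' resampling. Provided as a robustness companion to the joint-significance
#' rule of [simple_mediation()]; resamples that are degenerate (zero
#' variance or collinear x/m) are skipped and counted.
#'
#' @param x,m,y Numeric vectors as in [simple_mediation()].
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A list: `estimate` (a*b on the full sample), `ci` (two-sided
#'   percentile interval), `n_boot`, `n_skipped`, `n`.
#' @export
bootstrap_indirect <- function(x, m, y, n_boot = 2000, seed = NULL,
                               conf = 0.95) {
  stopifnot(n_boot >= 1000)
  cc <- stats::complete.cases(x, m, y)
  n <- sum(cc)
  if (n < 10) stop("need at least 10 complete cases")
  x <- x[cc]; m <- m[cc]; y <- y[cc]
  if (!is.null(seed)) withr::local_seed(seed)
  indirect <- function(xi, mi, yi) {
    sx <- stats::sd(xi); sm <- stats::sd(mi); sy <- stats::sd(yi)
    if (sx == 0 || sm == 0 || sy == 0) return(NA_real_)
    rxm <- stats::cor(xi, mi)
    if (abs(rxm) > 0.999) return(NA_real_)
    rmy <- stats::cor(mi, yi); rxy <- stats::cor(xi, yi)
    a <- rxm
    b <- (rmy - rxy * rxm) / (1 - rxm^2)
    a * b
  }
  ab <- vapply(seq_len(n_boot), function(i) {
    s <- sample.int(n, n, replace = TRUE)
    indirect(x[s], m[s], y[s])
  }, numeric(1))
  skipped <- sum(is.na(ab))
  alpha <- (1 - conf) / 2
  list(estimate = indirect(x, m, y),
       ci = unname(stats::quantile(ab, c(alpha, 1 - alpha), na.rm = TRUE)),
       n_boot = n_boot, n_skipped = skipped, n = n)
}
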