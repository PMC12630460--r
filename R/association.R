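#' Yeo-Johnson normalisation with maximum-likelihood power selection
#'
#' Applies the Yeo-Johnson power transformation — a Box-Cox variant defined
#' on the whole real line — with the power `lambda` chosen by maximising the
#' Gaussian profile log-likelihood over `[-5, 5]` (Brent's method via
#' [stats::optimize()]), then standardizes the result to mean 0 and SD 1.
#' The transform is strictly monotone for any `lambda`, so rank-based
#' statistics are unchanged by it. `NA` values are excluded from the fit and
#' re-inserted as `NA`.
#'
#' @param x Numeric vector with at least 3 finite values; a constant vector
#'   is an error (no normalising transform exists).
#' @param lambda Optional fixed power; when `NULL` (default) it is estimated.
#' @return A list of class `"yeo_johnson"`: `y` (transformed, standardized
#'   vector, same length as `x`), `lambda`, and the pre-standardization
#'   `mean` and `sd`.
#' @seealso [yj_transform()] for the raw transform at a given power.
#' @export
#' @examples
#' z <- yeo_johnson(rlnorm(100))
#' z$lambda
yeo_johnson <- function(x, lambda = NULL) {
  x <- as.numeric(x)
  ok <- is.finite(x)
  v <- x[ok]
  if (length(v) < 3L) stop("need at least 3 finite values")
  if (max(v) - min(v) == 0) stop("constant vector: no transform defined")
  if (is.null(lambda)) {
    # profile log-likelihood: -n/2 log sigma2_hat + (lambda-1) * Jacobian term
    jac <- sum(sign(v) * log(abs(v) + 1))
    n <- length(v)
    ll <- function(l) {
      y <- yj_transform(v, l)
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * jac
    }
    lambda <- optimize(ll, c(-5, 5), maximum = TRUE, tol = 1e-6)$maximum
  }
  y <- yj_transform(v, lambda)
  mu <- mean(y)
  s <- sd(y)
  out <- rep(NA_real_, length(x))
  out[ok] <- (y - mu) / s
  structure(list(y = out, lambda = lambda, mean = mu, sd = s),
            class = "yeo_johnson")
}

#' Yeo-Johnson transform at a fixed power
#'
#' For `x >= 0`: `((x+1)^lambda - 1)/lambda` (or `log(x+1)` at `lambda = 0`);
#' for `x < 0`: `-((1-x)^(2-lambda) - 1)/(2-lambda)` (or `-log(1-x)` at
#' `lambda = 2`).
#'
#' @param x Numeric vector.
#' @param lambda Power parameter.
#' @return Transformed vector (not standardized).
#' @export
yj_transform <- function(x, lambda) {
  pos <- !is.na(x) & x >= 0
  y <- x
  if (abs(lambda) > 1e-10) {
    y[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    y[pos] <- log(x[pos] + 1)
  }
  if (abs(lambda - 2) > 1e-10) {
    y[!pos & !is.na(x)] <- -((1 - x[!pos & !is.na(x)])^(2 - lambda) - 1) /
      (2 - lambda)
  } else {
    y[!pos & !is.na(x)] <- -log(1 - x[!pos & !is.na(x)])
  }
  y
}

# All permutations of 1..n as an n! x n matrix (n <= 9).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Computes rho as the Pearson correlation of midranks (average ranks for
#' ties). For fewer than 10 complete pairs the two-sided p-value is exact,
#' from full enumeration of all rank permutations (the null distribution of
#' rho given the observed tie pattern); for larger samples the usual
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom is used.
#'
#' @param x,y Paired numeric vectors. Pairs with a missing value in either
#'   are dropped; fewer than 3 complete pairs yields an all-`NA` result with
#'   a warning.
#' @return A list of class `"association"`: `rho`, `p`, `n` (complete pairs
#'   used), `method`.
#' @export
#' @examples
#' spearman_cor(1:3, c(9, 4, 1))  # rho = -1, exact p = 1/3
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    warning("fewer than 3 complete pairs; correlation undefined",
            call. = FALSE)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = "none"), class = "association"))
  }
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("a variable is constant on the complete pairs; correlation ",
            "undefined", call. = FALSE)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = "none"), class = "association"))
  }
  rho <- cor(rx, ry)
  if (n < 10L) {
    perms <- permutations_of(n)
    # one permutation per column; cor() against the matrix vectorizes
    rho_null <- as.vector(cor(rx, matrix(ry[t(perms)], nrow = n)))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p = min(p, 1), n = n, method = method),
            class = "association")
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("<association> rho = %.4f, p = %.4g, n = %d (%s)\n",
              x$rho, x$p, x$n, x$method))
  invisible(x)
}

#' Pairwise Spearman correlations among diversity metrics
#'
#' Computes rho, two-sided p and the per-pair sample size for every
#' unordered pair of the requested variables, with pairwise (not listwise)
#' deletion of missing values so that nulls in one metric (typically Pielou
#' J) do not shrink unrelated comparisons. A Holm-adjusted p-value column is
#' included for convenience; the raw p-values are the primary output.
#'
#' @param profiles Data frame of per-region metric values (e.g. from
#'   [compute_diversity_profiles()]); at least 10 rows.
#' @param variables Character vector of column names to correlate. Columns
#'   with fewer than 3 finite values are dropped with a warning.
#' @return Data frame with columns `var_a`, `var_b`, `rho`, `p`, `p_holm`,
#'   `n`, one row per unordered pair (`var_a` < `var_b` in `variables`
#'   order).
#' @seealso [as_cor_matrix()] to reshape into a symmetric matrix.
#' @export
correlation_matrix <- function(profiles,
                               variables = intersect(
                                 c("H", "Hbc", "G", "J", "FAD", "MFAD",
                                   "APWD", "PD", "SR", "PD_resid"),
                                 names(profiles))) {
  stopifnot(is.data.frame(profiles))
  if (nrow(profiles) < 10L)
    stop("need at least 10 profiles for the correlation analysis; got ",
         nrow(profiles))
  usable <- vapply(variables,
                   function(v) sum(is.finite(profiles[[v]])) >= 3L,
                   logical(1))
  if (any(!usable))
    warning("dropping variable(s) with fewer than 3 finite values: ",
            paste(variables[!usable], collapse = ", "), call. = FALSE)
  variables <- variables[usable]
  pairs <- which(upper.tri(diag(length(variables))), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- variables[pairs[k, 1L]]; b <- variables[pairs[k, 2L]]
    s <- suppressWarnings(spearman_cor(profiles[[a]], profiles[[b]]))
    data.frame(var_a = a, var_b = b, rho = s$rho, p = s$p, n = s$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out[, c("var_a", "var_b", "rho", "p", "p_holm", "n")]
}

#' Reshape a pairwise correlation table into a symmetric matrix
#'
#' @param cor_table Output of [correlation_matrix()].
#' @param value Which column to spread (default `"rho"`).
#' @return Symmetric numeric matrix with unit diagonal (for `rho`).
#' @export
as_cor_matrix <- function(cor_table, value = "rho") {
  vars <- unique(c(cor_table$var_a, cor_table$var_b))
  m <- matrix(if (value == "rho") 1 else NA_real_,
              length(vars), length(vars), dimnames = list(vars, vars))
  for (k in seq_len(nrow(cor_table))) {
    m[cor_table$var_a[k], cor_table$var_b[k]] <- cor_table[[value]][k]
    m[cor_table$var_b[k], cor_table$var_a[k]] <- cor_table[[value]][k]
  }
  m
}

#' Flag regions whose metric departs from its LOWESS trend on PD
#'
#' Fits a robust LOWESS curve of a diversity metric on phylogenetic
#' diversity (or any other predictor), converts the residuals to z-scores
#' with the sample (n-1) standard deviation, and flags regions lying more
#' than `k` SD above ("high": more chemically diverse than their PD
#' predicts) or below ("low") the trend.
#'
#' @param profiles Data frame with a `region` column plus the predictor and
#'   response columns; at least 10 complete rows.
#' @param y_var Response metric column name.
#' @param x_var Predictor column name (default `"PD"`).
#' @param k Flagging threshold in residual SD units (default 2).
#' @param frac,iters LOWESS parameters as in [sr_independent_pd()].
#' @return Data frame with columns `region`, `metric`, `residual`, `z`,
#'   `direction` — one row per flagged region (zero rows when none).
#' @export
flag_outliers <- function(profiles, y_var, x_var = "PD", k = 2,
                          frac = 2/3, iters = 3L) {
  stopifnot(is.data.frame(profiles), "region" %in% names(profiles))
  ok <- is.finite(profiles[[x_var]]) & is.finite(profiles[[y_var]])
  if (sum(ok) < 10L)
    stop("need at least 10 complete (", x_var, ", ", y_var,
         ") profiles; got ", sum(ok))
  x <- profiles[[x_var]][ok]; y <- profiles[[y_var]][ok]
  r <- y - lowess_fitted(x, y, frac, iters)
  s <- sd(r)
  if (!is.finite(s) || s <= 1e-12 * max(abs(y), 1)) {
    # residual spread is numerically zero: nothing departs from the trend
    return(data.frame(region = character(0), metric = character(0),
                      residual = numeric(0), z = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  z <- (r - mean(r)) / s
  flagged <- which(abs(z) > k)
  data.frame(region = profiles$region[ok][flagged],
             metric = rep(y_var, length(flagged)),
             residual = r[flagged],
             z = z[flagged],
             direction = ifelse(z[flagged] > 0, "high", "low"),
             stringsAsFactors = FALSE)
}
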