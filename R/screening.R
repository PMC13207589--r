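#' Pairwise Pearson correlation screen
#'
#' Product-moment correlations between covariates with two-sided p-values
#' from the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom.  Used to screen a block of bioclimatic variables
#' (temperature `bio1..bio11` or precipitation `bio12..bio19`) for
#' collinearity before co-kriging auxiliary selection.
#'
#' @param records Site table (any data frame holding the variables).
#' @param vars Character vector of column names (>= 2).
#' @return A `correlation_screen` object: `variables`, symmetric `r_matrix`
#'   with unit diagonal, `p_matrix` (diagonal `NA`), and `n`.
#' @examples
#' d <- data.frame(a = 1:4, b = c(1, 3, 2, 4))
#' pearson_matrix(d, c("a", "b"))$r_matrix["a", "b"]  # 0.8
#' @export
pearson_matrix <- function(records, vars) {
  stopifnot(length(vars) >= 2)
  x <- as.matrix(as.data.frame(records)[, vars, drop = FALSE])
  n <- nrow(x)
  if (n < 3) stop("need at least 3 sites for a correlation screen")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance variable(s): ",
         paste(vars[v == 0], collapse = ", "))
  }
  r <- stats::cor(x)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 0  # |r| = 1
  diag(p) <- NA_real_
  structure(list(variables = vars, r_matrix = r, p_matrix = p, n = n),
            class = "correlation_screen")
}

#' Collinearity-based selection within a covariate block
#'
#' Applies the block-screening rule: a variable *passes* when it has no
#' significant correlation (two-sided, level `alpha`) with any other
#' variable of its block; the *representative* of the block is the variable
#' with the largest count of significant correlations (the "highest
#' correlation" variable), ties broken by largest mean absolute correlation
#' with the rest of the block, then by name order (logged).  The variable
#' with the smallest count is also reported as `least_collinear`.
#'
#' @param screen A `correlation_screen` from [pearson_matrix()], or a list
#'   with `variables`, `r_matrix`, `p_matrix`.
#' @param alpha Significance level (default 0.05).
#' @return List: `passing`, `representative`, `least_collinear`,
#'   `sig_counts`, `alpha`.
#' @export
select_by_collinearity <- function(screen, alpha = 0.05) {
  vars <- screen$variables
  if (length(vars) == 0) stop("empty variable block")
  p <- screen$p_matrix
  r <- screen$r_matrix
  sig <- !is.na(p) & p < alpha
  counts <- rowSums(sig)
  mean_abs_r <- vapply(seq_along(vars), function(i) {
    mean(abs(r[i, -i]))
  }, 0)
  ord <- order(-counts, -mean_abs_r, vars)
  top <- counts == max(counts)
  if (sum(top) > 1) {
    iso_log("info",
            "representative tie among {%s}; broken by mean |r| then name",
            paste(vars[top], collapse = ", "))
  }
  list(
    passing = vars[counts == 0],
    representative = vars[ord[1]],
    least_collinear = vars[order(counts, mean_abs_r, vars)[1]],
    sig_counts = stats::setNames(counts, vars),
    alpha = alpha
  )
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, with `R2_j` the coefficient of determination of
#' variable `j` regressed (OLS with intercept) on all other listed
#' variables.  VIF <= 10 is conventionally read as absence of collinearity.
#' Perfectly collinear variables get `Inf` rather than an error.
#'
#' @inheritParams pearson_matrix
#' @return Named numeric vector of VIFs (>= 1, possibly `Inf`).
#' @export
vif_table <- function(records, vars) {
  x <- as.data.frame(records)[, vars, drop = FALSE]
  n <- nrow(x)
  if (n <= length(vars)) {
    stop("need more sites (", n, ") than variables (", length(vars), ")")
  }
  out <- vapply(seq_along(vars), function(j) {
    fit <- stats::lm(x[[j]] ~ ., data = x[, -j, drop = FALSE])
    # a perfect fit is expected under exact collinearity; reported as Inf
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  if (any(!is.finite(out))) {
    iso_log("warn", "perfect collinearity: VIF infinite for %s",
            paste(vars[!is.finite(out)], collapse = ", "))
  }
  stats::setNames(out, vars)
}

#' Correlation of covariates with the isotope target
#'
#' Pearson r of each candidate covariate with the site-mean delta-13C,
#' together with the adjusted R-squared of the simple regression, the
#' two-sided p-value, a significance flag at `alpha`, and the auxiliary
#' shortlist ranked by |r| among significant variables.  Adjusted (not
#' plain) R-squared is reported because with small n it can go negative,
#' which is informative about useless covariates.
#'
#' @inheritParams pearson_matrix
#' @param target Column name of the response (default `"d13c_mean"`).
#' @param alpha Significance level (default 0.05).
#' @param shortlist_n Max length of the auxiliary shortlist (default 4).
#' @return A `target_correlation` data frame (one row per variable) with
#'   attribute `shortlist`.
#' @export
correlate_with_target <- function(records, vars, target = "d13c_mean",
                                  alpha = 0.05, shortlist_n = 4L) {
  df <- as.data.frame(records)
  y <- df[[target]]
  n <- length(y)
  if (n < 3) stop("need at least 3 sites")
  if (stats::var(y) == 0) stop("zero-variance target: ", target)
  rows <- lapply(vars, function(v) {
    x <- df[[v]]
    if (stats::var(x) == 0) stop("zero-variance variable(s): ", v)
    r <- stats::cor(x, y)
    r2 <- r^2
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    tstat <- r * sqrt(n - 2) / sqrt(max(1 - r2, 0))
    p <- if (is.finite(tstat)) {
      2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    } else 0
    data.frame(variable = v, r = r, adj_r2 = adj_r2, p = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sig <- out[out$significant, ]
  shortlist <- sig$variable[order(-abs(sig$r))]
  shortlist <- utils::head(shortlist, shortlist_n)
  attr(out, "shortlist") <- shortlist
  attr(out, "alpha") <- alpha
  class(out) <- c("target_correlation", "data.frame")
  out
}
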