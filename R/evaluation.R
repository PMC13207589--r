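#' Cross-validation metric quartet
#'
#' The four leave-one-out summary metrics, from fold errors `e_i =
#' predicted_i - observed_i` and fold kriging standard errors `sigma_i`:
#' RMSE `sqrt(mean(e^2))`, mean standardized error `mean(e/sigma)`, root
#' mean square standardized error `sqrt(mean((e/sigma)^2))`, and average
#' standard error `mean(sigma)`.  RMSSE near 1 indicates well-calibrated
#' prediction uncertainty; above 1 the prediction variability is
#' underestimated, below 1 overestimated.
#'
#' @param errors Fold errors (predicted minus observed).
#' @param sigmas Fold kriging standard errors (> 0).
#' @return Named list `rmse`, `mean_se`, `rmsse`, `ase`, and
#'   `calibration_flag` (`"underestimated"`, `"overestimated"` or
#'   `"calibrated"` at RMSSE exactly 1).
#' @examples
#' cv_metrics(c(1, -1), c(2, 2))  # rmse 1, mean_se 0, rmsse 0.5, ase 2
#' @export
cv_metrics <- function(errors, sigmas) {
  stopifnot(length(errors) == length(sigmas), all(sigmas > 0))
  std <- errors / sigmas
  rmsse <- sqrt(mean(std^2))
  list(
    rmse = sqrt(mean(errors^2)),
    mean_se = mean(std),
    rmsse = rmsse,
    ase = mean(sigmas),
    calibration_flag = if (rmsse > 1) "underestimated"
                       else if (rmsse < 1) "overestimated" else "calibrated"
  )
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Predicts each site from the remaining `n - 1` sites and summarizes the
#' fold errors with [cv_metrics()].  By default the (co)variogram model is
#' held fixed across folds (only the kriging system is re-solved, matching
#' standard GIS cross-validation); `refit = "per_fold"` refits the
#' semivariogram from the reduced data in every fold.  For co-kriging the
#' auxiliary value at the held-out site is kept by default (climate
#' auxiliaries are known everywhere, including at a validation location);
#' `drop_aux = TRUE` removes the whole site instead.
#'
#' @inheritParams ordinary_krige
#' @param model A [variogram_model()] or [lmc_model()].
#' @param aux_values Auxiliary values at the sites (co-kriging only).
#' @param refit `"fixed"` (default) or `"per_fold"`.
#' @param drop_aux Drop the auxiliary datum of the held-out site too
#'   (default `FALSE`).
#' @param label Model label for reports (default from the model).
#' @param ... Passed to [fit_semivariogram()] when `refit = "per_fold"`.
#' @return A `cv_report` list: `model_label`, `observed`, `predicted`,
#'   `std_error`, `n_folds`, `n_failed`, and the four metrics.
#' @export
krige_loocv <- function(coords, values, model, aux_values = NULL,
                        refit = c("fixed", "per_fold"), drop_aux = FALSE,
                        method = c("haversine", "euclidean"),
                        label = NULL, ...) {
  refit <- match.arg(refit)
  method <- match.arg(method)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4) stop("need at least 4 sites for leave-one-out")
  is_ck <- inherits(model, "lmc_model")
  if (is_ck && is.null(aux_values)) stop("co-kriging needs aux_values")
  if (is.null(label)) {
    label <- if (is_ck) paste0("cokriging_", model$family) else model$family
  }
  pred <- se <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mod_i <- model
    if (refit == "per_fold" && !is_ck) {
      emp <- empirical_semivariogram(coords[tr, , drop = FALSE], values[tr],
                                     method = method)
      mod_i <- tryCatch(fit_semivariogram(emp, model$family, ...),
                        error = function(e) model)
    }
    res <- tryCatch({
      if (is_ck) {
        if (drop_aux) {
          ordinary_cokrige(coords[tr, , drop = FALSE], values[tr],
                           aux_values[tr], mod_i, coords[i, ],
                           method = method)
        } else {
          ordinary_cokrige(coords[tr, , drop = FALSE], values[tr],
                           aux_values, mod_i, coords[i, ],
                           aux_coords = coords, method = method)
        }
      } else {
        ordinary_krige(coords[tr, , drop = FALSE], values[tr], mod_i,
                       coords[i, ], method = method)
      }
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    pred[i] <- res$value
    se[i] <- res$std_error
  }
  if (failed > 0) {
    iso_log("warn", "%d LOOCV fold(s) failed (singular system); metrics on %d folds",
            failed, n - failed)
  }
  ok <- !is.na(pred) & se > 0
  if (!any(ok)) stop("all LOOCV folds failed")
  met <- cv_metrics(pred[ok] - values[ok], se[ok])
  structure(c(list(model_label = label, observed = values,
                   predicted = pred, std_error = se, n_folds = n,
                   n_failed = failed), met),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "LOOCV %s (n = %d): RMSE %.4f  MeanSE %.4f  RMSSE %.4f  ASE %.4f [%s]\n",
    x$model_label, x$n_folds, x$rmse, x$mean_se, x$rmsse, x$ase,
    x$calibration_flag))
  invisible(x)
}

#' Rank cross-validated models
#'
#' Lexicographic ranking of candidate models by their LOOCV metrics:
#' (1) lowest RMSE; ties by (2) smallest `|RMSSE - 1|`, (3) smallest
#' `|MeanSE|`, (4) smallest `|ASE - RMSE|`; residual ties broken by model
#' name order and logged.  Returns the full score table so the choice is
#' auditable.
#'
#' @param reports List of `cv_report` objects, or a data frame with columns
#'   `model`, `rmse`, `mean_se`, `rmsse`, `ase`.
#' @return List: `table` (data frame sorted by rank), `selected` (best
#'   model's label).
#' @export
rank_models <- function(reports) {
  if (is.data.frame(reports)) {
    tab <- reports
    names(tab) <- tolower(names(tab))
    stopifnot(all(c("model", "rmse", "mean_se", "rmsse", "ase") %in%
                    names(tab)))
  } else {
    if (length(reports) == 0) stop("no models to rank")
    tab <- do.call(rbind, lapply(reports, function(r) {
      data.frame(model = r$model_label, rmse = r$rmse, mean_se = r$mean_se,
                 rmsse = r$rmsse, ase = r$ase, stringsAsFactors = FALSE)
    }))
  }
  if (nrow(tab) == 0) stop("no models to rank")
  ord <- order(tab$rmse, abs(tab$rmsse - 1), abs(tab$mean_se),
               abs(tab$ase - tab$rmse), tab$model)
  tab <- tab[ord, , drop = FALSE]
  dup <- duplicated(tab[, c("rmse", "rmsse", "mean_se", "ase")]) |
    duplicated(tab[, c("rmse", "rmsse", "mean_se", "ase")], fromLast = TRUE)
  if (any(dup)) {
    iso_log("info", "metric tie among {%s}; broken by model name order",
            paste(tab$model[dup], collapse = ", "))
  }
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(table = tab, selected = tab$model[1])
}

#' Exploratory spatial data analysis products
#'
#' From a LOOCV report: the least-squares line of predicted on observed
#' values (slope 1 / intercept 0 indicate agreement with the 1:1 line) and
#' the normal Q-Q pairing of the sorted standardized errors against
#' standard-normal quantiles at plotting positions `(k - 0.5) / n`.
#'
#' @param report A `cv_report`.
#' @return List: `slope`, `intercept`, `qq` (data frame `theoretical`,
#'   `standardized_error`, both ascending).
#' @export
esda_products <- function(report) {
  ok <- !is.na(report$predicted) & report$std_error > 0
  obs <- report$observed[ok]
  pred <- report$predicted[ok]
  n <- length(obs)
  if (n < 3) stop("need at least 3 folds")
  if (stats::var(obs) == 0) stop("degenerate (constant) observations")
  b <- stats::cov(obs, pred) / stats::var(obs)
  a <- mean(pred) - b * mean(obs)
  std <- sort((pred - obs) / report$std_error[ok])
  qq <- data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
                   standardized_error = std)
  list(slope = b, intercept = a, qq = qq)
}

#' Cross-validate the whole model catalog
#'
#' Fits each candidate family to the empirical (cross-)semivariograms of the
#' site data, runs fixed-model LOOCV for each, and returns a table shaped
#' like a published model-comparison table (model, RMSE, MeanSE, RMSSE, ASE)
#' together with the [rank_models()] selection.  With `aux` the catalog is
#' cross-validated as co-kriging under a fitted LMC per family; without it,
#' ordinary kriging.
#'
#' @param sites Validated site table ([read_site_table()]).
#' @param aux Auxiliary covariate column name (e.g. `"bio15"`), or `NULL`
#'   for ordinary kriging.
#' @param families Candidate families (default all 11).
#' @param n_lags,cutoff Lag binning for the empirical variograms.
#' @param method Distance metric.
#' @param seed Seed for the fitting starts.
#' @return List: `table`, `selected`, `reports` (named list of `cv_report`),
#'   `models` (named list of fitted models).
#' @export
cv_model_catalog <- function(sites, aux = NULL,
                             families = variogram_families(),
                             n_lags = 12, cutoff = NULL,
                             method = c("haversine", "euclidean"),
                             seed = 20240457) {
  method <- match.arg(method)
  sites <- validate_site_table(sites)
  coords <- as.matrix(sites[, c("lon", "lat")])
  z <- sites$d13c_mean
  reports <- list()
  models <- list()
  emp11 <- empirical_semivariogram(coords, z, n_lags = n_lags,
                                   cutoff = cutoff, method = method)
  if (!is.null(aux)) {
    x <- sites[[aux]]
    emp22 <- empirical_semivariogram(coords, x, n_lags = n_lags,
                                     cutoff = cutoff, method = method)
    emp12 <- empirical_cross_semivariogram(coords, z, x, n_lags = n_lags,
                                           cutoff = cutoff, method = method)
  }
  for (fam in families) {
    fit <- tryCatch({
      if (is.null(aux)) {
        fit_semivariogram(emp11, fam, seed = seed)
      } else {
        fit_lmc(emp11, emp22, emp12, fam)
      }
    }, error = function(e) {
      iso_log("warn", "family %s: fit failed (%s); skipped", fam,
              conditionMessage(e))
      NULL
    })
    if (is.null(fit)) next
    rep <- tryCatch(
      krige_loocv(coords, z, fit,
                  aux_values = if (is.null(aux)) NULL else sites[[aux]],
                  method = method, label = fam),
      error = function(e) {
        iso_log("warn", "family %s: LOOCV failed (%s); skipped", fam,
                conditionMessage(e))
        NULL
      })
    if (is.null(rep)) next
    models[[fam]] <- fit
    reports[[fam]] <- rep
  }
  if (length(reports) == 0) stop("no family could be cross-validated")
  rk <- rank_models(reports)
  list(table = rk$table, selected = rk$selected, reports = reports,
       models = models)
}
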