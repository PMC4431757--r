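# Covariate sets of the five model specifications.  Sex and age are always
# present; women are coded 1, men 0.
MODEL_COVARIATES <- list(
  M1 = c("sex_woman", "age", "energy_expenditure_mets_h", "energy_intake_kcal"),
  M2 = c("sex_woman", "age", "efficiency"),
  M3 = c("sex_woman", "age", "gps"),
  M4 = c("sex_woman", "age", "energy_expenditure_mets_h",
         "energy_intake_kcal", "gps"),
  M5 = c("sex_woman", "age", "gps", "efficiency")
)

#' Specify one of the five obesity-risk regression models
#'
#' Model 1 uses the environment variables (expenditure, intake); Model 2
#' the DEA efficiency score; Model 3 the genetic predisposition score;
#' Model 4 environment plus genetics; Model 5 genetics plus efficiency.
#' Every model adjusts for age and sex (women vs men).
#'
#' @param model_id one of \code{"M1".."M5"}.
#' @param dependent \code{"bmi_baseline"} or \code{"yearly_bmi_change"}.
#' @return list of class \code{"model_spec"} with \code{model_id},
#'   \code{dependent}, \code{covariates}.
#' @export
model_spec <- function(model_id = c("M1", "M2", "M3", "M4", "M5"),
                       dependent = c("bmi_baseline", "yearly_bmi_change")) {
  model_id <- match.arg(model_id)
  dependent <- match.arg(dependent)
  structure(list(model_id = model_id, dependent = dependent,
                 covariates = MODEL_COVARIATES[[model_id]]),
            class = "model_spec")
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y equal-length finite numeric vectors, n >= 3, each with
#'   nonzero variance.
#' @param pair optional character(2) labels for the variable pair.
#' @return list of class \code{"correlation_result"}: \code{pair}, \code{r},
#'   \code{p}, \code{n}.
#' @export
pearson_correlation <- function(x, y, pair = c(deparse(substitute(x)),
                                               deparse(substitute(y)))) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(pair = pair, r = unname(ct$estimate), p = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%s, %s) = %.3f, p = %.3g, n = %d\n",
              x$pair[1L], x$pair[2L], x$r, x$p, x$n))
  invisible(x)
}

# assemble the analysis frame for one model spec; listwise deletion
model_frame <- function(spec, cohort) {
  cohort$sex_woman <- as.numeric(cohort$sex == "woman")
  y <- switch(spec$dependent,
              bmi_baseline = cohort$bmi_baseline,
              yearly_bmi_change = yearly_bmi_change(cohort))
  need <- spec$covariates
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort lacks covariate column(s): ", paste(miss, collapse = ", "))
  }
  d <- cbind(data.frame(.y = y), cohort[need])
  d[stats::complete.cases(d), , drop = FALSE]
}

#' Fit one obesity-risk regression model
#'
#' The production estimator is an MM-type robust linear regression
#' (bisquare psi, 95\% asymptotic efficiency, high-breakdown S-estimate
#' start via resampling), reporting each covariate's partial coefficient
#' with its robust (asymptotic) standard error and a normal-approximation
#' p-value.  \code{method = "ols"} fits ordinary least squares instead and
#' is the oracle mode used in verification tests.
#'
#' The reported R2 in MM mode is the weighted coefficient of determination
#' computed with the final IRWLS weights, adjusted by the classical
#' \eqn{(n-1)/(n-p-1)} factor; in OLS mode it is the classical (adjusted)
#' R2.  Rows with any missing variable are dropped (listwise deletion).
#'
#' @param spec a [model_spec()].
#' @param cohort cohort data frame holding the model's covariates (and
#'   follow-up columns when the dependent is the yearly BMI change).
#' @param method \code{"mm"} (robust, default) or \code{"ols"}.
#' @return list of class \code{"regression_fit"}: \code{model_id},
#'   \code{dependent}, \code{coefficients} (data frame with term, estimate,
#'   se, p), \code{r2}, \code{adj_r2}, \code{n}, \code{method}.
#' @export
fit_model <- function(spec, cohort, method = c("mm", "ols")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "model_spec"))
  d <- model_frame(spec, cohort)
  p <- length(spec$covariates)
  if (nrow(d) < p + 2L) {
    stop("model ", spec$model_id, ": only ", nrow(d),
         " complete rows for ", p, " covariates")
  }
  mm <- stats::model.matrix(~ ., data = d[-1L])
  qrX <- qr(mm)
  if (qrX$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrX$pivot[(qrX$rank + 1L):ncol(mm)]]
    stop("rank-deficient design in ", spec$model_id, "; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  if (method == "ols") {
    fit <- stats::lm(.y ~ ., data = d)
    sm <- summary(fit)
    co <- sm$coefficients
    tab <- data.frame(term = rownames(co), estimate = co[, 1L],
                      se = co[, 2L], p = co[, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
    r2 <- sm$r.squared
    adj <- sm$adj.r.squared
  } else {
    # degenerate case: an (essentially) exact linear fit has zero residual
    # scale, where the MM loss is undefined; the interpolant is the unique
    # robust solution, so report the least-squares coefficients.
    ls0 <- stats::lm(.y ~ ., data = d)
    if (stats::sigma(ls0) < 1e-8 * max(stats::sd(d$.y), 1)) {
      co <- suppressWarnings(summary(ls0))$coefficients
      tab <- data.frame(term = rownames(co), estimate = co[, 1L],
                        se = co[, 2L], p = co[, 4L], row.names = NULL,
                        stringsAsFactors = FALSE)
      tab$term[tab$term == "(Intercept)"] <- "intercept"
      return(structure(list(model_id = spec$model_id,
                            dependent = spec$dependent,
                            coefficients = tab, r2 = 1, adj_r2 = 1,
                            n = nrow(d), method = method),
                       class = "regression_fit"))
    }
    fit <- MASS::rlm(.y ~ ., data = d, method = "MM",
                     psi = MASS::psi.bisquare, maxit = 100L)
    if (!fit$converged) {
      stop("MM estimator failed to converge for ", spec$model_id)
    }
    co <- summary(fit)$coefficients  # Value, Std. Error, t value
    tab <- data.frame(term = rownames(co), estimate = co[, 1L],
                      se = co[, 2L],
                      p = 2 * stats::pnorm(-abs(co[, 3L])),
                      row.names = NULL, stringsAsFactors = FALSE)
    w <- fit$w
    ybar <- sum(w * d$.y) / sum(w)
    r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (d$.y - ybar)^2)
    adj <- 1 - (1 - r2) * (nrow(d) - 1) / (nrow(d) - ncol(mm))
  }
  tab$term[tab$term == "(Intercept)"] <- "intercept"
  structure(list(model_id = spec$model_id, dependent = spec$dependent,
                 coefficients = tab, r2 = r2, adj_r2 = adj,
                 n = nrow(d), method = method),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s (%s, %s): n = %d, adjusted R2 = %.4f\n",
              x$model_id, x$dependent, x$method, x$n, x$adj_r2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Compare the five regression models on a cohort
#'
#' Fits Models 1-5 on the same dependent variable.  For the yearly BMI
#' change the analysis set is restricted first: subjects with a normal
#' baseline BMI and available follow-up ([change_analysis_filter()]).
#'
#' @inheritParams fit_model
#' @param dependent \code{"bmi_baseline"} or \code{"yearly_bmi_change"}.
#' @return list of class \code{"model_comparison"}: \code{fits} (list of
#'   five [fit_model()] results) and \code{table} (stacked coefficient
#'   table with model_id, adj_r2, n).
#' @export
model_comparison <- function(cohort, dependent = c("bmi_baseline",
                                                   "yearly_bmi_change"),
                             method = c("mm", "ols")) {
  dependent <- match.arg(dependent)
  method <- match.arg(method)
  if (dependent == "yearly_bmi_change") cohort <- change_analysis_filter(cohort)
  fits <- lapply(names(MODEL_COVARIATES), function(m) {
    fit_model(model_spec(m, dependent), cohort, method)
  })
  names(fits) <- names(MODEL_COVARIATES)
  tab <- do.call(rbind, lapply(fits, function(f) {
    cbind(model_id = f$model_id, f$coefficients,
          adj_r2 = f$adj_r2, n = f$n, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab, dependent = dependent,
                 method = method),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (", x$dependent, ", ", x$method, "):\n", sep = "")
  r2 <- vapply(x$fits, function(f) f$adj_r2, numeric(1L))
  print(round(r2, 4))
  invisible(x)
}

#' Model-5 fits within age strata
#'
#' Fits the genetics + efficiency model separately below and at/above the
#' age cutoff.
#'
#' @inheritParams fit_model
#' @param cutoff age threshold in years (default 60).
#' @param dependent dependent variable, as in [model_spec()].
#' @return named list with elements \code{younger} (age < cutoff) and
#'   \code{older} (age >= cutoff), each a [fit_model()] result.
#' @export
age_subgroup_fits <- function(cohort, cutoff = 60,
                              dependent = c("bmi_baseline",
                                            "yearly_bmi_change"),
                              method = c("mm", "ols")) {
  dependent <- match.arg(dependent)
  method <- match.arg(method)
  lt <- cohort[cohort$age < cutoff, , drop = FALSE]
  ge <- cohort[cohort$age >= cutoff, , drop = FALSE]
  if (nrow(lt) == 0L || nrow(ge) == 0L) {
    stop("age cutoff ", cutoff, " leaves an empty stratum (ages ",
         min(cohort$age), "-", max(cohort$age), ")")
  }
  list(younger = fit_model(model_spec("M5", dependent), lt, method),
       older   = fit_model(model_spec("M5", dependent), ge, method))
}

#' Mean DEA inputs by efficiency-score quartile
#'
#' Ranks subjects by efficiency score (stable tie-break on subject id),
#' splits them into four groups of near-equal size (sizes differ by at most
#' one), and reports each group's mean expenditure and mean inverse intake.
#'
#' @param cohort cohort data frame with an \code{efficiency} column.
#' @return data frame with one row per quartile: \code{quartile}, \code{n},
#'   \code{mean_efficiency}, \code{mean_expenditure},
#'   \code{mean_inverse_intake}.
#' @export
quartile_summary <- function(cohort) {
  if (is.null(cohort$efficiency)) stop("cohort lacks an efficiency column")
  n <- nrow(cohort)
  if (n < 4L) stop("need at least 4 subjects for quartiles")
  ord <- order(cohort$efficiency, cohort$subject_id)
  q <- integer(n)
  q[ord] <- ceiling(seq_len(n) * 4 / n)
  out <- do.call(rbind, lapply(1:4, function(k) {
    g <- cohort[q == k, , drop = FALSE]
    data.frame(quartile = k, n = nrow(g),
               mean_efficiency = mean(g$efficiency),
               mean_expenditure = mean(g$energy_expenditure_mets_h),
               mean_inverse_intake = mean(1 / g$energy_intake_kcal))
  }))
  rownames(out) <- NULL
  out
}
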