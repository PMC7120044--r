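#' Kaplan--Meier survival curve
#'
#' Product-limit estimate of the survival function under right censoring
#' (via `survival::survfit`). The curve starts at 1 and is a
#' non-increasing right-continuous step function.
#'
#' @param times Positive follow-up times (days).
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @return A data frame of class `"km_curve"` with columns `time`,
#'   `n_risk`, `n_event` and `surv`, one row per distinct observed time.
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
km_curve <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (any(!is.finite(times)) || any(times <= 0))
    stop("follow-up times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survfit(Surv(times, events) ~ 1)
  res <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(res) <- c("km_curve", "data.frame")
  res
}

#' @export
plot.km_curve <- function(x, xlab = "time (days)",
                          ylab = "survival probability", ...) {
  plot(c(0, x$time), c(1, x$surv), type = "s", ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  cens <- x$n_event == 0
  if (any(cens))
    points(x$time[cens], x$surv[cens], pch = 3, cex = 0.7)
  invisible(x)
}

#' Median-split log-rank screen for one feature
#'
#' Splits the cohort at the feature's median expression (values strictly
#' greater than the median form the high group; ties go to the low group,
#' so splits are reproducible) and compares the two survival distributions
#' with a two-sample log-rank test (1-df chi-square).
#'
#' @param expr Named numeric vector of one feature's expression, names =
#'   sample ids covering the clinical table.
#' @param clinical A [clinical_table()] (cohort >= 4, >= 1 event).
#' @param feature_id Optional id recorded in the result.
#' @return An object of class `"surv_screen"`: list with `feature_id`,
#'   `statistic`, `p`, `n_high`, `n_low`.
#' @export
median_split_logrank <- function(expr, clinical, feature_id = NA_character_) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (nrow(clinical) < 4L) stop("cohort must have at least 4 samples")
  if (sum(clinical$event) < 1L) stop("no events observed")
  if (!is.null(names(expr))) {
    missing <- setdiff(clinical$sample_id, names(expr))
    if (length(missing))
      stop("expression missing for samples: ",
           paste(head(missing, 5L), collapse = ", "))
    expr <- expr[clinical$sample_id]
  } else if (length(expr) != nrow(clinical))
    stop("unnamed expression vector must match the clinical table length")
  grp <- factor(ifelse(expr > median(expr), "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) == 0L))
    stop("median split left one group empty (constant expression?)")
  sd <- survdiff(Surv(clinical$time, clinical$event) ~ grp)
  structure(list(feature_id = feature_id,
                 statistic = unname(sd$chisq),
                 p = pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
                 n_high = sum(grp == "high"), n_low = sum(grp == "low")),
            class = "surv_screen")
}

#' @export
print.surv_screen <- function(x, ...) {
  cat(sprintf(
    "median-split log-rank%s: chi-square = %.3f, p = %.4g (high n=%d, low n=%d)\n",
    if (is.na(x$feature_id)) "" else paste0(" [", x$feature_id, "]"),
    x$statistic, x$p, x$n_high, x$n_low))
  invisible(x)
}

#' Median-split log-rank screen across features
#'
#' Runs [median_split_logrank()] for each requested feature of an
#' expression matrix against a clinical table.
#'
#' @param em An [expression_matrix()] whose samples cover the clinical
#'   table.
#' @param clinical A [clinical_table()].
#' @param features Feature ids to screen (default: all rows).
#' @return Data frame with `feature_id`, `logrank_statistic`, `logrank_p`,
#'   `high_group_n`, `low_group_n`, sorted by p-value.
#' @export
survival_screen <- function(em, clinical, features = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (is.null(features)) features <- rownames(em$values)
  missing <- setdiff(features, rownames(em$values))
  if (length(missing))
    stop("features not in expression matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  rows <- lapply(features, function(f) {
    s <- median_split_logrank(em$values[f, ], clinical, feature_id = f)
    data.frame(feature_id = f, logrank_statistic = s$statistic,
               logrank_p = s$p, high_group_n = s$n_high,
               low_group_n = s$n_low, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$logrank_p, res$feature_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Multivariable Cox proportional-hazards risk model
#'
#' Fits a Cox model (Breslow tie handling, Newton--Raphson to a tight
#' convergence tolerance) of survival on the selected features' expression
#' and derives each sample's risk score as the linear predictor
#' `sum(coef * expr)`. More than `n/5` features triggers an overfitting
#' warning; non-convergence or complete separation (diverging
#' coefficients) is an error.
#'
#' @param em An [expression_matrix()]; samples must cover the clinical
#'   table.
#' @param clinical A [clinical_table()] with at least one event.
#' @param features Feature ids used as covariates (default: all rows).
#' @return An object of class `"cerna_risk"`: list with `coefficients`
#'   (named numeric), `risk_score` (named numeric, one per sample), `fit`
#'   (the underlying `coxph` object) and `features`.
#' @export
cox_fit <- function(em, clinical, features = NULL) {
  stopifnot(inherits(em, "expr_matrix"), inherits(clinical, "clinical_table"))
  if (is.null(features)) features <- rownames(em$values)
  if (!length(features)) stop("no features supplied to the Cox model")
  missing <- setdiff(features, rownames(em$values))
  if (length(missing))
    stop("features not in expression matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  if (sum(clinical$event) < 1L) stop("no events observed")
  if (length(features) > nrow(clinical) / 5)
    warning(sprintf(
      "%d covariates for %d samples; risk of overfitting (> n/5)",
      length(features), nrow(clinical)))
  X <- t(em$values[features, clinical$sample_id, drop = FALSE])
  df <- data.frame(X, check.names = FALSE)
  df$..time <- clinical$time
  df$..event <- clinical$event
  fml <- stats::as.formula(paste(
    "Surv(..time, ..event) ~",
    paste(sprintf("`%s`", features), collapse = " + ")))
  fit <- withCallingHandlers(
    coxph(fml, data = df, ties = "breslow",
          control = coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("Cox fit failed (separation or non-convergence): ",
             conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    stop("Cox coefficients diverged; complete separation likely")
  names(beta) <- features
  score <- as.vector(X %*% beta)
  names(score) <- clinical$sample_id
  structure(list(coefficients = beta, risk_score = score, fit = fit,
                 features = features),
            class = "cerna_risk")
}

#' @export
coef.cerna_risk <- function(object, ...) object$coefficients

#' @export
print.cerna_risk <- function(x, ...) {
  cat(sprintf("Cox risk model on %d feature(s):\n", length(x$coefficients)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.cerna_risk <- function(object, ...) {
  s <- summary(object$fit)
  cat("Cox proportional-hazards risk model (Breslow ties)\n")
  print(s$coefficients)
  invisible(s)
}

#' Risk scores for new expression data
#' @param object A `"cerna_risk"` model.
#' @param newdata An [expression_matrix()] containing the model's features
#'   (default: scores fitted at training time).
#' @param ... Unused.
#' @return Named numeric vector of risk scores (linear predictors).
#' @export
predict.cerna_risk <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$risk_score)
  stopifnot(inherits(newdata, "expr_matrix"))
  X <- t(newdata$values[object$features, , drop = FALSE])
  score <- as.vector(X %*% object$coefficients)
  names(score) <- colnames(newdata$values)
  score
}

#' Fixed-horizon ROC AUC of a risk score
#'
#' At a fixed horizon (default three years = 1095 days), cases are samples
#' with an observed event at or before the horizon and controls are
#' samples still under observation beyond it; samples censored before the
#' horizon carry no information under this estimator and are excluded.
#' The AUC is the Mann--Whitney probability that a random case's risk
#' score exceeds a random control's, with ties counted one half.
#'
#' @param model A `"cerna_risk"` model or a named numeric vector of risk
#'   scores covering the clinical samples.
#' @param clinical A [clinical_table()].
#' @param horizon Horizon in days (default 1095 = 3 years).
#' @return The AUC in `[0, 1]`, with attributes `n_cases`, `n_controls`
#'   and `method`.
#' @export
auc_at_horizon <- function(model, clinical, horizon = 1095) {
  stopifnot(inherits(clinical, "clinical_table"))
  score <- if (inherits(model, "cerna_risk")) model$risk_score
           else model
  missing <- setdiff(clinical$sample_id, names(score))
  if (length(missing))
    stop("risk scores missing for samples: ",
         paste(head(missing, 5L), collapse = ", "))
  score <- score[clinical$sample_id]
  case <- clinical$time <= horizon & clinical$event == 1
  control <- clinical$time > horizon
  if (!any(case)) stop("no cases (events before the horizon)")
  if (!any(control)) stop("no controls (follow-up beyond the horizon)")
  sc <- score[case]; sn <- score[control]
  cmp <- outer(sc, sn, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  attr(auc, "n_cases") <- sum(case)
  attr(auc, "n_controls") <- sum(control)
  attr(auc, "method") <- "censoring-exclusion Mann-Whitney"
  auc
}
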