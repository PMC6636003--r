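# Binary logistic biomarker panels.

#' Fit a logistic biomarker panel
#'
#' Maximum-likelihood binary logistic regression of response class on a
#' set of marker columns (via [stats::glm()]).  When the fit does not
#' converge or quasi-complete separation is detected (fitted
#' probabilities numerically 0 or 1), the panel is refit with a small
#' ridge penalty (`ridge_lambda`, default 1e-4) by iteratively
#' reweighted least squares, and the penalization is recorded in the
#' training log.
#'
#' @param markers Data frame or matrix of numeric marker values, one row
#'   per patient.  A `patient_id` column, if present, is carried along
#'   but not used as a marker.
#' @param labels Character/factor vector of class labels, one per row.
#' @param positive_class The label whose probability the panel score
#'   models (default `"Limited"`: the score is the predicted probability
#'   of limited response).
#' @param ridge_lambda Ridge penalty used in the separation fallback.
#' @param max_iterations,tolerance IRLS stopping rule for the penalized
#'   fallback: stop when the largest absolute score-equation gradient
#'   falls below `tolerance`.
#' @return An object of class `panel_model`: `marker_names`,
#'   `intercept`, `coefficients`, `positive_class` and `training_log`
#'   (`iterations`, `converged`, `penalized`, deviances).
#' @export
fit_logistic_panel <- function(markers, labels, positive_class = "Limited",
                               ridge_lambda = 1e-4,
                               max_iterations = 100, tolerance = 1e-8) {
  X <- panel_design(markers)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) {
    ms1_abort("`labels` must annotate every row of `markers`")
  }
  classes <- unique(labels)
  if (length(classes) < 2L) ms1_abort("labels contain a single class")
  if (!positive_class %in% classes) {
    ms1_abort(sprintf("positive_class '%s' absent from labels", positive_class))
  }
  if (min(table(labels)) < 2L) ms1_abort("each class needs >= 2 patients")
  y <- as.numeric(labels == positive_class)

  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = as.data.frame(X), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )

  if (!separated && fit$converged) {
    beta <- coef(fit)
    log_entry <- list(iterations = fit$iter, converged = TRUE,
                      penalized = FALSE,
                      deviance = fit$deviance,
                      null_deviance = fit$null.deviance)
  } else {
    ridge <- ridge_logistic_irls(cbind(`(Intercept)` = 1, X), y,
                                 lambda = ridge_lambda,
                                 max_iterations = max_iterations,
                                 tolerance = tolerance)
    beta <- ridge$beta
    log_entry <- list(iterations = ridge$iterations,
                      converged = ridge$converged, penalized = TRUE,
                      lambda = ridge_lambda,
                      deviance = ridge$deviance,
                      null_deviance = null_binomial_deviance(y))
  }

  structure(
    list(
      marker_names = colnames(X),
      intercept = unname(beta[1]),
      coefficients = setNames(unname(beta[-1]), colnames(X)),
      positive_class = positive_class,
      n = length(y),
      training_log = log_entry
    ),
    class = "panel_model"
  )
}

# Numeric design matrix from a marker table; patient_id is dropped.
panel_design <- function(markers) {
  df <- as.data.frame(markers)
  df$patient_id <- NULL
  if (ncol(df) == 0L) ms1_abort("no marker columns supplied")
  not_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(not_num) > 0L) {
    ms1_abort(sprintf("non-numeric marker column(s): %s",
                      paste(not_num, collapse = ", ")))
  }
  X <- as.matrix(df)
  if (anyNA(X)) ms1_abort("marker values contain missing entries")
  constant <- colnames(X)[apply(X, 2L, function(v) var(v) == 0)]
  if (length(constant) > 0L) {
    ms1_abort(sprintf("constant marker column(s): %s",
                      paste(constant, collapse = ", ")))
  }
  X
}

null_binomial_deviance <- function(y) {
  p <- mean(y)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# Ridge-penalized logistic IRLS (penalty on non-intercept coefficients).
# Convergence: max |X'(y - p) - 2 lambda D beta| < tolerance.
ridge_logistic_irls <- function(X, y, lambda, max_iterations = 100,
                                tolerance = 1e-8) {
  p_dim <- ncol(X)
  D <- diag(c(0, rep(1, p_dim - 1L)), p_dim)
  beta <- rep(0, p_dim)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iterations)) {
    iterations <- it
    eta <- as.vector(X %*% beta)
    prob <- 1 / (1 + exp(-eta))
    grad <- as.vector(t(X) %*% (y - prob)) - 2 * lambda * as.vector(D %*% beta)
    if (max(abs(grad)) < tolerance) {
      converged <- TRUE
      break
    }
    w <- pmax(prob * (1 - prob), 1e-10)
    H <- t(X) %*% (X * w) + 2 * lambda * D
    beta <- beta + solve(H, grad)
  }
  eta <- as.vector(X %*% beta)
  prob <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  list(
    beta = setNames(beta, colnames(X)),
    iterations = iterations, converged = converged,
    deviance = -2 * sum(y * log(prob) + (1 - y) * log(1 - prob))
  )
}

#' Panel scores for new patients
#'
#' @param object A `panel_model`.
#' @param newdata Data frame covering the model's marker columns.
#' @param ... Unused.
#' @return Numeric vector of predicted probabilities of the model's
#'   positive class.
#' @export
predict.panel_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  missing_cols <- setdiff(object$marker_names, names(df))
  if (length(missing_cols) > 0L) {
    ms1_abort(sprintf("newdata lacks marker(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(df[object$marker_names])
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    who <- if (!is.null(df$patient_id)) df$patient_id[bad[1, 1]] else
      sprintf("row %d", bad[1, 1])
    ms1_abort(sprintf("missing value of marker '%s' for patient %s",
                      object$marker_names[bad[1, 2]], who))
  }
  eta <- object$intercept + as.vector(X %*% object$coefficients)
  1 / (1 + exp(-eta))
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf(
    "<panel_model> P(%s) ~ %s%s\n", x$positive_class,
    paste(x$marker_names, collapse = " + "),
    if (isTRUE(x$training_log$penalized)) "  [ridge-penalized]" else ""
  ))
  invisible(x)
}

#' @export
tidy.panel_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$marker_names),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.panel_model <- function(x, ...) {
  lg <- x$training_log
  lr <- lg$null_deviance - lg$deviance
  tibble::tibble(
    n = x$n,
    n_markers = length(x$marker_names),
    deviance = lg$deviance,
    null_deviance = lg$null_deviance,
    lr_statistic = lr,
    lr_p_value = pchisq(lr, df = length(x$marker_names), lower.tail = FALSE),
    converged = lg$converged,
    penalized = isTRUE(lg$penalized),
    iterations = lg$iterations
  )
}
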