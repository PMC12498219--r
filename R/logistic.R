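#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression fitted by Newton scoring,
#' converging when the largest score component falls below `tol` (default
#' 1e-8) or after `max_iter` iterations. `model = "firth"` applies Firth's
#' bias-reducing Jeffreys-prior penalty (modified score
#' `X'(y - p + h * (1/2 - p))` with `h` the leverages of the weighted design),
#' which yields finite estimates under (near-)separation -- relevant when the
#' outcome has very few events. Under plain MLE, divergence of a coefficient
#' or non-convergence raises a warning advising the Firth fit.
#'
#' @param y binary 0/1 response vector containing both classes.
#' @param X numeric covariate matrix or data.frame (no intercept column; one
#'   is added internally).
#' @param model `"plain_mle"` or `"firth"`.
#' @param max_iter,tol scoring controls.
#' @return list of class `logistic_fit` with `coefficients`, `se`, `vcov`,
#'   `fitted`, `p_values` (Wald), `odds_ratio`, `ci_low`, `ci_high` (Wald 95%),
#'   `converged`, `model`, `n`, `n_events`.
#' @export
logistic_fit <- function(y, X, model = c("plain_mle", "firth"),
                         max_iter = 100L, tol = 1e-8) {
  model <- match.arg(model)
  X <- as.matrix(cbind(`(Intercept)` = 1, X))
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop_input("X and y sizes differ")
  if (!all(y %in% c(0, 1))) stop_input("y must be binary 0/1")
  if (sum(y) == 0 || sum(y) == n) stop_input("y must contain both classes")
  if (n <= ncol(X)) stop_input("need n > number of covariates + 1")

  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XtWX <- crossprod(X * w, X)
    info_inv <- tryCatch(solve(XtWX), error = function(e) {
      stop_input("singular information matrix: collinear covariates or separation")
    })
    if (model == "firth") {
      # leverages of W^(1/2) X
      h <- rowSums((X %*% info_inv) * X) * w
      score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    } else {
      score <- drop(crossprod(X, y - p))
    }
    step <- drop(info_inv %*% score)
    beta <- beta + step
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    # under separation the plain-MLE coefficients diverge; stop before the
    # information matrix becomes numerically singular
    if (model == "plain_mle" && max(abs(beta)) > 15) break
  }
  if (model == "plain_mle" && (!converged || max(abs(beta)) > 15)) {
    warning("possible separation or non-convergence under plain MLE; ",
            "consider model = \"firth\"", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  vcov <- solve(crossprod(X * w, X))
  se <- sqrt(diag(vcov))
  zval <- beta / se
  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         se = stats::setNames(se, colnames(X)), vcov = vcov, fitted = p,
         p_values = stats::setNames(2 * stats::pnorm(-abs(zval)), colnames(X)),
         odds_ratio = exp(beta), ci_low = exp(beta - 1.96 * se),
         ci_high = exp(beta + 1.96 * se),
         converged = converged, model = model, n = n, n_events = sum(y)),
    class = "logistic_fit"
  )
}

#' Backward elimination for logistic regression
#'
#' Starts from the full model and iteratively refits after removing the
#' covariate with the largest Wald p-value above `alpha_remove`, stopping
#' when every retained covariate satisfies `p <= alpha_remove` (the intercept
#' is never removed). An intercept-only final model is allowed. The default
#' stay criterion of 0.10 matches common backward-selection software
#' defaults; set `alpha_remove = 1` to keep the full model.
#'
#' @param y binary response.
#' @param X covariate matrix or data.frame with named columns.
#' @param alpha_remove stay threshold on Wald p-values.
#' @param model passed to [logistic_fit()].
#' @param outcome label stored in the result.
#' @return list of class `association_result` with `outcome`, `table`
#'   (data.frame: variable, coefficient, odds_ratio, ci_low, ci_high,
#'   p_value), `elimination_trace` (data.frame: variable, p_at_removal),
#'   `fit` (final [logistic_fit()]), `model`, `alpha_remove`.
#' @export
backward_select <- function(y, X, alpha_remove = 0.10,
                            model = c("plain_mle", "firth"), outcome = "outcome") {
  model <- match.arg(model)
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X)))) stop_input("X needs column names")
  vars <- names(X)
  trace <- data.frame(variable = character(), p_at_removal = numeric())
  repeat {
    fit <- logistic_fit(y, X[, vars, drop = FALSE], model = model)
    pv <- fit$p_values[-1]  # drop intercept
    if (!length(pv) || max(pv) <= alpha_remove) break
    worst <- names(pv)[which.max(pv)]
    trace <- rbind(trace,
                   data.frame(variable = worst, p_at_removal = unname(max(pv))))
    vars <- setdiff(vars, worst)
  }
  keep <- names(fit$coefficients)[-1]
  tab <- data.frame(
    variable = keep,
    coefficient = unname(fit$coefficients[-1]),
    odds_ratio = unname(fit$odds_ratio[-1]),
    ci_low = unname(fit$ci_low[-1]),
    ci_high = unname(fit$ci_high[-1]),
    p_value = unname(fit$p_values[-1])
  )
  structure(
    list(outcome = outcome, table = tab, elimination_trace = trace, fit = fit,
         model = model, alpha_remove = alpha_remove),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ..., clip = TRUE) {
  cat(sprintf("Backward-selected logistic model for %s (%s, stay p <= %.2g)\n",
              x$outcome, x$model, x$alpha_remove))
  if (!nrow(x$table)) {
    cat("  intercept-only model retained\n")
    return(invisible(x))
  }
  tab <- x$table
  fmt_or <- function(v) {
    if (clip) v <- pmin(pmax(v, 0.001), 999)  # display clipping only
    formatC(v, digits = 2, format = "fg")
  }
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-24s OR %s (%s-%s), p = %.3g\n", tab$variable[i],
                fmt_or(tab$odds_ratio[i]), fmt_or(tab$ci_low[i]),
                fmt_or(tab$ci_high[i]), tab$p_value[i]))
  }
  invisible(x)
}
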