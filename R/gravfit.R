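#' Fit the CoM displacement-on-gravity regression
#'
#' Per-sex ordinary least squares of a pelvis-relative CoM displacement
#' component on the gravity-level indicator (0 = 1/6 g, 1 = 1 g) and the task
#' indicator (0 = static, 1 = dynamic):
#' `d = constant + beta_g * g_level + beta_task * task + error`.
#'
#' The fit is the closed-form normal-equations solution
#' `beta = (X'X)^-1 X'y`, with classical standard errors from
#' `sigma^2 (X'X)^-1` and two-sided t p-values on `n - p` degrees of freedom.
#' The three windows of each trial enter as separate observations (pooled
#' OLS); an optional cluster-robust covariance (clustered on participant)
#' is available for sensitivity analysis.
#'
#' An indicator column that is constant in the data is dropped from the design
#' (and recorded in `$dropped`); a genuinely collinear design is an error
#' naming the offending columns.
#'
#' @param data data frame of window-level rows as produced by
#'   [summarize_trial()] (needs the response column plus `g_level`,
#'   `task_dynamic`; `sex` and `participant` if used).
#' @param response `"dY"` or `"dZ"` (cm).
#' @param sex optional `"male"`/`"female"` filter applied to `data$sex`.
#' @param robust logical; also compute cluster-robust standard errors.
#' @param cluster column name used for clustering when `robust = TRUE`.
#' @return Object of class `com_gravfit` with elements `coefficients`, `se`,
#'   `t`, `p.value`, `n`, `r.squared`, `adj.r.squared`, `sigma` (residual
#'   standard error, cm), `fstatistic` (`value`, `df1`, `df2`, `p.value`),
#'   `residuals`, `fitted`, `vcov`, and `se_robust` when requested.
#' @export
#' @examples
#' d <- data.frame(dY = c(0, 1, 2, 3), g_level = c(0, 0, 1, 1),
#'                 task_dynamic = 0L)
#' coef(com_gravfit(d, "dY"))
com_gravfit <- function(data, response = c("dY", "dZ"), sex = NULL,
                        robust = FALSE, cluster = "participant") {
  response <- match.arg(response)
  stopifnot(is.data.frame(data),
            all(c(response, "g_level", "task_dynamic") %in% names(data)))
  if (!is.null(sex)) {
    stopifnot("sex" %in% names(data))
    data <- data[data$sex == sex, , drop = FALSE]
  }
  y <- data[[response]]
  keep <- is.finite(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 4L) stop("need at least 4 usable rows to fit the model")

  terms <- c(g_level = "g_level", task = "task_dynamic")
  X <- cbind(constant = rep(1, n),
             g_level = as.numeric(data$g_level),
             task = as.numeric(data$task_dynamic))
  dropped <- character(0)
  for (nm in c("g_level", "task")) {
    if (length(unique(X[, nm])) == 1L) {
      dropped <- c(dropped, nm)
    }
  }
  if (length(dropped)) X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  p <- ncol(X)
  if (n <= p) stop("more parameters than observations")

  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    stop("singular design: columns ", paste(colnames(X)[-1L], collapse = ", "),
         " are collinear")
  }
  XtXinv <- solve(XtX)
  beta <- drop(XtXinv %*% crossprod(X, y))
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  df <- n - p
  sigma2 <- rss / df
  vc <- sigma2 * XtXinv
  se <- sqrt(diag(vc))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adj <- 1 - (1 - r2) * (n - 1) / df
  f <- if (p > 1L) {
    fv <- ((tss - rss) / (p - 1)) / sigma2
    c(value = fv, df1 = p - 1, df2 = df,
      p.value = stats::pf(fv, p - 1, df, lower.tail = FALSE))
  } else c(value = NA_real_, df1 = 0, df2 = df, p.value = NA_real_)

  fit <- structure(list(
    coefficients = beta, se = se, t = tval, p.value = pval,
    n = n, df.residual = df, r.squared = r2, adj.r.squared = adj,
    sigma = sqrt(sigma2), fstatistic = f, residuals = resid, fitted = fitted,
    vcov = vc, response = response, sex = sex, dropped = dropped,
    X = X, call = match.call()
  ), class = "com_gravfit")

  if (robust) {
    if (!cluster %in% names(data)) stop("cluster column '", cluster, "' not found")
    fit$se_robust <- cluster_robust_se(X, resid, data[[cluster]], XtXinv)
  }
  fit
}

# CR1 cluster-robust standard errors
cluster_robust_se <- function(X, resid, cl, XtXinv) {
  cl <- as.character(cl)
  G <- length(unique(cl))
  n <- nrow(X); p <- ncol(X)
  meat <- matrix(0, p, p)
  for (g in unique(cl)) {
    i <- cl == g
    s <- crossprod(X[i, , drop = FALSE], resid[i])
    meat <- meat + tcrossprod(s)
  }
  adj <- G / (G - 1) * (n - 1) / (n - p)
  sqrt(diag(adj * XtXinv %*% meat %*% XtXinv))
}

#' @export
coef.com_gravfit <- function(object, ...) object$coefficients

#' @export
vcov.com_gravfit <- function(object, ...) object$vcov

#' @export
residuals.com_gravfit <- function(object, ...) object$residuals

#' @export
fitted.com_gravfit <- function(object, ...) object$fitted

#' @export
predict.com_gravfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- cbind(constant = rep(1, nrow(newdata)),
             g_level = as.numeric(newdata$g_level),
             task = as.numeric(newdata$task_dynamic))
  drop(X[, names(object$coefficients), drop = FALSE] %*% object$coefficients)
}

#' @export
simulate.com_gravfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.com_gravfit <- function(x, digits = 3, ...) {
  cat("CoM displacement regression (", x$response,
      if (!is.null(x$sex)) paste0(", ", x$sex), "), n = ", x$n, "\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.com_gravfit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$t, `Pr(>|t|)` = object$p.value)
  structure(list(fit = object, coefficients = tab), class = "summary.com_gravfit")
}

#' @export
print.summary.com_gravfit <- function(x, ...) {
  f <- x$fit
  cat("CoM displacement regression: ", f$response,
      if (!is.null(f$sex)) paste0(" (", f$sex, ")"), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nn = %d, R^2 = %.4f, adj. R^2 = %.4f, residual SE = %.4f cm\n",
              f$n, f$r.squared, f$adj.r.squared, f$sigma))
  if (is.finite(f$fstatistic["value"])) {
    cat(sprintf("F(%d, %d) = %.2f, p = %.4g\n", f$fstatistic["df1"],
                f$fstatistic["df2"], f$fstatistic["value"],
                f$fstatistic["p.value"]))
  }
  if (!is.null(f$se_robust)) {
    cat("cluster-robust SE:", paste(sprintf("%s %.3f", names(f$se_robust),
                                            f$se_robust), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.com_gravfit <- function(x, ...) {
  g <- x$X[, "g_level"]
  y <- x$fitted + x$residuals
  graphics::boxplot(y ~ factor(g, c(0, 1), c("1/6 g", "1 g")),
                    ylab = paste0(x$response, " (cm)"), xlab = "gravity level",
                    main = "Pelvis-relative CoM displacement", ...)
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper over the AS R94 (Royston) Shapiro-Wilk implementation in
#' `stats::shapiro.test`, with the preconditions made explicit. Used as a
#' screening report for the regression residuals; no automatic branching to
#' non-parametric methods is performed.
#'
#' @param values numeric sample, 3 <= n <= 5000, finite, not all equal.
#' @return `list(W, p.value)`.
#' @export
shapiro_wilk <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(values)) == 0) stop("all sample values are equal")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p.value = ht$p.value)
}
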