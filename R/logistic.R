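#' Logistic regression by iteratively reweighted least squares
#'
#' Maximizes the binomial log-likelihood for a binary outcome over a
#' design matrix that already contains its intercept column. Each IRLS
#' step solves the weighted least-squares problem via a QR decomposition;
#' iteration stops when the largest coefficient change falls below `tol`
#' (default 1e-8) or after `max_iter` steps. The coefficient covariance
#' is the inverse observed information at the final estimate. A term is
#' flagged for complete/quasi-separation when every fitted probability on
#' its support (rows where the column is non-zero) lies within 1e-8 of 0
#' or 1.
#'
#' @param design numeric matrix with named columns, including an intercept.
#' @param outcome 0/1 vector (1 = case).
#' @param tol,max_iter convergence control.
#' @return object of class `logistic_fit`: coefficients, vcov, deviance,
#'   log_likelihood, fitted, converged, n_iter, separation (named logical),
#'   n.
#' @export
logistic_irls <- function(design, outcome, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(design)
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more terms than subjects")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- rep(0, p)
  converged <- FALSE; it <- 0L
  repeat {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; converged <- TRUE; break }
    beta <- beta_new
    if (it >= max_iter) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  loglik <- sum(y * eta - log1p(exp(eta)))
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  extreme <- mu < 1e-8 | mu > 1 - 1e-8
  separation <- vapply(seq_len(p), function(j) {
    sup <- X[, j] != 0
    any(sup) && all(extreme[sup])
  }, logical(1))
  names(separation) <- colnames(X)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = vcov,
                 deviance = -2 * loglik,
                 log_likelihood = loglik,
                 fitted = mu,
                 converged = converged,
                 n_iter = it,
                 separation = separation,
                 n = n,
                 terms = colnames(X)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: n = %d, %d terms, deviance = %.4f (%s in %d iter)\n",
              x$n, length(x$coefficients), x$deviance,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$coefficients, se = se), 4))
  if (any(x$separation))
    cat("separation flagged:", paste(names(which(x$separation)), collapse = ", "), "\n")
  invisible(x)
}

#' Global deviance likelihood-ratio test between nested logistic fits
#'
#' The statistic is the deviance of the reduced (covariates-only) model
#' minus the deviance of the full model, clipped at zero, referred to a
#' chi-square distribution with degrees of freedom equal to the number of
#' terms added by the full model. Both fits must use the same subjects
#' and the reduced model's terms must be a subset of the full model's.
#'
#' @param full,reduced logistic_fit objects.
#' @return list(statistic, df, p_value)
#' @export
global_lrt <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (full$n != reduced$n)
    stop("models fitted on different numbers of subjects")
  if (!all(reduced$terms %in% full$terms))
    stop("models are not nested: reduced terms must be a subset of full terms")
  df <- length(full$terms) - length(reduced$terms)
  if (df < 0L) stop("full model has fewer terms than reduced model")
  stat <- max(0, reduced$deviance - full$deviance)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}
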