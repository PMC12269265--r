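#' Multivariable logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares (Newton scoring with step-halving, which makes the
#' log-likelihood non-decreasing across iterations). Convergence when the
#' largest absolute score component falls below `tol_score` (1e-8) or the
#' relative change in log-likelihood falls below `tol_ll` (1e-10). Wald
#' standard errors come from the inverse observed information; odds ratios
#' are per unit of the covariate, so a calendar-year column gives the
#' adjusted OR per 1-year increment.
#'
#' Categorical covariates (factor/character columns) enter with their most
#' frequent level as the reference. Rows with missing values are dropped
#' (complete-case analysis) with the count recorded in `n_dropped`.
#'
#' @param outcome Binary vector (logical or 0/1).
#' @param covariates data.frame of covariates (numeric, logical, factor or
#'   character columns).
#' @param max_iter Iteration cap (default 100); exceeding it is an error.
#' @param tol_score,tol_ll Convergence tolerances.
#' @return A list with class `logistic_fit`: `coefficients` (data.table:
#'   term, estimate, se, or, or_low, or_high, z, p_value), `converged`,
#'   `n_iterations`, `loglik` (per-iteration trace), `n`, `n_dropped`.
#' @export
logistic_fit <- function(outcome, covariates, max_iter = 100L,
                         tol_score = 1e-8, tol_ll = 1e-10) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("logistic_fit: outcome must be binary")
  df <- as.data.frame(covariates)
  keep <- if (ncol(df)) stats::complete.cases(df) & !is.na(y) else !is.na(y)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  y <- y[keep]

  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      ref <- names(which.max(table(v)))
      df[[j]] <- stats::relevel(factor(v), ref = ref)
    } else if (is.logical(v)) df[[j]] <- as.numeric(v)
  }
  X <- if (ncol(df)) stats::model.matrix(~ ., data = df) else
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  const <- apply(X[, -1, drop = FALSE], 2, function(col)
    length(unique(col)) == 1L)
  if (any(const))
    stop("logistic_fit: constant covariate(s): ",
         paste(colnames(X)[-1][const], collapse = ", "))
  if (length(y) <= ncol(X))
    stop("logistic_fit: need more observations than parameters")
  ## centre non-intercept columns so the working intercept is the log-odds
  ## at covariate means (keeps the information matrix well conditioned for
  ## covariates like calendar year and makes the divergence check
  ## scale-sensible); the intercept is mapped back afterwards
  centres <- c(0, colMeans(X[, -1, drop = FALSE]))
  X_orig <- X
  X[, -1] <- sweep(X[, -1, drop = FALSE], 2, centres[-1])

  ll <- function(b) {
    eta <- drop(X %*% b)
    ## numerically safe log(1 + exp(eta))
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  beta <- numeric(ncol(X))
  ll_trace <- ll(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e)
      stop("logistic_fit: singular information matrix", call. = FALSE))
    ## step-halving keeps the log-likelihood non-decreasing
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (ll(cand) >= ll_trace[it] - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
    ll_trace <- c(ll_trace, ll(beta))
    if (any(abs(beta) > 15))
      stop("logistic_fit: quasi-complete separation detected ",
           "(coefficient diverging beyond 15)", call. = FALSE)
    rel <- abs(ll_trace[it + 1] - ll_trace[it]) /
      (abs(ll_trace[it]) + 1e-300)
    if (max(abs(score)) < tol_score || rel < tol_ll) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("logistic_fit: no convergence in ", max_iter, " iterations",
         call. = FALSE)

  ## map back to the uncentred parametrisation
  beta[1] <- beta[1] - sum(beta[-1] * centres[-1])
  X <- X_orig
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  coefs <- data.table(term = colnames(X), estimate = beta, se = se,
                      or = exp(beta), or_low = exp(beta - 1.96 * se),
                      or_high = exp(beta + 1.96 * se), z = z,
                      p_value = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = coefs, converged = converged,
                 n_iterations = it, loglik = ll_trace, n = length(y),
                 n_dropped = n_dropped),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("IRLS logistic fit: n =", x$n, "(", x$n_dropped, "dropped ),",
      x$n_iterations, "iterations\n")
  print(x$coefficients[, list(term, or = round(or, digits),
                              or_low = round(or_low, digits),
                              or_high = round(or_high, digits),
                              p_value = signif(p_value, 2))])
  invisible(x)
}
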