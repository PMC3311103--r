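# Core penalized logistic fit. Newton/IRLS with step halving on the
# (weighted) binomial log-likelihood minus 0.5 * ridge * sum(beta^2); the
# intercept is never penalized. Deterministic; converges on max |gradient|
# < 1e-8 or stops at maxit with converged = FALSE (expected under complete
# separation with a tiny ridge, where the optimum is finite but flat).
fit_logistic_core <- function(X, y01, weights = NULL, ridge = 1e-6,
                              intercept = TRUE, start = NULL,
                              maxit = 100L, tol = 1e-8) {
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  X1 <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  p <- ncol(X1)
  pen <- rep(ridge, p)
  if (intercept) pen[1L] <- 0
  beta <- if (!is.null(start) && length(start) == p) start else rep(0, p)

  nll <- function(b) {
    eta <- drop(X1 %*% b)
    # log(1 + exp(eta)) computed stably
    ll <- sum(weights * (y01 * eta - ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))))
    -ll + 0.5 * sum(pen * b^2)
  }

  converged <- FALSE
  iter <- 0L
  f_cur <- nll(beta)
  f_prev <- Inf
  for (iter in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- clamp_prob(stats::plogis(eta))
    grad <- drop(crossprod(X1, weights * (mu - y01))) + pen * beta
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    # flat-optimum stop: under complete separation with a tiny ridge the
    # likelihood plateaus long before the gradient tolerance is reachable
    if (abs(f_prev - f_cur) < 1e-10 * (abs(f_cur) + 1)) {
      converged <- TRUE; break
    }
    f_prev <- f_cur
    w <- weights * mu * (1 - mu)
    H <- crossprod(X1, X1 * w) + diag(pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, p), grad)
    })
    # step halving on the penalized objective
    lam <- 1
    repeat {
      cand <- beta - lam * step
      f_new <- nll(cand)
      if (is.finite(f_new) && f_new <= f_cur + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; f_new <- f_cur; break }
    }
    beta <- cand
    f_cur <- f_new
  }
  list(coef = beta, converged = converged, iterations = iter,
       intercept = intercept)
}

#' Fit the k-mer mixture logistic regression
#'
#' Maximizes the (optionally weighted, L2-penalized) binomial log-likelihood
#' of the model \eqn{y = 1/(1 + e^{-f(x)})},
#' \eqn{f(x) = \beta_0 + \sum_i \beta_i x_i}, where the design matrix holds
#' k-mer occurrence counts. A small ridge penalty (default `1e-6`, never on
#' the intercept) keeps the optimum finite under complete separation, which
#' rare long k-mers readily produce. The fit is deterministic given its
#' inputs.
#'
#' @param X Numeric design matrix (instances x k-mers); column names are
#'   taken as the k-mer identities.
#' @param labels `+`/`-` labels (character, factor, logical, or 0/1).
#' @param weights Optional non-negative sample weights.
#' @param ridge L2 penalty strength (>= 0, default `1e-6`).
#' @param intercept Include an unpenalized intercept (default `TRUE`).
#' @return A [KmerLogisticModel-class].
#' @examples
#' X <- cbind(kmer = c(0, 0, 3, 4))
#' m <- fitKmerLogistic(X, c("-", "-", "+", "+"))
#' predictProbability(m, c(kmer = 4))
#' @export
fitKmerLogistic <- function(X, labels, weights = NULL, ridge = 1e-6,
                            intercept = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("design matrix contains non-finite values")
  lab <- as_plus_label(labels)
  if (length(lab) != nrow(X)) stop("labels must align with rows of X")
  if (all(lab) || !any(lab)) {
    stop("degenerate labels: both classes are required to fit")
  }
  stopifnot(ridge >= 0)
  fit <- fit_logistic_core(X, as.numeric(lab), weights = weights,
                           ridge = ridge, intercept = intercept)
  b <- fit$coef
  kmers <- colnames(X)
  if (is.null(kmers)) kmers <- paste0("x", seq_len(ncol(X)))
  new("KmerLogisticModel",
      kmers = kmers,
      betas = if (intercept) unname(b[-1L]) else unname(b),
      intercept = if (intercept) unname(b[1L]) else 0,
      ridge = ridge, converged = fit$converged,
      iterations = as.integer(fit$iterations))
}

#' Predicted methylation susceptibility of one feature vector
#'
#' Evaluates \eqn{y = 1/(1 + e^{-(\beta_0 + \sum_i \beta_i x_i)})}. The
#' logistic output is the calibrated methylation level: it always lies
#' strictly inside (0, 1) and is numerically stable for \eqn{|f(x)|} far
#' beyond 1e4.
#'
#' @param model A [KmerLogisticModel-class].
#' @param x Numeric vector of k-mer counts aligned with `model@kmers`.
#' @return A probability in (0, 1).
#' @export
predictProbability <- function(model, x) {
  if (length(x) != length(model@kmers)) {
    stop("feature vector length ", length(x), " does not match the model's ",
         length(model@kmers), " k-mers")
  }
  clamp_prob(stats::plogis(model@intercept + sum(model@betas * x)))
}

#' Predicted methylation susceptibility for a design matrix
#'
#' Vectorized [predictProbability()]: one calibrated level in (0, 1) per row.
#'
#' @param model A [KmerLogisticModel-class].
#' @param X Numeric matrix, columns aligned with `model@kmers`.
#' @return Numeric vector of probabilities.
#' @export
decisionScores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@kmers)) {
    stop("design matrix has ", ncol(X), " columns but the model has ",
         length(model@kmers), " k-mers")
  }
  clamp_prob(stats::plogis(drop(model@intercept + X %*% model@betas)))
}
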