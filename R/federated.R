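# Federated logistic regression by summary-statistic aggregation.
#
# Each center evaluates, at a shared coefficient vector beta, the Bernoulli
# log-likelihood score g_c = X_c' (y_c - mu_c) and information
# I_c = X_c' W_c X_c with mu = logistic(X beta), W = diag(mu (1 - mu)).
# Because score and information are sums over rows, the aggregated
# quantities equal the pooled-data quantities exactly, so Newton-Raphson on
# the aggregates follows the identical iterate path as a centralized fit:
# only p-vectors and p x p matrices ever cross the center boundary, never a
# row of data.

#' Simulate a logistic-regression dataset
#'
#' A documented synthetic dataset for the federated proof of concept (the
#' original multi-center clinical dataset is not public): standard-normal
#' covariates and a Bernoulli outcome from a logistic model.
#'
#' @param n rows.
#' @param beta true coefficients, intercept first (its length minus one sets
#'   the number of covariates).
#' @param seed integer seed.
#' @return data.frame with `y` and covariates `x1`, `x2`, ...
#' @export
#' @examples
#' d <- simulate_logistic_data(400, c(-0.5, 0.8, -0.6, 0.4), seed = 42)
#' colMeans(d)
simulate_logistic_data <- function(n, beta = c(-0.5, 0.8, -0.6, 0.4),
                                   seed = 1L) {
  p <- length(beta) - 1L
  assert_that(p >= 1, "beta needs an intercept and at least one covariate")
  set.seed(as.integer(seed))
  X <- matrix(rnorm(n * p), n, p)
  eta <- beta[1] + X %*% beta[-1]
  y <- rbinom(n, 1L, plogis(eta))
  out <- data.frame(y = y, X)
  names(out) <- c("y", paste0("x", seq_len(p)))
  out
}

#' Partition a dataset across hypothetical centers
#'
#' Disjoint, exhaustive, near-equal split (sizes differ by at most one row),
#' deterministic under the seed.
#'
#' @param data data.frame.
#' @param k number of centers (>= 1, <= rows).
#' @param seed integer seed.
#' @return list of `k` data.frames.
#' @export
#' @examples
#' sizes <- sapply(split_centers(simulate_logistic_data(403, seed = 1), 4, 9),
#'                 nrow)
#' sort(sizes)  # 100 101 101 101
split_centers <- function(data, k, seed = 1L) {
  n <- nrow(data)
  assert_that(k >= 1 && k <= n, "k must be between 1 and the number of rows")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  idx <- split(perm, rep(seq_len(k), sizes))
  lapply(idx, function(i) data[sort(i), , drop = FALSE])
}

model_matrix_parts <- function(data, outcome, covariates) {
  assert_that(outcome %in% names(data), "outcome column '%s' not found",
              o = outcome)
  assert_that(length(covariates) > 0, "at least one covariate is required")
  missing_cov <- setdiff(covariates, names(data))
  assert_that(length(missing_cov) == 0, "covariate(s) not found: %s",
              paste(missing_cov, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  y <- data[[outcome]]
  assert_that(all(y %in% c(0, 1)), "outcome must be binary 0/1")
  list(X = X, y = as.numeric(y))
}

#' Per-center summary statistics at a shared coefficient vector
#'
#' The only objects a center ever shares: its row count, the score vector
#' `X'(y - mu)` and the information matrix `X'WX` evaluated at `beta`.
#'
#' @param data the center's data.frame.
#' @param beta shared coefficient vector (intercept first).
#' @param outcome,covariates column names.
#' @param center_id optional label.
#' @return a `center_summary`: list with `center_id`, `n`, `gradient`,
#'   `information`.
#' @export
local_summary <- function(data, beta, outcome = "y",
                          covariates = setdiff(names(data), outcome),
                          center_id = NA_character_) {
  mm <- model_matrix_parts(data, outcome, covariates)
  assert_that(length(beta) == ncol(mm$X),
              "beta has length %d but the model has %d terms",
              b = length(beta), p = ncol(mm$X))
  mu <- plogis(drop(mm$X %*% beta))
  w <- mu * (1 - mu)
  structure(list(center_id = center_id, n = nrow(mm$X),
                 gradient = drop(crossprod(mm$X, mm$y - mu)),
                 information = crossprod(mm$X * w, mm$X)),
            class = "center_summary")
}

# the aggregation boundary: only center_summary objects may enter
aggregate_summaries <- function(summaries) {
  assert_that(all(vapply(summaries, inherits, TRUE, "center_summary")),
              "aggregation accepts center_summary objects only")
  list(n = sum(vapply(summaries, `[[`, 0, "n")),
       gradient = Reduce(`+`, lapply(summaries, `[[`, "gradient")),
       information = Reduce(`+`, lapply(summaries, `[[`, "information")))
}

#' Fit logistic regression across centers without pooling rows
#'
#' Newton-Raphson from `beta = 0`: at each iteration every center returns a
#' [local_summary()] at the current coefficients, the summaries are summed,
#' and the update solves `I delta = g`. Convergence is declared when the
#' max-norm of the aggregated score drops to `tol`. Standard errors come
#' from the inverse aggregated information at convergence and the reported
#' confidence intervals are Wald intervals at `level`. The iterate path is
#' exactly the centralized Newton path, for any partition of the rows.
#'
#' @param centers list of data.frames (one per center), or a single
#'   data.frame (one center).
#' @param outcome,covariates column names; default: `y` and all other
#'   columns.
#' @param tol convergence tolerance on the max-norm of the aggregated score.
#' @param max_iter maximum Newton iterations.
#' @param level confidence level for Wald intervals.
#' @return a `fedfit` object: `coefficients`, `se`, `vcov`, `ci`,
#'   `n_iterations`, `converged`, `beta_path` (one row per iterate), `n`,
#'   `k_centers`.
#' @export
#' @examples
#' d <- simulate_logistic_data(400, seed = 11)
#' fit <- federated_fit(split_centers(d, 4, seed = 2))
#' coef(fit)
federated_fit <- function(centers, outcome = "y",
                          covariates = NULL, tol = 1e-8, max_iter = 25L,
                          level = 0.95) {
  if (is.data.frame(centers)) centers <- list(centers)
  assert_that(length(centers) >= 1, "at least one center is required")
  if (is.null(covariates))
    covariates <- setdiff(names(centers[[1]]), outcome)
  p <- length(covariates) + 1L
  for (d in centers)
    assert_that(nrow(d) >= p + 1, "every center needs at least p + 1 rows")

  beta <- rep(0, p)
  names(beta) <- c("(Intercept)", covariates)
  path <- matrix(beta, nrow = 1)
  converged <- FALSE
  iter <- 0L
  agg <- NULL
  while (iter < max_iter) {
    summaries <- lapply(seq_along(centers), function(c_i)
      local_summary(centers[[c_i]], beta, outcome, covariates,
                    center_id = as.character(c_i)))
    agg <- aggregate_summaries(summaries)
    if (max(abs(agg$gradient)) <= tol) {
      converged <- TRUE
      break
    }
    delta <- tryCatch(solve(agg$information, agg$gradient),
                      error = function(e) stop_pdw(
                        paste0("aggregated information is singular ",
                               "(complete separation or collinear ",
                               "covariates); remove the offending ",
                               "covariate or pool more data"),
                        "separation_error"))
    beta <- beta + delta
    iter <- iter + 1L
    path <- rbind(path, beta)
  }
  if (!converged)
    warning("federated_fit did not converge in ", max_iter, " iterations")

  # complete separation drives fitted probabilities to 0/1: the score
  # vanishes (so the loop "converges") while the information collapses
  # toward zero; an absolute eigenvalue floor catches this
  ev <- eigen(agg$information, symmetric = TRUE, only.values = TRUE)$values
  if (!all(is.finite(ev)) || min(ev) < sqrt(.Machine$double.eps))
    stop_pdw(paste0("aggregated information is numerically singular ",
                    "(complete separation or collinear covariates); ",
                    "remove the offending covariate or pool more data"),
             "separation_error")

  vc <- solve(agg$information)
  dimnames(vc) <- list(names(beta), names(beta))
  se <- sqrt(diag(vc))
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)
  rownames(path) <- NULL

  structure(list(coefficients = beta, se = se, vcov = vc, ci = ci,
                 level = level, n_iterations = iter, converged = converged,
                 beta_path = path, n = agg$n, k_centers = length(centers),
                 outcome = outcome, covariates = covariates),
            class = "fedfit")
}

#' @export
coef.fedfit <- function(object, ...) object$coefficients

#' @export
vcov.fedfit <- function(object, ...) object$vcov

#' @export
confint.fedfit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.fedfit <- function(object, newdata,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- cbind(1, as.matrix(newdata[, object$covariates, drop = FALSE]))
  eta <- drop(X %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

#' @export
print.fedfit <- function(x, ...) {
  cat(sprintf("Federated logistic regression (%d centers, n = %d)\n",
              x$k_centers, x$n))
  cat(sprintf("Converged: %s after %d Newton iterations\n",
              x$converged, x$n_iterations))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.fedfit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)),
               lower = object$ci[, "lower"], upper = object$ci[, "upper"])
  structure(list(fit = object, coefficients = tab),
            class = "summary.fedfit")
}

#' @export
print.summary.fedfit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE])
  cat(sprintf("\n%.0f%% Wald confidence intervals:\n", x$fit$level * 100))
  print(round(x$coefficients[, 5:6, drop = FALSE], 6))
  invisible(x)
}
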