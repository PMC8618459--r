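# Epsilon-insensitive support-vector regression with an RBF kernel, solved
# exactly as the convex dual QP via quadprog (no SVM package is available in
# the target environment). Defaults mirror the common library defaults:
# C = 1, epsilon = 0.1, gamma = 1 / (n_features * Var(X)) ("scale").

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit / predict support-vector regression
#'
#' Solves the epsilon-SVR dual
#' \deqn{\min_{\alpha,\alpha^*} \tfrac12 (\alpha-\alpha^*)^\top K
#'   (\alpha-\alpha^*) - y^\top(\alpha-\alpha^*) +
#'   \epsilon \sum (\alpha+\alpha^*)}
#' subject to the box \eqn{0 \le \alpha, \alpha^* \le C} and
#' \eqn{\sum(\alpha-\alpha^*) = 0}, as a quadratic program. The intercept is
#' recovered from the free (strictly inside the box) support vectors. The
#' kernel matrix is dense, so training cost grows cubically; beyond
#' `max_train_rows` rows a seeded subsample is used.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response.
#' @param C Box constraint (regularization).
#' @param epsilon Width of the insensitive tube.
#' @param gamma RBF width; `NULL` uses 1 / (ncol(X) * var(X)).
#' @param max_train_rows Subsample cap for tractability.
#' @param seed Seed for the subsample draw.
#' @return An object of class `svr_model`.
#' @export
svr_fit <- function(X, y, C = 1, epsilon = 0.1, gamma = NULL,
                    max_train_rows = 600L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(y) >= 2)
  if (nrow(X) > max_train_rows) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    keep <- sort(sample.int(nrow(X), max_train_rows))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  n <- nrow(X)
  if (is.null(gamma)) {
    vx <- stats::var(as.numeric(X)) * (length(X) - 1) / length(X)
    gamma <- if (vx > 0) 1 / (ncol(X) * vx) else 1
  }
  K <- rbf_kernel(X, X, gamma)
  D <- rbind(cbind(K, -K), cbind(-K, K))
  dvec <- c(y - epsilon, -y - epsilon)
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  bvec <- c(0, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- NULL
  jitter <- 1e-8 * mean(diag(D))
  for (trial in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(D + diag(jitter, 2 * n), dvec, A, bvec, meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
    jitter <- jitter * 100
  }
  if (is.null(sol)) stop("SVR dual QP did not solve", call. = FALSE)
  z <- pmin(C, pmax(0, sol$solution))
  alpha <- z[seq_len(n)]; alpha_star <- z[n + seq_len(n)]
  beta <- alpha - alpha_star
  f0 <- as.numeric(K %*% beta)
  tol <- 1e-6 * C
  free_u <- alpha > tol & alpha < C - tol
  free_l <- alpha_star > tol & alpha_star < C - tol
  b <- if (any(free_u) || any(free_l)) {
    mean(c(y[free_u] - epsilon - f0[free_u], y[free_l] + epsilon - f0[free_l]))
  } else {
    mean(y - f0)
  }
  structure(list(X = X, beta = beta, b = b, gamma = gamma,
                 C = C, epsilon = epsilon),
            class = "svr_model")
}

#' @param object An `svr_model`.
#' @param newdata Matrix of rows to predict.
#' @param ... Unused.
#' @rdname svr_fit
#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(rbf_kernel(newdata, object$X, object$gamma) %*% object$beta +
               object$b)
}
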