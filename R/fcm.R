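#' Fuzzy c-means clustering
#'
#' Bezdek's alternating optimisation: soft memberships `u` and centers `v`
#' minimising `J = sum_i sum_k u[i,k]^m ||x_i - v_k||^2`, with fuzziness
#' `m > 1`. Memberships are initialised from seeded uniform draws (row
#' normalised); centers are then alternated with memberships until the
#' objective improves by less than `tol` or `max_iter` is reached. The
#' objective is recorded once per iteration and is non-increasing.
#'
#' @param X numeric matrix, n samples x d features, finite.
#' @param c number of clusters, `1 <= c <= n`.
#' @param m fuzziness exponent, `> 1` (2 is the universal convention).
#' @param tol convergence tolerance on the objective decrease.
#' @param max_iter iteration cap.
#' @param seed integer seed for the membership initialisation.
#' @return An object of class `fcm_result`: `centers` (c x d), `memberships`
#'   (n x c, rows summing to 1), `objective_trace`, `m`, `iterations`.
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(100, -5), 50), matrix(rnorm(100, 5), 50))
#' fit <- fcm_cluster(X, c = 2, seed = 1)
#' fit$centers
fcm_cluster <- function(X, c, m = 2, tol = 1e-8, max_iter = 200, seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("X must be finite")
  n <- nrow(X); d <- ncol(X)
  if (c < 1 || c > n) stopf("need 1 <= c <= n (got c = %d, n = %d)", c, n)
  if (m <= 1) stopf("fuzziness m must exceed 1")

  if (c == 1L) {
    ctr <- matrix(colMeans(X), 1, d, dimnames = list(NULL, colnames(X)))
    obj <- sum(sweep(X, 2, ctr[1, ])^2)
    return(structure(list(centers = ctr,
                          memberships = matrix(1, n, 1),
                          objective_trace = obj, m = m, iterations = 0L),
                     class = "fcm_result"))
  }

  U <- with_seed(seed, {
    u0 <- matrix(stats::runif(n * c, min = 0.05), n, c)
    u0 / rowSums(u0)
  })

  sqdist <- function(V) {
    ## n x c matrix of squared Euclidean distances to centers
    d2 <- outer(rowSums(X^2), rep(1, nrow(V))) - 2 * X %*% t(V) +
      outer(rep(1, n), rowSums(V^2))
    pmax(d2, 0)
  }

  trace <- numeric(0)
  obj_prev <- Inf
  V <- NULL
  for (it in seq_len(max_iter)) {
    Um <- U^m
    V <- (t(Um) %*% X) / colSums(Um)
    D2 <- sqdist(V)
    ## membership update; exact hits get full membership on their cluster
    pow <- -1 / (m - 1)
    W <- (D2 + 1e-300)^pow
    U <- W / rowSums(W)
    hit <- D2 < 1e-24
    if (any(hit)) {
      rows <- which(rowSums(hit) > 0)
      U[rows, ] <- hit[rows, , drop = FALSE] / rowSums(hit[rows, , drop = FALSE])
    }
    obj <- sum(U^m * D2)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) && obj_prev - obj < tol) break
    obj_prev <- obj
  }
  colnames(V) <- colnames(X)
  structure(list(centers = V, memberships = U, objective_trace = trace,
                 m = m, iterations = length(trace)),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("fcm_result: %d clusters, %d samples, m = %.2f, %d iterations, J = %.6g\n",
              nrow(x$centers), nrow(x$memberships), x$m, x$iterations,
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}
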