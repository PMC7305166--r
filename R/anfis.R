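#' @name anfis
#' @title First-order Takagi--Sugeno neuro-fuzzy regression (ANFIS-FCM)
#' @description
#' The predictor at the core of the package: a rule base induced by fuzzy
#' c-means clustering, Gaussian premise membership functions, linear rule
#' consequents, and hybrid learning (global least squares for consequents,
#' gradient descent for premises). Model output is the firing-strength
#' weighted average of the rule consequents.
NULL

## ---- internal helpers -------------------------------------------------------

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

## log firing strengths, n x c (unnormalised Gaussian product memberships)
log_firing <- function(model, Xs) {
  n <- nrow(Xs)
  c <- length(model$rules)
  L <- matrix(0, n, c)
  for (k in seq_len(c)) {
    r <- model$rules[[k]]
    Z <- sweep(sweep(Xs, 2, r$center), 2, r$sigma, "/")
    L[, k] <- -0.5 * rowSums(Z^2)
  }
  L
}

## normalised firing strengths; max-shifted so at least one rule always fires
norm_firing <- function(L) {
  W <- exp(L - apply(L, 1, max))
  W / rowSums(W)
}

## per-rule linear consequent outputs, n x c
rule_outputs <- function(model, Xs) {
  Phi <- cbind(1, Xs)
  vapply(model$rules, function(r) drop(Phi %*% r$coef),
         numeric(nrow(Xs)))
}

fis_rmse <- function(model, Xs, y) {
  W <- norm_firing(log_firing(model, Xs))
  F <- rule_outputs(model, Xs)
  if (is.null(dim(F))) F <- matrix(F, nrow = 1)
  sqrt(mean((rowSums(W * F) - y)^2))
}

## Global least-squares estimate of all rule consequents with premises frozen.
## Design is the n x c(d+1) matrix of firing-weighted [1, x] blocks; rank
## deficiency falls back to the minimum-norm pseudo-solution.
lse_consequents <- function(model, Xs, y) {
  n <- nrow(Xs); d <- ncol(Xs); c <- length(model$rules)
  W <- norm_firing(log_firing(model, Xs))
  Phi <- cbind(1, Xs)
  A <- matrix(0, n, c * (d + 1))
  for (k in seq_len(c))
    A[, ((k - 1) * (d + 1) + 1):(k * (d + 1))] <- W[, k] * Phi
  qr_A <- qr(A)
  theta <- if (qr_A$rank < ncol(A)) {
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  } else qr.coef(qr_A, y)
  theta <- drop(theta)
  for (k in seq_len(c))
    model$rules[[k]]$coef <- theta[((k - 1) * (d + 1) + 1):(k * (d + 1))]
  model$lse_rank <- qr_A$rank
  model
}

## ---- construction -----------------------------------------------------------

#' Initialise a fuzzy inference system from an FCM partition
#'
#' One Takagi--Sugeno rule per cluster: Gaussian premise centers are the
#' cluster centers (projected onto the input dimensions when clustering ran on
#' the joint input--output space), premise widths are the membership-weighted
#' within-cluster standard deviations (floored to stay strictly positive), and
#' consequents are solved by one global least-squares pass.
#'
#' Clusters with negligible total membership are dropped with a warning.
#'
#' @param X numeric input matrix (already on the scale clustering used).
#' @param y numeric target vector (mm3).
#' @param fcm an [fcm_cluster()] result computed on `X` or on `cbind(X, y)`.
#' @param input_names feature names to bind to the model.
#' @return An object of class `fis_model`.
#' @export
init_fis_from_fcm <- function(X, y, fcm, input_names = colnames(X)) {
  stopifnot(inherits(fcm, "fcm_result"))
  X <- as.matrix(X)
  d <- ncol(X)
  U <- fcm$memberships
  Um <- U^fcm$m
  tot <- colSums(Um)
  keep <- tot > 1e-8 * sum(tot)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " degenerate (empty) cluster(s)")
    U <- U[, keep, drop = FALSE]
    Um <- Um[, keep, drop = FALSE]
    tot <- tot[keep]
  }
  centers <- fcm$centers[keep, seq_len(d), drop = FALSE]

  sd_floor <- pmax(0.05 * apply(X, 2, stats::sd), 1e-6)
  rules <- lapply(seq_len(nrow(centers)), function(k) {
    dev2 <- sweep(X, 2, centers[k, ])^2
    sig <- sqrt(colSums(Um[, k] * dev2) / tot[k])
    sig <- pmax(sig, sd_floor)
    list(center = unname(centers[k, ]), sigma = unname(sig),
         coef = rep(0, d + 1))
  })
  model <- structure(list(rules = rules, input_names = input_names,
                          scaler = NULL, fuzziness = fcm$m),
                     class = "fis_model")
  lse_consequents(model, X, y)
}

#' Evaluate a fuzzy inference system
#'
#' Standard first-order Takagi--Sugeno inference: each rule's firing strength
#' is the product over inputs of its Gaussian memberships; the output is the
#' firing-strength-weighted average of the rules' linear consequents, weights
#' normalised to sum to one. Strengths are max-shifted in log space, so the
#' nearest rule always fires even when all raw products underflow.
#'
#' @param model a `fis_model`.
#' @param X numeric matrix (rows = observations) or a single d-vector, on the
#'   raw input scale; the model's fitted scaler is applied internally.
#' @return Numeric vector of predicted volumes (mm3).
#' @export
evaluate_fis <- function(model, X) {
  stopifnot(inherits(model, "fis_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  d <- length(model$rules[[1]]$center)
  if (ncol(X) != d) stopf("input has %d columns, model expects %d", ncol(X), d)
  if (!all(is.finite(X))) stopf("inputs must be finite")
  Xs <- apply_scaler(X, model$scaler)
  W <- norm_firing(log_firing(model, Xs))
  F <- rule_outputs(model, Xs)
  if (is.null(dim(F))) F <- matrix(F, nrow = nrow(Xs))
  drop(rowSums(W * F))
}

#' @export
predict.fis_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix"))
    newdata <- newdata$X[, canonical_features(newdata, object$input_names),
                         drop = FALSE]
  evaluate_fis(object, newdata)
}

#' @export
print.fis_model <- function(x, ...) {
  cat(sprintf("fis_model: %d rule(s), %d input(s): %s\n", length(x$rules),
              length(x$rules[[1]]$center),
              paste(x$input_names, collapse = ", ")))
  invisible(x)
}

## ---- training ---------------------------------------------------------------

#' Training configuration for the hybrid learner
#'
#' @param epochs hybrid epochs (each: one least-squares pass over consequents,
#'   one gradient pass over premises); 0 returns the model untouched.
#' @param learn_rate initial premise step size (on z-scored inputs); halved
#'   whenever a step would increase training error.
#' @param tol stop when the epoch-to-epoch RMSE improvement falls below this.
#' @param seed integer seed (FCM initialisation and any internal splits).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, learn_rate = 0.01, tol = 1e-10,
                         seed = 1L) {
  stopifnot(epochs >= 0, learn_rate > 0, tol >= 0)
  structure(list(epochs = as.integer(epochs), learn_rate = learn_rate,
                 tol = tol, seed = as.integer(seed)),
            class = "train_config")
}

#' Hybrid training of a Takagi--Sugeno system
#'
#' Per epoch: (pass 1) all rule consequents are re-solved globally by linear
#' least squares with the premises frozen — optimal given the premises, so the
#' training RMSE after this pass never exceeds the RMSE before it; (pass 2)
#' premise centers and widths take one gradient-descent step on the squared
#' error, with the step rejected (and the rate halved) if it would increase
#' the error. The RMSE recorded after each least-squares pass is therefore
#' non-increasing across epochs.
#'
#' @param model an initialised `fis_model` (see [init_fis_from_fcm()]).
#' @param X training inputs on the scale the model was initialised with.
#' @param y training target (mm3).
#' @param cfg a [train_config()].
#' @return The trained `fis_model`, with an `rmse_trace` attribute (one entry
#'   per least-squares pass).
#' @export
train_hybrid <- function(model, X, y, cfg = train_config()) {
  stopifnot(inherits(model, "fis_model"))
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stopf("data must be finite")
  if (cfg$epochs == 0L) return(model)
  d <- ncol(X)
  lr <- cfg$learn_rate
  trace <- numeric(0)
  prev <- Inf
  for (ep in seq_len(cfg$epochs)) {
    ## pass 1: consequents by global LSE
    model <- lse_consequents(model, X, y)
    rmse <- fis_rmse(model, X, y)
    trace <- c(trace, rmse)
    if (prev - rmse < cfg$tol && ep > 1) break
    prev <- rmse

    ## pass 2: one guarded gradient step on premise centers and widths
    L <- log_firing(model, X)
    W <- norm_firing(L)
    F <- rule_outputs(model, X)
    yhat <- rowSums(W * F)
    e <- yhat - y
    scale_e <- stats::sd(y) + 1e-12
    old_rules <- model$rules
    for (k in seq_along(model$rules)) {
      r <- model$rules[[k]]
      ## d yhat_i / d theta_k = W_ik (F_ik - yhat_i) * d log w_ik / d theta_k
      gk <- W[, k] * (F[, k] - yhat) * e / scale_e^2
      dev <- sweep(X, 2, r$center)
      grad_c <- colSums(gk * sweep(dev, 2, r$sigma^2, "/")) * 2 / nrow(X)
      grad_s <- colSums(gk * sweep(dev^2, 2, r$sigma^3, "/")) * 2 / nrow(X)
      r$center <- r$center - lr * grad_c
      r$sigma <- pmax(r$sigma - lr * grad_s, 1e-6)
      model$rules[[k]] <- r
    }
    if (fis_rmse(model, X, y) > rmse) {
      model$rules <- old_rules
      lr <- lr / 2
    }
  }
  attr(model, "rmse_trace") <- trace
  model
}

## ---- the user-facing fit ---------------------------------------------------

#' Fit an ANFIS-FCM regressor
#'
#' The full predictor: inputs are z-scored with statistics of the supplied
#' (training) data, fuzzy c-means runs on the joint input--output space to
#' induce one rule per cluster (premises projected onto the inputs), and
#' hybrid learning refines the system. When `n_rules` is `NULL` the rule count
#' is chosen from `candidates` by held-out error on an internal 70/30 split,
#' then the winning count is refit on all supplied rows.
#'
#' @param X numeric input matrix with named columns, or a `feature_matrix`
#'   (with `features` naming the columns to use).
#' @param y numeric target (mm3); taken from the `feature_matrix` if omitted.
#' @param features character vector of feature names when `X` is a
#'   `feature_matrix`.
#' @param n_rules number of rules, or `NULL` to select from `candidates`.
#' @param candidates rule counts tried when `n_rules` is `NULL`.
#' @param fuzziness FCM fuzziness exponent, `> 1`.
#' @param cfg a [train_config()].
#' @param normalize z-score inputs (recommended: Gaussian premises need
#'   comparable scales).
#' @param cluster_space `"joint"` (cluster on inputs and target, the usual
#'   ANFIS-FCM practice) or `"input"`.
#' @return A trained `fis_model`.
#' @export
#' @examples
#' fm <- build_features(generate_cohort(cohort_spec(n_subjects = 120, seed = 3)))
#' mod <- anfis_fcm(fm, features = c("gender", "bmi"), n_rules = 2,
#'                  cfg = train_config(epochs = 5))
#' head(predict(mod, fm))
anfis_fcm <- function(X, y = NULL, features = NULL, n_rules = NULL,
                      candidates = 2:5, fuzziness = 2,
                      cfg = train_config(), normalize = TRUE,
                      cluster_space = c("joint", "input")) {
  cluster_space <- match.arg(cluster_space)
  if (inherits(X, "feature_matrix")) {
    if (is.null(features)) stopf("supply `features` with a feature_matrix")
    features <- canonical_features(X, features)
    if (is.null(y)) y <- X$target
    X <- X$X[, features, drop = FALSE]
  }
  X <- as.matrix(X)
  input_names <- colnames(X) %||% paste0("x", seq_len(ncol(X)))

  if (is.null(n_rules)) {
    n <- nrow(X)
    idx <- with_seed(derive_seed(cfg$seed, 101L),
                     sample.int(n, size = floor(0.7 * n)))
    errs <- vapply(candidates, function(c) {
      m <- fit_anfis_fixed(X[idx, , drop = FALSE], y[idx], c, fuzziness, cfg,
                           normalize, cluster_space, input_names)
      sqrt(mean((evaluate_fis(m, X[-idx, , drop = FALSE]) - y[-idx])^2))
    }, numeric(1))
    n_rules <- candidates[which.min(errs)]
  }
  fit_anfis_fixed(X, y, n_rules, fuzziness, cfg, normalize, cluster_space,
                  input_names)
}

fit_anfis_fixed <- function(X, y, n_rules, fuzziness, cfg, normalize,
                            cluster_space, input_names) {
  scaler <- if (normalize) fit_scaler(X) else NULL
  Xs <- apply_scaler(X, scaler)
  ys <- (y - mean(y)) / (stats::sd(y) + 1e-12)
  Z <- if (cluster_space == "joint") cbind(Xs, ys) else Xs
  fcm <- fcm_cluster(Z, c = min(n_rules, nrow(Xs)), m = fuzziness,
                     seed = derive_seed(cfg$seed, 7L, n_rules))
  model <- init_fis_from_fcm(Xs, y, fcm, input_names = input_names)
  model <- train_hybrid(model, Xs, y, cfg)
  model$scaler <- scaler
  model
}

## ---- serialization ---------------------------------------------------------

#' Serialize / restore a fuzzy inference system as JSON
#'
#' The JSON rule base (premise Gaussians, consequent coefficients, scaler,
#' input names) is the portable "pseudocode" artifact: a round-trip through
#' disk reproduces predictions bit-for-bit at double precision.
#'
#' @param model a `fis_model`.
#' @param path file path.
#' @return `read_fis()` returns the restored `fis_model`; `write_fis()`
#'   returns `path` invisibly.
#' @export
write_fis <- function(model, path) {
  stopifnot(inherits(model, "fis_model"))
  payload <- list(
    format = "ipfpfis-fis/1",
    input_names = model$input_names,
    fuzziness = model$fuzziness,
    scaler = model$scaler,
    rules = lapply(model$rules, function(r)
      list(center = r$center, sigma = r$sigma, coef = r$coef))
  )
  ## 17 significant digits: doubles survive the text round-trip bit-for-bit
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fis
#' @export
read_fis <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ipfpfis-fis/1")) stopf("unrecognised FIS file")
  rules <- if (is.data.frame(p$rules)) {
    lapply(seq_len(nrow(p$rules)), function(k)
      list(center = p$rules$center[[k]], sigma = p$rules$sigma[[k]],
           coef = p$rules$coef[[k]]))
  } else {
    lapply(p$rules, function(r)
      list(center = unlist(r$center), sigma = unlist(r$sigma),
           coef = unlist(r$coef)))
  }
  scaler <- if (is.null(p$scaler)) NULL else
    list(center = unlist(p$scaler$center), scale = unlist(p$scaler$scale))
  structure(list(rules = rules, input_names = p$input_names,
                 scaler = scaler, fuzziness = p$fuzziness),
            class = "fis_model")
}
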