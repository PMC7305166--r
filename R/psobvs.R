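#' @name psobvs
#' @title PSO-based variable selection (PSOBVS)
#' @description
#' Wrapper feature selection over the 48-column design: particles carry
#' continuous per-feature scores decoded to exact size-M subsets, the fitness
#' is the weighted train/test error of a fast surrogate regressor under
#' k-fold cross-validation, Monte-Carlo repetition over independent resplits
#' measures selection stability, and AIC across subset sizes picks the
#' winning model size.
NULL

#' Swarm / selection configuration
#'
#' Defaults are the standard global-best PSO values: swarm 30, 100 iterations,
#' inertia decaying linearly 0.9 to 0.4, cognitive and social constants 2.0,
#' velocity clamped at +/-4. The wrapper error is the 0.7/0.3 weighted
#' train/test RMSE (weights proportional to the split percentages) averaged
#' over k = 4 cross-validation folds.
#'
#' @param swarm_size particles per swarm.
#' @param iterations PSO iterations.
#' @param inertia two-element numeric, linear schedule start/end.
#' @param c1,c2 cognitive and social acceleration constants.
#' @param v_clamp velocity bound (absolute).
#' @param restart_after reinitialise all but the best particle after this many
#'   iterations without global-best improvement (counters premature
#'   convergence in the large subset lattice); `Inf` disables.
#' @param n_starts independent swarm starts per search (fitness cache shared;
#'   the best subset across starts is returned).
#' @param mc_repeats Monte-Carlo resplit repetitions.
#' @param train_weight,test_weight positive error weights; normalised to sum 1.
#' @param k_folds cross-validation folds, `>= 2`.
#' @param surrogate `"ridge"` (fast closed form, default) or `"ann"` (small
#'   single-hidden-layer network via \pkg{nnet}).
#' @param hidden,decay ANN surrogate size and weight decay.
#' @param ridge_lambda ridge penalty on per-column scale; 0 (the default) is
#'   plain least squares with a pseudo-inverse guard for singular systems.
#' @param seed master seed; every resplit, swarm init and surrogate init is
#'   derived from it.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(swarm_size = 30L, iterations = 100L,
                         inertia = c(0.9, 0.4), c1 = 2, c2 = 2, v_clamp = 4,
                         restart_after = 15L, n_starts = 3L, mc_repeats = 10L, train_weight = 0.7,
                         test_weight = 0.3, k_folds = 4L,
                         surrogate = c("ridge", "ann"), hidden = 8L,
                         decay = 1e-3, ridge_lambda = 0, seed = 1L) {
  surrogate <- match.arg(surrogate)
  if (swarm_size < 1 || iterations < 0) stopf("swarm_size >= 1, iterations >= 0")
  if (train_weight <= 0 || test_weight <= 0) stopf("error weights must be positive")
  if (k_folds < 2) stopf("k_folds must be >= 2")
  w <- c(train_weight, test_weight) / (train_weight + test_weight)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, c1 = c1, c2 = c2, v_clamp = v_clamp,
                 restart_after = restart_after, n_starts = as.integer(n_starts),
                 mc_repeats = as.integer(mc_repeats),
                 train_weight = w[1], test_weight = w[2],
                 k_folds = as.integer(k_folds), surrogate = surrogate,
                 hidden = as.integer(hidden), decay = decay,
                 ridge_lambda = ridge_lambda, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Decode a particle's continuous scores to a feature subset
#'
#' The `M` features with the highest scores, ties broken by canonical feature
#' order (the order of `names`); deterministic.
#'
#' @param position numeric vector of per-feature scores.
#' @param M subset size.
#' @param names feature names aligned with `position`.
#' @return Character vector: the decoded subset, in canonical order.
#' @export
decode_particle <- function(position, M, names) {
  if (!all(is.finite(position))) stopf("scores must be finite")
  if (M > length(position)) stopf("M exceeds the number of features")
  idx <- order(-position, seq_along(position))[seq_len(M)]
  names[sort(idx)]
}

#' Seeded k-fold partition
#'
#' Random disjoint folds covering `0 < i <= n` with sizes differing by at most
#' one; every index is a test index exactly once across the k rounds.
#'
#' @param n sample count.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed integer seed.
#' @return A list of `k` integer index vectors.
#' @export
kfold_split <- function(n, k, seed = 1L) {
  if (k < 2) stopf("k must be >= 2")
  if (k > n) stopf("k must not exceed n")
  perm <- with_seed(seed, sample.int(n))
  split(perm, rep_len(seq_len(k), n))
}

## ---- surrogate regressors ---------------------------------------------------

## The ridge surrogate is solved from per-fold Gram matrices: with the
## intercept-augmented design X1 = [1, X], the coefficients for any feature
## subset s come from G[s,s] and b[s] where G = X1'X1 and b = X1'y over the
## fold's training rows. The small ridge penalty (intercept unpenalised, on
## per-column scale) is a conditioning guard; residuals are then computed
## directly so realisable targets score ~0 without cancellation error.
prepare_fold_stats <- function(X1, y, folds, lambda) {
  col_scale <- diag(crossprod(X1)) / nrow(X1)
  lapply(folds, function(te) {
    tr <- setdiff(seq_len(nrow(X1)), te)
    Xtr <- X1[tr, , drop = FALSE]
    list(tr = tr, te = te,
         G = crossprod(Xtr),
         b = drop(crossprod(Xtr, y[tr])),
         pen = lambda * c(0, col_scale[-1]))
  })
}

ridge_beta <- function(fs, idx) {
  A <- fs$G[idx, idx, drop = FALSE] + diag(fs$pen[idx], length(idx))
  tryCatch(solve(A, fs$b[idx]), error = function(e) {
    s <- svd(A); pos <- s$d > max(s$d) * 1e-10
    drop(s$v[, pos, drop = FALSE] %*%
           ((t(s$u[, pos, drop = FALSE]) %*% fs$b[idx]) / s$d[pos]))
  })
}

fit_ann <- function(X, y, cfg, seed) {
  with_seed(seed,
    nnet::nnet(X, y / stats::sd(y), size = cfg$hidden, decay = cfg$decay,
               linout = TRUE, maxit = 200, trace = FALSE))
}

## ---- fitness ----------------------------------------------------------------

#' Wrapper fitness of a feature subset
#'
#' Fits the surrogate regressor on each cross-validation training fold
#' restricted to the subset and scores
#' `train_weight * RMSE_train + test_weight * RMSE_test`, averaged over the
#' `k_folds` rounds. Deterministic given the config seed (which fixes the
#' folds). Invariant to the order of the subset's names. Degenerate fits
#' (constant target, singular systems) return a large penalty fitness.
#'
#' @param subset character vector of feature names.
#' @param data a list with `X` (numeric matrix with named columns) and `y`,
#'   or a `feature_matrix`.
#' @param cfg a [swarm_config()].
#' @param folds optional precomputed [kfold_split()]; derived from `cfg$seed`
#'   otherwise.
#' @return The weighted error (numeric scalar).
#' @export
fitness <- function(subset, data, cfg = swarm_config(), folds = NULL) {
  data <- as_selection_data(data)
  if (length(subset) == 0L) stopf("subset must be non-empty")
  if (stats::sd(data$y) < 1e-12) return(1e12)
  folds <- folds %||% kfold_split(length(data$y), cfg$k_folds,
                                  derive_seed(cfg$seed, 11L))
  sub_idx <- match(subset, colnames(data$X))
  if (anyNA(sub_idx)) stopf("unknown feature(s): %s",
                            paste(subset[is.na(sub_idx)], collapse = ", "))
  fold_stats <- if (cfg$surrogate == "ridge")
    prepare_fold_stats(data$X1, data$y, folds, cfg$ridge_lambda) else NULL
  subset_cv(data, sub_idx, cfg, folds, fold_stats)[["fit"]]
}

as_selection_data <- function(data) {
  if (inherits(data, "feature_matrix"))
    data <- list(X = data$X, y = data$target)
  stopifnot(is.list(data), !is.null(data$X), !is.null(data$y))
  if (is.null(data$X1))
    data$X1 <- cbind(`(Intercept)` = 1, data$X)
  data
}

## Weighted train/test CV error and out-of-fold SSE for one column subset.
## The OOF SSE is what AIC scores, so the subset-search winner's fit is
## measured on rows it did not train on.
subset_cv <- function(data, sub_idx, cfg, folds, fold_stats = NULL) {
  y <- data$y
  werr <- 0
  sse <- 0
  for (i in seq_along(folds)) {
    if (cfg$surrogate == "ridge") {
      fs <- fold_stats[[i]]
      idx <- c(1L, sub_idx + 1L)
      beta <- ridge_beta(fs, idx)
      pred <- drop(data$X1[, idx, drop = FALSE] %*% beta)
      rtr <- sqrt(mean((pred[fs$tr] - y[fs$tr])^2))
      res_te <- pred[fs$te] - y[fs$te]
    } else {
      te <- folds[[i]]
      Xs <- data$X[, sub_idx, drop = FALSE]
      fit <- tryCatch(
        fit_ann(Xs[-te, , drop = FALSE], y[-te], cfg,
                derive_seed(cfg$seed, 13L, i)),
        error = function(e) NULL)
      if (is.null(fit)) return(c(fit = 1e12, sse = Inf))
      sc <- stats::sd(y[-te])
      rtr <- sqrt(mean((drop(stats::predict(fit, Xs[-te, , drop = FALSE])) * sc -
                          y[-te])^2))
      res_te <- drop(stats::predict(fit, Xs[te, , drop = FALSE])) * sc - y[te]
    }
    rte <- sqrt(mean(res_te^2))
    werr <- werr + cfg$train_weight * rtr + cfg$test_weight * rte
    sse <- sse + sum(res_te^2)
  }
  c(fit = werr / length(folds), sse = sse)
}

## ---- the swarm --------------------------------------------------------------

#' Global-best PSO over size-M feature subsets
#'
#' Standard continuous PSO (`v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`)
#' on per-feature scores, decoded by [decode_particle()] to exact size-`M`
#' subsets. Fitness values are memoised per subset within the search. The
#' global best fitness is non-increasing across iterations by construction.
#'
#' @param data selection data (see [fitness()]).
#' @param M subset size.
#' @param cfg a [swarm_config()].
#' @param folds optional precomputed folds shared across calls.
#' @param seed seed for this search (defaults to `cfg$seed`).
#' @return List of class `pso_result`: `subset`, `fitness`, `history`
#'   (gbest fitness per iteration), `evaluations` (unique subsets scored).
#' @export
pso_search <- function(data, M, cfg = swarm_config(), folds = NULL,
                       seed = cfg$seed) {
  data <- as_selection_data(data)
  d <- ncol(data$X)
  if (M > d) stopf("M exceeds the number of candidate features")
  nm <- colnames(data$X)
  folds <- folds %||% kfold_split(length(data$y), cfg$k_folds,
                                  derive_seed(cfg$seed, 11L))
  fold_stats <- if (cfg$surrogate == "ridge")
    prepare_fold_stats(data$X1, data$y, folds, cfg$ridge_lambda) else NULL

  cache <- new.env(parent = emptyenv())
  score <- function(subset) {
    key <- paste(subset, collapse = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- subset_cv(data, match(subset, colnames(data$X)), cfg, folds,
                     fold_stats)[["fit"]]
    cache[[key]] <- val
    val
  }

  one_start <- function() {
    P <- matrix(stats::runif(cfg$swarm_size * d, -1, 1), cfg$swarm_size, d)
    V <- matrix(stats::runif(cfg$swarm_size * d, -0.5, 0.5), cfg$swarm_size, d)
    pbest <- P
    pfit <- apply(P, 1, function(p) score(decode_particle(p, M, nm)))
    g <- which.min(pfit)
    gbest <- P[g, ]; gfit <- pfit[g]
    history <- gfit
    stall <- 0L
    if (cfg$iterations > 0) for (it in seq_len(cfg$iterations)) {
      w <- cfg$inertia[1] +
        (cfg$inertia[2] - cfg$inertia[1]) * (it - 1) / max(cfg$iterations - 1, 1)
      r1 <- matrix(stats::runif(cfg$swarm_size * d), cfg$swarm_size, d)
      r2 <- matrix(stats::runif(cfg$swarm_size * d), cfg$swarm_size, d)
      V <- w * V + cfg$c1 * r1 * (pbest - P) +
        cfg$c2 * r2 * matrix(gbest, cfg$swarm_size, d, byrow = TRUE) -
        cfg$c2 * r2 * P
      V <- pmin(pmax(V, -cfg$v_clamp), cfg$v_clamp)
      P <- P + V
      f <- apply(P, 1, function(p) score(decode_particle(p, M, nm)))
      upd <- f < pfit
      pbest[upd, ] <- P[upd, , drop = FALSE]
      pfit[upd] <- f[upd]
      if (min(pfit) < gfit) {
        g <- which.min(pfit); gbest <- pbest[g, ]; gfit <- pfit[g]
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= cfg$restart_after && it < cfg$iterations) {
        ## scatter every particle except the incumbent; personal memories of
        ## the scattered particles are reset so they explore afresh
        keep <- which.min(pfit)
        idx <- setdiff(seq_len(cfg$swarm_size), keep)
        P[idx, ] <- stats::runif(length(idx) * d, -1, 1)
        V[idx, ] <- stats::runif(length(idx) * d, -0.5, 0.5)
        pbest[idx, ] <- P[idx, , drop = FALSE]
        pfit[idx] <- apply(P[idx, , drop = FALSE], 1,
                           function(p) score(decode_particle(p, M, nm)))
        if (min(pfit) < gfit) {
          g <- which.min(pfit); gbest <- pbest[g, ]; gfit <- pfit[g]
        }
        stall <- 0L
      }
      history <- c(history, gfit)
    }
    list(position = gbest, fitness = gfit, history = history)
  }

  with_seed(seed, {
    n_starts <- max(cfg$n_starts %||% 1L, 1L)
    best <- NULL
    history <- numeric(0)
    for (s in seq_len(n_starts)) {
      run <- one_start()
      if (is.null(best) || run$fitness < best$fitness) best <- run
      ## running best across starts, so the reported trace stays monotone
      prior <- if (length(history)) history[length(history)] else Inf
      history <- c(history, pmin(run$history, prior))
    }
    structure(list(subset = decode_particle(best$position, M, nm),
                   fitness = best$fitness,
                   history = history,
                   evaluations = length(ls(cache))),
              class = "pso_result")
  })
}

#' Monte-Carlo selection at one subset size
#'
#' Repeats [pso_search()] over `mc_repeats` independent cross-validation
#' resplits (fresh fold seeds derived from the master seed), records each
#' feature's selection frequency, and returns the modal subset (ties broken by
#' best mean fitness). The returned AIC scores the final subset's out-of-fold
#' SSE under a seed-fixed split, with `p = M + 1` parameters.
#'
#' @param data selection data.
#' @param M subset size.
#' @param cfg a [swarm_config()].
#' @return List of class `mc_selection`: `subset`, `fitness`, `aic`,
#'   `frequency` (named, per feature), `runs` (per-repeat subsets/fitness).
#' @export
monte_carlo_select <- function(data, M, cfg = swarm_config()) {
  data <- as_selection_data(data)
  if (cfg$mc_repeats < 1) stopf("mc_repeats must be >= 1")
  n <- length(data$y)
  runs <- lapply(seq_len(cfg$mc_repeats), function(r) {
    folds <- kfold_split(n, cfg$k_folds, derive_seed(cfg$seed, 17L, r, M))
    pso_search(data, M, cfg, folds = folds,
               seed = derive_seed(cfg$seed, 19L, r, M))
  })
  subsets <- lapply(runs, `[[`, "subset")
  fits <- vapply(runs, `[[`, numeric(1), "fitness")

  keys <- vapply(subsets, paste, character(1), collapse = "\r")
  tab <- table(keys)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    mean_fit <- vapply(top, function(k) mean(fits[keys == k]), numeric(1))
    top <- top[which.min(mean_fit)]
  }
  final <- strsplit(top, "\r", fixed = TRUE)[[1]]

  freq <- vapply(colnames(data$X), function(f)
    mean(vapply(subsets, function(s) f %in% s, logical(1))), numeric(1))

  folds0 <- kfold_split(n, cfg$k_folds, derive_seed(cfg$seed, 23L, M))
  fold_stats0 <- if (cfg$surrogate == "ridge")
    prepare_fold_stats(data$X1, data$y, folds0, cfg$ridge_lambda) else NULL
  sse <- subset_cv(data, match(final, colnames(data$X)), cfg, folds0,
                   fold_stats0)[["sse"]]
  structure(list(subset = final, M = M,
                 fitness = mean(fits[keys == top]),
                 aic = aic_score(n, sse, length(final) + 1L),
                 frequency = freq, runs = list(subsets = subsets, fitness = fits)),
            class = "mc_selection")
}

#' Akaike information criterion for a least-squares model
#'
#' `AIC = n log(sse / n) + 2 p`, with `p` counting the selected variables plus
#' the intercept. Lower is better; two models with equal SSE and one extra
#' parameter differ by exactly 2.
#'
#' @param n sample count, `> 0`.
#' @param sse sum of squared errors, `> 0` (non-positive SSE returns `-Inf`
#'   with a warning — a degenerate perfect fit).
#' @param p parameter count.
#' @return The AIC value.
#' @export
aic_score <- function(n, sse, p) {
  if (n <= 0) stopf("n must be positive")
  if (sse <= 0) {
    warning("non-positive SSE: AIC is -Inf (degenerate perfect fit)")
    return(-Inf)
  }
  n * log(sse / n) + 2 * p
}

#' Run Monte-Carlo selection across subset sizes and pick the AIC winner
#'
#' One [monte_carlo_select()] per size; the winner is the size with the lowest
#' AIC ("lowest AIC is the best model").
#'
#' With `holdout > 0` (the default) a seeded fraction of the rows is set aside
#' before any searching; selection runs on the remaining rows only, each
#' size's final subset is then fit by least squares on the selection rows, and
#' the AIC compares sizes on the held-out residual SSE. This matters: the
#' swarm examines so many subsets that the best extra feature at each size has
#' an inflated in-sample fit, and any SSE measured on rows the search could
#' see systematically rewards one size too many. Rows the search never saw
#' restore the penalty's meaning. `holdout = 0` scores the out-of-fold CV SSE
#' instead (all rows available to the search).
#'
#' @param data selection data.
#' @param sizes integer vector of subset sizes to search.
#' @param cfg a [swarm_config()].
#' @param holdout fraction of rows reserved for AIC scoring, in [0, 0.5].
#' @return List of class `selection_result`: `by_size` (one `mc_selection`
#'   per size), `aic` (named vector used for the choice), `winner` (the
#'   minimum-AIC entry), `holdout_idx` (the scoring rows, if any).
#' @export
select_subsets <- function(data, sizes, cfg = swarm_config(), holdout = 0.3) {
  data <- as_selection_data(data)
  if (holdout < 0 || holdout > 0.5) stopf("holdout must lie in [0, 0.5]")
  n <- length(data$y)
  score_idx <- integer(0)
  sel_data <- data
  if (holdout > 0) {
    score_idx <- with_seed(derive_seed(cfg$seed, 29L),
                           sort(sample.int(n, size = round(holdout * n))))
    sel_rows <- setdiff(seq_len(n), score_idx)
    sel_data <- list(X = data$X[sel_rows, , drop = FALSE],
                     y = data$y[sel_rows])
    sel_data <- as_selection_data(sel_data)
  }
  by_size <- lapply(sizes, function(M) monte_carlo_select(sel_data, M, cfg))
  names(by_size) <- paste0("M", sizes)

  aics <- if (holdout > 0) {
    vapply(by_size, function(entry) {
      s <- entry$subset
      sel_rows <- setdiff(seq_len(n), score_idx)
      fit <- stats::lm.fit(cbind(1, data$X[sel_rows, s, drop = FALSE]),
                           data$y[sel_rows])
      coefs <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- drop(cbind(1, data$X[score_idx, s, drop = FALSE]) %*% coefs)
      aic_score(length(score_idx), sum((data$y[score_idx] - pred)^2),
                length(s) + 1L)
    }, numeric(1))
  } else vapply(by_size, `[[`, numeric(1), "aic")
  for (i in seq_along(by_size)) by_size[[i]]$aic <- aics[[i]]

  structure(list(by_size = by_size, sizes = sizes, aic = aics,
                 winner = by_size[[which.min(aics)]],
                 holdout_idx = score_idx),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("PSOBVS selection result\n")
  for (i in seq_along(x$sizes))
    cat(sprintf("  M=%2d  AIC=%10.2f  fitness=%10.4f  {%s}\n",
                x$sizes[i], x$aic[i], x$by_size[[i]]$fitness,
                paste(x$by_size[[i]]$subset, collapse = ", ")))
  cat(sprintf("  winner: M=%d (lowest AIC)\n", x$winner$M))
  invisible(x)
}
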