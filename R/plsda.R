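#' Auto-scale a data matrix
#'
#' Mean-centers each column and divides by its sample (n-1) standard
#' deviation — the only scaling applied ahead of PLS-DA. Constant columns
#' cannot be scaled and are dropped with a warning.
#'
#' @param x numeric matrix (samples x variables).
#' @return list with `x` (scaled matrix), `center`, `scale`, and `dropped`
#'   (ids of constant columns).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  keep <- is.finite(scl) & scl > 0
  if (!any(keep)) stop("all columns are constant; nothing to scale", call. = FALSE)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
  }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], `/`)
  list(x = xs, center = ctr[keep], scale = scl[keep],
       dropped = colnames(x)[!keep])
}

.encode_classes <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2) stop("exactly two classes are required", call. = FALSE)
  list(levels = levels(f), y = ifelse(as.integer(f) == 2L, 1, -1))
}

#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' NIPALS partial least squares regression on the +/-1-encoded class
#' response with X-deflation per component; class prediction is the sign of
#' the regression score. `x` is expected to be auto-scaled (see
#' [autoscale()]); the response is centered internally.
#'
#' @param x scaled numeric matrix (samples x variables).
#' @param y two-class factor/vector, one entry per row of `x`.
#' @param ncomp number of latent components.
#' @return object of class `plsda_model`: weights `W`, X-loadings `P`,
#'   response loadings `q`, scores `T`, regression coefficients per
#'   component count `B` (p x ncomp), cumulative `R2Y`, training accuracy,
#'   class `levels`.
#' @export
fit_plsda <- function(x, y, ncomp = 2) {
  x <- as.matrix(x)
  enc <- .encode_classes(y)
  if (min(table(enc$y)) < ncomp + 1) {
    stop("each class needs at least ncomp + 1 samples", call. = FALSE)
  }
  if (ncomp > min(nrow(x) - 1, ncol(x))) {
    stop("ncomp exceeds the rank of x", call. = FALSE)
  }
  n <- nrow(x); p <- ncol(x)
  f <- enc$y - mean(enc$y)
  e <- x
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  ssy <- sum(f^2)
  r2y <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    wv <- drop(crossprod(e, f))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) stop("residual X carries no covariance with y at component ", h,
                         call. = FALSE)
    wv <- wv / nw
    tv <- drop(e %*% wv)
    tt <- sum(tv^2)
    pv <- drop(crossprod(e, tv)) / tt
    qh <- sum(f * tv) / tt
    e <- e - tcrossprod(tv, pv)
    f <- f - qh * tv
    W[, h] <- wv; P[, h] <- pv; Tm[, h] <- tv; q[h] <- qh
    r2y[h] <- 1 - sum(f^2) / ssy
  }
  ## coefficients for every truncation 1..ncomp
  B <- matrix(0, p, ncomp)
  for (h in seq_len(ncomp)) {
    Wh <- W[, seq_len(h), drop = FALSE]
    Ph <- P[, seq_len(h), drop = FALSE]
    B[, h] <- Wh %*% solve(crossprod(Ph, Wh), q[seq_len(h)])
  }
  dimnames(B) <- list(colnames(x), NULL)
  model <- structure(list(
    ncomp = ncomp, W = W, P = P, q = q, scores = Tm, B = B,
    y_mean = mean(enc$y), levels = enc$levels,
    R2Y = r2y), class = "plsda_model")
  model$accuracy <- mean(predict(model, x) == enc$levels[(enc$y > 0) + 1])
  model
}

#' Predict classes or scores from a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata matrix on the same (scaled) variable space as training.
#' @param type `"class"` (default) or `"score"` (continuous regression score).
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @export
predict.plsda_model <- function(object, newdata, type = c("class", "score"),
                                ncomp = NULL, ...) {
  type <- match.arg(type)
  ncomp <- ncomp %||% object$ncomp
  yhat <- object$y_mean + drop(as.matrix(newdata) %*% object$B[, ncomp])
  if (type == "score") return(yhat)
  object$levels[(yhat > 0) + 1]
}

#' Cross-validated PLS-DA component selection
#'
#' Stratified k-fold cross-validation over component counts. Auto-scaling is
#' refit inside every training fold and applied to the held-out fold, so no
#' held-out information enters the scaling. Q2 = 1 - PRESS/TSS, with PRESS
#' pooled over folds and TSS measured against the training-fold response
#' mean; the chosen component count maximizes Q2.
#'
#' @param x unscaled numeric matrix (samples x variables).
#' @param y two-class response.
#' @param max_components largest component count to evaluate.
#' @param k number of folds (default 5).
#' @param seed integer controlling the fold shuffle (restored afterwards).
#' @return list with `table` (per-count accuracy, R2Y, Q2), `ncomp` (argmax
#'   Q2), `k`, `seed`.
#' @export
select_components_cv <- function(x, y, max_components = 3, k = 5, seed = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  enc <- .encode_classes(y)
  if (k > min(table(enc$y))) {
    stop("k exceeds the smallest class size", call. = FALSE)
  }
  folds <- with_seed(seed, {
    fold <- integer(nrow(x))
    for (cl in c(-1, 1)) {
      idx <- sample(which(enc$y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
  press <- tss <- numeric(max_components)
  correct <- numeric(max_components)
  for (fd in seq_len(k)) {
    tr <- folds != fd; te <- !tr
    sc <- suppressWarnings(autoscale(x[tr, , drop = FALSE]))
    xte <- sweep(sweep(x[te, colnames(sc$x), drop = FALSE], 2, sc$center),
                 2, sc$scale, `/`)
    fit <- fit_plsda(sc$x, enc$y[tr], ncomp = max_components)
    ytr_mean <- mean(enc$y[tr])
    for (h in seq_len(max_components)) {
      sc_te <- predict(fit, xte, type = "score", ncomp = h)
      press[h] <- press[h] + sum((enc$y[te] - sc_te)^2)
      tss[h] <- tss[h] + sum((enc$y[te] - ytr_mean)^2)
      correct[h] <- correct[h] + sum((sc_te > 0) == (enc$y[te] > 0))
    }
  }
  full <- fit_plsda(suppressWarnings(autoscale(x))$x, enc$y, ncomp = max_components)
  tab <- data.frame(ncomp = seq_len(max_components),
                    accuracy = correct / nrow(x),
                    R2Y = full$R2Y,
                    Q2 = 1 - press / tss)
  list(table = tab, ncomp = which.max(tab$Q2), k = k, seed = seed)
}

#' Permutation validation of a PLS-DA model
#'
#' Recomputes the model statistic under `B` random permutations of the class
#' labels and reports `p = (#{permuted >= observed} + 1) / (B + 1)`, whose
#' analytic floor is `1/(B+1)` (0.0005 at B = 2000 to within rounding). The
#' statistic is the cross-validated Q2 at the chosen component count by
#' default, or the cross-validated accuracy.
#'
#' @param x unscaled matrix; @param y two-class response.
#' @param B number of permutations (default 2000).
#' @param ncomp component count; default: chosen by [select_components_cv()].
#' @param statistic `"Q2"` (default) or `"accuracy"`.
#' @param k CV folds; @param seed RNG seed (restored afterwards).
#' @return object of class `permutation_report`: `B`, `statistic`,
#'   `observed`, `permuted` (length B), `p_value`, `ncomp`.
#' @export
permutation_test <- function(x, y, B = 2000, ncomp = NULL,
                             statistic = c("Q2", "accuracy"), k = 5, seed = 1) {
  statistic <- match.arg(statistic)
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  x <- as.matrix(x)
  obs_cv <- select_components_cv(x, y, max_components = ncomp %||% 3,
                                 k = k, seed = seed)
  if (is.null(ncomp)) ncomp <- obs_cv$ncomp
  observed <- if (statistic == "Q2") obs_cv$table$Q2[ncomp] else obs_cv$table$accuracy[ncomp]
  permuted <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      yp <- sample(as.vector(y))
      cv <- select_components_cv(x, yp, max_components = ncomp, k = k,
                                 seed = seed + b)
      if (statistic == "Q2") cv$table$Q2[ncomp] else cv$table$accuracy[ncomp]
    }, 0)
  })
  p <- (sum(permuted >= observed) + 1) / (B + 1)
  structure(list(B = B, statistic = statistic, observed = observed,
                 permuted = permuted, p_value = p, ncomp = ncomp),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("permutation test: %s = %.4f at %d component(s), B = %d, p = %.4g\n",
              x$statistic, x$observed, x$ncomp, x$B, x$p_value))
  invisible(x)
}
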