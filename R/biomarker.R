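#' Random discovery/validation split of patients
#'
#' Patients — not samples — are assigned uniformly at random to discovery
#' and validation sets at the requested ratio (4:1 by default), so a
#' patient's tumor and adjacent samples never straddle the sets. The
#' realized counts follow rounding of the exact ratio (80 patients at 4:1
#' give 64/16). Deterministic given the seed.
#'
#' @param samples sample metadata data.frame (paired tumor/adjacent rows).
#' @param ratio discovery:validation ratio as a single number (default 4).
#' @param seed integer seed (global RNG state is restored afterwards).
#' @return object of class `split_spec`: `assignment` (patient_id ->
#'   "discovery"/"validation"), `ratio`, `seed`.
#' @export
split_patients <- function(samples, ratio = 4, seed = 1) {
  tum <- samples$patient_id[samples$tissue_type == "tumor"]
  adj <- samples$patient_id[samples$tissue_type == "adjacent"]
  patients <- sort(intersect(tum, adj))
  n <- length(patients)
  if (n < 5) stop("need at least 5 paired patients to split", call. = FALSE)
  n_val <- round(n / (ratio + 1))
  val <- with_seed(seed, sample(patients, n_val))
  assignment <- setNames(ifelse(patients %in% val, "validation", "discovery"),
                         patients)
  structure(list(assignment = assignment, ratio = ratio, seed = seed),
            class = "split_spec")
}

#' Area under the ROC curve by pair counting
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)` — the
#' Mann-Whitney U relation, computed via average ranks.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels; the positive class is `TRUE`/`1`/the second
#'   factor level.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- factor(labels)
  if (nlevels(f) > 2) stop("labels must be binary", call. = FALSE)
  as.integer(f) == nlevels(f)
}

#' Empirical ROC curve coordinates
#'
#' Step-function ROC coordinates over all distinct score thresholds
#' (prediction positive when score >= threshold), suitable for trapezoidal
#' integration and threshold selection.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `sensitivity` (TPR), `specificity`,
#'   `fpr`, ordered from the lax to the strict end.
#' @export
roc_curve <- function(scores, labels) {
  pos <- .as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  th <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(th, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), 0)
  data.frame(threshold = th, sensitivity = sens, specificity = 1 - fpr,
             fpr = fpr)
}

#' Trapezoidal AUC from ROC coordinates
#'
#' @param curve result of [roc_curve()].
#' @return AUC by trapezoidal integration over (FPR, TPR).
#' @export
auc_trapezoid <- function(curve) {
  o <- order(curve$fpr, curve$sensitivity)
  x <- curve$fpr[o]; y <- curve$sensitivity[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Rank candidate markers by discovery-set p-value
#'
#' Ascending p-value order; ties broken by |log2 fold change| descending,
#' then metabolite id.
#'
#' @param differential result of [differential_analysis()] computed on the
#'   discovery set only.
#' @param top_k number of markers to return (whole list if larger).
#' @return character vector of metabolite ids.
#' @export
rank_markers <- function(differential, top_k = 10) {
  o <- order(differential$p_value, -abs(differential$log2_fold_change),
             differential$metabolite_id)
  utils::head(differential$metabolite_id[o], top_k)
}

#' Combine markers into a logistic score with discovery/validation ROC
#'
#' Fits a logistic regression on the auto-scaled marker values of the
#' discovery samples (tumor = positive class; both members of each pair
#' enter as independent observations), scores every sample with the linear
#' predictor, and reports AUC per set. The operating threshold is the
#' Youden-optimal point on the discovery ROC, applied unchanged to the
#' validation set. Scaling centers/scales and model coefficients come from
#' the discovery set only. Under perfect separation the logistic fit is
#' unstable and the score falls back to the sum of auto-scaled markers
#' oriented by their discovery AUC, with a warning.
#'
#' @param pt a normalized `peak_table`.
#' @param split a `split_spec` from [split_patients()].
#' @param marker_ids metabolite ids to combine (one id reduces to that
#'   single marker's ROC).
#' @return object of class `roc_result`: `markers`, `auc_discovery`,
#'   `auc_validation`, `threshold`, `sensitivity`/`specificity` per set,
#'   `coefficients`, `scores` (per-sample data.frame).
#' @export
combine_markers <- function(pt, split, marker_ids) {
  stopifnot(inherits(split, "split_spec"))
  smp <- pt$samples
  tissue <- smp$tissue_type %in% c("tumor", "adjacent")
  x <- intensity_matrix(pt, c("tumor", "adjacent"))
  absent <- setdiff(marker_ids, colnames(x))
  if (length(absent)) stop("marker(s) not in table: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  meta <- smp[tissue, ]
  set <- split$assignment[meta$patient_id]
  if (any(is.na(set))) stop("split does not cover every patient", call. = FALSE)
  y <- meta$tissue_type == "tumor"
  xm <- x[, marker_ids, drop = FALSE]
  disc <- set == "discovery"

  sc <- autoscale(xm[disc, , drop = FALSE])
  xs <- sweep(sweep(xm[, names(sc$center), drop = FALSE], 2, sc$center),
              2, sc$scale, `/`)
  df <- as.data.frame(xs[disc, , drop = FALSE])
  fit <- suppressWarnings(stats::glm(y[disc] ~ ., data = df,
                                     family = stats::binomial()))
  fitted_p <- stats::fitted(fit)
  separated <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 50) ||
    all(abs(fitted_p - 0.5) > 0.499)
  if (separated) {
    warning("perfect separation in the discovery fit; using rank-combination score",
            call. = FALSE)
    orient <- vapply(seq_len(ncol(xs)), function(j)
      sign(roc_auc(xs[disc, j], y[disc]) - 0.5), 0)
    orient[orient == 0] <- 1
    score <- drop(xs %*% orient)
    coefs <- setNames(orient, colnames(xs))
  } else {
    score <- drop(cbind(1, xs) %*% stats::coef(fit))
    coefs <- stats::coef(fit)
  }

  curve_d <- roc_curve(score[disc], y[disc])
  j <- curve_d$sensitivity + curve_d$specificity - 1
  thr <- curve_d$threshold[which.max(j)]
  metrics <- function(idx) {
    pred <- score[idx] >= thr
    c(auc = roc_auc(score[idx], y[idx]),
      sensitivity = mean(pred[y[idx]]),
      specificity = mean(!pred[!y[idx]]))
  }
  md <- metrics(disc); mv <- metrics(!disc)
  structure(list(
    markers = marker_ids,
    auc_discovery = unname(md["auc"]), auc_validation = unname(mv["auc"]),
    threshold = thr,
    sensitivity = c(discovery = unname(md["sensitivity"]),
                    validation = unname(mv["sensitivity"])),
    specificity = c(discovery = unname(md["specificity"]),
                    validation = unname(mv["specificity"])),
    coefficients = coefs, separated = separated,
    scores = data.frame(sample_id = meta$sample_id, set = unname(set),
                        tumor = y, score = score,
                        stringsAsFactors = FALSE)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("marker combination [%s]\n", paste(x$markers, collapse = " + ")))
  cat(sprintf("  AUC discovery %.3f / validation %.3f\n",
              x$auc_discovery, x$auc_validation))
  cat(sprintf("  at Youden threshold: sens %.3f/%.3f, spec %.3f/%.3f\n",
              x$sensitivity[1], x$sensitivity[2],
              x$specificity[1], x$specificity[2]))
  invisible(x)
}
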