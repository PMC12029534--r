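#' Internal-standard and tissue-weight normalization
#'
#' Each metabolite's raw MS response is divided by the response of its
#' assigned spiked internal standard in the same sample, and — for tissue
#' samples — further divided by the sample's tissue weight (mg), yielding
#' weight-adjusted relative responses. Pooled QC samples have no tissue
#' weight and are normalized by internal standard only. The construction is
#' invariant to any per-sample multiplicative factor that affects raw and
#' internal-standard responses jointly (injection volume, detector drift).
#'
#' Internal-standard columns themselves are dropped from the normalized
#' table (their normalized value is constant by construction). A zero or
#' missing internal-standard response renders the affected cells
#' flagged-missing (`NA`) with a warning; a non-positive tissue weight is a
#' hard error. Metabolites without an internal-standard assignment are
#' normalized by tissue weight alone, with a warning.
#'
#' @param pt a raw `peak_table`. Re-normalizing a normalized table errors.
#' @return a normalized `peak_table` (internal-standard columns removed,
#'   `normalized = TRUE`).
#' @export
normalize_intensities <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  if (pt$normalized) stop("peak table is already normalized", call. = FALSE)
  met <- pt$metabolites
  smp <- pt$samples
  x <- pt$intensities

  is_std <- met$is_internal_standard %in% TRUE
  targets <- which(!is_std)
  out <- x[, targets, drop = FALSE]

  no_is <- is.na(met$internal_standard_id[targets])
  if (any(no_is)) {
    warning("no internal standard assigned for: ",
            paste(met$metabolite_id[targets][no_is], collapse = ", "),
            "; normalized by tissue weight only", call. = FALSE)
  }

  n_flagged <- 0L
  for (k in seq_along(targets)) {
    j <- targets[k]
    is_id <- met$internal_standard_id[j]
    if (is.na(is_id)) next
    is_resp <- x[, is_id]
    bad <- is.na(is_resp) | is_resp == 0
    n_flagged <- n_flagged + sum(bad & !is.na(out[, k]))
    out[, k] <- ifelse(bad, NA_real_, out[, k] / is_resp)
  }
  if (n_flagged > 0) {
    warning(n_flagged, " cell(s) flagged missing (zero/missing internal-standard response)",
            call. = FALSE)
  }

  tissue <- smp$tissue_type != "QC"
  w <- smp$tissue_weight
  if (any(tissue & (is.na(w) | w <= 0))) {
    stop("zero or missing tissue weight for: ",
         paste(smp$sample_id[tissue & (is.na(w) | w <= 0)], collapse = ", "),
         call. = FALSE)
  }
  out[tissue, ] <- out[tissue, , drop = FALSE] / w[tissue]

  peak_table(out, smp, met[targets, , drop = FALSE][, , drop = FALSE],
             normalized = TRUE)
}

#' Pooled-QC relative standard deviation
#'
#' Platform-stability metric: for each metabolite, RSD% = 100 * sd / mean
#' over the pooled QC injections, plus the fractions of metabolites whose
#' RSD falls below the reporting thresholds (20% and 30% by default). The
#' sample (n-1) standard deviation is used. RSD evaluation is
#' reporting-only; it does not remove metabolites (use the `max_rsd`
#' argument of [handle_missing()]-style filtering downstream if desired).
#'
#' @param pt a `peak_table` containing QC samples.
#' @param min_qc minimum number of QC samples required (default 3).
#' @param thresholds RSD%% reporting thresholds.
#' @return list with `table` (per-metabolite mean, sd, rsd; `NA` rsd when the
#'   QC mean is zero), `fractions` (named fractions of metabolites below each
#'   threshold, computed over metabolites with a defined RSD) and `n_qc`.
#' @export
compute_qc_rsd <- function(pt, min_qc = 3, thresholds = c(20, 30)) {
  stopifnot(inherits(pt, "peak_table"))
  qc <- pt$samples$tissue_type == "QC"
  if (sum(qc) < min_qc) {
    stop("need at least ", min_qc, " QC samples, found ", sum(qc), call. = FALSE)
  }
  keep <- !(pt$metabolites$is_internal_standard %in% TRUE)
  x <- pt$intensities[qc, keep, drop = FALSE]
  mu <- colMeans(x, na.rm = TRUE)
  sdev <- apply(x, 2, stats::sd, na.rm = TRUE)
  rsd <- ifelse(is.na(mu) | mu == 0, NA_real_, 100 * sdev / mu)
  tab <- data.frame(metabolite_id = colnames(x), mean = mu, sd = sdev,
                    rsd = rsd, row.names = NULL, stringsAsFactors = FALSE)
  defined <- !is.na(rsd)
  fractions <- vapply(thresholds, function(th) mean(rsd[defined] < th), 0)
  names(fractions) <- paste0("rsd_lt_", thresholds)
  structure(list(table = tab, fractions = fractions, n_qc = sum(qc)),
            class = "qc_rsd")
}

#' @export
print.qc_rsd <- function(x, ...) {
  cat(sprintf("QC RSD over %d pooled QC samples, %d metabolites\n",
              x$n_qc, nrow(x$table)))
  for (nm in names(x$fractions)) {
    cat(sprintf("  %s: %.1f%%\n", nm, 100 * x$fractions[[nm]]))
  }
  invisible(x)
}

#' Missing-value policy: drop then impute
#'
#' Metabolites missing in more than `max_missing_fraction` of samples are
#' dropped (logged via message); remaining missing cells are imputed with
#' half the metabolite's observed minimum — the common limit-of-detection
#' surrogate in peak-table metabolomics.
#'
#' @param pt a normalized `peak_table`.
#' @param max_missing_fraction drop threshold in `[0, 1]` (default 0.5).
#' @return a `peak_table` without missing cells.
#' @export
handle_missing <- function(pt, max_missing_fraction = 0.5) {
  stopifnot(inherits(pt, "peak_table"))
  if (!is.numeric(max_missing_fraction) || length(max_missing_fraction) != 1 ||
      is.na(max_missing_fraction) ||
      max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("max_missing_fraction must be a single value in [0, 1]", call. = FALSE)
  }
  x <- pt$intensities
  frac <- colMeans(is.na(x))
  drop <- frac > max_missing_fraction
  if (any(drop)) {
    message("dropping ", sum(drop), " metabolite(s) missing in more than ",
            round(100 * max_missing_fraction), "% of samples: ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- min(x[!miss, j]) / 2
  }
  peak_table(x, pt$samples, pt$metabolites[!drop, , drop = FALSE],
             normalized = pt$normalized)
}
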