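#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on the paired differences. Zero differences are dropped
#' (the classical Wilcoxon convention). With at most `exact_max` non-zero
#' differences the exact two-sided p-value is computed by full enumeration of
#' all 2^n sign assignments — this remains valid under tied absolute
#' differences, where the tabulated signed-rank distribution does not apply.
#' Larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param tumor,adjacent equal-length paired value vectors.
#' @param exact_max largest number of non-zero differences for which the
#'   exact enumeration is used (default 12).
#' @param correct continuity correction in the normal approximation.
#' @return list with `statistic` (W, sum of positive-difference ranks), `n`
#'   (non-zero differences), `p_value` and `method`.
#' @export
paired_wilcoxon <- function(tumor, adjacent, exact_max = 12, correct = TRUE) {
  if (length(tumor) != length(adjacent)) {
    stop("tumor and adjacent must have equal length", call. = FALSE)
  }
  d <- tumor - adjacent
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, n = 0L, p_value = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- .signrank_exact_p(w, r)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- w - mu
    if (correct) z <- z - sign(z) * 0.5
    p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    method <- "normal approximation"
  }
  list(statistic = w, n = n, p_value = p, method = method)
}

## Exact two-sided signed-rank p by enumerating all sign assignments of the
## observed (possibly tied) ranks; the null distribution of W is symmetric
## about sum(r)/2, so the two-sided p doubles the smaller tail.
.signrank_exact_p <- function(w, r) {
  n <- length(r)
  ## distribution of W via iterative convolution over 2^n assignments
  vals <- 0
  for (ri in r) vals <- c(vals, vals + ri)
  lo <- mean(vals <= w + 1e-9)
  hi <- mean(vals >= w - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney U test (rank-sum)
#'
#' Two-sided rank-sum test for a binary grouping. With total n at most
#' `exact_max` the exact p-value is computed by enumerating all group
#' assignments of the pooled (possibly tied) values; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param x,y value vectors for the two groups.
#' @param exact_max largest pooled n for exact enumeration (default 12).
#' @param correct continuity correction in the normal approximation.
#' @return list with `statistic` (U for the first group), `p_value`, `method`.
#' @export
mannwhitney_test <- function(x, y, exact_max = 12, correct = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (n <= exact_max) {
    combs <- utils::combn(n, n1)
    udist <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(udist <= u + 1e-9), mean(udist >= u - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u - mu
    if (correct) z <- z - sign(z) * 0.5
    ## sigma2 = 0 iff every pooled value is tied: no evidence either way
    p <- if (sigma2 <= 0) 1 else min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    method <- "normal approximation"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Benjamini-Hochberg (or Benjamini-Yekutieli) q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  .assert_prob(p_values)
  stats::p.adjust(p_values, method = method)
}

#' Paired tumor-vs-adjacent differential screen
#'
#' Runs the paired Wilcoxon test per metabolite across patient pairs, with
#' BH-FDR across metabolites. The fold change is log2 of the median of the
#' per-pair tumor/adjacent ratios, and `direction` follows its sign.
#'
#' @param pt a normalized `peak_table` with paired samples.
#' @param fdr_method passed to [bh_fdr()].
#' @param exact_max passed to [paired_wilcoxon()].
#' @return data.frame with one row per metabolite: `metabolite_id`,
#'   `n_pairs`, `statistic`, `p_value`, `fdr`, `log2_fold_change`,
#'   `direction`.
#' @export
differential_analysis <- function(pt, fdr_method = "BH", exact_max = 12) {
  pm <- paired_matrices(pt)
  mets <- colnames(pm$tumor)
  res <- lapply(mets, function(j) {
    tu <- pm$tumor[, j]; ad <- pm$adjacent[, j]
    ok <- !is.na(tu) & !is.na(ad)
    wt <- suppressWarnings(paired_wilcoxon(tu[ok], ad[ok], exact_max = exact_max))
    ratio <- ifelse(ad[ok] > 0, tu[ok] / ad[ok], NA_real_)
    l2fc <- log2(stats::median(ratio, na.rm = TRUE))
    data.frame(metabolite_id = j, n_pairs = sum(ok),
               statistic = wt$statistic, p_value = wt$p_value,
               log2_fold_change = l2fc,
               direction = ifelse(is.na(l2fc) | l2fc == 0, "none",
                                  ifelse(l2fc > 0, "up", "down")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_value, method = fdr_method)
  out[, c("metabolite_id", "n_pairs", "statistic", "p_value", "fdr",
          "log2_fold_change", "direction")]
}

#' Scan differential metabolites against clinical indices
#'
#' For each differential metabolite and each binary (or binarized pairwise)
#' contrast of a categorical clinical index, runs a Mann-Whitney test on the
#' tumor-tissue values. Multi-level indices contribute all pairwise level
#' contrasts. Levels named `"unknown"` or missing are excluded; indices left
#' with a single level are skipped with a warning.
#'
#' @param pt a normalized `peak_table`.
#' @param differential character vector of metabolite ids (typically the
#'   significant rows of [differential_analysis()]).
#' @param indices clinical-index column names; default: every sample-metadata
#'   column beyond the core fields.
#' @param alpha significance flag threshold (default 0.05).
#' @return list with `table` (metabolite, index, contrast, group ns, p,
#'   significant flag) and `index_counts` (per-index count of significant
#'   metabolites, the basis for ranking indices).
#' @export
clinical_association_scan <- function(pt, differential,
                                      indices = NULL, alpha = 0.05) {
  smp <- pt$samples
  indices <- indices %||% setdiff(names(smp), .sample_core_cols)
  tum <- smp$tissue_type == "tumor"
  x <- intensity_matrix(pt, "tumor")
  differential <- intersect(differential, colnames(x))
  rows <- list()
  if (length(differential)) {
    for (idx in indices) {
      v <- as.character(smp[[idx]][tum])
      keep <- !is.na(v) & v != "unknown"
      lev <- sort(unique(v[keep]))
      if (length(lev) < 2) {
        warning("clinical index '", idx, "' has fewer than two usable levels; skipped",
                call. = FALSE)
        next
      }
      for (pair in utils::combn(lev, 2, simplify = FALSE)) {
        g1 <- keep & v == pair[1]
        g2 <- keep & v == pair[2]
        for (met in differential) {
          mw <- mannwhitney_test(x[g1, met], x[g2, met])
          rows[[length(rows) + 1L]] <- data.frame(
            metabolite_id = met, index = idx,
            contrast = paste(pair, collapse = " vs "),
            n1 = sum(g1), n2 = sum(g2), p_value = mw$p_value,
            significant = mw$p_value < alpha, stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite_id = character(0), index = character(0),
               contrast = character(0), n1 = integer(0), n2 = integer(0),
               p_value = numeric(0), significant = logical(0))
  sig <- tab[tab$significant, , drop = FALSE]
  counts <- vapply(split(sig$metabolite_id, factor(sig$index, levels = unique(tab$index))),
                   function(v) length(unique(v)), 0L)
  list(table = tab, index_counts = sort(counts, decreasing = TRUE))
}

#' Hypergeometric pathway over-representation
#'
#' Upper-tail hypergeometric test of the overlap between the selected
#' metabolites and each pathway set, within the analysis universe, with
#' BH-FDR across pathways. Pathway sets are intersected with the universe;
#' sets smaller than `min_size` (default 1) are dropped.
#'
#' @param selected character vector of selected metabolite ids (non-empty,
#'   must be contained in `universe`).
#' @param pathways named list of metabolite-id sets (see [read_gmt()]).
#' @param universe character vector: all metabolites eligible for selection.
#' @param min_size minimum post-intersection pathway size.
#' @return data.frame with `pathway_id`, `pathway_size`, `overlap_count`,
#'   `universe_size`, `selected_count`, `p_value`, `fdr`.
#' @export
hypergeometric_enrichment <- function(selected, pathways, universe,
                                      min_size = 1) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!length(selected)) stop("selected set is empty", call. = FALSE)
  stray <- setdiff(selected, universe)
  if (length(stray)) {
    stop("selected metabolites outside the universe: ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(pathways, intersect, y = universe)
  sets <- sets[vapply(sets, length, 0L) >= min_size]
  N <- length(universe); k <- length(selected)
  res <- lapply(names(sets), function(pw) {
    K <- length(sets[[pw]])
    ov <- length(intersect(sets[[pw]], selected))
    p <- stats::phyper(ov - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(pathway_id = pw, pathway_size = K, overlap_count = ov,
               universe_size = N, selected_count = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(pathway_id = character(0), pathway_size = integer(0),
                      overlap_count = integer(0), universe_size = integer(0),
                      selected_count = integer(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  out$fdr <- bh_fdr(out$p_value)
  out[order(out$p_value), ]
}

#' Read pathway sets from a GMT file
#'
#' Thin wrapper over `fgsea::gmtPathways()`; each GMT line is
#' `pathway_id <TAB> description <TAB> member ids...`.
#'
#' @param path GMT file path.
#' @return named list of member-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("read_gmt requires the 'fgsea' package", call. = FALSE)
  }
  fgsea::gmtPathways(path)
}
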