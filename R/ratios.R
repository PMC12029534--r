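#' Canonicalize acylcarnitine identifiers
#'
#' Maps the mixed spellings found in annotation sheets ("carnitine C4_0-OH",
#' "C8:0", "carnitine_C16_0") onto the package's canonical ids
#' (`carnitine_C4-OH`, `carnitine_C8`, `carnitine_C16`): spaces and colons
#' become underscores, a bare chain tag gains the `carnitine_` prefix, and a
#' redundant `_0` saturation suffix is removed.
#'
#' @param ids character vector of identifiers.
#' @return canonical ids (non-carnitine ids pass through unchanged).
#' @export
canonical_carnitine_id <- function(ids) {
  out <- gsub("[ :]", "_", trimws(ids))
  bare <- grepl("^C[0-9]+(_[0-9]+)?(-OH)?$", out)
  out[bare] <- paste0("carnitine_", out[bare])
  carn <- grepl("^carnitine_", out)
  out[carn] <- sub("_0(-OH)?$", "\\1", out[carn])
  out
}

#' Built-in acylcarnitine ratio panel
#'
#' The eight ratios used as mitochondrial beta-oxidation enzyme-activity
#' proxies: (C16+C18)/C0 (proportional to CPT1 activity), C14:1/C16
#' (inversely proportional to VLCAD), C4/C3 (inversely proportional to
#' SCAD), C2/C0 (carnitine acetylation state), C8/C10 (inversely
#' proportional to MCAD), and the three hydroxy ratios C10-OH/C10, C8-OH/C8
#' and C4-OH/C4 (inversely related to ECHS1 activity).
#'
#' @return data.frame with `name`, `numerator` / `denominator`
#'   (`;`-separated metabolite ids) and `enzyme_interpretation`.
#' @export
builtin_ratio_panel <- function() {
  data.frame(
    name = c("CPT1", "VLCAD_inverse", "SCAD_inverse", "C2_to_C0",
             "MCAD_inverse", "ECHS1_C10", "ECHS1_C8", "ECHS1_C4"),
    numerator = c("carnitine_C16;carnitine_C18", "carnitine_C14_1",
                  "carnitine_C4", "carnitine_C2", "carnitine_C8",
                  "carnitine_C10-OH", "carnitine_C8-OH", "carnitine_C4-OH"),
    denominator = c("carnitine_C0", "carnitine_C16", "carnitine_C3",
                    "carnitine_C0", "carnitine_C10", "carnitine_C10",
                    "carnitine_C8", "carnitine_C4"),
    enzyme_interpretation = c(
      "proportional to carnitine palmitoyltransferase 1 activity",
      "inversely proportional to very-long-chain acyl-CoA dehydrogenase activity",
      "inversely proportional to short-chain acyl-CoA dehydrogenase activity",
      "acetylcarnitine over free carnitine",
      "inversely proportional to medium-chain acyl-CoA dehydrogenase activity",
      "inversely related to enoyl-CoA hydratase short chain 1 activity",
      "inversely related to enoyl-CoA hydratase short chain 1 activity",
      "inversely related to enoyl-CoA hydratase short chain 1 activity"),
    stringsAsFactors = FALSE)
}

#' Read ratio definitions from a TSV file
#'
#' Columns: `name`, `numerator` (`;`-separated ids), `denominator`, and
#' optionally `enzyme_interpretation`.
#'
#' @param path TSV path.
#' @return ratio-definition data.frame as in [builtin_ratio_panel()].
#' @export
read_ratio_definitions <- function(path) {
  df <- utils::read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "numerator", "denominator") %in% names(df)))
  if (is.null(df$enzyme_interpretation)) df$enzyme_interpretation <- ""
  df
}

.split_ids <- function(s) canonical_carnitine_id(strsplit(s, ";")[[1]])

#' Compute a ratio panel with paired tumor-vs-adjacent testing
#'
#' Per-sample ratio = sum of numerator metabolite values over sum of
#' denominator values; per-sample multiplicative factors (normalization
#' errors, dilution) cancel exactly. A missing component of a summed
#' numerator or denominator, or a zero/missing denominator, flags the ratio
#' missing for that sample; ratios referencing metabolites absent from the
#' table are skipped with a warning. Each retained ratio is tested tumor vs
#' adjacent with the paired Wilcoxon test across patient pairs.
#'
#' @param pt a normalized `peak_table` with paired samples.
#' @param defs ratio definitions (default [builtin_ratio_panel()]); extra
#'   user ratios can be row-bound without mutating the builtins.
#' @return object of class `ratio_panel`: `values` (samples x ratios
#'   matrix), `tests` (ratio, n_pairs, statistic, p_value, fdr,
#'   log2_fold_change, direction), `definitions`.
#' @export
compute_ratio_panel <- function(pt, defs = builtin_ratio_panel()) {
  stopifnot(inherits(pt, "peak_table"))
  if (!pt$normalized) {
    warning("ratio panel computed on a raw table; ratios are scale-invariant ",
            "per sample but raw responses are not weight-adjusted", call. = FALSE)
  }
  x <- intensity_matrix(pt, c("tumor", "adjacent", "QC"))
  colnames(x) <- canonical_carnitine_id(colnames(x))
  keep <- logical(nrow(defs))
  vals <- matrix(NA_real_, nrow(x), nrow(defs),
                 dimnames = list(rownames(x), defs$name))
  for (i in seq_len(nrow(defs))) {
    num <- .split_ids(defs$numerator[i])
    den <- .split_ids(defs$denominator[i])
    if (length(intersect(num, den))) {
      stop("ratio '", defs$name[i], "': numerator and denominator overlap",
           call. = FALSE)
    }
    absent <- setdiff(c(num, den), colnames(x))
    if (length(absent)) {
      warning("ratio '", defs$name[i], "' skipped; missing metabolite(s): ",
              paste(absent, collapse = ", "), call. = FALSE)
      next
    }
    keep[i] <- TRUE
    ns <- rowSums(x[, num, drop = FALSE])   # NA if any component missing
    ds <- rowSums(x[, den, drop = FALSE])
    vals[, i] <- ifelse(is.na(ds) | ds == 0, NA_real_, ns / ds)
  }
  vals <- vals[, keep, drop = FALSE]
  defs_kept <- defs[keep, , drop = FALSE]

  smp <- pt$samples
  tum <- smp[smp$tissue_type == "tumor", ]
  adj <- smp[smp$tissue_type == "adjacent", ]
  patients <- intersect(tum$patient_id, adj$patient_id)
  tests <- lapply(colnames(vals), function(rn) {
    tv <- vals[match(tum$sample_id[match(patients, tum$patient_id)], rownames(vals)), rn]
    av <- vals[match(adj$sample_id[match(patients, adj$patient_id)], rownames(vals)), rn]
    ok <- !is.na(tv) & !is.na(av)
    wt <- suppressWarnings(paired_wilcoxon(tv[ok], av[ok]))
    l2fc <- log2(stats::median(tv[ok] / av[ok], na.rm = TRUE))
    data.frame(ratio = rn, n_pairs = sum(ok), statistic = wt$statistic,
               p_value = wt$p_value, log2_fold_change = l2fc,
               direction = ifelse(is.na(l2fc) | l2fc == 0, "none",
                                  ifelse(l2fc > 0, "up", "down")),
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  if (!is.null(tests) && nrow(tests)) tests$fdr <- bh_fdr(tests$p_value)
  structure(list(values = vals, tests = tests, definitions = defs_kept),
            class = "ratio_panel")
}

#' @export
print.ratio_panel <- function(x, ...) {
  cat("acylcarnitine ratio panel:", ncol(x$values), "ratio(s)\n")
  if (!is.null(x$tests)) {
    sig <- x$tests$p_value < 0.05
    cat("  significant (p < 0.05):",
        paste(x$tests$ratio[sig], collapse = ", "), "\n")
  }
  invisible(x)
}
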