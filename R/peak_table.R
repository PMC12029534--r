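#' Construct a peak table
#'
#' A peak table bundles the samples-by-metabolites intensity matrix with the
#' sample metadata and metabolite annotations that every downstream stage
#' consumes. Intensities are non-negative MS responses (arbitrary units);
#' missing measurements are stored as `NA`.
#'
#' @param intensities numeric matrix, rows = samples, columns = metabolites.
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `tissue_type` (one of `"tumor"`, `"adjacent"`, `"QC"`), `tissue_weight`
#'   (mg; `NA` for QC), `tnm_stage` (`"I"`..`"IV"` or `"none"` for QC), plus
#'   any number of clinical-index columns (Lauren typing, infiltration depth,
#'   invasion, Borrmann, Her2, pN, pM, ...).
#' @param metabolites data.frame with columns `metabolite_id`,
#'   `display_name`, `chemical_class`, `internal_standard_id`,
#'   `ionization_mode` and logical `is_internal_standard`.
#' @param normalized logical; `TRUE` once [normalize_intensities()] has run.
#'   Normalized tables refuse a second normalization.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(intensities, samples, metabolites, normalized = FALSE) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  pt <- structure(
    list(intensities = intensities,
         samples = as.data.frame(samples),
         metabolites = as.data.frame(metabolites),
         normalized = isTRUE(normalized)),
    class = "peak_table")
  validate_peak_table(pt)
}

.metabolite_classes <- c("FFA", "carnitine", "OH-carnitine", "PC", "LPC",
                         "SM", "amino_acid", "nucleoside", "other")

#' Validate a peak table
#'
#' Checks the structural invariants: id/dimension agreement, id uniqueness,
#' finite-or-missing values, positive tissue weights, QC stage coding, and
#' resolvable internal-standard assignments.
#'
#' @param pt a `peak_table`.
#' @return `pt`, invisibly validated (errors on violation).
#' @export
validate_peak_table <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  m <- pt$intensities
  smp <- pt$samples
  met <- pt$metabolites

  if (anyDuplicated(smp$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(smp$sample_id[duplicated(smp$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(met$metabolite_id)) {
    stop("duplicate metabolite_id: ",
         paste(unique(met$metabolite_id[duplicated(met$metabolite_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(m) != nrow(smp) || !identical(rownames(m), as.character(smp$sample_id))) {
    stop("intensity rows must match samples$sample_id (same ids, same order)",
         call. = FALSE)
  }
  if (ncol(m) != nrow(met) || !identical(colnames(m), as.character(met$metabolite_id))) {
    stop("intensity columns must match metabolites$metabolite_id (same ids, same order)",
         call. = FALSE)
  }
  if (any(is.infinite(m))) stop("intensities must be finite or NA", call. = FALSE)
  if (any(m < 0, na.rm = TRUE)) stop("intensities must be non-negative", call. = FALSE)

  bad_type <- setdiff(unique(smp$tissue_type), c("tumor", "adjacent", "QC"))
  if (length(bad_type)) stop("unknown tissue_type: ", paste(bad_type, collapse = ", "), call. = FALSE)
  tissue <- smp$tissue_type != "QC"
  if (any(tissue & (is.na(smp$tissue_weight) | smp$tissue_weight <= 0))) {
    stop("tissue samples need tissue_weight > 0", call. = FALSE)
  }
  if (any(!tissue & !(is.na(smp$tnm_stage) | smp$tnm_stage == "none"))) {
    stop("QC samples must have tnm_stage 'none'", call. = FALSE)
  }

  ## normalized tables have had their internal-standard columns consumed and
  ## dropped, so the resolution requirement applies to raw tables only
  if (!pt$normalized && !is.null(met$internal_standard_id)) {
    is_ids <- met$internal_standard_id
    unresolved <- setdiff(is_ids[!is.na(is_ids)], met$metabolite_id)
    if (length(unresolved)) {
      stop("internal_standard_id not measured in the table: ",
           paste(unique(unresolved), collapse = ", "), call. = FALSE)
    }
  }
  invisible(pt)
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d samples x %d metabolites (%s)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$normalized) "normalized" else "raw"))
  tt <- table(x$samples$tissue_type)
  cat("  samples:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(x$intensities)), "\n")
  invisible(x)
}

#' Extract an intensity sub-matrix by tissue type
#'
#' @param pt a `peak_table`.
#' @param tissue tissue types to keep.
#' @param drop_standards drop internal-standard columns (default `TRUE`).
#' @return numeric matrix (samples x metabolites).
#' @export
intensity_matrix <- function(pt, tissue = c("tumor", "adjacent"),
                             drop_standards = TRUE) {
  keep_s <- pt$samples$tissue_type %in% tissue
  keep_m <- rep(TRUE, nrow(pt$metabolites))
  if (drop_standards && !is.null(pt$metabolites$is_internal_standard)) {
    keep_m <- !pt$metabolites$is_internal_standard
  }
  pt$intensities[keep_s, keep_m, drop = FALSE]
}

#' Patient-aligned tumor and adjacent matrices
#'
#' Returns the tumor and adjacent intensity matrices with rows aligned by
#' patient, so row i of both matrices belongs to the same patient.
#'
#' @param pt a `peak_table`.
#' @return list with elements `tumor`, `adjacent` (matrices) and `patients`.
#' @export
paired_matrices <- function(pt) {
  smp <- pt$samples
  tum <- smp[smp$tissue_type == "tumor", ]
  adj <- smp[smp$tissue_type == "adjacent", ]
  patients <- intersect(tum$patient_id, adj$patient_id)
  if (!length(patients)) stop("no paired patients found", call. = FALSE)
  mt <- intensity_matrix(pt, "tumor")
  ma <- intensity_matrix(pt, "adjacent")
  list(tumor = mt[match(patients, tum$patient_id), , drop = FALSE],
       adjacent = ma[match(patients, adj$patient_id), , drop = FALSE],
       patients = patients)
}

#' Read a peak table from delimited text files
#'
#' The intensity file must have `sample_id` as its first column and one
#' column per metabolite. The metadata file carries one row per sample; the
#' optional annotation file carries one row per metabolite (metabolites
#' missing from it get minimal default annotations).
#'
#' @param path intensity CSV/TSV path.
#' @param metadata_path sample metadata CSV/TSV path.
#' @param annotation_path optional metabolite annotation CSV/TSV path.
#' @param sep field separator (default `","`).
#' @return a `peak_table`.
#' @export
read_peak_table <- function(path, metadata_path, annotation_path = NULL,
                            sep = ",") {
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (names(raw)[1] != "sample_id") {
    stop("first column of ", path, " must be 'sample_id'", call. = FALSE)
  }
  ids <- raw$sample_id
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals == "" | toupper(as.matrix(vals)) == "NA"),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric intensity at sample '%s', metabolite '%s': '%s'",
                 ids[bad[1, 1]], names(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  rownames(num) <- ids

  smp <- utils::read.csv(metadata_path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_meta <- setdiff(ids, smp$sample_id)
  if (length(missing_meta)) {
    stop("samples missing from metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(smp$sample_id, ids)
  if (length(extra)) {
    stop("metadata samples absent from peak table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  smp <- smp[match(ids, smp$sample_id), , drop = FALSE]
  rownames(smp) <- NULL

  if (!is.null(annotation_path)) {
    met <- utils::read.csv(annotation_path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
    unknown <- setdiff(met$metabolite_id, colnames(num))
    if (length(unknown)) {
      stop("annotated metabolites absent from peak table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    met <- met[match(colnames(num), met$metabolite_id), , drop = FALSE]
    met$metabolite_id <- colnames(num)
    if (is.null(met$is_internal_standard)) met$is_internal_standard <- FALSE
    met$is_internal_standard <- as.logical(met$is_internal_standard) %in% TRUE
    rownames(met) <- NULL
  } else {
    met <- data.frame(metabolite_id = colnames(num),
                      display_name = colnames(num),
                      chemical_class = "other",
                      internal_standard_id = NA_character_,
                      ionization_mode = "ESI+",
                      is_internal_standard = FALSE,
                      stringsAsFactors = FALSE)
  }
  normalized <- isTRUE(all(smp$normalized %in% TRUE)) ||
    identical(attr(smp, "normalized"), TRUE)
  peak_table(num, smp[setdiff(names(smp), "normalized")], met,
             normalized = normalized)
}

#' Write a peak table to delimited text files
#'
#' Inverse of [read_peak_table()]: `read(write(pt))` reproduces the matrix
#' and metadata exactly (numbers are serialized at full precision).
#'
#' @param pt a `peak_table`.
#' @param path,metadata_path,annotation_path output CSV paths.
#' @return invisibly, the three paths.
#' @export
write_peak_table <- function(pt, path, metadata_path, annotation_path = NULL) {
  df <- data.frame(sample_id = rownames(pt$intensities),
                   format(pt$intensities, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[df == "NA"] <- NA
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  smp <- pt$samples
  smp$normalized <- pt$normalized
  utils::write.csv(smp, metadata_path, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(annotation_path)) {
    utils::write.csv(pt$metabolites, annotation_path, row.names = FALSE,
                     quote = FALSE, na = "NA")
  }
  invisible(c(path, metadata_path, annotation_path))
}
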