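#' Gaussian-copula parameter for a target Spearman correlation
#'
#' For a bivariate Gaussian copula with Pearson parameter `r`, the population
#' Spearman correlation is `(6/pi) * asin(r/2)`. Inverting gives
#' `r = 2 * sin(pi * rho_s / 6)`, which lets correlation targets be stated on
#' the Spearman scale the analyses consume, with no calibration loop.
#'
#' @param rho_target population Spearman correlation(s), each in (-1, 1).
#' @return Pearson parameter(s) of the latent Gaussian.
#' @export
rank_target_copula <- function(rho_target) {
  if (any(!is.finite(rho_target) | abs(rho_target) >= 1)) {
    stop("|rho_target| must be < 1", call. = FALSE)
  }
  2 * sin(pi * rho_target / 6)
}

#' Planted correlation-trajectory edge
#'
#' Declares one metabolite pair whose tumor-tissue Spearman correlation
#' follows a per-stage trajectory, with a separate target in adjacent tissue.
#'
#' @param m1,m2 metabolite ids.
#' @param rho_by_stage numeric length 3, target Spearman in tumor tissue for
#'   stages I, II, III (stage IV reuses the stage-III target).
#' @param rho_adjacent target Spearman in adjacent tissue (default 0).
#' @return a planted-block specification (list).
#' @export
planted_edge <- function(m1, m2, rho_by_stage, rho_adjacent = 0) {
  stopifnot(length(rho_by_stage) == 3)
  list(type = "pair", members = c(m1, m2),
       rho_by_stage = as.numeric(rho_by_stage),
       rho_adjacent = rho_adjacent)
}

#' Planted hub star with stage-wise correlation trajectory
#'
#' Declares a hub metabolite correlated with each partner at a per-stage
#' Spearman target. The star is realized through a single latent factor
#' (hub = factor, partner loadings set from the target), which guarantees a
#' positive-definite block; partner-partner correlations arise implicitly as
#' the product of loadings.
#'
#' @param hub hub metabolite id.
#' @param partners character vector of partner ids.
#' @inheritParams planted_edge
#' @return a planted-block specification (list).
#' @export
planted_star <- function(hub, partners, rho_by_stage, rho_adjacent = 0) {
  stopifnot(length(rho_by_stage) == 3, length(partners) >= 1)
  list(type = "star", hub = hub, members = c(hub, partners),
       rho_by_stage = as.numeric(rho_by_stage),
       rho_adjacent = rho_adjacent)
}

.default_class_proportions <- c(
  FFA = 0.17, carnitine = 0.08, `OH-carnitine` = 0.03, PC = 0.19,
  LPC = 0.09, SM = 0.06, amino_acid = 0.17, nucleoside = 0.04, other = 0.17)

## Named metabolites always emitted first within their class. The acylcarnitine
## entries cover the full built-in ratio panel; the lipid and amine entries
## cover the planted-network defaults.
.core_metabolites <- list(
  carnitine = c("carnitine_C0", "carnitine_C2", "carnitine_C3", "carnitine_C4",
                "carnitine_C8", "carnitine_C10", "carnitine_C14_1",
                "carnitine_C16", "carnitine_C18", "carnitine_C5",
                "carnitine_C6", "carnitine_C12", "carnitine_C14",
                "carnitine_C16_1"),
  `OH-carnitine` = c("carnitine_C4-OH", "carnitine_C8-OH", "carnitine_C10-OH",
                     "carnitine_C5-OH"),
  FFA = c("FFA_C15_0", "FFA_C17_1", "FFA_C18_1", "FFA_C18_2", "FFA_C20_1",
          "FFA_C20_2", "FFA_C20_3", "FFA_C22_3", "FFA_C22_4"),
  PC = c("PC_30_0", "PC_33_1"),
  LPC = c("LPC_14_0"),
  SM = c("SM_34_0"),
  amino_acid = c("glycine", "proline", "serine", "glutamate", "aspartate"),
  nucleoside = c("adenosine"),
  other = c("choline", "glycerophosphorylcholine", "acetylcholine"))

.filler_pool <- function(class) {
  switch(class,
    FFA = paste0("FFA_C", rep(8:30, each = 7), "_", 0:6),
    carnitine = c(paste0("carnitine_C", 2:20), paste0("carnitine_C", 2:20, "_1")),
    `OH-carnitine` = paste0("carnitine_C", 2:20, "-OH"),
    PC = paste0("PC_", rep(28:42, each = 7), "_", 0:6),
    LPC = paste0("LPC_", rep(10:24, each = 5), "_", 0:4),
    SM = paste0("SM_", rep(30:44, each = 4), "_", 0:3),
    amino_acid = c("alanine", "valine", "leucine", "isoleucine", "threonine",
                   "methionine", "phenylalanine", "tyrosine", "tryptophan",
                   "lysine", "histidine", "arginine", "asparagine", "glutamine",
                   "ornithine", "citrulline", "taurine", "betaine", "creatine",
                   "sarcosine", "hydroxyproline", paste0("dipeptide_", 1:80)),
    nucleoside = c("guanosine", "uridine", "cytidine", "inosine", "thymidine",
                   "xanthosine", paste0("nucleoside_", 1:40)),
    other = paste0("metabolite_", 1:200))
}

.internal_standards <- data.frame(
  metabolite_id = c("IS_carnitine_C2_d3", "IS_FA_C16_d3", "IS_LPC_19_0",
                    "IS_phenylalanine_d5", "IS_choline_d4"),
  stringsAsFactors = FALSE)

.is_for_class <- c(
  carnitine = "IS_carnitine_C2_d3", `OH-carnitine` = "IS_carnitine_C2_d3",
  FFA = "IS_FA_C16_d3", PC = "IS_LPC_19_0", LPC = "IS_LPC_19_0",
  SM = "IS_LPC_19_0", amino_acid = "IS_phenylalanine_d5",
  nucleoside = "IS_choline_d4", other = "IS_choline_d4")

#' Build the synthetic metabolite catalog
#'
#' Deterministically allocates `n_metabolites` across chemical classes,
#' emitting field-named metabolites (the acylcarnitine ratio-panel species,
#' the common lipids and amines) before generic fillers, and appends the
#' spiked internal-standard registry as extra measured columns.
#'
#' @param n_metabolites number of analyte metabolites (internal standards
#'   are additional).
#' @param class_proportions named fractions over the chemical classes
#'   (must sum to 1); defaults mirror a mixed-lipid/amine tissue panel.
#' @return metabolite annotation data.frame.
#' @export
metabolite_catalog <- function(n_metabolites = 234,
                               class_proportions = NULL) {
  props <- class_proportions %||% .default_class_proportions
  if (abs(sum(props) - 1) > 1e-8) stop("class_proportions must sum to 1", call. = FALSE)
  classes <- names(props)
  counts <- floor(props * n_metabolites)
  rem <- n_metabolites - sum(counts)
  if (rem > 0) {  # distribute rounding remainder by largest fractional part
    fr <- props * n_metabolites - counts
    add <- order(fr, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  ids <- character(0); cls <- character(0)
  for (cl in classes) {
    pool <- unique(c(.core_metabolites[[cl]], .filler_pool(cl)))
    pool <- setdiff(pool, ids)
    k <- counts[[cl]]
    if (k > length(pool)) stop("filler pool exhausted for class ", cl, call. = FALSE)
    ids <- c(ids, pool[seq_len(k)])
    cls <- c(cls, rep(cl, k))
  }
  neg_classes <- c("FFA", "nucleoside")
  met <- data.frame(
    metabolite_id = ids,
    display_name = ids,
    chemical_class = cls,
    internal_standard_id = unname(.is_for_class[cls]),
    ionization_mode = ifelse(cls %in% neg_classes, "ESI-", "ESI+"),
    is_internal_standard = FALSE,
    stringsAsFactors = FALSE)
  is_df <- data.frame(
    metabolite_id = .internal_standards$metabolite_id,
    display_name = .internal_standards$metabolite_id,
    chemical_class = "other",
    internal_standard_id = NA_character_,
    ionization_mode = "ESI+",
    is_internal_standard = TRUE,
    stringsAsFactors = FALSE)
  rbind(met, is_df)
}

.default_corr_blocks <- function() {
  structure(.default_block_list(), default = TRUE)
}

.default_block_list <- function() {
  list(
    planted_star("choline",
                 c("FFA_C20_1", "FFA_C20_2", "FFA_C15_0", "LPC_14_0",
                   "glycine", "proline", "serine", "glutamate"),
                 rho_by_stage = c(0.8, 0.5, 0.1), rho_adjacent = 0),
    planted_star("carnitine_C4-OH",
                 c("carnitine_C2", "carnitine_C3", "carnitine_C4",
                   "carnitine_C5", "carnitine_C0", "carnitine_C6"),
                 rho_by_stage = c(0.3, 0.55, 0.8), rho_adjacent = 0),
    ## long-chain fatty-acid co-regulation present in tumor tissue only and
    ## constant across stages: it feeds the tumor-vs-adjacent differential
    ## correlation network but is invisible to the monotone-trajectory filter
    planted_star("FFA_C20_3",
                 c("FFA_C18_1", "FFA_C18_2", "FFA_C22_3", "FFA_C22_4",
                   "FFA_C17_1", "SM_34_0", "PC_33_1"),
                 rho_by_stage = c(0.7, 0.7, 0.7), rho_adjacent = 0))
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the emulated study design: 80 patients with paired
#' tumor/adjacent tissue, TNM stage counts 13/24/39/4, 234 annotated
#' metabolites plus spiked internal standards, pooled QC injections every 10
#' tissue samples, log-normal intensities, ~55% of metabolites carrying a
#' planted tumor effect with |log2FC| in [0.5, 2], and two planted hub stars
#' whose tumor-tissue correlations follow monotone stage trajectories (one
#' decreasing, one increasing).
#'
#' @param n_patients number of paired patients.
#' @param stage_counts named integer vector of TNM stage sizes; must sum to
#'   `n_patients`.
#' @param n_metabolites number of analyte metabolites.
#' @param class_proportions see [metabolite_catalog()].
#' @param effect_table optional data.frame (`metabolite_id`, `log2fc`); when
#'   `NULL` an effect table is drawn from `effect_fraction`/`effect_range`.
#' @param effect_fraction fraction of metabolites with a planted effect.
#' @param effect_range range of |log2 fold change| for planted effects.
#' @param corr_blocks list of [planted_edge()]/[planted_star()] blocks.
#' @param qc_target_rsd target QC relative standard deviation, percent.
#' @param qc_every one pooled QC injection per this many tissue samples.
#' @param noise_sd biological log-scale (natural log) standard deviation.
#' @param is_noise_sd log-scale sd of per-sample internal-standard response.
#' @param weight_meanlog,weight_sdlog log-normal tissue-weight parameters
#'   (mg; default centers near 10 mg).
#' @param seed integer; fully determines the generated cohort.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 80,
                             stage_counts = c(I = 13, II = 24, III = 39, IV = 4),
                             n_metabolites = 234,
                             class_proportions = NULL,
                             effect_table = NULL,
                             effect_fraction = 0.55,
                             effect_range = c(0.5, 2),
                             corr_blocks = .default_corr_blocks(),
                             qc_target_rsd = 10,
                             qc_every = 10,
                             noise_sd = 0.4,
                             is_noise_sd = 0.15,
                             weight_meanlog = log(10),
                             weight_sdlog = 0.2,
                             seed = 1) {
  ## YAML/JSON configs deliver these as lists
  stage_counts <- unlist(stage_counts)
  if (!is.null(class_proportions)) class_proportions <- unlist(class_proportions)
  effect_range <- as.numeric(unlist(effect_range))
  if (sum(stage_counts) != n_patients) {
    stop("stage_counts must sum to n_patients", call. = FALSE)
  }
  structure(list(
    n_patients = n_patients, stage_counts = stage_counts,
    n_metabolites = n_metabolites, class_proportions = class_proportions,
    effect_table = effect_table, effect_fraction = effect_fraction,
    effect_range = effect_range, corr_blocks = corr_blocks,
    qc_target_rsd = qc_target_rsd, qc_every = qc_every,
    noise_sd = noise_sd, is_noise_sd = is_noise_sd,
    weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
    seed = seed), class = "synthetic_config")
}

## Latent-Gaussian correlation matrix for one condition.
## stage: "I","II","III","IV" (IV reuses III) or "adjacent".
.build_corr_matrix <- function(met_ids, blocks, stage) {
  m <- length(met_ids)
  R <- diag(m)
  dimnames(R) <- list(met_ids, met_ids)
  stage_idx <- c(I = 1, II = 2, III = 3, IV = 3)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    missing_ids <- setdiff(blk$members, met_ids)
    if (length(missing_ids)) {
      stop("corr_blocks[[", b, "]] references unknown metabolites: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    rho <- if (stage == "adjacent") blk$rho_adjacent else blk$rho_by_stage[stage_idx[[stage]]]
    r <- rank_target_copula(rho)
    if (blk$type == "pair") {
      R[blk$members[1], blk$members[2]] <- r
      R[blk$members[2], blk$members[1]] <- r
    } else {
      partners <- setdiff(blk$members, blk$hub)
      R[blk$hub, partners] <- r
      R[partners, blk$hub] <- r
      if (length(partners) > 1) {
        pp <- outer(rep(r, length(partners)), rep(r, length(partners)))
        diag(pp) <- 1
        R[partners, partners] <- pp
      }
    }
  }
  ch <- tryCatch(chol(R), error = function(e) {
    stop("target correlation matrix for condition '", stage,
         "' is not positive definite; revise corr_blocks", call. = FALSE)
  })
  list(R = R, chol = ch)
}

.planted_edge_table <- function(blocks) {
  rows <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    rho <- blk$rho_by_stage
    d <- diff(rho)
    trend <- if (all(d <= 0) && any(d < 0)) "decreasing"
             else if (all(d >= 0) && any(d > 0)) "increasing" else "flat"
    if (blk$type == "pair") {
      pairs <- matrix(blk$members, ncol = 2)
      hub <- NA_character_
    } else {
      partners <- setdiff(blk$members, blk$hub)
      pairs <- cbind(blk$hub, partners)
      hub <- blk$hub
    }
    rows[[b]] <- data.frame(
      m1 = pairs[, 1], m2 = pairs[, 2],
      rho_I = rho[1], rho_II = rho[2], rho_III = rho[3],
      rho_adjacent = blk$rho_adjacent, trend = trend,
      block = b, hub = hub, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic paired tumor/adjacent cohort
#'
#' Draws log-scale latent values from a Gaussian copula realizing the
#' per-condition Spearman targets (planted blocks on a diagonal background),
#' shifts tumor samples by the planted log2 fold changes, exponentiates, and
#' multiplies in per-sample internal-standard response and tissue-weight
#' nuisance factors so that [normalize_intensities()] recovers the latent
#' intensities. Pooled QC samples replicate the panel mean with noise tuned
#' to the target RSD. The same seed yields a bit-identical cohort.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_cohort` with elements `peak_table` (raw),
#'   and `ground_truth` (planted effects, planted edges with trends, hub ids,
#'   latent log-intensity matrix).
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)

  met <- metabolite_catalog(cfg$n_metabolites, cfg$class_proportions)
  analyte <- met$metabolite_id[!met$is_internal_standard]
  m <- length(analyte)
  n_is <- sum(met$is_internal_standard)
  is_ids <- met$metabolite_id[met$is_internal_standard]

  stages <- rep(names(cfg$stage_counts), cfg$stage_counts)
  n_pat <- cfg$n_patients
  patients <- sprintf("P%03d", seq_len(n_pat))

  small <- names(cfg$stage_counts)[cfg$stage_counts < 5]
  if (length(small) && length(cfg$corr_blocks)) {
    warning("stage(s) with fewer than 5 patients (",
            paste(small, collapse = ", "),
            "): planted correlations will be unstable there", call. = FALSE)
  }

  ## the stock planted blocks adapt to scaled-down catalogs; user-supplied
  ## blocks referencing unknown metabolites stay a hard error
  if (isTRUE(attr(cfg$corr_blocks, "default"))) {
    cfg$corr_blocks <- Filter(Negate(is.null), lapply(cfg$corr_blocks, function(b) {
      if (b$type == "star") {
        partners <- intersect(setdiff(b$members, b$hub), analyte)
        if (!(b$hub %in% analyte) || !length(partners)) return(NULL)
        planted_star(b$hub, partners, b$rho_by_stage, b$rho_adjacent)
      } else {
        if (!all(b$members %in% analyte)) return(NULL)
        b
      }
    }))
  }

  ## 1. baselines
  mu <- stats::rnorm(m, mean = 11.5, sd = 1.2)
  names(mu) <- analyte

  ## 2. planted effects
  eff <- cfg$effect_table
  if (is.null(eff)) {
    n_eff <- round(cfg$effect_fraction * m)
    idx <- sample.int(m, n_eff)
    eff <- data.frame(
      metabolite_id = analyte[idx],
      log2fc = stats::runif(n_eff, cfg$effect_range[1], cfg$effect_range[2]) *
        sample(c(-1, 1), n_eff, replace = TRUE),
      stringsAsFactors = FALSE)
  } else {
    unknown <- setdiff(eff$metabolite_id, analyte)
    if (length(unknown)) stop("effect_table references unknown metabolites: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
  }
  fc <- setNames(rep(0, m), analyte)
  fc[eff$metabolite_id] <- eff$log2fc

  ## 3. nuisance factors
  w_tum <- exp(stats::rnorm(n_pat, cfg$weight_meanlog, cfg$weight_sdlog))
  w_adj <- exp(stats::rnorm(n_pat, cfg$weight_meanlog, cfg$weight_sdlog))
  n_tissue <- 2L * n_pat
  n_qc <- max(3L, ceiling(n_tissue / cfg$qc_every))
  n_samples <- n_tissue + n_qc
  is_factor <- exp(matrix(stats::rnorm(n_samples * n_is, 0, cfg$is_noise_sd),
                          n_samples, n_is))

  ## 4. latent Gaussians per condition
  chol_adj <- .build_corr_matrix(analyte, cfg$corr_blocks, "adjacent")$chol
  z_adj <- matrix(stats::rnorm(n_pat * m), n_pat, m) %*% chol_adj
  z_tum <- matrix(0, n_pat, m)
  for (st in unique(stages)) {
    rows <- which(stages == st)
    ch <- .build_corr_matrix(analyte, cfg$corr_blocks, st)$chol
    z_tum[rows, ] <- matrix(stats::rnorm(length(rows) * m), length(rows), m) %*% ch
  }

  lat_tum <- sweep(cfg$noise_sd * z_tum, 2, mu + log(2) * fc, `+`)
  lat_adj <- sweep(cfg$noise_sd * z_adj, 2, mu, `+`)

  ## 5. QC replicates of the pooled panel mean
  sigma_qc <- sqrt(log1p((cfg$qc_target_rsd / 100)^2))
  lat_qc <- sweep(matrix(stats::rnorm(n_qc * m, 0, sigma_qc), n_qc, m), 2, mu, `+`)

  ## 6. assemble raw responses
  latent <- rbind(lat_tum, lat_adj, lat_qc)
  sample_ids <- c(paste0(patients, "_T"), paste0(patients, "_A"),
                  sprintf("QC%02d", seq_len(n_qc)))
  rownames(latent) <- sample_ids
  colnames(latent) <- analyte

  ## raw response = latent intensity x assigned-IS response x tissue weight,
  ## so dividing by the measured IS response and the weight recovers latent.
  is_nominal <- exp(10)
  is_cols <- is_factor * is_nominal
  colnames(is_cols) <- is_ids
  met_is_col <- match(met$internal_standard_id[!met$is_internal_standard], is_ids)
  raw <- exp(latent) * is_cols[, met_is_col, drop = FALSE]
  ## per-sample tissue weight applies to tissue rows only
  weights <- c(w_tum, w_adj, rep(NA_real_, n_qc))
  raw[seq_len(n_tissue), ] <- raw[seq_len(n_tissue), , drop = FALSE] *
    weights[seq_len(n_tissue)]
  raw <- cbind(raw, is_cols)

  clin <- .draw_clinical_indices(n_pat, stages)
  samples <- data.frame(
    sample_id = sample_ids,
    patient_id = c(patients, patients, rep(NA_character_, n_qc)),
    tissue_type = c(rep("tumor", n_pat), rep("adjacent", n_pat), rep("QC", n_qc)),
    tissue_weight = weights,
    tnm_stage = c(stages, stages, rep("none", n_qc)),
    stringsAsFactors = FALSE)
  samples <- cbind(samples, rbind(clin, clin,
                                  clin[rep(NA_integer_, n_qc), , drop = FALSE]))
  rownames(samples) <- NULL

  pt <- peak_table(raw, samples, met, normalized = FALSE)
  gt <- list(
    effects = eff[order(eff$metabolite_id), , drop = FALSE],
    planted_edges = .planted_edge_table(cfg$corr_blocks),
    hubs = unique(stats::na.omit(vapply(cfg$corr_blocks, function(b)
      if (b$type == "star") b$hub else NA_character_, ""))),
    latent_log = latent)
  structure(list(peak_table = pt, ground_truth = gt, config = cfg),
            class = "synthetic_cohort")
}

## Categorical clinical indices loosely shaped like a gastric-cancer cohort
## sheet (Lauren typing, infiltration depth, invasion flags, Borrmann, Her2,
## nodal/metastasis status). Drawn independently of the metabolome.
.draw_clinical_indices <- function(n_pat, stages) {
  data.frame(
    lauren = sample(c("intestinal", "mixed", "diffuse"), n_pat, TRUE,
                    prob = c(0.3, 0.3, 0.4)),
    infiltration_depth = sample(c("mucosa", "muscularis", "subserosa", "serosa"),
                                n_pat, TRUE, prob = c(0.1, 0.16, 0.29, 0.45)),
    nerve_invasion = sample(c("no", "yes"), n_pat, TRUE, prob = c(0.43, 0.57)),
    vascular_invasion = sample(c("no", "yes"), n_pat, TRUE, prob = c(0.62, 0.38)),
    borrmann = sample(c("1", "2", "3", "4"), n_pat, TRUE,
                      prob = c(0.05, 0.53, 0.4, 0.02)),
    her2 = sample(c("negative", "positive"), n_pat, TRUE, prob = c(0.81, 0.19)),
    pN = sample(c("0", "1", "2", "3"), n_pat, TRUE,
                prob = c(0.34, 0.19, 0.21, 0.26)),
    pM = ifelse(stages == "IV", "yes", "no"),
    stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort (seed ", x$config$seed, ")\n", sep = "")
  print(x$peak_table)
  cat("  planted effects:", nrow(x$ground_truth$effects),
      "| planted edges:", nrow(x$ground_truth$planted_edges),
      "| hubs:", paste(x$ground_truth$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to the package's CSV formats
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("peaktable.csv", "samples.csv", "metabolites.csv",
                            "ground_truth.json"))
  write_peak_table(cohort$peak_table, paths[1], paths[2], paths[3])
  gt <- cohort$ground_truth
  gt$latent_log <- NULL  # bulky; regenerable from the seed
  jsonlite::write_json(gt, paths[4], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
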