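#' Pipeline configuration
#'
#' Collects every stage's thresholds and seeds. Either `input` paths
#' (peak table / metadata / annotation CSVs) or a `synthetic` block
#' (arguments of [synthetic_config()]) must be supplied. Any field can be
#' overridden; the defaults mirror the standard protocol (alpha 0.05, FDR
#' 0.05, network alpha 0.01, trajectory thresholds 0.05/0.02, 15 hubs,
#' 4:1 split, 5-fold CV).
#'
#' @param input optional list(path, metadata_path, annotation_path).
#' @param synthetic optional list of [synthetic_config()] arguments.
#' @param out_dir output bundle directory.
#' @param seed master seed; stage seeds default to offsets of it.
#' @param stages character vector of stages to run, any of `"normalize"`,
#'   `"qc"`, `"univariate"`, `"plsda"`, `"enrich"`, `"diffcorr"`, `"ratios"`,
#'   `"biomarker"`, `"nam"` (default: all).
#' @param alpha univariate significance level.
#' @param fdr_threshold FDR threshold shared by the differential screen and
#'   the differential network.
#' @param missing_max_fraction see [handle_missing()].
#' @param plsda_max_components,plsda_folds,plsda_permutations PLS-DA
#'   settings (permutations default 2000).
#' @param nam_alpha,nam_diff_min,nam_equal_tol,nam_hub_k stage-network
#'   settings.
#' @param split_ratio discovery:validation ratio.
#' @param pathways optional GMT path for enrichment; by default pathway sets
#'   are derived from the chemical classes in the annotations.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            out_dir = "metnam_run", seed = 1,
                            stages = c("normalize", "qc", "univariate",
                                       "plsda", "enrich", "diffcorr",
                                       "ratios", "biomarker", "nam"),
                            alpha = 0.05, fdr_threshold = 0.05,
                            missing_max_fraction = 0.5,
                            plsda_max_components = 3, plsda_folds = 5,
                            plsda_permutations = 2000,
                            nam_alpha = 0.01, nam_diff_min = 0.05,
                            nam_equal_tol = 0.02, nam_hub_k = 15,
                            split_ratio = 4, pathways = NULL) {
  if (is.null(input) && is.null(synthetic)) {
    stop("pipeline_config needs 'input' paths or a 'synthetic' block",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

.class_pathways <- function(metabolites) {
  met <- metabolites[!metabolites$is_internal_standard, ]
  split(met$metabolite_id, paste0("class_", met$chemical_class))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — normalize, QC,
#' univariate screen, PLS-DA, enrichment, differential correlation network,
#' ratio panel, biomarker ROC, stage-wise network topology — writing one
#' TSV/JSON report per stage plus a provenance manifest (serialized config,
#' seeds, content hashes) into the output bundle. Identical configuration
#' and inputs yield a byte-identical bundle. Any stage error aborts the run,
#' removes the partially written bundle, and names the failing stage.
#'
#' @param cfg a `pipeline_config`.
#' @return invisibly, a list with the per-stage in-memory results and
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  if (dir.exists(out)) unlink(out, recursive = TRUE)
  dir.create(out, recursive = TRUE)
  results <- list()
  stage <- "input"
  tryCatch({
    if (!is.null(cfg$input)) {
      pt <- read_peak_table(cfg$input$path, cfg$input$metadata_path,
                            cfg$input$annotation_path)
      gt <- NULL
    } else {
      syn_args <- cfg$synthetic
      syn_args$seed <- syn_args$seed %||% cfg$seed
      cohort <- generate_cohort(do.call(synthetic_config, syn_args))
      pt <- cohort$peak_table
      gt <- cohort$ground_truth
      write_cohort(cohort, file.path(out, "00_synthetic_input"))
    }

    run_stage <- function(name) name %in% cfg$stages
    norm <- pt

    if (run_stage("normalize")) {
      stage <- "normalize"
      norm <- handle_missing(
        suppressWarnings(normalize_intensities(pt)),
        cfg$missing_max_fraction)
      write_peak_table(norm, file.path(out, "01_normalized_peaktable.tsv"),
                       file.path(out, "01_samples.tsv"))
      results$normalized <- norm
    }

    if (run_stage("qc")) {
      stage <- "qc"
      qc <- compute_qc_rsd(norm)
      write_tsv(qc$table, file.path(out, "02_qc_rsd.tsv"))
      jsonlite::write_json(
        list(n_qc = qc$n_qc, fractions = as.list(qc$fractions)),
        file.path(out, "02_qc_summary.json"), auto_unbox = TRUE, digits = NA)
      results$qc <- qc
    }

    diff <- NULL
    if (run_stage("univariate")) {
      stage <- "univariate"
      diff <- differential_analysis(norm)
      write_tsv(diff, file.path(out, "03_differential.tsv"))
      scan <- suppressWarnings(clinical_association_scan(
        norm, diff$metabolite_id[diff$p_value < cfg$alpha], alpha = cfg$alpha))
      write_tsv(scan$table, file.path(out, "03_clinical_associations.tsv"))
      results$differential <- diff
      results$clinical <- scan
    }

    if (run_stage("plsda")) {
      stage <- "plsda"
      pm <- paired_matrices(norm)
      x <- rbind(pm$tumor, pm$adjacent)
      y <- rep(c("tumor", "adjacent"), each = length(pm$patients))
      perm <- permutation_test(x, y, B = cfg$plsda_permutations,
                               k = cfg$plsda_folds, seed = cfg$seed + 1)
      cv <- select_components_cv(x, y, max_components = cfg$plsda_max_components,
                                 k = cfg$plsda_folds, seed = cfg$seed + 1)
      jsonlite::write_json(
        list(per_component = cv$table, chosen_ncomp = cv$ncomp,
             permutation = list(B = perm$B, statistic = perm$statistic,
                                observed = perm$observed, p_value = perm$p_value)),
        file.path(out, "04_plsda.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "columns")
      results$plsda <- list(cv = cv, permutation = perm)
    }

    if (run_stage("enrich")) {
      stage <- "enrich"
      if (is.null(diff)) diff <- differential_analysis(norm)
      sets <- if (is.null(cfg$pathways)) .class_pathways(norm$metabolites)
              else read_gmt(cfg$pathways)
      selected <- diff$metabolite_id[diff$fdr < cfg$fdr_threshold]
      enr <- if (length(selected)) {
        hypergeometric_enrichment(selected, sets, diff$metabolite_id)
      } else {
        data.frame()
      }
      write_tsv(enr, file.path(out, "05_enrichment.tsv"))
      results$enrichment <- enr
    }

    if (run_stage("diffcorr")) {
      stage <- "diffcorr"
      pm <- paired_matrices(norm)
      net <- build_differential_network(pm$adjacent, pm$tumor,
                                        fdr_threshold = cfg$fdr_threshold)
      write_tsv(net$edges, file.path(out, "06_diffcorr_edges.tsv"))
      write_tsv(net$degree, file.path(out, "06_diffcorr_degree.tsv"))
      write_graphml(net$graph, file.path(out, "06_diffcorr_network.graphml"))
      results$diffcorr <- net
    }

    if (run_stage("ratios")) {
      stage <- "ratios"
      rp <- suppressWarnings(compute_ratio_panel(norm))
      write_tsv(rp$tests, file.path(out, "07_ratio_panel.tsv"))
      results$ratios <- rp
    }

    if (run_stage("biomarker")) {
      stage <- "biomarker"
      split <- split_patients(norm$samples, ratio = cfg$split_ratio,
                              seed = cfg$seed + 2)
      disc_patients <- names(split$assignment)[split$assignment == "discovery"]
      keep <- norm$samples$tissue_type == "QC" |
        norm$samples$patient_id %in% disc_patients
      disc_pt <- peak_table(norm$intensities[keep, , drop = FALSE],
                            norm$samples[keep, , drop = FALSE],
                            norm$metabolites, normalized = TRUE)
      disc_diff <- differential_analysis(disc_pt)
      top <- rank_markers(disc_diff, top_k = 10)
      markers <- top[seq_len(min(2, length(top)))]
      roc <- suppressWarnings(combine_markers(norm, split, markers))
      split_df <- data.frame(patient_id = names(split$assignment),
                             set = unname(split$assignment))
      write_tsv(split_df, file.path(out, "08_split.tsv"))
      jsonlite::write_json(
        list(markers = roc$markers, auc_discovery = roc$auc_discovery,
             auc_validation = roc$auc_validation, threshold = roc$threshold,
             sensitivity = as.list(roc$sensitivity),
             specificity = as.list(roc$specificity)),
        file.path(out, "08_biomarker.json"), auto_unbox = TRUE, digits = NA)
      results$biomarker <- list(split = split, ranked = top, roc = roc)
    }

    if (run_stage("nam")) {
      stage <- "nam"
      nam <- suppressWarnings(nam_analysis(
        norm, alpha = cfg$nam_alpha, diff_min = cfg$nam_diff_min,
        equal_tol = cfg$nam_equal_tol, hub_k = cfg$nam_hub_k))
      write_tsv(nam$subnetworks$edges, file.path(out, "09_nam_monotone_edges.tsv"))
      hubs_df <- data.frame(
        stage = rep(names(nam$hubs$hub_by_stage),
                    vapply(nam$hubs$hub_by_stage, length, 0L)),
        node = unlist(nam$hubs$hub_by_stage, use.names = FALSE))
      write_tsv(hubs_df, file.path(out, "09_nam_hubs.tsv"))
      tri_df <- do.call(rbind, lapply(nam$triplets, function(t) {
        do.call(rbind, lapply(names(t$stars), function(st) {
          s <- t$stars[[st]]
          if (!nrow(s)) return(NULL)
          data.frame(hub = t$hub, stage = st, s, stringsAsFactors = FALSE)
        }))
      }))
      if (is.null(tri_df)) {
        tri_df <- data.frame(hub = character(0), stage = character(0),
                             neighbor = character(0), weight = numeric(0),
                             sign = character(0), trend = character(0))
      }
      write_tsv(tri_df, file.path(out, "09_nam_triplets.tsv"))
      results$nam <- nam
    }

    stage <- "manifest"
    cfg_json <- file.path(out, "config.json")
    cfg_ser <- cfg
    cfg_ser$out_dir <- NULL
    jsonlite::write_json(cfg_ser, cfg_json, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
    files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.json"))
    manifest <- list(
      config = "config.json",
      seed = cfg$seed,
      stages_run = intersect(c("normalize", "qc", "univariate", "plsda",
                               "enrich", "diffcorr", "ratios", "biomarker",
                               "nam"), cfg$stages),
      files = lapply(files, function(f)
        list(path = f, md5 = unname(tools::md5sum(file.path(out, f))))))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) {
    unlink(out, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(c(results, list(out_dir = out, ground_truth = if (exists("gt")) gt)))
}
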