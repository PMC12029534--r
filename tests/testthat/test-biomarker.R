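test_that("patient split honors the 4:1 ratio, pairing, and the seed", {
  co <- small_cohort(seed = 19, n_patients = 80,
                     stage_counts = c(I = 13, II = 24, III = 39, IV = 4),
                     n_metabolites = 20)
  smp <- co$peak_table$samples
  sp <- split_patients(smp, ratio = 4, seed = 5)
  expect_equal(sum(sp$assignment == "discovery"), 64)
  expect_equal(sum(sp$assignment == "validation"), 16)
  expect_identical(sp$assignment, split_patients(smp, 4, seed = 5)$assignment)
  ## tumor and adjacent samples of a patient never straddle the sets
  tis <- smp[smp$tissue_type != "QC", ]
  sets <- sp$assignment[tis$patient_id]
  expect_true(all(tapply(sets, tis$patient_id, function(v) length(unique(v))) == 1))
  expect_error(split_patients(smp[smp$patient_id %in% c("P001", "P002") &
                                    !is.na(smp$patient_id), ]),
               "at least 5")
})

test_that("pair-counting AUC matches hand examples and symmetries", {
  expect_equal(roc_auc(c(4, 5, 6, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 1)
  expect_equal(roc_auc(rep(2, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  ## label flip maps AUC to 1 - AUC
  s <- c(0.3, 0.8, 0.1, 0.9, 0.5); l <- c(0, 1, 0, 1, 1)
  expect_equal(roc_auc(s, l), 1 - roc_auc(s, 1 - l))
  ## invariant under strictly increasing transforms
  expect_equal(roc_auc(exp(s), l), roc_auc(s, l))
  expect_error(roc_auc(s, rep(1, 5)), "both classes")
})

test_that("pair counting, trapezoidal integration, and pROC agree", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    scores <- round(rnorm(n), sample(c(1, 3), 1))  # induce occasional ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    a1 <- roc_auc(scores, labels)
    a2 <- auc_trapezoid(roc_curve(scores, labels))
    expect_equal(a1, a2, tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(56)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("marker ranking uses p, then |fold change|, then id", {
  d <- data.frame(metabolite_id = c("b", "a", "c", "d"),
                  p_value = c(0.01, 0.01, 0.001, 0.5),
                  log2_fold_change = c(1, 2, 0.1, 3))
  expect_identical(rank_markers(d, 10), c("c", "a", "b", "d"))
  expect_identical(rank_markers(d, 2), c("c", "a"))
})

test_that("a single marker reduces to that marker's oriented ROC", {
  co <- small_cohort(seed = 29, n_patients = 30,
                     stage_counts = c(I = 15, II = 15), n_metabolites = 40)
  pt <- suppressWarnings(normalize_intensities(co$peak_table))
  sp <- split_patients(pt$samples, seed = 2)
  eff <- co$ground_truth$effects
  marker <- eff$metabolite_id[which.max(eff$log2fc)]   # increases in tumor
  roc <- suppressWarnings(combine_markers(pt, sp, marker))
  smp <- pt$samples[pt$samples$tissue_type != "QC", ]
  disc <- sp$assignment[smp$patient_id] == "discovery"
  x <- intensity_matrix(pt)[, marker]
  direct <- roc_auc(x[disc], smp$tissue_type[disc] == "tumor")
  expect_equal(roc$auc_discovery, max(direct, 1 - direct), tolerance = 1e-10)
})

test_that("no validation-set value influences the fitted combination", {
  co <- small_cohort(seed = 31, n_patients = 30,
                     stage_counts = c(I = 15, II = 15), n_metabolites = 40)
  pt <- suppressWarnings(normalize_intensities(co$peak_table))
  sp <- split_patients(pt$samples, seed = 7)
  markers <- rank_markers(differential_analysis(pt), 2)
  r1 <- suppressWarnings(combine_markers(pt, sp, markers))

  ## scramble validation samples' values; discovery-side outputs must not move
  x <- pt$intensities
  val_p <- names(sp$assignment)[sp$assignment == "validation"]
  val_rows <- which(pt$samples$patient_id %in% val_p)
  set.seed(1)
  x[val_rows, ] <- x[sample(val_rows), ]
  pt2 <- peak_table(x, pt$samples, pt$metabolites, normalized = TRUE)
  r2 <- suppressWarnings(combine_markers(pt2, sp, markers))
  expect_identical(r1$coefficients, r2$coefficients)
  expect_identical(r1$threshold, r2$threshold)
  expect_identical(r1$auc_discovery, r2$auc_discovery)
  expect_identical(unname(r1$sensitivity["discovery"]),
                   unname(r2$sensitivity["discovery"]))
})

test_that("combining two noisy markers beats either alone on discovery", {
  wins <- vapply(1:20, function(s) {
    set.seed(600 + s)
    n <- 120
    y <- rep(c(TRUE, FALSE), each = n / 2)
    m1 <- ifelse(y, 1.5, 0) + rnorm(n)
    m2 <- ifelse(y, 1.5, 0) + rnorm(n)
    x <- cbind(m1 = exp(m1), m2 = exp(m2), noise = exp(rnorm(n)))
    ids <- sprintf("P%03d", rep(seq_len(n / 2), each = 2))[seq_len(n)]
    ## build a paired-looking table: half tumor half adjacent
    samples <- data.frame(
      sample_id = paste0("S", seq_len(n)),
      patient_id = rep(sprintf("P%03d", seq_len(n / 2)), 2),
      tissue_type = rep(c("tumor", "adjacent"), each = n / 2),
      tissue_weight = 10, tnm_stage = "I", stringsAsFactors = FALSE)
    rownames(x) <- samples$sample_id
    mets <- data.frame(metabolite_id = colnames(x), display_name = colnames(x),
                       chemical_class = "other", internal_standard_id = NA,
                       ionization_mode = "ESI+", is_internal_standard = FALSE)
    pt <- peak_table(x, samples, mets, normalized = TRUE)
    sp <- split_patients(samples, seed = s)
    both <- suppressWarnings(combine_markers(pt, sp, c("m1", "m2")))
    one <- suppressWarnings(combine_markers(pt, sp, "m1"))
    two <- suppressWarnings(combine_markers(pt, sp, "m2"))
    both$auc_discovery > max(one$auc_discovery, two$auc_discovery)
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})
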