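test_that("peak table round-trips through CSV unchanged", {
  pt <- toy_peak_table()
  dir <- withr::local_tempdir()
  p <- file.path(dir, c("x.csv", "s.csv", "m.csv"))
  write_peak_table(pt, p[1], p[2], p[3])
  back <- read_peak_table(p[1], p[2], p[3])
  expect_identical(back$intensities, pt$intensities)
  expect_identical(back$samples$tissue_type, pt$samples$tissue_type)
  expect_identical(back$metabolites$internal_standard_id,
                   pt$metabolites$internal_standard_id)
  expect_false(back$normalized)

  ## write -> read -> write -> read is also the identity
  write_peak_table(back, p[1], p[2], p[3])
  again <- read_peak_table(p[1], p[2], p[3])
  expect_identical(again$intensities, pt$intensities)
})

test_that("malformed inputs are rejected with informative errors", {
  pt <- toy_peak_table()
  dir <- withr::local_tempdir()
  p <- file.path(dir, c("x.csv", "s.csv", "m.csv"))
  write_peak_table(pt, p[1], p[2], p[3])

  meta <- read.csv(p[2])
  write.csv(meta[-2, ], file.path(dir, "missing.csv"), row.names = FALSE)
  expect_error(read_peak_table(p[1], file.path(dir, "missing.csv"), p[3]),
               "P1_A")

  tab <- readLines(p[1])
  tab[3] <- sub("^P1_A,[0-9.e+]+", "P1_A,oops", tab[3])
  writeLines(tab, file.path(dir, "bad.csv"))
  expect_error(read_peak_table(file.path(dir, "bad.csv"), p[2], p[3]),
               "non-numeric.*P1_A.*m1")

  smp <- pt$samples; smp$sample_id[2] <- "P1_T"
  expect_error(peak_table(pt$intensities, smp, pt$metabolites), "duplicate")
  met <- pt$metabolites; met$internal_standard_id[1] <- "IS9"
  expect_error(peak_table(pt$intensities, pt$samples, met), "IS9")
})

test_that("normalization divides by internal standard then tissue weight", {
  pt <- toy_peak_table()
  norm <- normalize_intensities(pt)
  ## raw 100 / IS 50 / weight 10 mg -> 0.2 per mg
  expect_equal(norm$intensities["P1_T", "m1"], 0.2)
  ## QC samples skip the weight division
  expect_equal(norm$intensities["QC01", "m1"], 3)
  ## internal-standard columns are consumed
  expect_false("IS1" %in% colnames(norm$intensities))
  expect_true(norm$normalized)
  expect_error(normalize_intensities(norm), "already normalized")
})

test_that("normalization is invariant to joint per-sample rescaling", {
  pt <- toy_peak_table()
  scaled <- pt$intensities
  scaled["P1_T", ] <- scaled["P1_T", ] * 7   # raw and IS jointly
  pt2 <- peak_table(scaled, pt$samples, pt$metabolites)
  expect_identical(normalize_intensities(pt)$intensities,
                   normalize_intensities(pt2)$intensities)
})

test_that("zero internal standard flags cells missing, zero weight errors", {
  pt <- toy_peak_table()
  x <- pt$intensities
  x["P2_T", "IS1"] <- 0
  pt2 <- peak_table(x, pt$samples, pt$metabolites)
  expect_warning(norm <- normalize_intensities(pt2), "flagged missing")
  expect_true(all(is.na(norm$intensities["P2_T", ])))
  expect_false(anyNA(norm$intensities["P1_T", ]))

  smp <- pt$samples
  smp$tissue_weight[3] <- 0
  expect_error(peak_table(pt$intensities, smp, pt$metabolites),
               "tissue_weight")
})

test_that("QC RSD matches hand and two-pass computations", {
  x <- rbind(QC1 = c(10, 8), QC2 = c(10, 10), QC3 = c(10, 12))
  colnames(x) <- c("flat", "spread")
  samples <- data.frame(sample_id = rownames(x), patient_id = NA,
                        tissue_type = "QC", tissue_weight = NA,
                        tnm_stage = "none")
  mets <- data.frame(metabolite_id = colnames(x), display_name = colnames(x),
                     chemical_class = "other", internal_standard_id = NA,
                     ionization_mode = "ESI+", is_internal_standard = FALSE)
  qc <- compute_qc_rsd(peak_table(x, samples, mets))
  expect_equal(qc$table$rsd, c(0, 20))   # sd(8,10,12) = 2, mean 10
  expect_equal(unname(qc$fractions), c(0.5, 1))

  expect_error(compute_qc_rsd(peak_table(x[1:2, ], samples[1:2, ], mets)),
               "at least 3")

  set.seed(42)
  y <- matrix(rexp(5 * 8), 5, 8,
              dimnames = list(paste0("QC", 1:5), paste0("m", 1:8)))
  s2 <- data.frame(sample_id = rownames(y), patient_id = NA,
                   tissue_type = "QC", tissue_weight = NA, tnm_stage = "none")
  m2 <- data.frame(metabolite_id = colnames(y), display_name = colnames(y),
                   chemical_class = "other", internal_standard_id = NA,
                   ionization_mode = "ESI+", is_internal_standard = FALSE)
  got <- compute_qc_rsd(peak_table(y, s2, m2))$table$rsd
  want <- vapply(seq_len(ncol(y)),
                 function(j) 100 * sd(y[, j]) / mean(y[, j]), 0)
  expect_equal(got, want)
})

test_that("missing-value policy drops then half-min imputes", {
  co <- small_cohort(seed = 2)
  pt <- suppressWarnings(normalize_intensities(co$peak_table))
  expect_identical(handle_missing(pt)$intensities, pt$intensities)

  x <- pt$intensities
  x[seq_len(round(0.9 * nrow(x))), 1] <- NA     # 90% missing -> dropped
  x[1, 3] <- NA                                  # single cell -> imputed
  pt2 <- peak_table(x, pt$samples, pt$metabolites, normalized = TRUE)
  expect_message(fixed <- handle_missing(pt2, 0.5), "dropping 1")
  expect_false(colnames(x)[1] %in% colnames(fixed$intensities))
  expect_equal(fixed$intensities[1, colnames(x)[3]],
               min(x[-1, 3], na.rm = TRUE) / 2)
  expect_error(handle_missing(pt2, 1.5), "\\[0, 1\\]")
})
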