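test_that("paired Wilcoxon matches hand-derived exact p-values", {
  ## six positive differences: two one-sided tails of 1/64 each
  r <- paired_wilcoxon(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))
  expect_equal(r$p_value, 0.03125)
  expect_equal(r$statistic, 21)
  ## differences (1,2,3,4,-5): 10 of 32 sign vectors at or below W- = 5
  r2 <- paired_wilcoxon(c(1, 2, 3, 4, -5), rep(0, 5))
  expect_equal(r2$p_value, 0.625)
  expect_warning(r3 <- paired_wilcoxon(1:4, 1:4), "zero")
  expect_equal(r3$p_value, 1)
  expect_error(paired_wilcoxon(1:3, 1:4), "equal length")
})

test_that("exact signed-rank p equals enumeration and the classical distribution for n <= 10", {
  set.seed(7)
  for (n in 4:10) {
    for (rep in 1:3) {
      d <- round(rnorm(n), 2)
      d[d == 0] <- 0.11
      got <- paired_wilcoxon(d, rep(0, n))$p_value
      expect_equal(got, bf_signrank_p(d), info = paste("n =", n))
      if (!any(duplicated(abs(d)))) {
        ref <- wilcox.test(d, exact = TRUE)$p.value
        expect_equal(got, ref, tolerance = 1e-12, info = paste("n =", n))
      }
    }
    ## tied absolute differences still agree with enumeration
    d_tied <- c(rep(0.5, 2), seq_len(n - 2))
    expect_equal(paired_wilcoxon(d_tied, rep(0, n))$p_value,
                 bf_signrank_p(d_tied))
  }
})

test_that("Mann-Whitney matches enumeration, symmetry and the rank-sum oracle", {
  r <- mannwhitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2 / choose(6, 3)

  ## swapping groups maps U to n1*n2 - U with identical p
  a <- c(1.2, 3.1, 0.5, 2.2); b <- c(2.5, 4.1, 1.9)
  r1 <- mannwhitney_test(a, b); r2 <- mannwhitney_test(b, a)
  expect_equal(r1$statistic + r2$statistic, length(a) * length(b))
  expect_equal(r1$p_value, r2$p_value)

  expect_equal(mannwhitney_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mannwhitney_test(numeric(0), 1:3), "non-empty")

  set.seed(8)
  for (n1 in 2:5) {
    for (n2 in 2:(10 - n1)) {
      x <- round(runif(n1), 3); y <- round(runif(n2), 3)
      got <- mannwhitney_test(x, y)$p_value
      expect_equal(got, bf_mannwhitney_p(x, y),
                   info = paste(n1, n2, sep = "/"))
      if (!any(duplicated(c(x, y)))) {
        expect_equal(got, wilcox.test(x, y, exact = TRUE)$p.value,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("BH q-values match the step-up recursion and stay monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bf_bh(p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("differential screen flags planted effects with consistent directions", {
  co <- small_cohort(seed = 6, n_patients = 20,
                     stage_counts = c(I = 10, II = 10), n_metabolites = 40,
                     effect_fraction = 0.5)
  pt <- suppressWarnings(normalize_intensities(co$peak_table))
  d <- differential_analysis(pt)
  expect_setequal(d$metabolite_id, colnames(pt$intensities))
  expect_true(all(d$fdr >= 0 & d$fdr <= 1))
  eff <- co$ground_truth$effects
  hit <- d[match(eff$metabolite_id, d$metabolite_id), ]
  strong <- abs(eff$log2fc) > 1
  expect_gt(mean(hit$p_value[strong] < 0.05), 0.9)
  same_sign <- sign(hit$log2_fold_change[strong]) == sign(eff$log2fc[strong])
  expect_gt(mean(same_sign), 0.95)
  ## direction annotation is the sign of the fold change
  expect_true(all((d$log2_fold_change > 0) == (d$direction == "up")))
})

test_that("clinical association scan behaves on degenerate and planted inputs", {
  co <- small_cohort(seed = 13, n_patients = 40,
                     stage_counts = c(I = 20, II = 20), n_metabolites = 20)
  pt <- suppressWarnings(normalize_intensities(co$peak_table))
  expect_identical(nrow(clinical_association_scan(pt, character(0))$table), 0L)

  ## constant metabolite: every contrast p = 1
  x <- pt$intensities
  x[, 1] <- 1
  ptc <- peak_table(x, pt$samples, pt$metabolites, normalized = TRUE)
  scan <- suppressWarnings(
    clinical_association_scan(ptc, colnames(x)[1], indices = "lauren"))
  expect_true(all(scan$table$p_value == 1))

  ## metabolite shifted +3 sd in one Lauren class is flagged
  hits <- vapply(1:20, function(s) {
    set.seed(900 + s)
    xi <- pt$intensities
    tum <- pt$samples$tissue_type == "tumor"
    grp <- tum & pt$samples$lauren == "diffuse"
    xi[grp, 2] <- xi[grp, 2] + 3 * sd(xi[tum, 2])
    pts <- peak_table(xi, pt$samples, pt$metabolites, normalized = TRUE)
    sc <- suppressWarnings(
      clinical_association_scan(pts, colnames(xi)[2], indices = "lauren"))
    any(sc$table$significant[grepl("diffuse", sc$table$contrast)])
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  ## single-level index is skipped with a warning
  smp <- pt$samples
  smp$mono <- "same"
  ptm <- peak_table(pt$intensities, smp, pt$metabolites, normalized = TRUE)
  expect_warning(clinical_association_scan(ptm, colnames(x)[2], indices = "mono"),
                 "fewer than two")
})

test_that("hypergeometric enrichment matches combinatorial values", {
  universe <- paste0("m", 1:10)
  res <- hypergeometric_enrichment(universe[1:5],
                                   list(pw = universe[1:5]), universe)
  expect_equal(res$p_value, 1 / choose(10, 5))

  res2 <- hypergeometric_enrichment(universe[1:4],
                                    list(all = universe), universe)
  expect_equal(res2$p_value, 1)

  ## oracle equivalence against the explicit pmf sum
  set.seed(3)
  for (i in 1:25) {
    N <- sample(10:40, 1); K <- sample(1:N, 1); k <- sample(1:N, 1)
    uni <- paste0("x", 1:N)
    pw <- sample(uni, K); sel <- sample(uni, k)
    ov <- length(intersect(pw, sel))
    got <- hypergeometric_enrichment(sel, list(a = pw), uni)$p_value
    want <- sum(vapply(ov:min(K, k), function(j)
      choose(K, j) * choose(N - K, k - j) / choose(N, k), 0))
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(hypergeometric_enrichment(character(0), list(a = "m1"), universe),
               "empty")
  expect_error(hypergeometric_enrichment("zz", list(a = "m1"), universe),
               "outside the universe")
})

test_that("type-I error of the paired screen is calibrated under the null", {
  ## null cohorts: no planted effects, no planted correlations
  ps <- unlist(lapply(1:17, function(s) {
    co <- generate_cohort(synthetic_config(
      n_patients = 30, stage_counts = c(I = 15, II = 15),
      n_metabolites = 120, effect_fraction = 0, corr_blocks = list(),
      seed = 400 + s))
    pt <- suppressWarnings(normalize_intensities(co$peak_table))
    differential_analysis(pt)$p_value
  }))
  expect_gte(length(ps), 2000)
  expect_gte(mean(ps < 0.05), 0.03)
  expect_lte(mean(ps < 0.05), 0.07)
})
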