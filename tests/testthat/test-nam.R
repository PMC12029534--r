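test_that("monotone predicate follows the trajectory rules", {
  expect_identical(monotone_edge_predicate(c(0.8, 0.5, 0.1)), "decreasing")
  ## sub-tolerance steps count as equal and the 0.05 hurdle is unmet
  expect_identical(monotone_edge_predicate(c(0.50, 0.49, 0.48)), "reject")
  expect_identical(monotone_edge_predicate(c(0.2, 0.6, 0.3)), "reject")
  ## significant in stage II only: the zero weights break monotonicity
  expect_identical(monotone_edge_predicate(c(0, 0.6, 0)), "reject")
  ## significant in stage III only: zeros then a jump is monotone increasing
  expect_identical(monotone_edge_predicate(c(0, 0, 0.45)), "increasing")
  ## a 0.02 back-step is tolerated by default but not in strict mode
  expect_identical(monotone_edge_predicate(c(0.8, 0.81, 0.5)), "decreasing")
  expect_identical(monotone_edge_predicate(c(0.8, 0.81, 0.5), strict = TRUE),
                   "reject")
})

test_that("negating all weights swaps accepted trends", {
  set.seed(41)
  w <- matrix(runif(300, -1, 1), ncol = 3)
  a <- monotone_edge_predicate(w)
  b <- monotone_edge_predicate(-w)
  swap <- c(decreasing = "increasing", increasing = "decreasing",
            reject = "reject")
  expect_identical(unname(swap[a]), b)
})

test_that("stage networks keep significant correlations and drop stage IV by default", {
  co <- small_cohort(seed = 51, n_patients = 80,
                     stage_counts = c(I = 13, II = 24, III = 39, IV = 4),
                     n_metabolites = 30)
  pt <- suppressWarnings(normalize_intensities(co$peak_table))
  expect_warning(nets <- build_stage_networks(pt), "IV")
  expect_identical(nets$stages, c("I", "II", "III"))
  expect_equal(unname(nets$n), c(13, 24, 39))
  ## weights are correlations, bounded by construction
  for (st in nets$stages) {
    w <- nets$weights[[st]]
    expect_true(all(abs(w) <= 1))
    expect_true(all(diag(w) == 0))
  }
  expect_error(build_stage_networks(pt, stages = c("I", "II", "V")), "V")
  ## adjacent-tissue reference network is attached
  expect_false(is.null(nets$adjacent))
})

test_that("a perfectly correlated pair appears with weight 1; sub-threshold pairs get 0", {
  set.seed(61)
  n <- 30
  x <- cbind(a = 1:n + 0, b = (1:n)^2, c = rnorm(n), d = rnorm(n))
  stage <- rep(c("I", "II", "III"), each = 10)
  nets <- build_stage_networks(x, stage = stage)
  for (st in c("I", "II", "III")) {
    expect_equal(nets$weights[[st]]["a", "b"], 1)
  }
  ## a weight is zero whenever its p-value fails alpha
  cm <- spearman_matrix(x[stage == "I", , drop = FALSE])
  expect_identical(nets$weights[["I"]]["c", "d"] == 0,
                   !(cm$p["c", "d"] < 0.01))
})

test_that("subnetwork membership requires presence in the stage network", {
  ids <- c("a", "b", "c")
  mk <- function(w_ab) {
    m <- matrix(0, 3, 3, dimnames = list(ids, ids))
    m["a", "b"] <- m["b", "a"] <- w_ab
    m
  }
  nets <- structure(list(stages = c("I", "II", "III"),
                         weights = list(I = mk(0.8), II = mk(0.5), III = mk(0)),
                         rho = NULL, n = c(I = 10, II = 10, III = 10),
                         nodes = ids, adjacent = NULL, alpha = 0.01),
                    class = "stage_network_set")
  sub <- extract_monotone_subnetworks(nets)
  expect_identical(nrow(sub$edges), 1L)
  expect_identical(sub$edges$trend, "decreasing")
  expect_true(sub$edges$in_SG_I && sub$edges$in_SG_II)
  expect_false(sub$edges$in_SG_III)
  expect_identical(nrow(sub$by_stage$III), 0L)
})

test_that("hub selection keeps ties at the cutoff and unions across stages", {
  ids <- letters[1:6]
  edges <- data.frame(
    met_a = c("a", "a", "a", "b", "c"),
    met_b = c("b", "c", "d", "c", "d"),
    trend = "decreasing",
    w_I = 0.5, w_II = 0.3, w_III = 0.1,
    in_SG_I = TRUE, in_SG_II = FALSE, in_SG_III = FALSE,
    stringsAsFactors = FALSE)
  sub <- structure(list(edges = edges,
                        by_stage = list(I = edges, II = edges[0, ], III = edges[0, ]),
                        stages = c("I", "II", "III"), nodes = ids),
                   class = "monotone_subnetworks")
  ## degrees: a 3, b 2, c 3, d 2 -> k = 2 cutoff at degree 3? no: sorted (3,3,2,2)
  hubs <- suppressWarnings(select_hubs(sub, k = 2))
  expect_setequal(hubs$hub_by_stage$I, c("a", "c"))
  hubs3 <- suppressWarnings(select_hubs(sub, k = 3))
  expect_setequal(hubs3$hub_by_stage$I, c("a", "b", "c", "d"))  # tie inclusion
  expect_warning(select_hubs(sub, k = 15), "empty|positive-degree")
  expect_setequal(suppressWarnings(select_hubs(sub, k = 3))$hubs,
                  c("a", "b", "c", "d"))
})

test_that("triplets are the hubs' star subgraphs with sign annotations", {
  co <- small_cohort(seed = 71, n_patients = 45,
                     stage_counts = c(I = 15, II = 15, III = 15),
                     n_metabolites = 30)
  pt <- suppressWarnings(normalize_intensities(co$peak_table))
  nam <- suppressWarnings(nam_analysis(pt, hub_k = 3))
  for (t in nam$triplets) {
    for (st in names(t$stars)) {
      s <- t$stars[[st]]
      e <- nam$subnetworks$by_stage[[st]]
      inc <- e$met_a == t$hub | e$met_b == t$hub
      expect_identical(sort(s$neighbor),
                       sort(ifelse(e$met_a[inc] == t$hub, e$met_b[inc],
                                   e$met_a[inc])))
      expect_identical(unname(t$degree[st]), nrow(s))
      if (nrow(s)) expect_true(all((s$weight > 0) == (s$sign == "positive")))
    }
  }
})

test_that("SG_t is always contained in G_t", {
  co <- small_cohort(seed = 81, n_patients = 30,
                     stage_counts = c(I = 10, II = 10, III = 10),
                     n_metabolites = 25)
  pt <- suppressWarnings(normalize_intensities(co$peak_table))
  nets <- build_stage_networks(pt)
  sub <- extract_monotone_subnetworks(nets)
  for (st in nets$stages) {
    e <- sub$by_stage[[st]]
    if (!nrow(e)) next
    w <- nets$weights[[st]]
    expect_true(all(w[cbind(e$met_a, e$met_b)] != 0))
  }
})

test_that("a planted monotone star grows its triplet across stages", {
  cfg <- synthetic_config(
    n_patients = 120, stage_counts = c(I = 40, II = 40, III = 40),
    n_metabolites = 150, effect_fraction = 0,
    corr_blocks = list(planted_star("carnitine_C4-OH",
                                    c("carnitine_C2", "carnitine_C3",
                                      "carnitine_C4", "carnitine_C0"),
                                    rho_by_stage = c(0.2, 0.5, 0.8))),
    seed = 91)
  pt <- suppressWarnings(normalize_intensities(generate_cohort(cfg)$peak_table))
  nam <- suppressWarnings(nam_analysis(pt))
  expect_true("carnitine_C4-OH" %in% names(nam$triplets))
  deg <- nam$triplets[["carnitine_C4-OH"]]$degree
  expect_true(deg["III"] >= deg["I"])
  expect_gte(unname(deg["III"]), 3)
})

test_that("extraction matches the literal brute-force recipe on random instances", {
  set.seed(101)
  for (i in 1:10) {
    m <- sample(6:10, 1); n <- sample(12:18, 1)
    xs <- lapply(1:3, function(t) {
      x <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("f", 1:m)))
      if (runif(1) < 0.7) {
        g <- rnorm(n)
        k <- sample(2:m, 1)
        x[, 1:k] <- x[, 1:k] + outer(g, runif(k, 0.5, 1.5))
      }
      x
    })
    bf <- bf_nam(xs, k = 15)
    x_all <- do.call(rbind, xs)
    stage <- rep(c("I", "II", "III"), times = vapply(xs, nrow, 0L))
    nets <- build_stage_networks(x_all, stage = stage)
    sub <- extract_monotone_subnetworks(nets)
    hubs <- suppressWarnings(select_hubs(sub, k = 15))
    for (t in 1:3) {
      st <- c("I", "II", "III")[t]
      e <- sub$by_stage[[st]]
      got <- if (nrow(e)) paste(pmin(e$met_a, e$met_b), pmax(e$met_a, e$met_b))
             else character(0)
      want <- if (nrow(bf$edges[[t]])) paste(bf$edges[[t]]$a, bf$edges[[t]]$b)
              else character(0)
      expect_setequal(got, want)
      expect_identical(hubs$hub_by_stage[[st]], bf$hubs[[t]])
    }
  }
})
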