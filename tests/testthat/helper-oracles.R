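# Independent brute-force oracles. These re-derive expected values from first
# principles, structured differently from the package implementations.

## two-sided signed-rank p by explicit enumeration of sign vectors
bf_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

## two-sided Mann-Whitney p by enumeration of group assignments, with U
## computed from pairwise comparisons (not rank sums)
bf_mannwhitney_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  combs <- combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

## BH step-up written as the textbook backward recursion
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## all permutations of a vector, depth-first (independent of the package's)
bf_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, ncol = 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- bf_perms(v[-i])
    out <- cbind(out, rbind(v[i], sub))
  }
  out
}

## exact Spearman permutation p using the classical d^2 formula (untied data)
bf_spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(r2) 1 - 6 * sum((rx - r2)^2) / (n * (n^2 - 1))
  obs <- rho_of(ry)
  perms <- bf_perms(ry)
  null_rho <- apply(perms, 2, rho_of)
  mean(abs(null_rho) >= abs(obs) - 1e-12)
}

## literal stage-wise network-topology recipe: builds per-stage weights with
## cor.test, then applies the Temp/SG conditions, top-k-with-ties hubs and
## star subgraphs by direct set comprehension
bf_nam <- function(xs, alpha = 0.01, diff_min = 0.05, equal_tol = 0.02, k = 15) {
  m <- ncol(xs[[1]])
  ids <- colnames(xs[[1]])
  w <- lapply(xs, function(x) {
    wt <- matrix(0, m, m, dimnames = list(ids, ids))
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        ct <- suppressWarnings(stats::cor.test(x[, i], x[, j],
                                               method = "spearman",
                                               exact = FALSE))
        if (ct$p.value < alpha) wt[i, j] <- wt[j, i] <- unname(ct$estimate)
      }
    }
    wt
  })
  sg <- list(list(), list(), list())
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      tri <- c(w[[1]][i, j], w[[2]][i, j], w[[3]][i, j])
      d12 <- tri[1] - tri[2]; d23 <- tri[2] - tri[3]
      in_temp <- abs(d12) > diff_min || abs(d23) > diff_min
      dec <- d12 >= -equal_tol && d23 >= -equal_tol
      inc <- d12 <= equal_tol && d23 <= equal_tol
      if (in_temp && (dec || inc)) {
        for (t in 1:3) {
          if (tri[t] != 0) {
            sg[[t]][[length(sg[[t]]) + 1L]] <- c(ids[i], ids[j])
          }
        }
      }
    }
  }
  edge_df <- lapply(sg, function(e) {
    if (!length(e)) return(data.frame(a = character(0), b = character(0)))
    df <- as.data.frame(do.call(rbind, e), stringsAsFactors = FALSE)
    names(df) <- c("a", "b")
    df[order(df$a, df$b), , drop = FALSE]
  })
  hubs <- lapply(edge_df, function(e) {
    if (!nrow(e)) return(character(0))
    deg <- table(c(e$a, e$b))
    if (length(deg) <= k) return(sort(names(deg)))
    cutoff <- sort(as.integer(deg), decreasing = TRUE)[k]
    sort(names(deg)[deg >= cutoff])
  })
  hub_union <- sort(unique(unlist(hubs)))
  stars <- lapply(hub_union, function(v) {
    lapply(1:3, function(t) {
      e <- edge_df[[t]]
      inc <- e$a == v | e$b == v
      nb <- ifelse(e$a[inc] == v, e$b[inc], e$a[inc])
      sort(nb)
    })
  })
  names(stars) <- hub_union
  list(weights = w, edges = edge_df, hubs = hubs, hub_union = hub_union,
       stars = stars)
}

## small paired cohort used across module tests
small_cohort <- function(seed = 1, n_patients = 12,
                         stage_counts = c(I = 4, II = 4, III = 4),
                         n_metabolites = 30, ...) {
  suppressWarnings(generate_cohort(synthetic_config(
    n_patients = n_patients, stage_counts = stage_counts,
    n_metabolites = n_metabolites, seed = seed, ...)))
}

## paired peak table holding constant per-sample metabolite values
ratio_fixture <- function(values, n_pairs = 1) {
  ids <- names(values)
  n <- 2 * n_pairs
  x <- matrix(rep(unlist(values), each = n), n, length(ids),
              dimnames = list(c(paste0("P", seq_len(n_pairs), "_T"),
                                paste0("P", seq_len(n_pairs), "_A")), ids))
  samples <- data.frame(
    sample_id = rownames(x),
    patient_id = rep(paste0("P", seq_len(n_pairs)), 2),
    tissue_type = rep(c("tumor", "adjacent"), each = n_pairs),
    tissue_weight = 10, tnm_stage = "I", stringsAsFactors = FALSE)
  mets <- data.frame(metabolite_id = ids, display_name = ids,
                     chemical_class = "carnitine", internal_standard_id = NA,
                     ionization_mode = "ESI+", is_internal_standard = FALSE,
                     stringsAsFactors = FALSE)
  peak_table(x, samples, mets, normalized = TRUE)
}

## hand-built four-sample peak table with one internal standard
toy_peak_table <- function() {
  ids <- c("m1", "m2", "m3", "IS1")
  x <- rbind(
    P1_T = c(100, 40, 10, 50),
    P1_A = c(80, 20, 30, 40),
    P2_T = c(60, 50, 20, 20),
    QC01 = c(90, 30, 15, 30))
  colnames(x) <- ids
  samples <- data.frame(
    sample_id = rownames(x),
    patient_id = c("P1", "P1", "P2", NA),
    tissue_type = c("tumor", "adjacent", "tumor", "QC"),
    tissue_weight = c(10, 8, 5, NA),
    tnm_stage = c("I", "I", "II", "none"),
    stringsAsFactors = FALSE)
  mets <- data.frame(
    metabolite_id = ids,
    display_name = ids,
    chemical_class = c("FFA", "PC", "amino_acid", "other"),
    internal_standard_id = c("IS1", "IS1", "IS1", NA),
    ionization_mode = "ESI+",
    is_internal_standard = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  peak_table(x, samples, mets)
}
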