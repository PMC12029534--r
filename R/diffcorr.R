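#' Spearman correlation matrix with p-values
#'
#' Rank correlation (average ranks under ties) between all column pairs.
#' P-values use the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' n - 2 degrees of freedom; for n <= `exact_max` the exact permutation
#' p-value is computed instead by enumerating all n! orderings of one
#' variable's (possibly tied) ranks. Constant columns yield `NA`
#' correlations with a warning.
#'
#' @param x numeric matrix (samples x metabolites), n >= 4.
#' @param group optional group label carried in the result.
#' @param exact_max largest n for exact permutation p-values (default 8).
#' @return object of class `correlation_matrix`: `group`, `n`, `rho`, `p`.
#' @export
spearman_matrix <- function(x, group = NA_character_, exact_max = 8) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  const <- apply(x, 2, function(v) length(unique(v[!is.na(v)])) <= 1)
  if (any(const)) {
    warning("constant column(s), correlations undefined: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  }
  rho <- suppressWarnings(stats::cor(x, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho) <- ifelse(const, NA, 1)
  if (n <= exact_max) {
    p <- .spearman_exact_p_matrix(x, rho)
  } else {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    p[abs(rho) >= 1] <- 0
  }
  diag(p) <- NA
  structure(list(group = group, n = n, rho = rho, p = p),
            class = "correlation_matrix")
}

## Exact permutation null for every pair: the null distribution of rho given
## the two (tied) rank vectors is generated over all n! orderings.
.spearman_exact_p_matrix <- function(x, rho) {
  n <- nrow(x)
  perms <- .permutations(n)
  p <- rho * NA
  for (i in seq_len(ncol(x) - 1)) {
    for (j in (i + 1):ncol(x)) {
      if (is.na(rho[i, j])) next
      ri <- rank(x[, i]); rj <- rank(x[, j])
      null_rho <- suppressWarnings(
        stats::cor(ri, matrix(rj[perms], nrow = n), method = "pearson"))
      p[i, j] <- p[j, i] <- mean(abs(null_rho) >= abs(rho[i, j]) - 1e-12)
    }
  }
  p
}

## all permutations of 1..n as an n x n! index matrix
.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    block <- rbind(rep(k, ncol(sub)), sub + (sub >= k))
    out[, col + seq_len(ncol(sub))] <- block
    col <- col + ncol(sub)
  }
  out
}

#' Fisher-z test for a correlation difference between two groups
#'
#' `z = (atanh(rho_a) - atanh(rho_b)) / sqrt(v/(n_a-3) + v/(n_b-3))` with
#' `v = 1` by default (the convention of differential-correlation packages
#' when applied to Spearman coefficients) or `v = 1.06` (Fieller correction
#' for rank correlations) when `fieller = TRUE`; p from the standard normal.
#'
#' @param rho_a,rho_b correlations in groups A and B (vectors allowed).
#' @param n_a,n_b group sample sizes (> 3).
#' @param fieller use the 1.06/(n-3) variance.
#' @return list with `z` and two-sided `p_value`.
#' @export
diffcorr_test <- function(rho_a, n_a, rho_b, n_b, fieller = FALSE) {
  if (any(n_a <= 3) || any(n_b <= 3)) stop("group sizes must exceed 3", call. = FALSE)
  if (any(abs(c(rho_a, rho_b)) >= 1, na.rm = TRUE)) {
    stop("|rho| must be < 1 (Fisher z is infinite at |rho| = 1)", call. = FALSE)
  }
  v <- if (fieller) 1.06 else 1
  z <- (atanh(rho_a) - atanh(rho_b)) / sqrt(v / (n_a - 3) + v / (n_b - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Differential Spearman correlation network
#'
#' Tests every metabolite pair for a change in Spearman correlation between
#' two sample groups (Fisher z), controls the FDR over all pairs (BH), and
#' keeps the significant pairs as edges of an undirected network. Edges are
#' annotated `gain` (correlation higher in group B than A) or `loss`;
#' connected components are reported as modules and nodes are ranked by
#' degree (ties share the better rank).
#'
#' @param x_a,x_b matrices (samples x metabolites) with identical columns;
#'   e.g. adjacent tissue as A and tumor as B.
#' @param fdr_threshold edge-retention threshold on the BH q-value.
#' @param fieller passed to [diffcorr_test()].
#' @return object of class `diffcorr_network`: `edges` (pair, rho_a, rho_b,
#'   z, p_value, fdr, direction), `modules` (node, module), `degree` (node,
#'   degree, rank), `graph` (igraph), `n_tested`.
#' @export
build_differential_network <- function(x_a, x_b, fdr_threshold = 0.05,
                                       fieller = FALSE) {
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  if (!identical(colnames(x_a), colnames(x_b))) {
    stop("both groups must share the same metabolite set", call. = FALSE)
  }
  if (nrow(x_a) < 4 || nrow(x_b) < 4) stop("need at least 4 samples per group", call. = FALSE)
  ca <- spearman_matrix(x_a, "A")
  cb <- spearman_matrix(x_b, "B")
  ut <- which(upper.tri(ca$rho), arr.ind = TRUE)
  rho_a <- ca$rho[ut]; rho_b <- cb$rho[ut]
  ok <- !is.na(rho_a) & !is.na(rho_b) & abs(rho_a) < 1 & abs(rho_b) < 1
  z <- p <- rep(NA_real_, nrow(ut))
  if (any(ok)) {
    dt <- diffcorr_test(rho_a[ok], ca$n, rho_b[ok], cb$n, fieller = fieller)
    z[ok] <- dt$z; p[ok] <- dt$p_value
  }
  fdr <- rep(NA_real_, length(p))
  fdr[ok] <- bh_fdr(p[ok])
  mets <- colnames(x_a)
  edges <- data.frame(
    met_a = mets[ut[, 1]], met_b = mets[ut[, 2]],
    rho_group_a = rho_a, rho_group_b = rho_b,
    n_a = ca$n, n_b = cb$n, z = z, p_value = p, fdr = fdr,
    direction = ifelse(rho_b > rho_a, "gain", "loss"),
    stringsAsFactors = FALSE)
  keep <- !is.na(edges$fdr) & edges$fdr < fdr_threshold
  sig <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sig[, c("met_a", "met_b")],
                                     directed = FALSE, vertices = mets)
  comp <- igraph::components(g)
  in_module <- comp$membership[comp$csize[comp$membership] >= 2]
  modules <- data.frame(node = names(in_module),
                        module = match(unname(in_module), unique(unname(in_module))),
                        row.names = NULL, stringsAsFactors = FALSE)
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  degree <- data.frame(node = names(deg)[ord], degree = unname(deg)[ord],
                       rank = rank(-deg, ties.method = "min")[ord],
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(edges = sig, all_pairs = edges, modules = modules,
                 degree = degree, graph = g, n_tested = sum(ok),
                 fdr_threshold = fdr_threshold),
            class = "diffcorr_network")
}

#' @export
print.diffcorr_network <- function(x, ...) {
  cat(sprintf("differential correlation network: %d/%d pairs at FDR < %g, %d module(s)\n",
              nrow(x$edges), x$n_tested, x$fdr_threshold,
              length(unique(x$modules$module))))
  invisible(x)
}

#' Export a network in GraphML for external viewers
#'
#' @param graph an igraph object (e.g. `$graph` of a `diffcorr_network`).
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
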