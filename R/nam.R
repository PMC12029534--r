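#' Per-stage Spearman correlation networks
#'
#' Builds, for each ordered tumor stage, a weighted network on the common
#' metabolite set: an edge joins two metabolites when their stage-specific
#' Spearman correlation is significant (p < `alpha`, default 0.01), with the
#' correlation as the edge weight; otherwise the weight is 0 (the zero
#' weight participates as such in the monotone-trajectory test). Stages
#' with fewer than `min_samples` tumor samples are excluded with a warning —
#' on a cohort shaped like the emulated one (13/24/39/4) this retains
#' stages I-III. An adjacent-tissue reference network built at the same
#' alpha is attached for display parity; it plays no role in subnetwork
#' extraction.
#'
#' @param pt a normalized `peak_table`, or a samples x metabolites matrix
#'   (then `stage` must give one label per row and no reference network is
#'   built).
#' @param alpha per-edge significance threshold (default 0.01).
#' @param stages ordered stage labels to include; default: all stages with
#'   at least `min_samples` tumor samples, in I < II < III < IV order.
#' @param min_samples minimum tumor samples per included stage (default 5).
#' @param stage stage labels per row when `pt` is a matrix.
#' @return object of class `stage_network_set`: `stages`, `weights` (list of
#'   weight matrices), `rho`, `n` (per-stage sample counts), `nodes`,
#'   `adjacent` (reference weight matrix or `NULL`), `alpha`.
#' @export
build_stage_networks <- function(pt, alpha = 0.01, stages = NULL,
                                 min_samples = 5, stage = NULL) {
  if (inherits(pt, "peak_table")) {
    tum <- pt$samples$tissue_type == "tumor"
    x <- intensity_matrix(pt, "tumor")
    labels <- pt$samples$tnm_stage[tum]
    adj_x <- intensity_matrix(pt, "adjacent")
  } else {
    x <- as.matrix(pt)
    if (is.null(stage) || length(stage) != nrow(x)) {
      stop("when pt is a matrix, 'stage' must label every row", call. = FALSE)
    }
    labels <- as.character(stage)
    adj_x <- NULL
  }
  canonical <- c("I", "II", "III", "IV")
  present <- unique(labels)
  present <- c(intersect(canonical, present), setdiff(sort(present), canonical))
  if (!is.null(stages)) {
    absent <- setdiff(stages, present)
    if (length(absent)) {
      stop("stage(s) ", paste(absent, collapse = ", "),
           " absent from metadata; available: ", paste(present, collapse = ", "),
           call. = FALSE)
    }
  } else {
    counts <- table(labels)[present]
    too_small <- present[counts < min_samples]
    if (length(too_small)) {
      warning("excluding stage(s) with fewer than ", min_samples,
              " samples: ", paste(too_small, collapse = ", "), call. = FALSE)
    }
    stages <- present[counts >= min_samples]
  }
  if (length(stages) < 2) stop("need at least two stages", call. = FALSE)

  weight_of <- function(rows) {
    cm <- spearman_matrix(x[rows, , drop = FALSE])
    w <- ifelse(!is.na(cm$p) & cm$p < alpha, cm$rho, 0)
    diag(w) <- 0
    list(w = w, rho = cm$rho, n = cm$n)
  }
  nets <- lapply(stages, function(st) weight_of(labels == st))
  names(nets) <- stages
  adjacent <- NULL
  if (!is.null(adj_x) && nrow(adj_x) >= 4) {
    acm <- spearman_matrix(adj_x)
    adjacent <- ifelse(!is.na(acm$p) & acm$p < alpha, acm$rho, 0)
    diag(adjacent) <- 0
  }
  structure(list(
    stages = stages,
    weights = lapply(nets, `[[`, "w"),
    rho = lapply(nets, `[[`, "rho"),
    n = vapply(nets, `[[`, 0, "n"),
    nodes = colnames(x),
    adjacent = adjacent,
    alpha = alpha), class = "stage_network_set")
}

#' Monotone-trajectory edge predicate
#'
#' Classifies a weight triple (w_I, w_II, w_III) as an accepted decreasing
#' or increasing trajectory, or rejects it. Acceptance requires (1)
#' monotonicity across the three stage networks, where an adjacent-stage
#' change of at most `equal_tol` (default 0.02) counts as equality — i.e.
#' each step may violate the monotone order by at most `equal_tol` — and
#' (2) an adjacent-stage difference larger than `diff_min` (default 0.05) in
#' at least one of the two stage pairs. `strict = TRUE` drops the equality
#' tolerance. Non-significant stage weights enter as exact zeros.
#'
#' @param w numeric length-3 vector or 3-column matrix of weight triples.
#' @param diff_min required adjacent-stage difference (at least one pair).
#' @param equal_tol almost-equal tolerance on adjacent-stage changes.
#' @param strict require literal monotone order with no tolerance.
#' @return character vector: `"decreasing"`, `"increasing"`, or `"reject"`.
#' @export
monotone_edge_predicate <- function(w, diff_min = 0.05, equal_tol = 0.02,
                                    strict = FALSE) {
  if (is.null(dim(w))) w <- matrix(w, ncol = 3)
  stopifnot(ncol(w) == 3)
  tol <- if (strict) 0 else equal_tol
  dec <- (w[, 2] <= w[, 1] + tol) & (w[, 3] <= w[, 2] + tol)
  inc <- (w[, 2] >= w[, 1] - tol) & (w[, 3] >= w[, 2] - tol)
  big <- pmax(abs(w[, 1] - w[, 2]), abs(w[, 2] - w[, 3])) > diff_min
  out <- rep("reject", nrow(w))
  out[big & dec] <- "decreasing"
  out[big & inc] <- "increasing"
  ## a triple passing both relaxed orders has a dominant net drift
  both <- big & dec & inc
  out[both] <- ifelse(w[both, 3] >= w[both, 1], "increasing", "decreasing")
  out
}

#' Extract monotone-trajectory subnetworks
#'
#' For every metabolite pair, evaluates [monotone_edge_predicate()] on its
#' stage-weight triple; the stage-t subnetwork SG_t keeps the accepted pairs
#' that are edges of G_t (non-zero stage-t weight). An accepted pair absent
#' from one stage's network (weight 0 there) therefore belongs only to the
#' other stages' subnetworks.
#'
#' @param nets a `stage_network_set` with exactly 3 stages.
#' @param diff_min,equal_tol,strict passed to [monotone_edge_predicate()].
#' @return object of class `monotone_subnetworks`: `edges` (data.frame of
#'   accepted pairs with weight triples, trend, and per-stage membership
#'   flags), `stages`, per-stage edge lists in `by_stage`.
#' @export
extract_monotone_subnetworks <- function(nets, diff_min = 0.05,
                                         equal_tol = 0.02, strict = FALSE) {
  stopifnot(inherits(nets, "stage_network_set"))
  if (length(nets$stages) != 3) {
    stop("monotone extraction is defined over exactly 3 ordered stages; got ",
         length(nets$stages), call. = FALSE)
  }
  W <- nets$weights
  ut <- which(upper.tri(W[[1]]), arr.ind = TRUE)
  wt <- cbind(W[[1]][ut], W[[2]][ut], W[[3]][ut])
  verdict <- monotone_edge_predicate(wt, diff_min, equal_tol, strict)
  acc <- verdict != "reject"
  nodes <- nets$nodes
  edges <- data.frame(
    met_a = nodes[ut[acc, 1]], met_b = nodes[ut[acc, 2]],
    trend = verdict[acc], stringsAsFactors = FALSE)
  for (s in 1:3) {
    edges[[paste0("w_", nets$stages[s])]] <- wt[acc, s]
  }
  for (s in 1:3) {
    edges[[paste0("in_SG_", nets$stages[s])]] <- wt[acc, s] != 0
  }
  by_stage <- lapply(1:3, function(s) {
    edges[edges[[paste0("in_SG_", nets$stages[s])]], , drop = FALSE]
  })
  names(by_stage) <- nets$stages
  structure(list(edges = edges, by_stage = by_stage, stages = nets$stages,
                 nodes = nodes, diff_min = diff_min, equal_tol = equal_tol,
                 strict = strict),
            class = "monotone_subnetworks")
}

#' @export
print.monotone_subnetworks <- function(x, ...) {
  cat("monotone subnetworks over stages", paste(x$stages, collapse = " < "), "\n")
  for (st in x$stages) {
    cat(sprintf("  SG_%s: %d edge(s)\n", st, nrow(x$by_stage[[st]])))
  }
  invisible(x)
}

.stage_degrees <- function(subnets, st) {
  e <- subnets$by_stage[[st]]
  deg <- setNames(rep(0L, length(subnets$nodes)), subnets$nodes)
  if (nrow(e)) {
    tab <- table(c(e$met_a, e$met_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Select hub nodes of the monotone subnetworks
#'
#' Ranks nodes by degree within each stage subnetwork SG_t and takes the top
#' `k` (default 15) per stage; every node tied with the k-th degree value is
#' included, so the selection is order-independent. Stages with fewer than
#' `k` positive-degree nodes contribute all of them, with a warning. The hub
#' set is the union over stages.
#'
#' @param subnets a `monotone_subnetworks`.
#' @param k per-stage hub count (default 15).
#' @return list with `hub_by_stage` (named list of node sets), `hubs`
#'   (union), `degrees` (per-stage degree tables).
#' @export
select_hubs <- function(subnets, k = 15) {
  stopifnot(inherits(subnets, "monotone_subnetworks"))
  degrees <- lapply(subnets$stages, function(st) .stage_degrees(subnets, st))
  names(degrees) <- subnets$stages
  hub_by_stage <- lapply(subnets$stages, function(st) {
    deg <- degrees[[st]]
    pos <- deg[deg > 0]
    if (!length(pos)) {
      warning("SG_", st, " is empty; no hubs there", call. = FALSE)
      return(character(0))
    }
    if (length(pos) <= k) {
      if (length(pos) < k) {
        warning("SG_", st, " has only ", length(pos),
                " positive-degree node(s) (k = ", k, ")", call. = FALSE)
      }
      return(sort(names(pos)))
    }
    cutoff <- sort(pos, decreasing = TRUE)[k]
    sort(names(pos)[pos >= cutoff])
  })
  names(hub_by_stage) <- subnets$stages
  list(hub_by_stage = hub_by_stage,
       hubs = sort(unique(unlist(hub_by_stage))),
       degrees = degrees)
}

#' Informative star-subgraph triplets
#'
#' For each hub node v, returns the triplet of star subgraphs
#' (Info-SG_I(v), Info-SG_II(v), Info-SG_III(v)): v with its incident edges
#' in each stage subnetwork, annotated with the correlation sign (positive /
#' negative) of each edge in that stage.
#'
#' @param subnets a `monotone_subnetworks`.
#' @param hubs result of [select_hubs()] (or a character vector of node ids).
#' @return named list (one entry per hub) of class `nam_triplets`; each
#'   entry holds per-stage data.frames (`neighbor`, `weight`, `sign`,
#'   `trend`) and the per-stage degree of the hub.
#' @export
build_triplets <- function(subnets, hubs) {
  stopifnot(inherits(subnets, "monotone_subnetworks"))
  ids <- if (is.list(hubs)) hubs$hubs else hubs
  tri <- lapply(ids, function(v) {
    stars <- lapply(subnets$stages, function(st) {
      e <- subnets$by_stage[[st]]
      inc <- e$met_a == v | e$met_b == v
      e <- e[inc, , drop = FALSE]
      w <- e[[paste0("w_", st)]]
      data.frame(neighbor = ifelse(e$met_a == v, e$met_b, e$met_a),
                 weight = w,
                 sign = ifelse(w > 0, "positive", "negative"),
                 trend = e$trend, stringsAsFactors = FALSE)
    })
    names(stars) <- subnets$stages
    list(hub = v, stars = stars,
         degree = vapply(stars, nrow, 0L))
  })
  names(tri) <- ids
  structure(tri, class = "nam_triplets")
}

#' @export
print.nam_triplets <- function(x, ...) {
  cat("informative subnetwork triplets for", length(x), "hub(s)\n")
  for (t in x) {
    cat(sprintf("  %s: star sizes %s\n", t$hub,
                paste(t$degree, collapse = " / ")))
  }
  invisible(x)
}

#' Full stage-wise network-topology analysis
#'
#' Convenience wrapper running [build_stage_networks()],
#' [extract_monotone_subnetworks()], [select_hubs()] and [build_triplets()]
#' with the standard thresholds (edge alpha 0.01, trajectory difference
#' 0.05, equality tolerance 0.02, 15 hubs per stage).
#'
#' @param pt a normalized `peak_table` (or matrix; see
#'   [build_stage_networks()]).
#' @param alpha,stages,min_samples,stage passed to [build_stage_networks()].
#' @param diff_min,equal_tol,strict passed to
#'   [extract_monotone_subnetworks()].
#' @param hub_k passed to [select_hubs()].
#' @return list with `networks`, `subnetworks`, `hubs`, `triplets`.
#' @export
nam_analysis <- function(pt, alpha = 0.01, stages = NULL, min_samples = 5,
                         stage = NULL, diff_min = 0.05, equal_tol = 0.02,
                         strict = FALSE, hub_k = 15) {
  nets <- build_stage_networks(pt, alpha = alpha, stages = stages,
                               min_samples = min_samples, stage = stage)
  if (length(nets$stages) > 3) {
    nets_stages <- nets$stages[1:3]
    nets$weights <- nets$weights[nets_stages]
    nets$rho <- nets$rho[nets_stages]
    nets$n <- nets$n[nets_stages]
    nets$stages <- nets_stages
  }
  subnets <- extract_monotone_subnetworks(nets, diff_min = diff_min,
                                          equal_tol = equal_tol, strict = strict)
  hubs <- suppressWarnings(select_hubs(subnets, k = hub_k))
  trip <- build_triplets(subnets, hubs)
  list(networks = nets, subnetworks = subnets, hubs = hubs, triplets = trip)
}
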