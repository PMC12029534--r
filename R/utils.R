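#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd median pt pnorm phyper p.adjust glm binomial
#'   predict quantile rnorm runif setNames complete.cases
#' @importFrom utils read.csv write.csv write.table combn head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Reserved sample-metadata columns; anything else is a clinical index.
.sample_core_cols <- c("sample_id", "patient_id", "tissue_type",
                       "tissue_weight", "tnm_stage")

.assert_prob <- function(p, what = "p-values") {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

## Deterministic, side-effect-free use of a caller-supplied seed: the global
## RNG state is restored on exit so seeded helpers do not perturb each other.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
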