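#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows distinct rename pull n across
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap
#' @importFrom stats median quantile rnorm rlnorm rpois runif cor.test t.test
#'   plogis glm binomial coef predict setNames
#' @importFrom utils head tail
#' @importFrom mclust Mclust mclustBIC
NULL

# Deterministic sub-stream seed derivation: every generator consumes its own
# seed derived from the single pipeline seed, so components can be regenerated
# independently.  Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(as.numeric(seed)) * 48271 + 1103 * stream) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_range <- function(x, name) {
  if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2]) {
    abort(sprintf("`%s` must be a valid (min, max) range with min <= max.", name),
          class = "csefinder_config_error")
  }
  invisible(x)
}

# gene id from an exon id of the form "<gene>:E<index>"
exon_gene <- function(exon_id) sub(":E[0-9]+$", "", exon_id)

row_medians <- function(m) {
  if (is.null(dim(m))) return(median(m))
  apply(m, 1L, median)
}
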