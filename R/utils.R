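#' @keywords internal
#' @useDynLib spindlr, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. All stochastic entry points funnel through this so
# no function mutates global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stop_spindlr <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower)
    stop_spindlr(sprintf("`%s` must be a finite numeric scalar >= %s", name, lower))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
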