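# Shared internal helpers.

# Run `expr` under a temporary, isolated RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero at a given number of decimals
#'
#' Commercial ("half-up") rounding, used for integer intensity conversion and
#' for rendering metric tables at two decimals. Base `round()` rounds half to
#' even, which would turn 0.975 into 0.98 or 0.97 depending on binary
#' representation; reports here always round half up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(127.5)      # 128
#' round_half_up(0.975, 2)   # 0.98
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_invalid <- function(fmt, ..., class = "lbpfuse_invalid_input") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a
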