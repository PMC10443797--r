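# Internal validation helpers. All readers/constructors reject rather than
# coerce; error messages must identify the offending unit/row/column.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dm <- function(..., class = "dmrescue_error") {
  stop(structure(
    class = unique(c(class, "dmrescue_error", "error", "condition")),
    list(message = sprintf(...), call = NULL)
  ))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || anyNA(x) || (!is.null(len) && length(x) != len)) {
    stop_dm("'%s' must be a numeric vector of length %s without NA", name,
            if (is.null(len)) "> 0" else as.character(len),
            class = "dmrescue_validation_error")
  }
  if (any(x < lower) || any(x > upper)) {
    stop_dm("'%s' must lie in [%s, %s]", name, format(lower), format(upper),
            class = "dmrescue_validation_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_number(x, name, lower = min)
  if (x != as.integer(x)) {
    stop_dm("'%s' must be an integer", name, class = "dmrescue_validation_error")
  }
  invisible(as.integer(x))
}

# Deterministic sub-seeds below 2^31 derived from one master seed, so each
# simulated component has its own stream independent of call order.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Serialized numeric precision for all report TSVs (12 significant digits);
# round-trips are bit-exact at this precision.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12L, format = "g"))
}

# x first so matrix attributes survive pmin/pmax
clamp01 <- function(x) pmin(pmax(x, 0), 1)
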