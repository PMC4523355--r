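# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into (-pi, pi]
#'
#' @param a numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(a) {
  w <- ((a + pi) %% (2 * pi)) - pi
  # %% maps the upper boundary to -pi; the convention here is (-pi, pi]
  w[w == -pi] <- pi
  w
}

stop_if_not_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %s)", name, format(x)), call. = FALSE)
  }
  invisible(x)
}

require_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Run code with a seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
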