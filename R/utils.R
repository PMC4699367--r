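# Internal helpers shared across modules.

# All randomness in the package flows through explicit integer seeds passed
# down from the caller; helpers below derive reproducible child seeds so that
# independent stages never share a stream.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Comma-joined integer vectors used in the read-table TSV.
pack_blocks <- function(x) vapply(x, function(v) paste(v, collapse = ","), character(1))

unpack_blocks <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) as.integer(v))
}
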