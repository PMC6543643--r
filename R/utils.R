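# internal helpers shared across modules

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All exported stochastic operations route
# through this so identical (arguments, seed) give identical output without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_ <- function(...) stop(..., call. = FALSE)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_(what, " is missing required column(s): ",
          paste(missing, collapse = ", "))
  }
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# amino-acid alphabet accepted in variant sequences (20 residues + X)
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
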