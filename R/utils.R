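# Internal helpers shared across modules.

# Classed validation error: every user-facing validation failure carries a
# kinlr-specific condition class so callers (and tests) can discriminate
# failure modes without matching message text.
kinlr_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "kinlr_error", "error")))
}

kinlr_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(class, "kinlr_warning", "warning")))
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All simulator entry points route their
# randomness through this so that no call disturbs global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_prob <- function(x, open_left = FALSE, open_right = FALSE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
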