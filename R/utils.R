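# Internal helpers shared across modules.

DAYS_PER_MONTH <- 30.44

months_to_days <- function(m) m * DAYS_PER_MONTH
days_to_months <- function(d) d / DAYS_PER_MONTH

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed` and restores
#' the caller's RNG state afterwards, so seeded generators never perturb an
#' enclosing simulation.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

# Validation helpers: every error names the offending field.
check_prob <- function(x, field, open_right = FALSE) {
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    stop(sprintf("invalid `%s`: must be a proportion in [0, %s]", field,
                 if (open_right) "1)" else "1"), call. = FALSE)
  }
  invisible(x)
}

check_pos <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("invalid `%s`: must be %s", field,
                 if (strict) "> 0" else ">= 0"), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
  if (!ok) stop(sprintf("invalid `%s`: must be an integer >= %d", field, min), call. = FALSE)
  invisible(as.integer(x))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic CSV writer used for all pipeline artifacts.
write_table_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s'", path), call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}
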