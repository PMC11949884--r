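#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stage-tagged log line to stderr; honours options(causalcaps.log_level).
# Levels: debug < info < warn.
cc_log <- function(msg, ..., level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  threshold <- getOption("causalcaps.log_level", "info")
  if (levels[[level]] < levels[[threshold]]) return(invisible(NULL))
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(msg, ...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0

sigmoid <- function(z) 1 / (1 + exp(-z))
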