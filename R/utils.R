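# Internal helpers: logging, seeds, validation.

the_log <- new.env(parent = emptyenv())
the_log$quiet <- FALSE

gp_log <- function(fmt, ..., level = "INFO") {
  if (isTRUE(the_log$quiet)) return(invisible(NULL))
  message(sprintf("[gazepheno %s] %s", level, sprintf(fmt, ...)))
}

#' Silence or restore pipeline log messages
#'
#' @param quiet Logical; `TRUE` suppresses informational messages.
#' @return The previous setting, invisibly.
#' @export
gaze_quiet <- function(quiet = TRUE) {
  old <- the_log$quiet
  the_log$quiet <- isTRUE(quiet)
  invisible(old)
}

stop_gp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_gp("'%s' must be a single finite number", name)
  if (positive && x <= 0) stop_gp("'%s' must be > 0", name)
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_gp("'%s' must be a whole number", name)
  invisible(x)
}

# Set the RNG state for the duration of the calling function only when a seed
# is supplied; NULL continues the surrounding stream (used by internal calls
# made under an outer seed).
with_seed_if <- function(seed, expr) {
  if (!is.null(seed)) {
    assert_scalar_num(seed, "seed", integerish = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a bounded child seed from a parent seed and an index, so nested
# generators are reproducible yet decoupled.
child_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483562L + 1L
}
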