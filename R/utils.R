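# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores \code{.Random.seed} so that seeded package operations
#' never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# stopifnot-style check with a typed condition class so callers can
# distinguish validation errors from input errors programmatically.
ps_stop <- function(msg, class) {
  stop(structure(class = c(class, "pathospeech_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

ps_validate <- function(ok, msg) if (!isTRUE(ok)) ps_stop(msg, "ps_validation_error")
ps_input    <- function(ok, msg) if (!isTRUE(ok)) ps_stop(msg, "ps_input_error")

# x first so that pmin/pmax keep its dim attributes (matrices stay matrices)
clamp01_10 <- function(x) pmin(pmax(x, 0), 10)
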