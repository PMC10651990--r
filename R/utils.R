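# Internal helpers: seeded evaluation, deterministic sub-seeds, error classes.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic sub-stream seed: keeps every derived seed a valid 32-bit
# integer so the same root seed always yields the same component streams.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 7919 + as.double(k) * 104729
  as.integer(s %% 2147483629)
}

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "acinet_error")))
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar", name), "acinet_invalid_argument")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive", name), "acinet_invalid_argument")
  }
  invisible(x)
}
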