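# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible substream seed
#'
#' Maps a master seed and a stream index to an independent 31-bit seed so
#' regenerating one synthetic artifact never shifts another.
#'
#' @param master Integer master seed.
#' @param index Non-negative stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647  # 2^31 - 1 (Mersenne prime, Lehmer modulus)
  s <- (as.double(master) %% m) * 48271 + (as.double(index) + 1) * 16807
  as.integer(s %% (m - 1) + 1)
}

# round half away from zero at `digits` decimals (printed percents)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as a printed percent
#'
#' Rounds half away from zero to one decimal and drops a trailing ".0"
#' (so 0.47 prints as "47" and 0.81 as "81").
#'
#' @param x Proportion in `[0, 1]`.
#' @param digits Decimal places before trailing-zero stripping.
#' @return Character vector.
#' @export
format_pct <- function(x, digits = 1) {
  r <- round_half_away(100 * x, digits)
  out <- formatC(r, format = "f", digits = digits)
  sub("\\.0+$", "", out)
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("invalid-domain: `%s` must be a probability in [0, 1]", name),
         call. = FALSE)
}

stopifnot_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      abs(x - round(x)) > 1e-8)
    stop(sprintf("invalid-domain: `%s` must be a non-negative count", name),
         call. = FALSE)
}
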