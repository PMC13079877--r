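# Shared helpers.

# Universal gas constant, J/(mol K).  Temperatures are Kelvin and pressures
# bar everywhere in the package.
GAS_R <- 8.31446

# Run code with a fixed RNG state, restoring the caller's state afterwards.
# RNG kind is pinned so seeded results are reproducible across sessions.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Derive a reproducible child seed below 2^31 from a parent seed and a tag.
child_seed <- function(seed, tag) {
  h <- digest::digest(list(as.integer(seed), as.character(tag)), algo = "sha256")
  strtoi(substr(h, 1L, 7L), base = 16L)
}

check_mole_fractions <- function(x, tol = 1e-9) {
  if (any(!is.finite(x)) || any(x < -tol) || any(x > 1 + tol))
    stop("mole fractions must lie in [0, 1]")
  if (abs(sum(x) - 1) > tol)
    stop(sprintf("mole fractions must sum to 1 (got %.12g)", sum(x)))
  invisible(TRUE)
}

# Reconstruct the last mole fraction from the first N-1 so the summation
# condition holds exactly.
close_simplex <- function(x) {
  n <- length(x)
  x[n] <- 1 - sum(x[-n])
  x
}

# x * log(x) with the 0 * log(0) -> 0 convention.
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
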