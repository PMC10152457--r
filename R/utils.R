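# Internal helpers shared across modules.

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage seed fan-out from one pipeline seed.
# Kept below 2^31 - 1; exact in double arithmetic.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 131 + stage * 7919) %% 2147483647)
}

# Nearest stored channel for a target wavenumber.
# on_grid = TRUE additionally requires the target to sit within half a grid
# step of the matched channel.
match_channel <- function(wavenumbers, wn, on_grid = FALSE, what = "wavenumber") {
  if (wn < min(wavenumbers) || wn > max(wavenumbers)) {
    stop(sprintf("%s %g cm^-1 is outside the stored grid [%g, %g]",
                 what, wn, min(wavenumbers), max(wavenumbers)), call. = FALSE)
  }
  i <- which.min(abs(wavenumbers - wn))
  if (on_grid) {
    step <- if (length(wavenumbers) > 1) stats::median(diff(wavenumbers)) else 1
    if (abs(wavenumbers[i] - wn) > step / 2 + 1e-9) {
      stop(sprintf("%s %g cm^-1 does not lie on the stored grid", what, wn),
           call. = FALSE)
    }
  }
  i
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
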