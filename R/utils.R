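# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Circularly rotate a vector: element i of the result is x[i - m] (wrapping),
# i.e. m > 0 delays the waveform by m samples.
circshift <- function(x, m) {
  n <- length(x)
  if (n == 0L) return(x)
  m <- ((m %% n) + n) %% n
  if (m == 0L) return(x)
  c(x[(n - m + 1L):n], x[1L:(n - m)])
}

# Rotate the columns of a cycle matrix by `m` samples independently within
# each of `k` consecutive blocks of `T_cycle` columns.
circshift_cycles <- function(M, m, T_cycle, k) {
  stopifnot(ncol(M) == T_cycle * k)
  idx <- unlist(lapply(seq_len(k), function(ci) {
    off <- (ci - 1L) * T_cycle
    off + circshift(seq_len(T_cycle), -m)
  }))
  M[, idx, drop = FALSE]
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < 1)
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding of
# `pad_n` samples at each end to bound edge transients.
filtfilt_reflect <- function(filt, x, pad_n) {
  n <- length(x)
  pad_n <- max(1L, min(as.integer(pad_n), n - 1L))
  front <- 2 * x[1L] - x[(pad_n + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad_n)]
  xp <- c(front, x, back)
  y <- as.numeric(signal::filter(filt, xp))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(pad_n + 1L):(pad_n + n)]
}
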