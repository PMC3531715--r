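# Non-negative matrix factorization of the EMG cycle matrix by Lee-Seung
# multiplicative updates, with the multi-restart protocol and the VAF
# bookkeeping used throughout synergy analysis.

EPS_DIV <- 1e-12  # floor on update-rule denominators (guards zero rows/cols)

# One multiplicative-update run from a random positive initialisation.
# Convergence: relative Frobenius-cost decrease < tol over a 10-iteration
# window, or max_iter. Returns W, C, final cost and (optionally) the full
# per-iteration cost trace.
nmf_run <- function(E, s, max_iter, tol, track_cost = FALSE) {
  p <- nrow(E); n <- ncol(E)
  W <- matrix(runif(p * s, 0.1, 1), p, s)
  C <- matrix(runif(s * n, 0.1, 1), s, n)
  cost_prev <- Inf
  trace <- if (track_cost) numeric(max_iter) else NULL
  check_every <- if (track_cost) 1L else 10L
  it_done <- max_iter
  for (it in seq_len(max_iter)) {
    C <- C * crossprod(W, E) / (crossprod(W) %*% C + EPS_DIV)
    W <- W * (E %*% t(C)) / (W %*% tcrossprod(C) + EPS_DIV)
    if (track_cost || it %% check_every == 0L) {
      cost <- sqrt(sum((E - W %*% C)^2))
      if (track_cost) trace[it] <- cost
      if (it %% 10L == 0L) {
        if (is.finite(cost_prev) && cost_prev - cost < tol * cost_prev) {
          it_done <- it
          break
        }
        cost_prev <- cost
      }
    }
  }
  if (track_cost) trace <- trace[seq_len(it_done)]
  list(W = W, C = C, cost = sqrt(sum((E - W %*% C)^2)),
       iterations = it_done, cost_trace = trace)
}

#' Extract muscle synergies by multiplicative-update NMF
#'
#' Factorises the non-negative cycle matrix `E` as `W C + e`, minimising the
#' Frobenius norm of the residual with the standard two-sided Lee-Seung
#' multiplicative updates. The algorithm is restarted `n_restarts` times from
#' independent uniform-random positive initialisations and the lowest-cost
#' solution is kept (default 20 restarts, the usual guard against local
#' minima). Columns of `W` are then rescaled to unit Euclidean norm with the
#' inverse scale folded into `C`, and synergies are ordered by the time of the
#' peak of their cycle-averaged activation.
#'
#' @param E an [emg_cycle_matrix] or non-negative numeric matrix (muscles x
#'   time).
#' @param s number of synergies, `1 <= s <= p`.
#' @param n_restarts independent random restarts (default 20).
#' @param max_iter iteration cap per restart.
#' @param tol relative Frobenius-cost decrease (over a 10-iteration window)
#'   below which a restart is declared converged.
#' @param seed integer RNG seed; restarts draw from one seeded stream.
#' @param track_cost record the per-iteration cost trace of the winning
#'   restart's rerun (used to verify update monotonicity).
#' @return An object of class `synergy_decomposition`: `W` (p x s, unit-norm
#'   columns), `C` (s x n), residual `e = E - W C`, `VAF_total`, `VAF_muscle`,
#'   `VAF_synergy`, `cost`, `iterations`, `n_restarts`, `seed`, and the cycle
#'   geometry when known.
#' @export
nmf_extract <- function(E, s, n_restarts = 20, max_iter = 1000, tol = 1e-5,
                        seed = 1L, track_cost = FALSE) {
  cm <- if (inherits(E, "emg_cycle_matrix")) E else NULL
  Em <- as_cycle_mat(E)
  if (any(Em < 0)) stop("`E` must be non-negative", call. = FALSE)
  s <- stop_if_not_scalar_count(s, "s")
  if (s > nrow(Em))
    stop("`s` cannot exceed the number of muscles", call. = FALSE)
  n_restarts <- stop_if_not_scalar_count(n_restarts, "n_restarts")
  best <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      run <- nmf_run(Em, s, max_iter, tol, track_cost = track_cost)
      if (is.null(best) || run$cost < best$cost) best <- run
    }
    best
  })
  W <- best$W; C <- best$C
  # unit-norm W columns, inverse scale into C (reconstruction unchanged)
  scl <- sqrt(colSums(W^2))
  scl[scl < EPS_DIV] <- 1
  W <- sweep(W, 2L, scl, "/")
  C <- sweep(C, 1L, scl, "*")
  # order synergies by peak time of the cycle-averaged activation
  ord <- if (!is.null(cm)) {
    order(apply(cycle_average(C, cm$T_cycle, cm$k), 1L, which.max))
  } else order(apply(C, 1L, which.max))
  W <- W[, ord, drop = FALSE]
  C <- C[ord, , drop = FALSE]
  e <- Em - W %*% C
  structure(list(W = W, C = C, e = e,
                 VAF_total = vaf_total(Em, W, C),
                 VAF_muscle = vaf_muscle(Em, W, C),
                 VAF_synergy = vaf_synergy(Em, W, C),
                 cost = best$cost, iterations = best$iterations,
                 cost_trace = best$cost_trace,
                 n_restarts = n_restarts, seed = seed, s = s,
                 labels = if (!is.null(cm)) cm$labels else rownames(Em),
                 T_cycle = if (!is.null(cm)) cm$T_cycle else NULL,
                 k = if (!is.null(cm)) cm$k else NULL),
            class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf("<synergy_decomposition> %d muscles, s=%d, VAF=%.3f (cost %.4g, %d restarts)\n",
              nrow(x$W), ncol(x$W), x$VAF_total, x$cost, x$n_restarts))
  invisible(x)
}

#' Total variance accounted for
#'
#' `VAF = 1 - sum(e^2) / sum(E^2)` with `e = E - W C`: the fraction of the
#' total signal power reconstructed by the factorisation. Can be negative for
#' reconstructions worse than the zero matrix.
#'
#' @param E data matrix (or [emg_cycle_matrix]).
#' @param W,C factor matrices.
#' @return A single fraction.
#' @export
vaf_total <- function(E, W, C) {
  Em <- as_cycle_mat(E)
  den <- sum(Em^2)
  if (den == 0) stop("`E` is all zero; VAF undefined", call. = FALSE)
  1 - sum((Em - W %*% C)^2) / den
}

#' Per-muscle variance accounted for
#'
#' The VAF formula restricted to each muscle's row of `E`. Rows of `E` that
#' are identically zero have undefined VAF and are returned as `NA` with a
#' warning.
#'
#' @inheritParams vaf_total
#' @return A vector of `p` fractions (named by muscle when labels exist).
#' @export
vaf_muscle <- function(E, W, C) {
  Em <- as_cycle_mat(E)
  R <- Em - W %*% C
  den <- rowSums(Em^2)
  out <- 1 - rowSums(R^2) / den
  if (any(den == 0)) {
    warning("muscle row(s) with zero power: VAF_muscle undefined (NA)")
    out[den == 0] <- NA_real_
  }
  names(out) <- rownames(Em)
  out
}

#' Per-synergy variance accounted for
#'
#' For each synergy `j`, the VAF of the rank-1 reconstruction
#' `W[, j] %*% C[j, ]` against the full data matrix — how much of the data
#' each synergy explains on its own.
#'
#' @inheritParams vaf_total
#' @return A vector of `s` fractions.
#' @export
vaf_synergy <- function(E, W, C) {
  Em <- as_cycle_mat(E)
  vapply(seq_len(ncol(W)), function(j)
    vaf_total(Em, W[, j, drop = FALSE], C[j, , drop = FALSE]), numeric(1))
}

#' Entry-shuffled surrogate of a cycle matrix
#'
#' Returns a matrix of identical shape whose entries are the same multiset of
#' values with positions permuted uniformly over all cells (shuffled across
#' both time and muscles). Destroys all spatial and temporal structure while
#' preserving the amplitude distribution — the "unstructured" reference data
#' for the knee-point criterion.
#'
#' @param E an [emg_cycle_matrix] or matrix.
#' @param seed integer RNG seed.
#' @return An object of the same class and shape as `E`.
#' @export
shuffle_surrogate <- function(E, seed = 1L) {
  if (inherits(E, "emg_cycle_matrix")) {
    E$E[] <- with_seed(seed, sample(E$E))
    E
  } else {
    Em <- as.matrix(E)
    Em[] <- with_seed(seed, sample(Em))
    Em
  }
}

#' VAF as a function of the number of synergies
#'
#' Runs [nmf_extract] for every `s` in `s_range` (default 1 to `p`) and
#' collects `VAF_total`. Restart stochasticity can make the curve locally
#' non-monotone by a fraction of a point; more restarts tighten it.
#'
#' @inheritParams nmf_extract
#' @param s_range synergy numbers to evaluate.
#' @return A numeric vector of VAF fractions, one per entry of `s_range`,
#'   with `s_range` as names.
#' @export
vaf_curve <- function(E, n_restarts = 20, max_iter = 1000, tol = 1e-5,
                      seed = 1L, s_range = NULL) {
  Em <- as_cycle_mat(E)
  if (is.null(s_range)) s_range <- seq_len(nrow(Em))
  out <- vapply(seq_along(s_range), function(i)
    nmf_extract(Em, s_range[i], n_restarts = n_restarts, max_iter = max_iter,
                tol = tol, seed = seed + i)$VAF_total, numeric(1))
  names(out) <- s_range
  out
}
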