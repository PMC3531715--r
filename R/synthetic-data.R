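# Ground-truth EMG synthesis: known synergy vectors and activation waveforms
# run forward through the generative model E = W C + noise, so that every
# downstream stage (extraction, selection, cross-validation, similarity) can be
# validated against a known answer.

#' Random non-negative synergy basis
#'
#' Draws a `p x s` non-negative matrix with unit-Euclidean-norm columns to act
#' as ground-truth muscle synergy vectors. The muscles are partitioned into
#' `s` disjoint dominant groups (round-robin over a random muscle order):
#' within its group a muscle carries a strong weight (uniform on 0.5-1), while
#' off-group weights are weak co-activations (uniform on 0-0.3), of which a
#' `sparsity` fraction is zeroed. This mirrors how extracted muscle synergies
#' typically look — each synergy dominated by a distinct muscle group with
#' modest spillover — and guarantees every muscle participates in at least one
#' synergy. The draw is repeated if any pair of columns correlates at 0.9 or
#' above, so the synergies are always distinguishable.
#'
#' @param p number of muscles.
#' @param s number of synergies (`s <= p`).
#' @param sparsity fraction in `[0, 1)` of off-group weights zeroed per
#'   column.
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @param max_tries attempts before giving up on the correlation constraint.
#' @return A `p x s` non-negative matrix with unit-norm columns.
#' @export
make_synergy_basis <- function(p, s, sparsity = 0.4, seed = 1L,
                               max_tries = 100L) {
  p <- stop_if_not_scalar_count(p, "p")
  s <- stop_if_not_scalar_count(s, "s")
  if (p < s) stop("need at least as many muscles as synergies (p >= s)",
                  call. = FALSE)
  if (sparsity < 0 || sparsity >= 1)
    stop("`sparsity` must lie in [0, 1)", call. = FALSE)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      groups <- split(sample.int(p), rep(seq_len(s), length.out = p))
      W <- matrix(runif(p * s, 0, 0.3), p, s)
      for (j in seq_len(s)) {
        W[groups[[j]], j] <- runif(length(groups[[j]]), 0.5, 1)
        off <- setdiff(seq_len(p), groups[[j]])
        n_zero <- floor(sparsity * length(off))
        if (n_zero > 0L) W[sample(off, n_zero), j] <- 0
      }
      W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
      ok <- TRUE
      if (s > 1L) {
        cc <- suppressWarnings(cor(W))
        cc[!is.finite(cc)] <- 1
        diag(cc) <- 0
        ok <- max(abs(cc)) < 0.9
      }
      if (ok) return(W)
    }
    stop("could not draw a basis with pairwise column correlation < 0.9",
         call. = FALSE)
  })
}

# Circular Gaussian bump on 1..T_cycle centred at mu with sd sigma (samples).
circular_bump <- function(T_cycle, mu, sigma) {
  t <- seq_len(T_cycle)
  v <- numeric(T_cycle)
  for (off in c(-T_cycle, 0, T_cycle))
    v <- v + exp(-((t - mu + off)^2) / (2 * sigma^2))
  v
}

#' Ground-truth synergy activation waveforms
#'
#' Builds `s` non-negative activation time courses over `k` cycles of
#' `T_cycle` samples. Each synergy is a sum of one or two circular Gaussian
#' bumps per cycle (odd-numbered synergies single-peaked, even-numbered
#' double-peaked, emulating the uni/bimodal coefficient shapes typical of
#' cyclic whole-body movements), with per-cycle perturbations of peak time and
#' amplitude providing the inter-cycle variability on which synergy extraction
#' relies. Rows are scaled so the unjittered template has maximum 1.
#'
#' @param s number of synergies.
#' @param T_cycle samples per cycle (>= 8).
#' @param k number of cycles.
#' @param peak_jitter SD of the per-cycle peak-time perturbation, in % of the
#'   cycle.
#' @param amp_jitter SD of the per-cycle multiplicative amplitude perturbation
#'   (fraction; scale factors are clipped at 0).
#' @param seed integer RNG seed.
#' @return An `s x (k * T_cycle)` non-negative matrix.
#' @export
make_activation_waveforms <- function(s, T_cycle, k, peak_jitter = 2,
                                      amp_jitter = 0.1, seed = 1L) {
  s <- stop_if_not_scalar_count(s, "s")
  T_cycle <- stop_if_not_scalar_count(T_cycle, "T_cycle")
  k <- stop_if_not_scalar_count(k, "k")
  if (T_cycle < 8L) stop("`T_cycle` must be at least 8", call. = FALSE)
  if (peak_jitter < 0 || amp_jitter < 0)
    stop("jitters must be non-negative", call. = FALSE)
  sigma <- 0.05 * T_cycle
  # fixed bump layout: main peaks evenly staggered across the cycle;
  # even-numbered synergies carry a weaker secondary peak half a cycle away
  bumps <- lapply(seq_len(s), function(j) {
    mu1 <- T_cycle * (2 * j - 1) / (2 * s)
    if (j %% 2L == 1L) list(mu = mu1, amp = 1)
    else list(mu = c(mu1, (mu1 + 0.5 * T_cycle - 1) %% T_cycle + 1),
              amp = c(1, 0.3))
  })
  with_seed(seed, {
    C <- matrix(0, s, k * T_cycle)
    for (j in seq_len(s)) {
      template <- numeric(T_cycle)
      for (b in seq_along(bumps[[j]]$mu))
        template <- template +
          bumps[[j]]$amp[b] * circular_bump(T_cycle, bumps[[j]]$mu[b], sigma)
      scale <- max(template)
      for (ci in seq_len(k)) {
        cyc <- numeric(T_cycle)
        for (b in seq_along(bumps[[j]]$mu)) {
          mu <- bumps[[j]]$mu[b] + rnorm(1L, 0, peak_jitter / 100 * T_cycle)
          amp <- bumps[[j]]$amp[b] * max(0, 1 + rnorm(1L, 0, amp_jitter))
          cyc <- cyc + amp * circular_bump(T_cycle, mu, sigma)
        }
        C[j, (ci - 1L) * T_cycle + seq_len(T_cycle)] <- cyc / scale
      }
    }
    C
  })
}

#' Ground truth for synthetic EMG
#'
#' Bundles known synergy vectors `W_true`, activation waveforms `C_true` and
#' the noise/shift parameters of the generative model `E = W C + noise`.
#' Defaults describe a 12-muscle, 3-synergy, 9-cycle recording time-normalised
#' to 200 samples per cycle — the geometry of a set of linked giant swings.
#'
#' @param p muscles. @param s synergies. @param T_cycle samples per cycle.
#' @param k cycles. @param sparsity synergy-basis sparsity.
#' @param peak_jitter,amp_jitter inter-cycle variability of the activations
#'   (see [make_activation_waveforms]).
#' @param noise_sd additive Gaussian noise SD as a fraction of the RMS of
#'   `W C` (clipped at zero, since envelopes are non-negative).
#' @param subject_shift circular shift of the activations, in samples within
#'   each cycle (a subject-specific timing offset).
#' @param seed integer RNG seed.
#' @return An object of class `synergy_ground_truth` with elements `W_true`,
#'   `C_true`, `p`, `s`, `T_cycle`, `k`, `noise_sd`, `subject_shift`, `seed`.
#' @export
make_ground_truth <- function(p = 12, s = 3, T_cycle = 200, k = 9,
                              sparsity = 0.4, peak_jitter = 2,
                              amp_jitter = 0.1, noise_sd = 0.1,
                              subject_shift = 0L, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  W <- make_synergy_basis(p, s, sparsity = sparsity, seed = seed)
  C <- make_activation_waveforms(s, T_cycle, k, peak_jitter = peak_jitter,
                                 amp_jitter = amp_jitter, seed = seed + 1L)
  structure(list(W_true = W, C_true = C, p = p, s = s,
                 T_cycle = as.integer(T_cycle), k = as.integer(k),
                 noise_sd = noise_sd, subject_shift = as.integer(subject_shift),
                 seed = as.integer(seed)),
            class = "synergy_ground_truth")
}

#' @export
print.synergy_ground_truth <- function(x, ...) {
  cat(sprintf("<synergy_ground_truth> p=%d s=%d k=%d T=%d noise_sd=%g shift=%d\n",
              x$p, x$s, x$k, x$T_cycle, x$noise_sd, x$subject_shift))
  invisible(x)
}

#' Synthesise a normalised EMG cycle matrix from ground truth
#'
#' Runs the generative model forward: applies the subject's circular time
#' shift to `C_true` (within each cycle), forms `W_true %*% C_shifted`, adds
#' Gaussian noise with SD `noise_sd` times the signal RMS, clips negative
#' entries to zero, and normalises each muscle to maximum 1 — the same
#' amplitude convention the preprocessing chain produces.
#'
#' @param gt a [make_ground_truth] object.
#' @param seed optional seed for the noise draw; defaults to `gt$seed + 2`.
#' @return An [emg_cycle_matrix]; `meta` records the true synergy count, the
#'   shift, the seed and the pre-normalisation row maxima (`norms`).
#' @export
synthesize_emg <- function(gt, seed = NULL) {
  stopifnot(inherits(gt, "synergy_ground_truth"))
  if (ncol(gt$W_true) != nrow(gt$C_true))
    stop("W_true and C_true are not conformable", call. = FALSE)
  if (is.null(seed)) seed <- gt$seed + 2L
  C <- circshift_cycles(gt$C_true, gt$subject_shift, gt$T_cycle, gt$k)
  S <- gt$W_true %*% C
  if (gt$noise_sd > 0) {
    sd_n <- gt$noise_sd * sqrt(mean(S^2))
    S <- S + with_seed(seed, matrix(rnorm(length(S), 0, sd_n), nrow(S), ncol(S)))
    S[S < 0] <- 0
  }
  norms <- apply(S, 1L, max)
  if (any(norms <= 0))
    stop("a muscle row is identically zero; increase synergy density",
         call. = FALSE)
  E <- sweep(S, 1L, norms, "/")
  emg_cycle_matrix(E, gt$T_cycle, gt$k,
                   labels = paste0("M", seq_len(nrow(E))), norms = norms,
                   meta = list(true_s = gt$s, subject_shift = gt$subject_shift,
                               noise_sd = gt$noise_sd, seed = seed))
}

#' Synthesise a cohort of subjects sharing ground-truth synergies
#'
#' Each subject's data are generated from the common `W_true` (optionally
#' perturbed and re-normalised, modelling between-subject differences in
#' muscle weightings) and the common `C_true` circularly shifted by that
#' subject's timing offset, with an independent noise realisation per subject.
#'
#' @param n_subjects number of subjects.
#' @param gt a [make_ground_truth] object (its `subject_shift` is ignored in
#'   favour of `per_subject_shift`).
#' @param per_subject_shift integer vector, one circular shift (samples within
#'   the cycle) per subject.
#' @param per_subject_W_perturbation fraction of the mean weight used as the
#'   SD of additive Gaussian perturbation of `W_true` per subject (clipped at
#'   zero, columns re-normalised); 0 means all subjects share `W_true` exactly.
#' @param seed integer RNG seed controlling perturbations and noise.
#' @return A list of [emg_cycle_matrix] objects, one per subject; each `meta`
#'   records `subject`, `subject_shift` and the subject's true `W`.
#' @export
synthesize_cohort <- function(n_subjects, gt,
                              per_subject_shift = rep(0L, n_subjects),
                              per_subject_W_perturbation = 0,
                              seed = gt$seed) {
  n_subjects <- stop_if_not_scalar_count(n_subjects, "n_subjects")
  stopifnot(inherits(gt, "synergy_ground_truth"))
  if (length(per_subject_shift) != n_subjects)
    stop("`per_subject_shift` must have one entry per subject", call. = FALSE)
  if (per_subject_W_perturbation < 0)
    stop("`per_subject_W_perturbation` must be non-negative", call. = FALSE)
  lapply(seq_len(n_subjects), function(i) {
    W_i <- gt$W_true
    if (per_subject_W_perturbation > 0) {
      pert <- with_seed(seed + 1000L + i, {
        matrix(rnorm(length(W_i), 0,
                     per_subject_W_perturbation * mean(W_i[W_i > 0])),
               nrow(W_i), ncol(W_i))
      })
      W_i <- pmax(W_i + pert, 0)
      W_i <- sweep(W_i, 2L, sqrt(colSums(W_i^2)), "/")
    }
    gt_i <- gt
    gt_i$W_true <- W_i
    gt_i$subject_shift <- as.integer(per_subject_shift[i])
    out <- synthesize_emg(gt_i, seed = seed + 2000L + i)
    out$meta$subject <- i
    out$meta$W_subject <- W_i
    out
  })
}
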