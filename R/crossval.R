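# Cross-validation of extracted synergies: reconstruct one dataset while
# holding either the synergy vectors (W) or the activation coefficients (C)
# fixed from another dataset, and score the reconstruction by VAF.

# Shared single-sided multiplicative update loop. `fixed` names the matrix
# held constant.
fit_fixed <- function(E, fixed_mat, fixed = c("W", "C"), max_iter = 1000,
                      tol = 1e-5, seed = 1L) {
  fixed <- match.arg(fixed)
  if (any(E < 0) || any(fixed_mat < 0))
    stop("inputs must be non-negative", call. = FALSE)
  p <- nrow(E); n <- ncol(E)
  if (fixed == "W") {
    W <- fixed_mat
    if (nrow(W) != p) stop("W_control rows must match muscles of E", call. = FALSE)
    s <- ncol(W)
    C <- with_seed(seed, matrix(runif(s * n, 0.1, 1), s, n))
    WtW <- crossprod(W); WtE <- crossprod(W, E)
    cost_prev <- Inf
    for (it in seq_len(max_iter)) {
      C <- C * WtE / (WtW %*% C + EPS_DIV)
      if (it %% 10L == 0L) {
        cost <- sqrt(sum((E - W %*% C)^2))
        if (is.finite(cost_prev) && cost_prev - cost < tol * cost_prev) break
        cost_prev <- cost
      }
    }
    refit <- C
  } else {
    C <- fixed_mat
    if (ncol(C) != n) stop("C_control columns must match time points of E", call. = FALSE)
    s <- nrow(C)
    W <- with_seed(seed, matrix(runif(p * s, 0.1, 1), p, s))
    CCt <- tcrossprod(C); ECt <- E %*% t(C)
    cost_prev <- Inf
    for (it in seq_len(max_iter)) {
      W <- W * ECt / (W %*% CCt + EPS_DIV)
      if (it %% 10L == 0L) {
        cost <- sqrt(sum((E - W %*% C)^2))
        if (is.finite(cost_prev) && cost_prev - cost < tol * cost_prev) break
        cost_prev <- cost
      }
    }
    refit <- W
  }
  structure(list(fixed_part = paste0(fixed, "_fixed"), refit = refit,
                 W = W, C = C,
                 VAF_total = vaf_total(E, W, C),
                 VAF_muscle = vaf_muscle(E, W, C),
                 iterations = it, seed = seed),
            class = "cross_fit")
}

#' @export
print.cross_fit <- function(x, ...) {
  cat(sprintf("<cross_fit> %s, VAF=%.3f\n", x$fixed_part, x$VAF_total))
  invisible(x)
}

#' Reconstruct EMG with fixed synergy vectors
#'
#' Holds the muscle synergy vectors `W_control` fixed and updates only the
#' activation coefficients by the single-sided multiplicative rule
#' `C <- C * (W' E) / (W' W C)` from a random positive initialisation until
#' convergence. With `W` fixed the Frobenius objective is convex in `C`, so a
#' single initialisation suffices.
#'
#' @param E_subject non-negative data matrix (or [emg_cycle_matrix]) of the
#'   compared subject.
#' @param W_control non-negative `p x s` synergy-vector matrix of the control
#'   subject.
#' @param max_iter,tol,seed as in [nmf_extract].
#' @return A `cross_fit` object with the refit `C`, `VAF_total` and
#'   `VAF_muscle` of `W_control %*% C` against `E_subject`.
#' @export
fit_C_fixed_W <- function(E_subject, W_control, max_iter = 1000, tol = 1e-5,
                          seed = 1L) {
  fit_fixed(as_cycle_mat(E_subject), as.matrix(W_control), "W",
            max_iter = max_iter, tol = tol, seed = seed)
}

#' Reconstruct EMG with fixed activation coefficients
#'
#' The mirror of [fit_C_fixed_W]: holds `C_control` fixed and updates only the
#' synergy vectors, `W <- W * (E C') / (W C C')`.
#'
#' @param E_subject non-negative data matrix (or [emg_cycle_matrix]).
#' @param C_control non-negative `s x n` activation-coefficient matrix.
#' @inheritParams fit_C_fixed_W
#' @return A `cross_fit` object with the refit `W` and VAF diagnostics.
#' @export
fit_W_fixed_C <- function(E_subject, C_control, max_iter = 1000, tol = 1e-5,
                          seed = 1L) {
  fit_fixed(as_cycle_mat(E_subject), as.matrix(C_control), "C",
            max_iter = max_iter, tol = tol, seed = seed)
}

#' Within-subject set-to-set cross-validation
#'
#' Extracts synergies from one set of cycles and verifies that its synergy
#' vectors account for the EMG patterns of the other set (fixed-W refit). Also
#' extracts freely from both sets and reports the Pearson correlations of
#' matched synergy vectors and of matched cycle-averaged activation
#' coefficients.
#'
#' @param setA,setB two [emg_cycle_matrix] objects from the same muscles
#'   (same labels, same `T_cycle`).
#' @param s number of synergies.
#' @param n_restarts,max_iter,tol,seed as in [nmf_extract].
#' @return A list: `cross_fit` (the fixed-W refit of `setB`), `free_A`,
#'   `free_B` (free decompositions), `W_similarity` and `C_similarity`
#'   (matched per-synergy Pearson r).
#' @export
within_subject_crossval <- function(setA, setB, s, n_restarts = 20,
                                    max_iter = 1000, tol = 1e-5, seed = 1L) {
  stopifnot(inherits(setA, "emg_cycle_matrix"),
            inherits(setB, "emg_cycle_matrix"))
  if (!identical(setA$labels, setB$labels))
    stop("muscle labels of the two sets differ", call. = FALSE)
  if (setA$T_cycle != setB$T_cycle)
    stop("cycle lengths of the two sets differ", call. = FALSE)
  dA <- nmf_extract(setA, s, n_restarts = n_restarts, max_iter = max_iter,
                    tol = tol, seed = seed)
  dB <- nmf_extract(setB, s, n_restarts = n_restarts, max_iter = max_iter,
                    tol = tol, seed = seed + 1L)
  cf <- fit_C_fixed_W(setB, dA$W, max_iter = max_iter, tol = tol,
                      seed = seed + 2L)
  m <- match_synergies(dA$W, dB$W)
  Ca <- cycle_average(dA$C, setA$T_cycle, setA$k)
  Cb <- cycle_average(dB$C, setB$T_cycle, setB$k)
  C_r <- vapply(seq_len(s), function(j)
    cor(Ca[j, ], Cb[m$permutation[j], ]), numeric(1))
  list(cross_fit = cf, free_A = dA, free_B = dB,
       W_similarity = m$r, C_similarity = C_r, matching = m$permutation)
}

#' All-pairs cross-validation over a cohort
#'
#' Extracts synergies freely for every subject, then for every ordered pair
#' (control, compared) reconstructs the compared subject's data holding the
#' control subject's synergy vectors (`mode = "fix_W"`) or activation
#' coefficients (`mode = "fix_C"`) fixed. With `n` subjects this yields
#' `n * (n - 1)` comparisons.
#'
#' @param cohort list of [emg_cycle_matrix] objects.
#' @param s number of synergies.
#' @param mode which part to hold fixed across subjects.
#' @param n_restarts,max_iter,tol,seed as in [nmf_extract].
#' @param decompositions optional precomputed list of free
#'   `synergy_decomposition`s (one per subject), to avoid re-extraction.
#' @return A list: `pairs` (data frame with control, compared, VAF_total),
#'   `VAF_muscle` (pairs x muscles matrix), `mean_VAF`, `mean_VAF_muscle`,
#'   `free_fits`, `mode`.
#' @export
cohort_crossval <- function(cohort, s, mode = c("fix_W", "fix_C"),
                            n_restarts = 20, max_iter = 1000, tol = 1e-5,
                            seed = 1L, decompositions = NULL) {
  mode <- match.arg(mode)
  n <- length(cohort)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (is.null(decompositions)) {
    decompositions <- lapply(seq_len(n), function(i)
      nmf_extract(cohort[[i]], s, n_restarts = n_restarts,
                  max_iter = max_iter, tol = tol, seed = seed + i))
  }
  pairs <- expand.grid(control = seq_len(n), compared = seq_len(n))
  pairs <- pairs[pairs$control != pairs$compared, , drop = FALSE]
  pairs <- pairs[order(pairs$control, pairs$compared), , drop = FALSE]
  rownames(pairs) <- NULL
  p <- nrow(as_cycle_mat(cohort[[1L]]))
  vafs <- numeric(nrow(pairs))
  vmus <- matrix(NA_real_, nrow(pairs), p)
  for (i in seq_len(nrow(pairs))) {
    ctrl <- pairs$control[i]; comp <- pairs$compared[i]
    cf <- if (mode == "fix_W") {
      fit_C_fixed_W(cohort[[comp]], decompositions[[ctrl]]$W,
                    max_iter = max_iter, tol = tol, seed = seed + 100L + i)
    } else {
      fit_W_fixed_C(cohort[[comp]], decompositions[[ctrl]]$C,
                    max_iter = max_iter, tol = tol, seed = seed + 100L + i)
    }
    vafs[i] <- cf$VAF_total
    vmus[i, ] <- cf$VAF_muscle
  }
  colnames(vmus) <- if (inherits(cohort[[1L]], "emg_cycle_matrix"))
    cohort[[1L]]$labels else paste0("M", seq_len(p))
  pairs$VAF_total <- vafs
  list(pairs = pairs, VAF_muscle = vmus,
       mean_VAF = mean(vafs), mean_VAF_muscle = colMeans(vmus),
       free_fits = decompositions, mode = mode)
}

#' Flag muscles poorly reconstructed in a cross-fit
#'
#' Applies the conventional adequacy threshold: a muscle is flagged when its
#' `VAF_muscle` falls below `threshold` (default 0.75).
#'
#' @param VAF_muscle numeric vector of per-muscle VAF fractions.
#' @param threshold adequacy threshold (default 0.75).
#' @return A logical vector, `TRUE` where reconstruction is unsatisfactory.
#' @export
flag_low_vaf_muscles <- function(VAF_muscle, threshold = 0.75) {
  VAF_muscle < threshold
}
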