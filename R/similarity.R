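# Between-subject similarity statistics: Pearson r at zero lag, circular
# cross-correlation (r_max and lag), synergy matching, the analytic critical
# r, and permutation null distributions for synergy-vector similarity.

#' Pearson correlation of two waveforms
#'
#' Standard product-moment correlation with an explicit zero-variance guard:
#' a flat input has no defined correlation and returns `NA` with a warning
#' (callers exclude such pairs from aggregates).
#'
#' @param a,b numeric vectors of equal length (>= 3).
#' @return The correlation coefficient, or `NA` if either input has zero
#'   variance.
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance waveform: correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Circular cross-correlation of two cyclic waveforms
#'
#' Computes the Pearson correlation between `a` and every circular shift of
#' `b` over shifts in `(-T/2, T/2]`. `r_max` is the maximum; the lag is the
#' maximising shift expressed in % of the cycle, positive when `b` is delayed
#' relative to `a`. Exact ties are broken toward the smallest `|lag|` (then
#' toward the positive lag).
#'
#' @param a,b numeric vectors of equal length `T` (one cycle each).
#' @return An object of class `similarity_index`: `r` (zero-lag Pearson),
#'   `r_max`, `lag_pct` (signed, in `(-50, 50]`), `lag_abs_pct`.
#' @export
circular_xcorr <- function(a, b) {
  Tn <- length(a)
  stopifnot(length(b) == Tn, Tn >= 3L)
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance waveform: circular cross-correlation undefined",
         call. = FALSE)
  shifts <- seq.int(-floor(Tn / 2) + 1L, floor(Tn / 2))
  # evaluate in tie-break priority order: |lag| ascending, positive first
  ordering <- order(abs(shifts), -sign(shifts))
  rs <- vapply(shifts, function(m) cor(a, circshift(b, -m)), numeric(1))
  best <- ordering[which.max(rs[ordering])]
  r0 <- rs[shifts == 0L]
  structure(list(r = r0, r_max = rs[best],
                 lag_pct = shifts[best] * 100 / Tn,
                 lag_abs_pct = abs(shifts[best]) * 100 / Tn),
            class = "similarity_index")
}

#' @export
print.similarity_index <- function(x, ...) {
  cat(sprintf("<similarity_index> r=%.3f r_max=%.3f lag=%.1f%%\n",
              x$r, x$r_max, x$lag_pct))
  invisible(x)
}

# All permutations of 1..n (n small), as a list.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_perms(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

#' Match synergies between two decompositions
#'
#' Finds the one-to-one assignment of columns of `Wb` to columns of `Wa` that
#' maximises the summed column-wise Pearson correlation. Exhaustive over all
#' `s!` assignments for `s <= 7`; a greedy best-first assignment is used for
#' larger `s`.
#'
#' @param Wa,Wb `p x s` synergy-vector matrices with equal dimensions.
#' @return A list: `permutation` (index `j` of `Wb` matched to column `j` of
#'   `Wa`), `r` (the matched per-pair correlations) and `total` (their sum).
#' @export
match_synergies <- function(Wa, Wb) {
  Wa <- as.matrix(Wa); Wb <- as.matrix(Wb)
  if (!all(dim(Wa) == dim(Wb)))
    stop("`Wa` and `Wb` must have identical dimensions", call. = FALSE)
  s <- ncol(Wa)
  R <- suppressWarnings(cor(Wa, Wb))
  R[!is.finite(R)] <- -Inf
  if (s <= 7L) {
    perms <- all_perms(s)
    totals <- vapply(perms, function(p) sum(R[cbind(seq_len(s), p)]),
                     numeric(1))
    best <- perms[[which.max(totals)]]
  } else {
    best <- integer(s)
    avail <- seq_len(s)
    Rw <- R
    for (step in seq_len(s)) {
      idx <- which(Rw == max(Rw), arr.ind = TRUE)[1L, ]
      best[idx[1L]] <- idx[2L]
      Rw[idx[1L], ] <- -Inf
      Rw[, idx[2L]] <- -Inf
    }
  }
  list(permutation = best, r = R[cbind(seq_len(s), best)],
       total = sum(R[cbind(seq_len(s), best)]))
}

#' Analytic critical Pearson correlation
#'
#' The two-sided critical value of the Pearson correlation for
#' `p_muscles - 2` degrees of freedom at level `alpha`:
#' `r* = t* / sqrt(t*^2 + df)` with `t*` the two-sided Student critical value.
#' For 12 muscles at `alpha = 0.01` this is 0.71 (2 d.p.), the conventional
#' cut-off for declaring two 12-muscle synergy vectors similar.
#'
#' @param p_muscles number of weights per synergy vector (>= 3).
#' @param alpha two-sided significance level in (0, 1).
#' @return The critical correlation.
#' @export
critical_r <- function(p_muscles = 12, alpha = 0.01) {
  if (p_muscles < 3) stop("`p_muscles` must be at least 3", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  df <- p_muscles - 2
  tc <- qt(1 - alpha / 2, df)
  tc / sqrt(tc^2 + df)
}

#' Permutation null distribution for synergy-vector similarity
#'
#' Because non-negative weights correlate positively by chance, similarity
#' judgements need an empirical chance distribution. For each of `n_perm`
#' replicates, every subject's weight vector has its entries independently
#' permuted (set `joint = FALSE` to permute only the second member of each
#' pair) and the Pearson correlation is computed for every unordered subject
#' pair, pooling `C(n, 2) * n_perm` r-values.
#'
#' @param W_list a list of numeric weight vectors (one synergy per subject),
#'   or a `p x n_subjects` matrix.
#' @param n_perm permutation replicates (default 1000).
#' @param seed integer RNG seed.
#' @param joint permute every subject's vector independently (default) rather
#'   than only one member of each pair.
#' @return An object of class `permutation_null`: `r_values`, `n_perm`,
#'   `percentile_99` (linear-interpolation percentile), `seed`.
#' @export
permutation_null <- function(W_list, n_perm = 1000, seed = 1L, joint = TRUE) {
  if (is.matrix(W_list))
    W_list <- lapply(seq_len(ncol(W_list)), function(j) W_list[, j])
  n <- length(W_list)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  p <- length(W_list[[1L]])
  stopifnot(all(vapply(W_list, length, 1L) == p))
  ok <- vapply(W_list, function(w) sd(w) > 0, logical(1))
  if (!all(ok)) {
    warning("zero-variance weight vector(s) excluded from the null")
    W_list <- W_list[ok]
    n <- length(W_list)
    if (n < 2L) stop("fewer than 2 usable subjects", call. = FALSE)
  }
  prs <- utils::combn(n, 2L)
  r_values <- with_seed(seed, {
    out <- numeric(ncol(prs) * n_perm)
    idx <- 0L
    for (rep in seq_len(n_perm)) {
      Wp <- if (joint) lapply(W_list, sample) else W_list
      for (q in seq_len(ncol(prs))) {
        i <- prs[1L, q]; j <- prs[2L, q]
        b <- if (joint) Wp[[j]] else sample(W_list[[j]])
        idx <- idx + 1L
        out[idx] <- cor(Wp[[i]], b)
      }
    }
    out
  })
  structure(list(r_values = r_values, n_perm = n_perm,
                 n_pairs = ncol(prs),
                 percentile_99 = unname(quantile(r_values, 0.99, type = 7)),
                 seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d r-values (%d pairs x %d perms), 99th pct = %.3f\n",
              length(x$r_values), x$n_pairs, x$n_perm, x$percentile_99))
  invisible(x)
}

#' Pairwise similarity of cyclic waveforms across a cohort
#'
#' Computes `r`, `r_max` and absolute lag for every unordered pair of
#' subjects' waveforms and summarises each index by mean, min and max — the
#' standard similarity table for mechanical patterns, EMG patterns or synergy
#' activation coefficients.
#'
#' @param waveforms a list of equal-length numeric vectors (one cyclic
#'   waveform per subject) or a `n_subjects x T` matrix.
#' @return A list: `pairs` (data frame with i, j, r, r_max, lag_pct,
#'   lag_abs_pct) and `summary` (data frame with mean/min/max per index).
#' @export
pairwise_similarity <- function(waveforms) {
  if (is.matrix(waveforms))
    waveforms <- lapply(seq_len(nrow(waveforms)), function(i) waveforms[i, ])
  n <- length(waveforms)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  Tn <- length(waveforms[[1L]])
  stopifnot(all(vapply(waveforms, length, 1L) == Tn))
  prs <- utils::combn(n, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(q) {
    i <- prs[1L, q]; j <- prs[2L, q]
    sim <- circular_xcorr(waveforms[[i]], waveforms[[j]])
    data.frame(i = i, j = j, r = sim$r, r_max = sim$r_max,
               lag_pct = sim$lag_pct, lag_abs_pct = sim$lag_abs_pct)
  })
  pairs <- do.call(rbind, rows)
  idxs <- c("r", "r_max", "lag_abs_pct")
  summary <- data.frame(index = idxs,
                        mean = vapply(idxs, function(v) mean(pairs[[v]]), 1),
                        min = vapply(idxs, function(v) min(pairs[[v]]), 1),
                        max = vapply(idxs, function(v) max(pairs[[v]]), 1),
                        row.names = NULL)
  list(pairs = pairs, summary = summary)
}
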