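# Synergy-number selection: three complementary criteria applied to the
# VAF-versus-number-of-synergies curve.

#' VAF-threshold criterion
#'
#' Selects the least number of synergies whose VAF exceeds `vaf_threshold`
#' (default 0.90). If the curve never crosses the threshold, falls back to the
#' increment rule: the smallest `s` for which adding one more synergy does not
#' increase VAF by more than `increment` of the current VAF (relative reading;
#' set `relative = FALSE` for the absolute reading `delta <= increment`). If
#' neither rule fires, returns the curve length.
#'
#' @param curve numeric VAF curve, element `s` being the VAF with `s`
#'   synergies.
#' @param vaf_threshold VAF fraction to cross (default 0.90).
#' @param increment increment tolerance of the fallback rule (default 0.05).
#' @param relative interpret `increment` relative to the current VAF.
#' @return The selected number of synergies.
#' @export
select_threshold <- function(curve, vaf_threshold = 0.90, increment = 0.05,
                             relative = TRUE) {
  stopifnot(length(curve) >= 2L)
  hit <- which(curve > vaf_threshold)
  if (length(hit)) return(unname(hit[1L]))
  for (s in seq_len(length(curve) - 1L)) {
    gain <- curve[s + 1L] - curve[s]
    if (relative) gain <- gain / curve[s]
    if (gain <= increment) return(s)
  }
  length(curve)
}

#' Best-linear-fit (BLF) criterion
#'
#' Selects the smallest `n` such that a least-squares line through the points
#' `(n, curve[n]), ..., (p, curve[p])` has residual mean square below
#' `mse_threshold` — the point at which the VAF curve has flattened into a
#' straight line.
#'
#' @param curve numeric VAF curve of length `p`.
#' @param mse_threshold residual mean-square threshold (default `5e-5`).
#' @return The selected number of synergies (`p` if no tail is linear enough).
#' @export
select_blf <- function(curve, mse_threshold = 5e-5) {
  p <- length(curve)
  stopifnot(p >= 2L)
  for (n in seq_len(p - 1L)) {
    xs <- n:p
    fit <- lm(curve[xs] ~ xs)
    if (mean(fit$residuals^2) < mse_threshold) return(n)
  }
  p
}

#' Knee-point (KP) criterion against a shuffled surrogate
#'
#' Compares the slope of the VAF curve of the original data with that of the
#' curve obtained from entry-shuffled surrogate data. Slopes are forward first
#' differences, `slope[s] = curve[s + 1] - curve[s]`. Returns the smallest `s`
#' at which the original slope drops below `ratio` (default 0.75) of the
#' surrogate slope — beyond that point an extra synergy gains less VAF than
#' would be expected from unstructured data.
#'
#' @param curve VAF curve of the original data.
#' @param surrogate_curve VAF curve of the shuffled surrogate (same length).
#' @param ratio slope ratio threshold (default 0.75).
#' @return The selected number of synergies (`length(curve)` if the original
#'   slope never drops below the threshold).
#' @export
select_kp <- function(curve, surrogate_curve, ratio = 0.75) {
  stopifnot(length(curve) == length(surrogate_curve), length(curve) >= 2L)
  d_orig <- diff(curve)
  d_surr <- diff(surrogate_curve)
  hit <- which(d_orig < ratio * d_surr)
  if (length(hit)) unname(hit[1L]) else length(curve)
}

#' Full synergy-number selection report
#'
#' Computes the VAF curve of the data and of an entry-shuffled surrogate, then
#' applies the three selection criteria (threshold, best linear fit, knee
#' point).
#'
#' @inheritParams nmf_extract
#' @param vaf_threshold,increment,relative threshold-criterion parameters.
#' @param mse_threshold BLF residual mean-square threshold.
#' @param kp_ratio knee-point slope ratio.
#' @return An object of class `selection_report`: `vaf_curve`,
#'   `surrogate_curve`, and `chosen_s` (named vector with elements
#'   `threshold`, `blf`, `kp`).
#' @export
select_n_synergies <- function(E, n_restarts = 20, max_iter = 1000,
                               tol = 1e-5, seed = 1L,
                               vaf_threshold = 0.90, increment = 0.05,
                               relative = TRUE, mse_threshold = 5e-5,
                               kp_ratio = 0.75) {
  Em <- as_cycle_mat(E)
  curve <- vaf_curve(Em, n_restarts = n_restarts, max_iter = max_iter,
                     tol = tol, seed = seed)
  surr <- shuffle_surrogate(Em, seed = seed + 5000L)
  surr_curve <- vaf_curve(surr, n_restarts = n_restarts, max_iter = max_iter,
                          tol = tol, seed = seed + 6000L)
  chosen <- c(threshold = select_threshold(curve, vaf_threshold, increment,
                                           relative),
              blf = select_blf(curve, mse_threshold),
              kp = select_kp(curve, surr_curve, kp_ratio))
  structure(list(vaf_curve = curve, surrogate_curve = surr_curve,
                 chosen_s = chosen,
                 thresholds = list(vaf_threshold = vaf_threshold,
                                   increment = increment,
                                   relative = relative,
                                   mse_threshold = mse_threshold,
                                   kp_ratio = kp_ratio),
                 seed = seed),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n  VAF curve:",
      paste(sprintf("%.3f", x$vaf_curve), collapse = " "), "\n")
  cat(sprintf("  chosen s: threshold=%d blf=%d kp=%d\n",
              x$chosen_s["threshold"], x$chosen_s["blf"], x$chosen_s["kp"]))
  invisible(x)
}
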