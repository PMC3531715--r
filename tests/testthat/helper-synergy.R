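# Shared fixtures, all generated in code.

# Effective ground-truth basis for a normalised cycle matrix: per-muscle
# amplitude normalisation rescales rows of W_true, so the recoverable basis is
# D^-1 W_true with columns renormalised.
effective_truth_W <- function(gt, E) {
  W <- sweep(gt$W_true, 1L, E$norms, "/")
  sweep(W, 2L, sqrt(colSums(W^2)), "/")
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Small noise-free ground truth for fast exact-recovery tests.
tiny_gt <- function(p = 6, s = 2, T_cycle = 40, k = 3, noise_sd = 0,
                    seed = 1L, ...) {
  make_ground_truth(p = p, s = s, T_cycle = T_cycle, k = k,
                    noise_sd = noise_sd, peak_jitter = 0, amp_jitter = 0,
                    seed = seed, ...)
}

# Constant-pose marker frame repeated n times (a static body hanging from
# the bar), for potential-energy and geometry checks.
static_markers <- function(n = 5) {
  cfg <- swing_sim_config(n_cycles = 1)
  bc <- emgsynergy:::body_chain(cfg$model)
  J <- bc$joints
  df <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / 100)
  for (m in rownames(J)) {
    df[[paste0(m, "_x")]] <- rep(J[m, 1], n)
    df[[paste0(m, "_y")]] <- rep(J[m, 2], n)
  }
  df
}

# One-segment body model spanning two markers, for hand-computable cases.
one_segment_model <- function(M = 70, length = 1, cg_fraction = 0.5,
                              gyration_fraction = 0.3) {
  body_model(body_mass = M,
             segments = data.frame(name = "rod", from = "wrist", to = "hip",
                                   mass_fraction = 1,
                                   cg_fraction = cg_fraction,
                                   gyration_fraction = gyration_fraction,
                                   length = length))
}
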