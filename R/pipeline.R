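# End-to-end orchestration: simulate (or load) a cohort, extract synergies,
# select the synergy number, cross-validate across subjects, tabulate
# similarity statistics and (optionally) the swing biomechanics, and write
# tabular reports plus a machine-readable JSON summary.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline], populated with
#' the package defaults: a 9-subject synthetic cohort of 12 muscles, 3
#' ground-truth synergies, 9 cycles of 200 samples, the 20-restart NMF
#' protocol, the three selection criteria at their conventional thresholds,
#' and a 1000-replicate permutation null. Any element can be overridden via
#' `...` (nested lists are replaced wholesale) or by editing the returned
#' list; [run_pipeline] also accepts a YAML file with the same structure.
#'
#' @param ... named overrides of top-level elements.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(n_subjects = 9L, p = 12L, s = 3L, T_cycle = 200L, k = 9L,
                    sparsity = 0.4, peak_jitter = 2, amp_jitter = 0.1,
                    noise_sd = 0.1, shift_sd_pct = 3,
                    W_perturbation = 0.1),
    input_csv = NULL,      # alternatively: character vector of EMG CSV paths
    nmf = list(n_restarts = 20L, max_iter = 1000L, tol = 1e-5),
    selection = list(n_restarts = 5L, vaf_threshold = 0.90, increment = 0.05,
                     relative = TRUE, mse_threshold = 5e-5, kp_ratio = 0.75,
                     subjects = NULL),   # NULL = all subjects
    similarity = list(n_perm = 1000L),
    swing = list(enabled = TRUE, friction = 0, length_modulation = 0.3,
                 frame_rate = 100, n_cycles = 3)
  )
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg
}

#' Run the complete synergy-analysis pipeline
#'
#' Sequences the full analysis: obtain a cohort of normalised EMG cycle
#' matrices (synthetic by default, or loaded from CSV), extract synergies per
#' subject at the configured (or ground-truth) synergy number, compute the
#' synergy-number selection report per subject, run all-pairs cross-validation
#' with fixed synergy vectors and with fixed activation coefficients, compute
#' pairwise similarity of matched synergy vectors and activation waveforms
#' with a permutation null, and (optionally) simulate and profile a giant
#' swing. Identical configuration and seed give identical outputs.
#'
#' @param config a list from [pipeline_config] (possibly edited) or the path
#'   to a YAML file with the same structure.
#' @return A list with elements `cohort`, `decompositions`, `selection`,
#'   `crossval` (fix_W and fix_C results), `similarity`, `null`,
#'   `kinematics` (or `NULL`) and `summary` (the flat summary also written to
#'   JSON). When `config$out_dir` is set, writes per-subject W/C CSVs,
#'   selection, cross-validation and similarity tables, and `summary.json`
#'   there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set `seed`", call. = FALSE)
  seed <- as.integer(config$seed)

  # --- cohort -------------------------------------------------------------
  if (!is.null(config$input_csv)) {
    cohort <- lapply(config$input_csv, read_emg_csv)
    s <- config$nmf$s %||% config$simulate$s
  } else {
    sim <- config$simulate
    gt <- make_ground_truth(p = sim$p, s = sim$s, T_cycle = sim$T_cycle,
                            k = sim$k, sparsity = sim$sparsity,
                            peak_jitter = sim$peak_jitter,
                            amp_jitter = sim$amp_jitter,
                            noise_sd = sim$noise_sd, seed = seed)
    shifts <- with_seed(seed + 10L,
      round(rnorm(sim$n_subjects, 0, sim$shift_sd_pct / 100 * sim$T_cycle)))
    cohort <- synthesize_cohort(sim$n_subjects, gt,
                                per_subject_shift = shifts,
                                per_subject_W_perturbation = sim$W_perturbation,
                                seed = seed)
    s <- sim$s
  }
  n <- length(cohort)
  T_cycle <- cohort[[1L]]$T_cycle

  # --- extraction ---------------------------------------------------------
  nm <- config$nmf
  decomps <- lapply(seq_len(n), function(i)
    nmf_extract(cohort[[i]], s, n_restarts = nm$n_restarts,
                max_iter = nm$max_iter, tol = nm$tol, seed = seed + i))

  # --- synergy-number selection -------------------------------------------
  sel_cfg <- config$selection
  sel_subjects <- sel_cfg$subjects %||% seq_len(n)
  selection <- lapply(sel_subjects, function(i)
    select_n_synergies(cohort[[i]], n_restarts = sel_cfg$n_restarts,
                       max_iter = nm$max_iter, tol = nm$tol,
                       seed = seed + 100L * i,
                       vaf_threshold = sel_cfg$vaf_threshold,
                       increment = sel_cfg$increment,
                       relative = sel_cfg$relative,
                       mse_threshold = sel_cfg$mse_threshold,
                       kp_ratio = sel_cfg$kp_ratio))
  chosen <- t(vapply(selection, function(x) x$chosen_s, numeric(3)))

  # --- cross-validation (both modes share the free fits) -------------------
  cv_W <- cohort_crossval(cohort, s, mode = "fix_W",
                          max_iter = nm$max_iter, tol = nm$tol,
                          seed = seed + 7000L, decompositions = decomps)
  cv_C <- cohort_crossval(cohort, s, mode = "fix_C",
                          max_iter = nm$max_iter, tol = nm$tol,
                          seed = seed + 8000L, decompositions = decomps)

  # --- similarity ----------------------------------------------------------
  # match every subject's synergies onto subject 1's ordering
  perms <- lapply(decomps, function(d) match_synergies(decomps[[1L]]$W, d$W))
  W_aligned <- lapply(seq_len(n), function(i)
    decomps[[i]]$W[, perms[[i]]$permutation, drop = FALSE])
  C_aligned <- lapply(seq_len(n), function(i)
    cycle_average(decomps[[i]]$C, T_cycle,
                  cohort[[i]]$k)[perms[[i]]$permutation, , drop = FALSE])
  pr <- utils::combn(n, 2L)
  W_r <- matrix(NA_real_, ncol(pr), s)
  for (q in seq_len(ncol(pr)))
    for (j in seq_len(s))
      W_r[q, j] <- cor(W_aligned[[pr[1L, q]]][, j], W_aligned[[pr[2L, q]]][, j])
  C_sim <- lapply(seq_len(s), function(j)
    pairwise_similarity(lapply(C_aligned, function(Cm) Cm[j, ])))
  nulls <- lapply(seq_len(s), function(j)
    permutation_null(lapply(W_aligned, function(Wm) Wm[, j]),
                     n_perm = config$similarity$n_perm,
                     seed = seed + 9000L + j))
  r_crit <- critical_r(nrow(decomps[[1L]]$W), 0.01)

  # --- biomechanics --------------------------------------------------------
  kin <- NULL
  if (isTRUE(config$swing$enabled)) {
    sw <- config$swing
    scfg <- swing_sim_config(friction = sw$friction,
                             length_modulation = sw$length_modulation,
                             frame_rate = sw$frame_rate,
                             n_cycles = sw$n_cycles)
    markers <- simulate_giant_swing(scfg)
    kin <- swing_kinematics(markers, scfg$model, sw$frame_rate)
  }

  summary <- list(
    n_subjects = n, s = s,
    mean_VAF = mean(vapply(decomps, function(d) d$VAF_total, 1)),
    chosen_s_threshold = as.integer(chosen[, "threshold"]),
    chosen_s_blf = as.integer(chosen[, "blf"]),
    chosen_s_kp = as.integer(chosen[, "kp"]),
    crossval_VAF_fix_W = cv_W$mean_VAF,
    crossval_VAF_fix_C = cv_C$mean_VAF,
    synergy_vector_r_mean = colMeans(W_r),
    activation_r_max_mean = vapply(C_sim, function(x)
      x$summary$mean[x$summary$index == "r_max"], 1),
    critical_r = r_crit,
    null_percentile_99 = vapply(nulls, function(x) x$percentile_99, 1),
    seed = seed
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    for (i in seq_len(n)) {
      write.csv(data.frame(muscle = decomps[[i]]$labels, decomps[[i]]$W),
                file.path(od, sprintf("subject%02d_W.csv", i)),
                row.names = FALSE)
      write.csv(as.data.frame(decomps[[i]]$C),
                file.path(od, sprintf("subject%02d_C.csv", i)),
                row.names = FALSE)
    }
    write.csv(data.frame(subject = sel_subjects, chosen),
              file.path(od, "selection.csv"), row.names = FALSE)
    write.csv(cv_W$pairs, file.path(od, "crossval_fix_W.csv"),
              row.names = FALSE)
    write.csv(cv_C$pairs, file.path(od, "crossval_fix_C.csv"),
              row.names = FALSE)
    sim_tab <- do.call(rbind, lapply(seq_len(s), function(j)
      cbind(synergy = j, C_sim[[j]]$pairs,
            W_r = W_r[, j])))
    write.csv(sim_tab, file.path(od, "similarity.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(cohort = cohort, decompositions = decomps,
                 selection = selection, crossval = list(fix_W = cv_W,
                                                        fix_C = cv_C),
                 similarity = list(W_r = W_r, C = C_sim),
                 null = nulls, kinematics = kin, summary = summary))
}
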