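#' Benchmark values the synthetic defaults are built around
#'
#' The reported quantities of the emulated study, used as reference
#' columns in [run_report()] summaries: FRET state peaks, the
#' pattern-I share, the control spot-loss fraction, the conformer
#' angles and particle percentages, the bend-angle range of the linker
#' series, and the plateau count.
#'
#' @return A named list.
#' @export
reference_values <- function() {
  list(state_peaks = c(0.27, 0.42, 0.67, 0.88),
       pattern_I_percent = 55,
       control_spot_loss_percent = 94,
       conformer_angles = c(0, 20, 60, 100),
       complex_percentages = c(54, 30, 10, 6),
       ligase_amp_percentages = c(52, 23, 16, 9),
       theta_min_range = c(10, 130),
       n_plateaus = 4)
}

#' Run the full synthetic-data analysis chain and write a summary
#'
#' Simulates a trace ensemble, point clouds, spot fields and a gel
#' dataset, analyses each with the package pipeline, and writes TSV
#' outputs plus a `summary.tsv` juxtaposing the recovered quantities
#' with the benchmark [reference_values()]. A resolved-configuration
#' copy and a manifest with input checksums accompany the outputs so a
#' rerun with the same seed is byte-identical.
#'
#' @param out_dir output directory.
#' @param seed master integer seed.
#' @param n_traces ensemble size (default 300; enough for percentage
#'   recovery at a few-percent standard error).
#' @param n_clouds point clouds (default 1000).
#' @param trace_params a [trace_gen_params()].
#' @param model a [conformer_model()].
#' @param quantile minimum-angle quantile (default [min_bend_angle()]
#'   default).
#' @return Invisibly, the summary data.frame.
#' @export
run_report <- function(out_dir, seed = 1L, n_traces = 300L,
                       n_clouds = 1000L,
                       trace_params = trace_gen_params(seed = seed),
                       model = conformer_model(),
                       quantile = formals(min_bend_angle)$quantile) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  quantile <- eval(quantile)

  # --- smFRET branch -------------------------------------------------
  ens <- simulate_trace_ensemble(trace_params, n_traces,
                                 seed = derive_seed(seed, 1L))
  res <- analyze_trace_ensemble(ens)
  pct <- pattern_percentages(res$assignments, seed = derive_seed(seed, 2L))
  plate <- do.call(rbind, lapply(seq_along(res$fits), function(i) {
    p <- res$fits[[i]]$plateaus
    data.frame(trace_id = attr(ens, "manifest")$trace_id[i],
               start = p$start, end = p$end,
               mean = round(p$mean, 4))
  }))
  write_table_checked(plate, file.path(out_dir, "plateaus.tsv"))
  assign_df <- do.call(rbind, lapply(res$assignments, function(a) {
    data.frame(trace_id = a$trace_id, pattern = a$pattern,
               visited_states = paste(a$visited_states, collapse = "+"),
               n_excursions = a$n_excursions)
  }))
  write_table_checked(assign_df, file.path(out_dir, "assignments.tsv"))
  write_table_checked(pct, file.path(out_dir, "pattern_percentages.tsv"))

  # --- mechanics branch ----------------------------------------------
  linkers <- c(10, 15, 20, 25, 30, 40, 50, 60, 80)
  theta_min <- vapply(seq_along(linkers), function(i) {
    min_bend_angle(bow_construct(linkers[i]), quantile = quantile,
                   seed = derive_seed(seed, 100L + i))
  }, numeric(1))
  mech <- data.frame(linker_nt = linkers,
                     theta_min_deg = round(theta_min, 3),
                     quantile = quantile)
  write_table_checked(mech, file.path(out_dir, "mechanics.tsv"))

  # --- ligation branch -----------------------------------------------
  gel <- simulate_gel_experiment(model, seed = derive_seed(seed, 3L),
                                 quantile = quantile)
  fits <- lapply(unique(gel$data$construct), function(cc) {
    fit_c50(gel, cc)
  })
  plateaus <- detect_plateaus(fits)
  c50_df <- data.frame(construct = plateaus$construct,
                       c50_nM = plateaus$c50_nM,
                       plateau_id = plateaus$cluster)
  write_table_checked(c50_df, file.path(out_dir, "c50.tsv"))

  # --- point-cloud branch --------------------------------------------
  pcs <- simulate_complex_pointclouds(n_clouds,
                                      seed = derive_seed(seed, 4L))
  measured <- vapply(pcs$clouds, measure_bend_angle, numeric(1))
  classes <- classify_complex(measured)
  class_pct <- vapply(1:4, function(k) 100 * mean(classes == k),
                      numeric(1))

  # --- spot-field control --------------------------------------------
  spots <- simulate_spot_fields(repair_prob = 0,
                                seed = derive_seed(seed, 5L))
  spot_sum <- analyze_spot_fields(spots)

  ref <- reference_values()
  centers <- res$states$centers
  summary <- data.frame(
    quantity = c("pattern_I_percent",
                 paste0("state_peak_", seq_along(centers)),
                 "theta_min_10nt_deg", "theta_min_80nt_deg",
                 "n_plateaus", "class_I_percent",
                 "control_spot_loss_percent"),
    recovered = round(c(100 * pct$fraction[pct$pattern == "I"],
                        centers,
                        theta_min[1], theta_min[length(theta_min)],
                        plateaus$n_plateaus, class_pct[1],
                        100 * spot_sum$mean_lost), 4),
    reference = c(ref$pattern_I_percent,
                  ref$state_peaks[seq_along(centers)],
                  ref$theta_min_range[2], ref$theta_min_range[1],
                  ref$n_plateaus, ref$complex_percentages[1],
                  ref$control_spot_loss_percent))
  write_table_checked(summary, file.path(out_dir, "summary.tsv"))

  config <- data.frame(
    key = c("seed", "n_traces", "n_clouds", "quantile", "n_frames",
            "frame_time", "noise_sd", "total_intensity"),
    value = as.character(c(seed, n_traces, n_clouds, quantile,
                           trace_params$n_frames,
                           trace_params$frame_time,
                           trace_params$noise_sd,
                           trace_params$total_intensity)))
  write_table_checked(config, file.path(out_dir, "resolved_config.tsv"))
  outputs <- c("plateaus.tsv", "assignments.tsv",
               "pattern_percentages.tsv", "mechanics.tsv", "c50.tsv",
               "summary.tsv", "resolved_config.tsv")
  manifest <- data.frame(
    file = outputs,
    md5 = as.character(tools::md5sum(file.path(out_dir, outputs))))
  write_table_checked(manifest, file.path(out_dir, "run_manifest.tsv"))
  invisible(summary)
}
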