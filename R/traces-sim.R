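#' Parameters for synthetic two-channel smFRET trace generation
#'
#' Bundles everything needed to emulate a TIRF two-channel intensity
#' trace of a surface-bound nicked-DNA molecule being engaged by T4
#' ligase: camera timing, photon budget and noise, channel calibration,
#' the four true FRET state means, dwell times, and the kinetic mode.
#'
#' @param frame_time exposure time per frame in seconds (default 0.05,
#'   the acquisition rate of the experiments being emulated).
#' @param n_frames number of frames per trace.
#' @param total_intensity summed donor+acceptor photon budget per frame
#'   (arbitrary units).
#' @param noise_sd additive Gaussian noise per channel per frame, same
#'   units as `total_intensity`.
#' @param background_donor,background_acceptor constant channel
#'   backgrounds.
#' @param crosstalk_alpha fraction of (background-subtracted) donor
#'   signal leaking into the acceptor channel, in `[0, 1)`.
#' @param gamma detection-efficiency/quantum-yield factor applied to the
#'   acceptor channel, > 0.
#' @param state_efficiencies the four true FRET means, strictly
#'   increasing in (0, 1): the low (straight DNA) state followed by the
#'   three high (bent DNA) states. Defaults 0.27, 0.42, 0.67, 0.88.
#' @param dwell_low,dwell_high mean exponential dwell times (seconds)
#'   in the low state between excursions and in a high state.
#' @param mode `"nonsealable"` (excursions recur for the whole trace,
#'   as for a 3'-ddC blocked nick) or `"sealable"` (exactly one
#'   excursion, then low forever: the nick is sealed).
#' @param topology `"parallel"` (each excursion visits a single high
#'   state) or `"sequential"` (a ladder: excursions to state k pass
#'   through all lower high states en route; used only as the null
#'   alternative in the parallel-pathway test).
#' @param seed default integer seed for generators consuming these
#'   parameters.
#' @return A list of class `trace_gen_params`.
#' @seealso [simulate_trace()], [simulate_trace_ensemble()]
#' @export
trace_gen_params <- function(frame_time = 0.05,
                             n_frames = 600L,
                             total_intensity = 1000,
                             noise_sd = 60,
                             background_donor = 50,
                             background_acceptor = 50,
                             crosstalk_alpha = 0.05,
                             gamma = 1,
                             state_efficiencies = c(0.27, 0.42, 0.67, 0.88),
                             dwell_low = 2,
                             dwell_high = 1,
                             mode = c("nonsealable", "sealable"),
                             topology = c("parallel", "sequential"),
                             seed = 1L) {
  mode <- match.arg(mode)
  topology <- match.arg(topology)
  num1 <- function(x, name, lower = -Inf, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (strict && x <= lower) || (!strict && x < lower)) {
      stop(sprintf("`%s` must be a finite number %s %g", name,
                   if (strict) ">" else ">=", lower), call. = FALSE)
    }
    x
  }
  num1(frame_time, "frame_time", 0, strict = TRUE)
  n_frames <- as.integer(num1(n_frames, "n_frames", 2))
  num1(total_intensity, "total_intensity", 0, strict = TRUE)
  num1(noise_sd, "noise_sd", 0)
  num1(background_donor, "background_donor")
  num1(background_acceptor, "background_acceptor")
  num1(crosstalk_alpha, "crosstalk_alpha", 0)
  if (crosstalk_alpha >= 1) stop("`crosstalk_alpha` must be < 1", call. = FALSE)
  num1(gamma, "gamma", 0, strict = TRUE)
  if (!is.numeric(state_efficiencies) || length(state_efficiencies) != 4L ||
      anyNA(state_efficiencies) ||
      any(state_efficiencies <= 0) || any(state_efficiencies >= 1) ||
      any(diff(state_efficiencies) <= 0)) {
    stop("`state_efficiencies` must be 4 strictly increasing values in (0, 1)",
         call. = FALSE)
  }
  num1(dwell_low, "dwell_low", 0, strict = TRUE)
  num1(dwell_high, "dwell_high", 0, strict = TRUE)
  structure(
    list(frame_time = frame_time, n_frames = n_frames,
         total_intensity = total_intensity, noise_sd = noise_sd,
         background_donor = background_donor,
         background_acceptor = background_acceptor,
         crosstalk_alpha = crosstalk_alpha, gamma = gamma,
         state_efficiencies = state_efficiencies,
         dwell_low = dwell_low, dwell_high = dwell_high,
         mode = mode, topology = topology, seed = as.integer(seed)),
    class = "trace_gen_params")
}

# Continuous-time hidden state path for one trace.
# States are indexed 1 (low) .. 4; the trace pattern fixes the target
# high state. Returns a data.frame (state, t_start, t_end) covering at
# least [0, total_time].
simulate_state_segments <- function(params, pattern_index, total_time) {
  segs_state <- integer(0)
  segs_dur <- numeric(0)
  t <- 0
  add <- function(state, dur) {
    segs_state[[length(segs_state) + 1L]] <<- state
    segs_dur[[length(segs_dur) + 1L]] <<- dur
    t <<- t + dur
  }
  if (pattern_index == 1L) {
    add(1L, total_time)
  } else {
    rungs <- if (params$topology == "sequential") 2L:pattern_index
             else pattern_index
    repeat {
      add(1L, stats::rexp(1L, rate = 1 / params$dwell_low))
      if (t >= total_time) break
      for (s in rungs) {
        add(s, stats::rexp(1L, rate = 1 / params$dwell_high))
      }
      if (params$mode == "sealable") {
        add(1L, max(total_time - t, 0) + params$frame_time)
        break
      }
      if (t >= total_time) break
    }
  }
  t_end <- cumsum(segs_dur)
  data.frame(state = segs_state,
             t_start = c(0, t_end[-length(t_end)]),
             t_end = t_end)
}

#' Simulate a single two-channel smFRET trace
#'
#' Generates the hidden conformational state path for one of the four
#' trace patterns and renders it as noisy donor/acceptor intensities.
#' Pattern I stays in the low-FRET (straight DNA) state throughout;
#' patterns II--IV alternate between the low state and the pattern's
#' single recurring high state with exponential dwells. The per-frame
#' emissions are constructed so that [correct_trace()] with the matching
#' calibration recovers the true efficiency path exactly at zero noise:
#' `donor = bg_D + (1 - E) I + noise` and
#' `acceptor = bg_A + gamma E I + alpha (1 - E) I + noise`.
#'
#' @param params a [trace_gen_params()] object.
#' @param pattern one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param seed integer seed; defaults to `params$seed`.
#' @return A list of class `fluorescence_trace` with elements `frames`
#'   (0-based), `donor`, `acceptor`, and `metadata` carrying the
#'   generation parameters, the true pattern, the per-frame true state
#'   indices and efficiencies, and the continuous-time state segments.
#' @examples
#' tr <- simulate_trace(trace_gen_params(n_frames = 200), "III")
#' table(tr$metadata$state_path)
#' @export
simulate_trace <- function(params, pattern = c("I", "II", "III", "IV"),
                           seed = params$seed) {
  if (!inherits(params, "trace_gen_params")) {
    stop("`params` must come from trace_gen_params()", call. = FALSE)
  }
  pattern <- match.arg(pattern)
  pattern_index <- match(pattern, c("I", "II", "III", "IV"))
  with_seed(seed, {
    n <- params$n_frames
    total_time <- n * params$frame_time
    segs <- simulate_state_segments(params, pattern_index, total_time)
    # state at each frame midpoint
    t_mid <- (seq_len(n) - 0.5) * params$frame_time
    idx <- findInterval(t_mid, segs$t_start)
    state_path <- segs$state[idx]
    e_path <- params$state_efficiencies[state_path]
    i_tot <- params$total_intensity
    donor <- params$background_donor + (1 - e_path) * i_tot +
      stats::rnorm(n, sd = params$noise_sd)
    acceptor <- params$background_acceptor +
      params$gamma * e_path * i_tot +
      params$crosstalk_alpha * (1 - e_path) * i_tot +
      stats::rnorm(n, sd = params$noise_sd)
    structure(
      list(frames = 0:(n - 1L), donor = donor, acceptor = acceptor,
           metadata = list(params = params, pattern = pattern,
                           state_path = state_path,
                           efficiency_path = e_path,
                           segments = segs, seed = as.integer(seed))),
      class = "fluorescence_trace")
  })
}

#' Simulate an ensemble of smFRET traces
#'
#' Draws each trace's pattern from a seeded multinomial over the four
#' patterns and generates the traces with per-trace seeds derived
#' deterministically from the master seed, so identical calls are
#' byte-identical and traces are reproducible individually.
#'
#' @param params a [trace_gen_params()] object shared by all traces.
#' @param n_traces number of traces.
#' @param pattern_proportions length-4 simplex of pattern I--IV
#'   proportions. Default `c(0.55, 0.25, 0.12, 0.08)`: the pattern-I
#'   share reported for the emulated experiments, with the remainder
#'   split across II--IV.
#' @param seed master integer seed; defaults to `params$seed`.
#' @return A list of [simulate_trace()] objects with an attribute
#'   `manifest`: a data.frame (trace_id, true_pattern, seed).
#' @export
simulate_trace_ensemble <- function(params, n_traces,
                                    pattern_proportions =
                                      c(0.55, 0.25, 0.12, 0.08),
                                    seed = params$seed) {
  if (!inherits(params, "trace_gen_params")) {
    stop("`params` must come from trace_gen_params()", call. = FALSE)
  }
  if (!is.numeric(n_traces) || length(n_traces) != 1L || n_traces < 1) {
    stop("`n_traces` must be a positive count", call. = FALSE)
  }
  check_simplex(pattern_proportions, 4L, "pattern_proportions")
  n_traces <- as.integer(n_traces)
  patterns <- with_seed(seed, {
    sample(c("I", "II", "III", "IV"), n_traces, replace = TRUE,
           prob = pattern_proportions)
  })
  seeds <- vapply(seq_len(n_traces), function(i) derive_seed(seed, i),
                  integer(1))
  traces <- lapply(seq_len(n_traces), function(i) {
    simulate_trace(params, patterns[i], seed = seeds[i])
  })
  attr(traces, "manifest") <- data.frame(
    trace_id = sprintf("trace_%05d", seq_len(n_traces)),
    true_pattern = patterns, seed = seeds,
    stringsAsFactors = FALSE)
  traces
}
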