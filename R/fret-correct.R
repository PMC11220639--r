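#' Channel calibration for FRET efficiency computation
#'
#' @param background_donor,background_acceptor constant local channel
#'   backgrounds subtracted before anything else.
#' @param crosstalk_alpha fraction of background-subtracted donor
#'   signal leaking into the acceptor channel, in `[0, 1)`.
#' @param gamma factor absorbing relative quantum yield and detection
#'   efficiency between the channels, > 0.
#' @return A list of class `correction_params`.
#' @export
correction_params <- function(background_donor = 0,
                              background_acceptor = 0,
                              crosstalk_alpha = 0,
                              gamma = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0) {
    stop("`gamma` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(crosstalk_alpha) || length(crosstalk_alpha) != 1L ||
      !is.finite(crosstalk_alpha) || crosstalk_alpha < 0 ||
      crosstalk_alpha >= 1) {
    stop("`crosstalk_alpha` must be in [0, 1)", call. = FALSE)
  }
  structure(list(background_donor = background_donor,
                 background_acceptor = background_acceptor,
                 crosstalk_alpha = crosstalk_alpha, gamma = gamma),
            class = "correction_params")
}

#' Extract the calibration that matches a synthetic trace
#'
#' Convenience accessor returning the [correction_params()] that
#' exactly invert the generation model of a [simulate_trace()] object.
#'
#' @param trace a `fluorescence_trace`.
#' @return A `correction_params` object.
#' @export
matched_calibration <- function(trace) {
  p <- trace$metadata$params
  correction_params(background_donor = p$background_donor,
                    background_acceptor = p$background_acceptor,
                    crosstalk_alpha = p$crosstalk_alpha,
                    gamma = p$gamma)
}

#' Compute a corrected FRET efficiency trace
#'
#' Applies background subtraction, donor-to-acceptor crosstalk removal
#' and gamma correction: `D' = donor - bg_D`,
#' `A' = acceptor - bg_A - alpha D'`, `E = A' / (A' + gamma D')`.
#' Frames with non-positive total corrected signal carry no distance
#' information and are flagged unassignable (`NA` efficiency).
#'
#' @param raw a `fluorescence_trace` (from [simulate_trace()] or
#'   [read_traces()]).
#' @param cal a [correction_params()] object; defaults to the
#'   calibration stored with a synthetic trace.
#' @param clip soft clipping range for the efficiency; noisy frames may
#'   legitimately exceed `[0, 1]`. Default `c(-0.2, 1.2)`.
#' @return A list of class `efficiency_trace` with `frames`,
#'   `efficiency` (NA where unassignable) and `source` metadata.
#' @examples
#' tr <- simulate_trace(trace_gen_params(noise_sd = 0), "I")
#' e <- correct_trace(tr)
#' stopifnot(all(abs(e$efficiency - 0.27) < 1e-12))
#' @export
correct_trace <- function(raw, cal = matched_calibration(raw),
                          clip = c(-0.2, 1.2)) {
  if (!inherits(raw, "fluorescence_trace")) {
    stop("`raw` must be a fluorescence_trace", call. = FALSE)
  }
  if (!inherits(cal, "correction_params")) {
    stop("`cal` must come from correction_params()", call. = FALSE)
  }
  n <- length(raw$donor)
  if (n == 0L) stop("trace is empty", call. = FALSE)
  d <- raw$donor - cal$background_donor
  a <- raw$acceptor - cal$background_acceptor - cal$crosstalk_alpha * d
  tot <- a + cal$gamma * d
  e <- ifelse(tot > 0, a / tot, NA_real_)
  if (all(is.na(e))) {
    stop("all frames unassignable: no signal after correction",
         call. = FALSE)
  }
  e <- pmin(pmax(e, clip[1]), clip[2])
  structure(list(frames = raw$frames, efficiency = e,
                 source = raw$metadata),
            class = "efficiency_trace")
}
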