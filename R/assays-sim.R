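#' Simulate repair-and-then-cut spot-count fields
#'
#' Each fluorescent spot is a surface-tethered nicked DNA. During the
#' repair step the nick is sealed with probability `repair_prob`; in
#' the subsequent nicking-endonuclease step an unrepaired molecule is
#' cleaved (and its spot vanishes) with probability `cut_prob`. A spot
#' therefore survives with probability
#' `repair_prob + (1 - repair_prob) * (1 - cut_prob)`, and the
#' per-field count after cutting is the corresponding binomial draw.
#'
#' @param n_fields number of imaged fields (default 10).
#' @param spots_per_field spots per field before cutting (default 300).
#' @param repair_prob probability a nick is sealed (0 for a no-ligase
#'   control).
#' @param cut_prob probability an unrepaired molecule is cleaved
#'   (default 0.94, the observed control cutting efficiency).
#' @param seed integer seed.
#' @return A list of class `spot_field_dataset` with `fields`
#'   (data.frame `field`, `spots_before`, `spots_after`) and the true
#'   probabilities.
#' @export
simulate_spot_fields <- function(n_fields = 10L, spots_per_field = 300L,
                                 repair_prob, cut_prob = 0.94,
                                 seed = 1L) {
  if (n_fields < 1L) stop("`n_fields` must be >= 1", call. = FALSE)
  stopifnot_scalar_prob(repair_prob, "repair_prob")
  stopifnot_scalar_prob(cut_prob, "cut_prob")
  p_survive <- repair_prob + (1 - repair_prob) * (1 - cut_prob)
  after <- with_seed(seed, {
    stats::rbinom(n_fields, spots_per_field, p_survive)
  })
  structure(list(fields = data.frame(field = seq_len(n_fields),
                                     spots_before = spots_per_field,
                                     spots_after = after),
                 true_repair_prob = repair_prob,
                 true_cut_prob = cut_prob,
                 seed = as.integer(seed)),
            class = "spot_field_dataset")
}

#' Default bow-construct linker series
#'
#' The 10--80 nt linker grid of the emulated dose-response experiments
#' plus two unconstrained controls.
#'
#' @return A named list of [bow_construct()] objects.
#' @export
default_construct_series <- function() {
  linkers <- c(10, 15, 20, 25, 30, 40, 50, 60, 80)
  out <- lapply(linkers, bow_construct)
  names(out) <- paste0("L", linkers)
  out$unconstrained_0 <- bow_construct(Inf)
  out$unconstrained_80 <- bow_construct(Inf)
  out
}

#' Simulate a ligation dose-response (gel densitometry) dataset
#'
#' For each construct the noiseless repaired fraction at each ligase
#' concentration comes from [repair_fraction()] with the effective
#' rate of [effective_rate()]; replicate observations add truncated
#' Gaussian noise clipped to `[0, 1]`, emulating densitometry scatter.
#'
#' @param model a [conformer_model()].
#' @param constructs named list of [bow_construct()] objects (default
#'   [default_construct_series()]).
#' @param concentrations ligase concentrations in nM, strictly
#'   increasing; default a 12-point log grid from 0.03 to 100 nM.
#' @param incubation_time seconds (default 600).
#' @param noise_sd replicate noise on the fraction scale (default
#'   0.03).
#' @param n_replicates replicates per point (default 3).
#' @param seed master integer seed (also seeds the bend-angle
#'   Monte-Carlo for each construct).
#' @param ... passed to [min_bend_angle()] (e.g. `quantile`,
#'   `n_samples`).
#' @return A list of class `gel_dataset` with `data` (long data.frame:
#'   `construct`, `linker_nt`, `concentration_nM`, `replicate`,
#'   `repaired_fraction`), `truth` (per-construct `theta_min`,
#'   `k_eff`, accessible set), and the run parameters.
#' @export
simulate_gel_experiment <- function(model = conformer_model(),
                                    constructs = default_construct_series(),
                                    concentrations =
                                      10^seq(-1.5, 2, length.out = 12),
                                    incubation_time = 600,
                                    noise_sd = 0.03,
                                    n_replicates = 3L,
                                    seed = 1L, ...) {
  if (length(concentrations) == 0L) {
    stop("empty concentration grid", call. = FALSE)
  }
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop("`concentrations` must be positive and strictly increasing",
         call. = FALSE)
  }
  if (is.null(names(constructs))) {
    names(constructs) <- paste0("construct_", seq_along(constructs))
  }
  truth <- lapply(seq_along(constructs), function(i) {
    er <- effective_rate(constructs[[i]], model,
                         seed = derive_seed(seed, 1000L + i), ...)
    data.frame(construct = names(constructs)[i],
               linker_nt = constructs[[i]]$linker_nt,
               theta_min = er$theta_min, k_eff = er$k_eff,
               accessible = paste(er$accessible, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truth)
  rows <- with_seed(seed, {
    out <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      f0 <- repair_fraction(concentrations, incubation_time,
                            truth$k_eff[i])
      obs <- rep(f0, each = n_replicates) +
        stats::rnorm(length(f0) * n_replicates, sd = noise_sd)
      out[[i]] <- data.frame(
        construct = truth$construct[i],
        linker_nt = truth$linker_nt[i],
        concentration_nM = rep(concentrations, each = n_replicates),
        replicate = rep(seq_len(n_replicates), length(concentrations)),
        repaired_fraction = pmin(pmax(obs, 0), 1),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  structure(list(data = rows, truth = truth,
                 concentrations = concentrations,
                 incubation_time = incubation_time,
                 noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "gel_dataset")
}
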