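#' The four-conformer selectivity model of the ligase--AMP complex
#'
#' The adenylylated ligase pre-exists in four conformations, each able
#' to engage nicked DNA only up to a characteristic bend angle. A
#' construct whose minimum bend angle exceeds a conformer's
#' accessibility threshold cannot be repaired through that conformer's
#' pathway; the surviving pathways act in parallel.
#'
#' @param angles conformer bend angles in degrees (defaults 0, 20, 60,
#'   100).
#' @param proportions conformer population fractions; defaults to the
#'   DNA-free ligase--AMP percentages 0.52, 0.23, 0.16, 0.09 (the
#'   conformational selection happens before DNA binding); the
#'   DNA-bound set 0.54, 0.30, 0.10, 0.06 may be supplied instead.
#' @param rates intrinsic per-conformer rate constants in
#'   per-nM-per-second; default equal rates chosen so the
#'   unconstrained construct has a half-repair concentration of 1 nM
#'   in a 600 s incubation.
#' @param thresholds accessibility thresholds in degrees: conformer j
#'   repairs a construct iff its minimum bend angle is strictly below
#'   `thresholds[j]`. Defaults 20, 60, 100, Inf, read off the observed
#'   accessibility table rather than derived from the conformer angles
#'   (no single angular tolerance reproduces that table).
#' @return A list of class `conformer_model`.
#' @export
conformer_model <- function(angles = c(0, 20, 60, 100),
                            proportions = c(0.52, 0.23, 0.16, 0.09),
                            rates = rep(log(2) / 600, 4),
                            thresholds = c(20, 60, 100, Inf)) {
  check_simplex(proportions, 4L, "proportions")
  if (any(diff(thresholds) < 0)) {
    stop("`thresholds` must be non-decreasing", call. = FALSE)
  }
  if (any(angles >= thresholds)) {
    stop("each conformer angle must lie below its threshold",
         call. = FALSE)
  }
  if (any(rates < 0)) stop("`rates` must be >= 0", call. = FALSE)
  structure(list(angles = angles, proportions = proportions,
                 rates = rates, thresholds = thresholds,
                 labels = c("I", "II", "III", "IV")),
            class = "conformer_model")
}

#' Conformers able to repair a construct of given minimum bend angle
#'
#' @param theta_min minimum bend angle in degrees, `[0, 180)`.
#' @param model a [conformer_model()].
#' @return Character subset of `c("I", "II", "III", "IV")`.
#' @examples
#' accessible_conformers(130)   # only "IV"
#' accessible_conformers(0)     # all four
#' @export
accessible_conformers <- function(theta_min, model = conformer_model()) {
  if (theta_min < 0 || theta_min >= 180) {
    stop("`theta_min` must be in [0, 180)", call. = FALSE)
  }
  model$labels[theta_min < model$thresholds]
}

#' Effective ligation rate of a construct under conformer selectivity
#'
#' `k_eff` is the proportion-weighted sum of intrinsic rates over the
#' conformers whose accessibility threshold exceeds the construct's
#' minimum bend angle. Blocking conformers can only remove terms, which
#' is what quantizes the dose-response curves into plateaus.
#'
#' @param construct a [bow_construct()] (or a precomputed
#'   `theta_min` in degrees).
#' @param model a [conformer_model()].
#' @param ... passed to [min_bend_angle()] (`quantile`, `n_samples`,
#'   `seed`).
#' @return A list: `k_eff` (per nM per second), `theta_min`,
#'   `accessible` (conformer labels).
#' @export
effective_rate <- function(construct, model = conformer_model(), ...) {
  theta_min <- if (inherits(construct, "bow_construct")) {
    min_bend_angle(construct, ...)
  } else {
    as.numeric(construct)
  }
  acc <- accessible_conformers(theta_min, model)
  sel <- model$labels %in% acc
  list(k_eff = sum(model$proportions[sel] * model$rates[sel]),
       theta_min = theta_min, accessible = acc)
}

#' Repaired fraction under pseudo-first-order kinetics
#'
#' `f = 1 - exp(-k_eff * concentration * time)`: first order in enzyme
#' concentration at fixed incubation time, the simplest law with a
#' well-defined half-repair concentration `C50 = ln 2 / (k_eff t)`.
#'
#' @param concentration ligase concentration(s) in nM.
#' @param time incubation time in seconds (default 600: the 10-min
#'   incubation of the emulated assay).
#' @param k_eff effective rate in per nM per second.
#' @return Repaired fraction(s) in `[0, 1)`.
#' @export
repair_fraction <- function(concentration, time = 600, k_eff) {
  if (any(concentration < 0) || time < 0 || k_eff < 0) {
    stop("`concentration`, `time` and `k_eff` must be >= 0",
         call. = FALSE)
  }
  1 - exp(-k_eff * concentration * time)
}

#' Fit the half-repair concentration C50 for one construct
#'
#' Weighted least-squares fit of the pseudo-first-order dose-response
#' law to the replicate-averaged repaired fractions of one construct,
#' with per-concentration weights equal to the replicate counts (the
#' dose grid is log-spaced, so this is a fit across log-concentration).
#' `C50 = ln 2 / (k_hat t)`; its standard error follows from the
#' standard error of `k_hat` by the delta method. If the averaged curve
#' never crosses 0.5 the fit is flagged and the C50 reported as a
#' bound.
#'
#' @param dataset a [simulate_gel_experiment()] result or data.frame
#'   with columns `construct`, `concentration_nM`, `repaired_fraction`.
#' @param construct construct label to fit.
#' @param time incubation time in seconds (default the dataset's, else
#'   600).
#' @return A list of class `c50_fit`: `construct`, `c50_nM`, `se`,
#'   `k_eff`, `k_se`, `flag` (`"ok"`, `"lower_bound"` when the curve
#'   stays below 0.5, `"upper_bound"` when it stays above).
#' @export
fit_c50 <- function(dataset, construct, time = NULL) {
  df <- if (inherits(dataset, "gel_dataset")) dataset$data else dataset
  if (is.null(time)) {
    time <- if (inherits(dataset, "gel_dataset")) dataset$incubation_time
            else 600
  }
  rows <- df[df$construct == construct, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("construct '%s' not in dataset", construct),
         call. = FALSE)
  }
  agg <- stats::aggregate(repaired_fraction ~ concentration_nM,
                          data = rows, FUN = mean)
  wts <- stats::aggregate(repaired_fraction ~ concentration_nM,
                          data = rows, FUN = length)$repaired_fraction
  agg <- agg[order(agg$concentration_nM), ]
  if (nrow(agg) < 4L) {
    warning("fewer than 4 concentration points: C50 is an extrapolation")
  }
  conc <- agg$concentration_nM
  f <- agg$repaired_fraction
  flag <- if (max(f) < 0.5) "lower_bound"
          else if (min(f) > 0.5) "upper_bound"
          else "ok"
  # objective in log k for positivity and scale invariance
  obj <- function(logk) {
    k <- exp(logk)
    sum(wts * (f - (1 - exp(-k * conc * time)))^2)
  }
  # crude start: linear regression of -log(1 - f) on c*t over safe points
  safe <- f < 0.999 & f > 1e-6
  k0 <- if (any(safe)) {
    max(1e-12, sum(-log(1 - f[safe])) / sum(conc[safe] * time))
  } else 1e-9
  opt <- stats::optim(log(k0), obj, method = "Brent",
                      lower = log(k0) - 20, upper = log(k0) + 20)
  k_hat <- exp(opt$par)
  # delta-method SE from the Gauss-Newton approximation
  jac <- conc * time * exp(-k_hat * conc * time)
  resid <- f - (1 - exp(-k_hat * conc * time))
  dof <- max(length(f) - 1L, 1L)
  sigma2 <- sum(wts * resid^2) / dof
  jtj <- sum(wts * jac^2)
  k_se <- if (jtj > 0) sqrt(sigma2 / jtj) else NA_real_
  c50 <- log(2) / (k_hat * time)
  c50_se <- if (is.na(k_se)) NA_real_ else log(2) / (k_hat^2 * time) * k_se
  structure(list(construct = construct, c50_nM = c50, se = c50_se,
                 k_eff = k_hat, k_se = k_se, flag = flag,
                 time = time),
            class = "c50_fit")
}

#' Detect C50 plateaus by gap clustering on the log scale
#'
#' Sorts `log10(C50)` and cuts wherever a consecutive gap exceeds
#' `gap_factor` times the median gap, so the number of plateaus is an
#' output of the data, never an input. With a degenerate (zero) median
#' gap -- identical C50s within plateaus -- every positive gap is a
#' cut, which is the intended behaviour.
#'
#' @param profiles list of [fit_c50()] results (or numeric C50s in nM,
#'   optionally named).
#' @param gap_factor multiplier on the median log10 gap (default 5).
#' @return A list of class `plateau_clustering`: `n_plateaus`,
#'   `cluster` (per profile, ordered by increasing C50 cluster mean),
#'   `c50_nM`, `construct`.
#' @export
detect_plateaus <- function(profiles, gap_factor = 5) {
  if (inherits(profiles, "c50_fit")) profiles <- list(profiles)
  if (is.list(profiles)) {
    c50 <- vapply(profiles, function(p) p$c50_nM, numeric(1))
    labs <- vapply(profiles, function(p) as.character(p$construct),
                   character(1))
  } else {
    c50 <- as.numeric(profiles)
    labs <- if (!is.null(names(profiles))) names(profiles)
            else as.character(seq_along(c50))
  }
  if (length(c50) < 2L) stop("need at least 2 profiles", call. = FALSE)
  ord <- order(c50)
  lx <- log10(c50[ord])
  gaps <- diff(lx)
  med <- stats::median(gaps)
  cut <- gaps > gap_factor * med & gaps > 0
  cl_sorted <- cumsum(c(1L, as.integer(cut)))
  cluster <- integer(length(c50))
  cluster[ord] <- cl_sorted
  structure(list(n_plateaus = max(cl_sorted), cluster = cluster,
                 c50_nM = c50, construct = labs,
                 gap_factor = gap_factor),
            class = "plateau_clustering")
}

#' Summarize a repair-and-then-cut spot-field dataset
#'
#' Per-field surviving fraction `spots_after / spots_before`, then the
#' mean and standard deviation across fields -- the statistic the
#' single-molecule repair-and-then-nicking assay reports.
#'
#' @param data a [simulate_spot_fields()] result, or data.frame with
#'   columns `spots_before`, `spots_after`.
#' @return A list of class `spot_field_summary`: `mean_surviving`,
#'   `sd_surviving`, `mean_lost`, `n_fields`, `surviving_fractions`.
#' @export
analyze_spot_fields <- function(data) {
  df <- if (inherits(data, "spot_field_dataset")) data$fields else data
  if (!all(c("spots_before", "spots_after") %in% names(df))) {
    stop("need columns spots_before and spots_after", call. = FALSE)
  }
  if (nrow(df) < 1L) stop("need at least one field", call. = FALSE)
  zero <- df$spots_before == 0
  if (any(zero)) {
    warning(sprintf("excluding %d field(s) with zero spots", sum(zero)))
    df <- df[!zero, , drop = FALSE]
  }
  frac <- df$spots_after / df$spots_before
  structure(list(mean_surviving = mean(frac),
                 sd_surviving = if (nrow(df) >= 2L) stats::sd(frac)
                                else NA_real_,
                 mean_lost = 1 - mean(frac),
                 n_fields = nrow(df),
                 surviving_fractions = frac),
            class = "spot_field_summary")
}
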