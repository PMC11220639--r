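#' Locate FRET state peaks from plateau means
#'
#' Fits one-dimensional Gaussian mixtures to the pooled plateau means,
#' selecting the component count by BIC, and reduces the fitted
#' components to at most `k_max` distinct state centers. Plateau means
#' of a given state mix very different plateau lengths, so their
#' spread is strongly heteroscedastic; the mixture is therefore fitted
#' with unequal variances and a few spare components
#' (`G = 1 .. k_max + extra`), after which components whose means
#' nearly coincide -- duplicate descriptions of one physical state at
#' different plateau lengths -- are merged by mixing weight. The
#' sorted merged means are the state centers (the first being the low,
#' straight-DNA state). The assignment halfwidth used downstream is a
#' multiple of the typical within-state spread, capped at half the
#' smallest gap between adjacent centers so windows never overlap.
#'
#' @param plateau_means numeric vector of plateau mean efficiencies,
#'   pooled over traces.
#' @param k_max maximum number of distinct states returned (default 4:
#'   one low plus up to three high states).
#' @param halfwidth_sds multiple of the within-state spread defining
#'   the assignment halfwidth (default 3).
#' @param merge_eps components with means closer than this are treated
#'   as one state (default 0.06, well below the 0.13 minimum spacing
#'   of resolvable FRET states here).
#' @param extra_components spare mixture components available to
#'   absorb heteroscedasticity before merging (default 3).
#' @return A list of class `state_model` with `centers` (increasing),
#'   `sds` (per returned state), `weights`, `assignment_halfwidth`,
#'   `k`, and the BIC table.
#' @importFrom mclust mstep em unmap mstepV emV
#' @export
locate_state_peaks <- function(plateau_means, k_max = 4L,
                               halfwidth_sds = 3, merge_eps = 0.06,
                               extra_components = 3L) {
  x <- as.numeric(plateau_means)
  x <- x[is.finite(x)]
  if (length(x) < 3L * k_max) {
    stop(sprintf("too few plateau means (%d) for up to %d states",
                 length(x), k_max), call. = FALSE)
  }
  if (stats::sd(x) < 1e-9) {
    return(structure(list(centers = mean(x), sds = 0, weights = 1,
                          assignment_halfwidth = halfwidth_sds * 1e-3,
                          k = 1L, bic = NULL),
                     class = "state_model"))
  }
  g_max <- k_max + extra_components
  # Per-G EM fits seeded by kmeans from centers spread across the data
  # range: the default agglomerative initialization funnels several
  # components into the heaviest state and never reaches the sparse
  # high-FRET states, a local optimum BIC cannot escape.
  fits <- vector("list", g_max)
  bic <- rep(NA_real_, g_max)
  n <- length(x)
  bic[1] <- 2 * sum(stats::dnorm(x, mean(x), stats::sd(x), log = TRUE)) -
    2 * log(n)
  fits[[1]] <- list(mean = mean(x), sigmasq = stats::var(x), pro = 1)
  for (G in 2:g_max) {
    seeds <- seq(min(x), max(x), length.out = G)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = seeds, iter.max = 100L)),
      error = function(e) NULL)
    if (is.null(km)) next
    z <- mclust::unmap(km$cluster, groups = seq_len(G))
    ms <- mclust::mstep(data = x, modelName = "V", z = z)
    ef <- tryCatch(mclust::em(data = x, modelName = "V",
                              parameters = ms$parameters),
                   error = function(e) NULL)
    if (is.null(ef) || !is.finite(ef$loglik)) next
    bic[G] <- 2 * ef$loglik - (3 * G - 1) * log(n)
    fits[[G]] <- list(mean = as.numeric(ef$parameters$mean),
                      sigmasq = ef$parameters$variance$sigmasq,
                      pro = ef$parameters$pro)
  }
  g_best <- which.max(bic)
  best <- fits[[g_best]]
  mu <- best$mean
  var <- best$sigmasq
  if (length(var) == 1L) var <- rep(var, length(mu))
  w <- best$pro
  ord <- order(mu)
  mu <- mu[ord]; var <- var[ord]; w <- w[ord]
  # merge adjacent components into states while means are within eps
  grp <- cumsum(c(1L, as.integer(diff(mu) >= merge_eps)))
  centers <- as.numeric(tapply(mu * w, grp, sum) / tapply(w, grp, sum))
  wts <- as.numeric(tapply(w, grp, sum))
  sds <- sqrt(as.numeric(tapply(var * w, grp, sum) / tapply(w, grp, sum)))
  # cap at k_max states, keeping the heaviest
  if (length(centers) > k_max) {
    keep <- sort(order(wts, decreasing = TRUE)[seq_len(k_max)])
    centers <- centers[keep]; wts <- wts[keep]; sds <- sds[keep]
  }
  hw <- halfwidth_sds * max(sds)
  if (length(centers) > 1L) hw <- min(hw, min(diff(centers)) / 2)
  structure(list(centers = centers, sds = sds, weights = wts,
                 assignment_halfwidth = hw, k = length(centers),
                 bic = bic),
            class = "state_model")
}

#' Classify an idealized trace into transition patterns I--IV
#'
#' Each plateau is assigned to the nearest state center provided it
#' lies within the assignment halfwidth. Out-of-window plateaus
#' shorter than `min_plateau_length` are ignored (transition artefacts);
#' a longer out-of-window plateau marks the whole trace unassigned.
#' A state counts as visited only when it is established by at least
#' one plateau of `min_plateau_length` or more frames: shorter
#' plateaus are re-admitted only if they recur to an established
#' state, because frame-averaging over sub-resolution flickers
#' produces brief plateaus at intermediate efficiencies inside windows
#' the molecule never genuinely occupied. A trace whose only high-state
#' evidence is such short plateaus is `"unassigned"` (unresolved
#' dynamics).
#' A trace visiting only the low state is pattern I; exactly one of the
#' three high states (any number of recurrences) gives patterns
#' II--IV; two or more distinct high states give `"mixed"` -- the
#' signature a sequential pathway topology would produce.
#'
#' @param fit a [fit_steps()] result.
#' @param states a [locate_state_peaks()] result.
#' @param min_plateau_length out-of-window plateaus shorter than this
#'   are dropped as transition artefacts; longer ones invalidate the
#'   trace (default 20 frames, i.e. 1 s at the default frame time:
#'   long enough that a genuine state would sit inside its window).
#' @param trace_id optional identifier carried through.
#' @return A list of class `pattern_assignment` with `pattern` (one of
#'   `"I"`, `"II"`, `"III"`, `"IV"`, `"mixed"`, `"unassigned"`),
#'   `visited_states` (center indices), `n_excursions`, and the
#'   per-plateau state indices.
#' @export
classify_trace <- function(fit, states, min_plateau_length = 20L,
                           trace_id = NA_character_) {
  if (!inherits(fit, "step_fit")) stop("`fit` must be a step_fit",
                                       call. = FALSE)
  if (!inherits(states, "state_model")) {
    stop("`states` must be a state_model", call. = FALSE)
  }
  pl <- fit$plateaus
  idx <- vapply(pl$mean, function(m) which.min(abs(states$centers - m)),
                integer(1))
  dist <- abs(states$centers[idx] - pl$mean)
  inside <- dist <= states$assignment_halfwidth
  len <- pl$end - pl$start
  state_idx <- ifelse(inside, idx, NA_integer_)
  if (any(!inside & len >= min_plateau_length)) {
    return(structure(list(trace_id = trace_id, pattern = "unassigned",
                          visited_states = integer(0), n_excursions = 0L,
                          plateau_states = state_idx),
                     class = "pattern_assignment"))
  }
  # Only plateaus of resolvable duration can establish a state visit:
  # frame-averaging of sub-resolution flickers yields short plateaus at
  # intermediate efficiencies that fall inside a window the molecule
  # never genuinely occupied.
  established <- sort(unique(state_idx[!is.na(state_idx) &
                                         len >= min_plateau_length]))
  corroborated <- !is.na(state_idx) &
    (len >= min_plateau_length | state_idx %in% established)
  any_high_evidence <- any(!is.na(state_idx) & state_idx > 1L)
  seq_states <- state_idx[corroborated]
  if (length(seq_states) == 0L ||
      (any_high_evidence && !any(established > 1L))) {
    return(structure(list(trace_id = trace_id, pattern = "unassigned",
                          visited_states = integer(0), n_excursions = 0L,
                          plateau_states = state_idx),
                     class = "pattern_assignment"))
  }
  visited_high <- sort(unique(seq_states[seq_states > 1L]))
  is_high <- seq_states > 1L
  n_exc <- sum(is_high & !c(FALSE, is_high[-length(is_high)]))
  pattern <- if (length(visited_high) == 0L) "I"
    else if (length(visited_high) == 1L) c("I", "II", "III", "IV")[visited_high]
    else "mixed"
  structure(list(trace_id = trace_id, pattern = pattern,
                 visited_states = visited_high,
                 n_excursions = as.integer(n_exc),
                 plateau_states = state_idx),
            class = "pattern_assignment")
}

#' Pattern percentages with bootstrap confidence intervals
#'
#' Fractions of each trace pattern over the assigned traces
#' (`unassigned` traces are excluded, mirroring how only analyzable
#' traces enter the reported percentages), with seeded percentile
#' bootstrap confidence intervals.
#'
#' @param assignments list of [classify_trace()] results.
#' @param n_bootstrap bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return A data.frame with one row per category
#'   (I, II, III, IV, mixed): `fraction`, `lower`, `upper`, `n_assigned`.
#' @export
pattern_percentages <- function(assignments, n_bootstrap = 1000L,
                                conf = 0.95, seed = 1L) {
  pats <- vapply(assignments, function(a) a$pattern, character(1))
  pats <- pats[pats != "unassigned"]
  if (length(pats) == 0L) stop("no assigned traces", call. = FALSE)
  cats <- c("I", "II", "III", "IV", "mixed")
  frac <- vapply(cats, function(cc) mean(pats == cc), numeric(1))
  boot <- with_seed(seed, {
    replicate(n_bootstrap, {
      s <- sample(pats, replace = TRUE)
      vapply(cats, function(cc) mean(s == cc), numeric(1))
    })
  })
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  data.frame(pattern = cats, fraction = frac,
             lower = ci[1, ], upper = ci[2, ],
             n_assigned = length(pats), row.names = NULL)
}

#' Run the trace-analysis pipeline on an ensemble
#'
#' Correction (matched calibration for synthetic traces), step
#' fitting, pooled state-peak location, and per-trace pattern
#' classification.
#'
#' @param traces list of `fluorescence_trace` objects.
#' @param cal a [correction_params()]; `NULL` (default) uses each
#'   synthetic trace's own calibration.
#' @param cfg a [step_fit_config()].
#' @param k_max maximum state count for peak location.
#' @return A list with `fits`, `states` (the [locate_state_peaks()]
#'   model), `assignments`, and `plateau_means`.
#' @export
analyze_trace_ensemble <- function(traces, cal = NULL,
                                   cfg = step_fit_config(), k_max = 4L) {
  fits <- lapply(traces, function(tr) {
    e <- if (is.null(cal)) correct_trace(tr) else correct_trace(tr, cal)
    fit_steps(e, cfg)
  })
  plateau_means <- unlist(lapply(fits, function(f) f$plateaus$mean))
  plateau_lengths <- unlist(lapply(fits, function(f) {
    f$plateaus$end - f$plateaus$start
  }))
  # locate peaks on plateaus long enough to have well-determined means;
  # fall back to all plateaus for sparse ensembles
  long <- plateau_lengths >= 2L * cfg$min_plateau_length
  pm_fit <- if (sum(long) >= 10L * k_max) plateau_means[long]
            else plateau_means
  states <- locate_state_peaks(pm_fit, k_max = k_max)
  ids <- attr(traces, "manifest")$trace_id
  if (is.null(ids)) ids <- sprintf("trace_%05d", seq_along(traces))
  assignments <- lapply(seq_along(fits), function(i) {
    classify_trace(fits[[i]], states, trace_id = ids[i])
  })
  list(fits = fits, states = states, assignments = assignments,
       plateau_means = plateau_means)
}

#' Monte-Carlo test of parallel versus sequential pathway topology
#'
#' The observed statistic is the fraction of analyzable traces
#' classified `mixed` (visiting two or more distinct high-FRET
#' states). Under a sequential ladder topology, excursions to the
#' upper states traverse the lower ones and produce mixed traces; under
#' parallel pathways each trace revisits a single high state. The null
#' distribution is obtained by simulating `n_null` ensembles in
#' sequential topology with otherwise matched parameters and running
#' the identical analysis pipeline on each. The one-sided p-value uses
#' the add-one Monte-Carlo estimator `(k + 1) / (n_null + 1)` for the
#' probability of a mixed fraction at or below the observed one.
#'
#' @param assignments list of [classify_trace()] results for the
#'   observed ensemble.
#' @param params the [trace_gen_params()] describing the matched rates
#'   and noise (its `topology` is overridden to `"sequential"`).
#' @param pattern_proportions simplex used for the null ensembles.
#' @param n_null number of null ensembles (default 19).
#' @param n_traces_null traces per null ensemble (default 200; the
#'   null needs the distribution of a fraction, not per-trace power).
#' @param cfg a [step_fit_config()] shared with the observed analysis.
#' @param seed master seed for the null simulations.
#' @return A list of class `parallel_stats`: `n_traces`, `n_mixed`,
#'   `fraction_mixed` with a binomial (Wilson) confidence interval,
#'   `null_fractions`, `expected_null`, and `p_value`.
#' @export
parallel_vs_sequential_statistic <- function(assignments, params,
                                             pattern_proportions =
                                               c(0.55, 0.25, 0.12, 0.08),
                                             n_null = 19L,
                                             n_traces_null = 200L,
                                             cfg = step_fit_config(),
                                             seed = 1L) {
  if (n_null < 1L) stop("`n_null` must be >= 1", call. = FALSE)
  pats <- vapply(assignments, function(a) a$pattern, character(1))
  pats <- pats[pats != "unassigned"]
  n <- length(pats)
  n_mixed <- sum(pats == "mixed")
  frac <- n_mixed / n
  wilson <- stats::prop.test(n_mixed, n, correct = FALSE)$conf.int
  null_params <- params
  null_params$topology <- "sequential"
  null_frac <- vapply(seq_len(n_null), function(b) {
    ens <- simulate_trace_ensemble(null_params, n_traces_null,
                                   pattern_proportions,
                                   seed = derive_seed(seed, b))
    res <- analyze_trace_ensemble(ens, cfg = cfg)
    np <- vapply(res$assignments, function(a) a$pattern, character(1))
    np <- np[np != "unassigned"]
    mean(np == "mixed")
  }, numeric(1))
  p <- (sum(null_frac <= frac) + 1) / (n_null + 1)
  structure(list(n_traces = n, n_mixed = n_mixed,
                 fraction_mixed = frac,
                 conf_int = as.numeric(wilson),
                 null_fractions = null_frac,
                 expected_null = mean(null_frac),
                 p_value = p),
            class = "parallel_stats")
}
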