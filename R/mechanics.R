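#' Freely-jointed-chain parameters for ssDNA
#'
#' @param contour_per_nt contour length per nucleotide in nm
#'   (default 0.63).
#' @param kuhn_length Kuhn segment length in nm (default 1.5).
#' @return A list of class `ssdna_params`.
#' @export
ssdna_params <- function(contour_per_nt = 0.63, kuhn_length = 1.5) {
  if (contour_per_nt <= 0 || kuhn_length <= 0) {
    stop("ssDNA parameters must be strictly positive", call. = FALSE)
  }
  structure(list(contour_per_nt = contour_per_nt,
                 kuhn_length = kuhn_length),
            class = "ssdna_params")
}

#' A bending-constrained ("bow") nicked-DNA construct
#'
#' Two rigid duplex arms hinged at a central nick, with the duplex
#' outer ends tethered by an ssDNA linker modelled as a freely jointed
#' chain. The linker's finite extensibility imposes a minimum bend
#' angle on the duplex.
#'
#' @param linker_nt linker length in nucleotides (the emulated series
#'   spans 10--80 nt), or `Inf` / `NA` for an unconstrained control.
#' @param arm_bp base pairs per duplex arm (default 25: a 50-bp nicked
#'   duplex with a central nick).
#' @param rise_per_bp helical rise in nm per bp (default 0.34).
#' @param ssdna an [ssdna_params()] object.
#' @return A list of class `bow_construct`.
#' @export
bow_construct <- function(linker_nt, arm_bp = 25L, rise_per_bp = 0.34,
                          ssdna = ssdna_params()) {
  unconstrained <- length(linker_nt) == 1L &&
    (is.na(linker_nt) || is.infinite(linker_nt))
  if (!unconstrained &&
      (!is.numeric(linker_nt) || linker_nt < 0)) {
    stop("`linker_nt` must be >= 0, Inf, or NA", call. = FALSE)
  }
  if (arm_bp < 1) stop("`arm_bp` must be >= 1", call. = FALSE)
  structure(list(linker_nt = if (unconstrained) Inf else linker_nt,
                 arm_bp = arm_bp, rise_per_bp = rise_per_bp,
                 ssdna = ssdna, unconstrained = unconstrained),
            class = "bow_construct")
}

#' Arm length of a bow construct in nm
#' @param construct a [bow_construct()].
#' @return Arm length `arm_bp * rise_per_bp` in nm.
#' @export
arm_length_nm <- function(construct) {
  construct$arm_bp * construct$rise_per_bp
}

#' Chord length between the duplex outer ends at a given bend angle
#'
#' The nicked duplex is treated as two rigid rods of length `a` hinged
#' at the nick; at bend angle `theta` (deviation from straight, so
#' 0 degrees = straight) the outer ends are `d = 2 a cos(theta / 2)`
#' apart -- the span the ssDNA linker must bridge.
#'
#' @param theta bend angle(s) in degrees, in `[0, 180]`.
#' @param construct a [bow_construct()].
#' @return Chord length(s) in nm.
#' @examples
#' chord_length(0, bow_construct(30))    # 17 nm: straight 50-bp duplex
#' @export
chord_length <- function(theta, construct) {
  if (any(theta < 0 | theta > 180)) {
    stop("`theta` must be in [0, 180] degrees", call. = FALSE)
  }
  2 * arm_length_nm(construct) * cos(deg2rad(theta) / 2)
}

# Monte-Carlo end-to-end distances of an N-segment FJC (segment b).
# Chunked over samples so long chains stay within memory.
fjc_mc_distances <- function(N, b, n_samples, seed) {
  with_seed(seed, {
    chunk <- max(1L, as.integer(ceiling(1e7 / N)))
    out <- numeric(n_samples)
    done <- 0L
    while (done < n_samples) {
      m <- min(chunk, n_samples - done)
      z <- matrix(stats::runif(m * N, -1, 1), m, N)
      phi <- matrix(stats::runif(m * N, 0, 2 * pi), m, N)
      s <- sqrt(1 - z^2)
      out[done + seq_len(m)] <-
        b * sqrt(rowSums(s * cos(phi))^2 + rowSums(s * sin(phi))^2 +
                   rowSums(z)^2)
      done <- done + m
    }
    out
  })
}

# Number of Kuhn segments for a linker.
fjc_segments <- function(linker_nt, ssdna) {
  as.integer(ceiling(linker_nt * ssdna$contour_per_nt /
                       ssdna$kuhn_length))
}

#' Radial end-to-end density of the ssDNA linker
#'
#' Exact discrete freely-jointed-chain radial density, estimated by
#' seeded Monte-Carlo sampling of segment orientations and binned into
#' a histogram density (zero beyond the `N * kuhn_length` maximal
#' extension by construction). A Gaussian-chain closed form
#' (`backend = "gaussian"`) is available as a large-`N` cross-check;
#' short linkers (a handful of Kuhn segments) are far from Gaussian,
#' which is why the discrete chain is the default.
#'
#' @param r distances in nm at which to evaluate the density.
#' @param linker_nt linker length in nucleotides (> 0).
#' @param ssdna an [ssdna_params()].
#' @param backend `"mc"` (default) or `"gaussian"`.
#' @param n_samples Monte-Carlo sample count (default 2e5).
#' @param n_bins histogram bins for the Monte-Carlo density.
#' @param seed integer seed.
#' @return Density values (per nm) at `r`; integrates to 1 over
#'   `[0, N * kuhn_length]`.
#' @export
fjc_radial_density <- function(r, linker_nt, ssdna = ssdna_params(),
                               backend = c("mc", "gaussian"),
                               n_samples = 2e5, n_bins = 400L,
                               seed = 1L) {
  backend <- match.arg(backend)
  if (any(r < 0)) stop("`r` must be >= 0", call. = FALSE)
  if (!is.numeric(linker_nt) || length(linker_nt) != 1L || linker_nt <= 0 ||
      !is.finite(linker_nt)) {
    stop("`linker_nt` must be a finite positive length; a zero-length ",
         "linker is degenerate (point mass at r = 0)", call. = FALSE)
  }
  N <- fjc_segments(linker_nt, ssdna)
  b <- ssdna$kuhn_length
  if (backend == "gaussian") {
    s2 <- N * b^2
    return(4 * pi * r^2 * (3 / (2 * pi * s2))^1.5 *
             exp(-3 * r^2 / (2 * s2)))
  }
  d <- fjc_mc_distances(N, b, n_samples, seed)
  h <- graphics::hist(d, breaks = seq(0, N * b, length.out = n_bins + 1L),
                      plot = FALSE)
  f <- stats::approxfun(h$mids, h$density, yleft = 0, yright = 0)
  out <- f(r)
  out[r > N * b] <- 0
  out
}

#' Equilibrium bend-angle distribution of a bow construct
#'
#' A free three-dimensional hinge has inter-arm angle distributed with
#' the solid-angle weight `sin(180 - theta)`; the linker reweights each
#' hinge angle by the probability that the chain closes the gap -- its
#' end-to-end density per unit volume at the chord displacement the
#' bend requires: `P(theta) ~ sin(180 - theta) * rho(d(theta)) /
#' d(theta)^2` (the radial density divided by the spherical shell
#' area; constants drop out in normalization). This form reduces to
#' the free-hinge law for linkers much longer than the duplex span and
#' agrees with brute-force simulation of hinge plus chain. Evaluated
#' by quadrature on a fine degree grid using the seeded Monte-Carlo
#' chain density, and normalized.
#'
#' @param construct a [bow_construct()]. Unconstrained constructs get
#'   the free-hinge law (no reweighting).
#' @param grid_step angular grid resolution in degrees (default 0.025;
#'   small because low-probability tails define the minimum angle).
#' @param n_samples Monte-Carlo sample count for the chain density.
#' @param seed integer seed.
#' @param backend chain-density backend passed to
#'   [fjc_radial_density()]: `"mc"` (default) or `"gaussian"` (the
#'   large-`N` closed form, useful for very long linkers where a
#'   histogram over the full contour length cannot resolve the short
#'   chord range).
#' @return A list of class `bend_angle_distribution` with `theta`
#'   (degrees), `density` (per degree, summing to 1 times the grid
#'   step), `cdf`, `provenance`, `n_samples`, `seed`.
#' @export
bend_angle_distribution <- function(construct, grid_step = 0.025,
                                    n_samples = 2e5, seed = 1L,
                                    backend = c("mc", "gaussian")) {
  backend <- match.arg(backend)
  if (!inherits(construct, "bow_construct")) {
    stop("`construct` must come from bow_construct()", call. = FALSE)
  }
  theta <- seq(grid_step / 2, 180 - grid_step / 2, by = grid_step)
  w <- sin(deg2rad(180 - theta))
  provenance <- "quadrature"
  if (!construct$unconstrained) {
    if (construct$linker_nt == 0) {
      # degenerate: chord must vanish, the construct is folded flat
      w <- rep(0, length(theta))
      w[length(w)] <- 1
    } else {
      d <- chord_length(theta, construct)
      rho <- fjc_radial_density(d, construct$linker_nt, construct$ssdna,
                                backend = backend,
                                n_samples = n_samples, seed = seed)
      # closure probability per hinge angle: volume density at the chord
      w <- w * rho / pmax(d, 1e-9)^2
    }
  }
  if (!any(w > 0)) {
    stop("bend-angle distribution has no support; linker too short to ",
         "close the construct", call. = FALSE)
  }
  dens <- w / sum(w) / grid_step
  structure(list(theta = theta, density = dens,
                 cdf = cumsum(w) / sum(w),
                 provenance = provenance,
                 n_samples = if (construct$unconstrained) NA else n_samples,
                 seed = seed),
            class = "bend_angle_distribution")
}

#' Minimum bend angle of a bow construct
#'
#' The quantile-level lower quantile of the equilibrium bend-angle
#' distribution: the smallest bend angle the construct reaches with
#' probability at least `quantile`. The default quantile (2e-4) is the
#' package's calibration constant, chosen once so that the 10--80 nt
#' linker series spans approximately 130 degrees down to 10 degrees
#' (see the methods vignette). Unconstrained constructs return 0 by
#' convention: with no linker the duplex can be straight.
#'
#' @param construct a [bow_construct()].
#' @param quantile tail probability in `(0, 0.5]` defining "minimum".
#' @param n_samples,seed,grid_step passed to
#'   [bend_angle_distribution()].
#' @return Minimum bend angle in degrees.
#' @export
min_bend_angle <- function(construct, quantile = 2e-4,
                           n_samples = 2e5, seed = 1L,
                           grid_step = 0.025) {
  if (quantile <= 0 || quantile > 0.5) {
    stop("`quantile` must be in (0, 0.5]", call. = FALSE)
  }
  if (construct$unconstrained) return(0)
  dist <- bend_angle_distribution(construct, grid_step = grid_step,
                                  n_samples = n_samples, seed = seed)
  dist$theta[which(dist$cdf >= quantile)[1]]
}

#' Dye geometry and Forster radius for the hinge FRET model
#'
#' @param angles conformer bend angles in degrees (defaults 0, 20, 60,
#'   100, the four ligase-bound DNA conformations).
#' @param dye_separation_bp distance between donor and acceptor dyes
#'   in bp (default 21), centred on the nick.
#' @param rise_per_bp helical rise in nm per bp.
#' @param forster_radius Forster radius in nm; the default is
#'   calibrated so the straight state gives efficiency 0.27 (see
#'   [calibrate_forster_radius()]), landing near commonly cited
#'   Cy3/Cy5 values of about 6 nm.
#' @return A list of class `conformer_geometry`.
#' @export
conformer_geometry <- function(angles = c(0, 20, 60, 100),
                               dye_separation_bp = 21,
                               rise_per_bp = 0.34,
                               forster_radius =
                                 calibrate_forster_radius(
                                   dye_separation_bp = dye_separation_bp,
                                   rise_per_bp = rise_per_bp)) {
  if (any(diff(angles) <= 0) || any(angles < 0 | angles >= 180)) {
    stop("`angles` must be strictly increasing in [0, 180)", call. = FALSE)
  }
  structure(list(angles = angles,
                 dye_separation_bp = dye_separation_bp,
                 rise_per_bp = rise_per_bp,
                 forster_radius = forster_radius),
            class = "conformer_geometry")
}

#' Calibrate the Forster radius from the straight-state efficiency
#'
#' Solves `E0 = 1 / (1 + (r0 / R0)^6)` for `R0`, where `r0` is the
#' dye--dye distance of the straight duplex. Anchoring the model at the
#' measured unbound (straight) efficiency replaces an external `R0`
#' estimate.
#'
#' @param e_straight efficiency of the straight state (default 0.27).
#' @param dye_separation_bp,rise_per_bp dye geometry.
#' @return Forster radius in nm.
#' @export
calibrate_forster_radius <- function(e_straight = 0.27,
                                     dye_separation_bp = 21,
                                     rise_per_bp = 0.34) {
  r0 <- dye_separation_bp * rise_per_bp
  r0 / (1 / e_straight - 1)^(1 / 6)
}

#' Qualitative FRET efficiency versus bend angle
#'
#' Dyes sit equidistant about the nick, `dye_separation_bp / 2` bp
#' into each arm; bending folds them together along the chord, so the
#' dye--dye distance is
#' `r = dye_separation_bp * rise_per_bp * cos(theta / 2)` and
#' `E = 1 / (1 + (r / R0)^6)`. This is a monotone, qualitative model:
#' duplex twist at the nick also moves the dyes in the real system, so
#' only the ordering of the high states is claimed, not their values.
#'
#' @param theta bend angle(s) in degrees, `[0, 180)`.
#' @param geom a [conformer_geometry()].
#' @return FRET efficiency in (0, 1), strictly increasing in `theta`.
#' @examples
#' fret_vs_angle(0)   # 0.27 by calibration
#' @export
fret_vs_angle <- function(theta, geom = conformer_geometry()) {
  if (any(theta < 0 | theta >= 180)) {
    stop("`theta` must be in [0, 180) degrees", call. = FALSE)
  }
  r <- geom$dye_separation_bp * geom$rise_per_bp * cos(deg2rad(theta) / 2)
  1 / (1 + (r / geom$forster_radius)^6)
}
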