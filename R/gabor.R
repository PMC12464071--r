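#' Gabor stimulus specification
#'
#' Full parameterization of one Gabor grating: a sinusoidal luminance carrier
#' under a circular Gaussian envelope on a uniform background. Defaults follow
#' a standard peripheral orientation-discrimination setup: 2 degree-of-visual-
#' angle (dva) aperture, 2.5 cycles/deg carrier, 0.28 dva envelope SD, 45 deg
#' reference orientation, 45% Michelson contrast on a 52.42 cd/m2 background.
#'
#' Orientation convention: 0 deg = vertical carrier stripes, angles increase
#' clockwise and are taken modulo 180. Phase is measured at the envelope
#' center, in carrier-cycle degrees, reduced to [0, 360).
#'
#' @param size_deg aperture diameter, dva.
#' @param sf_cpd carrier spatial frequency, cycles/deg (> 0).
#' @param sigma_deg Gaussian envelope standard deviation, dva (> 0).
#' @param orientation_deg carrier orientation in degrees; stored modulo 180.
#' @param phase_deg spatial phase at the envelope center, degrees in [0, 360).
#' @param contrast nominal carrier Michelson contrast in [0, 1].
#' @param background_lum mean (background) luminance, cd/m2 (> 0).
#' @return An object of class `gabor_spec` (a named list).
#' @examples
#' spec <- gabor_spec(contrast = 0.45)
#' img <- render_gabor(spec, pixels_per_deg = 20)
#' michelson_contrast(img)
#' @export
gabor_spec <- function(size_deg = 2, sf_cpd = 2.5, sigma_deg = 0.28,
                       orientation_deg = 45, phase_deg = 0, contrast = 0.45,
                       background_lum = 52.42) {
  stopifnot(is.numeric(contrast), length(contrast) == 1L)
  if (is.na(contrast) || contrast < 0 || contrast > 1)
    stop("contrast must lie in [0, 1]")
  if (!is.numeric(sigma_deg) || sigma_deg <= 0) stop("sigma_deg must be > 0")
  if (!is.numeric(sf_cpd) || sf_cpd <= 0) stop("sf_cpd must be > 0")
  if (!is.numeric(size_deg) || size_deg <= 0) stop("size_deg must be > 0")
  if (!is.numeric(background_lum) || background_lum <= 0)
    stop("background_lum must be > 0")
  spec <- list(
    size_deg = size_deg, sf_cpd = sf_cpd, sigma_deg = sigma_deg,
    orientation_deg = orientation_deg %% 180,
    phase_deg = phase_deg %% 360,
    contrast = contrast, background_lum = background_lum
  )
  class(spec) <- "gabor_spec"
  spec
}

#' @export
print.gabor_spec <- function(x, ...) {
  cat(sprintf(
    "Gabor: %g dva, %g cpd, sigma %g dva, ori %g deg, phase %g deg, contrast %.3f, bg %g cd/m2\n",
    x$size_deg, x$sf_cpd, x$sigma_deg, x$orientation_deg, x$phase_deg,
    x$contrast, x$background_lum))
  invisible(x)
}

#' Render a Gabor grating as a luminance map
#'
#' Evaluates
#' \deqn{L(x,y) = L_{bg}\,[1 + c\, e^{-(x^2+y^2)/(2\sigma^2)}
#'   \cos(2\pi f (x\cos\theta + y\sin\theta) + \phi)]}
#' on a square pixel grid centered on the envelope, then clips negative
#' luminances to 0 (no display gamma model). The sampling rate must satisfy
#' the Nyquist requirement `pixels_per_deg >= 4 * sf_cpd`; coarser grids alias
#' and raise an error.
#'
#' @param spec a [gabor_spec()].
#' @param pixels_per_deg spatial sampling rate, pixels per dva.
#' @param field_deg side length of the rendered field, dva; must cover the
#'   aperture. Defaults to the aperture size.
#' @return A numeric matrix of luminances (cd/m2); rows index y (top = +y),
#'   columns index x.
#' @export
render_gabor <- function(spec, pixels_per_deg, field_deg = spec$size_deg) {
  stopifnot(inherits(spec, "gabor_spec"))
  if (!is.numeric(pixels_per_deg) || pixels_per_deg <= 0)
    stop("pixels_per_deg must be positive")
  if (pixels_per_deg < 4 * spec$sf_cpd)
    stop(sprintf(
      "aliasing: pixels_per_deg = %g is below the Nyquist requirement %g for sf_cpd = %g",
      pixels_per_deg, 4 * spec$sf_cpd, spec$sf_cpd))
  if (field_deg < spec$size_deg)
    stop("field_deg must cover the stimulus aperture")
  n <- max(2L, round(field_deg * pixels_per_deg))
  # pixel centers, symmetric about the envelope center
  coord <- (seq_len(n) - (n + 1) / 2) / pixels_per_deg
  x <- matrix(coord, n, n, byrow = TRUE)
  y <- matrix(rev(coord), n, n) # +y upward
  theta <- spec$orientation_deg * pi / 180
  phi <- spec$phase_deg * pi / 180
  envelope <- exp(-(x^2 + y^2) / (2 * spec$sigma_deg^2))
  carrier <- cos(2 * pi * spec$sf_cpd * (x * cos(theta) + y * sin(theta)) + phi)
  L <- spec$background_lum * (1 + spec$contrast * envelope * carrier)
  pmax(L, 0)
}

#' Michelson contrast of a luminance map
#'
#' `(Lmax - Lmin) / (Lmax + Lmin)` over all finite entries.
#'
#' @param map numeric matrix (or vector) of nonnegative luminances.
#' @return A number in \[0, 1\].
#' @export
michelson_contrast <- function(map) {
  map <- as.numeric(map)
  if (any(!is.finite(map))) stop("map contains non-finite values")
  if (any(map < 0)) stop("map must be nonnegative")
  lo <- min(map); hi <- max(map)
  if (hi + lo == 0) stop("all-zero map: Michelson contrast undefined")
  (hi - lo) / (hi + lo)
}

#' Task-irrelevant randomization scheme
#'
#' Exactly one stimulus dimension varies from trial to trial:
#' `kind = "phase"` draws the spatial phase uniformly on `phase_range_deg`
#' (default \[0, 180), half-open) with contrast fixed at `fixed_contrast`
#' (default 0.45); `kind = "contrast"` draws Michelson contrast uniformly on
#' `contrast_range` (default \[0.33, 0.66\]) with phase fixed at
#' `fixed_phase_deg` (default 0).
#'
#' @param kind `"phase"` or `"contrast"`.
#' @param phase_range_deg length-2 numeric, subinterval of \[0, 360).
#' @param contrast_range length-2 numeric, subinterval of \[0, 1\].
#' @param fixed_phase_deg phase used when `kind = "contrast"`.
#' @param fixed_contrast contrast used when `kind = "phase"`.
#' @return An object of class `randomization_scheme`.
#' @export
randomization_scheme <- function(kind = c("phase", "contrast"),
                                 phase_range_deg = c(0, 180),
                                 contrast_range = c(0.33, 0.66),
                                 fixed_phase_deg = 0,
                                 fixed_contrast = 0.45) {
  kind <- match.arg(kind)
  stopifnot(length(phase_range_deg) == 2L, length(contrast_range) == 2L)
  if (diff(phase_range_deg) <= 0 || phase_range_deg[1] < 0 ||
      phase_range_deg[2] > 360)
    stop("phase_range_deg must be a non-empty subinterval of [0, 360)")
  if (diff(contrast_range) <= 0 || contrast_range[1] < 0 ||
      contrast_range[2] > 1)
    stop("contrast_range must be a non-empty subinterval of [0, 1]")
  if (fixed_contrast < 0 || fixed_contrast > 1)
    stop("fixed_contrast must lie in [0, 1]")
  out <- list(kind = kind, phase_range_deg = phase_range_deg,
              contrast_range = contrast_range,
              fixed_phase_deg = fixed_phase_deg %% 360,
              fixed_contrast = fixed_contrast)
  class(out) <- "randomization_scheme"
  out
}

#' Sample the stimulus specification for one trial
#'
#' Applies a [randomization_scheme()] to a base [gabor_spec()]: the scheme's
#' varying dimension is drawn uniformly (phase from a half-open interval),
#' the other is pinned to the scheme's fixed value. Uses R's global RNG, so
#' draws are reproducible under `set.seed()`.
#'
#' @param scheme a [randomization_scheme()].
#' @param base the base [gabor_spec()] (orientation, envelope, background).
#' @return A [gabor_spec()] for the trial.
#' @export
sample_trial_stimulus <- function(scheme, base) {
  stopifnot(inherits(scheme, "randomization_scheme"),
            inherits(base, "gabor_spec"))
  if (scheme$kind == "phase") {
    # half-open [lo, hi): runif never returns hi (P = 0), lo mapped exactly
    phase <- stats::runif(1, scheme$phase_range_deg[1], scheme$phase_range_deg[2])
    base$phase_deg <- phase %% 360
    base$contrast <- scheme$fixed_contrast
  } else {
    base$contrast <- stats::runif(1, scheme$contrast_range[1], scheme$contrast_range[2])
    base$phase_deg <- scheme$fixed_phase_deg
  }
  base
}
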