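#' Bandpass-filtered noise texture
#'
#' Generates an isotropic bandpass Gaussian noise texture by filtering white
#' noise in the frequency domain with a log-Gaussian annulus centred on
#' `center_sf`, then renormalising to exactly zero mean and unit variance.
#' This is the carrier texture for correlation-modulated dichoptic stimuli.
#'
#' @param center_sf Centre spatial frequency of the passband, cycles/degree.
#' @param octave_bandwidth Full bandwidth at half height, octaves. Default 1.
#' @param extent_deg Width/height of the (square) texture, degrees.
#' @param pixels_per_degree Sampling density, pixels/degree.
#' @param seed Integer seed; identical seeds give identical textures.
#' @return A square numeric matrix with mean 0 and variance 1 (denominator
#'   `n`, i.e. the population variance of the pixel values).
#' @examples
#' tex <- make_bandpass_noise(4, extent_deg = 4, pixels_per_degree = 16, seed = 1)
#' c(mean(tex), mean(tex^2))
#' @export
make_bandpass_noise <- function(center_sf, octave_bandwidth = 1,
                                extent_deg = 12.8, pixels_per_degree = 40,
                                seed = 1L) {
  stopifnot(center_sf > 0, octave_bandwidth > 0,
            extent_deg > 0, pixels_per_degree > 0)
  if (center_sf >= pixels_per_degree / 2) {
    stop("center_sf (", center_sf, " c/d) violates the Nyquist limit of ",
         pixels_per_degree / 2, " c/d at ", pixels_per_degree, " px/deg")
  }
  npx <- round(extent_deg * pixels_per_degree)
  if (npx < 4) stop("texture too small: fewer than 4 pixels across")

  white <- with_local_seed(seed, matrix(stats::rnorm(npx * npx), npx, npx))

  # radial frequency of each DFT bin, cycles/degree
  fx <- c(seq_len(npx) - 1)
  fx <- ifelse(fx > npx / 2, fx - npx, fx) / extent_deg
  fr <- sqrt(outer(fx^2, fx^2, "+"))

  # log-Gaussian annulus: full width at half maximum = octave_bandwidth octaves
  sigma <- octave_bandwidth * log(2) / (2 * sqrt(2 * log(2)))
  filt <- matrix(0, npx, npx)
  nz <- fr > 0
  filt[nz] <- exp(-(log(fr[nz] / center_sf))^2 / (2 * sigma^2))

  tex <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / (npx * npx)
  tex <- tex - mean(tex)
  tex / sqrt(mean(tex^2))
}

#' Carrier set for a correlation-modulated dichoptic stimulus
#'
#' One correlated carrier shared by the two eyes plus two independent
#' uncorrelated carriers, all with identical filter parameters but
#' independent seeded noise streams.
#'
#' @inheritParams make_bandpass_noise
#' @param seed Base seed; the three carriers use `seed`, `seed + 1`,
#'   `seed + 2` offsets through independent streams.
#' @return A list of class `carrier_set` with matrices `common`, `left`,
#'   `right` and the generating parameters.
#' @export
make_carrier_set <- function(center_sf, octave_bandwidth = 1,
                             extent_deg = 12.8, pixels_per_degree = 40,
                             seed = 1L) {
  sub <- derive_seed(seed, 11L, 0:2)
  carriers <- lapply(sub, function(s)
    make_bandpass_noise(center_sf, octave_bandwidth, extent_deg,
                        pixels_per_degree, seed = s))
  structure(list(common = carriers[[1]], left = carriers[[2]],
                 right = carriers[[3]], center_sf = center_sf,
                 octave_bandwidth = octave_bandwidth,
                 extent_deg = extent_deg,
                 pixels_per_degree = pixels_per_degree, seed = seed),
            class = "carrier_set")
}

#' Specification of a correlation-modulated dichoptic stimulus
#'
#' @param M Modulation (blending) parameter in `[0, 1]`. At `M = 0` the whole
#'   stimulus is 50% interocularly correlated; at `M = 1` the correlated
#'   stripes are 100% correlated and the anticorrelated stripes 0%.
#' @param fm Envelope spatial frequency, cycles/degree. The carrier is fixed
#'   at four times this frequency.
#' @param orientation Envelope stripe orientation, 45 or 135 degrees.
#' @param extent_deg,pixels_per_degree Stimulus geometry.
#' @param octave_bandwidth Carrier filter bandwidth, octaves.
#' @param seed Integer seed for the carriers.
#' @return A list of class `correlation_stimulus_spec`.
#' @export
correlation_stimulus_spec <- function(M, fm, orientation = 45,
                                      extent_deg = 12.8,
                                      pixels_per_degree = 40,
                                      octave_bandwidth = 1, seed = 1L) {
  if (!is.numeric(M) || M < 0 || M > 1) stop("M must lie in [0, 1]")
  if (!orientation %in% c(45, 135)) stop("orientation must be 45 or 135")
  stopifnot(fm > 0, extent_deg > 0, pixels_per_degree > 0)
  structure(list(M = M, fm = fm, carrier_sf = 4 * fm,
                 orientation = orientation, extent_deg = extent_deg,
                 pixels_per_degree = pixels_per_degree,
                 octave_bandwidth = octave_bandwidth, seed = seed),
            class = "correlation_stimulus_spec")
}

# signed distance (degrees) of each pixel from the image centre along the
# axis orthogonal to the envelope stripes
envelope_coordinate <- function(spec) {
  npx <- round(spec$extent_deg * spec$pixels_per_degree)
  u <- (seq_len(npx) - (npx + 1) / 2) / spec$pixels_per_degree
  s <- 1 / sqrt(2)
  if (spec$orientation == 45) {
    outer(u, u, function(y, x) (x + y) * s)
  } else {
    outer(u, u, function(y, x) (x - y) * s)
  }
}

#' Complementary correlation envelopes
#'
#' The sinusoidal envelopes weighting the correlated and the uncorrelated
#' carriers: `M_C(x) = (1 + M sin(2 pi fm x)) / 2` and
#' `M_eye(x) = (1 - M sin(2 pi fm x)) / 2`, with `x` the distance in degrees
#' along the axis perpendicular to the oblique stripes, origin at the image
#' centre. The two envelopes sum to 1 at every pixel; both eyes share the
#' same uncorrelated-carrier envelope.
#'
#' @param spec A [correlation_stimulus_spec()].
#' @param x Optional coordinate (scalar, vector or matrix, degrees). When
#'   omitted, the pixel grid implied by `spec` is used.
#' @return A list with elements `M_C` and `M_eye`, shaped like `x`.
#' @export
correlation_envelopes <- function(spec, x = NULL) {
  stopifnot(inherits(spec, "correlation_stimulus_spec"))
  if (is.null(x)) x <- envelope_coordinate(spec)
  s <- sin(2 * pi * spec$fm * x)
  list(M_C = (1 + spec$M * s) / 2, M_eye = (1 - spec$M * s) / 2)
}

#' Blend carriers and envelopes into a dichoptic image pair
#'
#' Pointwise blend `I_eye = C_common * M_C + C_eye * M_eye`, giving a pair of
#' noise images whose local interocular correlation follows the envelope.
#'
#' @param carriers A [make_carrier_set()] result (or any list with `common`,
#'   `left`, `right` matrices of one shape).
#' @param envelopes A list with `M_C`, `M_eye` matrices of the same shape.
#' @param spec Optional spec to attach to the result.
#' @return A list of class `dichoptic_pair` with `left` and `right` image
#'   matrices.
#' @export
blend_dichoptic <- function(carriers, envelopes, spec = NULL) {
  dm <- dim(carriers$common)
  same <- function(a) identical(dim(a), dm)
  if (!same(carriers$left) || !same(carriers$right) ||
      !same(envelopes$M_C) || !same(envelopes$M_eye)) {
    stop("carriers and envelopes must share one shape")
  }
  structure(list(
    left  = carriers$common * envelopes$M_C + carriers$left  * envelopes$M_eye,
    right = carriers$common * envelopes$M_C + carriers$right * envelopes$M_eye,
    spec  = spec), class = "dichoptic_pair")
}

#' Generate a correlation-modulated dichoptic stimulus
#'
#' Convenience wrapper: carriers (at four times the envelope frequency),
#' envelopes, and blend, from one spec.
#'
#' @param spec A [correlation_stimulus_spec()].
#' @return A `dichoptic_pair`.
#' @export
make_correlation_stimulus <- function(spec) {
  stopifnot(inherits(spec, "correlation_stimulus_spec"))
  carriers <- make_carrier_set(spec$carrier_sf, spec$octave_bandwidth,
                               spec$extent_deg, spec$pixels_per_degree,
                               seed = spec$seed)
  blend_dichoptic(carriers, correlation_envelopes(spec), spec = spec)
}

#' Expected local interocular correlation
#'
#' Closed-form expected Pearson correlation between the two eyes' images at
#' an envelope phase `psi`, for independent zero-mean unit-variance carriers:
#' with weights `mC = (1 + M sin(psi)) / 2` and `me = (1 - M sin(psi)) / 2`,
#' the correlation is `mC^2 / (mC^2 + me^2)`. At `M = 1` it reaches 1 (100%)
#' at the correlated-stripe peak; at `M = 0` it is 0.5 (50%) everywhere.
#'
#' @param M Modulation parameter in `[0, 1]`.
#' @param envelope_phase Envelope phase `psi = 2 pi fm x`, radians. Default
#'   `pi / 2`, the correlated-stripe peak.
#' @return Expected correlation in `[0, 1]` (vectorised over both arguments).
#' @export
expected_local_correlation <- function(M, envelope_phase = pi / 2) {
  if (any(M < 0 | M > 1)) stop("M must lie in [0, 1]")
  s <- sin(envelope_phase)
  mC <- (1 + M * s) / 2
  me <- (1 - M * s) / 2
  mC^2 / (mC^2 + me^2)
}

#' Specification of a phase-combination grating pair
#'
#' Horizontal sine-wave gratings with equal-and-opposite phase shifts of
#' `theta0` (22.5 degrees by default). The nondominant eye's contrast is
#' fixed at 100%; the dominant eye is scaled by the interocular contrast
#' ratio `delta`. Configuration 1 puts `+theta0` in the dominant eye;
#' configuration 2 reverses the signs.
#'
#' @param contrast_ratio Dominant-eye contrast multiplier `delta` in `(0, 1]`.
#' @param theta0 Half phase offset, degrees.
#' @param grating_sf Grating spatial frequency, cycles/degree.
#' @param configuration 1 or 2.
#' @param extent_deg,pixels_per_degree Stimulus geometry.
#' @return A list of class `phase_stimulus_spec`.
#' @export
phase_stimulus_spec <- function(contrast_ratio = 1, theta0 = 22.5,
                                grating_sf = 0.46, configuration = 1,
                                extent_deg = 8.7, pixels_per_degree = 40) {
  if (contrast_ratio <= 0 || contrast_ratio > 1)
    stop("contrast_ratio must lie in (0, 1]")
  if (!configuration %in% c(1, 2)) stop("configuration must be 1 or 2")
  stopifnot(grating_sf > 0, extent_deg > 0, pixels_per_degree > 0)
  structure(list(contrast_ratio = contrast_ratio, theta0 = theta0,
                 grating_sf = grating_sf, configuration = configuration,
                 extent_deg = extent_deg,
                 pixels_per_degree = pixels_per_degree),
            class = "phase_stimulus_spec")
}

#' Dichoptic grating pair for the phase-combination task
#'
#' @param spec A [phase_stimulus_spec()].
#' @return A list of class `dichoptic_pair` with `left` (dominant eye) and
#'   `right` (nondominant eye) luminance matrices in `[0, 2]` around a mean
#'   of 1 (relative luminance units).
#' @export
make_phase_gratings <- function(spec) {
  stopifnot(inherits(spec, "phase_stimulus_spec"))
  npx <- round(spec$extent_deg * spec$pixels_per_degree)
  y <- (seq_len(npx) - (npx + 1) / 2) / spec$pixels_per_degree
  sgn <- if (spec$configuration == 1) 1 else -1
  th <- sgn * spec$theta0 * pi / 180
  lum <- function(contrast, phase)
    matrix(1 + contrast * sin(2 * pi * spec$grating_sf * y + phase),
           npx, npx)  # horizontal grating: luminance varies with row only
  structure(list(left = lum(spec$contrast_ratio, th),
                 right = lum(1, -th),
                 spec = spec), class = "dichoptic_pair")
}

#' Export a dichoptic pair as portable greymaps with a metadata sidecar
#'
#' Writes `<stem>_left.pgm` and `<stem>_right.pgm` (binary 8-bit PGM, the
#' range `[-3, 3]` mapped affinely onto 0..255 and clipped) plus
#' `<stem>.json` holding the full spec.
#'
#' @param pair A `dichoptic_pair`.
#' @param stem Output path stem (no extension).
#' @param range Numeric range mapped onto the grey levels.
#' @return Invisibly, the paths written.
#' @export
write_dichoptic_pair <- function(pair, stem, range = c(-3, 3)) {
  stopifnot(inherits(pair, "dichoptic_pair"))
  to8 <- function(img) {
    g <- round(255 * (img - range[1]) / (range[2] - range[1]))
    matrix(as.integer(pmin(pmax(g, 0), 255)), nrow(img), ncol(img))
  }
  paths <- c(left = paste0(stem, "_left.pgm"),
             right = paste0(stem, "_right.pgm"),
             meta = paste0(stem, ".json"))
  write_pgm(to8(pair$left), paths[["left"]])
  write_pgm(to8(pair$right), paths[["right"]])
  meta <- pair$spec
  class(meta) <- NULL
  jsonlite::write_json(list(spec = meta, grey_range = range),
                       paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), "255"), con)
  writeBin(as.raw(t(img)), con)
}

#' Display a dichoptic pair side by side
#'
#' @param object A `dichoptic_pair`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dichoptic_pair <- function(object, ...) {
  df <- purrr::map_dfr(c("left", "right"), function(eye) {
    img <- object[[eye]]
    tibble::tibble(eye = eye,
                   x = rep(seq_len(ncol(img)), each = nrow(img)),
                   y = rep(rev(seq_len(nrow(img))), ncol(img)),
                   value = as.vector(img))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~eye) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}
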