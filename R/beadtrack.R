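# Defocusing-microscopy z-tracking: a defocused fluorescent bead images as
# concentric rings whose outer radius reports the bead's distance to the
# focal plane. The tracker extracts a sub-pixel outer-ring radius from a
# diametric intensity profile and converts radius changes to z via a
# piezo-step calibration.

#' Synthesize a concentric-ring bead image
#'
#' Parametric fixture for the ring tracker: a sum of Gaussian annuli of
#' decreasing amplitude about a common centre, plus background and
#' optional Gaussian or Poisson noise. The ground truth is stored
#' alongside (never inside) the pixel data.
#'
#' @param outer_radius Outer ring radius, px (>= 3 x `width`).
#' @param seed RNG seed (mandatory when noise > 0).
#' @param n_rings Number of rings.
#' @param width Gaussian ring width (sd), px.
#' @param contrast Amplitude of the outer ring above background.
#' @param noise_sd Noise level: sd of additive Gaussian noise (or, for
#'   `noise = "poisson"`, the image is Poisson-resampled).
#' @param size Frame side, px (default: fits the outer ring plus margin).
#' @param centre Ring centre `c(x, y)` in px (default: frame centre).
#' @param background Background intensity.
#' @param noise `"gaussian"` or `"poisson"`.
#' @param pixel_size_um Physical pixel size, um/px.
#' @return A list of class `ring_image`: `image` (matrix, rows = y),
#'   `pixel_size_um`, and `truth` (centre, radius, width, contrast,
#'   noise_sd).
#' @export
synthesize_ring_image <- function(outer_radius, seed = NULL, n_rings = 3,
                                  width = 2, contrast = 100, noise_sd = 0,
                                  size = NULL, centre = NULL,
                                  background = 10,
                                  noise = c("gaussian", "poisson"),
                                  pixel_size_um = 0.1) {
  noise <- match.arg(noise)
  if (outer_radius < 3 * width)
    abort("Outer radius must be at least 3 ring widths.")
  if (is.null(size)) size <- 2L * ceiling(outer_radius + 5 * width) + 1L
  if (is.null(centre)) centre <- c((size + 1) / 2, (size + 1) / 2)
  if (outer_radius + 3 * width > min(centre[1], centre[2],
                                     size - centre[1], size - centre[2]) + 1)
    abort("Outer ring does not fit inside the frame.")
  spacing <- max(5 * width, outer_radius / (n_rings + 0.5))
  radii <- outer_radius - (seq_len(n_rings) - 1L) * spacing
  radii <- radii[radii > width]
  amps <- contrast * 0.75^(seq_along(radii) - 1L)
  x <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  rho <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
  img <- matrix(background, size, size)
  for (j in seq_along(radii))
    img <- img + amps[j] * exp(-(rho - radii[j])^2 / (2 * width^2))
  if (noise_sd > 0 || noise == "poisson") {
    if (is.null(seed)) abort("`seed` is mandatory when noise is requested.")
    img <- with_seed(seed, {
      if (noise == "gaussian")
        img + matrix(rnorm(length(img), sd = noise_sd), size, size)
      else matrix(stats::rpois(length(img), pmax(img, 0)), size, size)
    })
  }
  structure(list(image = img, pixel_size_um = pixel_size_um,
                 truth = list(centre = centre, outer_radius = outer_radius,
                              width = width, contrast = contrast,
                              noise_sd = noise_sd, radii = radii)),
            class = "ring_image")
}

#' @export
print.ring_image <- function(x, ...) {
  cat(sprintf("<ring_image> %d x %d px, outer radius %.2f px (truth)\n",
              nrow(x$image), ncol(x$image),
              x$truth$outer_radius %||% NA_real_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# intensity-weighted centroid, a fallback centre estimate
intensity_centroid <- function(img) {
  w <- img - min(img)
  tot <- sum(w)
  xs <- seq_len(ncol(img)); ys <- seq_len(nrow(img))
  c(sum(colSums(w) * xs) / tot, sum(rowSums(w) * ys) / tot)
}

# Gaussian-plus-linear-baseline fit around one profile peak; the linear
# term absorbs the sloping tail of the neighbouring ring so the fitted
# centre stays unbiased. Returns the sub-pixel centre position.
fit_profile_peak <- function(pos, val, peak_idx, halfwin) {
  sel <- abs(pos - pos[peak_idx]) <= halfwin
  dat <- data.frame(x = pos[sel] - pos[peak_idx], y = val[sel])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b0 + b1 * x + A * exp(-(x - m)^2 / (2 * s^2)),
                      data = dat,
                      start = list(b0 = min(dat$y), b1 = 0,
                                   A = max(dat$y) - min(dat$y),
                                   m = 0, s = max(halfwin / 3, 1)),
                      lower = c(-Inf, -Inf, 0, min(dat$x), 0.3),
                      upper = c(Inf, Inf, Inf, max(dat$x), 4 * halfwin),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["m", "Std. Error"],
                 error = function(e) NA_real_)
  list(centre = unname(co["m"]) + pos[peak_idx], se = se)
}

#' Outer ring radius from a diametric intensity profile
#'
#' Extracts a horizontal line intensity profile through the ring centre
#' (averaged over a band of rows to reduce noise), locates the first and
#' last peaks above the noise floor, fits a Gaussian to each, and returns
#' half the distance between the two fitted peak centres. Sub-pixel
#' output; invariant to global intensity scaling and offset.
#'
#' @param image A `ring_image` or plain intensity matrix.
#' @param centre Ring centre `c(x, y)`, px; defaults to the stored truth
#'   centre for synthetic images, else the intensity centroid.
#' @param band Width of the averaging band, px (odd).
#' @param peak_halfwin Half-window for each Gaussian peak fit, px.
#' @return A one-row tibble: `radius_px`, `se_px`, `centre_x`, `centre_y`.
#'   Detection failure (no ring above the noise floor) is an error of
#'   class `poroflow_no_rings`, never a silent zero.
#' @export
outer_ring_radius <- function(image, centre = NULL, band = 3,
                              peak_halfwin = NULL) {
  img <- if (inherits(image, "ring_image")) image$image else image
  if (is.null(centre))
    centre <- if (inherits(image, "ring_image") && !is.null(image$truth$centre))
      image$truth$centre else intensity_centroid(img)
  if (centre[1] < 1 || centre[1] > ncol(img) ||
      centre[2] < 1 || centre[2] > nrow(img))
    abort("`centre` lies outside the frame.")
  width_guess <- if (inherits(image, "ring_image") &&
                     !is.null(image$truth$width)) image$truth$width else 2
  if (is.null(peak_halfwin)) peak_halfwin <- max(4, 2.5 * width_guess)

  rows <- round(centre[2]) + seq(-(band %/% 2), band %/% 2)
  rows <- rows[rows >= 1 & rows <= nrow(img)]
  prof <- colMeans(img[rows, , drop = FALSE])
  pos <- seq_along(prof) - centre[1]

  # noise floor: background level (low quantile of the profile) plus the
  # larger of a prominence fraction and a few noise sds (noise estimated
  # from the first difference); invariant to intensity scale and offset
  bg <- unname(stats::quantile(prof, 0.2))
  sd_noise <- stats::mad(diff(prof)) / sqrt(2)
  floor_lvl <- bg + max(0.25 * (max(prof) - bg), 5 * sd_noise)
  peaks <- which(diff(sign(diff(prof))) == -2) + 1L
  peaks <- peaks[prof[peaks] > floor_lvl]
  # need peaks on both sides of the centre
  left <- peaks[pos[peaks] < 0]; right <- peaks[pos[peaks] > 0]
  if (length(left) == 0L || length(right) == 0L)
    abort("No ring peaks above the noise floor.", class = "poroflow_no_rings")
  first_pk <- left[which.min(pos[left])]    # outermost on the left
  last_pk <- right[which.max(pos[right])]   # outermost on the right
  # keep the neighbouring (above-floor) ring out of each fit window
  gap_of <- function(pk) {
    gaps <- abs(pos[setdiff(peaks, pk)] - pos[pk])
    if (length(gaps) == 0L) peak_halfwin else 0.6 * min(gaps)
  }
  f1 <- fit_profile_peak(pos, prof, first_pk,
                         max(2.5, min(peak_halfwin, gap_of(first_pk))))
  f2 <- fit_profile_peak(pos, prof, last_pk,
                         max(2.5, min(peak_halfwin, gap_of(last_pk))))
  if (is.null(f1) || is.null(f2))
    abort("Peak fit failed.", class = "poroflow_no_rings")
  radius <- (f2$centre - f1$centre) / 2
  tibble(radius_px = radius,
         se_px = sqrt(mean(c(f1$se, f2$se)^2, na.rm = TRUE)) / sqrt(2),
         centre_x = centre[1], centre_y = centre[2])
}

#' Calibrate ring radius against z position
#'
#' Least-squares linear map from outer-ring radius (px) to bead z (um),
#' from a piezo-stage staircase of known z steps. The radius-defocus
#' relation is taken as locally linear over the calibrated range.
#'
#' @param radii_px Measured outer-ring radii, px.
#' @param z_um Known stage z positions, um (strictly monotone, >= 3).
#' @return A list of class `ring_calibration`: `slope_um_px`,
#'   `intercept_um`, `r_squared`, `n`.
#' @export
calibrate <- function(radii_px, z_um) {
  if (length(radii_px) != length(z_um) || length(z_um) < 3L)
    abort("Need at least 3 paired (radius, z) points.")
  dz <- diff(z_um)
  if (!(all(dz > 0) || all(dz < 0)))
    abort("`z_um` must be strictly monotone.")
  if (sd(radii_px) == 0)
    abort("Degenerate calibration: radius does not vary.")
  fit <- lm(z_um ~ radii_px)
  sl <- unname(coef(fit)[2])
  if (sl == 0) abort("Degenerate calibration: zero slope.")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact staircases fit perfectly
  structure(list(slope_um_px = sl, intercept_um = unname(coef(fit)[1]),
                 r_squared = r2, n = length(z_um)),
            class = "ring_calibration")
}

#' @export
print.ring_calibration <- function(x, ...) {
  cat(sprintf("<ring_calibration> z = %.4g * r + %.4g um (r^2 = %.4f, n = %d)\n",
              x$slope_um_px, x$intercept_um, x$r_squared, x$n))
  invisible(x)
}

#' Track a defocused-bead image stack into a z-displacement trace
#'
#' Applies [outer_ring_radius()] frame by frame, converts radii to z via a
#' [calibrate()]d linear map, and subtracts the first valid frame as
#' baseline. Frames whose ring detection fails are carried as `NA` gaps,
#' never interpolated; more than 50% failed frames aborts the stack.
#'
#' @param images List of `ring_image`s / matrices, or a 3D array
#'   (y, x, frame).
#' @param calibration A `ring_calibration`.
#' @param centre Ring centre `c(x, y)`, px (shared across frames;
#'   default: per-frame truth/centroid).
#' @param dt Frame interval, s.
#' @param times Optional explicit frame times, s (overrides `dt`).
#' @return A bead-trace tibble: `t_s`, `z_um` (baseline-subtracted),
#'   `radius_px`, `gap`.
#' @export
track_stack <- function(images, calibration, centre = NULL, dt = 0.1,
                        times = NULL) {
  stopifnot(inherits(calibration, "ring_calibration"))
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  if (length(images) == 0L) abort("Empty stack.")
  radii <- vapply(images, function(im) {
    tryCatch(outer_ring_radius(im, centre = centre)$radius_px,
             poroflow_no_rings = function(e) NA_real_)
  }, numeric(1))
  if (mean(is.na(radii)) > 0.5)
    abort("Ring detection failed on more than half of the frames.")
  z <- calibration$slope_um_px * radii + calibration$intercept_um
  z0 <- z[which(!is.na(z))[1]]
  if (is.null(times)) times <- (seq_along(radii) - 1L) * dt
  tibble(t_s = times, z_um = z - z0, radius_px = radii, gap = is.na(radii))
}

#' Synthesize a defocused-bead image stack from a known z trajectory
#'
#' Inverse of the tracking pipeline: given z(t) and a calibration, builds
#' one ring image per frame with radius \eqn{(z - b)/m}.
#'
#' @param z_um z positions per frame, um.
#' @param calibration A `ring_calibration`.
#' @param seed RNG seed (mandatory when noise is requested).
#' @param noise_sd Per-frame Gaussian noise level.
#' @param ... Further arguments to [synthesize_ring_image()].
#' @return List of `ring_image`s.
#' @export
gen_ring_stack <- function(z_um, calibration, seed = NULL, noise_sd = 0, ...) {
  stopifnot(inherits(calibration, "ring_calibration"))
  radii <- (z_um - calibration$intercept_um) / calibration$slope_um_px
  if (any(radii <= 0)) abort("Trajectory maps to non-positive radii.")
  lapply(seq_along(radii), function(i) {
    synthesize_ring_image(radii[i],
                          seed = if (!is.null(seed)) seed + i else NULL,
                          noise_sd = noise_sd, ...)
  })
}

#' Read a TIFF stack into a list of intensity matrices
#'
#' @param path TIFF file path.
#' @return List of numeric matrices.
#' @export
read_ring_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("Package 'tiff' is required to read TIFF stacks.")
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(im) if (length(dim(im)) == 3L) im[, , 1] else im)
}
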