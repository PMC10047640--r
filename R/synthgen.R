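## Synthetic MRI-like phantoms: smooth anatomical background, lesion blobs
## with soft (logistic) edges, Rician magnitude noise, and slice stacks in
## which only a fraction of slices carry a lesion.

#' Generate a synthetic MRI-like phantom slice
#'
#' Builds a noise-free grayscale slice consisting of a smooth anatomical
#' background (a constant offset plus 2--4 broad Gaussian bumps) and zero or
#' more lesion blobs with smoothly decaying edges, together with the binary
#' ground-truth mask. The blob profile is a radial logistic kernel
#' \eqn{k(r) = 1/(1+\exp((r-R)/s))}; the mask thresholds the pre-noise kernel
#' at half peak, so the mask is exactly the disk of radius \eqn{R} and its
#' area is close to \eqn{\pi R^2}.
#'
#' @param shape integer vector `(rows, cols)`, at least 32 x 32.
#' @param lesion_spec list with elements `count` (number of blobs),
#'   `radius` (length-2 range of blob radii in pixels), `contrast`
#'   (intensity difference between blob core and local background) and
#'   `softness` (logistic edge width in pixels).
#' @param seed integer; the phantom is a pure function of its arguments.
#' @param polarity `"dark"` (lesion darker than background, the default,
#'   matching the screening filter's literal decision rule) or `"bright"`.
#' @param background baseline background intensity on the `[0, 255]` scale.
#' @return an object of class `"phantom"`: a list with `clean` (numeric
#'   matrix in `[0, 255]`), `mask` (0/1 integer matrix), `label`
#'   (`"lesion"` or `"normal"`) and `seed`.
#' @examples
#' ph <- make_phantom(c(64, 64), list(count = 1, radius = c(8, 8),
#'                    contrast = 100, softness = 2), seed = 1)
#' sum(ph$mask)  # close to pi * 8^2
#' @export
make_phantom <- function(shape = c(224L, 224L),
                         lesion_spec = list(count = 1L, radius = c(8, 20),
                                            contrast = 100, softness = 2),
                         seed = 1L,
                         polarity = c("dark", "bright"),
                         background = 150) {
  polarity <- match.arg(polarity)
  if (length(shape) != 2L || any(shape < 32L)) {
    stop("shape must be at least 32 x 32")
  }
  spec <- lesion_spec
  if (is.null(spec$count)) spec$count <- 1L
  if (is.null(spec$radius)) spec$radius <- c(8, 20)
  if (length(spec$radius) == 1L) spec$radius <- rep(spec$radius, 2L)
  if (is.null(spec$contrast)) spec$contrast <- 100
  if (is.null(spec$softness)) spec$softness <- 2
  margin <- max(spec$radius) + 3 * spec$softness
  if (spec$count > 0L && 2 * margin >= min(shape)) {
    stop("lesion of radius ", max(spec$radius), " does not fit in a ",
         shape[1], " x ", shape[2], " image")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  H <- shape[1]; W <- shape[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)

  ## smooth background: offset + 2-4 broad Gaussian bumps
  img <- matrix(background, H, W)
  for (b in seq_len(sample(2:4, 1L))) {
    amp <- stats::runif(1, -30, 30)
    cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
    wdt <- stats::runif(1, 0.2, 0.4) * min(H, W)
    img <- img + amp * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * wdt^2))
  }

  mask <- matrix(0L, H, W)
  sgn <- if (polarity == "dark") -1 else 1
  if (spec$count > 0L) {
    for (k in seq_len(spec$count)) {
      R <- stats::runif(1, spec$radius[1], spec$radius[2])
      cy <- stats::runif(1, margin + 1, H - margin)
      cx <- stats::runif(1, margin + 1, W - margin)
      r <- sqrt((rr - cy)^2 + (cc - cx)^2)
      kern <- 1 / (1 + exp((r - R) / spec$softness))
      img <- img + sgn * spec$contrast * kern
      mask[kern > 0.5] <- 1L
    }
  }
  img <- pmin(pmax(img, 0), 255)

  structure(list(clean = img, mask = mask,
                 label = if (spec$count > 0L) "lesion" else "normal",
                 seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom %dx%d, label=%s, mask area=%d px, seed=%d\n",
              nrow(x$clean), ncol(x$clean), x$label, sum(x$mask),
              x$seed))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Add Rician magnitude noise to a noise-free image
#'
#' MR magnitude images are formed from complex data whose real and
#' imaginary channels carry independent zero-mean Gaussian noise:
#' \eqn{X = |S e^{i\theta} + \eta_1 + i \eta_2|} with
#' \eqn{\eta_1, \eta_2 \sim N(0, \sigma^2)}. The resulting magnitude is
#' Rician distributed and biased upward, with
#' \eqn{E[X^2] = S^2 + 2\sigma^2}.
#'
#' @param clean numeric matrix of noise-free intensities `S` (nonnegative).
#' @param sigma per-channel Gaussian standard deviation, `>= 0`.
#' @param theta phase in radians, a scalar or a matrix the shape of
#'   `clean`; the magnitude is invariant to it (default 0).
#' @param seed integer seed; output is deterministic per seed.
#' @return numeric matrix of noisy magnitudes, same shape as `clean`.
#' @export
add_rician_noise <- function(clean, sigma, theta = 0, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(clean)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(clean)
  eta1 <- matrix(stats::rnorm(n, 0, sigma), nrow(clean), ncol(clean))
  eta2 <- matrix(stats::rnorm(n, 0, sigma), nrow(clean), ncol(clean))
  sqrt((clean * cos(theta) + eta1)^2 + (clean * sin(theta) + eta2)^2)
}

#' Rician probability density
#'
#' Density of the magnitude \eqn{X} of complex data with underlying signal
#' `S` and per-channel noise std `sigma`:
#' \deqn{p(x \mid S, \sigma) = \frac{x}{\sigma^2}
#'   e^{-(x^2+S^2)/(2\sigma^2)} I_0\!\left(\frac{xS}{\sigma^2}\right)}
#' computed with the exponentially scaled Bessel function for stability.
#'
#' @param x vector of nonnegative magnitudes.
#' @param S underlying noise-free signal (scalar).
#' @param sigma per-channel noise std, `> 0`.
#' @return density values.
#' @export
drician <- function(x, S, sigma) {
  stopifnot(sigma > 0, S >= 0)
  out <- numeric(length(x))
  ok <- x >= 0
  xi <- x[ok]
  out[ok] <- xi / sigma^2 * exp(-(xi - S)^2 / (2 * sigma^2)) *
    besselI(xi * S / sigma^2, 0, expon.scaled = TRUE)
  out
}

#' Generate a stack of phantom slices
#'
#' Emulates a clinical slice series in which only a small fraction of
#' slices contains a lesion: each slice is independently lesion-bearing
#' with probability `lesion_fraction`.
#'
#' @param n_slices number of slices, `> 0`.
#' @param lesion_fraction probability in `[0, 1]` that a slice carries a
#'   lesion.
#' @param shape slice shape `(rows, cols)`.
#' @param seed integer master seed; slice seeds are derived from it.
#' @param lesion_spec lesion specification passed to [make_phantom()] for
#'   lesion-bearing slices (its `count` is forced to `>= 1`).
#' @param ... further arguments passed to [make_phantom()].
#' @return object of class `"slice_stack"`: list with `slices` (list of
#'   phantoms), `lesion_fraction` and `seed`.
#' @export
make_stack <- function(n_slices, lesion_fraction, shape = c(64L, 64L),
                       seed = 1L,
                       lesion_spec = list(count = 1L, radius = c(8, 14),
                                          contrast = 100, softness = 2),
                       ...) {
  if (n_slices <= 0L) stop("n_slices must be positive")
  stopifnot(lesion_fraction >= 0, lesion_fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  has_lesion <- stats::rbinom(n_slices, 1L, lesion_fraction) == 1L
  sub_seeds <- sample.int(.Machine$integer.max, n_slices)
  slices <- vector("list", n_slices)
  normal_spec <- lesion_spec
  normal_spec$count <- 0L
  if (is.null(lesion_spec$count) || lesion_spec$count < 1L) {
    lesion_spec$count <- 1L
  }
  for (i in seq_len(n_slices)) {
    spec <- if (has_lesion[i]) lesion_spec else normal_spec
    slices[[i]] <- make_phantom(shape, spec, seed = sub_seeds[i], ...)
  }
  structure(list(slices = slices, lesion_fraction = lesion_fraction,
                 seed = seed),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  labs <- vapply(x$slices, `[[`, "", "label")
  cat(sprintf("slice stack: %d slices, %d lesion (target fraction %.3f)\n",
              length(x$slices), sum(labs == "lesion"), x$lesion_fraction))
  invisible(x)
}

#' Read a grayscale image file
#'
#' Reads an 8- or 16-bit PNG or TIFF file and returns intensities on the
#' `[0, 255]` scale (16-bit content keeps its sub-integer resolution).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix of intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * 255
}

#' Write a grayscale image file
#'
#' Intensities on the `[0, 255]` scale are quantized on export: 8-bit PNG
#' for `depth = 8`, 16-bit TIFF for `depth = 16` (preserving sub-integer
#' resolution, used for noisy magnitudes).
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param path output path; extension should match `depth` (`.png` or
#'   `.tif`).
#' @param depth 8 or 16 bits per sample.
#' @export
write_gray_image <- function(img, path, depth = 8L) {
  x <- pmin(pmax(img / 255, 0), 1)
  if (depth == 8L) {
    png::writePNG(x, path)
  } else if (depth == 16L) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("writing 16-bit images requires the 'tiff' package")
    }
    tiff::writeTIFF(x, path, bits.per.sample = 16L)
  } else {
    stop("depth must be 8 or 16")
  }
  invisible(path)
}

#' Write a phantom dataset to disk
#'
#' Writes each slice's noisy image (16-bit TIFF), clean image and mask
#' (8-bit PNG) plus a plain-text manifest recording filename, label, seed
#' and noise level.
#'
#' @param stack a `"slice_stack"` (or plain list of phantoms).
#' @param dir output directory (created if missing).
#' @param sigma Rician noise std applied to each clean slice.
#' @return path of the manifest file, invisibly.
#' @export
write_phantom_dataset <- function(stack, dir, sigma = 20) {
  slices <- if (inherits(stack, "slice_stack")) stack$slices else stack
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    ph <- slices[[i]]
    base <- sprintf("slice_%04d", i)
    noisy <- add_rician_noise(ph$clean, sigma, seed = ph$seed)
    write_gray_image(noisy, file.path(dir, paste0(base, "_noisy.tif")), 16L)
    write_gray_image(ph$clean, file.path(dir, paste0(base, "_clean.png")), 8L)
    write_gray_image(ph$mask * 255, file.path(dir, paste0(base, "_mask.png")),
                     8L)
    rows[[i]] <- data.frame(file = paste0(base, "_noisy.tif"),
                            label = ph$label, seed = ph$seed, sigma = sigma)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
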