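## Pixel-wise non-local means (NLM) denoising. The naive implementation
## enumerates patch distances directly; the fast implementation evaluates
## every translation's patch-distance field as a single FFT convolution of
## the pointwise squared-difference field with the (flipped) patch kernel.
## Rician bias in MR magnitude images is handled by denoising the squared
## magnitudes and subtracting the 2*sigma^2 bias before taking the root.

#' Non-local-means configuration
#'
#' @param h filtering parameter (intensity units); weights are
#'   `exp(-p / h^2)` for a kernel-weighted squared patch distance `p`.
#'   `NULL` defaults to `0.75 * sigma * c` (patch side `c = 2*ds+1`)
#'   when `sigma > 0`.
#' @param patch_radius patch half side `ds >= 1` (patch side
#'   `c = 2*ds + 1`).
#' @param search_radius search-window half side `Cs >= 1`; candidate
#'   translations are `t` with max-norm at most `Cs`.
#' @param kernel `"uniform"` (default), `"gaussian"`, or an explicit
#'   nonnegative `c x c` matrix summing to 1.
#' @param sigma Rician noise std; `> 0` enables [rician_correct()] and
#'   the default `h`.
#' @param self_weight `"literal"` includes the central pixel with
#'   distance 0 (weight `1/Z`); `"max_neighbor"` replaces the self
#'   weight with the maximum neighbour weight.
#' @return list of class `"nlm_config"`.
#' @export
nlm_config <- function(h = NULL, patch_radius = 2L, search_radius = 5L,
                       kernel = "uniform", sigma = 0,
                       self_weight = c("literal", "max_neighbor")) {
  self_weight <- match.arg(self_weight)
  ds <- as.integer(patch_radius); Cs <- as.integer(search_radius)
  if (ds < 1L || Cs < 1L) stop("patch_radius and search_radius must be >= 1")
  cside <- 2L * ds + 1L
  K <- if (is.matrix(kernel)) {
    kernel
  } else if (identical(kernel, "uniform")) {
    matrix(1 / cside^2, cside, cside)
  } else if (identical(kernel, "gaussian")) {
    u <- seq(-ds, ds)
    g <- exp(-outer(u^2, u^2, "+") / (2 * max(ds / 2, 0.5)^2))
    g / sum(g)
  } else stop("unknown kernel")
  if (!all(dim(K) == cside) || any(K < 0) ||
      abs(sum(K) - 1) > 1e-12) {
    stop("kernel must be a nonnegative ", cside, " x ", cside,
         " matrix summing to 1")
  }
  if (!is.null(h) && h <= 0) stop("h must be positive")
  structure(list(h = h, patch_radius = ds, search_radius = Cs,
                 kernel = K, sigma = sigma, self_weight = self_weight),
            class = "nlm_config")
}

.nlm_h <- function(cfg) {
  if (!is.null(cfg$h)) return(cfg$h)
  if (cfg$sigma > 0) return(0.75 * cfg$sigma * (2 * cfg$patch_radius + 1))
  stop("h not set and sigma unknown: supply h in nlm_config()")
}

## reflect (symmetric) padding by r on all sides
pad_reflect <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  stopifnot(r <= n, r <= m)
  ri <- c(r:1, 1:n, n:(n - r + 1L))
  ci <- c(r:1, 1:m, m:(m - r + 1L))
  x[ri, ci]
}

#' Naive non-local means
#'
#' Direct evaluation of the NLM average: each output pixel is the
#' weight-normalized average of the intensities in its search window,
#' with weights `exp(-p / h^2)` for the kernel-weighted squared Euclidean
#' distance `p` between the surrounding patches. Reflect padding by
#' `ds + Cs` handles the borders.
#'
#' @param image numeric matrix, larger than the patch.
#' @param cfg an [nlm_config()].
#' @return denoised matrix of the same shape.
#' @export
nlm_naive <- function(image, cfg = nlm_config(h = 10)) {
  ds <- cfg$patch_radius; Cs <- cfg$search_radius
  h <- .nlm_h(cfg)
  K <- cfg$kernel
  R <- ds + Cs
  H <- nrow(image); W <- ncol(image)
  if (H <= 2 * ds || W <= 2 * ds) stop("image smaller than patch")
  v <- pad_reflect(image, R)
  out <- matrix(0, H, W)
  ts <- expand.grid(t1 = -Cs:Cs, t2 = -Cs:Cs)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      pi <- i + R; pj <- j + R
      P0 <- v[(pi - ds):(pi + ds), (pj - ds):(pj + ds)]
      w <- numeric(nrow(ts)); val <- numeric(nrow(ts))
      for (k in seq_len(nrow(ts))) {
        t1 <- ts$t1[k]; t2 <- ts$t2[k]
        Pt <- v[(pi + t1 - ds):(pi + t1 + ds),
                (pj + t2 - ds):(pj + t2 + ds)]
        p <- sum(K * (P0 - Pt)^2)
        w[k] <- exp(-p / h^2)
        val[k] <- v[pi + t1, pj + t2]
      }
      if (cfg$self_weight == "max_neighbor") {
        self <- which(ts$t1 == 0L & ts$t2 == 0L)
        w[self] <- max(w[-self])
      }
      out[i, j] <- sum(w * val) / sum(w)
    }
  }
  out
}

#' Normalized NLM weights at one pixel
#'
#' Exposes the per-translation weights the NLM average uses at a single
#' pixel (for inspection and testing of the normalization property).
#'
#' @param image numeric matrix.
#' @param cfg an [nlm_config()].
#' @param pixel `(row, col)` of the target pixel.
#' @return `(2Cs+1) x (2Cs+1)` matrix of weights summing to 1, indexed
#'   by translation.
#' @export
nlm_weights <- function(image, cfg, pixel) {
  ds <- cfg$patch_radius; Cs <- cfg$search_radius
  h <- .nlm_h(cfg)
  K <- cfg$kernel
  R <- ds + Cs
  v <- pad_reflect(image, R)
  pi <- pixel[1] + R; pj <- pixel[2] + R
  P0 <- v[(pi - ds):(pi + ds), (pj - ds):(pj + ds)]
  w <- matrix(0, 2 * Cs + 1, 2 * Cs + 1)
  for (t1 in -Cs:Cs) {
    for (t2 in -Cs:Cs) {
      Pt <- v[(pi + t1 - ds):(pi + t1 + ds),
              (pj + t2 - ds):(pj + t2 + ds)]
      w[t1 + Cs + 1, t2 + Cs + 1] <- exp(-sum(K * (P0 - Pt)^2) / h^2)
    }
  }
  if (cfg$self_weight == "max_neighbor") {
    w[Cs + 1, Cs + 1] <- max(w[-((Cs) * (2 * Cs + 1) + Cs + 1)])
  }
  w / sum(w)
}

## linear 'same' convolution of the flipped kernel with a field, via FFT
.conv_same_fft <- function(FKt, s, cside, ds, Pr, Pc) {
  sp <- matrix(0, Pr, Pc)
  sp[seq_len(nrow(s)), seq_len(ncol(s))] <- s
  full <- Re(stats::fft(FKt * stats::fft(sp), inverse = TRUE)) / (Pr * Pc)
  full[(ds + 1):(ds + nrow(s)), (ds + 1):(ds + ncol(s))]
}

#' Per-translation patch distance field
#'
#' For a translation `t`, the kernel-weighted squared patch distance at
#' every pixel equals the discrete convolution of the flipped kernel with
#' the pointwise squared-difference field
#' \eqn{s_t(i) = (v_i - v_{i+t})^2}; this computes it with an FFT.
#'
#' @param image numeric matrix.
#' @param t integer translation `(dr, dc)`.
#' @param patch_radius patch half side `ds`.
#' @param kernel optional explicit patch kernel (defaults to uniform).
#' @return numeric matrix of nonnegative distances, one per pixel.
#' @export
patch_distance_field <- function(image, t, patch_radius = 2L,
                                 kernel = NULL) {
  ds <- as.integer(patch_radius)
  cside <- 2L * ds + 1L
  if (is.null(kernel)) kernel <- matrix(1 / cside^2, cside, cside)
  R <- ds + max(abs(t), 1L)
  v <- pad_reflect(image, R)
  nr <- nrow(v); nc <- ncol(v)
  st <- matrix(0, nr, nc)
  r1 <- max(1L, 1L - t[1]); r2 <- min(nr, nr - t[1])
  c1 <- max(1L, 1L - t[2]); c2 <- min(nc, nc - t[2])
  st[r1:r2, c1:c2] <- (v[r1:r2, c1:c2] -
                         v[(r1 + t[1]):(r2 + t[1]),
                           (c1 + t[2]):(c2 + t[2])])^2
  Kt <- kernel[cside:1, cside:1]
  Pr <- nr + cside - 1L; Pc <- nc + cside - 1L
  Kp <- matrix(0, Pr, Pc)
  Kp[seq_len(cside), seq_len(cside)] <- Kt
  dist_pad <- .conv_same_fft(stats::fft(Kp), st, cside, ds, Pr, Pc)
  pmax(dist_pad[(R + 1):(R + nrow(image)), (R + 1):(R + ncol(image))], 0)
}

#' FFT-accelerated non-local means
#'
#' Identical contract to [nlm_naive()]: for each translation in the
#' search window the patch-distance field is evaluated as a single
#' zero-padded (linear) FFT convolution, and the per-pixel weights and
#' accumulators are formed per translation. Complexity drops from
#' `O(N D^2 c^2)` to `O(N D^2 log N)` for `N` pixels, `D = 2Cs+1`.
#'
#' @inheritParams nlm_naive
#' @return denoised matrix of the same shape.
#' @export
nlm_fft <- function(image, cfg = nlm_config(h = 10)) {
  ds <- cfg$patch_radius; Cs <- cfg$search_radius
  h <- .nlm_h(cfg)
  K <- cfg$kernel
  cside <- 2L * ds + 1L
  R <- ds + Cs
  H <- nrow(image); W <- ncol(image)
  if (H <= 2 * ds || W <= 2 * ds) stop("image smaller than patch")
  v <- pad_reflect(image, R)
  nr <- nrow(v); nc <- ncol(v)
  Pr <- nr + cside - 1L; Pc <- nc + cside - 1L
  Kt <- K[cside:1, cside:1]
  Kp <- matrix(0, Pr, Pc)
  Kp[seq_len(cside), seq_len(cside)] <- Kt
  FKt <- stats::fft(Kp)

  num <- matrix(0, H, W); den <- matrix(0, H, W)
  wmax <- matrix(0, H, W)
  orow <- (R + 1):(R + H); ocol <- (R + 1):(R + W)
  for (t1 in -Cs:Cs) {
    for (t2 in -Cs:Cs) {
      if (t1 == 0L && t2 == 0L) next
      st <- matrix(0, nr, nc)
      r1 <- max(1L, 1L - t1); r2 <- min(nr, nr - t1)
      c1 <- max(1L, 1L - t2); c2 <- min(nc, nc - t2)
      st[r1:r2, c1:c2] <- (v[r1:r2, c1:c2] -
                             v[(r1 + t1):(r2 + t1), (c1 + t2):(c2 + t2)])^2
      dist_pad <- .conv_same_fft(FKt, st, cside, ds, Pr, Pc)
      w <- exp(-pmax(dist_pad[orow, ocol], 0) / h^2)
      num <- num + w * v[orow + t1, ocol + t2]
      den <- den + w
      wmax <- pmax(wmax, w)
    }
  }
  w0 <- if (cfg$self_weight == "literal") 1 else wmax
  num <- num + w0 * v[orow, ocol]
  den <- den + w0
  num / den
}

#' Rician-bias-corrected non-local means
#'
#' The squared magnitude of Rician data satisfies
#' \eqn{E[X^2] = S^2 + 2\sigma^2}: NLM is applied to the squared
#' magnitudes, the `2 sigma^2` bias subtracted, negative values clamped
#' to zero and the square root returned. The default filtering parameter
#' scales with the noise std of the squared intensities,
#' \eqn{2\sigma\sqrt{\hat S^2 + \sigma^2}}.
#'
#' @param noisy noisy magnitude image.
#' @param cfg an [nlm_config()] with `sigma > 0`.
#' @param method `"fft"` (default) or `"naive"`.
#' @return bias-corrected denoised magnitude image.
#' @export
rician_correct <- function(noisy, cfg, method = c("fft", "naive")) {
  method <- match.arg(method)
  if (cfg$sigma <= 0) {
    stop("rician_correct requires sigma > 0; ",
         "use nlm_fft()/nlm_naive() for plain NLM")
  }
  sq <- noisy^2
  if (is.null(cfg$h)) {
    S2hat <- max(mean(sq) - 2 * cfg$sigma^2, 0)
    cfg$h <- 0.75 * (2 * cfg$patch_radius + 1) *
      2 * cfg$sigma * sqrt(S2hat + cfg$sigma^2)
  } else {
    cfg$h <- cfg$h
  }
  den <- if (method == "fft") nlm_fft(sq, cfg) else nlm_naive(sq, cfg)
  sqrt(pmax(den - 2 * cfg$sigma^2, 0))
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(peak^2 / MSE)` in dB, with `peak` the maximum of the
#' reference's dynamic range and MSE the per-pixel mean squared error.
#' A zero-error estimate returns `Inf`.
#'
#' @param estimate,reference numeric matrices of equal shape; the
#'   reference must not be identically zero.
#' @param peak reference peak; defaults to `max(reference)`.
#' @return PSNR in dB.
#' @export
psnr <- function(estimate, reference, peak = NULL) {
  stopifnot(all(dim(estimate) == dim(reference)))
  if (all(reference == 0)) stop("reference is identically zero")
  if (is.null(peak)) peak <- max(reference)
  mse <- mean((estimate - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}
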