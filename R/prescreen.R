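## Threshold Screening Filter (TSF): sliding-window slice pre-screening.
## Each n1 x n1 window is coarse-denoised by transform-domain thresholding,
## then a window fires when its intensity sum falls below the
## 0.5*lambda_T*n1^2 + lambda_T level; a slice is kept ("lesion image")
## when any window fires.

#' Configuration for the threshold screening filter
#'
#' @param n1 window side length in pixels (odd, `>= 3`); default 7.
#' @param lambda_t screening threshold hyperparameter \eqn{\lambda_T};
#'   reasonable values lie in 90--160, default 133.
#' @param lambda_fft fixed threshold multiplier for the coarse
#'   transform-domain denoising, default 0.82.
#' @param sigma noise std estimate used by the coarse denoiser; `NULL`
#'   (default) estimates it from the finest-scale detail coefficients of
#'   the image being screened.
#' @param stride window step in pixels; default `n1` (non-overlapping).
#' @param polarity `"dark_lesion"` (the literal decision rule: fire on
#'   low-intensity windows) or `"bright_lesion"` (negated rule).
#' @param transform `"dct"` (orthonormal type-II DCT, default) or
#'   `"fft"`; coefficients are thresholded by magnitude either way.
#' @param shrinkage `"hard"` (keep coefficients with magnitude at or
#'   above the threshold, default) or `"literal"` (the printed shrinkage
#'   rule, which clips surviving coefficients to the threshold value;
#'   kept for auditability).
#' @return list of class `"prescreen_config"`.
#' @export
prescreen_config <- function(n1 = 7L, lambda_t = 133, lambda_fft = 0.82,
                             sigma = NULL, stride = NULL,
                             polarity = c("dark_lesion", "bright_lesion"),
                             transform = c("dct", "fft"),
                             shrinkage = c("hard", "literal")) {
  polarity <- match.arg(polarity)
  transform <- match.arg(transform)
  shrinkage <- match.arg(shrinkage)
  n1 <- as.integer(n1)
  if (n1 < 3L || n1 %% 2L == 0L) stop("n1 must be odd and >= 3")
  if (lambda_t <= 0) stop("lambda_t must be positive")
  if (is.null(stride)) stride <- n1
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  structure(list(n1 = n1, lambda_t = lambda_t, lambda_fft = lambda_fft,
                 sigma = sigma, stride = stride, polarity = polarity,
                 transform = transform, shrinkage = shrinkage),
            class = "prescreen_config")
}

## orthonormal type-II DCT matrix
dct_matrix <- function(n) {
  D <- matrix(0, n, n)
  for (k in 0:(n - 1)) {
    for (j in 0:(n - 1)) {
      D[k + 1, j + 1] <- cos(pi * (2 * j + 1) * k / (2 * n)) *
        if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    }
  }
  D
}

#' Robust noise-level estimate from finest-scale detail coefficients
#'
#' Median absolute deviation of the diagonal Haar detail band divided by
#' the Gaussian consistency constant 0.6745.
#'
#' @param image numeric matrix.
#' @return estimated noise standard deviation.
#' @export
estimate_noise_sd <- function(image) {
  H <- 2L * (nrow(image) %/% 2L)
  W <- 2L * (ncol(image) %/% 2L)
  x <- image[seq_len(H), seq_len(W), drop = FALSE]
  o <- seq(1L, H, 2L); e <- o + 1L
  oc <- seq(1L, W, 2L); ec <- oc + 1L
  d <- (x[o, oc] - x[o, ec] - x[e, oc] + x[e, ec]) / 2
  stats::median(abs(d)) / 0.6745
}

#' Coarse transform-domain denoising of a window block
#'
#' Forward orthonormal 2-D transform of the `n1 x n1` block, thresholding
#' of coefficient magnitudes at
#' \eqn{\lambda = \lambda_{FFT} \sqrt{2 \sigma^2 \log n_1^2}},
#' inverse transform. With `sigma = 0` the threshold is zero and the block
#' is returned unchanged.
#'
#' @param block numeric `n1 x n1` matrix.
#' @param lambda_fft threshold multiplier.
#' @param sigma noise std (`>= 0`).
#' @param transform,shrinkage see [prescreen_config()].
#' @return denoised real-valued block of the same shape.
#' @export
coarse_denoise_window <- function(block, lambda_fft = 0.82, sigma = 0,
                                  transform = c("dct", "fft"),
                                  shrinkage = c("hard", "literal")) {
  transform <- match.arg(transform)
  shrinkage <- match.arg(shrinkage)
  stopifnot(sigma >= 0, nrow(block) == ncol(block))
  n1 <- nrow(block)
  lam <- lambda_fft * sqrt(2 * sigma^2 * log(n1^2))
  if (transform == "dct") {
    D <- dct_matrix(n1)
    cf <- D %*% block %*% t(D)
    cf <- .shrink(cf, lam, shrinkage)
    Re(t(D) %*% cf %*% D)
  } else {
    cf <- stats::fft(block) / n1  # orthonormal scaling
    keep <- Mod(cf) >= lam
    if (shrinkage == "hard") {
      cf[!keep] <- 0
    } else {
      cf[!keep] <- 0
      cf[keep] <- lam * cf[keep] / Mod(cf)[keep]
    }
    Re(stats::fft(cf, inverse = TRUE) / n1)
  }
}

.shrink <- function(cf, lam, shrinkage) {
  if (shrinkage == "hard") {
    cf[abs(cf) < lam] <- 0
  } else {
    out <- matrix(0, nrow(cf), ncol(cf))
    out[cf >= lam] <- lam
    out[cf <= -lam] <- lam
    cf <- out
  }
  cf
}

#' TSF lesion decision for a single (denoised) window
#'
#' Evaluates the activation of the screening rule
#' \eqn{a = \sum_{ij} \bar B_a(i,j) - 0.5 \lambda_T n_1^2 - \lambda_T}
#' and returns \eqn{k(a) = 1} if \eqn{a < 0}, else 0 (dark-lesion
#' polarity; bright-lesion polarity negates `a` first). Ties
#' (\eqn{a = 0}) decide "no lesion".
#'
#' @param denoised numeric `n1 x n1` window (output of
#'   [coarse_denoise_window()]).
#' @param lambda_t screening threshold.
#' @param polarity `"dark_lesion"` or `"bright_lesion"`.
#' @return integer 0 or 1.
#' @export
tsf_decision <- function(denoised, lambda_t = 133,
                         polarity = c("dark_lesion", "bright_lesion")) {
  polarity <- match.arg(polarity)
  n1 <- nrow(denoised)
  a <- sum(denoised) - 0.5 * lambda_t * n1^2 - lambda_t
  if (polarity == "bright_lesion") a <- -a
  if (a < 0) 1L else 0L
}

#' Screen one slice with the TSF
#'
#' Slides an `n1 x n1` window over the image at the configured stride
#' (edge-aligned tail windows are added so the full image is covered),
#' coarse-denoises each window and applies the decision rule. The slice
#' is labelled `"lesion"` iff any window fires.
#'
#' @param image numeric matrix, at least `n1 x n1`.
#' @param cfg a [prescreen_config()].
#' @return object of class `"screen_result"`: list with `label`,
#'   `flagged_windows` (2-column matrix of firing top-left origins,
#'   possibly 0 rows) and `n_windows`.
#' @export
screen_image <- function(image, cfg = prescreen_config()) {
  n1 <- cfg$n1
  H <- nrow(image); W <- ncol(image)
  if (H < n1 || W < n1) {
    stop("image (", H, " x ", W, ") smaller than screening window ", n1)
  }
  sigma <- if (is.null(cfg$sigma)) estimate_noise_sd(image) else cfg$sigma
  org <- function(n) {
    s <- seq(1L, n - n1 + 1L, cfg$stride)
    if (s[length(s)] != n - n1 + 1L) s <- c(s, n - n1 + 1L)
    s
  }
  rows <- org(H); cols <- org(W)
  flags <- matrix(0L, 0L, 2L)
  for (r in rows) {
    for (cl in cols) {
      blk <- image[r:(r + n1 - 1L), cl:(cl + n1 - 1L)]
      den <- coarse_denoise_window(blk, cfg$lambda_fft, sigma,
                                   transform = cfg$transform,
                                   shrinkage = cfg$shrinkage)
      if (tsf_decision(den, cfg$lambda_t, cfg$polarity) == 1L) {
        flags <- rbind(flags, c(r, cl))
      }
    }
  }
  structure(list(label = if (nrow(flags) > 0L) "lesion" else "normal",
                 flagged_windows = flags,
                 n_windows = length(rows) * length(cols)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("TSF screening: label=%s (%d of %d windows fired)\n",
              x$label, nrow(x$flagged_windows), x$n_windows))
  invisible(x)
}

#' Screen a stack of slices, keeping lesion-labelled ones
#'
#' @param stack a `"slice_stack"`, or a plain list of numeric matrices.
#' @param cfg a [prescreen_config()].
#' @param images optional list of matrices to screen in place of the
#'   stack's clean slices (e.g. their noisy counterparts).
#' @return list with `kept` (the slices labelled lesion, order
#'   preserved), `kept_idx` and `results` (per-slice
#'   `"screen_result"`).
#' @export
screen_stack <- function(stack, cfg = prescreen_config(), images = NULL) {
  slices <- if (inherits(stack, "slice_stack")) stack$slices else stack
  if (length(slices) == 0L) stop("empty stack")
  if (is.null(images)) {
    images <- lapply(slices, function(s) {
      if (is.list(s)) s$clean else s
    })
  }
  results <- lapply(images, screen_image, cfg = cfg)
  keep <- vapply(results, function(r) r$label == "lesion", logical(1))
  list(kept = slices[keep], kept_idx = which(keep), results = results)
}

#' Slice classification accuracy
#'
#' Fraction of slices whose predicted lesion/normal label matches the
#' reference label: `CA = correct / total`.
#'
#' @param predicted,truth equal-length label vectors.
#' @return accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("empty label vectors")
  if (length(predicted) != length(truth)) {
    stop("label vectors differ in length")
  }
  mean(as.character(predicted) == as.character(truth))
}
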