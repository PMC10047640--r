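## Training objective (Dice + boundary loss over a signed distance map)
## and segmentation / classification evaluation metrics.

#' Combined loss configuration
#'
#' @param alpha Dice weight (default 1).
#' @param beta boundary-loss weight (default 0.01).
#' @param beta_ramp optional length-2 vector `c(from, to)`; when supplied
#'   to the trainer, `beta` ramps linearly between the two values across
#'   the epochs.
#' @param normalize_boundary divide the boundary integral by the pixel
#'   count (default `TRUE`), keeping `beta`'s scale image-size invariant.
#' @return list of class `"loss_config"`.
#' @export
loss_config <- function(alpha = 1, beta = 0.01, beta_ramp = NULL,
                        normalize_boundary = TRUE) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta > 0)
  structure(list(alpha = alpha, beta = beta, beta_ramp = beta_ramp,
                 normalize_boundary = normalize_boundary),
            class = "loss_config")
}

#' Soft Dice loss (squared-denominator form)
#'
#' \deqn{L_{Dice} = 1 - \frac{2 \sum PT + \epsilon}
#'   {\sum P^2 + \sum T^2 + \epsilon}}
#' For binary `P` this is 0 iff `P = T`; two empty masks give 0 by the
#' epsilon convention.
#'
#' @param P probability map in `[0, 1]`.
#' @param T_ binary reference mask of the same shape.
#' @param eps smoothing constant (default 1e-6).
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(P, T_, eps = 1e-6) {
  stopifnot(all(dim(P) == dim(T_)) || length(P) == length(T_))
  if (any(P < -1e-9) || any(P > 1 + 1e-9)) {
    stop("P must lie in [0, 1]")
  }
  1 - (2 * sum(P * T_) + eps) / (sum(P^2) + sum(T_^2) + eps)
}

#' Signed Euclidean distance map of a binary mask
#'
#' For pixels inside the reference set `G` the value is the negative
#' Euclidean distance to the nearest pixel outside `G`; outside `G` it is
#' the positive distance to the nearest pixel of `G` (pixel-centre
#' distances). Boundary pixels of `G` therefore have magnitude `>= 1`.
#' Empty masks return an all-positive constant sentinel, full masks an
#' all-negative one (the image diagonal).
#'
#' @param G binary (0/1 or logical) matrix.
#' @return numeric matrix, negative exactly on `G`.
#' @export
signed_distance <- function(G) {
  G <- (G != 0) + 0
  sentinel <- sqrt(nrow(G)^2 + ncol(G)^2)
  if (all(G == 0)) return(matrix(sentinel, nrow(G), ncol(G)))
  if (all(G == 1)) return(matrix(-sentinel, nrow(G), ncol(G)))
  din <- EBImage::distmap(G, metric = "euclidean")    # inside: dist to bg
  dout <- EBImage::distmap(1 - G, metric = "euclidean")
  as.matrix(dout) - as.matrix(din)
}

#' Boundary loss
#'
#' Discretization of \eqn{L_{BD} = \int_\Omega \phi_G(i)\, g(i)\, di}: the
#' pixelwise product of the signed distance map of the ground truth with
#' the network's foreground probability, summed (and by default divided
#' by the pixel count). It is negative when probability mass lies inside
#' the reference region.
#'
#' @param g probability map in `[0, 1]`.
#' @param phi signed distance map from [signed_distance()].
#' @param normalize divide by pixel count (default `TRUE`).
#' @return scalar.
#' @export
boundary_loss <- function(g, phi, normalize = TRUE) {
  stopifnot(length(g) == length(phi))
  s <- sum(phi * g)
  if (normalize) s / length(g) else s
}

#' Combined Dice + boundary loss
#'
#' \eqn{L = \alpha L_{Dice} + \beta L_{BD}} with \eqn{\phi_G} computed
#' from the reference mask.
#'
#' @param P probability map.
#' @param T_ binary reference mask.
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
combined_loss <- function(P, T_, cfg = loss_config()) {
  cfg$alpha * dice_loss(P, T_) +
    cfg$beta * boundary_loss(P, signed_distance(T_),
                             normalize = cfg$normalize_boundary)
}

#' Overlap metrics between predicted and reference masks
#'
#' `IOU = |I1 n I2| / |I1 u I2|` and `DSC = 2 |I1 n I2| / (|I1| + |I2|)`;
#' when both masks are empty both metrics are 1 by convention.
#'
#' @param pred,truth binary masks of equal shape.
#' @return list with `iou` and `dsc`.
#' @export
segmentation_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  p <- pred != 0; t <- truth != 0
  inter <- sum(p & t)
  uni <- sum(p | t)
  if (uni == 0) return(list(iou = 1, dsc = 1))
  list(iou = inter / uni, dsc = 2 * inter / (sum(p) + sum(t)))
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn nonnegative integer tallies.
#' @return list of class `"confusion_counts"`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP+TN)/total`, `Pre = TP/(TP+FP)`, `Re = TP/(TP+FN)`,
#' `F1 = 2 Pre Re / (Pre + Re)`; metrics with zero denominator are
#' returned as `NA`.
#'
#' @param c_ a [confusion_counts()] object (or list with tp/tn/fp/fn).
#' @return list with `acc`, `pre`, `re`, `f1`.
#' @export
classification_metrics <- function(c_) {
  tp <- c_$tp; tn <- c_$tn; fp <- c_$fp; fn <- c_$fn
  total <- tp + tn + fp + fn
  pre <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  re <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(pre) && !is.na(re) && pre + re > 0) {
    2 * pre * re / (pre + re)
  } else NA_real_
  list(acc = (tp + tn) / total, pre = pre, re = re, f1 = f1)
}
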