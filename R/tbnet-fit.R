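## Fitting TBNet with Adam on the combined Dice + boundary objective.

.adam_init <- function(params) {
  lapply(params, function(p) {
    list(m = array(0, dim(p$value) %||% length(p$value)),
         v = array(0, dim(p$value) %||% length(p$value)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, state, lr, t, scale = 1,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad * scale
    st <- state[[nm]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    mh <- st$m / (1 - b1^t)
    vh <- st$v / (1 - b2^t)
    p$value <- p$value - lr * mh / (sqrt(vh) + eps)
    state[[nm]] <- st
  }
  state
}

## loss assembled on the tape so it can be differentiated
.tape_loss <- function(tape, prob, mask, alpha, beta, normalize) {
  Tarr <- array(mask, dim(prob$value))
  eps <- 1e-6
  s1 <- ad_sum(tape, ad_mul(tape, prob, Tarr))
  s2 <- ad_sum(tape, ad_mul(tape, prob, prob))
  num <- ad_add(tape, ad_scale(tape, s1, 2), eps)
  den <- ad_add(tape, s2, sum(Tarr^2) + eps)
  dice <- ad_sub(tape, 1, ad_div(tape, num, den))
  total <- ad_scale(tape, dice, alpha)
  if (beta != 0) {
    phi <- array(signed_distance(mask), dim(prob$value))
    bl <- ad_sum(tape, ad_mul(tape, prob, phi))
    if (normalize) bl <- ad_scale(tape, bl, 1 / length(phi))
    total <- ad_add(tape, total, ad_scale(tape, bl, beta))
  }
  total
}

#' Fit the TBNet segmentation network
#'
#' Trains TBNet (skip-free U-Net + channel cross-fusion transformer +
#' edge-enhanced cross-attention) on paired images and binary masks with
#' the combined objective \eqn{L = \alpha L_{Dice} + \beta L_{BD}},
#' optimized by Adam. Fully deterministic for a fixed seed.
#'
#' @param x list of grayscale image matrices on the `[0, 255]` scale,
#'   all with the configured input size.
#' @param y list of matching binary masks (0/1).
#' @param config a [tbnet_config()].
#' @param epochs training epochs (default 200).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size gradient-accumulation batch size (default 4).
#' @param loss a [loss_config()].
#' @param seed integer seed controlling initialization and shuffling.
#' @param target_dsc optional early-exit threshold: training stops once
#'   the epoch's mean training DSC reaches it.
#' @param validation optional list with elements `x` and `y` for
#'   per-epoch validation DSC; the best-validation parameter set is
#'   retained.
#' @param verbose print per-epoch progress.
#' @return object of class `"tbnet"` with elements `params`, `config`,
#'   `history` (per-epoch loss and DSC) and `seed`.
#' @seealso [predict.tbnet()], [tbnet_forward()], [tbnet_save()]
#' @export
tbnet <- function(x, y, config = tbnet_config(), epochs = 200L,
                  lr = 1e-4, batch_size = 4L, loss = loss_config(),
                  seed = 1L, target_dsc = NULL, validation = NULL,
                  verbose = FALSE) {
  stopifnot(length(x) == length(y), length(x) > 0L)
  model <- tbnet_untrained(config, seed = seed)
  P <- model$params
  state <- .adam_init(P)
  n <- length(x)
  hist <- vector("list", epochs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  tstep <- 0L
  best_val <- -Inf; best_values <- NULL
  for (ep in seq_len(epochs)) {
    beta_ep <- if (!is.null(loss$beta_ramp)) {
      loss$beta_ramp[1] + (loss$beta_ramp[2] - loss$beta_ramp[1]) *
        (ep - 1) / max(epochs - 1, 1)
    } else loss$beta
    ord <- sample.int(n)
    losses <- numeric(0); dscs <- numeric(0)
    for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
      ad_zero_grads(P)
      for (i in bs) {
        tape <- ad_tape()
        prob <- .fw_tbnet(tape, P, config, x[[i]])
        lnode <- .tape_loss(tape, prob, y[[i]], loss$alpha, beta_ep,
                            loss$normalize_boundary)
        if (!is.finite(lnode$value)) {
          stop("training diverged: non-finite loss at epoch ", ep,
               " (sample ", i, ")")
        }
        ad_backward(tape, lnode)
        losses <- c(losses, lnode$value)
        pm <- prob$value[, , 1] >= 0.5
        dscs <- c(dscs, segmentation_metrics(pm, y[[i]])$dsc)
      }
      tstep <- tstep + 1L
      state <- .adam_step(P, state, lr, tstep, scale = 1 / length(bs))
    }
    val_dsc <- NA_real_
    if (!is.null(validation)) {
      vd <- vapply(seq_along(validation$x), function(k) {
        pm <- tbnet_forward(model, validation$x[[k]]) >= 0.5
        segmentation_metrics(pm, validation$y[[k]])$dsc
      }, numeric(1))
      val_dsc <- mean(vd)
      if (val_dsc > best_val) {
        best_val <- val_dsc
        best_values <- lapply(P, `[[`, "value")
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = mean(losses),
                             dsc = mean(dscs), val_dsc = val_dsc,
                             beta = beta_ep)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train DSC %.3f%s", ep,
                      mean(losses), mean(dscs),
                      if (is.na(val_dsc)) "" else
                        sprintf("  val DSC %.3f", val_dsc)))
    }
    if (!is.null(target_dsc) && mean(dscs) >= target_dsc) break
  }
  if (!is.null(best_values)) {
    for (nm in names(best_values)) P[[nm]]$value <- best_values[[nm]]
  }
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$fitted <- TRUE
  model$loss <- loss
  model
}

#' @export
print.tbnet <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("TBNet (%s), input %dx%d, channels (%s), N=%d heads, L=%d layers, d=%d\n",
              if (isTRUE(x$fitted)) "fitted" else "untrained",
              cfg$input_size[1], cfg$input_size[2],
              paste(cfg$channels, collapse = ","), cfg$heads, cfg$layers,
              cfg$seq_len))
  cat(sprintf("  parameters: %s\n", format(npar, big.mark = ",")))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f, train DSC %.3f\n",
                nrow(x$history), last$loss, last$dsc))
  }
  invisible(x)
}

#' @export
summary.tbnet <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  loss: first %.4f -> best %.4f; DSC: first %.3f -> best %.3f\n",
                h$loss[1], min(h$loss), h$dsc[1], max(h$dsc)))
    if (any(is.finite(h$val_dsc))) {
      cat(sprintf("  best validation DSC %.3f\n",
                  max(h$val_dsc, na.rm = TRUE)))
    }
  }
  invisible(object)
}

#' @export
coef.tbnet <- function(object, ...) {
  lapply(object$params, `[[`, "value")
}

#' Segment images with a fitted TBNet
#'
#' @param object a `"tbnet"` model.
#' @param newdata a grayscale matrix or list of matrices on the
#'   `[0, 255]` scale.
#' @param type `"prob"` for foreground probability maps, `"mask"` for
#'   thresholded binary masks.
#' @param threshold mask threshold (default 0.5).
#' @param ... unused.
#' @return a matrix, or a list of matrices when `newdata` is a list.
#' @export
predict.tbnet <- function(object, newdata, type = c("prob", "mask"),
                          threshold = 0.5, ...) {
  type <- match.arg(type)
  single <- is.matrix(newdata)
  if (single) newdata <- list(newdata)
  out <- lapply(newdata, function(im) {
    p <- tbnet_forward(object, im)
    if (type == "mask") (p >= threshold) + 0 else p
  })
  if (single) out[[1]] else out
}

#' @export
plot.tbnet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  graphics::plot(h$epoch, h$dsc, type = "l", xlab = "epoch",
                 ylab = "DSC", ylim = c(0, 1), main = "training DSC", ...)
  if (any(is.finite(h$val_dsc))) {
    graphics::lines(h$epoch, h$val_dsc, lty = 2)
  }
  invisible(x)
}

#' Save / load a TBNet checkpoint
#'
#' Checkpoints hold the configuration, parameter values, history and
#' seed in R's standard serialized form.
#'
#' @param model a `"tbnet"` object.
#' @param path checkpoint file path (`.rds`).
#' @export
tbnet_save <- function(model, path) {
  saveRDS(list(config = model$config,
               values = lapply(model$params, `[[`, "value"),
               history = model$history, seed = model$seed,
               fitted = model$fitted), path)
  invisible(path)
}

#' @rdname tbnet_save
#' @export
tbnet_load <- function(path) {
  ck <- readRDS(path)
  model <- tbnet_untrained(ck$config, seed = ck$seed %||% 1L)
  for (nm in names(ck$values)) model$params[[nm]]$value <- ck$values[[nm]]
  model$history <- ck$history
  model$fitted <- isTRUE(ck$fitted)
  model
}
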