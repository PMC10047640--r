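## End-to-end orchestration: simulate -> prescreen -> denoise ->
## train/segment -> evaluate, with dataset splitting and rotation
## augmentation.

#' Split items into train / validation / test sets
#'
#' Sizes follow the ratio by largest-remainder rounding (10 items at
#' 7:1:2 give 7/1/2); the assignment is a seeded permutation. When
#' `patients` is supplied, whole patients are assigned to splits (no
#' patient appears in two splits), greedily filling the largest
#' remaining quota.
#'
#' @param items vector or list to split.
#' @param ratio positive length-3 weights, default `c(7, 1, 2)`.
#' @param seed integer seed.
#' @param patients optional vector of patient identifiers, one per item.
#' @return list with `train`, `val`, `test` (subsets of `items`) and
#'   `idx` (the index sets).
#' @export
split_dataset <- function(items, ratio = c(7, 1, 2), seed = 1L,
                          patients = NULL) {
  n <- length(items)
  if (n < 3L) stop("fewer items than splits")
  stopifnot(length(ratio) == 3L, all(ratio > 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  target <- n * ratio / sum(ratio)
  sizes <- floor(target)
  rem <- target - sizes
  for (k in order(rem, decreasing = TRUE)[seq_len(n - sum(sizes))]) {
    sizes[k] <- sizes[k] + 1L
  }
  if (is.null(patients)) {
    ord <- sample.int(n)
    idx <- list(train = sort(ord[seq_len(sizes[1])]),
                val = sort(ord[sizes[1] + seq_len(sizes[2])]),
                test = sort(ord[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  } else {
    stopifnot(length(patients) == n)
    groups <- split(seq_len(n), patients)
    groups <- groups[sample.int(length(groups))]
    take <- list(integer(0), integer(0), integer(0))
    got <- c(0, 0, 0)
    for (g in groups) {
      k <- which.max(target - got)
      take[[k]] <- c(take[[k]], g)
      got[k] <- got[k] + length(g)
    }
    idx <- list(train = sort(take[[1]]), val = sort(take[[2]]),
                test = sort(take[[3]]))
  }
  list(train = items[idx$train], val = items[idx$val],
       test = items[idx$test], idx = idx)
}

## clockwise rotation by 90 degrees
.rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Rotation augmentation of an image/mask pair
#'
#' Returns the original pair plus one pair per requested rotation, the
#' mask rotated identically to the image.
#'
#' @param image,mask numeric matrices (square when 90 or 270 degrees are
#'   requested).
#' @param rotations subset of `c(90, 180, 270)` degrees.
#' @return list of `list(image, mask)` pairs (original first).
#' @export
augment <- function(image, mask, rotations = c(90, 180, 270)) {
  if (!all(rotations %in% c(90, 180, 270))) {
    stop("rotations must be a subset of {90, 180, 270}")
  }
  if (any(rotations %in% c(90, 270)) && nrow(image) != ncol(image)) {
    stop("90/270 degree rotation requires square images")
  }
  out <- list(list(image = image, mask = mask))
  for (r in rotations) {
    k <- r / 90
    im <- image; mk <- mask
    for (j in seq_len(k)) { im <- .rot90(im); mk <- .rot90(mk) }
    out[[length(out) + 1L]] <- list(image = im, mask = mk)
  }
  out
}

#' Pipeline configuration
#'
#' Bundles the study conditions of the full workflow: simulation,
#' pre-screening, denoising, training and evaluation. The split ratio
#' (7:1:2), rotation set and 200-epoch default mirror the study design;
#' image size, noise level and optimizer settings are package choices.
#'
#' @param n_slices number of simulated slices.
#' @param lesion_fraction fraction of slices carrying a lesion.
#' @param shape slice shape (must satisfy [tbnet_config()] constraints).
#' @param sigma Rician noise std on the 0--255 intensity scale.
#' @param stages named logical vector enabling `prescreen`, `denoise`
#'   and `train`.
#' @param split_ratio train/val/test weights, default `c(7, 1, 2)`.
#' @param augment_rotations rotation set for training augmentation
#'   (`NULL` disables).
#' @param seed master seed.
#' @param epochs,lr,batch_size optimizer settings (defaults 200, 1e-4,
#'   4).
#' @param model a [tbnet_config()] matching `shape`.
#' @param prescreen a [prescreen_config()].
#' @param loss a [loss_config()].
#' @param lesion_spec lesion geometry passed to [make_stack()].
#' @param out_dir optional directory for the manifest and artifacts.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_slices = 60L, lesion_fraction = 0.5,
                            shape = c(64L, 64L), sigma = 20,
                            stages = c(prescreen = TRUE, denoise = TRUE,
                                       train = TRUE),
                            split_ratio = c(7, 1, 2),
                            augment_rotations = c(90, 180, 270),
                            seed = 1L, epochs = 200L, lr = 1e-4,
                            batch_size = 4L,
                            model = NULL, prescreen = prescreen_config(),
                            loss = loss_config(),
                            lesion_spec = list(count = 1L,
                                               radius = c(6, 10),
                                               contrast = 100,
                                               softness = 1.5),
                            out_dir = NULL) {
  if (is.null(model)) {
    model <- tbnet_config(input_size = shape,
                          channels = c(8L, 16L, 32L, 64L),
                          heads = 2L, layers = 2L, patch_size = 16L)
  }
  structure(list(n_slices = n_slices, lesion_fraction = lesion_fraction,
                 shape = shape, sigma = sigma, stages = stages,
                 split_ratio = split_ratio,
                 augment_rotations = augment_rotations, seed = seed,
                 epochs = epochs, lr = lr, batch_size = batch_size,
                 model = model, prescreen = prescreen, loss = loss,
                 lesion_spec = lesion_spec, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full diagnosis pipeline on synthetic data
#'
#' Simulates a slice stack, optionally pre-screens it with the TSF,
#' optionally denoises the kept slices with Rician-corrected NLM, splits
#' them 7:1:2, augments the training set by rotation, trains TBNet and
#' evaluates on the held-out test split. Each stage's inputs, outputs
#' and metrics are recorded in a run manifest.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage progress.
#' @return list of class `"run_manifest"` with per-stage records,
#'   the fitted `model` and a `metrics` list (`prescreen_ca`,
#'   `psnr_noisy`, `psnr_denoised`, `test_dsc`, `test_iou`, pixel-level
#'   `acc`/`pre`/`re`/`f1`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(config = cfg, seed = cfg$seed, stages = list())
  t0 <- proc.time()[3]

  ## -- simulate ----------------------------------------------------------
  stack <- make_stack(cfg$n_slices, cfg$lesion_fraction, cfg$shape,
                      seed = cfg$seed, lesion_spec = cfg$lesion_spec)
  truth <- vapply(stack$slices, `[[`, "", "label")
  noisy <- lapply(stack$slices, function(s) {
    add_rician_noise(s$clean, cfg$sigma, seed = s$seed + 1L)
  })
  manifest$stages$simulate <- list(n = cfg$n_slices,
                                   n_lesion = sum(truth == "lesion"),
                                   elapsed = proc.time()[3] - t0)
  say("simulate: %d slices (%d lesion)", cfg$n_slices,
      sum(truth == "lesion"))

  ## -- prescreen ---------------------------------------------------------
  metrics <- list()
  if (isTRUE(cfg$stages[["prescreen"]])) {
    sc <- screen_stack(stack, cfg$prescreen, images = noisy)
    pred <- vapply(sc$results, `[[`, "", "label")
    metrics$prescreen_ca <- classification_accuracy(pred, truth)
    keep <- sc$kept_idx
    manifest$stages$prescreen <- list(kept = keep,
                                      ca = metrics$prescreen_ca)
    say("prescreen: kept %d/%d (CA %.3f)", length(keep), cfg$n_slices,
        metrics$prescreen_ca)
  } else {
    keep <- seq_len(cfg$n_slices)
  }
  if (length(keep) < 3L) {
    stop("pipeline stage 'prescreen' left fewer than 3 slices")
  }

  ## -- denoise -----------------------------------------------------------
  if (isTRUE(cfg$stages[["denoise"]])) {
    nlm <- nlm_config(sigma = cfg$sigma)
    proc <- lapply(noisy[keep], rician_correct, cfg = nlm)
    clean_kept <- lapply(stack$slices[keep], `[[`, "clean")
    metrics$psnr_noisy <- mean(mapply(psnr, noisy[keep], clean_kept))
    metrics$psnr_denoised <- mean(mapply(psnr, proc, clean_kept))
    manifest$stages$denoise <- list(n = length(keep),
                                    psnr_noisy = metrics$psnr_noisy,
                                    psnr_denoised = metrics$psnr_denoised)
    say("denoise: PSNR %.2f -> %.2f dB", metrics$psnr_noisy,
        metrics$psnr_denoised)
  } else {
    proc <- noisy[keep]
  }
  masks <- lapply(stack$slices[keep], `[[`, "mask")

  ## -- split / augment / train ------------------------------------------
  model <- NULL
  if (isTRUE(cfg$stages[["train"]])) {
    sp <- split_dataset(seq_along(proc), cfg$split_ratio, seed = cfg$seed)
    tr_x <- proc[sp$idx$train]; tr_y <- masks[sp$idx$train]
    if (!is.null(cfg$augment_rotations)) {
      aug_x <- list(); aug_y <- list()
      for (k in seq_along(tr_x)) {
        for (p in augment(tr_x[[k]], tr_y[[k]], cfg$augment_rotations)) {
          aug_x[[length(aug_x) + 1L]] <- p$image
          aug_y[[length(aug_y) + 1L]] <- p$mask
        }
      }
      tr_x <- aug_x; tr_y <- aug_y
    }
    manifest$stages$split <- sp$idx
    say("train: %d samples (after augmentation), %d epochs",
        length(tr_x), cfg$epochs)
    model <- tbnet(tr_x, tr_y, config = cfg$model, epochs = cfg$epochs,
                   lr = cfg$lr, batch_size = cfg$batch_size,
                   loss = cfg$loss, seed = cfg$seed,
                   validation = if (length(sp$idx$val) > 0)
                     list(x = proc[sp$idx$val], y = masks[sp$idx$val])
                   else NULL)
    manifest$stages$train <- list(n_train = length(tr_x),
                                  history = model$history)

    ## -- evaluate --------------------------------------------------------
    te_x <- proc[sp$idx$test]; te_y <- masks[sp$idx$test]
    dsc <- iou <- numeric(length(te_x))
    tp <- tn <- fp <- fn <- 0
    for (k in seq_along(te_x)) {
      pm <- predict(model, te_x[[k]], type = "mask")
      sm <- segmentation_metrics(pm, te_y[[k]])
      dsc[k] <- sm$dsc; iou[k] <- sm$iou
      tp <- tp + sum(pm == 1 & te_y[[k]] == 1)
      tn <- tn + sum(pm == 0 & te_y[[k]] == 0)
      fp <- fp + sum(pm == 1 & te_y[[k]] == 0)
      fn <- fn + sum(pm == 0 & te_y[[k]] == 1)
    }
    metrics$test_dsc <- mean(dsc)
    metrics$test_iou <- mean(iou)
    cm <- classification_metrics(confusion_counts(tp, tn, fp, fn))
    metrics <- c(metrics, cm)
    manifest$stages$evaluate <- list(n_test = length(te_x),
                                     per_slice_dsc = dsc)
    say("evaluate: test DSC %.3f, IOU %.3f", metrics$test_dsc,
        metrics$test_iou)
  }

  manifest$metrics <- metrics
  manifest$model <- model
  manifest$elapsed <- proc.time()[3] - t0
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(metric = names(unlist(metrics)),
                 value = unlist(metrics)),
      file.path(cfg$out_dir, "metrics.csv"), row.names = FALSE)
    if (!is.null(model)) {
      tbnet_save(model, file.path(cfg$out_dir, "model.rds"))
    }
  }
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run manifest\n")
  cat(sprintf("  stages: %s\n",
              paste(names(x$stages), collapse = " -> ")))
  for (nm in names(x$metrics)) {
    cat(sprintf("  %-16s %.4f\n", nm, x$metrics[[nm]]))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' Preprocessing ablation benchmark
#'
#' Trains the same (reduced-size) TBNet under three preprocessing
#' conditions on a common synthetic stack -- raw noisy slices, denoised
#' slices, and denoised slices kept by the TSF pre-screen -- and
#' evaluates each variant's mean DSC on a common set of held-out lesion
#' slices (processed per variant).
#'
#' @param n_slices training-pool size.
#' @param lesion_fraction fraction of pool slices with a lesion.
#' @param n_test number of held-out lesion slices.
#' @param shape slice shape.
#' @param sigma Rician noise std.
#' @param epochs,lr training settings per variant.
#' @param seed master seed shared by all variants.
#' @param model a [tbnet_config()] (reduced default for `shape`).
#' @return named numeric vector with mean test DSC for `raw`,
#'   `denoise` and `denoise_prescreen`.
#' @export
ablation_benchmark <- function(n_slices = 48L, lesion_fraction = 0.25,
                               n_test = 8L, shape = c(32L, 32L),
                               sigma = 30, epochs = 30L, lr = 1e-3,
                               seed = 1L, model = NULL) {
  if (is.null(model)) {
    model <- tbnet_config(input_size = shape,
                          channels = c(4L, 8L, 16L, 32L),
                          heads = 2L, layers = 1L, patch_size = 16L)
  }
  spec <- list(count = 1L, radius = c(5, 9), contrast = 100,
               softness = 1.5)
  stack <- make_stack(n_slices, lesion_fraction, shape, seed = seed,
                      lesion_spec = spec)
  noisy <- lapply(stack$slices, function(s) {
    add_rician_noise(s$clean, sigma, seed = s$seed + 1L)
  })
  masks <- lapply(stack$slices, `[[`, "mask")

  test <- lapply(seq_len(n_test), function(k) {
    make_phantom(shape, spec, seed = seed + 100000L + k)
  })
  test_noisy <- lapply(test, function(s) {
    add_rician_noise(s$clean, sigma, seed = s$seed + 1L)
  })
  test_masks <- lapply(test, `[[`, "mask")

  nlm <- nlm_config(sigma = sigma)
  den <- lapply(noisy, rician_correct, cfg = nlm)
  test_den <- lapply(test_noisy, rician_correct, cfg = nlm)

  sc <- screen_stack(stack, prescreen_config(), images = noisy)
  keep <- sc$kept_idx
  if (length(keep) < 2L) keep <- seq_along(noisy)

  ## variants see different pool sizes; equalize the number of parameter
  ## updates so the comparison isolates data quality, not training budget
  total_steps <- epochs * ceiling(n_slices / 4)
  eval_variant <- function(tr_x, tr_y, te_x) {
    ep <- ceiling(total_steps / ceiling(length(tr_x) / 4))
    m <- tbnet(tr_x, tr_y, config = model, epochs = ep, lr = lr,
               batch_size = 4L, seed = seed)
    mean(vapply(seq_along(te_x), function(k) {
      pm <- predict(m, te_x[[k]], type = "mask")
      segmentation_metrics(pm, test_masks[[k]])$dsc
    }, numeric(1)))
  }
  c(raw = eval_variant(noisy, masks, test_noisy),
    denoise = eval_variant(den, masks, test_den),
    denoise_prescreen = eval_variant(den[keep], masks[keep], test_den))
}
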