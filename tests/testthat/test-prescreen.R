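test_that("zero noise level makes the coarse denoiser an identity", {
  set.seed(1)
  blk <- matrix(runif(49, 0, 255), 7, 7)
  expect_lt(max(abs(coarse_denoise_window(blk, sigma = 0) - blk)), 1e-10)
})

test_that("constant blocks survive coarse denoising (DC dominates)", {
  blk <- matrix(100, 7, 7)
  # DC coefficient magnitude c * n1 = 700 far above the sigma=20 threshold
  out <- coarse_denoise_window(blk, lambda_fft = 0.82, sigma = 20)
  expect_lt(max(abs(out - 100)), 1e-10)
  out_fft <- coarse_denoise_window(blk, lambda_fft = 0.82, sigma = 20,
                                   transform = "fft")
  expect_lt(max(abs(out_fft - 100)), 1e-10)
})

test_that("sub-threshold coefficients are annihilated", {
  n1 <- 7; sigma <- 20; lfft <- 0.82
  lam <- lfft * sqrt(2 * sigma^2 * log(n1^2))
  D <- oracle_dct(n1)
  cf <- matrix(0, n1, n1)
  cf[3, 5] <- lam / 2
  blk <- t(D) %*% cf %*% D  # block whose only coefficient is lam/2
  out <- coarse_denoise_window(blk, lfft, sigma)
  expect_lt(max(abs(out)), 1e-12)
  # and a coefficient at lam survives untouched under hard thresholding
  cf[3, 5] <- lam * 1.01
  blk2 <- t(D) %*% cf %*% D
  expect_lt(max(abs(coarse_denoise_window(blk2, lfft, sigma) - blk2)),
            1e-12)
})

test_that("coarse denoising is a projection (idempotent)", {
  set.seed(2)
  for (k in 1:5) {
    blk <- matrix(runif(49, 0, 255), 7, 7)
    once <- coarse_denoise_window(blk, sigma = 30)
    twice <- coarse_denoise_window(once, sigma = 30)
    expect_lt(max(abs(once - twice)), 1e-9)
  }
})

test_that("the literal printed shrinkage clips surviving coefficients", {
  n1 <- 7; sigma <- 20; lfft <- 0.82
  lam <- lfft * sqrt(2 * sigma^2 * log(n1^2))
  D <- oracle_dct(n1)
  cf <- matrix(0, n1, n1); cf[2, 2] <- 3 * lam
  blk <- t(D) %*% cf %*% D
  out <- coarse_denoise_window(blk, lfft, sigma, shrinkage = "literal")
  cf_out <- D %*% out %*% t(D)
  expect_equal(cf_out[2, 2], lam, tolerance = 1e-10)
})

test_that("the TSF decision reproduces the worked activations", {
  # all-zero window: a = -0.5*133*49 - 133 = -3391.5 < 0 -> fires
  expect_identical(tsf_decision(matrix(0, 7, 7), 133), 1L)
  # all-255 window: a = 12495 - 3391.5 = 9103.5 >= 0 -> no lesion
  expect_identical(tsf_decision(matrix(255, 7, 7), 133), 0L)
  # exact boundary (lambda_T = 98 gives integer mean 51): a = 0 -> 0
  expect_identical(tsf_decision(matrix(51, 7, 7), 98), 0L)
  # bright-lesion polarity negates the activation
  expect_identical(tsf_decision(matrix(255, 7, 7), 133,
                                polarity = "bright_lesion"), 1L)
  expect_identical(tsf_decision(matrix(0, 7, 7), 133,
                                polarity = "bright_lesion"), 0L)
})

test_that("blank bright slices pass, dark-lesion slices are flagged", {
  blank <- matrix(200, 63, 63)
  r0 <- screen_image(blank, prescreen_config(sigma = 0))
  expect_identical(r0$label, "normal")
  expect_identical(nrow(r0$flagged_windows), 0L)

  ph <- make_phantom(c(63, 63), list(count = 1, radius = c(10, 10),
                                     contrast = 120, softness = 1.5),
                     seed = 4)
  r1 <- screen_image(ph$clean, prescreen_config())
  expect_identical(r1$label, "lesion")
  expect_gt(nrow(r1$flagged_windows), 0)
  # flags cluster on the blob: every flagged window intersects the mask
  n1 <- 7
  hits <- apply(r1$flagged_windows, 1, function(o) {
    sum(ph$mask[o[1]:(o[1] + n1 - 1), o[2]:(o[2] + n1 - 1)]) > 0
  })
  expect_true(all(hits))
})

test_that("stride-1 flags are a superset of the stride-n1 flags", {
  ph <- make_phantom(c(63, 63), list(count = 1, radius = c(10, 10),
                                     contrast = 120, softness = 1.5),
                     seed = 4)
  f_coarse <- screen_image(ph$clean, prescreen_config(stride = 7))
  f_fine <- screen_image(ph$clean, prescreen_config(stride = 1))
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(f_coarse$flagged_windows) %in%
                    key(f_fine$flagged_windows)))
})

test_that("the flagged set grows monotonically with lambda_T", {
  set.seed(9)
  img <- matrix(runif(63 * 63, 40, 110), 63, 63)
  key <- function(m) paste(m[, 1], m[, 2])
  prev <- character(0)
  for (lt in c(90, 110, 133, 160)) {
    f <- screen_image(img, prescreen_config(lambda_t = lt, sigma = 0))
    cur <- key(f$flagged_windows)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("screening is invariant to stride-aligned lesion translation", {
  base <- matrix(200, 63, 63)
  place <- function(r, c) {
    img <- base
    img[r:(r + 6), c:(c + 6)] <- 20
    img
  }
  cfg <- prescreen_config(sigma = 0)
  a <- screen_image(place(8, 15), cfg)
  b <- screen_image(place(15, 22), cfg)  # shifted by one stride
  expect_identical(a$label, "lesion")
  expect_identical(a$label, b$label)
  expect_identical(nrow(a$flagged_windows), nrow(b$flagged_windows))
})

test_that("stacks are filtered with high accuracy on separable phantoms", {
  st <- make_stack(100, 0.4, shape = c(63, 63), seed = 21,
                   lesion_spec = list(count = 1, radius = c(9, 12),
                                      contrast = 110, softness = 1.5))
  truth <- vapply(st$slices, `[[`, "", "label")
  sc <- screen_stack(st, prescreen_config())
  pred <- vapply(sc$results, `[[`, "", "label")
  expect_gte(classification_accuracy(pred, truth), 0.95)
  expect_identical(sc$kept_idx, which(pred == "lesion"))

  all_norm <- make_stack(5, 0, shape = c(63, 63), seed = 1)
  expect_length(screen_stack(all_norm, prescreen_config())$kept, 0)
  all_les <- make_stack(5, 1, shape = c(63, 63), seed = 1,
                        lesion_spec = list(count = 1, radius = c(9, 12),
                                           contrast = 110,
                                           softness = 1.5))
  expect_length(screen_stack(all_les, prescreen_config())$kept, 5)
})

test_that("classification accuracy follows its definition", {
  expect_identical(classification_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_identical(classification_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_error(classification_accuracy(character(0), character(0)),
               "empty")
  expect_error(classification_accuracy("a", c("a", "b")), "length")
})

test_that("images smaller than the window are rejected", {
  expect_error(screen_image(matrix(0, 5, 5), prescreen_config()),
               "smaller")
})
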