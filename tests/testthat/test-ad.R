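# Finite-difference verification of the reverse-mode engine that
# differentiates the segmentation network.

O <- asNamespace("osteoseg")

grad_check <- function(build, x, tol = 1e-4, eps = 1e-6) {
  f <- function(xv) {
    tape <- O$ad_tape()
    build(tape, O$ad_node(xv))$value
  }
  tape <- O$ad_tape()
  nx <- O$ad_node(x)
  loss <- build(tape, nx)
  O$ad_backward(tape, loss)
  gn <- num_grad(f, x, eps)
  expect_lt(max(abs(nx$grad - gn)), tol * max(1, max(abs(gn))))
}

wsum <- function(tape, node, w) O$ad_sum(tape, O$ad_mul(tape, node, w))

test_that("elementwise and scalar op gradients match finite differences", {
  set.seed(1)
  x <- array(runif(24, -1, 1), c(3, 4, 2))
  w <- array(runif(24), c(3, 4, 2))
  grad_check(function(tp, n) wsum(tp, O$ad_sigmoid(tp, n), w), x)
  grad_check(function(tp, n) wsum(tp, O$ad_mul(tp, n, x + 2), w), x)
  grad_check(function(tp, n) O$ad_mean(tp, O$ad_sqrt(tp, O$ad_mul(tp, n, n))),
             x + 3)
  grad_check(function(tp, n) {
    O$ad_div(tp, O$ad_sum(tp, n), O$ad_add(tp, O$ad_sum(tp, O$ad_mul(tp, n, n)), 5))
  }, x)
  xr <- x; xr[abs(xr) < 0.05] <- 0.5  # keep clear of the ReLU kink
  grad_check(function(tp, n) wsum(tp, O$ad_relu(tp, n), w), xr)
})

test_that("matrix op gradients match finite differences", {
  set.seed(2)
  A <- matrix(runif(12, -1, 1), 3, 4)
  B <- matrix(runif(20, -1, 1), 4, 5)
  W <- matrix(runif(15), 3, 5)
  grad_check(function(tp, n) wsum(tp, O$ad_matmul(tp, n, B), W), A)
  grad_check(function(tp, n) wsum(tp, O$ad_matmul(tp, A, n), W), B)
  C <- matrix(runif(20, -1, 1), 5, 4)
  grad_check(function(tp, n) wsum(tp, O$ad_matmul_bt(tp, n, C), W), A)
  grad_check(function(tp, n) wsum(tp, O$ad_matmul_bt(tp, A, n), W), C)
  b <- runif(5)
  grad_check(function(tp, n) wsum(tp, O$ad_affine(tp, A, n, b), W), B)
  grad_check(function(tp, n) wsum(tp, O$ad_affine(tp, A, B, n), W), b)
  grad_check(function(tp, n) wsum(tp, O$ad_softmax_rows(tp, n), W),
             matrix(runif(15, -2, 2), 3, 5))
  grad_check(function(tp, n) wsum(tp, O$ad_inorm(tp, n), W),
             matrix(runif(15, -2, 2), 3, 5), tol = 1e-3)
  W84 <- matrix(runif(32), 8, 4)
  grad_check(function(tp, n) {
    wsum(tp, O$ad_rbind(tp, list(n, O$ad_node(C))), W84)
  }, matrix(runif(12), 3, 4))
})

test_that("convolution and pooling gradients match finite differences", {
  set.seed(3)
  x <- array(runif(32, -1, 1), c(4, 4, 2))
  w <- matrix(runif(3 * 9 * 2, -0.5, 0.5), 3, 18)
  b <- runif(3)
  wt <- array(runif(48), c(4, 4, 3))
  grad_check(function(tp, n) {
    wsum(tp, O$ad_conv2d(tp, n, w, b, 3L, 3L, 1L, 1L), wt)
  }, x)
  grad_check(function(tp, n) {
    wsum(tp, O$ad_conv2d(tp, x, n, b, 3L, 3L, 1L, 1L), wt)
  }, w)
  grad_check(function(tp, n) {
    wsum(tp, O$ad_conv2d(tp, x, w, n, 3L, 3L, 1L, 1L), wt)
  }, b)
  # strided patch embedding (kernel = stride = 2)
  w2 <- matrix(runif(2 * 4 * 2), 2, 8)
  wt2 <- array(runif(8), c(2, 2, 2))
  grad_check(function(tp, n) {
    wsum(tp, O$ad_conv2d(tp, n, w2, c(0, 0), 2L, 2L, 2L, 0L), wt2)
  }, x)
  wp <- array(runif(8), c(2, 2, 2))
  grad_check(function(tp, n) {
    wsum(tp, O$ad_maxpool2(tp, n), wp)
  }, x)
})

test_that("resize, pooling descriptors and reshaping gradients match", {
  set.seed(4)
  x <- array(runif(18, -1, 1), c(3, 3, 2))
  U <- O$bilinear_matrix(6, 3); V <- O$bilinear_matrix(6, 3)
  w662 <- array(runif(72), c(6, 6, 2))
  w331 <- array(runif(9), c(3, 3, 1))
  w332 <- array(runif(18), c(3, 3, 2))
  w334 <- array(runif(36), c(3, 3, 4))
  w29 <- matrix(runif(18), 2, 9)
  w2 <- runif(2)
  grad_check(function(tp, n) wsum(tp, O$ad_resize(tp, n, U, V), w662), x)
  grad_check(function(tp, n) wsum(tp, O$ad_gap(tp, n), w2), x)
  grad_check(function(tp, n) wsum(tp, O$ad_chan_mean(tp, n), w331), x)
  grad_check(function(tp, n) wsum(tp, O$ad_sum_c(tp, n), w331), x)
  grad_check(function(tp, n) wsum(tp, O$ad_slice_c(tp, n, 2L), w331), x)
  s <- runif(2)
  grad_check(function(tp, n) wsum(tp, O$ad_chan_gate(tp, n, s), w332), x)
  grad_check(function(tp, n) wsum(tp, O$ad_chan_gate(tp, x, n), w332), s)
  a <- matrix(runif(9), 3, 3); bb <- runif(2)
  grad_check(function(tp, n) wsum(tp, O$ad_outer_sc(tp, n, bb), w332), a)
  grad_check(function(tp, n) wsum(tp, O$ad_outer_sc(tp, a, n), w332), bb)
  grad_check(function(tp, n) {
    wsum(tp, O$ad_concat_c(tp, list(n, O$ad_node(x))), w334)
  }, x)
  grad_check(function(tp, n) wsum(tp, O$ad_grid_to_tokens(tp, n), w29), x)
  grad_check(function(tp, n) wsum(tp, O$ad_tokens_to_grid(tp, n, 3, 3),
                                  w332),
             matrix(runif(18), 2, 9))
  grad_check(function(tp, n) wsum(tp, O$ad_inorm_channels(tp, n), w332),
             x, tol = 1e-3)
})

test_that("token reconstruction is exact in its identity configuration", {
  # patch side 1 (no pooling), identity projections: reshaping tokens to
  # the grid, resizing by the identity and convolving with a centred
  # delta kernel must return the embedded input
  set.seed(5)
  tokens <- matrix(runif(2 * 9, 0.1, 1), 2, 9)  # 2 channels, 3x3 grid
  tape <- O$ad_tape()
  g <- O$ad_tokens_to_grid(tape, O$ad_node(tokens), 3, 3)
  up <- O$ad_resize(tape, g, diag(3), diag(3))
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  wid <- rbind(c(as.numeric(delta), numeric(9)),
               c(numeric(9), as.numeric(delta)))
  y <- O$ad_conv2d(tape, up, wid, c(0, 0), 3L, 3L, 1L, 1L)
  back <- O$ad_grid_to_tokens(tape, O$ad_relu(tape, y))
  expect_lt(max(abs(back$value - tokens)), 1e-6)
})

test_that("the tape accumulates gradients over repeated use of a node", {
  x <- matrix(c(1, 2, 3, 4), 2, 2)
  tape <- O$ad_tape()
  n <- O$ad_node(x)
  y <- O$ad_sum(tape, O$ad_add(tape, O$ad_mul(tape, n, n), n))
  O$ad_backward(tape, y)
  expect_equal(n$grad, 2 * x + 1)
})
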