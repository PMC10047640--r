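## Reverse-mode automatic differentiation on a tape.
##
## Values are plain numeric arrays: H x W x C cubes for feature maps,
## C x d matrices for token sequences, length-1 vectors for scalars.
## A node is an environment holding $value and (after the backward pass)
## $grad; recording an op pushes a closure that maps the node's gradient
## onto its parents. Parameters are plain leaf nodes reused across tapes.

is_adnode <- function(x) inherits(x, "adnode")

#' @noRd
ad_node <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  class(nd) <- "adnode"
  nd
}

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$ops <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_record <- function(tape, nd, backward) {
  n <- tape$n + 1L
  if (n > length(tape$ops)) {
    tape$ops <- c(tape$ops, vector("list", length(tape$ops)))
  }
  tape$ops[[n]] <- list(node = nd, backward = backward)
  tape$n <- n
  nd
}

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

## Run the tape in reverse from a scalar loss node.
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (k in seq.int(tape$n, 1L)) {
    op <- tape$ops[[k]]
    g <- op$node$grad
    if (!is.null(g)) op$backward(g)
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

.v <- function(x) if (is_adnode(x)) x$value else x

## gradient of a broadcast scalar operand
.bg <- function(x, g) if (length(.v(x)) == 1L) sum(g) else g

ad_add <- function(tape, a, b) {
  nd <- ad_node(.v(a) + .v(b))
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) ad_accum(a, .bg(a, g))
    if (is_adnode(b)) ad_accum(b, .bg(b, g))
  })
}

ad_sub <- function(tape, a, b) {
  nd <- ad_node(.v(a) - .v(b))
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) ad_accum(a, .bg(a, g))
    if (is_adnode(b)) ad_accum(b, .bg(b, -g))
  })
}

ad_mul <- function(tape, a, b) {
  av <- .v(a); bv <- .v(b)
  nd <- ad_node(av * bv)
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) ad_accum(a, .bg(a, g * bv))
    if (is_adnode(b)) ad_accum(b, .bg(b, g * av))
  })
}

## division of scalars (used in loss assembly)
ad_div <- function(tape, a, b) {
  av <- .v(a); bv <- .v(b)
  nd <- ad_node(av / bv)
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) ad_accum(a, g / bv)
    if (is_adnode(b)) ad_accum(b, -g * av / bv^2)
  })
}

## multiply by a fixed constant
ad_scale <- function(tape, a, k) {
  nd <- ad_node(.v(a) * k)
  ad_record(tape, nd, function(g) if (is_adnode(a)) ad_accum(a, g * k))
}

ad_sum <- function(tape, a) {
  av <- .v(a)
  nd <- ad_node(sum(av))
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) {
      gr <- if (is.null(dim(av))) rep(g, length(av)) else array(g, dim(av))
      ad_accum(a, gr)
    }
  })
}

ad_mean <- function(tape, a) {
  n <- length(.v(a))
  ad_scale(tape, ad_sum(tape, a), 1 / n)
}

ad_relu <- function(tape, a) {
  av <- .v(a)
  mask <- av > 0
  nd <- ad_node(av * mask)
  ad_record(tape, nd, function(g) if (is_adnode(a)) ad_accum(a, g * mask))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-.v(a)))
  nd <- ad_node(s)
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) ad_accum(a, g * s * (1 - s))
  })
}

ad_sqrt <- function(tape, a, eps = 1e-8) {
  s <- sqrt(.v(a) + eps)
  nd <- ad_node(s)
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) ad_accum(a, g * 0.5 / s)
  })
}

ad_matmul <- function(tape, a, b) {
  av <- .v(a); bv <- .v(b)
  nd <- ad_node(av %*% bv)
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) ad_accum(a, g %*% t(bv))
    if (is_adnode(b)) ad_accum(b, t(av) %*% g)
  })
}

## X %*% W + row-broadcast bias
ad_affine <- function(tape, x, w, b) {
  xv <- .v(x); wv <- .v(w); bv <- .v(b)
  y <- xv %*% wv
  y <- sweep(y, 2L, bv, "+")
  nd <- ad_node(y)
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) ad_accum(x, g %*% t(wv))
    if (is_adnode(w)) ad_accum(w, t(xv) %*% g)
    if (is_adnode(b)) ad_accum(b, colSums(g))
  })
}

## row-wise softmax of a matrix
ad_softmax_rows <- function(tape, a) {
  av <- .v(a)
  m <- av - apply(av, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  nd <- ad_node(s)
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) {
      rs <- rowSums(g * s)
      ad_accum(a, s * (g - rs))
    }
  })
}

## standardize all elements to zero mean / unit variance (instance norm
## over the whole matrix, as applied to the similarity logits)
ad_inorm <- function(tape, a, eps = 1e-5) {
  av <- .v(a)
  n <- length(av)
  mu <- mean(av)
  sd_ <- sqrt(mean((av - mu)^2) + eps)
  z <- (av - mu) / sd_
  nd <- ad_node(z)
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) {
      ad_accum(a, (g - mean(g) - z * mean(g * z)) / sd_)
    }
  })
}

## per-channel instance normalization of an H x W x C map
ad_inorm_channels <- function(tape, a, eps = 1e-5) {
  av <- .v(a)
  d <- dim(av)
  n <- d[1] * d[2]
  m <- matrix(av, n, d[3])
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  sds <- sqrt(colMeans(ctr^2) + eps)
  zm <- sweep(ctr, 2L, sds, "/")
  z <- array(zm, d)
  nd <- ad_node(z)
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) {
      gm <- matrix(g, n, d[3])
      gc <- sweep(gm, 2L, colMeans(gm))
      gz <- colMeans(gm * zm)
      gx <- sweep(gc - sweep(zm, 2L, gz, "*"), 2L, sds, "/")
      ad_accum(a, array(gx, d))
    }
  })
}

## 2-D convolution; x: H x W x Cin node, w: (Cout x kh*kw*Cin) flat weight
## node (or constant), b: Cout bias node (or constant).
ad_conv2d <- function(tape, x, w, b, kh, kw, stride = 1L, pad = 0L) {
  xv <- .v(x); wv <- .v(w); bv <- .v(b)
  if (length(dim(xv)) == 2L) dim(xv) <- c(dim(xv), 1L)
  d <- dim(xv)
  fw <- .cpp_conv2d_fw(xv, wv, bv, kh, kw, stride, pad)
  nd <- ad_node(fw$y)
  cols <- fw$cols
  ad_record(tape, nd, function(g) {
    bw <- .cpp_conv2d_bw(g, wv, cols, d[1], d[2], d[3], kh, kw, stride, pad)
    if (is_adnode(x)) ad_accum(x, bw$gx)
    if (is_adnode(w)) ad_accum(w, bw$gw)
    if (is_adnode(b)) ad_accum(b, as.numeric(bw$gb))
  })
}

ad_maxpool2 <- function(tape, x) {
  xv <- .v(x)
  d <- dim(xv)
  fw <- .cpp_maxpool2_fw(xv)
  nd <- ad_node(fw$y)
  idx <- fw$idx
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) ad_accum(x, .cpp_maxpool2_bw(g, idx, d[1], d[2]))
  })
}

## interpolation matrix mapping n_in samples to n_out (bilinear,
## half-pixel-centre convention); exact inverse-permutation adjoint
bilinear_matrix <- function(n_out, n_in) {
  U <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5 + 1  # 1-based
    lo <- floor(src)
    whi <- src - lo
    lo <- min(max(lo, 1L), n_in)
    hi <- min(lo + 1L, n_in)
    U[i, lo] <- U[i, lo] + (1 - whi)
    U[i, hi] <- U[i, hi] + whi
  }
  U
}

## separable linear-map resize: y[,,c] = U %*% x[,,c] %*% t(V)
ad_resize <- function(tape, x, U, V) {
  xv <- .v(x)
  d <- dim(xv)
  y <- array(0, c(nrow(U), nrow(V), d[3]))
  for (c in seq_len(d[3])) y[, , c] <- U %*% xv[, , c] %*% t(V)
  nd <- ad_node(y)
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) {
      gx <- array(0, d)
      for (c in seq_len(d[3])) gx[, , c] <- t(U) %*% g[, , c] %*% V
      ad_accum(x, gx)
    }
  })
}

## global average pooling xi: H x W x C -> length-C vector
ad_gap <- function(tape, x) {
  xv <- .v(x)
  d <- dim(xv)
  nd <- ad_node(apply(xv, 3L, mean))
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) {
      gx <- array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d)
      ad_accum(x, gx)
    }
  })
}

## per-channel gate: y[,,c] = x[,,c] * s[c]
ad_chan_gate <- function(tape, x, s) {
  xv <- .v(x); sv <- .v(s)
  d <- dim(xv)
  y <- xv * array(rep(sv, each = d[1] * d[2]), d)
  nd <- ad_node(y)
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) {
      ad_accum(x, g * array(rep(sv, each = d[1] * d[2]), d))
    }
    if (is_adnode(s)) {
      ad_accum(s, as.numeric(apply(g * xv, 3L, sum)))
    }
  })
}

## spatial x channel outer product: a (H x W), b (C) -> H x W x C
ad_outer_sc <- function(tape, a, b) {
  av <- .v(a); bv <- .v(b)
  if (length(dim(av)) == 3L) av <- av[, , 1]
  d <- c(dim(av), length(bv))
  y <- array(av, d) * array(rep(bv, each = d[1] * d[2]), d)
  nd <- ad_node(y)
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) {
      ga <- matrix(0, d[1], d[2])
      for (c in seq_len(d[3])) ga <- ga + g[, , c] * bv[c]
      if (length(dim(.v(a))) == 3L) dim(ga) <- c(d[1], d[2], 1L)
      ad_accum(a, ga)
    }
    if (is_adnode(b)) {
      ad_accum(b, as.numeric(apply(g * array(av, d), 3L, sum)))
    }
  })
}

## channel concatenation of H x W x C_k maps
ad_concat_c <- function(tape, xs) {
  vals <- lapply(xs, .v)
  dims <- vapply(vals, function(v) dim(v)[3], numeric(1))
  y <- array(0, c(dim(vals[[1]])[1:2], sum(dims)))
  at <- 0L
  for (v in vals) {
    y[, , at + seq_len(dim(v)[3])] <- v
    at <- at + dim(v)[3]
  }
  nd <- ad_node(y)
  ad_record(tape, nd, function(g) {
    at <- 0L
    for (k in seq_along(xs)) {
      ck <- dims[k]
      if (is_adnode(xs[[k]])) {
        ad_accum(xs[[k]], g[, , at + seq_len(ck), drop = FALSE])
      }
      at <- at + ck
    }
  })
}

## h x w x C grid -> C x (h*w) channel-major token matrix
ad_grid_to_tokens <- function(tape, x) {
  xv <- .v(x)
  d <- dim(xv)
  nd <- ad_node(t(matrix(xv, d[1] * d[2], d[3])))
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) ad_accum(x, array(t(g), d))
  })
}

ad_tokens_to_grid <- function(tape, x, h, w) {
  xv <- .v(x)  # C x d
  C <- nrow(xv)
  nd <- ad_node(array(t(xv), c(h, w, C)))
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) ad_accum(x, t(matrix(g, h * w, C)))
  })
}

## row-wise concatenation of matrices (token sequences across scales)
ad_rbind <- function(tape, xs) {
  vals <- lapply(xs, .v)
  rws <- vapply(vals, nrow, numeric(1))
  nd <- ad_node(do.call(rbind, vals))
  ad_record(tape, nd, function(g) {
    at <- 0L
    for (k in seq_along(xs)) {
      if (is_adnode(xs[[k]])) {
        ad_accum(xs[[k]], g[at + seq_len(rws[k]), , drop = FALSE])
      }
      at <- at + rws[k]
    }
  })
}

## a %*% t(b)
ad_matmul_bt <- function(tape, a, b) {
  av <- .v(a); bv <- .v(b)
  nd <- ad_node(av %*% t(bv))
  ad_record(tape, nd, function(g) {
    if (is_adnode(a)) ad_accum(a, g %*% bv)
    if (is_adnode(b)) ad_accum(b, t(g) %*% av)
  })
}

## mean over channels: H x W x C -> H x W x 1
ad_chan_mean <- function(tape, x) {
  xv <- .v(x)
  d <- dim(xv)
  y <- array(rowMeans(matrix(xv, d[1] * d[2], d[3])), c(d[1], d[2], 1L))
  nd <- ad_node(y)
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) {
      ad_accum(x, array(rep(g, d[3]), d) / d[3])
    }
  })
}

## sum over channels: H x W x C -> H x W x 1
ad_sum_c <- function(tape, x) {
  xv <- .v(x)
  d <- dim(xv)
  y <- array(rowSums(matrix(xv, d[1] * d[2], d[3])), c(d[1], d[2], 1L))
  nd <- ad_node(y)
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) ad_accum(x, array(rep(g, d[3]), d))
  })
}

## extract one channel: H x W x C -> H x W x 1
ad_slice_c <- function(tape, x, c) {
  xv <- .v(x)
  d <- dim(xv)
  nd <- ad_node(xv[, , c, drop = FALSE])
  ad_record(tape, nd, function(g) {
    if (is_adnode(x)) {
      gx <- array(0, d)
      gx[, , c] <- g
      ad_accum(x, gx)
    }
  })
}

## treat a node's value as a constant downstream
ad_stopgrad <- function(x) ad_node(.v(x))
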