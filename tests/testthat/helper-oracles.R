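# Independent brute-force oracles used across the suite.

# nearest-opposite-pixel signed distance (exhaustive search)
brute_signed_distance <- function(G) {
  G <- (G != 0) + 0
  H <- nrow(G); W <- ncol(G)
  out <- matrix(0, H, W)
  idx1 <- which(G == 1, arr.ind = TRUE)
  idx0 <- which(G == 0, arr.ind = TRUE)
  sent <- sqrt(H^2 + W^2)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (G[i, j] == 1) {
        out[i, j] <- if (nrow(idx0) == 0) -sent else
          -sqrt(min((idx0[, 1] - i)^2 + (idx0[, 2] - j)^2))
      } else {
        out[i, j] <- if (nrow(idx1) == 0) sent else
          sqrt(min((idx1[, 1] - i)^2 + (idx1[, 2] - j)^2))
      }
    }
  }
  out
}

# direct double-loop NLM (independent of the package implementation)
brute_nlm <- function(image, ds, Cs, h, K = NULL) {
  cside <- 2 * ds + 1
  if (is.null(K)) K <- matrix(1 / cside^2, cside, cside)
  R <- ds + Cs
  n <- nrow(image); m <- ncol(image)
  ri <- c(R:1, 1:n, n:(n - R + 1)); ci <- c(R:1, 1:m, m:(m - R + 1))
  v <- image[ri, ci]
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    pi <- i + R; pj <- j + R
    P0 <- v[(pi - ds):(pi + ds), (pj - ds):(pj + ds)]
    num <- 0; den <- 0
    for (t1 in -Cs:Cs) for (t2 in -Cs:Cs) {
      Pt <- v[(pi + t1 - ds):(pi + t1 + ds), (pj + t2 - ds):(pj + t2 + ds)]
      w <- exp(-sum(K * (P0 - Pt)^2) / h^2)
      num <- num + w * v[pi + t1, pj + t2]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# brute-force patch distance at one translation (explicit patch sum),
# matching the package's reflect-padding convention
brute_patch_distance <- function(image, t, ds, K = NULL) {
  cside <- 2 * ds + 1
  if (is.null(K)) K <- matrix(1 / cside^2, cside, cside)
  R <- ds + max(abs(t), 1)
  n <- nrow(image); m <- ncol(image)
  ri <- c(R:1, 1:n, n:(n - R + 1)); ci <- c(R:1, 1:m, m:(m - R + 1))
  v <- image[ri, ci]
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    pi <- i + R; pj <- j + R
    s <- 0
    for (b1 in -ds:ds) for (b2 in -ds:ds) {
      s <- s + K[b1 + ds + 1, b2 + ds + 1] *
        (v[pi + b1, pj + b2] - v[pi + t[1] + b1, pj + t[2] + b2])^2
    }
    out[i, j] <- s
  }
  out
}

# orthonormal type-II DCT matrix, written independently
oracle_dct <- function(n) {
  outer(0:(n - 1), 0:(n - 1), function(k, j) {
    ifelse(k == 0, sqrt(1 / n), sqrt(2 / n)) *
      cos(pi * (2 * j + 1) * k / (2 * n))
  })
}

small_phantom_spec <- function(radius = c(6, 10), contrast = 100,
                               softness = 1.5) {
  list(count = 1L, radius = radius, contrast = contrast,
       softness = softness)
}

# finite-difference gradient of f at x (elementwise)
num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
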