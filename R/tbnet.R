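## TBNet: skip-free U-Net encoder/decoder whose four encoder scales are
## fused by a multi-head channel cross-attention transformer (MCT) and
## whose decoder fuses transformer and decoder features through an
## edge-enhanced cross-attention module (ECA).

#' TBNet architecture configuration
#'
#' @param input_size `(H, W)`, both divisible by the patch size and
#'   by 16 (the encoder has four 2x downsampling stages plus a
#'   bottleneck). Default `c(224, 224)`.
#' @param channels encoder channel sizes `(C1, C2, C3, C4)`; default
#'   `c(64, 128, 256, 512)`.
#' @param heads number of attention heads `N` (default 4).
#' @param layers number of transformer layers `L` (default 4).
#' @param patch_size level-1 token patch side `P` (divisible by 8; the
#'   four scales use `P, P/2, P/4, P/8` so that every scale tokenizes to
#'   the same sequence length `d = (H/P) * (W/P)`). Default 16.
#' @param mlp_ratio expansion factor of the transformer MLP (default 4).
#' @param eca_literal_gate if `TRUE`, the ECA channel-attention mask is
#'   built from the transformer descriptor alone (the printed form)
#'   rather than from both transformer and decoder descriptors.
#' @param reconstruct_norm apply per-channel instance normalization in
#'   the token-reconstruction block (default `TRUE`).
#' @return list of class `"tbnet_config"`, including the derived
#'   sequence length `seq_len`.
#' @export
tbnet_config <- function(input_size = c(224L, 224L),
                         channels = c(64L, 128L, 256L, 512L),
                         heads = 4L, layers = 4L, patch_size = 16L,
                         mlp_ratio = 4L, eca_literal_gate = FALSE,
                         reconstruct_norm = TRUE) {
  H <- as.integer(input_size[1]); W <- as.integer(input_size[2])
  P <- as.integer(patch_size)
  if (length(channels) != 4L) stop("channels must have four entries")
  if (H %% 16L != 0L || W %% 16L != 0L) {
    stop("input size must be divisible by 16")
  }
  if (H %% P != 0L || W %% P != 0L) {
    stop("input size must be divisible by the patch size")
  }
  if (P %% 8L != 0L) stop("patch_size must be divisible by 8")
  if (heads < 1L || layers < 1L) stop("heads and layers must be >= 1")
  d <- (H %/% P) * (W %/% P)
  structure(list(input_size = c(H, W), channels = as.integer(channels),
                 heads = as.integer(heads), layers = as.integer(layers),
                 patch_size = P, mlp_ratio = as.integer(mlp_ratio),
                 seq_len = d, eca_literal_gate = eca_literal_gate,
                 reconstruct_norm = reconstruct_norm),
            class = "tbnet_config")
}

## -- parameter initialization -------------------------------------------

.init_conv_w <- function(cout, cin, k, gain = sqrt(2)) {
  matrix(stats::rnorm(cout * k * k * cin, 0, gain / sqrt(k * k * cin)),
         cout, k * k * cin)
}

.init_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, 1 / sqrt(nr)), nr, nc)
}

## Build the full parameter set as named leaf nodes.
tbnet_init_params <- function(cfg, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  C <- cfg$channels
  d <- cfg$seq_len
  dh <- d * cfg$mlp_ratio
  P <- list()
  add <- function(name, v) P[[name]] <<- ad_node(v)

  enc_in <- c(1L, C[1], C[2], C[3])
  for (l in 1:4) {
    add(sprintf("enc%d_w1", l), .init_conv_w(C[l], enc_in[l], 3))
    add(sprintf("enc%d_b1", l), numeric(C[l]))
    add(sprintf("enc%d_w2", l), .init_conv_w(C[l], C[l], 3))
    add(sprintf("enc%d_b2", l), numeric(C[l]))
  }
  add("bot_w1", .init_conv_w(C[4], C[4], 3)); add("bot_b1", numeric(C[4]))
  add("bot_w2", .init_conv_w(C[4], C[4], 3)); add("bot_b2", numeric(C[4]))

  for (l in 1:4) {
    pl <- cfg$patch_size %/% 2L^(l - 1L)
    add(sprintf("emb%d_w", l), .init_conv_w(C[l], C[l], pl, gain = 1))
    add(sprintf("emb%d_b", l), numeric(C[l]))
  }

  for (ly in seq_len(cfg$layers)) {
    for (h in seq_len(cfg$heads)) {
      for (l in 1:4) {
        add(sprintf("wq_%d_%d_%d", ly, h, l), .init_mat(d, d))
      }
      add(sprintf("wk_%d_%d", ly, h), .init_mat(d, d))
      add(sprintf("wv_%d_%d", ly, h), .init_mat(d, d))
    }
    for (l in 1:4) {
      add(sprintf("mlp%d_%d_w1", ly, l), .init_mat(d, dh))
      add(sprintf("mlp%d_%d_b1", ly, l), numeric(dh))
      add(sprintf("mlp%d_%d_w2", ly, l), .init_mat(dh, d))
      add(sprintf("mlp%d_%d_b2", ly, l), numeric(d))
    }
  }

  for (l in 1:4) {
    add(sprintf("rec%d_w", l), .init_conv_w(C[l], C[l], 3))
    add(sprintf("rec%d_b", l), numeric(C[l]))
  }

  cnext <- c(C[2], C[3], C[4], C[4])  # channels of f_{i+1} for i = 1..4
  for (i in 1:4) {
    add(sprintf("dec%d_w", i), .init_conv_w(C[i], cnext[i], 3))
    add(sprintf("dec%d_b", i), numeric(C[i]))
    add(sprintf("eca%d_x1", i), .init_mat(C[i], C[i]))
    add(sprintf("eca%d_x2", i), .init_mat(C[i], C[i]))
    add(sprintf("eca%d_d1_w", i), .init_conv_w(C[i], C[i] + 1L + cnext[i], 1))
    add(sprintf("eca%d_d1_b", i), numeric(C[i]))
    add(sprintf("eca%d_c1_w", i), .init_conv_w(C[i], C[i], 3))
    add(sprintf("eca%d_c1_b", i), numeric(C[i]))
    add(sprintf("eca%d_c2_w", i), .init_conv_w(C[i], C[i], 3))
    add(sprintf("eca%d_c2_b", i), numeric(C[i]))
    add(sprintf("eca%d_fa_w", i), .init_conv_w(1L, C[i], 1))
    add(sprintf("eca%d_fa_b", i), numeric(1L))
    add(sprintf("eca%d_out_w", i), .init_conv_w(C[i], C[i], 3))
    add(sprintf("eca%d_out_b", i), numeric(C[i]))
  }
  add("head_w", .init_conv_w(2L, C[1], 1, gain = 1))
  add("head_b", numeric(2L))
  P
}

#' Create an untrained TBNet model
#'
#' @param config a [tbnet_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `"tbnet"` (untrained).
#' @export
tbnet_untrained <- function(config = tbnet_config(), seed = 1L) {
  structure(list(config = config, params = tbnet_init_params(config, seed),
                 history = NULL, seed = seed, fitted = FALSE),
            class = "tbnet")
}

## -- forward building blocks (tape level) -------------------------------

.conv3 <- function(tape, x, w, b) ad_conv2d(tape, x, w, b, 3L, 3L, 1L, 1L)
.conv1 <- function(tape, x, w, b) ad_conv2d(tape, x, w, b, 1L, 1L, 1L, 0L)

.conv_block <- function(tape, x, P, pre) {
  h <- .conv3(tape, x, P[[paste0(pre, "_w1")]], P[[paste0(pre, "_b1")]])
  h <- ad_relu(tape, ad_inorm_channels(tape, h))
  h <- .conv3(tape, h, P[[paste0(pre, "_w2")]], P[[paste0(pre, "_b2")]])
  ad_relu(tape, ad_inorm_channels(tape, h))
}

.fw_encoder <- function(tape, P, x) {
  E1 <- .conv_block(tape, x, P, "enc1")
  E2 <- .conv_block(tape, ad_maxpool2(tape, E1), P, "enc2")
  E3 <- .conv_block(tape, ad_maxpool2(tape, E2), P, "enc3")
  E4 <- .conv_block(tape, ad_maxpool2(tape, E3), P, "enc4")
  B <- .conv_block(tape, ad_maxpool2(tape, E4), P, "bot")
  list(E1 = E1, E2 = E2, E3 = E3, E4 = E4, bottleneck = B)
}

.fw_embed <- function(tape, P, cfg, E) {
  L <- vector("list", 4L)
  for (l in 1:4) {
    pl <- cfg$patch_size %/% 2L^(l - 1L)
    g <- ad_conv2d(tape, E[[l]], P[[sprintf("emb%d_w", l)]],
                   P[[sprintf("emb%d_b", l)]], pl, pl, pl, 0L)
    L[[l]] <- ad_grid_to_tokens(tape, g)
  }
  list(L = L, Lsum = ad_rbind(tape, L))
}

## channel-axis attention: Mi = softmax(inorm(Ti TKey' / C_sum)), CA = Mi TValue
.fw_cca <- function(tape, Ti, TKey, TValue, Csum) {
  logits <- ad_scale(tape, ad_matmul_bt(tape, Ti, TKey), 1 / Csum)
  M <- ad_softmax_rows(tape, ad_inorm(tape, logits))
  list(M = M, CA = ad_matmul(tape, M, TValue))
}

.fw_mct <- function(tape, P, cfg, tokens) {
  Csum <- sum(cfg$channels)
  for (ly in seq_len(cfg$layers)) {
    Lsum <- ad_rbind(tape, tokens)
    newtok <- vector("list", 4L)
    for (l in 1:4) {
      acc <- NULL
      for (h in seq_len(cfg$heads)) {
        q <- ad_matmul(tape, tokens[[l]], P[[sprintf("wq_%d_%d_%d", ly, h, l)]])
        k <- ad_matmul(tape, Lsum, P[[sprintf("wk_%d_%d", ly, h)]])
        v <- ad_matmul(tape, Lsum, P[[sprintf("wv_%d_%d", ly, h)]])
        ca <- .fw_cca(tape, q, k, v, Csum)$CA
        acc <- if (is.null(acc)) ca else ad_add(tape, acc, ca)
      }
      mca <- ad_scale(tape, acc, 1 / cfg$heads)
      z <- ad_add(tape, tokens[[l]], mca)
      h1 <- ad_relu(tape, ad_affine(tape, z, P[[sprintf("mlp%d_%d_w1", ly, l)]],
                                    P[[sprintf("mlp%d_%d_b1", ly, l)]]))
      m <- ad_affine(tape, h1, P[[sprintf("mlp%d_%d_w2", ly, l)]],
                     P[[sprintf("mlp%d_%d_b2", ly, l)]])
      newtok[[l]] <- ad_add(tape, mca, m)
    }
    tokens <- newtok
  }
  tokens
}

.fw_reconstruct <- function(tape, P, cfg, Oi, level) {
  H <- cfg$input_size[1] %/% 2L^(level - 1L)
  W <- cfg$input_size[2] %/% 2L^(level - 1L)
  h <- cfg$input_size[1] %/% cfg$patch_size
  w <- cfg$input_size[2] %/% cfg$patch_size
  g <- ad_tokens_to_grid(tape, Oi, h, w)
  up <- ad_resize(tape, g, bilinear_matrix(H, h), bilinear_matrix(W, w))
  y <- .conv3(tape, up, P[[sprintf("rec%d_w", level)]],
              P[[sprintf("rec%d_b", level)]])
  if (cfg$reconstruct_norm) y <- ad_inorm_channels(tape, y)
  ad_relu(tape, y)
}

.sobel_wmat <- function() {
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dcol
  gy <- t(gx)                                                # d/drow
  rbind(as.numeric(gy), as.numeric(gx))  # 2 x 9, kh-fastest layout
}

## Edge cue: Sobel gradient magnitude of the channel mean, rescaled by
## its (gradient-detached) maximum to [0, 1].
.fw_edge_map <- function(tape, x) {
  cm <- ad_chan_mean(tape, x)
  sob <- ad_conv2d(tape, cm, .sobel_wmat(), c(0, 0), 3L, 3L, 1L, 1L)
  mag <- ad_sqrt(tape, ad_sum_c(tape, ad_mul(tape, sob, sob)), eps = 1e-12)
  ad_scale(tape, mag, 1 / (max(mag$value) + 1e-8))
}

.fw_eca <- function(tape, P, cfg, level, O, Fi, fnext) {
  i <- level
  gO <- ad_gap(tape, O)
  gF <- if (cfg$eca_literal_gate) gO else ad_gap(tape, Fi)
  m <- ad_add(tape,
              ad_matmul(tape, P[[sprintf("eca%d_x1", i)]], gO),
              ad_matmul(tape, P[[sprintf("eca%d_x2", i)]], gF))
  Ohat <- ad_chan_gate(tape, O, ad_sigmoid(tape, m))

  Mhat <- .fw_edge_map(tape, Ohat)
  cat_ <- ad_concat_c(tape, list(Fi, Mhat, fnext))
  h <- ad_relu(tape, .conv1(tape, cat_, P[[sprintf("eca%d_d1_w", i)]],
                            P[[sprintf("eca%d_d1_b", i)]]))
  h <- ad_relu(tape, .conv3(tape, h, P[[sprintf("eca%d_c1_w", i)]],
                            P[[sprintf("eca%d_c1_b", i)]]))
  Fab <- .conv3(tape, h, P[[sprintf("eca%d_c2_w", i)]],
                P[[sprintf("eca%d_c2_b", i)]])
  Fa <- ad_sigmoid(tape, .conv1(tape, Fab, P[[sprintf("eca%d_fa_w", i)]],
                                P[[sprintf("eca%d_fa_b", i)]]))
  Fb <- ad_sigmoid(tape, ad_gap(tape, Fab))
  Fhat <- ad_mul(tape, ad_outer_sc(tape, Fa, Fb), Fab)
  ad_relu(tape, .conv3(tape, ad_add(tape, Ohat, Fhat),
                       P[[sprintf("eca%d_out_w", i)]],
                       P[[sprintf("eca%d_out_b", i)]]))
}

.fw_tbnet <- function(tape, P, cfg, image, details = FALSE) {
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  if (nrow(image) != H || ncol(image) != W) {
    stop("image shape must match config input_size")
  }
  x <- ad_node(array(image / 255, c(H, W, 1L)))
  E <- .fw_encoder(tape, P, x)
  emb <- .fw_embed(tape, P, cfg, E)
  O <- .fw_mct(tape, P, cfg, emb$L)
  Rmaps <- lapply(1:4, function(l) .fw_reconstruct(tape, P, cfg, O[[l]], l))
  f <- E$bottleneck
  for (i in 4:1) {
    Hi <- H %/% 2L^(i - 1L); Wi <- W %/% 2L^(i - 1L)
    dn <- dim(f$value)
    up <- ad_resize(tape, f, bilinear_matrix(Hi, dn[1]),
                    bilinear_matrix(Wi, dn[2]))
    Fi <- ad_relu(tape, .conv3(tape, up, P[[sprintf("dec%d_w", i)]],
                               P[[sprintf("dec%d_b", i)]]))
    f <- .fw_eca(tape, P, cfg, i, Rmaps[[i]], Fi, up)
  }
  logits <- .conv1(tape, f, P[["head_w"]], P[["head_b"]])
  diffl <- ad_sub(tape, ad_slice_c(tape, logits, 1L),
                  ad_slice_c(tape, logits, 2L))
  prob <- ad_sigmoid(tape, diffl)
  if (details) {
    list(prob = prob, encoder = E, tokens = emb, O = O, recon = Rmaps,
         final = f)
  } else {
    prob
  }
}

## -- exported component surfaces (plain arrays in, plain arrays out) -----

#' Run the TBNet encoder
#'
#' @param model a `"tbnet"` object.
#' @param image numeric matrix on the `[0, 255]` scale with the
#'   configured input size.
#' @return list of the four per-level feature maps `E1..E4`
#'   (`H_i x W_i x C_i` arrays) and the `bottleneck`.
#' @export
tbnet_encoder <- function(model, image) {
  tape <- ad_tape()
  lapply(.fw_encoder(tape, model$params,
                     ad_node(array(image / 255,
                                   c(nrow(image), ncol(image), 1L)))),
         `[[`, "value")
}

#' Tokenize encoder features into multi-scale channel-major sequences
#'
#' Each scale is patch-embedded with kernel = stride = its patch side and
#' flattened to a `C_i x d` token matrix; all scales share the sequence
#' length `d`, and `Lsum` is their row-wise concatenation.
#'
#' @param model a `"tbnet"` object.
#' @param E list of encoder feature arrays as returned by
#'   [tbnet_encoder()].
#' @return list with `L` (four token matrices) and `Lsum`.
#' @export
tbnet_embed <- function(model, E) {
  tape <- ad_tape()
  emb <- .fw_embed(tape, model$params, model$config,
                   lapply(E[1:4], ad_node))
  list(L = lapply(emb$L, `[[`, "value"), Lsum = emb$Lsum$value)
}

#' Channel-wise cross-attention
#'
#' Computes the similarity matrix
#' \eqn{M_i = \mathrm{softmax}(\psi(T_i T_{Key}^\top)/C_\Sigma)} (instance
#' normalization \eqn{\psi} of the scaled logits, softmax over the
#' \eqn{C_\Sigma} axis) and the attended output
#' \eqn{CA_i = M_i T_{Value}}.
#'
#' @param Ti query token matrix, `Ci x d`.
#' @param TKey,TValue key/value token matrices, `Csum x d`.
#' @param Csum scaling constant (defaults to `nrow(TKey)`).
#' @return list with `similarity` (`Ci x Csum`, rows sum to 1) and
#'   `ca` (`Ci x d`).
#' @export
channel_cross_attention <- function(Ti, TKey, TValue, Csum = nrow(TKey)) {
  if (ncol(Ti) != ncol(TKey) || !all(dim(TKey) == dim(TValue))) {
    stop("token dimensions do not conform")
  }
  tape <- ad_tape()
  r <- .fw_cca(tape, ad_node(Ti), ad_node(TKey), ad_node(TValue), Csum)
  list(similarity = r$M$value, ca = r$CA$value)
}

#' Average attention-head outputs
#'
#' @param heads list of equally shaped head outputs.
#' @return their arithmetic mean.
#' @export
multi_head <- function(heads) {
  Reduce(`+`, heads) / length(heads)
}

#' Apply the MCT transformer layer stack to token sequences
#'
#' @param model a `"tbnet"` object.
#' @param tokens list of four `C_i x d` token matrices.
#' @return list of four output token matrices `O1..O4`.
#' @export
tbnet_mct <- function(model, tokens) {
  tape <- ad_tape()
  lapply(.fw_mct(tape, model$params, model$config, lapply(tokens, ad_node)),
         `[[`, "value")
}

#' Reconstruct a token sequence into a feature map
#'
#' Reshapes the `d` tokens onto the token grid, upsamples bilinearly by
#' the level's patch side and applies a 3x3 convolution (with optional
#' per-channel normalization) and rectification.
#'
#' @param model a `"tbnet"` object.
#' @param Oi `C_i x d` token matrix.
#' @param level scale index 1--4.
#' @return `H_i x W_i x C_i` feature array.
#' @export
tbnet_reconstruct <- function(model, Oi, level) {
  tape <- ad_tape()
  .fw_reconstruct(tape, model$params, model$config, ad_node(Oi),
                  level)$value
}

#' Edge-enhanced cross-attention fusion
#'
#' Fuses a reconstructed transformer feature map `Oi` with the decoder
#' feature `Fi` of the same level: channel gating of `Oi` by a learned
#' mask built from global-average-pooled descriptors, an edge branch that
#' concatenates `Fi`, an edge cue and the upsampled coarser decoder map
#' `f_next`, and a final 3x3 fusion convolution.
#'
#' @param model a `"tbnet"` object.
#' @param level scale index 1--4.
#' @param Oi,Fi `H_i x W_i x C_i` feature arrays.
#' @param f_next upsampled coarser decoder feature
#'   (`H_i x W_i x C_{i+1}`).
#' @return fused `H_i x W_i x C_i` feature array.
#' @export
tbnet_eca <- function(model, level, Oi, Fi, f_next) {
  if (!all(dim(Oi) == dim(Fi))) stop("Oi and Fi shapes differ")
  tape <- ad_tape()
  .fw_eca(tape, model$params, model$config, level, ad_node(Oi),
          ad_node(Fi), ad_node(f_next))$value
}

#' TBNet forward pass
#'
#' @param model a `"tbnet"` object.
#' @param image numeric matrix on the `[0, 255]` scale matching the
#'   configured input size.
#' @param details if `TRUE`, also return encoder features, token
#'   sequences and transformer outputs.
#' @return foreground probability matrix in `[0, 1]` with the input's
#'   spatial shape (or a detail list when `details = TRUE`).
#' @export
tbnet_forward <- function(model, image, details = FALSE) {
  tape <- ad_tape()
  out <- .fw_tbnet(tape, model$params, model$config, image,
                   details = details)
  if (details) {
    list(prob = out$prob$value[, , 1],
         encoder = lapply(out$encoder, `[[`, "value"),
         tokens = lapply(out$tokens$L, `[[`, "value"),
         O = lapply(out$O, `[[`, "value"))
  } else {
    out$value[, , 1]
  }
}
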