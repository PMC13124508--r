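# Patch encoders: continuous time embedding, transformable time-aware
# convolution (TTCN), irregular Fourier analysis network (IFAN), and the
# dual-domain fusion. The exported functions run the same tape code the
# trained model uses, on a one-patch tape, so there is a single
# implementation of each operation.

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

#' Continuous time-embedding parameters
#'
#' Channel 0 is linear in `t` (`omega_0 * t + alpha_0`); channels `d > 0` are
#' periodic (`sin(omega_d * t + alpha_d)`), with learnable frequencies and
#' phases.
#'
#' @param d_t Embedding dimension (default 10).
#' @param seed Integer seed for initialization.
#' @return Parameter list with 1 x `d_t` matrices `omega`, `alpha`.
#' @export
time_embed_params <- function(d_t = 10L, seed = 1L) {
  with_seed(seed, {
    omega <- matrix(c(1, 2 * pi * seq_len(d_t - 1L) / 2), 1L)
    alpha <- matrix(stats::runif(d_t, -0.1, 0.1), 1L)
    list(omega = omega, alpha = alpha, d_t = as.integer(d_t))
  })
}

tape_time_embed <- function(tape, tnode, omega, alpha) {
  p <- ad_add_bias(tape, ad_matmul(tape, tnode, omega), alpha)
  d_t <- ncol(omega$value)
  if (d_t == 1L) return(p)
  ad_cbind(tape, list(
    ad_slice_cols(tape, p, 1L),
    ad_sin(tape, ad_slice_cols(tape, p, 2:d_t))
  ))
}

#' Continuous time embedding of rescaled timestamps
#'
#' @param t Numeric vector of rescaled times in `[0, 1)`.
#' @param params A [time_embed_params()] list.
#' @return `length(t) x d_t` matrix.
#' @export
time_embed <- function(t, params) {
  tape <- ad_tape()
  tnode <- ad_const(tape, matrix(t, ncol = 1L))
  tape_time_embed(tape, tnode,
                  ad_const(tape, params$omega), ad_const(tape, params$alpha))$value
}

#' TTCN meta-network parameters
#'
#' One shared two-layer MLP per output channel generates, for every
#' observation in a patch, a score vector that is normalized channel-wise by a
#' softmax over the observation index; the resulting filter adapts its length
#' to the patch, so the parameter count is independent of how many
#' observations a patch holds.
#'
#' @param d_in Augmented input dimension (`d_t + d_v`).
#' @param d_time Number of output channels.
#' @param d_h Meta-network hidden size.
#' @param seed Integer seed.
#' @return Parameter list with per-channel weight matrices.
#' @export
ttcn_params <- function(d_in, d_time = 32L, d_h = 32L, seed = 1L) {
  with_seed(seed, {
    ks <- lapply(seq_len(d_time), function(k) {
      list(w1 = glorot(d_in, d_h), b1 = matrix(0, 1L, d_h),
           w2 = glorot(d_h, d_in), b2 = matrix(0, 1L, d_in))
    })
    list(channels = ks, d_in = as.integer(d_in), d_time = as.integer(d_time),
         d_h = as.integer(d_h))
  })
}

tape_ttcn <- function(tape, z, seg, nseg, ch_leaves) {
  cols <- lapply(ch_leaves, function(ch) {
    h <- ad_gelu(tape, ad_add_bias(tape, ad_matmul(tape, z, ch$w1), ch$b1))
    s <- ad_add_bias(tape, ad_matmul(tape, h, ch$w2), ch$b2)
    f <- ad_segment_softmax(tape, s, seg, nseg)
    ad_segment_wsum(tape, f, z, seg, nseg)
  })
  ad_cbind(tape, cols)
}

#' Encode one patch with the transformable time-aware convolution
#'
#' @param patch List with `t_rescaled` (in `[0,1)`) and `value` vectors, or a
#'   one-patch slice of a `patch_grid`.
#' @param time_params [time_embed_params()].
#' @param params [ttcn_params()] (its `d_in` must equal `d_t + 1`).
#' @return Numeric vector of length `d_time`. The generated filters are
#'   attached as attribute `"filters"` (list of `L x d_in` matrices, one per
#'   channel), each of which sums to 1 over observations in every column.
#' @export
ttcn_encode <- function(patch, time_params, params) {
  t <- patch$t_rescaled; v <- patch$value
  if (length(t) == 0L) stop("ttcn_encode requires a non-empty patch")
  tape <- ad_tape()
  tnode <- ad_const(tape, matrix(t, ncol = 1L))
  phi <- tape_time_embed(tape, tnode, ad_const(tape, time_params$omega),
                         ad_const(tape, time_params$alpha))
  z <- ad_cbind(tape, list(phi, ad_const(tape, matrix(v, ncol = 1L))))
  seg <- rep(1L, length(t))
  ch <- lapply(params$channels, function(p) lapply(p, ad_const, tape = tape))
  out <- tape_ttcn(tape, z, seg, 1L, ch)
  filters <- lapply(params$channels, function(p) {
    s <- gelu(z$value %*% p$w1 + matrix(p$b1, length(t), ncol(p$b1), byrow = TRUE)) %*%
      p$w2 + matrix(p$b2, length(t), ncol(p$b2), byrow = TRUE)
    e <- exp(sweep(s, 2L, apply(s, 2L, max)))
    sweep(e, 2L, colSums(e), "/")
  })
  structure(as.vector(out$value), filters = filters)
}

#' IFAN parameters
#'
#' A stack of time-aware Fourier analysis layers. Layer `l` maps its input
#' `x` and the rescaled timestamp `t` to
#' `[cos(W_p x + U_p t) || sin(W_p x + U_p t) || GELU(B + W x + V t)]`, so its
#' output width is `2 d_p + d_pbar`; layer 1 takes the raw observation value.
#'
#' @param d_v Observation value dimension (layer-1 input).
#' @param d_freq Target output width; split as `d_p = ceiling(d_freq / 4)`,
#'   `d_pbar = d_freq - 2 d_p` (half the width to the non-linear branch).
#' @param n_layers Depth `L_IFAN`.
#' @param seed Integer seed.
#' @return Parameter list with one weight set per layer.
#' @export
ifan_params <- function(d_v = 1L, d_freq = 32L, n_layers = 2L, seed = 1L) {
  d_p <- ceiling(d_freq / 4)
  d_pbar <- d_freq - 2L * d_p
  stopifnot(d_pbar >= 1L)
  with_seed(seed, {
    d_in <- d_v
    layers <- lapply(seq_len(n_layers), function(l) {
      # periodic time weights start as a Fourier-series basis on the patch
      # (integer harmonics of the rescaled within-patch time) — a frequency
      # is hard to reach by gradient descent when initialized far from it
      fgrid <- 2 * pi * seq_len(d_p)
      out <- list(wp = glorot(d_in, d_p),
                  up = matrix(fgrid * sample(c(-1, 1), d_p, replace = TRUE), 1L),
                  wpb = glorot(d_in, d_pbar), vpb = glorot(1L, d_pbar),
                  bpb = matrix(0, 1L, d_pbar))
      d_in <<- 2L * d_p + d_pbar
      out
    })
    list(layers = layers, d_p = as.integer(d_p), d_pbar = as.integer(d_pbar),
         d_freq = as.integer(2L * d_p + d_pbar), n_layers = as.integer(n_layers))
  })
}

tape_ifan <- function(tape, x0, tnode, layer_leaves) {
  x <- x0
  for (ly in layer_leaves) {
    u <- ad_add(tape, ad_matmul(tape, x, ly$wp), ad_matmul(tape, tnode, ly$up))
    g <- ad_gelu(tape, ad_add_bias(
      tape,
      ad_add(tape, ad_matmul(tape, x, ly$wpb), ad_matmul(tape, tnode, ly$vpb)),
      ly$bpb
    ))
    x <- ad_cbind(tape, list(ad_cos(tape, u), ad_sin(tape, u), g))
  }
  x
}

#' Encode one patch with the irregular Fourier analysis network
#'
#' Observations are transformed point-wise by the shared IFAN layers (the
#' rescaled timestamp modulates both the periodic and the non-linear branch)
#' and mean-pooled, so the result is invariant to observation order.
#'
#' @inheritParams ttcn_encode
#' @param params [ifan_params()].
#' @return Numeric vector of length `2 d_p + d_pbar`.
#' @export
ifan_encode <- function(patch, params) {
  t <- patch$t_rescaled; v <- patch$value
  if (length(t) == 0L) stop("ifan_encode requires a non-empty patch")
  tape <- ad_tape()
  tnode <- ad_const(tape, matrix(t, ncol = 1L))
  x0 <- ad_const(tape, matrix(v, ncol = 1L))
  layers <- lapply(params$layers, function(p) lapply(p, ad_const, tape = tape))
  x <- tape_ifan(tape, x0, tnode, layers)
  out <- ad_segment_mean(tape, x, rep(1L, length(t)), 1L)
  as.vector(out$value)
}

#' Dual-domain fusion parameters
#' @param d_time,d_freq Widths of the temporal and frequency embeddings.
#' @param d_fused Output width.
#' @param n_scales Number of patch scales (one empty-patch token per scale).
#' @param seed Integer seed.
#' @return Parameter list (`w`, `b`, `empty_tokens`).
#' @export
fusion_params <- function(d_time = 32L, d_freq = 32L, d_fused = 64L,
                          n_scales = 5L, seed = 1L) {
  with_seed(seed, list(
    w = glorot(d_time + d_freq, d_fused), b = matrix(0, 1L, d_fused),
    empty_tokens = matrix(stats::rnorm(n_scales * d_fused, 0, 0.02),
                          n_scales, d_fused)
  ))
}

#' Fuse the two patch embeddings into a dual-domain embedding
#'
#' Concatenation followed by a linear projection. An empty patch has no
#' observations to encode, so it is represented by the learned per-scale
#' empty-patch token instead, flagged via the `"empty"` attribute.
#'
#' @param h_time Temporal embedding (or `NULL` for an empty patch).
#' @param h_freq Frequency embedding (or `NULL`).
#' @param params [fusion_params()].
#' @param empty Set `TRUE` for an empty patch.
#' @param scale_idx Scale index of the patch (selects the empty token).
#' @return Numeric vector of length `d_fused` with attribute `empty`.
#' @export
fuse_patch <- function(h_time, h_freq, params, empty = FALSE, scale_idx = 1L) {
  if (empty) {
    return(structure(as.vector(params$empty_tokens[scale_idx, ]), empty = TRUE))
  }
  h <- c(h_time, h_freq)
  if (length(h) != nrow(params$w)) stop("embedding width does not match fusion weights")
  structure(as.vector(h %*% params$w + params$b), empty = FALSE)
}

#' Multi-scale fusion parameters (canonical-interval projection)
#' @param n_scales Number of scales `S`.
#' @param d_fused Patch embedding width.
#' @param d_input_tf Output token width.
#' @param seed Integer seed.
#' @return Parameter list (`w`, `b`).
#' @export
scale_fusion_params <- function(n_scales, d_fused, d_input_tf = 64L, seed = 1L) {
  with_seed(seed, list(w = glorot(n_scales * d_fused, d_input_tf),
                       b = matrix(0, 1L, d_input_tf)))
}

#' Fuse the per-scale embeddings of one canonical interval
#'
#' `m = GELU(W [h^(1) || ... || h^(S)] + b)`, the token handed to the
#' temporal transformer.
#'
#' @param embeddings List of `S` numeric vectors (fixed scale order) or a
#'   matrix with one row per scale.
#' @param params [scale_fusion_params()].
#' @return Numeric vector of length `d_input_tf`.
#' @export
fuse_scales <- function(embeddings, params) {
  if (is.matrix(embeddings)) embeddings <- asplit(embeddings, 1L)
  h <- unlist(embeddings, use.names = FALSE)
  if (length(h) != nrow(params$w)) {
    stop("expected ", nrow(params$w), " concatenated features, got ", length(h))
  }
  as.vector(gelu(h %*% params$w + params$b))
}

#' Map multi-scale patch embeddings onto the canonical timeline
#'
#' For canonical interval `k` (finest scale), the scale-`s` representative is
#' the unique scale-`s` patch whose span covers the interval
#' (`p = ceiling(k L_1 / L_s)`); coarse patches are replicated across every
#' canonical interval they cover.
#'
#' @param spec A [patch_spec()].
#' @return Integer matrix `P_1 x S`: entry `[k, s]` is the representative
#'   patch index of scale `s` for canonical interval `k`.
#' @export
align_to_canonical <- function(spec) {
  p1 <- patch_counts(spec)[1L]
  out <- vapply(seq_along(spec$scales), function(s) {
    covering_patch(seq_len(p1), spec$scales[s], spec)
  }, integer(p1))
  matrix(out, nrow = p1,
         dimnames = list(NULL, paste0("scale", seq_along(spec$scales))))
}

#' Time-aware prediction head
#'
#' Maps the last-interval context vector of a variable and a normalized
#' future timestamp `t_fut = (tau - T)/H` to a forecast: the context passes
#' through a time-aware Fourier layer
#' `[cos(W_p x + U_p t) || sin(W_p x + U_p t) || GELU(B + W x + V t)]`
#' followed by a linear output projection.
#'
#' @param context `n x d` matrix of context vectors (one row per query).
#' @param t_future Normalized future times in `(0, 1]`, length `n`.
#' @param params List with `wp` (`d x d_p`), `up` (`1 x d_p`), `wpb`, `vpb`,
#'   `bpb`, `wout` (`(2 d_p + d_pbar) x d_v`), `bout` — the `hd_*` entries of
#'   a fitted model, without the prefix.
#' @return `n x d_v` matrix of predictions, with the pre-projection features
#'   attached as attribute `"features"`.
#' @export
prediction_head <- function(context, t_future, params) {
  tf_ <- matrix(t_future, ncol = 1L)
  u <- context %*% params$wp + tf_ %*% params$up
  g <- gelu(sweep(context %*% params$wpb + tf_ %*% params$vpb, 2L,
                  params$bpb, "+"))
  z <- cbind(cos(u), sin(u), g)
  structure(sweep(z %*% params$wout, 2L, params$bout, "+"), features = z)
}

# fixed sinusoidal positional encodings, one row per position
pe_table <- function(maxlen, d) {
  pos <- seq_len(maxlen)
  out <- matrix(0, maxlen, d)
  for (j in seq_len(ceiling(d / 2))) {
    w <- 1 / 10000^((2 * (j - 1)) / d)
    out[, 2L * j - 1L] <- sin(pos * w)
    if (2L * j <= d) out[, 2L * j] <- cos(pos * w)
  }
  out
}

#' Transformer encoder parameters (pre-norm, single stack)
#' @param d Token width (`d_input_tf`), divisible by `n_heads`.
#' @param n_heads Attention heads.
#' @param n_layers Encoder layers.
#' @param ff_mult Feed-forward width multiplier.
#' @param seed Integer seed.
#' @return Parameter list, one element per layer.
#' @export
transformer_params <- function(d, n_heads = 1L, n_layers = 1L, ff_mult = 4L,
                               seed = 1L) {
  if (d %% n_heads != 0L) stop("d must be divisible by n_heads")
  with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(l) list(
      ln1_g = matrix(1, 1L, d), ln1_b = matrix(0, 1L, d),
      wq = glorot(d, d), wk = glorot(d, d), wv = glorot(d, d),
      wo = glorot(d, d), bo = matrix(0, 1L, d),
      ln2_g = matrix(1, 1L, d), ln2_b = matrix(0, 1L, d),
      w1 = glorot(d, ff_mult * d), b1 = matrix(0, 1L, ff_mult * d),
      w2 = glorot(ff_mult * d, d), b2 = matrix(0, 1L, d)
    ))
    list(layers = layers, d = as.integer(d), n_heads = as.integer(n_heads))
  })
}

tape_transformer <- function(tape, x, lens, layer_leaves, n_heads,
                             dropout = 0, train = FALSE) {
  d <- ncol(x$value)
  dh <- d %/% n_heads
  maybe_drop <- function(node) {
    if (!train || dropout <= 0) return(node)
    mask <- matrix(stats::rbinom(length(node$value), 1L, 1 - dropout),
                   nrow(node$value)) / (1 - dropout)
    ad_mul(tape, node, ad_const(tape, mask))
  }
  for (ly in layer_leaves) {
    h1 <- ad_layernorm(tape, x, ly$ln1_g, ly$ln1_b)
    q <- ad_matmul(tape, h1, ly$wq)
    k <- ad_matmul(tape, h1, ly$wk)
    v <- ad_matmul(tape, h1, ly$wv)
    heads <- lapply(seq_len(n_heads), function(h) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      ad_block_attention(tape,
                         ad_slice_cols(tape, q, idx),
                         ad_slice_cols(tape, k, idx),
                         ad_slice_cols(tape, v, idx), lens)
    })
    att <- if (n_heads == 1L) heads[[1L]] else ad_cbind(tape, heads)
    att <- ad_add_bias(tape, ad_matmul(tape, att, ly$wo), ly$bo)
    x <- ad_add(tape, x, maybe_drop(att))
    h2 <- ad_layernorm(tape, x, ly$ln2_g, ly$ln2_b)
    ff <- ad_add_bias(tape, ad_matmul(
      tape,
      maybe_drop(ad_gelu(tape, ad_add_bias(tape, ad_matmul(tape, h2, ly$w1), ly$b1))),
      ly$w2
    ), ly$b2)
    x <- ad_add(tape, x, maybe_drop(ff))
  }
  x
}

#' Contextualize a variable's canonical-interval token sequence
#'
#' Pre-norm transformer encoder applied to one variable's sequence of fused
#' multi-scale tokens (channel-independent: each variable is processed
#' separately). Fixed sinusoidal positional encodings are added to the input.
#'
#' @param m `P_1 x d` matrix of fused tokens.
#' @param params [transformer_params()].
#' @param positional Add sinusoidal positional encodings (default `TRUE`).
#' @return `P_1 x d` matrix of contextualized tokens.
#' @export
contextualize <- function(m, params, positional = TRUE) {
  tape <- ad_tape()
  if (positional) m <- m + pe_table(nrow(m), ncol(m))
  x <- ad_const(tape, m)
  layers <- lapply(params$layers, function(p) lapply(p, ad_const, tape = tape))
  tape_transformer(tape, x, lens = nrow(m), layers, params$n_heads)$value
}
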