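# Reverse-mode automatic differentiation on a linear tape.
#
# Every node holds a numeric matrix `value`; operations append a node whose
# `backfn(grad)` returns one gradient per parent. Backward walks the tape in
# reverse, accumulating gradients. All shapes are matrices (vectors are n x 1
# or 1 x n); backward rules are checked against central finite differences in
# the test suite.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

ad_node <- function(tape, value, parents = NULL, backfn = NULL, leaf = FALSE) {
  stopifnot(is.numeric(value))
  if (!is.matrix(value)) value <- matrix(value, ncol = 1L)
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node <- list(
    id = tape$n, value = value,
    parents = if (is.null(parents)) integer(0) else vapply(parents, `[[`, 0L, "id"),
    backfn = backfn, leaf = leaf
  )
  tape$nodes[[tape$n]] <- node
  node
}

ad_leaf <- function(tape, value) ad_node(tape, value, leaf = TRUE)
ad_const <- function(tape, value) ad_node(tape, value, leaf = FALSE)

#' @noRd
ad_backward <- function(tape, root) {
  grads <- vector("list", tape$n)
  grads[[root$id]] <- matrix(1, nrow(root$value), ncol(root$value))
  for (id in seq(tape$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$backfn) || length(node$parents) == 0L) next
    pg <- node$backfn(g)
    for (j in seq_along(node$parents)) {
      if (is.null(pg[[j]])) next
      pid <- node$parents[j]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
    grads[[id]] <- NULL # free
  }
  grads
}

# ---- primitive ops ---------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

# x (m x n) + bias (1 x n), broadcast over rows
ad_add_bias <- function(tape, x, b) {
  xv <- x$value
  bv <- b$value
  val <- xv + matrix(bv, nrow(xv), ncol(xv), byrow = TRUE)
  ad_node(tape, val, list(x, b),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(g) list(g * k))
}

ad_add_constm <- function(tape, a, m) {
  ad_node(tape, a$value + m, list(a), function(g) list(g))
}

ad_sin <- function(tape, a) {
  av <- a$value
  ad_node(tape, sin(av), list(a), function(g) list(g * cos(av)))
}

ad_cos <- function(tape, a) {
  av <- a$value
  ad_node(tape, cos(av), list(a), function(g) list(-g * sin(av)))
}

ad_relu <- function(tape, a) {
  av <- a$value
  ad_node(tape, pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

# exact GELU x * pnorm(x); derivative pnorm(x) + x * dnorm(x)
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

ad_gelu <- function(tape, a) {
  av <- a$value
  ph <- stats::pnorm(av)
  ad_node(tape, av * ph, list(a),
          function(g) list(g * (ph + av * stats::dnorm(av))))
}

ad_square <- function(tape, a) {
  av <- a$value
  ad_node(tape, av * av, list(a), function(g) list(2 * g * av))
}

ad_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, `[[`, "value")
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# rows of x selected by idx (with repetition); backward scatter-adds
ad_gather_rows <- function(tape, x, idx) {
  xv <- x$value
  nr <- nrow(xv)
  ad_node(tape, xv[idx, , drop = FALSE], list(x), function(g) {
    gi <- rowsum(g, group = idx, reorder = FALSE)
    out <- matrix(0, nr, ncol(xv))
    out[as.integer(rownames(gi)), ] <- gi
    list(out)
  })
}

# Fill an n_out-row matrix: row r gets tokens[tok_idx[r], ] unless r is in
# filled_idx, in which case it gets the corresponding row of x. Used to place
# per-scale empty-patch tokens behind encoded non-empty patches.
ad_scatter_fill <- function(tape, x, tokens, filled_idx, tok_idx, n_out) {
  xv <- x$value; tv <- tokens$value
  val <- tv[tok_idx, , drop = FALSE]
  val[filled_idx, ] <- xv
  empty_rows <- setdiff(seq_len(n_out), filled_idx)
  ad_node(tape, val, list(x, tokens), function(g) {
    gt <- matrix(0, nrow(tv), ncol(tv))
    if (length(empty_rows)) {
      gi <- rowsum(g[empty_rows, , drop = FALSE],
                   group = tok_idx[empty_rows], reorder = FALSE)
      gt[as.integer(rownames(gi)), ] <- gi
    }
    list(g[filled_idx, , drop = FALSE], gt)
  })
}

ad_slice_cols <- function(tape, x, idx) {
  xv <- x$value
  ad_node(tape, xv[, idx, drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(xv), ncol(xv))
    out[, idx] <- g
    list(out)
  })
}

# row-wise softmax
ad_row_softmax <- function(tape, x) {
  xv <- x$value
  m <- apply(xv, 1L, max)
  e <- exp(xv - m)
  p <- e / rowSums(e)
  ad_node(tape, p, list(x), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# softmax over rows within contiguous segments, per column (channel-wise
# softmax over the observation index). Column-max subtraction guards overflow.
ad_segment_softmax <- function(tape, x, seg, nseg) {
  xv <- x$value
  cm <- matrix(apply(xv, 2L, max), nrow(xv), ncol(xv), byrow = TRUE)
  e <- exp(xv - cm)
  denom <- rowsum(e, seg, reorder = FALSE)
  p <- e / denom[seg, , drop = FALSE]
  ad_node(tape, p, list(x), function(g) {
    s <- rowsum(g * p, seg, reorder = FALSE)
    list(p * (g - s[seg, , drop = FALSE]))
  })
}

# per-segment mean of rows
ad_segment_mean <- function(tape, x, seg, nseg) {
  xv <- x$value
  cnt <- as.vector(rowsum(rep(1, nrow(xv)), seg, reorder = FALSE))
  val <- rowsum(xv, seg, reorder = FALSE) / cnt
  ad_node(tape, val, list(x), function(g) {
    list((g / cnt)[seg, , drop = FALSE])
  })
}

# per-segment sum of rowSums(f * z): the transformable-convolution
# aggregation h[k] = sum_j f_k[j]^T z_j, one output column per call
ad_segment_wsum <- function(tape, f, z, seg, nseg) {
  fv <- f$value; zv <- z$value
  val <- rowsum(rowSums(fv * zv), seg, reorder = FALSE)
  ad_node(tape, matrix(val, ncol = 1L), list(f, z), function(g) {
    gr <- g[seg, 1L]
    list(gr * zv, gr * fv)
  })
}

ad_sum <- function(tape, x) {
  xv <- x$value
  ad_node(tape, matrix(sum(xv), 1L, 1L), list(x), function(g) {
    list(matrix(g[1L, 1L], nrow(xv), ncol(xv)))
  })
}

# row-wise layer normalization with learnable gain/bias (1 x d each)
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- gamma$value
  val <- xhat * matrix(gv, nrow(xv), d, byrow = TRUE) +
    matrix(beta$value, nrow(xv), d, byrow = TRUE)
  ad_node(tape, val, list(x, gamma, beta), function(g) {
    ggam <- matrix(colSums(g * xhat), 1L)
    gbet <- matrix(colSums(g), 1L)
    gh <- g * matrix(gv, nrow(xv), d, byrow = TRUE)
    gx <- inv * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat))
    list(gx, ggam, gbet)
  })
}

# Scaled dot-product self-attention over contiguous equal-role sequences.
# q, k, v: (sum(len) x d) stacked by sequence; lens gives each sequence's
# length. Single head.
ad_block_attention <- function(tape, q, k, v, lens) {
  qv <- q$value; kv <- k$value; vv <- v$value
  d <- ncol(qv)
  sc <- 1 / sqrt(d)
  ends <- cumsum(lens); starts <- ends - lens + 1L
  nb <- length(lens)
  out <- matrix(0, nrow(qv), d)
  probs <- vector("list", nb)
  for (b in seq_len(nb)) {
    r <- starts[b]:ends[b]
    s <- (qv[r, , drop = FALSE] %*% t(kv[r, , drop = FALSE])) * sc
    m <- apply(s, 1L, max)
    e <- exp(s - m)
    p <- e / rowSums(e)
    probs[[b]] <- p
    out[r, ] <- p %*% vv[r, , drop = FALSE]
  }
  ad_node(tape, out, list(q, k, v), function(g) {
    gq <- matrix(0, nrow(qv), d); gk <- gq; gv_ <- gq
    for (b in seq_len(nb)) {
      r <- starts[b]:ends[b]
      p <- probs[[b]]
      gb <- g[r, , drop = FALSE]
      gv_[r, ] <- t(p) %*% gb
      gp <- gb %*% t(vv[r, , drop = FALSE])
      gs <- p * (gp - rowSums(gp * p))
      gq[r, ] <- (gs %*% kv[r, , drop = FALSE]) * sc
      gk[r, ] <- (t(gs) %*% qv[r, , drop = FALSE]) * sc
    }
    list(gq, gk, gv_)
  })
}

# Per-interval graph construction + GCN aggregation, batched over contiguous
# blocks of N rows (one block = one canonical interval of one episode).
#   per block: S = Es Et^T; A = rowSoftmax(ReLU(S)); Ahat = A + I;
#              Abar = D^-1/2 Ahat D^-1/2; out = GELU(Abar %*% M %*% Wgnn)
# Returns the node plus the adjacency array (N x N x nblocks) as an attribute
# on the tape for graph summaries.
# Vectorized across blocks: all quantities are held as (nb, i, j) arrays so
# the loops run over the N^2 variable pairs, not over the (much larger)
# number of interval blocks.
ad_graph_gcn <- function(tape, es, et, m, wgnn, n_vars, store_adj = FALSE) {
  esv <- es$value; etv <- et$value; mv <- m$value; wv <- wgnn$value
  N <- n_vars
  nb <- nrow(esv) / N
  stopifnot(nb == as.integer(nb))
  nb <- as.integer(nb)
  ridx <- lapply(seq_len(N), function(i) seq.int(i, nb * N, by = N))
  Es <- lapply(ridx, function(r) esv[r, , drop = FALSE])
  Et <- lapply(ridx, function(r) etv[r, , drop = FALSE])
  Mv <- lapply(ridx, function(r) mv[r, , drop = FALSE])
  S <- array(0, c(nb, N, N))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    S[, i, j] <- rowSums(Es[[i]] * Et[[j]])
  }
  Rl <- pmax(S, 0)
  mx <- Rl[, , 1L]
  for (j in seq_len(N)[-1L]) mx <- pmax(mx, Rl[, , j])
  E <- exp(Rl - as.vector(mx)) # recycles over j
  denom <- rowSums(E, dims = 2L)
  A <- E / as.vector(denom)
  Ahat <- A
  for (i in seq_len(N)) Ahat[, i, i] <- Ahat[, i, i] + 1
  dg <- rowSums(Ahat, dims = 2L) # (nb, i)
  rinv <- 1 / sqrt(dg)
  Abar <- Ahat
  for (i in seq_len(N)) for (j in seq_len(N)) {
    Abar[, i, j] <- Ahat[, i, j] * rinv[, i] * rinv[, j]
  }
  D <- ncol(mv)
  Hfull <- matrix(0, nb * N, D)
  for (i in seq_len(N)) {
    acc <- matrix(0, nb, D)
    for (j in seq_len(N)) acc <- acc + Abar[, i, j] * Mv[[j]]
    Hfull[ridx[[i]], ] <- acc
  }
  P <- Hfull %*% wv
  phP <- stats::pnorm(P)
  out <- P * phP
  adj <- if (store_adj) aperm(A, c(2L, 3L, 1L)) else NULL
  node <- ad_node(tape, out, list(es, et, m, wgnn), function(g) {
    gP <- g * (phP + P * stats::dnorm(P))
    gw <- crossprod(Hfull, gP)
    gHfull <- gP %*% t(wv)
    gH <- lapply(ridx, function(r) gHfull[r, , drop = FALSE])
    gAbar <- array(0, c(nb, N, N))
    gm <- matrix(0, nrow(mv), ncol(mv))
    for (j in seq_len(N)) {
      accM <- matrix(0, nb, D)
      for (i in seq_len(N)) {
        gAbar[, i, j] <- rowSums(gH[[i]] * Mv[[j]])
        accM <- accM + Abar[, i, j] * gH[[i]]
      }
      gm[ridx[[j]], ] <- accM
    }
    gAhat <- array(0, c(nb, N, N))
    grinv <- matrix(0, nb, N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      gAhat[, i, j] <- gAbar[, i, j] * rinv[, i] * rinv[, j]
      grinv[, i] <- grinv[, i] + gAbar[, i, j] * Ahat[, i, j] * rinv[, j]
      grinv[, j] <- grinv[, j] + gAbar[, i, j] * Ahat[, i, j] * rinv[, i]
    }
    gdg <- -0.5 * dg^(-1.5) * grinv
    gAhat <- gAhat + as.vector(gdg) # d_i = sum_j Ahat_ij, broadcast over j
    rowdot <- rowSums(gAhat * A, dims = 2L)
    gS <- A * (gAhat - as.vector(rowdot)) * (S > 0)
    ges <- matrix(0, nrow(esv), ncol(esv))
    get_ <- matrix(0, nrow(etv), ncol(etv))
    for (i in seq_len(N)) {
      accE <- matrix(0, nb, ncol(esv))
      for (j in seq_len(N)) accE <- accE + gS[, i, j] * Et[[j]]
      ges[ridx[[i]], ] <- accE
    }
    for (j in seq_len(N)) {
      accE <- matrix(0, nb, ncol(etv))
      for (i in seq_len(N)) accE <- accE + gS[, i, j] * Es[[i]]
      get_[ridx[[j]], ] <- accE
    }
    list(ges, get_, gm, gw)
  })
  list(node = node, adjacency = adj)
}
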