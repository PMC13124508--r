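#' Model configuration
#'
#' Collects every architectural and training hyperparameter of the
#' forecaster. Defaults follow the reference setting: hidden width 64, scale
#' set `{1, 2, 4, 8, 24}` h over a 24 h window with a 24 h horizon, time and
#' graph embedding width 10, one attention head, one transformer layer, one
#' intra/inter modelling block, Adam at learning rate 0.001, batch size 32,
#' early-stopping patience 20.
#'
#' @param scales Patch duration scales (hours).
#' @param window_end,horizon Observation window end `T` and horizon `H` (hours).
#' @param d_v Observation value dimension (1 for scalar vitals).
#' @param d_t Time-embedding width.
#' @param d_time,d_freq,d_fused TTCN / IFAN / fused patch embedding widths.
#' @param d_input_tf Canonical-interval token width.
#' @param d_h TTCN meta-network hidden width.
#' @param l_ifan IFAN depth.
#' @param d_fourier Number of Lomb-Scargle probe frequencies.
#' @param d_g Graph source/target embedding width.
#' @param n_heads,n_layers_tf,ff_mult,dropout Transformer settings.
#' @param n_blocks Number of stacked intra/inter modelling blocks `K`.
#' @param alpha Horizon-weight slope of the interval-weighted loss.
#' @param lr,batch_size,patience,max_epochs,grad_clip Training protocol.
#' @param no_patching,single_scale,no_frequency,no_transformer,no_graph
#'   Ablation switches (`-P`, `-M`, `-F`, `-T`, `-G`).
#' @return A `model_config` list.
#' @export
model_config <- function(scales = c(1, 2, 4, 8, 24), window_end = 24,
                         horizon = 24, d_v = 1L, d_t = 10L,
                         d_time = 32L, d_freq = 32L, d_fused = 64L,
                         d_input_tf = 64L, d_h = 32L, l_ifan = 2L,
                         d_fourier = 10L, d_g = 10L,
                         n_heads = 1L, n_layers_tf = 1L, ff_mult = 4L,
                         dropout = 0.1, n_blocks = 1L, alpha = 0.1,
                         lr = 0.001, batch_size = 32L, patience = 20L,
                         max_epochs = 100L, grad_clip = 5,
                         no_patching = FALSE, single_scale = FALSE,
                         no_frequency = FALSE, no_transformer = FALSE,
                         no_graph = FALSE) {
  if (single_scale) scales <- scales[1L]
  cfg <- list(
    scales = scales, window_end = window_end, horizon = horizon,
    d_v = as.integer(d_v), d_t = as.integer(d_t), d_time = as.integer(d_time),
    d_freq = as.integer(d_freq), d_fused = as.integer(d_fused),
    d_input_tf = as.integer(d_input_tf), d_h = as.integer(d_h),
    l_ifan = as.integer(l_ifan), d_fourier = as.integer(d_fourier),
    d_g = as.integer(d_g), n_heads = as.integer(n_heads),
    n_layers_tf = as.integer(n_layers_tf), ff_mult = as.integer(ff_mult),
    dropout = dropout, n_blocks = as.integer(n_blocks), alpha = alpha,
    lr = lr, batch_size = as.integer(batch_size),
    patience = as.integer(patience), max_epochs = as.integer(max_epochs),
    grad_clip = grad_clip,
    no_patching = no_patching, single_scale = single_scale,
    no_frequency = no_frequency, no_transformer = no_transformer,
    no_graph = no_graph
  )
  cfg$spec <- if (!no_patching) patch_spec(scales, window_end) else NULL
  cfg$n_scales <- if (no_patching) 1L else length(scales)
  structure(cfg, class = "model_config")
}

#' A reduced-width configuration preset for desk-scale experiments
#'
#' Same architecture, smaller widths (token width 16, 8 TTCN channels, IFAN
#' width 16) so that full training studies run on a single CPU.
#'
#' @param ... Overrides passed on to [model_config()].
#' @return A `model_config`.
#' @export
model_config_small <- function(...) {
  args <- list(d_t = 6L, d_time = 8L, d_freq = 16L, d_fused = 16L,
               d_input_tf = 16L, d_h = 8L, d_fourier = 6L, d_g = 6L,
               ff_mult = 2L, dropout = 0, max_epochs = 30L, patience = 5L)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

#' Initialize model parameters
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the parameter-initialization stream (kept
#'   separate from data-order streams).
#' @return An `imts_model`: list with `config` and the flat named parameter
#'   list `params`.
#' @export
init_model <- function(config, seed = 1L) {
  cfg <- config
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 64L))
  si <- 0L; nxt <- function() { si <<- si + 1L; sub[si] }
  p <- list()
  te <- time_embed_params(cfg$d_t, nxt())
  p$te_omega <- te$omega; p$te_alpha <- te$alpha
  d_in <- cfg$d_t + cfg$d_v
  tt <- ttcn_params(d_in, cfg$d_time, cfg$d_h, nxt())
  for (k in seq_len(cfg$d_time)) {
    p[[paste0("ttcn", k, "_w1")]] <- tt$channels[[k]]$w1
    p[[paste0("ttcn", k, "_b1")]] <- tt$channels[[k]]$b1
    p[[paste0("ttcn", k, "_w2")]] <- tt$channels[[k]]$w2
    p[[paste0("ttcn", k, "_b2")]] <- tt$channels[[k]]$b2
  }
  if (!cfg$no_frequency) {
    ifp <- ifan_params(cfg$d_v, cfg$d_freq, cfg$l_ifan, nxt())
    for (l in seq_len(cfg$l_ifan)) {
      for (nm in names(ifp$layers[[l]])) {
        p[[paste0("ifan", l, "_", nm)]] <- ifp$layers[[l]][[nm]]
      }
    }
    d_freq_eff <- ifp$d_freq
  } else {
    d_freq_eff <- 0L
  }
  fus <- fusion_params(cfg$d_time, d_freq_eff, cfg$d_fused, cfg$n_scales, nxt())
  p$fus_w <- fus$w; p$fus_b <- fus$b; p$etok <- fus$empty_tokens
  ms <- scale_fusion_params(cfg$n_scales, cfg$d_fused, cfg$d_input_tf, nxt())
  p$ms_w <- ms$w; p$ms_b <- ms$b
  d_fourier_eff <- if (cfg$no_frequency) 0L else cfg$d_fourier
  for (b in seq_len(cfg$n_blocks)) {
    if (!cfg$no_transformer) {
      tfp <- transformer_params(cfg$d_input_tf, cfg$n_heads, cfg$n_layers_tf,
                                cfg$ff_mult, nxt())
      for (l in seq_len(cfg$n_layers_tf)) {
        for (nm in names(tfp$layers[[l]])) {
          p[[paste0("bl", b, "_tf", l, "_", nm)]] <- tfp$layers[[l]][[nm]]
        }
      }
    }
    if (!cfg$no_graph) {
      gp <- graph_params(cfg$d_input_tf + d_fourier_eff, cfg$d_g,
                         cfg$d_input_tf, nxt())
      p[[paste0("bl", b, "_g_ws")]] <- gp$w_source
      p[[paste0("bl", b, "_g_wt")]] <- gp$w_target
      p[[paste0("bl", b, "_g_wgnn")]] <- gp$w_gnn
    }
  }
  hs <- with_seed(nxt(), {
    d_p <- ceiling(cfg$d_freq / 4); d_pb <- cfg$d_freq - 2L * d_p
    # head time weights start as a Fourier-series basis on the horizon
    # (integer harmonics; with the cos/sin pair this spans every phase up to
    # order d_p) — frequencies are poor gradient-descent targets when
    # initialized off-harmonic; the context-to-phase coupling starts small
    # so the periodic basis is not scrambled by episode-specific phase
    # offsets before the time pathway has been learned
    fgrid <- 2 * pi * seq_len(d_p)
    list(wp = 0.05 * glorot(cfg$d_input_tf, d_p),
         up = matrix(fgrid * sample(c(-1, 1), d_p, replace = TRUE), 1L),
         wpb = glorot(cfg$d_input_tf, d_pb), vpb = glorot(1L, d_pb),
         bpb = matrix(0, 1L, d_pb),
         wout = glorot(2L * d_p + d_pb, cfg$d_v), bout = matrix(0, 1L, cfg$d_v))
  })
  for (nm in names(hs)) p[[paste0("hd_", nm)]] <- hs[[nm]]
  structure(list(config = cfg, params = p), class = "imts_model")
}

#' Number of trainable parameters
#' @param model An `imts_model` or `imts_fit`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

# ---- per-episode preparation ----------------------------------------------

# precompute patch assignments, spectral features and query rows for one
# episode (values must already be standardized)
prepare_episode <- function(obs, queries, config, probe_freqs) {
  cfg <- config
  out <- list(queries = queries)
  if (cfg$no_patching) {
    ut <- sort(unique(obs$time_hours))
    P <- length(ut)
    out$P <- P
    d <- data.frame(i = obs$variable_id, p = match(obs$time_hours, ut),
                    t = 0, v = obs$value)
    out$scale_tabs <- list(d[order(d$i, d$p), ])
    out$P_s <- P
  } else {
    spec <- cfg$spec
    P <- patch_counts(spec)[1L]
    out$P <- P
    out$P_s <- patch_counts(spec)
    out$scale_tabs <- lapply(seq_along(spec$scales), function(s) {
      L <- spec$scales[s]
      p <- patch_index(obs$time_hours, L, spec)
      d <- data.frame(i = obs$variable_id, p = p,
                      t = rescale_time(obs$time_hours, p, L), v = obs$value)
      d[order(d$i, d$p, d$t), ]
    })
  }
  out
}

prepare_cohort <- function(cohort, config, probe_freqs) {
  cfg <- config
  n <- cohort$n_variables
  cfg$n_variables_cache <- n
  ids <- episode_ids(cohort)
  obs_split <- split(cohort$observations, cohort$observations$episode_id)
  qry_split <- split(cohort$queries, cohort$queries$episode_id)
  d_fourier_eff <- if (cfg$no_frequency) 0L else cfg$d_fourier
  preps <- lapply(ids, function(id) {
    obs <- obs_split[[id]]
    if (is.null(obs)) obs <- cohort$observations[0, ]
    qr <- qry_split[[id]]
    if (is.null(qr)) qr <- cohort$queries[0, ]
    pe <- prepare_episode(obs, qr, cfg, probe_freqs)
    pe$id <- id
    pe$n_vars <- n
    # spectral features, rows ordered (k, i)
    if (d_fourier_eff > 0L && !cfg$no_patching) {
      spec <- cfg$spec
      ls_scale <- spec$scales[length(spec$scales)]
      n_coarse <- patch_counts(spec)[length(spec$scales)]
      per_coarse <- array(0, c(n, n_coarse, d_fourier_eff))
      for (i in seq_len(n)) {
        oi <- obs[obs$variable_id == i, ]
        for (pc in seq_len(n_coarse)) {
          lo <- (pc - 1) * ls_scale
          hi <- min(pc * ls_scale, spec$window_end)
          sel <- oi$time_hours >= lo &
            (oi$time_hours < hi | hi >= spec$window_end)
          if (sum(sel) >= 3L) {
            per_coarse[i, pc, ] <- lomb_scargle_power(
              oi$time_hours[sel], oi$value[sel], probe_freqs
            )
          }
        }
      }
      lm <- matrix(0, pe$P * n, d_fourier_eff)
      cov_k <- covering_patch(seq_len(pe$P), ls_scale, spec)
      for (k in seq_len(pe$P)) {
        lm[((k - 1L) * n + 1L):(k * n), ] <- per_coarse[, cov_k[k], ]
      }
      pe$ls_mat <- lm
    } else {
      pe$ls_mat <- matrix(0, pe$P * n, d_fourier_eff)
    }
    pe
  })
  names(preps) <- ids
  preps
}

# ---- batch assembly --------------------------------------------------------

assemble_batch <- function(preps, config) {
  cfg <- config
  nb <- length(preps)
  n <- preps[[1L]]$n_vars
  S <- cfg$n_scales
  P_b <- vapply(preps, `[[`, 0L, "P")
  # slot bookkeeping: slots ordered by (scale, episode, variable, patch)
  n_slots_sb <- matrix(0L, S, nb)
  for (s in seq_len(S)) {
    for (b in seq_len(nb)) {
      ps <- if (cfg$no_patching) P_b[b] else preps[[b]]$P_s[s]
      n_slots_sb[s, b] <- n * ps
    }
  }
  slot_off <- matrix(c(0L, cumsum(as.vector(t(n_slots_sb)))[-(S * nb)]),
                     S, nb, byrow = TRUE)
  n_slots <- sum(n_slots_sb)
  # observation rows
  tv <- list(); vv <- list(); slot <- list()
  for (s in seq_len(S)) {
    for (b in seq_len(nb)) {
      tab <- preps[[b]]$scale_tabs[[s]]
      ps <- n_slots_sb[s, b] / n
      if (nrow(tab)) {
        slot[[length(slot) + 1L]] <- slot_off[s, b] + (tab$i - 1L) * ps + tab$p
        tv[[length(tv) + 1L]] <- tab$t
        vv[[length(vv) + 1L]] <- tab$v
      }
    }
  }
  slot <- unlist(slot); tvec <- unlist(tv); vvec <- unlist(vv)
  nonempty <- unique(slot) # ascending by construction
  seg <- match(slot, nonempty)
  tok_idx <- integer(n_slots) # scale of each slot
  pos <- 1L
  for (s in seq_len(S)) for (b in seq_len(nb)) {
    cnt <- n_slots_sb[s, b]
    if (cnt > 0L) tok_idx[pos:(pos + cnt - 1L)] <- s
    pos <- pos + cnt
  }
  # canonical rows ordered (episode, variable, interval)
  canon_off <- c(0L, cumsum(n * P_b))[seq_len(nb)]
  n_canon <- sum(n * P_b)
  align <- matrix(0L, n_canon, S)
  pe_mat <- matrix(0, n_canon, cfg$d_input_tf)
  pe_full <- pe_table(max(P_b), cfg$d_input_tf)
  for (b in seq_len(nb)) {
    P <- P_b[b]
    reps <- if (cfg$no_patching) matrix(seq_len(P), P, 1L) else {
      al <- align_to_canonical(cfg$spec)
      al[seq_len(P), , drop = FALSE]
    }
    for (i in seq_len(n)) {
      rows <- canon_off[b] + (i - 1L) * P + seq_len(P)
      pe_mat[rows, ] <- pe_full[seq_len(P), ]
      for (s in seq_len(S)) {
        ps <- n_slots_sb[s, b] / n
        align[rows, s] <- slot_off[s, b] + (i - 1L) * ps + reps[, s]
      }
    }
  }
  # graph ordering (episode, interval, variable) and spectral features
  perm <- integer(n_canon)
  ls_rows <- vector("list", nb)
  j <- 0L
  for (b in seq_len(nb)) {
    P <- P_b[b]
    for (k in seq_len(P)) {
      for (i in seq_len(n)) {
        j <- j + 1L
        perm[j] <- canon_off[b] + (i - 1L) * P + k
      }
    }
    ls_rows[[b]] <- preps[[b]]$ls_mat
  }
  invperm <- integer(n_canon); invperm[perm] <- seq_len(n_canon)
  ls_mat <- do.call(rbind, ls_rows)
  # sequences, contexts, queries
  lens <- rep(P_b, each = n)
  ctx_idx <- unlist(lapply(seq_len(nb), function(b) {
    canon_off[b] + (seq_len(n) - 1L) * P_b[b] + P_b[b]
  }))
  qtab <- do.call(rbind, lapply(seq_len(nb), function(b) {
    q <- preps[[b]]$queries
    if (!nrow(q)) return(NULL)
    data.frame(ctx = (b - 1L) * n + q$variable_id,
               tfut = (q$query_time_hours - cfg$window_end) / cfg$horizon,
               target = q$target_value,
               w = 1 + cfg$alpha * (q$query_time_hours - cfg$window_end),
               episode_id = preps[[b]]$id,
               variable_id = q$variable_id,
               query_time_hours = q$query_time_hours)
  }))
  # block -> (episode, interval) map for adjacency attribution
  block_map <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(episode_id = preps[[b]]$id, interval = seq_len(P_b[b]))
  }))
  list(nb = nb, n = n, S = S, P_b = P_b,
       n_slots = n_slots, tvec = tvec, vvec = vvec, seg = seg,
       nonempty = nonempty, tok_idx = tok_idx, n_nonempty = length(nonempty),
       align = align, pe_mat = pe_mat, perm = perm, invperm = invperm,
       ls_mat = ls_mat, lens = lens, ctx_idx = ctx_idx, qtab = qtab,
       block_map = block_map, n_canon = n_canon)
}

# ---- forward pass ----------------------------------------------------------

# builds the tape for one batch; returns loss/prediction nodes plus the
# per-interval adjacency arrays when requested
forward_batch <- function(model, batch, train = FALSE, store_adj = FALSE,
                          params = model$params) {
  cfg <- model$config
  tape <- ad_tape()
  L <- lapply(params, ad_leaf, tape = tape)
  n_obs <- length(batch$tvec)
  have_obs <- n_obs > 0L
  # --- patch encoders over all (scale, observation) rows
  if (have_obs) {
    tnode <- ad_const(tape, matrix(batch$tvec, ncol = 1L))
    vnode <- ad_const(tape, matrix(batch$vvec, ncol = 1L))
    phi <- tape_time_embed(tape, tnode, L$te_omega, L$te_alpha)
    z <- ad_cbind(tape, list(phi, vnode))
    ch <- lapply(seq_len(cfg$d_time), function(k) list(
      w1 = L[[paste0("ttcn", k, "_w1")]], b1 = L[[paste0("ttcn", k, "_b1")]],
      w2 = L[[paste0("ttcn", k, "_w2")]], b2 = L[[paste0("ttcn", k, "_b2")]]
    ))
    h_time <- tape_ttcn(tape, z, batch$seg, batch$n_nonempty, ch)
    if (!cfg$no_frequency) {
      lys <- lapply(seq_len(cfg$l_ifan), function(l) list(
        wp = L[[paste0("ifan", l, "_wp")]], up = L[[paste0("ifan", l, "_up")]],
        wpb = L[[paste0("ifan", l, "_wpb")]], vpb = L[[paste0("ifan", l, "_vpb")]],
        bpb = L[[paste0("ifan", l, "_bpb")]]
      ))
      xf <- tape_ifan(tape, vnode, tnode, lys)
      h_freq <- ad_segment_mean(tape, xf, batch$seg, batch$n_nonempty)
      h_cat <- ad_cbind(tape, list(h_time, h_freq))
    } else {
      h_cat <- h_time
    }
    h_fused <- ad_add_bias(tape, ad_matmul(tape, h_cat, L$fus_w), L$fus_b)
    h_full <- ad_scatter_fill(tape, h_fused, L$etok, batch$nonempty,
                              batch$tok_idx, batch$n_slots)
  } else {
    h_full <- ad_gather_rows(tape, L$etok, batch$tok_idx)
  }
  # --- canonical alignment + multi-scale fusion
  per_scale <- lapply(seq_len(batch$S), function(s) {
    ad_gather_rows(tape, h_full, batch$align[, s])
  })
  h_ms <- if (batch$S == 1L) per_scale[[1L]] else ad_cbind(tape, per_scale)
  m <- ad_gelu(tape, ad_add_bias(tape, ad_matmul(tape, h_ms, L$ms_w), L$ms_b))
  m <- ad_add_constm(tape, m, batch$pe_mat)
  # --- K blocks of transformer + dynamic graph
  adjacency <- list()
  x <- m
  for (b in seq_len(cfg$n_blocks)) {
    if (!cfg$no_transformer) {
      lys <- lapply(seq_len(cfg$n_layers_tf), function(l) {
        nms <- c("ln1_g", "ln1_b", "wq", "wk", "wv", "wo", "bo",
                 "ln2_g", "ln2_b", "w1", "b1", "w2", "b2")
        stats::setNames(lapply(nms, function(nm) {
          L[[paste0("bl", b, "_tf", l, "_", nm)]]
        }), nms)
      })
      x <- tape_transformer(tape, x, batch$lens, lys, cfg$n_heads,
                            dropout = cfg$dropout, train = train)
    }
    if (!cfg$no_graph) {
      xg <- ad_gather_rows(tape, x, batch$perm)
      feats <- if (cfg$no_frequency || ncol(batch$ls_mat) == 0L) xg else
        ad_cbind(tape, list(xg, ad_const(tape, batch$ls_mat)))
      es <- ad_matmul(tape, feats, L[[paste0("bl", b, "_g_ws")]])
      et <- ad_matmul(tape, feats, L[[paste0("bl", b, "_g_wt")]])
      gg <- ad_graph_gcn(tape, es, et, xg, L[[paste0("bl", b, "_g_wgnn")]],
                         batch$n, store_adj = store_adj)
      if (store_adj) adjacency[[b]] <- gg$adjacency
      x <- ad_gather_rows(tape, gg$node, batch$invperm)
    }
  }
  # --- time-aware prediction head at the query times
  qtab <- batch$qtab
  result <- list(tape = tape, leaves = L, adjacency = adjacency, qtab = qtab)
  if (is.null(qtab) || !nrow(qtab)) return(result)
  ctx <- ad_gather_rows(tape, x, batch$ctx_idx)
  xq <- ad_gather_rows(tape, ctx, qtab$ctx)
  tf_ <- ad_const(tape, matrix(qtab$tfut, ncol = 1L))
  u <- ad_add(tape, ad_matmul(tape, xq, L$hd_wp), ad_matmul(tape, tf_, L$hd_up))
  g <- ad_gelu(tape, ad_add_bias(
    tape, ad_add(tape, ad_matmul(tape, xq, L$hd_wpb),
                 ad_matmul(tape, tf_, L$hd_vpb)), L$hd_bpb
  ))
  zq <- ad_cbind(tape, list(ad_cos(tape, u), ad_sin(tape, u), g))
  yhat <- ad_add_bias(tape, ad_matmul(tape, zq, L$hd_wout), L$hd_bout)
  result$yhat <- yhat
  scored <- which(!is.na(qtab$target))
  if (length(scored)) {
    ys <- ad_gather_rows(tape, yhat, scored)
    e <- ad_add_constm(tape, ys, -matrix(qtab$target[scored], ncol = 1L))
    wse <- ad_mul(tape, ad_square(tape, e),
                  ad_const(tape, matrix(qtab$w[scored], ncol = 1L)))
    result$loss <- ad_scale(tape, ad_sum(tape, wse), 1 / length(scored))
    result$n_scored <- length(scored)
  }
  result
}
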