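# The fragment-pair attention network.
#
# Architecture, applied identically (shared weights) to every fragment:
#   1. initial projections: atom features (40) -> F for targets; concatenated
#      atom+bond features (50) -> F for layer-1 neighbour messages
#   2. `atom_layers` rounds of neighbourhood attention (leakyrelu-scored,
#      softmax-normalized per target, elu on the aggregated message) followed
#      by a GRU state update per atom
#   3. a supernode whose state starts as the mean of the final atom states and
#      is refined by `mol_layers` rounds of attention over all atoms plus GRU
#      updates; its final state is the fragment embedding
#   4. the two fragment embeddings of a pair are summed, pair embeddings are
#      averaged over all pairs, and a single affine head maps to logS
#
# Everything below is vectorized over a batch: the fragments of all molecules
# in a minibatch are concatenated into one block-diagonal graph, so each layer
# is a handful of dense matrix products plus grouped softmax reductions.

#' Model configuration
#'
#' @param hidden_width Embedding width F of atom states, supernode states and
#'   fragment embeddings.
#' @param atom_layers Number of atom-level attention+GRU layers.
#' @param mol_layers Number of supernode-level attention+GRU layers.
#' @param dropout Dropout rate applied to attention weights and GRU inputs
#'   during training only.
#' @param leaky_slope Negative slope of the leaky-relu attention scoring.
#' @return A `fragsol_config` list.
#' @export
fragsol_config <- function(hidden_width = 128, atom_layers = 3,
                           mol_layers = 2, dropout = 0.002,
                           leaky_slope = 0.01) {
  stopifnot(hidden_width >= 1, atom_layers >= 1, mol_layers >= 1,
            dropout >= 0, dropout < 1, leaky_slope >= 0)
  structure(list(hidden_width = as.integer(hidden_width),
                 atom_layers = as.integer(atom_layers),
                 mol_layers = as.integer(mol_layers),
                 dropout = dropout, leaky_slope = leaky_slope),
            class = "fragsol_config")
}

gru_param_names <- c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh")

#' Initialize model parameters
#'
#' Fan-balanced (Glorot) uniform initialization for all projection, attention
#' and GRU matrices; biases start at zero. The parameter count depends only on
#' the configuration, never on molecule size or the number of fragment pairs.
#'
#' @param cfg A [fragsol_config()].
#' @param seed Integer seed making the draw reproducible.
#' @param n_atom_feat,n_bond_feat Input feature widths (40 and 10 for the
#'   default featurization).
#' @return Named list of parameter arrays (class `fragsol_params`).
#' @export
fragsol_params <- function(cfg, seed = 1, n_atom_feat = 40L,
                           n_bond_feat = 10L) {
  stopifnot(inherits(cfg, "fragsol_config"))
  F <- cfg$hidden_width
  gru_block <- function() {
    g <- list(Wz = glorot(F, F), Uz = glorot(F, F), bz = numeric(F),
              Wr = glorot(F, F), Ur = glorot(F, F), br = numeric(F),
              Wh = glorot(F, F), Uh = glorot(F, F), bh = numeric(F))
    g
  }
  with_local_seed(seed, {
    p <- list(Q = glorot(n_atom_feat, F),
              P = glorot(n_atom_feat + n_bond_feat, F))
    for (l in seq_len(cfg$atom_layers)) {
      blk <- c(list(W = glorot(F, F), s1 = glorot_vec(F), s2 = glorot_vec(F)),
               gru_block())
      names(blk) <- paste0("A", l, ".", names(blk))
      p <- c(p, blk)
    }
    for (t in seq_len(cfg$mol_layers)) {
      blk <- c(list(W = glorot(F, F), s1 = glorot_vec(F), s2 = glorot_vec(F)),
               gru_block())
      names(blk) <- paste0("M", t, ".", names(blk))
      p <- c(p, blk)
    }
    p$w <- matrix(glorot_vec(F), F, 1)
    p$b <- 0
    structure(p, class = "fragsol_params")
  })
}

fs_param_count <- function(params) {
  sum(vapply(params, length, 0L))
}

# --- compilation -------------------------------------------------------------

# one fragment -> dense arrays; directed edges sorted by target atom
fs_compile_fragment <- function(fg) {
  nb <- nrow(fg$bonds)
  if (nb > 0) {
    et <- c(fg$bonds[, "u"], fg$bonds[, "v"])
    ei <- c(fg$bonds[, "v"], fg$bonds[, "u"])
    xe <- rbind(fg$bond_features, fg$bond_features)
    o <- order(et)
    et <- et[o]; ei <- ei[o]
    xe <- xe[o, , drop = FALSE]
  } else {
    et <- integer(0); ei <- integer(0)
    xe <- matrix(0, 0, ncol(fg$bond_features))
  }
  list(X = fg$atom_features, et = et, ei = ei, xe = xe, n = fg$n_atoms)
}

# one molecule -> its fragments plus the pair structure. In fragment mode a
# molecule with no breakable bond falls back to a single whole-molecule
# "pair"; in null mode every molecule takes that path.
fs_compile_molecule <- function(g, null_fragment = FALSE) {
  pairs <- if (null_fragment) list() else fragment_pairs(g)
  if (length(pairs) == 0) {
    frags <- list(fs_compile_fragment(g))
    frag_pair <- 1L
    m <- 1L
  } else {
    frags <- vector("list", 2L * length(pairs))
    frag_pair <- integer(2L * length(pairs))
    for (i in seq_along(pairs)) {
      frags[[2L * i - 1L]] <- fs_compile_fragment(pairs[[i]]$frag1)
      frags[[2L * i]] <- fs_compile_fragment(pairs[[i]]$frag2)
      frag_pair[c(2L * i - 1L, 2L * i)] <- i
    }
    m <- length(pairs)
  }
  list(frags = frags, frag_pair = frag_pair, m = m)
}

# concatenate compiled molecules into one block-diagonal batch graph
fs_make_batch <- function(compiled) {
  Xs <- list(); ets <- list(); eis <- list(); xes <- list()
  frag_of_atom <- list(); n_frag <- integer(0)
  pair_of_frag <- integer(0); mol_of_pair <- integer(0); m_of_mol <- integer(0)
  atom_off <- 0L; frag_id <- 0L; pair_id <- 0L
  for (mi in seq_along(compiled)) {
    cm <- compiled[[mi]]
    pair_base <- pair_id
    for (fi in seq_along(cm$frags)) {
      fr <- cm$frags[[fi]]
      frag_id <- frag_id + 1L
      Xs[[frag_id]] <- fr$X
      ets[[frag_id]] <- fr$et + atom_off
      eis[[frag_id]] <- fr$ei + atom_off
      xes[[frag_id]] <- fr$xe
      frag_of_atom[[frag_id]] <- rep.int(frag_id, fr$n)
      n_frag[frag_id] <- fr$n
      pair_of_frag[frag_id] <- pair_base + cm$frag_pair[fi]
      atom_off <- atom_off + fr$n
    }
    pair_id <- pair_base + cm$m
    mol_of_pair[pair_base + seq_len(cm$m)] <- mi
    m_of_mol[mi] <- cm$m
  }
  X <- do.call(rbind, Xs)
  et <- unlist(ets); ei <- unlist(eis)
  xe <- do.call(rbind, xes)
  K <- length(et)
  M <- nrow(X)
  b <- list(X = X, et = et, ei = ei,
            XeX = if (K > 0) cbind(X[ei, , drop = FALSE], xe)
                  else matrix(0, 0, ncol(X) + ncol(xe)),
            K = K, M = M,
            frag_of_atom = unlist(frag_of_atom), n_frag = n_frag,
            pair_of_frag = pair_of_frag, mol_of_pair = mol_of_pair,
            m_of_mol = m_of_mol,
            n_mol = length(compiled), n_frags = frag_id, n_pairs = pair_id)
  if (K > 0) {
    # edges arrive sorted by target; contiguous target groups for the softmax
    b$gposA <- cumsum(c(1L, diff(et) != 0L))
    b$tgtA <- et[!duplicated(et)]
    b$grpA <- split(seq_len(K), b$gposA)
  }
  b$grpM <- split(seq_len(M), b$frag_of_atom)
  b
}

# --- forward pass ------------------------------------------------------------

grouped_softmax <- function(eps, gpos, grp) {
  gmax <- vapply(grp, function(ix) max(eps[ix]), 0)
  ex <- exp(eps - gmax[gpos])
  den <- drop(rowsum(matrix(ex, ncol = 1), gpos))
  ex / den[gpos]
}

gru_forward <- function(p, prefix, x, h) {
  pf <- function(nm) p[[paste0(prefix, nm)]]
  F <- ncol(h)
  i1 <- seq_len(F); i2 <- F + i1; i3 <- 2L * F + i1
  px <- x %*% cbind(pf("Wr"), pf("Wz"), pf("Wh"))   # one GEMM for all gates
  ph <- h %*% cbind(pf("Ur"), pf("Uz"))
  r <- sigmoid(addb(px[, i1, drop = FALSE] + ph[, i1, drop = FALSE],
                    pf("br")))
  zg <- sigmoid(addb(px[, i2, drop = FALSE] + ph[, i2, drop = FALSE],
                     pf("bz")))
  ht <- tanh(addb(px[, i3, drop = FALSE] + (r * h) %*% pf("Uh"), pf("bh")))
  list(out = (1 - zg) * h + zg * ht, r = r, zg = zg, ht = ht)
}

fs_forward <- function(batch, params, cfg, training = FALSE,
                       keep_cache = FALSE, collect_attention = FALSE) {
  F <- cfg$hidden_width
  L <- cfg$atom_layers
  Tm <- cfg$mol_layers
  slope <- cfg$leaky_slope
  p_drop <- if (training) cfg$dropout else 0
  M <- batch$M; K <- batch$K
  a0 <- batch$X %*% params$Q
  n0 <- if (K > 0) batch$XeX %*% params$P else matrix(0, 0, F)
  h <- a0
  cacheA <- if (keep_cache) vector("list", L)
  att <- if (collect_attention) list()
  for (l in seq_len(L)) {
    pre <- paste0("A", l, ".")
    W <- params[[paste0(pre, "W")]]
    s1 <- params[[paste0(pre, "s1")]]
    s2 <- params[[paste0(pre, "s2")]]
    U <- h %*% W
    if (K > 0) {
      V <- if (l == 1) n0 %*% W else U[batch$ei, , drop = FALSE]
      z <- drop(U %*% s1)[batch$et] + drop(V %*% s2)
      eps <- leakyrelu(z, slope)
      alpha <- grouped_softmax(eps, batch$gposA, batch$grpA)
      maskA <- NULL
      alpha_d <- alpha
      if (p_drop > 0) {
        maskA <- (stats::runif(K) >= p_drop) / (1 - p_drop)
        alpha_d <- alpha * maskA
      }
      S <- rowsum(alpha_d * V, batch$gposA)
      msg <- matrix(0, M, F)
      msg[batch$tgtA, ] <- S
    } else {
      V <- matrix(0, 0, F); z <- numeric(0); alpha <- numeric(0)
      alpha_d <- numeric(0); maskA <- NULL
      msg <- matrix(0, M, F)
    }
    C <- elu(msg)
    maskC <- NULL
    Cd <- C
    if (p_drop > 0) {
      maskC <- matrix((stats::runif(M * F) >= p_drop) / (1 - p_drop), M, F)
      Cd <- C * maskC
    }
    gr <- gru_forward(params, pre, Cd, h)
    if (keep_cache)
      cacheA[[l]] <- list(h_in = h, U = U, V = V, z = z, alpha = alpha,
                          maskA = maskA, msg = msg, maskC = maskC, Cd = Cd,
                          r = gr$r, zg = gr$zg, ht = gr$ht)
    if (collect_attention && K > 0)
      att[[paste0("atom", l)]] <- list(weights = alpha, group = batch$gposA)
    h <- gr$out
  }
  A_L <- h
  g0 <- rowsum(A_L, batch$frag_of_atom) / batch$n_frag
  gs <- g0
  cacheM <- if (keep_cache) vector("list", Tm)
  for (t in seq_len(Tm)) {
    pre <- paste0("M", t, ".")
    W <- params[[paste0(pre, "W")]]
    s1 <- params[[paste0(pre, "s1")]]
    s2 <- params[[paste0(pre, "s2")]]
    Ug <- gs %*% W
    Va <- A_L %*% W
    z <- drop(Ug %*% s1)[batch$frag_of_atom] + drop(Va %*% s2)
    eps <- leakyrelu(z, slope)
    alpha <- grouped_softmax(eps, batch$frag_of_atom, batch$grpM)
    maskA <- NULL
    alpha_d <- alpha
    if (p_drop > 0) {
      maskA <- (stats::runif(M) >= p_drop) / (1 - p_drop)
      alpha_d <- alpha * maskA
    }
    Smat <- rowsum(alpha_d * Va, batch$frag_of_atom)
    Cm <- elu(Smat)
    maskC <- NULL
    Cd <- Cm
    if (p_drop > 0) {
      maskC <- matrix((stats::runif(length(Cm)) >= p_drop) / (1 - p_drop),
                      nrow(Cm), ncol(Cm))
      Cd <- Cm * maskC
    }
    gr <- gru_forward(params, pre, Cd, gs)
    if (keep_cache)
      cacheM[[t]] <- list(h_in = gs, Ug = Ug, Va = Va, z = z, alpha = alpha,
                          maskA = maskA, Smat = Smat, maskC = maskC, Cd = Cd,
                          r = gr$r, zg = gr$zg, ht = gr$ht)
    if (collect_attention)
      att[[paste0("mol", t)]] <- list(weights = alpha,
                                      group = batch$frag_of_atom)
    gs <- gr$out
  }
  y <- gs
  ypair <- rowsum(y, batch$pair_of_frag)
  ymol <- rowsum(ypair, batch$mol_of_pair) / batch$m_of_mol
  pred <- drop(ymol %*% params$w) + params$b
  out <- list(pred = pred)
  if (keep_cache)
    out$cache <- list(a0 = a0, n0 = n0, A_L = A_L, g0 = g0, y = y,
                      ypair = ypair, ymol = ymol, A = cacheA, M = cacheM)
  if (collect_attention) out$attention <- att
  out
}

#' Predict logS for molecular graphs with explicit parameters
#'
#' Low-level deterministic (evaluation-mode) forward pass: enumerates fragment
#' pairs, embeds every fragment, fuses and averages, and applies the affine
#' head. Molecules with no breakable bond automatically take the
#' whole-molecule path; `null_fragment = TRUE` forces that path for all
#' molecules (the ablation configuration).
#'
#' @param graphs A `mol_graph` or list of them.
#' @param params A [fragsol_params()] parameter set.
#' @param cfg The matching [fragsol_config()].
#' @param null_fragment Skip fragmentation and embed whole molecules.
#' @param collect_attention If `TRUE`, attach the per-layer attention weights
#'   (and their target groupings) as attribute `"attention"`.
#' @return Numeric vector of predictions, one per molecule.
#' @export
fragsol_forward <- function(graphs, params, cfg, null_fragment = FALSE,
                            collect_attention = FALSE) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  compiled <- lapply(graphs, fs_compile_molecule, null_fragment = null_fragment)
  batch <- fs_make_batch(compiled)
  out <- fs_forward(batch, params, cfg, training = FALSE,
                    collect_attention = collect_attention)
  pred <- out$pred
  if (collect_attention) attr(pred, "attention") <- out$attention
  pred
}
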