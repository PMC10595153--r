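# Reverse-mode gradients for the fragment attention network. Mirrors
# fs_forward() stage by stage; verified against central finite differences in
# the test suite.

gru_backward <- function(p, prefix, dh_out, x, hprev, r, zg, ht, grads) {
  pf <- function(nm) p[[paste0(prefix, nm)]]
  gn <- function(nm) paste0(prefix, nm)
  F <- ncol(hprev)
  i1 <- seq_len(F); i2 <- F + i1
  dzg <- dh_out * (ht - hprev)
  dht <- dh_out * zg
  dhprev <- dh_out * (1 - zg)
  dht_pre <- dht * (1 - ht^2)
  drh <- tcrossprod(dht_pre, pf("Uh"))
  dr <- drh * hprev
  dhprev <- dhprev + drh * r
  dzg_pre <- dzg * zg * (1 - zg)
  dr_pre <- dr * r * (1 - r)
  dgates <- cbind(dr_pre, dzg_pre, dht_pre)
  dx <- tcrossprod(dgates, cbind(pf("Wr"), pf("Wz"), pf("Wh")))
  dhprev <- dhprev + tcrossprod(dgates[, c(i1, i2), drop = FALSE],
                                cbind(pf("Ur"), pf("Uz")))
  gW <- crossprod(x, dgates)
  grads[[gn("Wr")]] <- grads[[gn("Wr")]] + gW[, i1, drop = FALSE]
  grads[[gn("Wz")]] <- grads[[gn("Wz")]] + gW[, i2, drop = FALSE]
  grads[[gn("Wh")]] <- grads[[gn("Wh")]] + gW[, 2L * F + i1, drop = FALSE]
  gU <- crossprod(hprev, dgates[, c(i1, i2), drop = FALSE])
  grads[[gn("Ur")]] <- grads[[gn("Ur")]] + gU[, i1, drop = FALSE]
  grads[[gn("Uz")]] <- grads[[gn("Uz")]] + gU[, i2, drop = FALSE]
  grads[[gn("Uh")]] <- grads[[gn("Uh")]] + crossprod(r * hprev, dht_pre)
  grads[[gn("br")]] <- grads[[gn("br")]] + colSums(dr_pre)
  grads[[gn("bz")]] <- grads[[gn("bz")]] + colSums(dzg_pre)
  grads[[gn("bh")]] <- grads[[gn("bh")]] + colSums(dht_pre)
  list(dx = dx, dhprev = dhprev, grads = grads)
}

# backward through score -> leakyrelu -> grouped softmax -> weighted message.
# dpre: gradient at the pre-elu aggregated message, already restricted to
# target-group rows (G x F). Returns per-edge dV, per-group dU rows, ds1, ds2.
attention_backward <- function(dpre_grp, U_t, V, z, alpha, maskA, gpos, s1, s2,
                               slope) {
  dAV <- dpre_grp[gpos, , drop = FALSE]
  alpha_d <- if (is.null(maskA)) alpha else alpha * maskA
  dalpha_d <- rowSums(dAV * V)
  dV <- dAV * alpha_d
  dalpha <- if (is.null(maskA)) dalpha_d else dalpha_d * maskA
  sg <- drop(rowsum(matrix(alpha * dalpha, ncol = 1), gpos))
  deps <- alpha * (dalpha - sg[gpos])
  dz <- deps * leakyrelu_grad(z, slope)
  ds1 <- drop(crossprod(U_t, dz))
  ds2 <- drop(crossprod(V, dz))
  dU_grp <- drop(rowsum(matrix(dz, ncol = 1), gpos)) %o% s1
  dV <- dV + dz %o% s2
  list(dV = dV, dU_grp = dU_grp, ds1 = ds1, ds2 = ds2)
}

fs_backward <- function(batch, params, cfg, fwd, dpred) {
  F <- cfg$hidden_width
  L <- cfg$atom_layers
  Tm <- cfg$mol_layers
  slope <- cfg$leaky_slope
  M <- batch$M; K <- batch$K
  cache <- fwd$cache
  grads <- lapply(params, function(x) if (is.matrix(x)) matrix(0, nrow(x),
                                                               ncol(x))
                  else numeric(length(x)))
  grads$b <- 0

  # head and pair bookkeeping
  grads$w <- grads$w + crossprod(cache$ymol, dpred)
  grads$b <- sum(dpred)
  dymol <- (dpred %o% drop(params$w)) / batch$m_of_mol
  dypair <- dymol[batch$mol_of_pair, , drop = FALSE]
  dy <- dypair[batch$pair_of_frag, , drop = FALSE]

  # supernode stack, reversed
  dA_L <- matrix(0, M, F)
  dg <- dy
  for (t in rev(seq_len(Tm))) {
    pre <- paste0("M", t, ".")
    cc <- cache$M[[t]]
    gb <- gru_backward(params, pre, dg, cc$Cd, cc$h_in, cc$r, cc$zg, cc$ht,
                       grads)
    grads <- gb$grads
    dCd <- gb$dx
    dC <- if (is.null(cc$maskC)) dCd else dCd * cc$maskC
    dpre_grp <- dC * elu_grad(cc$Smat)
    ab <- attention_backward(dpre_grp, cc$Ug[batch$frag_of_atom, ,
                                             drop = FALSE],
                             cc$Va, cc$z, cc$alpha, cc$maskA,
                             batch$frag_of_atom, params[[paste0(pre, "s1")]],
                             params[[paste0(pre, "s2")]], slope)
    W <- params[[paste0(pre, "W")]]
    grads[[paste0(pre, "s1")]] <- grads[[paste0(pre, "s1")]] + ab$ds1
    grads[[paste0(pre, "s2")]] <- grads[[paste0(pre, "s2")]] + ab$ds2
    grads[[paste0(pre, "W")]] <- grads[[paste0(pre, "W")]] +
      crossprod(cc$h_in, ab$dU_grp) + crossprod(cache$A_L, ab$dV)
    dg <- gb$dhprev + tcrossprod(ab$dU_grp, W)
    dA_L <- dA_L + tcrossprod(ab$dV, W)
  }
  # supernode initialization (mean of atom states)
  dA_L <- dA_L + (dg / batch$n_frag)[batch$frag_of_atom, , drop = FALSE]

  # atom stack, reversed
  dh <- dA_L
  dn0 <- if (K > 0) matrix(0, K, F) else matrix(0, 0, F)
  for (l in rev(seq_len(L))) {
    pre <- paste0("A", l, ".")
    cc <- cache$A[[l]]
    gb <- gru_backward(params, pre, dh, cc$Cd, cc$h_in, cc$r, cc$zg, cc$ht,
                       grads)
    grads <- gb$grads
    dCd <- gb$dx
    dC <- if (is.null(cc$maskC)) dCd else dCd * cc$maskC
    dpre <- dC * elu_grad(cc$msg)
    W <- params[[paste0(pre, "W")]]
    dh_new <- gb$dhprev
    if (K > 0) {
      dpre_grp <- dpre[batch$tgtA, , drop = FALSE]
      ab <- attention_backward(dpre_grp, cc$U[batch$et, , drop = FALSE],
                               cc$V, cc$z, cc$alpha, cc$maskA, batch$gposA,
                               params[[paste0(pre, "s1")]],
                               params[[paste0(pre, "s2")]], slope)
      grads[[paste0(pre, "s1")]] <- grads[[paste0(pre, "s1")]] + ab$ds1
      grads[[paste0(pre, "s2")]] <- grads[[paste0(pre, "s2")]] + ab$ds2
      dU <- matrix(0, M, F)
      dU[batch$tgtA, ] <- ab$dU_grp
      if (l == 1) {
        grads[[paste0(pre, "W")]] <- grads[[paste0(pre, "W")]] +
          crossprod(cc$h_in, dU) + crossprod(cache$n0, ab$dV)
        dn0 <- dn0 + tcrossprod(ab$dV, W)
      } else {
        src <- rowsum(ab$dV, batch$ei)
        dU[as.integer(rownames(src)), ] <-
          dU[as.integer(rownames(src)), ] + src
        grads[[paste0(pre, "W")]] <- grads[[paste0(pre, "W")]] +
          crossprod(cc$h_in, dU)
      }
      dh_new <- dh_new + tcrossprod(dU, W)
    }
    dh <- dh_new
  }
  grads$Q <- grads$Q + crossprod(batch$X, dh)
  if (K > 0) grads$P <- grads$P + crossprod(batch$XeX, dn0)
  grads
}
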