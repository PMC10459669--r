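# Analytic backpropagation for equivs_forward(). Gradients are exact for
# the cached dropout masks, so finite-difference checks are run with
# dropout disabled. Structure mirrors the forward pass in reverse; the
# coordinate path is differentiated through both the residual update and
# the squared-distance message inputs.

zero_like <- function(params) {
  lapply(params, function(x) if (is.matrix(x)) {
    matrix(0, nrow(x), ncol(x))
  } else {
    numeric(length(x))
  })
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(a, s) lapply(a, function(x) x * s)

# dyG: scalar; dyGm: length-M vector (or NULL); dalpha: length-M vector of
# direct loss partials w.r.t. alpha (or NULL). Returns a named gradient
# list matching params.
equivs_backward <- function(out, params, config, dyG, dyGm = NULL,
                            dalpha = NULL) {
  cache <- out$cache
  if (is.null(cache)) {
    abort("forward pass must be run with training = TRUE to backpropagate.")
  }
  p <- params
  g <- zero_like(params)
  h <- config$hidden_dim
  nd <- config$node_dim
  rate <- cache$rate
  M <- cache$M
  Mn <- cache$Mn
  n <- cache$n
  K <- skip_width(config)
  HGm <- cache$HGm
  dHGm <- matrix(0, M, K)

  ## ---- bag head ------------------------------------------------------
  da_bag_d <- dyG * p$bag_w2
  g$bag_w2 <- g$bag_w2 + dyG * cache$a_bag_d
  g$bag_b2 <- g$bag_b2 + dyG
  da_bag <- if (is.null(cache$mask_bag)) da_bag_d else {
    da_bag_d * as.numeric(cache$mask_bag) / (1 - rate)
  }
  dz_bag <- da_bag * (cache$z_bag > 0)
  g$bag_W1 <- g$bag_W1 + outer(dz_bag, cache$inp_bag)
  g$bag_b1 <- g$bag_b1 + dz_bag
  dinp <- as.numeric(dz_bag %*% p$bag_W1)
  dH1 <- dinp[seq_len(h)]
  dHG <- dinp[h + seq_len(K)]

  ## ---- instance head -------------------------------------------------
  if (config$variant != "no_ip" && !is.null(dyGm)) {
    da_ins_d <- outer(dyGm, p$ins_w2)
    g$ins_w2 <- g$ins_w2 + as.numeric(crossprod(cache$a_ins_d, dyGm))
    g$ins_b2 <- g$ins_b2 + sum(dyGm)
    da_ins <- apply_dropout(da_ins_d, cache$mask_ins, rate)
    dz_ins <- da_ins * (cache$z_ins > 0)
    g$ins_W1 <- g$ins_W1 + crossprod(dz_ins, HGm)
    g$ins_b1 <- g$ins_b1 + colSums(dz_ins)
    dHGm <- dHGm + dz_ins %*% p$ins_W1
  }

  ## ---- attention aggregation -----------------------------------------
  if (config$variant == "no_aa") {
    dHGm <- dHGm + matrix(dHG, M, K, byrow = TRUE)
  } else {
    alpha <- cache$alpha
    dal <- as.numeric(HGm %*% dHG)
    if (!is.null(dalpha)) dal <- dal + dalpha
    dw <- alpha * (dal - sum(alpha * dal))
    dT <- outer(dw, p$attn_q)
    g$attn_q <- g$attn_q + as.numeric(crossprod(cache$a_tanh, dw))
    dA_pre <- dT * (1 - cache$a_tanh^2)
    g$attn_Wa <- g$attn_Wa + crossprod(dA_pre, HGm)
    g$attn_ba <- g$attn_ba + colSums(dA_pre)
    dHGm <- dHGm + dA_pre %*% p$attn_Wa + outer(alpha, dHG)
  }

  ## ---- equivariant layers (reverse) ----------------------------------
  L <- config$n_layers
  dreads <- vector("list", L)
  if (config$variant == "no_skip") {
    for (l in seq_len(L)) dreads[[l]] <- matrix(0, M, h)
    dreads[[L]] <- dHGm
  } else {
    for (l in seq_len(L)) {
      dreads[[l]] <- dHGm[, (l - 1) * h + seq_len(h), drop = FALSE]
    }
  }
  sei <- cache$sei
  sej <- cache$sej
  conf <- cache$conf_of_node
  C <- cache$C
  dH_next <- matrix(0, Mn, h)   # grad w.r.t. layer output H_out
  dX_next <- matrix(0, Mn, 3)   # grad w.r.t. layer output coords
  for (l in rev(seq_len(L))) {
    lc <- cache$layers[[l]]
    d_in <- lc$d_in
    We <- p[[sprintf("egnn%d_We", l)]]
    Wh <- p[[sprintf("egnn%d_Wh", l)]]
    Wr <- p[[sprintf("egnn%d_Wr", l)]]
    wx <- p[[sprintf("egnn%d_wx", l)]]
    # readout path into this layer's output
    dcontrib <- dreads[[l]][conf, , drop = FALSE]
    dgate <- dcontrib * lc$H_out
    dpre_gate <- dgate * lc$gate * (1 - lc$gate)
    dH_out <- dH_next + dcontrib * lc$gate + dpre_gate %*% Wr
    g[[sprintf("egnn%d_Wr", l)]] <- g[[sprintf("egnn%d_Wr", l)]] +
      crossprod(dpre_gate, lc$H_out)
    g[[sprintf("egnn%d_br", l)]] <- g[[sprintf("egnn%d_br", l)]] +
      colSums(dpre_gate)
    # dropout, node update
    dH_pre <- apply_dropout(dH_out, lc$mask, rate)
    g[[sprintf("egnn%d_Wh", l)]] <- g[[sprintf("egnn%d_Wh", l)]] +
      crossprod(dH_pre, lc$comb)
    g[[sprintf("egnn%d_bh", l)]] <- g[[sprintf("egnn%d_bh", l)]] +
      colSums(dH_pre)
    dcomb <- dH_pre %*% Wh
    dH_in <- dcomb[, seq_len(d_in), drop = FALSE]
    dS <- dcomb[, d_in + seq_len(h), drop = FALSE]
    # coordinate residual + update term
    dX_in <- dX_next
    if (length(sei) > 0) {
      dterm <- C * dX_next[sei, , drop = FALSE]
      drel <- dterm * lc$phix
      dphix <- rowSums(dterm * lc$rel)
      dmg <- dS[sei, , drop = FALSE] + outer(dphix, wx)
      g[[sprintf("egnn%d_wx", l)]] <- g[[sprintf("egnn%d_wx", l)]] +
        as.numeric(crossprod(lc$mg, dphix))
      g[[sprintf("egnn%d_bx", l)]] <- g[[sprintf("egnn%d_bx", l)]] +
        sum(dphix)
      g[[sprintf("egnn%d_We", l)]] <- g[[sprintf("egnn%d_We", l)]] +
        crossprod(dmg, lc$msg_in)
      g[[sprintf("egnn%d_be", l)]] <- g[[sprintf("egnn%d_be", l)]] +
        colSums(dmg)
      dmsg <- dmg %*% We
      dH_in <- dH_in + scatter_add(dmsg[, seq_len(d_in), drop = FALSE],
                                   sei, Mn)
      dH_in <- dH_in +
        scatter_add(dmsg[, d_in + seq_len(d_in), drop = FALSE], sej, Mn)
      dd2 <- dmsg[, 2 * d_in + 1]
      drel <- drel + 2 * lc$rel * dd2
      dX_in <- dX_in + scatter_add(drel, sei, Mn) -
        scatter_add(drel, sej, Mn)
    }
    dH_next <- dH_in
    dX_next <- dX_in
  }
  # dH_next now holds the gradient w.r.t. the stacked input node features
  # (the raw featurization); nothing upstream is trainable on that path.

  ## ---- topological encoder -------------------------------------------
  dcontrib1 <- matrix(dH1, n, h, byrow = TRUE)
  dgate1 <- dcontrib1 * cache$h1
  dpre_gate1 <- dgate1 * cache$gate1 * (1 - cache$gate1)
  dh1 <- dcontrib1 * cache$gate1 + dpre_gate1 %*% p$gcn_Wr
  g$gcn_Wr <- g$gcn_Wr + crossprod(dpre_gate1, cache$h1)
  g$gcn_br <- g$gcn_br + colSums(dpre_gate1)
  dh1_pre <- apply_dropout(dh1, cache$mask1, rate)
  if (config$variant == "no_gcn") {
    g$lin_W <- g$lin_W + crossprod(dh1_pre, cache$hv)
    g$lin_b <- g$lin_b + colSums(dh1_pre)
  } else {
    g$gcn_Wh <- g$gcn_Wh + crossprod(dh1_pre, cache$comb_g)
    g$gcn_bh <- g$gcn_bh + colSums(dh1_pre)
    dcomb_g <- dh1_pre %*% p$gcn_Wh
    dS_g <- dcomb_g[, nd + seq_len(h), drop = FALSE]
    if (nrow(cache$mg_g) > 0) {
      dmg_g <- dS_g[cache$ei, , drop = FALSE]
      g$gcn_We <- g$gcn_We + crossprod(dmg_g, cache$msg_in_g)
      g$gcn_be <- g$gcn_be + colSums(dmg_g)
    }
  }
  g
}
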