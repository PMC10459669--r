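# The conformer-ensemble network: a GCN topological encoder, L stacked
# E(3)-equivariant message-passing layers per conformer (with gated-sum
# readouts and skip concatenation), attention-based multiple-instance
# aggregation, and two ReLU MLP heads (per-conformer and per-molecule).
#
# All transformation functions (phi_e, phi_h, phi_x) are single linear maps
# on concatenated inputs; activations appear only in the readout gates
# (sigmoid), attention scorer (tanh) and MLP heads (ReLU). Forward and
# backward passes are written out explicitly; conformers are processed as
# one stacked disjoint-union graph for speed.

#' Model configuration
#'
#' @param hidden_dim Hidden feature width (default 128).
#' @param n_layers Number of equivariant message-passing layers (default 2).
#' @param dropout Dropout rate applied after every GNN layer and every MLP
#'   hidden layer at training time (default 0.05).
#' @param variant Architecture variant: `"full"` (default) or one of the
#'   ablations `"single"` (only the first conformer), `"no_gcn"` (plain
#'   linear layer instead of the GCN encoder), `"no_skip"` (last-layer
#'   readout only), `"no_aa"` (unweighted sum instead of attention
#'   aggregation; attention coefficients unavailable), `"no_ip"`
#'   (conformer-level predictor and instance loss disabled).
#' @param coord_norm Normalization constant C of the coordinate update:
#'   `"divide"` (default) uses 1/(n-1), `"multiply"` uses (n-1), where n is
#'   the heavy-atom count.
#' @param node_dim,edge_dim Input feature widths (74 and 12; fixed by the
#'   featurization).
#' @return An `equivs_config` list.
#' @export
equivs_config <- function(hidden_dim = 128, n_layers = 2, dropout = 0.05,
                          variant = c("full", "single", "no_gcn", "no_skip",
                                      "no_aa", "no_ip"),
                          coord_norm = c("divide", "multiply"),
                          node_dim = 74, edge_dim = 12) {
  variant <- match.arg(variant)
  coord_norm <- match.arg(coord_norm)
  stopifnot(hidden_dim >= 1, n_layers >= 1, dropout >= 0, dropout < 1)
  structure(
    list(hidden_dim = as.integer(hidden_dim),
         n_layers = as.integer(n_layers),
         dropout = dropout, variant = variant, coord_norm = coord_norm,
         node_dim = as.integer(node_dim), edge_dim = as.integer(edge_dim)),
    class = "equivs_config"
  )
}

skip_width <- function(config) {
  if (config$variant == "no_skip") config$hidden_dim
  else config$n_layers * config$hidden_dim
}

glorot <- function(nrow, ncol) {
  limit <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -limit, limit), nrow, ncol)
}

glorot_vec <- function(n) {
  limit <- sqrt(6 / (1 + n))
  runif(n, -limit, limit)
}

#' Initialize trainable parameters
#'
#' Weight matrices use uniform Glorot initialization, biases start at zero.
#'
#' @param config An [equivs_config()].
#' @param seed Integer seed for reproducible initialization.
#' @return Named list of parameter arrays (`equivs_params`).
#' @export
init_equivs_params <- function(config, seed = 1) {
  h <- config$hidden_dim
  nd <- config$node_dim
  ed <- config$edge_dim
  K <- skip_width(config)
  with_seed(seed, {
    p <- list()
    if (config$variant == "no_gcn") {
      p$lin_W <- glorot(h, nd)
      p$lin_b <- numeric(h)
    } else {
      p$gcn_We <- glorot(h, 2 * nd)
      p$gcn_be <- numeric(h)
      p$gcn_Wh <- glorot(h, nd + h)
      p$gcn_bh <- numeric(h)
    }
    p$gcn_Wr <- glorot(h, h)
    p$gcn_br <- numeric(h)
    for (l in seq_len(config$n_layers)) {
      d_in <- if (l == 1L) nd else h
      p[[sprintf("egnn%d_We", l)]] <- glorot(h, 2 * d_in + 1 + ed)
      p[[sprintf("egnn%d_be", l)]] <- numeric(h)
      p[[sprintf("egnn%d_wx", l)]] <- glorot_vec(h)
      p[[sprintf("egnn%d_bx", l)]] <- 0
      p[[sprintf("egnn%d_Wh", l)]] <- glorot(h, d_in + h)
      p[[sprintf("egnn%d_bh", l)]] <- numeric(h)
      p[[sprintf("egnn%d_Wr", l)]] <- glorot(h, h)
      p[[sprintf("egnn%d_br", l)]] <- numeric(h)
    }
    if (config$variant != "no_aa") {
      p$attn_Wa <- glorot(h, K)
      p$attn_ba <- numeric(h)
      p$attn_q <- glorot_vec(h)
    }
    if (config$variant != "no_ip") {
      p$ins_W1 <- glorot(h, K)
      p$ins_b1 <- numeric(h)
      p$ins_w2 <- glorot_vec(h)
      p$ins_b2 <- 0
    }
    p$bag_W1 <- glorot(h, h + K)
    p$bag_b1 <- numeric(h)
    p$bag_w2 <- glorot_vec(h)
    p$bag_b2 <- 0
    structure(p, class = "equivs_params")
  })
}

dropout_mask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(NULL)
  matrix(runif(dim1 * dim2) >= rate, dim1, dim2)
}

apply_dropout <- function(x, mask, rate) {
  if (is.null(mask)) x else x * mask / (1 - rate)
}

# gated-sum readout over groups of nodes; returns list(read = G x h, cache)
gated_readout <- function(hnodes, Wr, br, groups, n_groups) {
  gate <- sigmoid(sweep(hnodes %*% t(Wr), 2, br, `+`))
  contrib <- gate * hnodes
  read <- scatter_add(contrib, groups, n_groups)
  list(read = read, gate = gate)
}

#' Forward pass of the conformer-ensemble network
#'
#' Runs the full computing flow for a single molecule: topological encoding
#' of the 2D graph, L equivariant message-passing layers per conformer with
#' gated-sum readouts and skip concatenation, attention aggregation over
#' conformers, and both prediction heads. Predictions depend on conformer
#' coordinates only through interatomic distances, so they are invariant
#' under rigid motions of any conformer while the internal coordinate
#' updates transform equivariantly.
#'
#' @param graph A `molecular_graph` from [assemble_graph()].
#' @param params Parameters from [init_equivs_params()] (or a trained fit's
#'   `$params`).
#' @param config The matching [equivs_config()].
#' @param training Apply dropout and keep the backward cache.
#' @param return_coords Also return the coordinates after the last
#'   equivariant layer (per conformer), e.g. for equivariance checks.
#' @return List with `yG` (molecule-level prediction, -logM), `yGm`
#'   (per-conformer predictions; NULL for the `no_ip` variant), `alpha`
#'   (attention coefficients, summing to 1; NULL for the `no_aa` variant),
#'   `H1`, `HGm`, and (when `training`) a `cache` for backpropagation.
#' @export
equivs_forward <- function(graph, params, config, training = FALSE,
                           return_coords = FALSE) {
  stopifnot(inherits(graph, "molecular_graph"))
  h <- config$hidden_dim
  nd <- config$node_dim
  p <- params
  rate <- if (training) config$dropout else 0
  n <- graph$n
  hv <- graph$node_features
  ei <- graph$edge_index[, 1]
  ej <- graph$edge_index[, 2]
  nE <- length(ei)
  cache <- list()

  ## ---- topological encoder -------------------------------------------
  if (config$variant == "no_gcn") {
    h1_pre <- sweep(hv %*% t(p$lin_W), 2, p$lin_b, `+`)
  } else {
    if (nE > 0) {
      msg_in_g <- cbind(hv[ei, , drop = FALSE], hv[ej, , drop = FALSE])
      mg_g <- sweep(msg_in_g %*% t(p$gcn_We), 2, p$gcn_be, `+`)
      s_g <- scatter_add(mg_g, ei, n)
    } else {
      msg_in_g <- matrix(0, 0, 2 * nd)
      mg_g <- matrix(0, 0, h)
      s_g <- matrix(0, n, h)
    }
    comb_g <- cbind(hv, s_g)
    h1_pre <- sweep(comb_g %*% t(p$gcn_Wh), 2, p$gcn_bh, `+`)
    cache$msg_in_g <- msg_in_g
    cache$mg_g <- mg_g
    cache$comb_g <- comb_g
  }
  mask1 <- dropout_mask(n, h, rate)
  h1 <- apply_dropout(h1_pre, mask1, rate)
  ro1 <- gated_readout(h1, p$gcn_Wr, p$gcn_br, rep(1L, n), 1L)
  H1 <- as.numeric(ro1$read)
  cache$h1 <- h1
  cache$mask1 <- mask1
  cache$gate1 <- ro1$gate

  ## ---- equivariant layers over stacked conformers --------------------
  M <- if (config$variant == "single") 1L else graph$M
  Mn <- M * n
  offs <- rep((seq_len(M) - 1L) * n, each = nE)
  sei <- rep(ei, M) + offs
  sej <- rep(ej, M) + offs
  conf_of_node <- rep(seq_len(M), each = n)
  ef_st <- graph$edge_features[rep(seq_len(nE), M), , drop = FALSE]
  C <- if (n > 1) {
    if (config$coord_norm == "divide") 1 / (n - 1) else (n - 1)
  } else 0
  H <- hv[rep(seq_len(n), M), , drop = FALSE]
  X <- do.call(rbind, graph$coords[seq_len(M)])
  layers <- vector("list", config$n_layers)
  reads <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    d_in <- ncol(H)
    We <- p[[sprintf("egnn%d_We", l)]]
    be <- p[[sprintf("egnn%d_be", l)]]
    wx <- p[[sprintf("egnn%d_wx", l)]]
    bx <- p[[sprintf("egnn%d_bx", l)]]
    Wh <- p[[sprintf("egnn%d_Wh", l)]]
    bh <- p[[sprintf("egnn%d_bh", l)]]
    Wr <- p[[sprintf("egnn%d_Wr", l)]]
    br <- p[[sprintf("egnn%d_br", l)]]
    if (length(sei) > 0) {
      rel <- X[sei, , drop = FALSE] - X[sej, , drop = FALSE]
      d2 <- rowSums(rel^2)
      msg_in <- cbind(H[sei, , drop = FALSE], H[sej, , drop = FALSE],
                      d2, ef_st)
      mg <- sweep(msg_in %*% t(We), 2, be, `+`)
      phix <- as.numeric(mg %*% wx) + bx
      S <- scatter_add(mg, sei, Mn)
      Xn <- X + C * scatter_add(rel * phix, sei, Mn)
    } else {
      rel <- matrix(0, 0, 3); d2 <- numeric(0)
      msg_in <- matrix(0, 0, 2 * d_in + 1 + config$edge_dim)
      mg <- matrix(0, 0, h); phix <- numeric(0)
      S <- matrix(0, Mn, h); Xn <- X
    }
    comb <- cbind(H, S)
    H_pre <- sweep(comb %*% t(Wh), 2, bh, `+`)
    mask <- dropout_mask(Mn, h, rate)
    H_out <- apply_dropout(H_pre, mask, rate)
    ro <- gated_readout(H_out, Wr, br, conf_of_node, M)
    layers[[l]] <- list(rel = rel, d2 = d2, msg_in = msg_in, mg = mg,
                        phix = phix, comb = comb, mask = mask,
                        H_out = H_out, gate = ro$gate, d_in = d_in)
    reads[[l]] <- ro$read
    H <- H_out
    X <- Xn
  }
  HGm <- if (config$variant == "no_skip") {
    reads[[config$n_layers]]
  } else {
    do.call(cbind, reads)
  }

  ## ---- attention aggregation -----------------------------------------
  if (config$variant == "no_aa") {
    alpha <- NULL
    HG <- colSums(HGm)
  } else {
    a_pre <- sweep(HGm %*% t(p$attn_Wa), 2, p$attn_ba, `+`)
    a_tanh <- tanh(a_pre)
    w <- as.numeric(a_tanh %*% p$attn_q)
    alpha <- softmax(w)
    HG <- as.numeric(crossprod(HGm, alpha))
    cache$a_tanh <- a_tanh
  }

  ## ---- prediction heads ----------------------------------------------
  if (config$variant == "no_ip") {
    yGm <- NULL
  } else {
    z_ins <- sweep(HGm %*% t(p$ins_W1), 2, p$ins_b1, `+`)
    a_ins <- pmax(z_ins, 0)
    mask_ins <- dropout_mask(M, h, rate)
    a_ins_d <- apply_dropout(a_ins, mask_ins, rate)
    yGm <- as.numeric(a_ins_d %*% p$ins_w2) + p$ins_b2
    cache$z_ins <- z_ins
    cache$a_ins_d <- a_ins_d
    cache$mask_ins <- mask_ins
  }
  inp_bag <- c(H1, HG)
  z_bag <- as.numeric(p$bag_W1 %*% inp_bag) + p$bag_b1
  a_bag <- pmax(z_bag, 0)
  mask_bag <- dropout_mask(1, h, rate)
  a_bag_d <- if (is.null(mask_bag)) a_bag else {
    a_bag * as.numeric(mask_bag) / (1 - rate)
  }
  yG <- sum(a_bag_d * p$bag_w2) + p$bag_b2

  out <- list(yG = yG, yGm = yGm, alpha = alpha, H1 = H1, HGm = HGm,
              HG = HG)
  if (return_coords) {
    out$coords_final <- lapply(seq_len(M), function(m) {
      X[(m - 1) * n + seq_len(n), , drop = FALSE]
    })
  }
  if (training) {
    cache$layers <- layers
    cache$HGm <- HGm
    cache$alpha <- alpha
    cache$M <- M
    cache$Mn <- Mn
    cache$n <- n
    cache$sei <- sei
    cache$sej <- sej
    cache$conf_of_node <- conf_of_node
    cache$ei <- ei
    cache$hv <- hv
    cache$C <- C
    cache$inp_bag <- inp_bag
    cache$z_bag <- z_bag
    cache$a_bag_d <- a_bag_d
    cache$mask_bag <- mask_bag
    cache$rate <- rate
    out$cache <- cache
  }
  out
}
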