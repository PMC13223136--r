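# Small neural-network building blocks on top of the autodiff tape:
# parameter containers, Adam, MLPs, and a pre-LayerNorm transformer encoder.
# All internal.

nn_glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

nn_linear_init <- function(nin, nout, prefix) {
  out <- list(nn_glorot(nin, nout), matrix(0, 1, nout))
  names(out) <- paste0(prefix, c("_W", "_b"))
  out
}

# wrap every parameter matrix of `theta` in a fresh ad_param node for one pass
nn_nodes <- function(theta) lapply(theta, ad_param)

nn_grads <- function(nodes) {
  lapply(nodes, function(n) if (is.null(n$grad)) matrix(0, nrow(n$val), ncol(n$val)) else n$grad)
}

nn_linear <- function(nodes, prefix, x) {
  ad_add(ad_matmul(x, nodes[[paste0(prefix, "_W")]]), nodes[[paste0(prefix, "_b")]])
}

# ---- MLP -------------------------------------------------------------------

# sizes = c(nin, hidden..., nout); activation on hidden layers only
mlp_init <- function(sizes, prefix = "l") {
  theta <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    theta <- c(theta, nn_linear_init(sizes[i], sizes[i + 1L], paste0(prefix, i)))
  }
  theta
}

mlp_forward <- function(nodes, x, n_layers, prefix = "l", act = ad_tanh) {
  h <- x
  for (i in seq_len(n_layers)) {
    h <- nn_linear(nodes, paste0(prefix, i), h)
    if (i < n_layers) h <- act(h)
  }
  h
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(theta) {
  list(
    m = lapply(theta, function(x) x * 0),
    v = lapply(theta, function(x) x * 0),
    t = 0L
  )
}

adam_step <- function(theta, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(theta)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    theta[[k]] <- theta[[k]] - lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}

# cosine learning-rate decay over total steps
lr_cosine <- function(lr0, step, total) lr0 * 0.5 * (1 + cos(pi * min(step / max(total, 1), 1)))

# ---- transformer encoder ---------------------------------------------------

transformer_init <- function(d, layers, ff_mult = 2L) {
  theta <- list()
  for (l in seq_len(layers)) {
    p <- function(nm) paste0("blk", l, "_", nm)
    theta <- c(
      theta,
      nn_linear_init(d, d, p("q")), nn_linear_init(d, d, p("k")),
      nn_linear_init(d, d, p("v")), nn_linear_init(d, d, p("o")),
      nn_linear_init(d, d * ff_mult, p("f1")), nn_linear_init(d * ff_mult, d, p("f2"))
    )
    theta[[p("ln1_g")]] <- matrix(1, 1, d)
    theta[[p("ln1_b")]] <- matrix(0, 1, d)
    theta[[p("ln2_g")]] <- matrix(1, 1, d)
    theta[[p("ln2_b")]] <- matrix(0, 1, d)
  }
  theta[["lnf_g"]] <- matrix(1, 1, d)
  theta[["lnf_b"]] <- matrix(0, 1, d)
  theta
}

nn_layernorm <- function(nodes, prefix, x) {
  ad_add(ad_mul(ad_layernorm_rows(x), nodes[[paste0(prefix, "_g")]]),
         nodes[[paste0(prefix, "_b")]])
}

nn_attention <- function(nodes, prefix, x, heads, dropout = 0, train = FALSE) {
  d <- ncol(x$val)
  dk <- d %/% heads
  q <- nn_linear(nodes, paste0(prefix, "q"), x)
  k <- nn_linear(nodes, paste0(prefix, "k"), x)
  v <- nn_linear(nodes, paste0(prefix, "v"), x)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    qh <- ad_slice_cols(q, idx)
    kh <- ad_slice_cols(k, idx)
    vh <- ad_slice_cols(v, idx)
    scores <- ad_scale(ad_matmul(qh, ad_transpose(kh)), 1 / sqrt(dk))
    a <- ad_softmax_rows(scores)
    a <- ad_dropout(a, dropout, train)
    outs[[h]] <- ad_matmul(a, vh)
  }
  nn_linear(nodes, paste0(prefix, "o"), ad_cbind(outs))
}

# pre-LN transformer encoder over a token matrix (L x d)
transformer_forward <- function(nodes, x, layers, heads, dropout = 0, train = FALSE) {
  h <- x
  for (l in seq_len(layers)) {
    p <- function(nm) paste0("blk", l, "_", nm)
    att <- nn_attention(nodes, p(""), nn_layernorm(nodes, p("ln1"), h),
                        heads, dropout, train)
    h <- ad_add(h, ad_dropout(att, dropout, train))
    ff <- nn_linear(nodes, p("f2"),
                    ad_gelu(nn_linear(nodes, p("f1"), nn_layernorm(nodes, p("ln2"), h))))
    h <- ad_add(h, ad_dropout(ff, dropout, train))
  }
  nn_layernorm(nodes, "lnf", h)
}
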