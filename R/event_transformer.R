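# Event-triplet sequence encoder: continuous-time sinusoidal positions,
# modality-specific value projections + modality embeddings, a pre-LN
# transformer, and masked-value self-supervised pre-training.

#' Encoder configuration
#'
#' Defaults mirror the full-scale architecture (four layers, eight heads,
#' width 256, GELU, dropout 0.15, 30% masking); tests and the bundled smoke
#' profiles scale the width and depth down.
#'
#' @param layers,heads,d Transformer depth, attention heads, model width
#'   (`d` must be divisible by `heads`).
#' @param dropout Dropout rate during training.
#' @param mask_rate Fraction of events whose value is masked during
#'   self-supervised pre-training.
#' @param pretrain_epochs,lr Pre-training epochs and Adam learning rate
#'   (cosine-decayed).
#' @param max_events Per-episode event-sequence cap; longer sequences are
#'   thinned to an evenly spaced subsequence (desk-scale control).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(layers = 4L, heads = 8L, d = 256L, dropout = 0.15,
                           mask_rate = 0.30, pretrain_epochs = 50L, lr = 1e-4,
                           max_events = 512L) {
  if (d %% heads != 0) stop("width d must be divisible by heads", call. = FALSE)
  structure(as.list(environment()), class = "encoder_config")
}

#' Continuous-time sinusoidal positional encoding
#'
#' Standard sinusoid pairs evaluated at the continuous timestamp (in hours),
#' not at the sequence index: column 2i-1 is `sin(t * w_i)`, column 2i is
#' `cos(t * w_i)` with `w_i = (1/10000)^((i-1)/(width/2))`. Rows align with
#' events; equal timestamps give identical rows, and the encoding at `t + dt`
#' is the per-frequency rotation of the encoding at `t`.
#'
#' @param t_sec Event timestamps in seconds since induction.
#' @param width Encoding width (even).
#' @return A `length(t_sec) x width` matrix.
#' @export
time_positional_encoding <- function(t_sec, width) {
  if (width %% 2 != 0) stop("width must be even", call. = FALSE)
  t_h <- t_sec / 3600
  half <- width %/% 2
  w <- 10000^(-(seq_len(half) - 1) / half)
  ang <- outer(t_h, w)
  out <- matrix(0, length(t_h), width)
  out[, seq(1, width, by = 2)] <- sin(ang)
  out[, seq(2, width, by = 2)] <- cos(ang)
  out
}

encoder_init <- function(cfg) {
  nv <- nrow(modality_vocabulary())
  theta <- c(
    transformer_init(cfg$d, cfg$layers),
    list(
      val_W = nn_glorot(nv, cfg$d),     # per-modality value projection rows
      mod_E = nn_glorot(nv, cfg$d),     # modality embeddings
      mask_E = nn_glorot(1, cfg$d),     # learned mask embedding
      cls_E = nn_glorot(1, cfg$d)       # summary token
    ),
    nn_linear_init(cfg$d, 1, "recon")   # pre-training reconstruction head
  )
  theta
}

#' Create an (untrained) encoder
#'
#' A randomly initialized encoder; used directly for the "-SSL" ablation arm
#' or as the starting point of [pretrain_masked_modality()]. The standardizer
#' travels with the encoder so downstream modules always embed standardized
#' values.
#'
#' @param std A fitted [fit_standardizer()].
#' @param cfg An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ctdose_encoder`.
#' @export
new_encoder <- function(std, cfg = encoder_config(), seed = 1L) {
  theta <- with_seed_local(seed, encoder_init(cfg))
  structure(list(theta = theta, cfg = cfg, std = std,
                 vocabulary = modality_vocabulary(), pretrained = FALSE,
                 loss_history = numeric(0)),
            class = "ctdose_encoder")
}

# thin long sequences to an evenly spaced subsequence
thin_events <- function(ev, max_events) {
  if (nrow(ev) <= max_events) return(ev)
  ev[unique(round(seq(1, nrow(ev), length.out = max_events))), , drop = FALSE]
}

#' Embed one episode's events as a token matrix
#'
#' Each event becomes `value * val_W[modality, ] + mod_E[modality, ] + PE(t)`.
#' Values must already be standardized (the encoder's standardizer is applied
#' by the caller or by [encode_episode()]).
#'
#' @param events A single episode's event tibble (already standardized),
#'   time-sorted.
#' @param encoder A `ctdose_encoder`.
#' @param nodes Optional live parameter nodes (used inside training); defaults
#'   to constant embedding of the stored weights.
#' @param masked Optional logical vector: events whose value projection is
#'   replaced by the learned mask embedding.
#' @param value_node Optional autodiff node (L x 1) carrying the event values
#'   (used for input attributions).
#' @return An autodiff node holding the `L x d` token matrix.
#' @export
embed_events <- function(events, encoder, nodes = NULL, masked = NULL,
                         value_node = NULL) {
  if (nrow(events) == 0L) stop("cannot embed an empty event sequence", call. = FALSE)
  code <- modality_code(events$modality)
  if (is.null(nodes)) nodes <- lapply(encoder$theta, ad_const)
  d <- encoder$cfg$d
  vals <- events$value
  vals[!is.finite(vals)] <- 0
  vnode <- if (is.null(value_node)) ad_const(matrix(vals, ncol = 1)) else value_node
  valproj <- ad_mul(ad_embed(nodes$val_W, code),
                    ad_matmul(vnode, ad_const(matrix(1, 1, d))))
  if (!is.null(masked) && any(masked)) {
    keep <- ad_const(matrix(as.numeric(!masked), nrow(events), d))
    mrows <- ad_mul(ad_embed(nodes$mask_E, rep(1L, nrow(events))),
                    ad_const(matrix(as.numeric(masked), nrow(events), d)))
    valproj <- ad_add(ad_mul(valproj, keep), mrows)
  }
  tok <- ad_add(valproj, ad_embed(nodes$mod_E, code))
  ad_add(tok, ad_const(time_positional_encoding(events$t_sec, d)))
}

encoder_forward <- function(events, encoder, nodes = NULL, masked = NULL,
                            train = FALSE, value_node = NULL) {
  if (is.null(nodes)) nodes <- lapply(encoder$theta, ad_const)
  tok <- embed_events(events, encoder, nodes, masked, value_node)
  cls <- ad_add(ad_embed(nodes$cls_E, 1L),
                ad_const(time_positional_encoding(min(events$t_sec) - 1, encoder$cfg$d)))
  x <- ad_node(rbind(cls$val, tok$val), list(cls, tok), function(n) {
    ad_accum(cls, n$grad[1, , drop = FALSE])
    ad_accum(tok, n$grad[-1, , drop = FALSE])
  })
  h <- transformer_forward(nodes, x, encoder$cfg$layers, encoder$cfg$heads,
                           dropout = encoder$cfg$dropout, train = train)
  h
}

#' Encode an episode into a context vector
#'
#' Standardizes the values, embeds the (thinned) event sequence with a
#' prepended summary token at `min(t) - 1` second, runs the transformer with
#' dropout disabled, and returns the summary-token output row.
#'
#' @param events One episode's raw event tibble (unstandardized).
#' @param encoder A `ctdose_encoder`.
#' @return Numeric context vector of length `d`.
#' @export
encode_episode <- function(events, encoder) {
  if (nrow(events) == 0L) {
    stop("empty event sequence: use the static-only fallback context", call. = FALSE)
  }
  events$value <- standardize_values(encoder$std, events$modality, events$value)
  events <- thin_events(events, encoder$cfg$max_events)
  out <- NULL
  ad_with_tape({
    h <- encoder_forward(events, encoder)
    out <- h$val[1, ]
  })
  out
}

#' Masked-value self-supervised pre-training
#'
#' At each step a random `mask_rate` fraction of the episode's events has its
#' value projection replaced by a learned mask embedding (time and modality
#' are kept), and the encoder is trained to reconstruct the standardized
#' values of the masked events with squared error, analogous to masked
#' language-model pre-training.
#'
#' @param es Unlabeled training `episode_set`.
#' @param std Fitted standardizer (frozen).
#' @param cfg [encoder_config()].
#' @param seed Integer seed (init, masking and episode order).
#' @return A pre-trained `ctdose_encoder` with a `loss_history` attribute
#'   (mean masked reconstruction loss per epoch).
#' @export
pretrain_masked_modality <- function(es, std, cfg = encoder_config(), seed = 1L) {
  if (cfg$mask_rate <= 0) stop("mask_rate must be positive for pre-training", call. = FALSE)
  enc <- new_encoder(std, cfg, seed)
  ses <- apply_standardizer(std, es)
  eps <- split(ses$events, ses$events$episode_id)
  eps <- lapply(eps, thin_events, max_events = cfg$max_events)
  theta <- enc$theta
  state <- adam_state(theta)
  total_steps <- cfg$pretrain_epochs * length(eps)
  losses <- numeric(cfg$pretrain_epochs)
  holder <- new.env(parent = emptyenv())
  with_seed_local(seed + 1L, {
    # untrained baseline: one masked pass with no updates
    l0 <- numeric(0)
    for (ev in eps) {
      L <- nrow(ev)
      if (L < 3L) next
      masked <- rep(FALSE, L)
      masked[sample(L, max(1L, round(cfg$mask_rate * L)))] <- TRUE
      ad_with_tape({
        nodes <- lapply(theta, ad_const)
        h <- encoder_forward(ev, enc, nodes, masked = masked, train = FALSE)
        pred <- nn_linear(nodes, "recon", h)
        pv <- ad_slice_rows(pred, which(masked) + 1L)
        y <- ad_const(matrix(ev$value[masked], ncol = 1))
        l0 <- c(l0, ad_mean(ad_square(ad_sub(pv, y)))$val[1, 1])
      })
    }
    holder$init_loss <- mean(l0)
    step <- 0L
    for (epoch in seq_len(cfg$pretrain_epochs)) {
      ep_losses <- numeric(length(eps))
      for (i in sample(seq_along(eps))) {
        ev <- eps[[i]]
        L <- nrow(ev)
        if (L < 3L) next
        masked <- rep(FALSE, L)
        masked[sample(L, max(1L, round(cfg$mask_rate * L)))] <- TRUE
        step <- step + 1L
        lr <- lr_cosine(cfg$lr, step, total_steps)
        ad_with_tape({
          nodes <- nn_nodes(theta)
          h <- encoder_forward(ev, enc, nodes, masked = masked, train = TRUE)
          pred <- nn_linear(nodes, "recon", h)
          pv <- ad_slice_rows(pred, which(masked) + 1L)  # +1 skips summary token
          y <- ad_const(matrix(ev$value[masked], ncol = 1))
          loss <- ad_mean(ad_square(ad_sub(pv, y)))
          ad_backward(loss)
          upd <- adam_step(theta, nn_grads(nodes), state, lr)
          theta <- upd$theta; state <- upd$state
          ep_losses[i] <- loss$val[1, 1]
        })
      }
      losses[epoch] <- mean(ep_losses[ep_losses > 0])
    }
  })
  enc$theta <- theta
  enc$pretrained <- TRUE
  enc$loss_history <- losses
  enc$init_loss <- holder$init_loss
  enc
}
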