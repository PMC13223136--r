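# Reverse-mode automatic differentiation on dense matrices.
#
# A "tape" records every intermediate node created during a forward pass;
# backward() walks it in reverse, accumulating gradients. Nodes are plain
# environments (value, grad, parents, backward closure). Everything here is
# internal; the model code (nn.R and friends) is the supported surface.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_with_tape <- function(expr) {
  old <- .ad$tape
  .ad$tape <- ad_tape_new()
  on.exit(.ad$tape <- old, add = TRUE)
  expr
}

ad_push <- function(node) {
  t <- .ad$tape
  if (is.null(t)) return(node)   # no tape active: pure forward evaluation
  if (t$n == length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$n <- t$n + 1L
  t$nodes[[t$n]] <- node
  node
}

ad_node <- function(val, parents = list(), back = NULL, requires = FALSE) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$back <- back
  n$requires <- requires || any(vapply(parents, function(p) p$requires, logical(1)))
  ad_push(n)
}

ad_const <- function(x) ad_node(as.matrix(x))
ad_param <- function(x) ad_node(as.matrix(x), requires = TRUE)

ad_val <- function(x) if (is.environment(x)) x$val else x

ad_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' @noRd
ad_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  t <- .ad$tape
  if (is.null(t)) stop("ad_backward() called with no active tape", call. = FALSE)
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (nd$requires && !is.null(nd$grad) && !is.null(nd$back)) nd$back(nd)
  }
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$val %*% b$val, list(a, b), function(n) {
    ad_accum(a, n$grad %*% t(b$val))
    ad_accum(b, t(a$val) %*% n$grad)
  })
}

# a + b where b may be a matrix of equal shape or a 1-row matrix broadcast
# across the rows of a.
ad_add <- function(a, b) {
  bv <- b$val
  broadcast <- nrow(bv) == 1L && nrow(a$val) > 1L
  val <- if (broadcast) sweep(a$val, 2L, as.numeric(bv), "+") else a$val + bv
  ad_node(val, list(a, b), function(n) {
    ad_accum(a, n$grad)
    ad_accum(b, if (broadcast) matrix(colSums(n$grad), 1L) else n$grad)
  })
}

ad_sub <- function(a, b) {
  ad_node(a$val - b$val, list(a, b), function(n) {
    ad_accum(a, n$grad)
    ad_accum(b, -n$grad)
  })
}

# elementwise product; b may be same shape, 1-row broadcast, or 1x1 scalar.
ad_mul <- function(a, b) {
  bv <- b$val
  av <- a$val
  kind <- if (length(bv) == 1L) "scalar" else if (nrow(bv) == 1L && nrow(av) > 1L) "row" else "full"
  val <- switch(kind,
    scalar = av * as.numeric(bv),
    row    = sweep(av, 2L, as.numeric(bv), "*"),
    full   = av * bv
  )
  ad_node(val, list(a, b), function(n) {
    ad_accum(a, switch(kind,
      scalar = n$grad * as.numeric(bv),
      row    = sweep(n$grad, 2L, as.numeric(bv), "*"),
      full   = n$grad * bv
    ))
    ad_accum(b, switch(kind,
      scalar = matrix(sum(n$grad * av), 1, 1),
      row    = matrix(colSums(n$grad * av), 1L),
      full   = n$grad * av
    ))
  })
}

ad_scale <- function(a, k) {
  ad_node(a$val * k, list(a), function(n) ad_accum(a, n$grad * k))
}

ad_unary <- function(a, f, df) {
  v <- f(a$val)
  ad_node(v, list(a), function(n) ad_accum(a, n$grad * df(a$val, v)))
}

ad_tanh     <- function(a) ad_unary(a, tanh, function(x, v) 1 - v^2)
ad_sigmoid  <- function(a) ad_unary(a, stats::plogis, function(x, v) v * (1 - v))
ad_exp      <- function(a) ad_unary(a, exp, function(x, v) v)
ad_log      <- function(a) ad_unary(a, log, function(x, v) 1 / x)
ad_square   <- function(a) ad_unary(a, function(x) x^2, function(x, v) 2 * x)
ad_abs      <- function(a) ad_unary(a, abs, function(x, v) sign(x))
ad_relu     <- function(a) ad_unary(a, function(x) pmax(x, 0), function(x, v) (x > 0) + 0)
ad_softplus <- function(a) ad_unary(a, function(x) log1p(exp(-abs(x))) + pmax(x, 0),
                                    function(x, v) stats::plogis(x))
ad_pnorm    <- function(a) ad_unary(a, stats::pnorm, function(x, v) stats::dnorm(x))
ad_dnorm    <- function(a) ad_unary(a, stats::dnorm, function(x, v) -x * v)
# exact GELU: x * pnorm(x)
ad_gelu     <- function(a) ad_unary(a, function(x) x * stats::pnorm(x),
                                    function(x, v) stats::pnorm(x) + x * stats::dnorm(x))
ad_recip    <- function(a) ad_unary(a, function(x) 1 / x, function(x, v) -v^2)

ad_sum <- function(a) {
  ad_node(matrix(sum(a$val), 1, 1), list(a), function(n) {
    ad_accum(a, matrix(as.numeric(n$grad), nrow(a$val), ncol(a$val)))
  })
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$val))

ad_transpose <- function(a) {
  ad_node(t(a$val), list(a), function(n) ad_accum(a, t(n$grad)))
}

ad_slice_cols <- function(a, idx) {
  ad_node(a$val[, idx, drop = FALSE], list(a), function(n) {
    g <- matrix(0, nrow(a$val), ncol(a$val))
    g[, idx] <- n$grad
    ad_accum(a, g)
  })
}

ad_slice_rows <- function(a, idx) {
  ad_node(a$val[idx, , drop = FALSE], list(a), function(n) {
    g <- matrix(0, nrow(a$val), ncol(a$val))
    g[idx, ] <- g[idx, ] + n$grad
    ad_accum(a, g)
  })
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, function(x) x$val)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ad_node(do.call(cbind, vals), nodes, function(n) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], n$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# rows of an embedding matrix selected by integer index (with repeats);
# backward scatter-adds.
ad_embed <- function(emb, idx) {
  ad_node(emb$val[idx, , drop = FALSE], list(emb), function(n) {
    g <- matrix(0, nrow(emb$val), ncol(emb$val))
    for (j in seq_along(idx)) g[idx[j], ] <- g[idx[j], ] + n$grad[j, ]
    ad_accum(emb, g)
  })
}

ad_softmax_rows <- function(a) {
  x <- a$val
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  s <- e / rowSums(e)
  ad_node(s, list(a), function(n) {
    dot <- rowSums(n$grad * s)
    ad_accum(a, s * (n$grad - dot))
  })
}

# row-wise layer normalization (zero mean, unit variance per row); affine
# gain/bias are applied by the caller with ad_mul/ad_add broadcasts.
ad_layernorm_rows <- function(a, eps = 1e-5) {
  x <- a$val
  m <- rowMeans(x)
  xc <- x - m
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  y <- xc * inv
  ad_node(y, list(a), function(n) {
    d <- ncol(x)
    g <- n$grad
    gy_sum <- rowMeans(g)
    gy_dot <- rowMeans(g * y)
    ad_accum(a, inv * (g - gy_sum - y * gy_dot))
  })
}

ad_dropout <- function(a, rate, train = TRUE) {
  if (!train || rate <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$val), 1L, 1 - rate), nrow(a$val)) / (1 - rate)
  ad_mul(a, ad_const(mask))
}
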