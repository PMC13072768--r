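# Internal neural-network primitives: small, explicit, matrix-algebra only.
# Layout convention throughout: batches are rows (B x features); weight
# matrices are (in x out); biases are length-out vectors recycled by row.

`%||%` <- function(a, b) if (is.null(a)) b else a

relu <- function(x) x * (x > 0)

leakyRelu <- function(x, slope = 0.2) {
  pos <- x > 0
  x * pos + (slope * x) * !pos
}

leakyReluGrad <- function(x, slope = 0.2) (x > 0) * (1 - slope) + slope

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

addBias <- function(m, b) sweep(m, 2L, b, `+`)

# deterministic per-position seed stream; keeps derived seeds in int range
deriveSeed <- function(seed, pos) {
  as.integer((as.double(seed) + 7919 * as.double(pos)) %% 2147483647)
}

newLinear <- function(nin, nout, sd = sqrt(2 / nin), zero = FALSE) {
  W <- if (zero) matrix(0, nin, nout)
       else matrix(rnorm(nin * nout, 0, sd), nin, nout)
  list(W = W, b = numeric(nout))
}

linFwd <- function(X, lin) addBias(X %*% lin$W, lin$b)

# dY: gradient wrt output; returns grads and gradient wrt input
linBwd <- function(dY, X, lin) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = tcrossprod(dY, lin$W))
}

# --- Adam ------------------------------------------------------------------
# params/grads are arbitrarily nested lists of numeric arrays with matching
# structure; state holds (m, v) mirrors plus the step counter.

adamInit <- function(params) {
  zero <- function(p) {
    if (is.list(p)) lapply(p, zero) else p * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     weightDecay = 0, decayGroups = NULL,
                     lrMult = 1, lrMultGroups = NULL) {
  state$t <- state$t + 1L
  t <- state$t
  # bias correction folded into the step size (one pass saved per leaf)
  alphaBase <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  epsHat <- eps * sqrt(1 - beta2^t)
  walk <- function(p, g, m, v, decay, alpha) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v,
                 MoreArgs = list(decay = decay, alpha = alpha))
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * (g * g)
      p <- p - alpha * (m / (sqrt(v) + epsHat))
      if (decay > 0) p <- p - (lr * decay) * p  # decoupled (AdamW-style)
      list(p = p, m = m, v = v)
    }
  }
  res <- Map(function(nm) {
    decay <- if (weightDecay > 0 &&
                 (is.null(decayGroups) || nm %in% decayGroups))
      weightDecay else 0
    alpha <- if (lrMult != 1 && !is.null(lrMultGroups) &&
                 nm %in% lrMultGroups) alphaBase * lrMult else alphaBase
    walk(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]], decay,
         alpha)
  }, names(params))
  list(params = lapply(res, `[[`, "p"),
       state = list(m = lapply(res, `[[`, "m"),
                    v = lapply(res, `[[`, "v"), t = t))
}

# elementwise sum of two identically shaped nested grad lists
gradAdd <- function(a, b) {
  if (is.list(a)) Map(gradAdd, a, b) else a + b
}

# numeric gradient by central differences over a nested param list; used by
# tests to guard the analytic backprop wiring
numericGrad <- function(lossFn, params, eps = 1e-5) {
  flatten <- function(p) if (is.list(p)) unlist(lapply(p, flatten)) else p
  g <- params
  walk <- function(path) {
    node <- params[[path]]
    NULL
  }
  # operate via unlist/relist on a flat copy
  skeleton <- params
  flat <- unlist(params)
  gflat <- numeric(length(flat))
  for (i in seq_along(flat)) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    gflat[i] <- (lossFn(relist(up, skeleton)) -
                 lossFn(relist(dn, skeleton))) / (2 * eps)
  }
  relist(gflat, skeleton)
}

# relist that preserves matrix dims (utils::relist drops them for matrices
# inside lists on some shapes); rebuild explicitly
relist <- function(flat, skeleton) {
  i <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    n <- length(node)
    out <- flat[(i + 1L):(i + n)]
    i <<- i + n
    if (!is.null(dim(node))) dim(out) <- dim(node)
    out
  }
  walk(skeleton)
}
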