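# Internal LSTM engine for next-event melody prediction.
#
# Events are encoded on four categorical axes — pitch (128), duration class
# (1..16 time units), velocity class (16 bins of 8), offset class (0..16
# units) — concatenated as a one-hot input of width 177. A stack of LSTM
# layers feeds four softmax output heads, one per axis, trained with summed
# cross-entropy by teacher forcing. Everything is plain (BLAS-backed) matrix
# algebra so training is exactly reproducible from the RNG seed.

VOCAB <- list(pitch = 128L, dur = 16L, vel = 16L, off = 17L)
INPUT_DIM <- 128L + 16L + 16L + 17L

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# event columns -> 1-based class indices
encode_classes <- function(events) {
  list(
    pitch = as.integer(clamp(events$pitch, 0, 127)) + 1L,
    dur = as.integer(clamp(events$duration, 1, 16)),
    vel = (as.integer(clamp(events$velocity, 1, 127)) - 1L) %/% 8L + 1L,
    off = as.integer(clamp(events$offset, 0, 16)) + 1L
  )
}

decode_classes <- function(pitch_ix, dur_ix, vel_ix, off_ix) {
  tibble(
    pitch = pitch_ix - 1L,
    duration = dur_ix,
    velocity = (vel_ix - 1L) * 8L + 4L,
    offset = off_ix - 1L
  )
}

onehot_batch <- function(cls, B) {
  X <- matrix(0, B, INPUT_DIM)
  off0 <- 0L
  X[cbind(seq_len(B), cls$pitch)] <- 1
  off0 <- VOCAB$pitch
  X[cbind(seq_len(B), off0 + cls$dur)] <- 1
  off0 <- off0 + VOCAB$dur
  X[cbind(seq_len(B), off0 + cls$vel)] <- 1
  off0 <- off0 + VOCAB$vel
  X[cbind(seq_len(B), off0 + cls$off)] <- 1
  X
}

sigmoid <- function(x) 1 / (1 + exp(-x))

init_lstm_params <- function(layers, hidden) {
  glorot <- function(nin, nout) {
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  }
  p <- list(layers = list())
  for (l in seq_len(layers)) {
    d_in <- if (l == 1L) INPUT_DIM else hidden
    b <- rep(0, 4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1 # forget-gate bias
    p$layers[[l]] <- list(W = glorot(d_in, 4 * hidden), U = glorot(hidden, 4 * hidden), b = b)
  }
  p$heads <- purrr::map(VOCAB, function(k) {
    list(W = glorot(hidden, k), b = rep(0, k))
  })
  p
}

# One forward step through the stack. state: list of list(h, c) per layer.
# Returns new state plus per-layer caches when `training`.
lstm_step <- function(params, X, state, hidden, dropout, masks = NULL, training = FALSE) {
  caches <- if (training) vector("list", length(params$layers)) else NULL
  inp <- X
  H <- hidden
  for (l in seq_along(params$layers)) {
    lay <- params$layers[[l]]
    st <- state[[l]]
    a <- inp %*% lay$W + st$h %*% lay$U + rep(lay$b, each = nrow(inp))
    i <- sigmoid(a[, 1:H, drop = FALSE])
    f <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * st$c + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    h_out <- h_new
    if (training && dropout > 0) {
      h_out <- h_new * masks[[l]] / (1 - dropout)
    }
    if (training) {
      caches[[l]] <- list(
        X = inp, h_prev = st$h, c_prev = st$c,
        i = i, f = f, g = g, o = o, c = c_new, tc = tc, h = h_new
      )
    }
    state[[l]] <- list(h = h_new, c = c_new)
    inp <- h_out
  }
  list(state = state, top = inp, caches = caches)
}

head_logits <- function(params, top) {
  purrr::map(params$heads, function(hd) {
    top %*% hd$W + rep(hd$b, each = nrow(top))
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

zero_like <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

# Full forward + backward over a (B x T) chunk of class-index matrices.
# ix: list of B x (T+1) integer matrices per axis; mask: B x T (1 where the
# step's target exists). Returns list(loss, grads).
lstm_forward_backward <- function(params, ix, mask, hidden, dropout) {
  B <- nrow(ix$pitch)
  T_ <- ncol(ix$pitch) - 1L
  L <- length(params$layers)
  H <- hidden
  state <- purrr::map(seq_len(L), function(l) {
    list(h = matrix(0, B, H), c = matrix(0, B, H))
  })
  masks_t <- caches_t <- tops <- vector("list", T_)
  probs_t <- vector("list", T_)
  n_valid <- sum(mask)
  loss <- 0

  for (t in seq_len(T_)) {
    cls <- list(
      pitch = ix$pitch[, t], dur = ix$dur[, t],
      vel = ix$vel[, t], off = ix$off[, t]
    )
    X <- onehot_batch(cls, B)
    masks <- if (dropout > 0) {
      purrr::map(seq_len(L), function(l) {
        matrix(as.numeric(stats::runif(B * H) >= dropout), B, H)
      })
    } else {
      NULL
    }
    step <- lstm_step(params, X, state, H, dropout, masks, training = TRUE)
    state <- step$state
    caches_t[[t]] <- step$caches
    masks_t[[t]] <- masks
    tops[[t]] <- step$top
    logits <- head_logits(params, step$top)
    probs <- purrr::map(logits, softmax_rows)
    probs_t[[t]] <- probs
    tgt <- list(
      pitch = ix$pitch[, t + 1L], dur = ix$dur[, t + 1L],
      vel = ix$vel[, t + 1L], off = ix$off[, t + 1L]
    )
    for (ax in names(VOCAB)) {
      pr <- probs[[ax]][cbind(seq_len(B), tgt[[ax]])]
      loss <- loss + sum(-log(pmax(pr, 1e-12)) * mask[, t])
    }
  }
  loss <- loss / max(n_valid, 1)

  grads <- zero_like(params)
  dh_next <- dc_next <- purrr::map(seq_len(L), function(l) matrix(0, B, H))
  for (t in rev(seq_len(T_))) {
    # head gradients
    dtop <- matrix(0, B, H)
    tgt <- list(
      pitch = ix$pitch[, t + 1L], dur = ix$dur[, t + 1L],
      vel = ix$vel[, t + 1L], off = ix$off[, t + 1L]
    )
    for (ax in names(VOCAB)) {
      dlog <- probs_t[[t]][[ax]]
      dlog[cbind(seq_len(B), tgt[[ax]])] <- dlog[cbind(seq_len(B), tgt[[ax]])] - 1
      dlog <- dlog * (mask[, t] / max(n_valid, 1))
      grads$heads[[ax]]$W <- grads$heads[[ax]]$W + crossprod(tops[[t]], dlog)
      grads$heads[[ax]]$b <- grads$heads[[ax]]$b + colSums(dlog)
      dtop <- dtop + tcrossprod(dlog, params$heads[[ax]]$W)
    }
    d_from_above <- dtop # gradient w.r.t. the (dropped-out) output of layer L
    for (l in rev(seq_len(L))) {
      cache <- caches_t[[t]][[l]]
      dh <- dh_next[[l]]
      if (dropout > 0) {
        dh <- dh + d_from_above * masks_t[[t]][[l]] / (1 - dropout)
      } else {
        dh <- dh + d_from_above
      }
      dc <- dc_next[[l]] + dh * cache$o * (1 - cache$tc^2)
      do_ <- dh * cache$tc
      di <- dc * cache$g
      dg <- dc * cache$i
      df <- dc * cache$c_prev
      da <- cbind(
        di * cache$i * (1 - cache$i),
        df * cache$f * (1 - cache$f),
        dg * (1 - cache$g^2),
        do_ * cache$o * (1 - cache$o)
      )
      grads$layers[[l]]$W <- grads$layers[[l]]$W + crossprod(cache$X, da)
      grads$layers[[l]]$U <- grads$layers[[l]]$U + crossprod(cache$h_prev, da)
      grads$layers[[l]]$b <- grads$layers[[l]]$b + colSums(da)
      dh_next[[l]] <- tcrossprod(da, params$layers[[l]]$U)
      dc_next[[l]] <- dc * cache$f
      d_from_above <- tcrossprod(da, params$layers[[l]]$W) # to layer below
    }
  }
  list(loss = loss, grads = grads)
}

# Adam with bias correction, operating on the nested param list.
adam_update <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  walk_update <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^opt$t)
    vhat <- v / (1 - beta2^opt$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (l in seq_along(params$layers)) {
    for (nm in c("W", "U", "b")) {
      r <- walk_update(
        params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
        opt$m$layers[[l]][[nm]], opt$v$layers[[l]][[nm]]
      )
      params$layers[[l]][[nm]] <- r$p
      opt$m$layers[[l]][[nm]] <- r$m
      opt$v$layers[[l]][[nm]] <- r$v
    }
  }
  for (ax in names(params$heads)) {
    for (nm in c("W", "b")) {
      r <- walk_update(
        params$heads[[ax]][[nm]], grads$heads[[ax]][[nm]],
        opt$m$heads[[ax]][[nm]], opt$v$heads[[ax]][[nm]]
      )
      params$heads[[ax]][[nm]] <- r$p
      opt$m$heads[[ax]][[nm]] <- r$m
      opt$v$heads[[ax]][[nm]] <- r$v
    }
  }
  list(params = params, opt = opt)
}

# Stack a corpus (list of event tibbles) into B x (chunk+1) class matrices
# plus a target mask.
corpus_tensors <- function(corpus, chunk_length) {
  Tp1 <- chunk_length + 1L
  B <- length(corpus)
  ix <- purrr::map(VOCAB, function(k) matrix(1L, B, Tp1))
  mask <- matrix(0, B, chunk_length)
  for (b in seq_len(B)) {
    ev <- corpus[[b]]
    len <- min(nrow(ev), Tp1)
    if (len < 2L) next
    cls <- encode_classes(ev[seq_len(len), ])
    ix$pitch[b, seq_len(len)] <- cls$pitch
    ix$dur[b, seq_len(len)] <- cls$dur
    ix$vel[b, seq_len(len)] <- cls$vel
    ix$off[b, seq_len(len)] <- cls$off
    mask[b, seq_len(len - 1L)] <- 1
  }
  list(ix = ix, mask = mask)
}
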