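# Training engine for the 1D CNN / CNN-LSTM classifiers.
#
# Windows are processed as a single (B*T) x C matrix with contiguous
# per-sample blocks of T rows; causal convolution is then K shifted matrix
# products, which keeps the whole forward/backward pass in BLAS calls.
# Parameters live in one flat named list so the Adam update is a single
# loop. Everything is deterministic given the seed in training_options().

glorot <- function(n_in, n_out, dims) {
  lim <- sqrt(6 / (n_in + n_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# Layer plan (metadata only; parameters are created separately).
build_layer_plan <- function(spec, in_channels) {
  layers <- list()
  c_in <- in_channels
  bi <- 0L
  for (f in spec$blocks) {
    bi <- bi + 1L
    layers[[length(layers) + 1L]] <-
      list(type = "conv", prefix = sprintf("conv%d", bi), c_in = c_in, c_out = f)
    layers[[length(layers) + 1L]] <- list(type = "relu")
    layers[[length(layers) + 1L]] <-
      list(type = "ln", prefix = sprintf("ln%d", bi), c_out = f)
    c_in <- f
  }
  if (!is.null(spec$trailing)) {
    layers[[length(layers) + 1L]] <-
      list(type = "conv", prefix = "convT", c_in = c_in, c_out = spec$trailing)
    c_in <- spec$trailing
  }
  if (is.null(spec$lstm_hidden)) {
    layers[[length(layers) + 1L]] <- list(type = "gap")
  } else {
    layers[[length(layers) + 1L]] <-
      list(type = "lstm", prefix = "lstm", c_in = c_in, hidden = spec$lstm_hidden)
    c_in <- spec$lstm_hidden
    layers[[length(layers) + 1L]] <- list(type = "dropout", p = spec$dropout)
  }
  layers[[length(layers) + 1L]] <-
    list(type = "fc", prefix = "fc", c_in = c_in, c_out = spec$n_classes)
  layers
}

init_params <- function(layers, kernel) {
  par <- list()
  for (ly in layers) {
    if (ly$type == "conv") {
      for (k in seq_len(kernel)) {
        par[[paste0(ly$prefix, ".W", k)]] <-
          glorot(kernel * ly$c_in, kernel * ly$c_out, c(ly$c_in, ly$c_out))
      }
      par[[paste0(ly$prefix, ".b")]] <- numeric(ly$c_out)
    } else if (ly$type == "ln") {
      par[[paste0(ly$prefix, ".g")]] <- rep(1, ly$c_out)
      par[[paste0(ly$prefix, ".b")]] <- numeric(ly$c_out)
    } else if (ly$type == "lstm") {
      h <- ly$hidden
      par[[paste0(ly$prefix, ".Wx")]] <- glorot(ly$c_in, 4 * h, c(ly$c_in, 4 * h))
      par[[paste0(ly$prefix, ".Wh")]] <- glorot(h, 4 * h, c(h, 4 * h))
      b <- numeric(4 * h)
      b[(h + 1):(2 * h)] <- 1    # forget-gate bias starts open
      par[[paste0(ly$prefix, ".b")]] <- b
    } else if (ly$type == "fc") {
      par[[paste0(ly$prefix, ".W")]] <- glorot(ly$c_in, ly$c_out, c(ly$c_in, ly$c_out))
      par[[paste0(ly$prefix, ".b")]] <- numeric(ly$c_out)
    }
  }
  par
}

# causal shift by d rows within each of B contiguous T-row blocks
shift_down <- function(Z, d, block_pos) {
  if (d == 0L) return(Z)
  out <- matrix(0, nrow(Z), ncol(Z))
  valid <- block_pos > d
  out[valid, ] <- Z[which(valid) - d, , drop = FALSE]
  out
}

shift_down_adj <- function(dY, d, block_pos) {
  if (d == 0L) return(dY)
  out <- matrix(0, nrow(dY), ncol(dY))
  valid <- block_pos > d
  out[which(valid) - d, ] <- dY[valid, , drop = FALSE]
  out
}

LN_EPS <- 1e-5

forward_net <- function(layers, par, kernel, X, training = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; C <- dim(X)[3]
  Z <- matrix(aperm(X, c(2, 1, 3)), nrow = B * Tn, ncol = C)
  block_pos <- rep(seq_len(Tn), times = B)
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      Y <- matrix(rep(par[[paste0(ly$prefix, ".b")]], each = nrow(Z)),
                  nrow(Z), ly$c_out)
      for (k in seq_len(kernel)) {
        Y <- Y + shift_down(Z, k - 1L, block_pos) %*% par[[paste0(ly$prefix, ".W", k)]]
      }
      caches[[i]] <- list(Zin = Z)
      Z <- Y
    } else if (ly$type == "relu") {
      caches[[i]] <- list(mask = Z > 0)
      Z <- Z * caches[[i]]$mask
    } else if (ly$type == "ln") {
      mu <- rowMeans(Z)
      xc <- Z - mu
      sd_ <- sqrt(rowMeans(xc^2) + LN_EPS)
      xhat <- xc / sd_
      caches[[i]] <- list(xhat = xhat, sd = sd_)
      Z <- sweep(sweep(xhat, 2, par[[paste0(ly$prefix, ".g")]], "*"),
                 2, par[[paste0(ly$prefix, ".b")]], "+")
    } else if (ly$type == "gap") {
      grp <- rep(seq_len(B), each = Tn)
      caches[[i]] <- list(B = B, Tn = Tn)
      Z <- rowsum(Z, grp) / Tn              # B x C
    } else if (ly$type == "lstm") {
      h <- ly$hidden
      Wx <- par[[paste0(ly$prefix, ".Wx")]]
      Wh <- par[[paste0(ly$prefix, ".Wh")]]
      b <- par[[paste0(ly$prefix, ".b")]]
      H <- matrix(0, B, h); Cst <- matrix(0, B, h)
      steps <- vector("list", Tn)
      idx_t <- function(t) (seq_len(B) - 1L) * Tn + t
      for (t in seq_len(Tn)) {
        Xt <- Z[idx_t(t), , drop = FALSE]
        G <- Xt %*% Wx + H %*% Wh + matrix(rep(b, each = B), B, 4 * h)
        ig <- 1 / (1 + exp(-G[, 1:h, drop = FALSE]))
        fg <- 1 / (1 + exp(-G[, (h + 1):(2 * h), drop = FALSE]))
        gg <- tanh(G[, (2 * h + 1):(3 * h), drop = FALSE])
        og <- 1 / (1 + exp(-G[, (3 * h + 1):(4 * h), drop = FALSE]))
        Cprev <- Cst
        Cst <- fg * Cprev + ig * gg
        tc <- tanh(Cst)
        Hprev <- H
        H <- og * tc
        steps[[t]] <- list(Xt = Xt, Hprev = Hprev, Cprev = Cprev,
                           i = ig, f = fg, g = gg, o = og, tc = tc)
      }
      caches[[i]] <- list(steps = steps, B = B, Tn = Tn)
      Z <- H                                 # B x hidden (last state)
    } else if (ly$type == "dropout") {
      if (training && ly$p > 0) {
        mask <- matrix((stats::runif(length(Z)) >= ly$p) / (1 - ly$p),
                       nrow(Z), ncol(Z))
        caches[[i]] <- list(mask = mask)
        Z <- Z * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (ly$type == "fc") {
      caches[[i]] <- list(Zin = Z)
      Z <- Z %*% par[[paste0(ly$prefix, ".W")]] +
        matrix(rep(par[[paste0(ly$prefix, ".b")]], each = nrow(Z)),
               nrow(Z), ly$c_out)
    }
  }
  list(logits = Z, caches = caches, block_pos = block_pos)
}

softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  e <- exp(L - m)
  e / rowSums(e)
}

# Backward pass; y is an integer class vector (1-based). Returns gradients
# as a flat list parallel to `par`, plus the mean cross-entropy loss.
backward_net <- function(layers, par, kernel, fwd, y) {
  P <- softmax_rows(fwd$logits)
  B <- nrow(P)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ / B
  grads <- list()
  block_pos <- fwd$block_pos
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cache <- fwd$caches[[i]]
    if (ly$type == "fc") {
      W <- par[[paste0(ly$prefix, ".W")]]
      grads[[paste0(ly$prefix, ".W")]] <- t(cache$Zin) %*% dZ
      grads[[paste0(ly$prefix, ".b")]] <- colSums(dZ)
      dZ <- dZ %*% t(W)
    } else if (ly$type == "dropout") {
      if (!is.null(cache$mask)) dZ <- dZ * cache$mask
    } else if (ly$type == "lstm") {
      h <- ly$hidden
      Wx <- par[[paste0(ly$prefix, ".Wx")]]
      Wh <- par[[paste0(ly$prefix, ".Wh")]]
      Bn <- cache$B; Tn <- cache$Tn
      dWx <- matrix(0, nrow(Wx), ncol(Wx))
      dWh <- matrix(0, nrow(Wh), ncol(Wh))
      db <- numeric(4 * h)
      dH <- dZ; dC <- matrix(0, Bn, h)
      dXall <- matrix(0, Bn * Tn, ly$c_in)
      idx_t <- function(t) (seq_len(Bn) - 1L) * Tn + t
      for (t in rev(seq_len(Tn))) {
        st <- cache$steps[[t]]
        do_ <- dH * st$tc
        dC <- dC + dH * st$o * (1 - st$tc^2)
        di <- dC * st$g
        df <- dC * st$Cprev
        dg <- dC * st$i
        dCprev <- dC * st$f
        dG <- cbind(di * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    dg * (1 - st$g^2),
                    do_ * st$o * (1 - st$o))
        dWx <- dWx + t(st$Xt) %*% dG
        dWh <- dWh + t(st$Hprev) %*% dG
        db <- db + colSums(dG)
        dXall[idx_t(t), ] <- dG %*% t(Wx)
        dH <- dG %*% t(Wh)
        dC <- dCprev
      }
      grads[[paste0(ly$prefix, ".Wx")]] <- dWx
      grads[[paste0(ly$prefix, ".Wh")]] <- dWh
      grads[[paste0(ly$prefix, ".b")]] <- db
      dZ <- dXall
    } else if (ly$type == "gap") {
      Bn <- cache$B; Tn <- cache$Tn
      dZ <- dZ[rep(seq_len(Bn), each = Tn), , drop = FALSE] / Tn
    } else if (ly$type == "ln") {
      g <- par[[paste0(ly$prefix, ".g")]]
      xhat <- cache$xhat
      grads[[paste0(ly$prefix, ".g")]] <- colSums(dZ * xhat)
      grads[[paste0(ly$prefix, ".b")]] <- colSums(dZ)
      dxhat <- sweep(dZ, 2, g, "*")
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * xhat)
      dZ <- (dxhat - m1 - xhat * m2) / cache$sd
    } else if (ly$type == "relu") {
      dZ <- dZ * cache$mask
    } else if (ly$type == "conv") {
      Zin <- cache$Zin
      dIn <- matrix(0, nrow(Zin), ncol(Zin))
      for (k in seq_len(kernel)) {
        Wk <- par[[paste0(ly$prefix, ".W", k)]]
        grads[[paste0(ly$prefix, ".W", k)]] <-
          t(shift_down(Zin, k - 1L, block_pos)) %*% dZ
        dIn <- dIn + shift_down_adj(dZ %*% t(Wk), k - 1L, block_pos)
      }
      grads[[paste0(ly$prefix, ".b")]] <- colSums(dZ)
      dZ <- dIn
    }
  }
  list(grads = grads, loss = loss)
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}
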