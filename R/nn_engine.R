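#' Minimal 1-D neural-network engine
#'
#' A compact, dependency-free engine for the architecture zoo: 1-D
#' convolution, max pooling, global average pooling, dense, dropout,
#' residual blocks, (bi)LSTM and GRU layers, trained with Adam on a mean
#' squared error loss. Tensors are base-R arrays laid out as
#' (batch, time, channel); dense activations are (batch, feature) matrices.
#' Convolutions are computed by patch-matrix multiplication. Everything is
#' deterministic given the R RNG state.
#'
#' @name ppgbp-nn
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

uniform_init <- function(nrow, ncol, scale) {
  matrix(stats::runif(nrow * ncol, -scale, scale), nrow, ncol)
}

conv_out_len <- function(t_in, kernel, stride, pad) {
  floor((t_in + 2 * pad - kernel) / stride) + 1
}

# --- layer constructors -----------------------------------------------------

nn_conv1d <- function(in_ch, out_ch, kernel, stride = 1, pad = 0) {
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       stride = stride, pad = pad,
       params = list(W = he_init(kernel * in_ch, out_ch, kernel * in_ch),
                     b = numeric(out_ch)))
}

nn_dense <- function(in_dim, out_dim, is_head = FALSE) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim, is_head = is_head,
       params = list(W = he_init(in_dim, out_dim, in_dim),
                     b = numeric(out_dim)))
}

nn_relu <- function() list(type = "relu", params = list())
nn_flatten <- function() list(type = "flatten", params = list())
nn_gap <- function() list(type = "gap", params = list())
nn_dropout <- function(p = 0.5) list(type = "dropout", p = p, params = list())

nn_maxpool <- function(kernel, stride = kernel) {
  list(type = "maxpool", kernel = kernel, stride = stride, params = list())
}

nn_residual <- function(branch, shortcut = NULL) {
  list(type = "residual", branch = branch, shortcut = shortcut,
       params = list())
}

nn_lstm <- function(in_ch, hidden, bidirectional = TRUE,
                    return_seq = TRUE) {
  mk_dir <- function() {
    s <- 1 / sqrt(hidden)
    list(Wx = uniform_init(in_ch, 4 * hidden, s),
         Wh = uniform_init(hidden, 4 * hidden, s),
         b = numeric(4 * hidden))
  }
  params <- list(fwd = mk_dir())
  if (bidirectional) params$bwd <- mk_dir()
  list(type = "lstm", in_ch = in_ch, hidden = hidden,
       bidirectional = bidirectional, return_seq = return_seq,
       params = params)
}

nn_gru <- function(in_ch, hidden, return_seq = FALSE) {
  s <- 1 / sqrt(hidden)
  list(type = "gru", in_ch = in_ch, hidden = hidden,
       return_seq = return_seq,
       params = list(Wx = uniform_init(in_ch, 3 * hidden, s),
                     Wh = uniform_init(hidden, 3 * hidden, s),
                     b = numeric(3 * hidden)))
}

# Fixed linear interpolation along the time axis (no parameters).
nn_interp <- function(in_len, out_len) {
  pos <- if (out_len == 1) 1 else (seq_len(out_len) - 1) *
    (in_len - 1) / (out_len - 1) + 1
  i0 <- pmin(floor(pos), in_len - 1)
  w <- pos - i0
  list(type = "interp", in_len = in_len, out_len = out_len,
       i0 = as.integer(i0), w = w, params = list())
}

# Parallel front: a temporal conv branch on the raw input and a branch on a
# fixed log-magnitude spectrogram of channel 1; outputs are concatenated
# along the channel axis (branch outputs must share the time length).
nn_two_branch <- function(branch_a, branch_b, nfft, hop) {
  list(type = "two_branch", branch_a = branch_a, branch_b = branch_b,
       nfft = nfft, hop = hop, params = list())
}

# --- fixed transforms -------------------------------------------------------

# Log-magnitude STFT frames of a (batch, time) matrix -> (batch, frames,
# nfft/2 + 1). Hann window; natural log of power + epsilon.
stft_logmag <- function(x, nfft, hop) {
  B <- nrow(x); T <- ncol(x)
  if (T < nfft) stop("input shorter than one STFT frame")
  starts <- seq(1, T - nfft + 1, by = hop)
  nf <- length(starts)
  nb <- nfft %/% 2 + 1
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  out <- array(0, c(B, nf, nb))
  for (j in seq_len(nf)) {
    seg <- x[, starts[j]:(starts[j] + nfft - 1), drop = FALSE]
    seg <- sweep(seg, 2, win, "*")
    sp <- t(apply(seg, 1, function(r) Mod(stats::fft(r))[1:nb]^2))
    if (B == 1) sp <- matrix(sp, 1)
    out[, j, ] <- log(sp + 1e-6)
  }
  out
}

# --- forward / backward -----------------------------------------------------

ensure_3d <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
}

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv1d = {
      d <- dim(x); B <- d[1]; Tt <- d[2]; C <- d[3]
      pad <- layer$pad
      if (pad > 0) {
        xp <- array(0, c(B, Tt + 2 * pad, C))
        xp[, (pad + 1):(pad + Tt), ] <- x
        x <- xp; Tt <- Tt + 2 * pad
      }
      K <- layer$kernel
      starts <- seq(1, Tt - K + 1, by = layer$stride)
      To <- length(starts)
      Xcol <- matrix(0, B * To, K * C)
      col <- 1L
      for (c3 in seq_len(C)) for (k in seq_len(K)) {
        Xcol[, col] <- as.vector(x[, starts + k - 1, c3])
        col <- col + 1L
      }
      out2 <- sweep(Xcol %*% layer$params$W, 2, layer$params$b, "+")
      list(out = array(out2, c(B, To, layer$out_ch)),
           cache = list(Xcol = Xcol, starts = starts, B = B, Tp = Tt,
                        C = C, pad = pad))
    },
    dense = {
      list(out = sweep(x %*% layer$params$W, 2, layer$params$b, "+"),
           cache = list(x = x))
    },
    relu = {
      mask <- x > 0
      out <- x
      out[!mask] <- 0
      list(out = out, cache = list(mask = mask))
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], d[2] * d[3]), cache = list(d = d))
    },
    gap = {
      d <- dim(x)
      out <- matrix(0, d[1], d[3])
      for (c3 in seq_len(d[3])) {
        out[, c3] <- rowMeans(matrix(x[, , c3], d[1], d[2]))
      }
      list(out = out, cache = list(d = d))
    },
    dropout = {
      if (train && layer$p > 0) {
        mask <- array(stats::runif(length(x)) >= layer$p,
                      dim(x)) / (1 - layer$p)
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    maxpool = {
      d <- dim(x); B <- d[1]; Tt <- d[2]; C <- d[3]
      K <- layer$kernel
      starts <- seq(1, Tt - K + 1, by = layer$stride)
      cur <- x[, starts, , drop = FALSE]
      arg <- array(1L, dim(cur))
      if (K > 1) for (k in 2:K) {
        sl <- x[, starts + k - 1, , drop = FALSE]
        upd <- sl > cur
        cur[upd] <- sl[upd]
        arg[upd] <- k
      }
      list(out = cur, cache = list(arg = arg, starts = starts, d = d))
    },
    residual = {
      caches <- vector("list", length(layer$branch))
      h <- x
      for (i in seq_along(layer$branch)) {
        fw <- layer_forward(layer$branch[[i]], h, train)
        h <- fw$out; caches[[i]] <- fw$cache
      }
      if (is.null(layer$shortcut)) {
        s <- x; scache <- NULL
      } else {
        fw <- layer_forward(layer$shortcut, x, train)
        s <- fw$out; scache <- fw$cache
      }
      pre <- h + s
      mask <- pre > 0
      out <- pre; out[!mask] <- 0
      list(out = out, cache = list(branch = caches, shortcut = scache,
                                   mask = mask))
    },
    lstm = {
      fwd <- lstm_dir_forward(x, layer$params$fwd, layer$hidden,
                              reverse = FALSE)
      if (layer$bidirectional) {
        bwd <- lstm_dir_forward(x, layer$params$bwd, layer$hidden,
                                reverse = TRUE)
      } else bwd <- NULL
      d <- dim(x); B <- d[1]; Tt <- d[2]; H <- layer$hidden
      if (layer$return_seq) {
        out <- array(0, c(B, Tt, if (is.null(bwd)) H else 2 * H))
        for (t in seq_len(Tt)) {
          out[, t, 1:H] <- fwd$h[[t]]
          if (!is.null(bwd)) out[, t, (H + 1):(2 * H)] <- bwd$h[[Tt - t + 1]]
        }
      } else {
        out <- if (is.null(bwd)) fwd$h[[Tt]] else
          cbind(fwd$h[[Tt]], bwd$h[[Tt]])  # bwd final state saw t = 1..T
      }
      list(out = out, cache = list(fwd = fwd, bwd = bwd, x = x))
    },
    gru = {
      res <- gru_forward(x, layer$params, layer$hidden)
      d <- dim(x); Tt <- d[2]
      out <- if (layer$return_seq) {
        o <- array(0, c(d[1], Tt, layer$hidden))
        for (t in seq_len(Tt)) o[, t, ] <- res$h[[t]]
        o
      } else res$h[[Tt]]
      list(out = out, cache = list(res = res, x = x))
    },
    interp = {
      d <- dim(x)
      out <- array(0, c(d[1], layer$out_len, d[3]))
      for (j in seq_len(layer$out_len)) {
        i0 <- layer$i0[j]; w <- layer$w[j]
        out[, j, ] <- (1 - w) * x[, i0, ] + w * x[, i0 + 1, ]
      }
      list(out = out, cache = list(d = d))
    },
    two_branch = {
      ca <- list(); h <- x
      for (i in seq_along(layer$branch_a)) {
        fw <- layer_forward(layer$branch_a[[i]], h, train)
        h <- fw$out; ca[[i]] <- fw$cache
      }
      spec <- stft_logmag(matrix(x[, , 1], dim(x)[1], dim(x)[2]),
                          layer$nfft, layer$hop)
      cb <- list(); g <- spec
      for (i in seq_along(layer$branch_b)) {
        fw <- layer_forward(layer$branch_b[[i]], g, train)
        g <- fw$out; cb[[i]] <- fw$cache
      }
      if (dim(h)[2] != dim(g)[2]) {
        stop("branch time lengths differ; check interp configuration")
      }
      da <- dim(h); db <- dim(g)
      out <- array(0, c(da[1], da[2], da[3] + db[3]))
      out[, , 1:da[3]] <- h
      out[, , (da[3] + 1):(da[3] + db[3])] <- g
      list(out = out, cache = list(a = ca, b = cb, na = da[3], nb = db[3],
                                   spec_dim = dim(spec)))
    },
    stop(sprintf("unknown layer type '%s'", layer$type))
  )
}

layer_backward <- function(layer, cache, gout) {
  switch(layer$type,
    conv1d = {
      B <- cache$B; To <- length(cache$starts)
      Fch <- layer$out_ch
      g2 <- matrix(gout, B * To, Fch)
      gW <- crossprod(cache$Xcol, g2)
      gb <- colSums(g2)
      gXcol <- g2 %*% t(layer$params$W)
      gx <- array(0, c(B, cache$Tp, cache$C))
      col <- 1L
      for (c3 in seq_len(cache$C)) for (k in seq_len(layer$kernel)) {
        gx[, cache$starts + k - 1, c3] <-
          gx[, cache$starts + k - 1, c3] + matrix(gXcol[, col], B, To)
        col <- col + 1L
      }
      if (cache$pad > 0) {
        gx <- gx[, (cache$pad + 1):(cache$Tp - cache$pad), , drop = FALSE]
      }
      list(gin = gx, grads = list(W = gW, b = gb))
    },
    dense = {
      list(gin = gout %*% t(layer$params$W),
           grads = list(W = crossprod(cache$x, gout), b = colSums(gout)))
    },
    relu = {
      g <- gout
      g[!cache$mask] <- 0
      list(gin = g, grads = list())
    },
    flatten = {
      list(gin = array(gout, cache$d), grads = list())
    },
    gap = {
      d <- cache$d
      gx <- array(0, d)
      for (c3 in seq_len(d[3])) gx[, , c3] <- matrix(gout[, c3] / d[2],
                                                     d[1], d[2])
      list(gin = gx, grads = list())
    },
    dropout = {
      list(gin = if (is.null(cache$mask)) gout else gout * cache$mask,
           grads = list())
    },
    maxpool = {
      d <- cache$d
      gx <- array(0, d)
      for (k in seq_len(layer$kernel)) {
        mask <- cache$arg == k
        if (any(mask)) {
          gx[, cache$starts + k - 1, ] <-
            gx[, cache$starts + k - 1, ] + gout * mask
        }
      }
      list(gin = gx, grads = list())
    },
    residual = {
      g <- gout
      g[!cache$mask] <- 0
      grads_branch <- vector("list", length(layer$branch))
      gb <- g
      for (i in rev(seq_along(layer$branch))) {
        bw <- layer_backward(layer$branch[[i]], cache$branch[[i]], gb)
        grads_branch[[i]] <- bw$grads
        gb <- bw$gin
      }
      if (is.null(layer$shortcut)) {
        gs <- g; grads_short <- NULL
      } else {
        bw <- layer_backward(layer$shortcut, cache$shortcut, g)
        gs <- bw$gin; grads_short <- bw$grads
      }
      list(gin = gb + gs,
           grads = list(branch = grads_branch, shortcut = grads_short))
    },
    lstm = {
      d <- dim(cache$x); B <- d[1]; Tt <- d[2]; H <- layer$hidden
      if (layer$return_seq) {
        gf <- lapply(seq_len(Tt), function(t)
          matrix(gout[, t, 1:H], B, H))
        gb_list <- if (layer$bidirectional) {
          lapply(seq_len(Tt), function(t)
            matrix(gout[, Tt - t + 1, (H + 1):(2 * H)], B, H))
        } else NULL
      } else {
        zero <- matrix(0, B, H)
        gf <- c(rep(list(zero), Tt - 1), list(matrix(gout[, 1:H], B, H)))
        gb_list <- if (layer$bidirectional) {
          c(rep(list(zero), Tt - 1),
            list(matrix(gout[, (H + 1):(2 * H)], B, H)))
        } else NULL
      }
      bwf <- lstm_dir_backward(cache$x, layer$params$fwd, cache$fwd, gf,
                               reverse = FALSE)
      gin <- bwf$gx
      grads <- list(fwd = bwf$grads)
      if (layer$bidirectional) {
        bwb <- lstm_dir_backward(cache$x, layer$params$bwd, cache$bwd,
                                 gb_list, reverse = TRUE)
        gin <- gin + bwb$gx
        grads$bwd <- bwb$grads
      }
      list(gin = gin, grads = grads)
    },
    gru = {
      d <- dim(cache$x); B <- d[1]; Tt <- d[2]; H <- layer$hidden
      gh <- if (layer$return_seq) {
        lapply(seq_len(Tt), function(t) matrix(gout[, t, ], B, H))
      } else {
        c(rep(list(matrix(0, B, H)), Tt - 1), list(gout))
      }
      bw <- gru_backward(cache$x, layer$params, cache$res, gh)
      list(gin = bw$gx, grads = bw$grads)
    },
    interp = {
      d <- cache$d
      gx <- array(0, d)
      for (j in seq_len(layer$out_len)) {
        i0 <- layer$i0[j]; w <- layer$w[j]
        gx[, i0, ] <- gx[, i0, ] + (1 - w) * gout[, j, ]
        gx[, i0 + 1, ] <- gx[, i0 + 1, ] + w * gout[, j, ]
      }
      list(gin = gx, grads = list())
    },
    two_branch = {
      na <- cache$na; nb <- cache$nb
      ga <- gout[, , 1:na, drop = FALSE]
      gb <- gout[, , (na + 1):(na + nb), drop = FALSE]
      grads_a <- vector("list", length(layer$branch_a))
      g <- ga
      for (i in rev(seq_along(layer$branch_a))) {
        bw <- layer_backward(layer$branch_a[[i]], cache$a[[i]], g)
        grads_a[[i]] <- bw$grads
        g <- bw$gin
      }
      grads_b <- vector("list", length(layer$branch_b))
      g <- gb
      for (i in rev(seq_along(layer$branch_b))) {
        bw <- layer_backward(layer$branch_b[[i]], cache$b[[i]], g)
        grads_b[[i]] <- bw$grads
        g <- bw$gin
      }
      # gradient into the fixed spectrogram is discarded; the raw input is
      # the network input, so no upstream parameters exist
      list(gin = NULL, grads = list(branch_a = grads_a, branch_b = grads_b))
    },
    stop(sprintf("unknown layer type '%s'", layer$type))
  )
}

# --- recurrent internals ----------------------------------------------------

lstm_dir_forward <- function(x, p, H, reverse = FALSE) {
  d <- dim(x); B <- d[1]; Tt <- d[2]
  ts <- if (reverse) rev(seq_len(Tt)) else seq_len(Tt)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", Tt); gates <- vector("list", Tt)
  cs <- vector("list", Tt); tcs <- vector("list", Tt)
  cprev <- vector("list", Tt); hprev <- vector("list", Tt)
  step <- 0L
  for (t in ts) {
    step <- step + 1L
    xt <- matrix(x[, t, ], B, d[3])
    z <- sweep(xt %*% p$Wx + h %*% p$Wh, 2, p$b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cprev[[step]] <- cc; hprev[[step]] <- h
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    hs[[step]] <- h
    gates[[step]] <- list(i = i, f = f, o = o, g = g)
    cs[[step]] <- cc; tcs[[step]] <- tc
  }
  list(h = hs, gates = gates, c = cs, tc = tcs, cprev = cprev,
       hprev = hprev, ts = ts)
}

# gh: list over processing steps (aligned with cache$ts) of (B, H) gradients
lstm_dir_backward <- function(x, p, cache, gh, reverse = FALSE) {
  d <- dim(x); B <- d[1]; Tt <- d[2]; C <- d[3]
  H <- ncol(cache$h[[1]])
  gWx <- matrix(0, C, 4 * H); gWh <- matrix(0, H, 4 * H); gb <- numeric(4 * H)
  gx <- array(0, d)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (step in rev(seq_len(Tt))) {
    t <- cache$ts[step]
    gt <- cache$gates[[step]]
    dh <- gh[[step]] + dh_next
    tc <- cache$tc[[step]]
    do <- dh * tc
    dc <- dc_next + dh * gt$o * (1 - tc^2)
    di <- dc * gt$g
    dg <- dc * gt$i
    df <- dc * cache$cprev[[step]]
    dc_next <- dc * gt$f
    dz <- cbind(di * gt$i * (1 - gt$i),
                df * gt$f * (1 - gt$f),
                do * gt$o * (1 - gt$o),
                dg * (1 - gt$g^2))
    xt <- matrix(x[, t, ], B, C)
    gWx <- gWx + crossprod(xt, dz)
    gWh <- gWh + crossprod(cache$hprev[[step]], dz)
    gb <- gb + colSums(dz)
    dh_next <- dz %*% t(p$Wh)
    gx[, t, ] <- gx[, t, ] + dz %*% t(p$Wx)
  }
  list(gx = gx, grads = list(Wx = gWx, Wh = gWh, b = gb))
}

gru_forward <- function(x, p, H) {
  d <- dim(x); B <- d[1]; Tt <- d[2]
  h <- matrix(0, B, H)
  hs <- vector("list", Tt); gates <- vector("list", Tt)
  hprev <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- matrix(x[, t, ], B, d[3])
    zx <- sweep(xt %*% p$Wx, 2, p$b, "+")
    zh <- h %*% p$Wh
    r <- sigmoid(zx[, 1:H, drop = FALSE] + zh[, 1:H, drop = FALSE])
    z <- sigmoid(zx[, (H + 1):(2 * H), drop = FALSE] +
                   zh[, (H + 1):(2 * H), drop = FALSE])
    n_pre <- zx[, (2 * H + 1):(3 * H), drop = FALSE] +
      (r * h) %*% p$Wh[, (2 * H + 1):(3 * H), drop = FALSE]
    n <- tanh(n_pre)
    hprev[[t]] <- h
    h <- (1 - z) * n + z * h
    hs[[t]] <- h
    gates[[t]] <- list(r = r, z = z, n = n)
  }
  list(h = hs, gates = gates, hprev = hprev)
}

gru_backward <- function(x, p, cache, gh) {
  d <- dim(x); B <- d[1]; Tt <- d[2]; C <- d[3]
  H <- ncol(cache$h[[1]])
  Whr <- p$Wh[, 1:H, drop = FALSE]
  Whz <- p$Wh[, (H + 1):(2 * H), drop = FALSE]
  Whn <- p$Wh[, (2 * H + 1):(3 * H), drop = FALSE]
  gWx <- matrix(0, C, 3 * H); gWh <- matrix(0, H, 3 * H); gb <- numeric(3 * H)
  gx <- array(0, d)
  dh_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tt))) {
    gt <- cache$gates[[t]]
    hp <- cache$hprev[[t]]
    dh <- gh[[t]] + dh_next
    dz <- dh * (hp - gt$n)
    dn <- dh * (1 - gt$z)
    dhp <- dh * gt$z
    dn_pre <- dn * (1 - gt$n^2)
    drh <- dn_pre %*% t(Whn)
    dr <- drh * hp
    dhp <- dhp + drh * gt$r
    dz_pre <- dz * gt$z * (1 - gt$z)
    dr_pre <- dr * gt$r * (1 - gt$r)
    dhp <- dhp + dz_pre %*% t(Whz) + dr_pre %*% t(Whr)
    xt <- matrix(x[, t, ], B, C)
    dzx <- cbind(dr_pre, dz_pre, dn_pre)
    gWx <- gWx + crossprod(xt, dzx)
    gb <- gb + colSums(dzx)
    gWh <- gWh + cbind(crossprod(hp, dr_pre), crossprod(hp, dz_pre),
                       crossprod(gt$r * hp, dn_pre))
    gx[, t, ] <- gx[, t, ] + dzx %*% t(p$Wx)
    dh_next <- dhp
  }
  list(gx = gx, grads = list(Wx = gWx, Wh = gWh, b = gb))
}

# --- network-level plumbing -------------------------------------------------

nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  h <- x
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], h, train)
    h <- fw$out; caches[[i]] <- fw$cache
  }
  list(out = h, caches = caches)
}

nn_backward <- function(layers, caches, gout) {
  grads <- vector("list", length(layers))
  g <- gout
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], g)
    grads[[i]] <- bw$grads
    g <- bw$gin
  }
  grads
}

# Recursive map over the (possibly nested) parameter structure of a layer
# and its matching gradient structure. `prefix` keeps the optimizer-state
# key unique per nested sub-layer.
map_params <- function(layer, grad, fn, prefix = character(0)) {
  if (layer$type == "residual") {
    for (i in seq_along(layer$branch)) {
      layer$branch[[i]] <- map_params(layer$branch[[i]], grad$branch[[i]],
                                      fn, c(prefix, paste0("br", i)))
    }
    if (!is.null(layer$shortcut)) {
      layer$shortcut <- map_params(layer$shortcut, grad$shortcut, fn,
                                   c(prefix, "sc"))
    }
    return(layer)
  }
  if (layer$type == "two_branch") {
    for (i in seq_along(layer$branch_a)) {
      layer$branch_a[[i]] <- map_params(layer$branch_a[[i]],
                                        grad$branch_a[[i]], fn,
                                        c(prefix, paste0("a", i)))
    }
    for (i in seq_along(layer$branch_b)) {
      layer$branch_b[[i]] <- map_params(layer$branch_b[[i]],
                                        grad$branch_b[[i]], fn,
                                        c(prefix, paste0("b", i)))
    }
    return(layer)
  }
  if (layer$type == "lstm") {
    for (dir in names(layer$params)) {
      for (nm in names(layer$params[[dir]])) {
        layer$params[[dir]][[nm]] <-
          fn(layer$params[[dir]][[nm]], grad[[dir]][[nm]],
             c(prefix, layer$type, dir, nm))
      }
    }
    return(layer)
  }
  for (nm in names(layer$params)) {
    layer$params[[nm]] <- fn(layer$params[[nm]], grad[[nm]],
                             c(prefix, layer$type, nm))
  }
  layer
}

# Adam optimizer over a layer list. State is kept in a closure environment
# keyed by "layeridx/path"; the update itself is the standard bias-corrected
# first/second moment rule.
adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  env <- new.env(parent = emptyenv())
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, state = env,
       t = 0L)
}

adam_step <- function(opt, layers, grads, trainable_only_head = FALSE) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  for (i in seq_along(layers)) {
    if (trainable_only_head && !isTRUE(layers[[i]]$is_head)) next
    if (!length(grads[[i]])) next
    key_base <- paste0("L", i)
    layers[[i]] <- map_params(layers[[i]], grads[[i]], function(p, g, path) {
      if (is.null(g)) return(p)
      key <- paste(c(key_base, path), collapse = "/")
      st <- opt$state[[key]]
      if (is.null(st)) st <- list(m = p * 0, v = p * 0)
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      opt$state[[key]] <- st
      p - opt$lr * (st$m / corr1) / (sqrt(st$v / corr2) + opt$eps)
    })
  }
  list(opt = opt, layers = layers)
}
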