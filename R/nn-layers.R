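# Layer primitives and parameter plumbing for the denoising network.
# Feature maps are (H, W, C) arrays; convolution weights (k, k, Cin, Cout).
# Every forward returns list(y, cache); every backward consumes the cache
# and returns list(gx, grads) with grads shaped like the parameter node.

nn_conv_fw <- function(x, p) {
  .conv2d_fw(x, as.numeric(p$w), p$b, dim(p$w)[1], dim(p$w)[4])
}

nn_conv_bw <- function(x, p, gy) {
  r <- .conv2d_bw(x, as.numeric(p$w), gy, dim(p$w)[1])
  list(gx = r$gx, grads = list(w = array(r$gw, dim(p$w)), b = r$gb))
}

nn_upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

nn_upsample2_bw <- function(gy) {
  d <- dim(gy)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  gy[io, jo, , drop = FALSE] + gy[io + 1, jo, , drop = FALSE] +
    gy[io, jo + 1, , drop = FALSE] + gy[io + 1, jo + 1, , drop = FALSE]
}

nn_concat <- function(a, b) {
  da <- dim(a)
  out <- array(0, c(da[1], da[2], da[3] + dim(b)[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(dim(b)[3])] <- b
  out
}

nn_split <- function(g, c1) {
  d <- dim(g)
  list(a = g[, , seq_len(c1), drop = FALSE],
       b = g[, , (c1 + 1):d[3], drop = FALSE])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# He-normal conv weight init; projection convs get small init so that an
# untrained block is close to the identity map.
init_conv <- function(k, cin, cout, gain = 2) {
  list(w = array(rnorm(k * k * cin * cout, 0,
                       sqrt(gain / (k * k * cin))), c(k, k, cin, cout)),
       b = numeric(cout))
}

# Residual double-convolution block: y = conv2(relu(conv1(x))) + proj(x).
# proj is a 1x1 channel-matching convolution, present iff cin != cout.
init_resblock <- function(k, cin, cout) {
  p <- list(conv1 = init_conv(k, cin, cout), conv2 = init_conv(k, cout, cout))
  if (cin != cout) p$proj <- init_conv(1, cin, cout)
  p
}

resblock_fw <- function(x, p) {
  h1 <- nn_conv_fw(x, p$conv1)
  a1 <- h1 * (h1 > 0)
  y <- nn_conv_fw(a1, p$conv2)
  y <- y + if (is.null(p$proj)) x else nn_conv_fw(x, p$proj)
  list(y = y, cache = list(x = x, mask = h1 > 0, a1 = a1))
}

resblock_bw <- function(gy, p, cache) {
  r2 <- nn_conv_bw(cache$a1, p$conv2, gy)
  gh1 <- r2$gx * cache$mask
  r1 <- nn_conv_bw(cache$x, p$conv1, gh1)
  grads <- list(conv1 = r1$grads, conv2 = r2$grads)
  if (is.null(p$proj)) {
    gx <- r1$gx + gy
  } else {
    rp <- nn_conv_bw(cache$x, p$proj, gy)
    grads$proj <- rp$grads
    gx <- r1$gx + rp$gx
  }
  list(gx = gx, grads = grads)
}

# ---- Residual U-Net (4 levels, shared across frames) ----------------------

init_unet <- function(spec, in_channels = 1, out_channels = NULL) {
  base <- spec$base_channels; k <- spec$kernel_size
  if (is.null(out_channels)) out_channels <- base
  ch <- base * 2^(0:3)                   # encoder channels per level
  cb <- base * 16                        # bottleneck
  P <- list(enc = vector("list", 4), up = vector("list", 4),
            dec = vector("list", 4))
  cin <- in_channels
  for (l in 1:4) {
    P$enc[[l]] <- init_resblock(k, cin, ch[l])
    cin <- ch[l]
  }
  P$bott <- init_resblock(k, ch[4], cb)
  cup <- cb
  for (l in 4:1) {
    P$up[[l]] <- init_conv(k, cup, ch[l])       # conv after 2x upsample
    P$dec[[l]] <- init_resblock(k, 2 * ch[l], ch[l])
    cup <- ch[l]
  }
  P$head <- init_conv(1, ch[1], out_channels)
  P
}

unet_fw <- function(x, P) {
  skips <- vector("list", 4)
  cache <- list(enc = vector("list", 4), pool = vector("list", 4),
                up = vector("list", 4), dec = vector("list", 4))
  cur <- x
  for (l in 1:4) {
    r <- resblock_fw(cur, P$enc[[l]])
    cache$enc[[l]] <- r$cache
    skips[[l]] <- r$y
    mp <- .maxpool2_fw(r$y)
    cache$pool[[l]] <- list(idx = mp$idx, H = dim(r$y)[1], W = dim(r$y)[2])
    cur <- mp$y
  }
  r <- resblock_fw(cur, P$bott)
  cache$bott <- r$cache
  cur <- r$y
  for (l in 4:1) {
    up <- nn_upsample2(cur)
    u <- nn_conv_fw(up, P$up[[l]])
    cat3 <- nn_concat(u, skips[[l]])
    r <- resblock_fw(cat3, P$dec[[l]])
    cache$up[[l]] <- up
    cache$dec[[l]] <- r$cache
    cur <- r$y
  }
  cache$pre_head <- cur
  list(y = nn_conv_fw(cur, P$head), cache = cache)
}

unet_bw <- function(gy, P, cache) {
  rh <- nn_conv_bw(cache$pre_head, P$head, gy)
  grads <- list(enc = vector("list", 4), up = vector("list", 4),
                dec = vector("list", 4), head = rh$grads)
  gcur <- rh$gx
  gskip <- vector("list", 4)
  for (l in 1:4) {
    rd <- resblock_bw(gcur, P$dec[[l]], cache$dec[[l]])
    grads$dec[[l]] <- rd$grads
    sp <- nn_split(rd$gx, dim(rd$gx)[3] / 2)  # u and skip: equal channels
    ru <- nn_conv_bw(cache$up[[l]], P$up[[l]], sp$a)
    grads$up[[l]] <- ru$grads
    gskip[[l]] <- sp$b
    gcur <- nn_upsample2_bw(ru$gx)
  }
  rb <- resblock_bw(gcur, P$bott, cache$bott)
  grads$bott <- rb$grads
  gcur <- rb$gx
  for (l in 4:1) {
    pl <- cache$pool[[l]]
    g <- .maxpool2_bw(gcur, pl$idx, pl$H, pl$W) + gskip[[l]]
    re <- resblock_bw(g, P$enc[[l]], cache$enc[[l]])
    grads$enc[[l]] <- re$grads
    gcur <- re$gx
  }
  list(gx = gcur, grads = grads)
}

# ---- Convolutional LSTM ---------------------------------------------------

# Gate convolution maps (Cin + hid) channels to 4*hid: i, f, o, g.
init_convlstm <- function(k, cin, hid) {
  p <- init_conv(k, cin + hid, 4 * hid, gain = 1)
  p$b[hid + seq_len(hid)] <- 1          # forget-gate bias
  p
}

convlstm_fw <- function(feats, p, hid) {
  nT <- length(feats)
  d <- dim(feats[[1]])
  h <- array(0, c(d[1], d[2], hid)); cc <- h
  hs <- vector("list", nT); cache <- vector("list", nT)
  for (t in seq_len(nT)) {
    inp <- nn_concat(feats[[t]], h)
    z <- nn_conv_fw(inp, p)
    i <- sigmoid(z[, , seq_len(hid), drop = FALSE])
    f <- sigmoid(z[, , hid + seq_len(hid), drop = FALSE])
    o <- sigmoid(z[, , 2 * hid + seq_len(hid), drop = FALSE])
    g <- tanh(z[, , 3 * hid + seq_len(hid), drop = FALSE])
    cprev <- cc
    cc <- f * cprev + i * g
    tc <- tanh(cc)
    h <- o * tc
    hs[[t]] <- h
    cache[[t]] <- list(inp = inp, i = i, f = f, o = o, g = g,
                       cprev = cprev, tc = tc)
  }
  list(hs = hs, cache = cache)
}

convlstm_bw <- function(ghs, p, cache, hid, cin) {
  nT <- length(ghs)
  d <- dim(ghs[[1]])
  dh <- array(0, d); dc <- array(0, d)
  gfeat <- vector("list", nT)
  gw <- array(0, dim(p$w)); gb <- numeric(length(p$b))
  for (t in rev(seq_len(nT))) {
    cc <- cache[[t]]
    dh <- dh + ghs[[t]]
    do <- dh * cc$tc
    dcc <- dc + dh * cc$o * (1 - cc$tc^2)
    df <- dcc * cc$cprev
    di <- dcc * cc$g
    dg <- dcc * cc$i
    dc <- dcc * cc$f
    dz <- array(0, c(d[1], d[2], 4 * hid))
    dz[, , seq_len(hid)] <- di * cc$i * (1 - cc$i)
    dz[, , hid + seq_len(hid)] <- df * cc$f * (1 - cc$f)
    dz[, , 2 * hid + seq_len(hid)] <- do * cc$o * (1 - cc$o)
    dz[, , 3 * hid + seq_len(hid)] <- dg * (1 - cc$g^2)
    r <- nn_conv_bw(cc$inp, p, dz)
    gw <- gw + r$grads$w; gb <- gb + r$grads$b
    sp <- nn_split(r$gx, cin)
    gfeat[[t]] <- sp$a
    dh <- sp$b
  }
  list(gfeat = gfeat, grads = list(w = gw, b = gb))
}

# ---- generic parameter-tree arithmetic ------------------------------------

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
    else seq_along(a)
    for (n in keys)
      out[[n]] <- if (is.null(a[[n]])) NULL else param_map2(a[[n]], b[[n]], f)
    out
  } else f(a, b)
}

param_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (n in seq_along(a))
      out[[n]] <- if (is.null(a[[n]])) NULL else param_map(a[[n]], f)
    out
  } else f(a)
}

param_count <- function(a) {
  if (is.list(a)) sum(vapply(a, param_count, numeric(1))) else length(a)
}

param_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, param_flatten), use.names = FALSE)
  else as.numeric(a)
}
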