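# Minimal convolutional network primitives (im2col convolutions, 2x2 max
# pooling, nearest-neighbor upsampling, softmax cross-entropy, Adam), enough
# to train the desk-scale encoder-decoder segmenter. Feature maps are
# rows x cols x channels arrays; convolution kernels are (9 * in_ch) x out_ch
# matrices acting on im2col-expanded inputs.

# im2col for a 3x3 neighborhood with zero padding ("same"); returns
# (nr*nc) x (9*ch) matrix, offsets ordered (dr, dc) in {-1,0,1}^2
im2col3 <- function(a) {
  d <- dim(a); nr <- d[1]; nc <- d[2]; ch <- d[3]
  out <- matrix(0, nr * nc, 9L * ch)
  pad <- array(0, c(nr + 2L, nc + 2L, ch))
  pad[2:(nr + 1L), 2:(nc + 1L), ] <- a
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    block <- pad[dr + seq_len(nr), dc + seq_len(nc), , drop = FALSE]
    out[, (k - 1L) * ch + seq_len(ch)] <- matrix(block, nr * nc, ch)
  }
  out
}

# adjoint of im2col3: fold a (nr*nc) x (9*ch) gradient back to nr x nc x ch
col2im3 <- function(g, nr, nc, ch) {
  pad <- array(0, c(nr + 2L, nc + 2L, ch))
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    blk <- array(g[, (k - 1L) * ch + seq_len(ch)], c(nr, nc, ch))
    pad[dr + seq_len(nr), dc + seq_len(nc), ] <-
      pad[dr + seq_len(nr), dc + seq_len(nc), , drop = FALSE] + blk
  }
  pad[2:(nr + 1L), 2:(nc + 1L), , drop = FALSE]
}

conv3_forward <- function(a, K, b) {
  d <- dim(a)
  X <- im2col3(a)
  Y <- X %*% K
  Y <- sweep(Y, 2L, b, `+`)
  list(out = array(Y, c(d[1], d[2], ncol(K))), X = X)
}

conv3_backward <- function(cache, dout, K, in_ch) {
  d <- dim(dout)
  dY <- matrix(dout, d[1] * d[2], d[3])
  list(dK = crossprod(cache$X, dY),
       db = colSums(dY),
       dx = col2im3(dY %*% t(K), d[1], d[2], in_ch))
}

relu <- function(x) { x[x < 0] <- 0; x }
relu_backward <- function(dout, x) { dout[x <= 0] <- 0; dout }

maxpool2_forward <- function(a) {
  d <- dim(a); nr <- d[1]; nc <- d[2]; ch <- d[3]
  i1 <- seq(1L, nr, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, nc, 2L); j2 <- j1 + 1L
  A1 <- a[i1, j1, , drop = FALSE]; A2 <- a[i2, j1, , drop = FALSE]
  A3 <- a[i1, j2, , drop = FALSE]; A4 <- a[i2, j2, , drop = FALSE]
  out <- pmax(A1, A2, A3, A4)
  # first-maximum tie-break, consistent with the scatter in the backward pass
  arg <- ifelse(A1 >= A2 & A1 >= A3 & A1 >= A4, 1L,
         ifelse(A2 >= A3 & A2 >= A4, 2L, ifelse(A3 >= A4, 3L, 4L)))
  list(out = out, arg = array(arg, dim(out)))
}

maxpool2_backward <- function(cache, dout, nr, nc) {
  d <- dim(dout); ch <- d[3]
  dx <- array(0, c(nr, nc, ch))
  hr <- d[1]; hc <- d[2]
  idx <- expand.grid(r = seq_len(hr), c = seq_len(hc), k = seq_len(ch))
  arg <- as.vector(cache$arg)
  # argmax 1..4 maps to (row offset, col offset) in the 2x2 window
  roff <- c(0L, 1L, 0L, 1L)[arg]
  coff <- c(0L, 0L, 1L, 1L)[arg]
  dx[cbind(2L * idx$r - 1L + roff, 2L * idx$c - 1L + coff, idx$k)] <-
    as.vector(dout)
  dx
}

upsample2 <- function(a) {
  d <- dim(a)
  a[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

downsample2_sum <- function(dout) {
  d <- dim(dout); nr <- d[1]; nc <- d[2]
  i1 <- seq(1L, nr, 2L); j1 <- seq(1L, nc, 2L)
  dout[i1, j1, , drop = FALSE] + dout[i1 + 1L, j1, , drop = FALSE] +
    dout[i1, j1 + 1L, , drop = FALSE] + dout[i1 + 1L, j1 + 1L, , drop = FALSE]
}

# pixel-wise softmax cross-entropy; labels 0 = ignore, 1..K = class.
# returns loss (mean over labeled pixels) and dlogits
softmax_xent <- function(logits, labels) {
  d <- dim(logits)
  L <- matrix(logits, d[1] * d[2], d[3])
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  P <- E / rowSums(E)
  lab <- as.vector(labels)
  use <- lab > 0L
  n <- sum(use)
  if (n == 0L) stop("no labeled pixels")
  pick <- cbind(which(use), lab[use])
  loss <- -mean(log(pmax(P[pick], 1e-12)))
  dL <- P
  dL[pick] <- dL[pick] - 1
  dL[!use, ] <- 0
  list(loss = loss, dlogits = array(dL / n, d), prob = P)
}

# He-uniform initialization for a conv kernel matrix
init_kernel <- function(fan_in, out_ch) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * out_ch, -lim, lim), fan_in, out_ch)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# -- encoder-decoder with one pooling level per depth step and skip
#    connections; returns parameter list
unet_init <- function(in_ch, base_ch, depth, n_classes) {
  p <- list()
  ch <- in_ch
  enc_ch <- integer(depth + 1L)
  for (lev in seq_len(depth + 1L)) {
    out_ch <- base_ch * 2^(lev - 1L)
    p[[paste0("enc", lev, "_K1")]] <- init_kernel(9L * ch, out_ch)
    p[[paste0("enc", lev, "_b1")]] <- numeric(out_ch)
    p[[paste0("enc", lev, "_K2")]] <- init_kernel(9L * out_ch, out_ch)
    p[[paste0("enc", lev, "_b2")]] <- numeric(out_ch)
    enc_ch[lev] <- out_ch
    ch <- out_ch
  }
  for (lev in rev(seq_len(depth))) {
    in_up <- ch + enc_ch[lev]              # upsampled + skip concat
    out_ch <- enc_ch[lev]
    p[[paste0("dec", lev, "_K")]] <- init_kernel(9L * in_up, out_ch)
    p[[paste0("dec", lev, "_b")]] <- numeric(out_ch)
    ch <- out_ch
  }
  p[["out_K"]] <- init_kernel(ch, n_classes)   # 1x1 conv
  p[["out_b"]] <- numeric(n_classes)
  p
}

unet_forward <- function(p, x, depth) {
  cache <- list(x = x)
  a <- x
  skips <- vector("list", depth)
  for (lev in seq_len(depth + 1L)) {
    c1 <- conv3_forward(a, p[[paste0("enc", lev, "_K1")]], p[[paste0("enc", lev, "_b1")]])
    r1 <- relu(c1$out)
    c2 <- conv3_forward(r1, p[[paste0("enc", lev, "_K2")]], p[[paste0("enc", lev, "_b2")]])
    r2 <- relu(c2$out)
    cache[[paste0("enc", lev)]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                                        in_dim = dim(a))
    if (lev <= depth) {
      skips[[lev]] <- r2
      mp <- maxpool2_forward(r2)
      cache[[paste0("pool", lev)]] <- mp
      a <- mp$out
    } else a <- r2
  }
  for (lev in rev(seq_len(depth))) {
    up <- upsample2(a)
    cat_in <- array(c(up, skips[[lev]]),
                    c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(skips[[lev]])[3]))
    cd <- conv3_forward(cat_in, p[[paste0("dec", lev, "_K")]], p[[paste0("dec", lev, "_b")]])
    rd <- relu(cd$out)
    cache[[paste0("dec", lev)]] <- list(cd = cd, rd = rd,
                                        up_ch = dim(up)[3],
                                        skip_ch = dim(skips[[lev]])[3],
                                        cat_dim = dim(cat_in))
    a <- rd
  }
  d <- dim(a)
  A <- matrix(a, d[1] * d[2], d[3])
  logits <- array(sweep(A %*% p$out_K, 2L, p$out_b, `+`),
                  c(d[1], d[2], ncol(p$out_K)))
  cache$final <- list(a = a, A = A)
  list(logits = logits, cache = cache)
}

unet_backward <- function(p, cache, dlogits, depth) {
  g <- list()
  d <- dim(dlogits)
  dY <- matrix(dlogits, d[1] * d[2], d[3])
  g$out_K <- crossprod(cache$final$A, dY)
  g$out_b <- colSums(dY)
  da <- array(dY %*% t(p$out_K), dim(cache$final$a))
  for (lev in seq_len(depth)) {
    cc <- cache[[paste0("dec", lev)]]
    da <- relu_backward(da, cc$cd$out)
    bb <- conv3_backward(cc$cd, da, p[[paste0("dec", lev, "_K")]], cc$cat_dim[3])
    g[[paste0("dec", lev, "_K")]] <- bb$dK
    g[[paste0("dec", lev, "_b")]] <- bb$db
    dup <- bb$dx[, , seq_len(cc$up_ch), drop = FALSE]
    dskip <- bb$dx[, , cc$up_ch + seq_len(cc$skip_ch), drop = FALSE]
    cache[[paste0("skipgrad", lev)]] <- dskip
    da <- downsample2_sum(dup)
  }
  for (lev in rev(seq_len(depth + 1L))) {
    cc <- cache[[paste0("enc", lev)]]
    if (lev <= depth) {
      mp <- cache[[paste0("pool", lev)]]
      da <- maxpool2_backward(mp, da, dim(cc$r2)[1], dim(cc$r2)[2]) +
        cache[[paste0("skipgrad", lev)]]
    }
    da <- relu_backward(da, cc$c2$out)
    b2 <- conv3_backward(cc$c2, da, p[[paste0("enc", lev, "_K2")]], dim(cc$r1)[3])
    g[[paste0("enc", lev, "_K2")]] <- b2$dK
    g[[paste0("enc", lev, "_b2")]] <- b2$db
    da <- relu_backward(b2$dx, cc$c1$out)
    b1 <- conv3_backward(cc$c1, da, p[[paste0("enc", lev, "_K1")]], cc$in_dim[3])
    g[[paste0("enc", lev, "_K1")]] <- b1$dK
    g[[paste0("enc", lev, "_b1")]] <- b1$db
    da <- b1$dx
  }
  g
}
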