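## Numerical layers of the coupling flow.
##
## Activations are 4-D double arrays dim c(H, W, C, B) (batch last).
## Convolutions are evaluated as one BLAS matrix product per layer via
## im2col; the backward passes are written by hand and checked against
## finite differences in the test suite.

## ---- im2col machinery -------------------------------------------------

## Precompute, for an HxW output grid with a k x k kernel and zero padding
## (k-1)/2, the linear indices into the padded (Hp x Wp) plane for every
## (kernel offset, output pixel) pair. Rows: k^2 offsets (fastest), columns:
## H*W output pixels in column-major order.
conv_index <- function(H, W, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  i <- rep(seq_len(H), times = W)           # output row, fastest
  j <- rep(seq_len(W), each = H)            # output col
  di <- rep(seq_len(k) - 1L, times = k)     # kernel row offset, fastest
  dj <- rep(seq_len(k) - 1L, each = k)
  ## padded source position for offset o and pixel q
  rows <- outer(di, i, "+")                 # k^2 x HW
  cols <- outer(dj, j, "+")
  idx <- (cols - 1L) * Hp + rows
  list(idx = as.integer(idx), H = H, W = W, k = as.integer(k),
       p = p, Hp = Hp, Wp = W + 2L * p)
}

## x: (H, W, Cin, B) -> column matrix (k^2 * Cin) x (H * W * B)
im2col <- function(x, ci) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; B <- d[4]
  xp <- array(0, c(ci$Hp, ci$Wp, Cin, B))
  xp[ci$p + seq_len(H), ci$p + seq_len(W), , ] <- x
  dim(xp) <- c(ci$Hp * ci$Wp, Cin * B)
  g <- xp[ci$idx, , drop = FALSE]           # (k^2 * HW) x (Cin * B)
  dim(g) <- c(ci$k^2, H * W, Cin, B)
  g <- aperm(g, c(1, 3, 2, 4))              # k^2, Cin, HW, B
  dim(g) <- c(ci$k^2 * Cin, H * W * B)
  g
}

## scatter-add of column gradients back onto the input array
col2im <- function(gcol, Cin, B, ci) {
  H <- ci$H; W <- ci$W; k2 <- ci$k^2
  dim(gcol) <- c(k2, Cin, H * W, B)
  gcol <- aperm(gcol, c(1, 3, 2, 4))        # k^2, HW, Cin, B
  dim(gcol) <- c(k2 * H * W, Cin * B)
  ## every padded position is hit at least once for stride-1 same-padding,
  ## so rowsum over the index vector yields all Hp*Wp rows in order
  gpad <- rowsum(gcol, group = ci$idx, reorder = TRUE)
  dim(gpad) <- c(ci$Hp, ci$Wp, Cin, B)
  gpad[ci$p + seq_len(H), ci$p + seq_len(W), , , drop = FALSE]
}

## W: (Cout) x (k^2 * Cin), b: length Cout
conv2d_forward <- function(x, Wm, b, ci, keep_cache = FALSE) {
  d <- dim(x); B <- d[4]
  xcol <- im2col(x, ci)
  y <- Wm %*% xcol + b                      # Cout x (HW * B)
  Cout <- nrow(Wm)
  dim(y) <- c(Cout, ci$H * ci$W, B)
  y <- aperm(y, c(2, 1, 3))
  dim(y) <- c(ci$H, ci$W, Cout, B)
  if (keep_cache) list(y = y, xcol = xcol) else list(y = y)
}

conv2d_backward <- function(gy, Wm, xcol, Cin, B, ci) {
  Cout <- nrow(Wm)
  gy <- aperm(array(gy, c(ci$H * ci$W, Cout, B)), c(2, 1, 3))
  dim(gy) <- c(Cout, ci$H * ci$W * B)
  gW <- gy %*% t(xcol)
  gb <- rowSums(gy)
  gx <- col2im(t(Wm) %*% gy, Cin, B, ci)
  list(gx = gx, gW = gW, gb = gb)
}

## ---- squeeze / unsqueeze ----------------------------------------------

## (H, W, C, B) -> (H/2, W/2, 4C, B); pure permutation, zero log-det
squeeze2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  dim(x) <- c(2L, H %/% 2L, 2L, W %/% 2L, C, B)
  x <- aperm(x, c(2, 4, 1, 3, 5, 6))
  dim(x) <- c(H %/% 2L, W %/% 2L, 4L * C, B)
  x
}

unsqueeze2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C4 <- d[3]; B <- d[4]
  dim(x) <- c(H, W, 2L, 2L, C4 %/% 4L, B)
  x <- aperm(x, c(3, 1, 4, 2, 5, 6))
  dim(x) <- c(2L * H, 2L * W, C4 %/% 4L, B)
  x
}

## ---- activation normalization ------------------------------------------

actnorm_forward <- function(x, logs, b) {
  d <- dim(x); HW <- d[1] * d[2]
  s <- exp(logs)
  y <- (x + rep(b, each = HW)) * rep(s, each = HW)
  list(y = y, logdet = HW * sum(logs))      # per-sample log-det
}

actnorm_backward <- function(gy, y, logs, B) {
  d <- dim(y); HW <- d[1] * d[2]; C <- d[3]
  s <- exp(logs)
  gx <- gy * rep(s, each = HW)
  gyy <- gy * y
  per_chan <- function(a) {
    dim(a) <- c(HW, C, B)
    rowSums(aperm(a, c(2, 1, 3)), dims = 1L)
  }
  glogs <- per_chan(gyy) - HW               # -HW from the mean log-det term
  gb <- per_chan(gx)
  list(gx = gx, glogs = glogs, gb = gb)
}

## data-dependent init: output gets per-channel mean 0, variance 1
actnorm_init <- function(x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  xm <- aperm(x, c(3, 1, 2, 4))
  dim(xm) <- c(C, HW * B)
  mu <- rowMeans(xm)
  v <- rowMeans((xm - mu)^2)                # population variance
  list(logs = -0.5 * log(v + 1e-8), b = -mu)
}

## ---- invertible 1x1 convolution ----------------------------------------

chan_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(3, 1, 2, 4))
  dim(m) <- c(d[3], d[1] * d[2] * d[4])
  m
}

unchan_mat <- function(m, d) {
  dim(m) <- c(d[3], d[1], d[2], d[4])
  aperm(m, c(2, 3, 1, 4))
}

invconv_forward <- function(x, Wc) {
  d <- dim(x)
  y <- unchan_mat(Wc %*% chan_mat(x), d)
  ld <- d[1] * d[2] * as.numeric(determinant(Wc, logarithm = TRUE)$modulus)
  list(y = y, logdet = ld)
}

invconv_inverse <- function(y, Wc) {
  d <- dim(y)
  Winv <- tryCatch(solve(Wc), error = function(e)
    stop_input("singular 1x1 convolution weight; re-project it with ",
               "svd_reproject_weights() before inverting"))
  unchan_mat(Winv %*% chan_mat(y), d)
}

invconv_backward <- function(gy, x, Wc, B) {
  d <- dim(x); HW <- d[1] * d[2]
  gym <- chan_mat(gy)
  xm <- chan_mat(x)
  gx <- unchan_mat(t(Wc) %*% gym, d)
  gW <- gym %*% t(xm) - HW * solve(t(Wc))   # second term: mean log-det
  list(gx = gx, gW = gW)
}

## ---- affine coupling ----------------------------------------------------

## Coupling network: n_coupling_convs same-padding convolutions with ReLU
## between them; the last layer is zero-initialized so the step starts as
## the identity. Input: first half of the channels; output: raw scale and
## shift for the second half. Scale s = exp(tanh(raw)) is bounded in
## [1/e, e] and equals 1 at zero weights.
coupling_net_forward <- function(xa, convs, ci, keep_cache = FALSE) {
  n <- length(convs)
  acts <- vector("list", n)                 # pre-ReLU outputs
  cols <- vector("list", n)
  h <- xa
  for (i in seq_len(n)) {
    cv <- conv2d_forward(h, convs[[i]]$W, convs[[i]]$b, ci, keep_cache)
    if (keep_cache) cols[[i]] <- cv$xcol
    acts[[i]] <- cv$y
    h <- if (i < n) pmax(cv$y, 0) else cv$y
  }
  list(out = h, acts = acts, cols = cols)
}

coupling_net_backward <- function(gout, convs, acts, cols, Cin_first, B, ci) {
  n <- length(convs)
  gconvs <- vector("list", n)
  g <- gout
  for (i in rev(seq_len(n))) {
    if (i < n) g <- g * (acts[[i]] > 0)     # ReLU mask
    cin_i <- if (i == 1L) Cin_first else ncol(convs[[i]]$W) %/% ci$k^2
    bk <- conv2d_backward(g, convs[[i]]$W, cols[[i]], cin_i, B, ci)
    gconvs[[i]] <- list(gW = bk$gW, gb = bk$gb)
    g <- bk$gx
  }
  list(gxa = g, gconvs = gconvs)
}

coupling_forward <- function(x, convs, ci, keep_cache = FALSE) {
  d <- dim(x); C <- d[3]; ch <- C %/% 2L
  xa <- x[, , seq_len(ch), , drop = FALSE]
  xb <- x[, , ch + seq_len(ch), , drop = FALSE]
  net <- coupling_net_forward(xa, convs, ci, keep_cache)
  sraw <- net$out[, , seq_len(ch), , drop = FALSE]
  tt <- net$out[, , ch + seq_len(ch), , drop = FALSE]
  u <- tanh(sraw)
  s <- exp(u)
  yb <- xb * s + tt
  y <- x
  y[, , ch + seq_len(ch), ] <- yb
  ## per-sample log-det = sum over elements of u
  ld <- colSums(matrix(u, d[1] * d[2] * ch, d[4]))
  cache <- if (keep_cache)
    list(xa = xa, xb = xb, u = u, s = s, acts = net$acts, cols = net$cols)
  list(y = y, logdet = ld, cache = cache)
}

coupling_inverse <- function(y, convs, ci) {
  d <- dim(y); C <- d[3]; ch <- C %/% 2L
  ya <- y[, , seq_len(ch), , drop = FALSE]
  yb <- y[, , ch + seq_len(ch), , drop = FALSE]
  net <- coupling_net_forward(ya, convs, ci)
  sraw <- net$out[, , seq_len(ch), , drop = FALSE]
  tt <- net$out[, , ch + seq_len(ch), , drop = FALSE]
  s <- exp(tanh(sraw))
  x <- y
  x[, , ch + seq_len(ch), ] <- (yb - tt) / s
  x
}

coupling_backward <- function(gy, convs, cache, ci, B) {
  d <- dim(gy); C <- d[3]; ch <- C %/% 2L
  gya <- gy[, , seq_len(ch), , drop = FALSE]
  gyb <- gy[, , ch + seq_len(ch), , drop = FALSE]
  gxb <- gyb * cache$s
  ## d loss / d u: through s (yb = xb * e^u + t) and the -mean(logdet) term
  gu <- gyb * cache$xb * cache$s - 1 / B
  gsraw <- gu * (1 - cache$u^2)
  gt <- gyb
  gout <- array(0, c(d[1], d[2], 2L * ch, B))
  gout[, , seq_len(ch), ] <- gsraw
  gout[, , ch + seq_len(ch), ] <- gt
  bk <- coupling_net_backward(gout, convs, cache$acts, cache$cols, ch, B, ci)
  gx <- gy
  gx[, , seq_len(ch), ] <- gya + bk$gxa
  gx[, , ch + seq_len(ch), ] <- gxb
  list(gx = gx, gconvs = bk$gconvs)
}
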