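# Neural-network building blocks with hand-written forward/backward
# passes. Feature maps are arrays (D, H, W, C); 2D maps (for the
# perceptual feature extractor) are the same arrays with D = 1.
#
# Convolutions go through the im2col + GEMM kernels in src/ops.cpp. Each
# forward returns the output plus the cache its backward needs.

conv_fwd <- function(x, w, b, stride = c(1L, 1L, 1L), pad = NULL) {
  kd <- dim(w)[1:3]; cin <- dim(w)[4]; cout <- dim(w)[5]
  if (is.null(pad)) pad <- as.integer((kd - 1L) / 2L)
  cpp_conv_fwd(x, dim(x)[1:3], w, kd, cin, cout, b,
               as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, w, dout, stride = c(1L, 1L, 1L), pad = NULL) {
  kd <- dim(w)[1:3]; cin <- dim(w)[4]; cout <- dim(w)[5]
  if (is.null(pad)) pad <- as.integer((kd - 1L) / 2L)
  cpp_conv_bwd(x, dim(x)[1:3], w, kd, cin, cout, dout,
               as.integer(stride), as.integer(pad))
}

relu_fwd <- function(x) pmax(x, 0)

relu_bwd <- function(x, dout) dout * (x > 0)

# Group normalization over (voxels x channels-in-group), per group.
gn_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x); C <- d[4]; V <- prod(d[1:3])
  cg <- C / groups
  xm <- matrix(x, V, C)
  xhat <- xm
  inv <- numeric(groups)
  for (g in seq_len(groups)) {
    cols <- ((g - 1) * cg + 1):(g * cg)
    mu <- mean(xm[, cols])
    va <- mean((xm[, cols] - mu)^2)
    inv[g] <- 1 / sqrt(va + eps)
    xhat[, cols] <- (xm[, cols] - mu) * inv[g]
  }
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(out) <- d
  list(out = out, xhat = xhat, inv = inv, dims = d)
}

gn_bwd <- function(cache, gamma, dout) {
  d <- cache$dims; C <- d[4]; V <- prod(d[1:3])
  groups <- length(cache$inv); cg <- C / groups
  dy <- matrix(dout, V, C)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, `*`)
  dx <- dxhat
  for (g in seq_len(groups)) {
    cols <- ((g - 1) * cg + 1):(g * cg)
    m1 <- mean(dxhat[, cols])
    m2 <- mean(dxhat[, cols] * xhat[, cols])
    dx[, cols] <- cache$inv[g] * (dxhat[, cols] - m1 - xhat[, cols] * m2)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# conv -> group-norm -> ReLU sub-block
cnr_fwd <- function(x, p, groups) {
  z <- conv_fwd(x, p$w, p$b)
  gn <- gn_fwd(z, p$gamma, p$beta, groups)
  list(out = relu_fwd(gn$out), x = x, z = z, gn = gn, a = gn$out)
}

cnr_bwd <- function(cache, p, groups, dout) {
  dgn_out <- relu_bwd(cache$a, dout)
  gb <- gn_bwd(cache$gn, p$gamma, dgn_out)
  cb <- conv_bwd(cache$x, p$w, gb$dx)
  list(dx = cb$dx,
       grads = list(w = cb$dw, b = cb$db, gamma = gb$dgamma, beta = gb$dbeta))
}

# Kaiming fan-in initialization for a conv kernel (kd,kh,kw,cin,cout)
init_conv <- function(kdim, cin, cout, gain = sqrt(2)) {
  fan_in <- prod(kdim) * cin
  list(w = array(rnorm(prod(kdim) * cin * cout, 0, gain / sqrt(fan_in)),
                 c(kdim, cin, cout)),
       b = numeric(cout))
}

init_cnr <- function(kdim, cin, cout) {
  p <- init_conv(kdim, cin, cout)
  p$gamma <- rep(1, cout)
  p$beta <- numeric(cout)
  p
}
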