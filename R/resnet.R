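# Compact fully connected residual network for feature-vector regression.
#
# Architecture: input dense layer; four processing stages (batch norm ->
# ReLU -> dense); a fifth stage (batch norm -> dense) producing the scalar
# regression output; skip additions after stages 2 and 4. Trained with Adam
# on mini-batches of standardized features and targets. Inference batch-norm
# statistics are full-pass statistics over the training set, so prediction
# is deterministic.

#' Hidden width of the residual network for a given input dimension
#'
#' Chooses the smallest hidden width of at least 8 whose total trainable
#' parameter count is closest to the 840-parameter budget of the reference
#' architecture.
#'
#' @param d Input dimension (32 or 34 in this pipeline).
#' @param target Parameter budget (default 840).
#' @return `list(width, n_params)`.
#' @export
residual_net_width <- function(d, target = 840) {
  widths <- 8:64
  counts <- vapply(widths, function(w) {
    (d + 1) * w + 4 * (w^2 + w) + 5 * 2 * w + (w + 1)
  }, numeric(1))
  best <- which.min(abs(counts - target))
  list(width = widths[best], n_params = counts[best])
}

rn_init <- function(d, w, seed) {
  with_seed(seed, {
    he <- function(nin, nout) {
      matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
    }
    p <- list(
      W0 = he(d, w), b0 = rep(0, w),
      W1 = he(w, w), b1 = rep(0, w),
      W2 = he(w, w), b2 = rep(0, w),
      W3 = he(w, w), b3 = rep(0, w),
      W4 = he(w, w), b4 = rep(0, w),
      W5 = he(w, 1), b5 = 0
    )
    for (k in 1:5) {
      p[[paste0("g", k)]] <- rep(1, w)
      p[[paste0("be", k)]] <- rep(0, w)
    }
    p
  })
}

bn_fwd <- function(x, gamma, beta, stats = NULL, eps = 1e-5) {
  if (is.null(stats)) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
  } else {
    mu <- stats$mu
    v <- stats$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, ivar, `*`)
  list(
    out = sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`),
    xhat = xhat, ivar = ivar, mu = mu, var = v
  )
}

bn_bwd <- function(dy, cache, gamma) {
  m1 <- colMeans(dy)
  m2 <- colMeans(dy * cache$xhat)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dx <- sweep(
    dy - matrix(m1, nrow(dy), ncol(dy), byrow = TRUE) -
      cache$xhat * matrix(m2, nrow(dy), ncol(dy), byrow = TRUE),
    2, gamma * cache$ivar, `*`
  )
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

rn_forward <- function(p, X, stats = NULL) {
  st <- function(k) if (is.null(stats)) NULL else stats[[k]]
  h0 <- sweep(X %*% p$W0, 2, p$b0, `+`)
  bn1 <- bn_fwd(h0, p$g1, p$be1, st(1))
  r1 <- pmax(bn1$out, 0)
  h1 <- sweep(r1 %*% p$W1, 2, p$b1, `+`)
  bn2 <- bn_fwd(h1, p$g2, p$be2, st(2))
  r2 <- pmax(bn2$out, 0)
  h2 <- sweep(r2 %*% p$W2, 2, p$b2, `+`)
  s2 <- h2 + h0
  bn3 <- bn_fwd(s2, p$g3, p$be3, st(3))
  r3 <- pmax(bn3$out, 0)
  h3 <- sweep(r3 %*% p$W3, 2, p$b3, `+`)
  bn4 <- bn_fwd(h3, p$g4, p$be4, st(4))
  r4 <- pmax(bn4$out, 0)
  h4 <- sweep(r4 %*% p$W4, 2, p$b4, `+`)
  s4 <- h4 + s2
  bn5 <- bn_fwd(s4, p$g5, p$be5, st(5))
  yhat <- as.numeric(bn5$out %*% p$W5 + p$b5)
  list(
    yhat = yhat,
    cache = list(
      X = X, h0 = h0, bn1 = bn1, r1 = r1, bn2 = bn2, r2 = r2, s2 = s2,
      bn3 = bn3, r3 = r3, bn4 = bn4, r4 = r4, s4 = s4, bn5 = bn5
    )
  )
}

rn_backward <- function(p, fw, y) {
  cc <- fw$cache
  B <- length(y)
  g <- list()
  dy <- matrix(2 * (fw$yhat - y) / B, ncol = 1)
  g$W5 <- t(cc$bn5$out) %*% dy
  g$b5 <- sum(dy)
  da5 <- dy %*% t(p$W5)
  bb5 <- bn_bwd(da5, cc$bn5, p$g5)
  g$g5 <- bb5$dgamma
  g$be5 <- bb5$dbeta
  ds4 <- bb5$dx
  # stage 4 (+ skip from s2)
  g$W4 <- t(cc$r4) %*% ds4
  g$b4 <- colSums(ds4)
  dr4 <- ds4 %*% t(p$W4)
  da4 <- dr4 * (cc$bn4$out > 0)
  bb4 <- bn_bwd(da4, cc$bn4, p$g4)
  g$g4 <- bb4$dgamma
  g$be4 <- bb4$dbeta
  dh3 <- bb4$dx
  g$W3 <- t(cc$r3) %*% dh3
  g$b3 <- colSums(dh3)
  dr3 <- dh3 %*% t(p$W3)
  da3 <- dr3 * (cc$bn3$out > 0)
  bb3 <- bn_bwd(da3, cc$bn3, p$g3)
  g$g3 <- bb3$dgamma
  g$be3 <- bb3$dbeta
  ds2 <- bb3$dx + ds4 # skip junction
  g$W2 <- t(cc$r2) %*% ds2
  g$b2 <- colSums(ds2)
  dr2 <- ds2 %*% t(p$W2)
  da2 <- dr2 * (cc$bn2$out > 0)
  bb2 <- bn_bwd(da2, cc$bn2, p$g2)
  g$g2 <- bb2$dgamma
  g$be2 <- bb2$dbeta
  dh1 <- bb2$dx
  g$W1 <- t(cc$r1) %*% dh1
  g$b1 <- colSums(dh1)
  dr1 <- dh1 %*% t(p$W1)
  da1 <- dr1 * (cc$bn1$out > 0)
  bb1 <- bn_bwd(da1, cc$bn1, p$g1)
  g$g1 <- bb1$dgamma
  g$be1 <- bb1$dbeta
  dh0 <- bb1$dx + ds2 # skip junction
  g$W0 <- t(cc$X) %*% dh0
  g$b0 <- colSums(dh0)
  g
}

# collect full-pass batch-norm statistics layer by layer
rn_collect_stats <- function(p, X) {
  stats <- vector("list", 5)
  fw <- rn_forward(p, X, stats = NULL)
  cc <- fw$cache
  for (k in 1:5) {
    bn <- cc[[paste0("bn", k)]]
    stats[[k]] <- list(mu = bn$mu, var = bn$var)
  }
  stats
}

rn_train <- function(X, y, width, epochs = 50, lr = 0.001, batch = 64,
                     seed = 1L) {
  d <- ncol(X)
  p <- rn_init(d, width, derive_seed(seed, 17))
  mom <- lapply(p, function(z) z * 0)
  vel <- lapply(p, function(z) z * 0)
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  n <- nrow(X)
  step <- 0
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 31, ep), sample.int(n))
    ep_loss <- 0
    nb <- 0
    for (s in seq(1, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1, n)]
      if (length(idx) < 2) next
      fw <- rn_forward(p, X[idx, , drop = FALSE])
      g <- rn_backward(p, fw, y[idx])
      step <- step + 1
      for (nm in names(g)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^step)
        vhat <- vel[[nm]] / (1 - beta2^step)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + mean((fw$yhat - y[idx])^2)
      nb <- nb + 1
    }
    losses[ep] <- ep_loss / max(nb, 1)
  }
  stats <- rn_collect_stats(p, X)
  list(params = p, stats = stats, loss_curve = losses)
}

rn_predict <- function(fit, X) {
  rn_forward(fit$params, X, stats = fit$stats)$yhat
}
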