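# Internal neural-network engine. Activations are stored channels-first
# as (C, H*W*N) matrices: column p + H*W*n holds the C channel values of
# pixel p (column-major H x W plane) of image n. A convolution is im2col
# followed by one BLAS GEMM whose output is directly the next activation;
# batch normalization and ReLU are fused C++ passes.
#
# All large tensors live in a workspace of buffers allocated once per
# training or prediction call and reused across minibatches: fresh
# multi-hundred-MB allocations are far more expensive than the arithmetic
# on them, so every kernel writes into a preallocated buffer, with the
# used extent passed explicitly (the last minibatch may be smaller).

# spatial geometry of every layer for a given input side
.layerGeom <- function(spec) {
  H <- spec@inputSide
  Fn <- spec@nFilters
  g <- vector("list", 6L)
  blkOf <- rep(1:3, each = 2L)
  for (li in 1:6) {
    g[[li]] <- list(H = H, W = H, Cin = if (li == 1L) 1L else Fn)
    if (li %% 2L == 0L) H <- H %/% spec@poolSizes[blkOf[li]]
  }
  list(layers = g, outHW = H * H)
}

.makeWorkspace <- function(spec, Ncap, training = TRUE) {
  geom <- .layerGeom(spec)
  Fn <- spec@nFilters
  ws <- new.env(parent = emptyenv())
  ws$Ncap <- as.integer(Ncap)
  ws$X0 <- numeric(as.double(spec@inputSide)^2 * Ncap)
  ws$Xc <- ws$conv <- ws$act <- ws$xh <- vector("list", 6L)
  ws$pool <- ws$amax <- ws$dmask <- ws$Da <- ws$Db <- vector("list", 3L)
  for (li in 1:6) {
    gl <- geom$layers[[li]]
    S <- as.double(gl$H) * gl$W * Ncap
    ws$Xc[[li]] <- numeric(9 * gl$Cin * S)
    ws$conv[[li]] <- numeric(Fn * S)
    ws$act[[li]] <- numeric(Fn * S)
    if (training) ws$xh[[li]] <- numeric(Fn * S)
  }
  for (blk in 1:3) {
    gl <- geom$layers[[2L * blk]]
    p <- spec@poolSizes[blk]
    Sp <- as.double(gl$H %/% p) * (gl$W %/% p) * Ncap
    Sc <- as.double(gl$H) * gl$W * Ncap
    ws$pool[[blk]] <- numeric(Fn * Sp)
    ws$amax[[blk]] <- integer(Fn * Sp)
    if (training) {
      ws$dmask[[blk]] <- numeric(Fn * Sp)
      ws$Da[[blk]] <- numeric(Fn * Sc)
      ws$Db[[blk]] <- numeric(Fn * Sc)
    }
  }
  ws
}

# gradient of a convolution w.r.t. its input, computed as the transposed
# convolution: dA = M %*% im2col(dY) with M[c, k2*F + f] = W[f, (8-k2)*C
# + c] (spatially flipped kernels). This keeps the GEMM in the efficient
# wide-inner-dimension shape.
.convBackWeight <- function(W, Cin) {
  F <- nrow(W)
  arr <- array(W, c(F, Cin, 9L))
  matrix(aperm(arr[, , 9:1, drop = FALSE], c(2L, 1L, 3L)), Cin, 9L * F)
}

.denseFwd <- function(X, prm) prm$W %*% X + prm$b

.denseBwd <- function(dY, X, prm) {
  list(dW = tcrossprod(dY, X), db = rowSums(dY),
       dX = crossprod(prm$W, dY))
}

# head: GAP features -> feature dense layer (linear) -> sigmoid hazards
.nnForwardHead <- function(params, G) {
  Fv <- .denseFwd(G, params$fc)
  logits <- .denseFwd(Fv, params$out)
  list(features = Fv, logits = logits, hazards = plogis(logits))
}

# ---- training step (forward + backward) ---------------------------------

# One minibatch: forward with batch statistics and dropout, loss,
# backward, gradients for every layer. X is (side, side, N); d and r are
# (J, N) event / at-risk indicators. Batch-norm running statistics are
# updated on params. Returns loss, grads, params.
.trainStep <- function(params, spec, ws, X, d, r, momentum = 0.9) {
  N <- dim(X)[3L]
  stopifnot(N <= ws$Ncap)
  Fn <- spec@nFilters
  geom <- .layerGeom(spec)
  .cpp_scale_into(ws$X0, X, length(X), 1 / 255)
  A <- ws$X0
  drop <- spec@dropoutRate
  for (blk in 1:3) {
    for (cv in 1:2) {
      li <- (blk - 1L) * 2L + cv
      gl <- geom$layers[[li]]
      S <- as.double(gl$H) * gl$W * N
      cw <- params[[paste0("conv", li)]]
      bn <- params[[paste0("bn", li)]]
      .cpp_im2col3_into(ws$Xc[[li]], A, gl$Cin, gl$H, gl$W, N)
      .cpp_dgemm_into(ws$conv[[li]], cw$W, ws$Xc[[li]],
                      Fn, S, 9L * gl$Cin, FALSE, FALSE)
      mom <- .cpp_bn_relu_fwd_into(ws$conv[[li]], cw$b, bn$gamma,
                                   bn$beta, 1e-5, Fn, S,
                                   ws$act[[li]], ws$xh[[li]])
      bn$mean <- momentum * bn$mean + (1 - momentum) * mom$mu
      bn$var <- momentum * bn$var + (1 - momentum) * mom$var
      bn$.invstd <- mom$invstd  # batch inverse sd, kept for backward
      params[[paste0("bn", li)]] <- bn
      A <- ws$act[[li]]
    }
    gl <- geom$layers[[2L * blk]]
    p <- spec@poolSizes[blk]
    .cpp_maxpool_fwd_into(A, Fn, gl$H, gl$W, N, p,
                          ws$pool[[blk]], ws$amax[[blk]])
    Sp <- as.double(gl$H %/% p) * (gl$W %/% p) * N
    if (drop > 0)
      .cpp_dropout_inplace(ws$pool[[blk]], Fn * Sp, drop,
                           ws$dmask[[blk]])
    A <- ws$pool[[blk]]
  }
  HW <- geom$outHW
  G <- .cpp_gap_fwd(ws$pool[[3L]], Fn, HW, N)
  hd <- .nnForwardHead(params, G)
  h <- .clipHazards(hd$hazards)
  loss <- -sum(d * log(h)) - sum((r - d) * log1p(-h))
  dLogits <- (hd$hazards - d) * r

  grads <- list()
  ob <- .denseBwd(dLogits, hd$features, params$out)
  grads$out <- list(W = ob$dW, b = ob$db)
  fb <- .denseBwd(ob$dX, G, params$fc)
  grads$fc <- list(W = fb$dW, b = fb$db)
  dP <- .cpp_gap_bwd(fb$dX, Fn, HW, N)
  for (blk in 3:1) {
    gl <- geom$layers[[2L * blk]]
    p <- spec@poolSizes[blk]
    Sc <- as.double(gl$H) * gl$W * N
    Sp <- as.double(gl$H %/% p) * (gl$W %/% p) * N
    if (drop > 0) .cpp_mul_inplace(dP, ws$dmask[[blk]], Fn * Sp)
    .cpp_maxpool_bwd_into(dP, ws$amax[[blk]], Fn * Sp, Fn * Sc,
                          ws$Da[[blk]])
    dA <- ws$Da[[blk]]
    for (cv in 2:1) {
      li <- (blk - 1L) * 2L + cv
      gl <- geom$layers[[li]]
      S <- as.double(gl$H) * gl$W * N
      bn <- params[[paste0("bn", li)]]
      cw <- params[[paste0("conv", li)]]
      bb <- .cpp_bn_relu_bwd_into(dA, ws$act[[li]], ws$xh[[li]],
                                  bn$.invstd, bn$gamma, Fn, S,
                                  ws$Db[[blk]])
      grads[[paste0("bn", li)]] <- list(gamma = bb$dgamma,
                                        beta = bb$dbeta)
      dW <- matrix(0, Fn, 9L * gl$Cin)
      .cpp_dgemm_into(dW, ws$Db[[blk]], ws$Xc[[li]],
                      Fn, 9L * gl$Cin, S, FALSE, TRUE)
      grads[[paste0("conv", li)]] <- list(
        W = dW, b = .cpp_rowsums(ws$Db[[blk]], Fn, S))
      if (li > 1L) {
        # input gradient as transposed convolution; the first layer's is
        # never needed. Xc[[li]] is re-used: its forward content has
        # served its purpose in the weight gradient above.
        .cpp_im2col3_into(ws$Xc[[li]], ws$Db[[blk]], Fn, gl$H, gl$W, N)
        .cpp_dgemm_into(ws$Da[[blk]], .convBackWeight(cw$W, gl$Cin),
                        ws$Xc[[li]], gl$Cin, S, 9L * Fn, FALSE, FALSE)
        dA <- ws$Da[[blk]]
      }
    }
    dP <- ws$Da[[blk]]
  }
  list(loss = loss, grads = grads, params = params,
       hazards = t(hd$hazards))
}

# ---- inference ----------------------------------------------------------

# forward to the global-average-pool features with running statistics and
# no dropout; X is (side, side, N) with N <= ws$Ncap
.inferTrunk <- function(params, spec, ws, X) {
  N <- dim(X)[3L]
  stopifnot(N <= ws$Ncap)
  Fn <- spec@nFilters
  geom <- .layerGeom(spec)
  .cpp_scale_into(ws$X0, X, length(X), 1 / 255)
  A <- ws$X0
  for (blk in 1:3) {
    for (cv in 1:2) {
      li <- (blk - 1L) * 2L + cv
      gl <- geom$layers[[li]]
      S <- as.double(gl$H) * gl$W * N
      cw <- params[[paste0("conv", li)]]
      bn <- params[[paste0("bn", li)]]
      .cpp_im2col3_into(ws$Xc[[li]], A, gl$Cin, gl$H, gl$W, N)
      .cpp_dgemm_into(ws$conv[[li]], cw$W, ws$Xc[[li]],
                      Fn, S, 9L * gl$Cin, FALSE, FALSE)
      .cpp_bn_relu_inf_into(ws$conv[[li]], cw$b, bn$gamma, bn$beta,
                            bn$mean, bn$var, 1e-5, Fn, S, ws$act[[li]])
      A <- ws$act[[li]]
    }
    gl <- geom$layers[[2L * blk]]
    .cpp_maxpool_fwd_into(A, Fn, gl$H, gl$W, N, spec@poolSizes[blk],
                          ws$pool[[blk]], ws$amax[[blk]])
    A <- ws$pool[[blk]]
  }
  .cpp_gap_fwd(ws$pool[[3L]], Fn, geom$outHW, N)
}

# ---- Adam ---------------------------------------------------------------

.layerNames <- function() {
  c(paste0("conv", 1:6), paste0("bn", 1:6), "fc", "out")
}

.trainSlots <- function(nm) {
  if (startsWith(nm, "bn")) c("gamma", "beta") else c("W", "b")
}

.adamInit <- function(params, trainable) {
  st <- list(t = 0L, m = list())
  for (nm in trainable) {
    st$m[[nm]] <- lapply(params[[nm]][.trainSlots(nm)], function(x)
      list(m = x * 0, v = x * 0))
  }
  st
}

.adamStep <- function(params, grads, state, trainable, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in trainable) {
    for (sl in .trainSlots(nm)) {
      g <- grads[[nm]][[sl]]
      ms <- state$m[[nm]][[sl]]
      ms$m <- beta1 * ms$m + (1 - beta1) * g
      ms$v <- beta2 * ms$v + (1 - beta2) * g * g
      mhat <- ms$m / (1 - beta1^t)
      vhat <- ms$v / (1 - beta2^t)
      params[[nm]][[sl]] <- params[[nm]][[sl]] -
        lr * mhat / (sqrt(vhat) + eps)
      state$m[[nm]][[sl]] <- ms
    }
  }
  list(params = params, state = state)
}
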