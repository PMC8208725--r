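# Minimal convolutional network engine used by the sequence model: three
# 1-D convolutional layers with max pooling, two fully connected layers,
# binary cross-entropy loss, Adam updates, and exact input gradients for
# attribution. Batches are stored as (position, sequence, channel) arrays so
# that im2col unfolding and reshaping are plain column-major operations with
# no permutes in the hot path.

#' One-hot encode DNA sequences
#'
#' @param seqs character vector of equal-length sequences.
#' @return numeric array of dim (length, n_sequences, 4); ambiguous bases are
#'   all-zero columns.
#' @export
encode_sequences <- function(seqs) {
  W <- unique(nchar(seqs))
  if (length(W) != 1L)
    stop("all sequences must have equal length", call. = FALSE)
  n <- length(seqs)
  code <- match(unlist(strsplit(toupper(seqs), "", fixed = TRUE)), .BASES)
  X <- array(0, c(W, n, 4L))
  pos <- rep(seq_len(W), n)
  seqi <- rep(seq_len(n), each = W)
  ok <- !is.na(code)
  X[cbind(pos[ok], seqi[ok], code[ok])] <- 1
  X
}

# ---- layers ----------------------------------------------------------------

.conv_fwd <- function(X, W, b) {
  # X: (w, B, C); W: (k*C, F); returns list(Y (o, B, F), M cache)
  k <- nrow(W) / dim(X)[3L]
  w <- dim(X)[1L]; B <- dim(X)[2L]; C <- dim(X)[3L]
  o <- w - k + 1L
  M <- array(0, c(o, B, k * C))
  for (j in seq_len(k))
    M[, , ((j - 1L) * C + 1L):(j * C)] <- X[j:(j + o - 1L), , , drop = FALSE]
  dim(M) <- c(o * B, k * C)
  Y <- M %*% W
  Y <- Y + rep(b, each = o * B)
  dim(Y) <- c(o, B, ncol(W))
  list(Y = Y, M = M, dims = c(w = w, B = B, C = C, k = k, o = o))
}

.conv_bwd <- function(dY, cache, W) {
  d <- cache$dims
  dYm <- dY; dim(dYm) <- c(d[["o"]] * d[["B"]], ncol(W))
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- dYm %*% t(W)
  dim(dM) <- c(d[["o"]], d[["B"]], d[["k"]] * d[["C"]])
  dX <- array(0, c(d[["w"]], d[["B"]], d[["C"]]))
  o <- d[["o"]]; C <- d[["C"]]
  for (j in seq_len(d[["k"]]))
    dX[j:(j + o - 1L), , ] <- dX[j:(j + o - 1L), , , drop = FALSE] +
      dM[, , ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

.pool_fwd <- function(X, p) {
  w <- dim(X)[1L]; B <- dim(X)[2L]; FF <- dim(X)[3L]
  wp <- (w %/% p) * p
  Xt <- X[seq_len(wp), , , drop = FALSE]
  dim(Xt) <- c(p, wp %/% p * B * FF)
  cur <- Xt[1L, ]; arg <- rep(1L, ncol(Xt))
  for (i in seq_len(p)[-1L]) {
    gt <- Xt[i, ] > cur
    cur[gt] <- Xt[i, gt]; arg[gt] <- i
  }
  Y <- cur; dim(Y) <- c(wp %/% p, B, FF)
  list(Y = Y, arg = arg, dims = c(w = w, B = B, FF = FF, p = p, wp = wp))
}

.pool_bwd <- function(dY, cache) {
  d <- cache$dims
  m <- d[["wp"]] %/% d[["p"]] * d[["B"]] * d[["FF"]]
  flat <- numeric(d[["p"]] * m)
  flat[(seq_len(m) - 1L) * d[["p"]] + cache$arg] <- dY
  dX <- array(0, c(d[["w"]], d[["B"]], d[["FF"]]))
  dim(flat) <- c(d[["wp"]], d[["B"]], d[["FF"]])
  dX[seq_len(d[["wp"]]), , ] <- flat
  dX
}

.gpool_fwd <- function(X) {
  # global max over positions: X (w, B, F) -> (B, F)
  w <- dim(X)[1L]; B <- dim(X)[2L]; FF <- dim(X)[3L]
  Xm <- X; dim(Xm) <- c(w, B * FF)
  arg <- max.col(t(Xm), ties.method = "first")
  Y <- Xm[cbind(arg, seq_len(B * FF))]
  dim(Y) <- c(B, FF)
  list(Y = Y, arg = arg, dims = c(w = w, B = B, FF = FF))
}

.gpool_bwd <- function(dY, cache) {
  d <- cache$dims
  dX <- matrix(0, d[["w"]], d[["B"]] * d[["FF"]])
  dX[cbind(cache$arg, seq_len(d[["B"]] * d[["FF"]]))] <- dY
  dim(dX) <- c(d[["w"]], d[["B"]], d[["FF"]])
  dX
}

.relu_fwd <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(Y = X, mask = mask)
}

# flatten (w, B, F) -> (B, w*F) so every conv-output position feeds the
# fully connected head (DeepSEA shape); gradients then reach all input
# positions, which matters for attribution
.flat_fwd <- function(X) {
  d <- dim(X)
  Y <- aperm(X, c(2L, 1L, 3L))
  dim(Y) <- c(d[2L], d[1L] * d[3L])
  list(Y = Y, dims = d)
}

.flat_bwd <- function(dY, cache) {
  d <- cache$dims
  dim(dY) <- c(d[2L], d[1L], d[3L])
  aperm(dY, c(2L, 1L, 3L))
}

# ---- network ---------------------------------------------------------------

.conv_stack_len <- function(arch) {
  w <- arch$seq_len
  for (i in seq_along(arch$filters)) {
    w <- w - arch$kernels[i] + 1L
    if (i <= length(arch$pools)) w <- w %/% arch$pools[i]
  }
  w
}

.init_net <- function(arch, in_ch = 4L) {
  he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  filters <- arch$filters
  ch <- c(in_ch, filters)
  params <- list()
  for (i in seq_along(filters)) {
    params[[paste0("Wc", i)]] <- he(arch$kernels[i] * ch[i], filters[i])
    params[[paste0("bc", i)]] <- numeric(filters[i])
  }
  flat <- .conv_stack_len(arch) * filters[length(filters)]
  params$W1 <- he(flat, arch$fc_units)
  params$b1 <- numeric(arch$fc_units)
  params$W2 <- he(arch$fc_units, 1L)
  params$b2 <- numeric(1L)
  params
}

.net_forward <- function(params, X, arch) {
  cache <- list()
  A <- X
  for (i in seq_along(arch$filters)) {
    cv <- .conv_fwd(A, params[[paste0("Wc", i)]], params[[paste0("bc", i)]])
    rl <- .relu_fwd(cv$Y)
    cache[[paste0("conv", i)]] <- cv
    cache[[paste0("relu", i)]] <- rl$mask
    A <- rl$Y
    if (i <= length(arch$pools)) {
      pl <- .pool_fwd(A, arch$pools[i])
      cache[[paste0("pool", i)]] <- pl
      A <- pl$Y
    }
  }
  fl <- .flat_fwd(A)
  cache$flat <- fl
  H <- fl$Y %*% params$W1 + rep(params$b1, each = nrow(fl$Y))
  hr <- .relu_fwd(H)
  cache$H <- fl$Y; cache$relu_fc <- hr$mask
  z <- hr$Y %*% params$W2 + params$b2[1L]
  cache$Hr <- hr$Y
  list(z = as.vector(z), cache = cache)
}

.net_backward <- function(params, X, arch, fwd, dz) {
  cache <- fwd$cache
  grads <- list()
  B <- length(dz)
  dz <- matrix(dz, B, 1L)
  grads$W2 <- crossprod(cache$Hr, dz)
  grads$b2 <- sum(dz)
  dHr <- dz %*% t(params$W2)
  dH <- dHr * cache$relu_fc
  grads$W1 <- crossprod(cache$H, dH)
  grads$b1 <- colSums(dH)
  dG <- dH %*% t(params$W1)
  dA <- .flat_bwd(dG, cache$flat)
  for (i in rev(seq_along(arch$filters))) {
    if (i <= length(arch$pools))
      dA <- .pool_bwd(dA, cache[[paste0("pool", i)]])
    dA <- dA * cache[[paste0("relu", i)]]
    cb <- .conv_bwd(dA, cache[[paste0("conv", i)]], params[[paste0("Wc", i)]])
    grads[[paste0("Wc", i)]] <- cb$dW
    grads[[paste0("bc", i)]] <- cb$db
    dA <- cb$dX
  }
  grads$input <- dA
  grads
}

.bce_loss <- function(z, y) {
  # numerically stable binary cross-entropy on logits
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

.adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

#' Area under the ROC curve
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels.
#' @return auROC in [0, 1], computed from rank statistics.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("need both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
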