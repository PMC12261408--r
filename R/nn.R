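# Neural-network internals for the convolution-transformer encoder:
# forward pass, analytic backward pass, and Adam. Written against base R
# matrix algebra; gradients are verified against finite differences in the
# test suite.

# add a row vector (bias) to every row of M without an explicit sweep
.addb <- function(M, b) M + rep(b, each = nrow(M))

.softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`: every output row is a convex combination
#' of the rows of `V`, weighted by the softmax-normalised query-key match.
#'
#' @param Q,K,V token matrices; `Q` is `Lq x d_k`, `K` and `V` share `Lk`
#'   rows, `K` has `d_k` columns.
#' @param d_k key dimension used in the temperature `sqrt(d_k)`; defaults
#'   to `ncol(K)`.
#' @return a `Lq x ncol(V)` matrix.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (!is.matrix(Q) || !is.matrix(K) || !is.matrix(V))
    stop_validation("Q, K, V must be matrices")
  if (ncol(Q) != ncol(K)) stop_validation("Q and K must agree in width")
  if (nrow(K) != nrow(V)) stop_validation("K and V must agree in row count")
  if (d_k <= 0) stop_validation("d_k must be positive")
  .softmax_rows(tcrossprod(Q, K) / sqrt(d_k)) %*% V
}

# sinusoidal position table, L x D (0-based positions, interleaved sin/cos)
.sinusoidal_pe <- function(L, D) {
  pos <- matrix(0, L, D)
  p <- seq_len(L) - 1
  for (j in seq_len(D)) {
    i <- j - 1L
    rate <- 10000^((i - i %% 2L) / D)
    pos[, j] <- if (i %% 2L == 0L) sin(p / rate) else cos(p / rate)
  }
  pos
}

# --- parameter initialisation ----------------------------------------------

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# one encoder's parameters; RNG state is the caller's responsibility
.encoder_init <- function(cfg, L) {
  D <- cfg$model_width; H <- cfg$ffn_hidden; w <- cfg$conv_kernel
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) list(
    attn = list(Wq = .glorot(D, D), bq = numeric(D),
                Wk = .glorot(D, D), bk = numeric(D),
                Wv = .glorot(D, D), bv = numeric(D),
                Wo = .glorot(D, D), bo = numeric(D)),
    ln1 = list(g = rep(1, D), b = numeric(D)),
    ffn = list(W1 = .glorot(D, H), b1 = numeric(H),
               W2 = .glorot(H, D), b2 = numeric(D)),
    ln2 = list(g = rep(1, D), b = numeric(D))))
  ep <- list(conv = list(W = .glorot(2L * w, D), b = numeric(D)), blocks = blocks)
  if (cfg$positional_encoding == "learned")
    ep$pos <- matrix(stats::rnorm(L * D, sd = 0.02), L, D)
  ep
}

.ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = .addb(xhat * rep(g, each = nrow(x)) , b), xhat = xhat, inv = inv)
}

.ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- dy * rep(g, each = nrow(dy))
  dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

# inverted dropout; draws from the current RNG stream
.dropout <- function(M, p, training) {
  if (!training || p <= 0) return(list(y = M, mask = NULL))
  mask <- matrix((stats::runif(length(M)) >= p) / (1 - p), nrow(M), ncol(M))
  list(y = M * mask, mask = mask)
}

# --- encoder forward / backward --------------------------------------------

# Two interchangeable engines compute the encoder: "arma" (compiled,
# default) and "r" (base-R reference). The suite asserts their agreement;
# options(atcct.engine = "r") forces the reference path.
.engine <- function() getOption("atcct.engine", "arma")

.encoder_forward <- function(ep, Xlist, cfg, training = FALSE,
                             engine = .engine()) {
  if (engine != "arma") return(.encoder_forward_r(ep, Xlist, cfg, training))
  S <- ncol(Xlist[[1L]])
  if (S < cfg$conv_kernel)
    stop_validation("sequence length %d is shorter than the convolution kernel %d",
                    S, cfg$conv_kernel)
  L <- (S - cfg$conv_kernel) %/% cfg$conv_stride + 1L
  pe <- switch(cfg$positional_encoding,
               sinusoidal = .sinusoidal_pe(L, cfg$model_width),
               learned = ep$pos,
               none = matrix(0, 0L, 0L))
  out <- .arma_encoder_forward(ep, Xlist, unclass(cfg), training, pe)
  out$cache$engine <- "arma"
  out
}

.encoder_backward <- function(ep, cfg, cache, dEmb) {
  if (identical(cache$engine, "arma"))
    .arma_encoder_backward(ep, unclass(cfg), cache, dEmb,
                           cfg$positional_encoding == "learned" && !is.null(ep$pos))
  else .encoder_backward_r(ep, cfg, cache, dEmb)
}

# Xlist: list of B feature matrices (2 x S). Returns embeddings (B x D) and
# the cache needed for the analytic backward pass.
.encoder_forward_r <- function(ep, Xlist, cfg, training = FALSE) {
  B <- length(Xlist)
  S <- ncol(Xlist[[1L]])
  w <- cfg$conv_kernel; s <- cfg$conv_stride
  D <- cfg$model_width; h <- cfg$n_heads; dk <- D %/% h
  if (S < w)
    stop_validation("sequence length %d is shorter than the convolution kernel %d", S, w)
  L <- (S - w) %/% s + 1L
  # linear indices of each token's 2 x w patch inside a 2 x S matrix
  cols <- outer(seq_len(w), (seq_len(L) - 1L) * s, "+")     # w x L
  pidx <- rbind(2L * c(cols) - 1L, 2L * c(cols))            # 2 x (w L)
  pidx <- matrix(c(pidx), nrow = 2L * w)                    # (2w) x L per-token patches
  flat <- as.integer(pidx)  # plain vector: a 2-column index matrix would be
                            # misread as (row, col) coordinate pairs
  P <- do.call(rbind, lapply(Xlist, function(X) t(matrix(X[flat], 2L * w, L))))
  Tn <- .addb(P %*% ep$conv$W, ep$conv$b)
  pe <- switch(cfg$positional_encoding,
               sinusoidal = .sinusoidal_pe(L, D),
               learned = ep$pos[seq_len(L), , drop = FALSE],
               none = NULL)
  if (!is.null(pe)) Tn <- Tn + pe[rep(seq_len(L), B), , drop = FALSE]
  rows_of <- function(i) ((i - 1L) * L + 1L):(i * L)
  caches <- vector("list", cfg$n_blocks)
  for (bi in seq_len(cfg$n_blocks)) {
    blk <- ep$blocks[[bi]]
    Tin <- Tn
    Q <- .addb(Tin %*% blk$attn$Wq, blk$attn$bq)
    K <- .addb(Tin %*% blk$attn$Wk, blk$attn$bk)
    V <- .addb(Tin %*% blk$attn$Wv, blk$attn$bv)
    O <- matrix(0, nrow(Tin), D)
    A <- vector("list", B)
    for (i in seq_len(B)) {
      r <- rows_of(i)
      Ai <- vector("list", h)
      for (hd in seq_len(h)) {
        cc <- ((hd - 1L) * dk + 1L):(hd * dk)
        Ah <- .softmax_rows(tcrossprod(Q[r, cc, drop = FALSE],
                                       K[r, cc, drop = FALSE]) / sqrt(dk))
        O[r, cc] <- Ah %*% V[r, cc, drop = FALSE]
        Ai[[hd]] <- Ah
      }
      A[[i]] <- Ai
    }
    O2 <- .addb(O %*% blk$attn$Wo, blk$attn$bo)
    d1 <- .dropout(O2, cfg$dropout, training)
    U1 <- Tin + d1$y
    l1 <- .ln_fwd(U1, blk$ln1$g, blk$ln1$b)
    T1 <- l1$y
    Hpre <- .addb(T1 %*% blk$ffn$W1, blk$ffn$b1)
    Hact <- pmax(Hpre, 0)
    F2 <- .addb(Hact %*% blk$ffn$W2, blk$ffn$b2)
    d2 <- .dropout(F2, cfg$dropout, training)
    U2 <- T1 + d2$y
    l2 <- .ln_fwd(U2, blk$ln2$g, blk$ln2$b)
    caches[[bi]] <- list(Tin = Tin, Q = Q, K = K, V = V, A = A, O = O,
                         m1 = d1$mask, l1 = l1, T1 = T1, relu = Hpre > 0,
                         Hact = Hact, m2 = d2$mask, l2 = l2)
    Tn <- l2$y
  }
  grp <- rep(seq_len(B), each = L)
  emb <- rowsum(Tn, grp) / L
  dimnames(emb) <- NULL
  list(emb = emb, cache = list(P = P, blocks = caches, B = B, L = L,
                               rows_of = rows_of, dk = dk, h = h, D = D))
}

# dEmb: B x D gradient at the pooled embedding; returns gradients with the
# same structure as the encoder parameters
.encoder_backward_r <- function(ep, cfg, cache, dEmb) {
  B <- cache$B; L <- cache$L; h <- cache$h; dk <- cache$dk; D <- cache$D
  rows_of <- cache$rows_of
  g <- list(conv = list(W = 0 * ep$conv$W, b = 0 * ep$conv$b),
            blocks = vector("list", cfg$n_blocks))
  dT <- dEmb[rep(seq_len(B), each = L), , drop = FALSE] / L
  for (bi in rev(seq_len(cfg$n_blocks))) {
    blk <- ep$blocks[[bi]]; ca <- cache$blocks[[bi]]
    lb2 <- .ln_bwd(dT, ca$l2, blk$ln2$g)
    dU2 <- lb2$dx
    dF2 <- if (is.null(ca$m2)) dU2 else dU2 * ca$m2
    dW2 <- crossprod(ca$Hact, dF2); db2 <- colSums(dF2)
    dHact <- tcrossprod(dF2, blk$ffn$W2)
    dHpre <- dHact * ca$relu
    dW1 <- crossprod(ca$T1, dHpre); db1 <- colSums(dHpre)
    dT1 <- dU2 + tcrossprod(dHpre, blk$ffn$W1)
    lb1 <- .ln_bwd(dT1, ca$l1, blk$ln1$g)
    dU1 <- lb1$dx
    dO2 <- if (is.null(ca$m1)) dU1 else dU1 * ca$m1
    dWo <- crossprod(ca$O, dO2); dbo <- colSums(dO2)
    dO <- tcrossprod(dO2, blk$attn$Wo)
    dQ <- matrix(0, nrow(dO), D); dK <- dQ; dV <- dQ
    for (i in seq_len(B)) {
      r <- rows_of(i)
      for (hd in seq_len(h)) {
        cc <- ((hd - 1L) * dk + 1L):(hd * dk)
        Ah <- ca$A[[i]][[hd]]
        dOh <- dO[r, cc, drop = FALSE]
        dAh <- tcrossprod(dOh, ca$V[r, cc, drop = FALSE])
        dV[r, cc] <- crossprod(Ah, dOh)
        dS <- Ah * (dAh - rowSums(dAh * Ah))
        dQ[r, cc] <- dS %*% ca$K[r, cc, drop = FALSE] / sqrt(dk)
        dK[r, cc] <- crossprod(dS, ca$Q[r, cc, drop = FALSE]) / sqrt(dk)
      }
    }
    gblk <- list(
      attn = list(Wq = crossprod(ca$Tin, dQ), bq = colSums(dQ),
                  Wk = crossprod(ca$Tin, dK), bk = colSums(dK),
                  Wv = crossprod(ca$Tin, dV), bv = colSums(dV),
                  Wo = dWo, bo = dbo),
      ln1 = list(g = lb1$dg, b = lb1$db),
      ffn = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
      ln2 = list(g = lb2$dg, b = lb2$db))
    g$blocks[[bi]] <- gblk
    dT <- dU1 + tcrossprod(dQ, blk$attn$Wq) + tcrossprod(dK, blk$attn$Wk) +
      tcrossprod(dV, blk$attn$Wv)
  }
  if (!is.null(ep$pos)) {
    dpe <- rowsum(dT, rep(seq_len(L), B))
    g$pos <- 0 * ep$pos
    g$pos[seq_len(L), ] <- dpe
  }
  g$conv$W <- crossprod(cache$P, dT)
  g$conv$b <- colSums(dT)
  g
}

# --- Adam over nested parameter lists --------------------------------------

.zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      mhat <- m2 / (1 - beta1^t)
      vhat <- v2 / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
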