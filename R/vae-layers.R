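# Minimal 1-D convolutional network primitives used by the VAE.
#
# All tensors are base-R arrays in (channels, length, batch) layout;
# convolutions are evaluated as one BLAS matrix product per layer via an
# im2col gather, and gradients are exact (reverse-mode, hand-derived).
# Stochastic steps draw from R's RNG only, so fixed-seed training is
# bitwise reproducible.

conv_pads <- function(L, k, stride) {
  L_out <- as.integer(ceiling(L / stride))
  pad <- max(0L, (L_out - 1L) * stride + k - L)
  list(L_out = L_out, Pl = pad %/% 2L, Pr = pad - pad %/% 2L)
}

# x: (C_in, L, B); W: (C_out, C_in*k); b: length C_out
conv_fwd <- function(x, W, b, k, stride, pads) {
  d <- dim(x)
  C <- d[1]; L <- d[2]; B <- d[3]
  Lp <- L + pads$Pl + pads$Pr
  L_out <- pads$L_out
  xp <- array(0, c(C, Lp, B))
  xp[, pads$Pl + seq_len(L), ] <- x
  starts <- (seq_len(L_out) - 1L) * stride          # 0-based window starts
  colpos <- outer(seq_len(k), starts, "+")          # k x L_out, 1-based cols
  slice_idx <- as.vector(outer(seq_len(C), (as.vector(colpos) - 1L) * C, "+"))
  # gather as row-indexing of the (C*Lp) x B matrix view: one C-level copy
  dim(xp) <- c(C * Lp, B)
  cols <- xp[slice_idx, , drop = FALSE]
  dim(cols) <- c(C * k, L_out * B)
  out_mat <- W %*% cols + b
  list(out = array(out_mat, c(nrow(W), L_out, B)),
       cache = list(cols = cols, slice_idx = slice_idx, Pl = pads$Pl, C = C,
                    L = L, Lp = Lp, B = B, L_out = L_out, k = k))
}

conv_bwd <- function(dout, W, cache) {
  ca <- cache
  dout_mat <- dout
  dim(dout_mat) <- c(nrow(W), ca$L_out * ca$B)
  dW <- tcrossprod(dout_mat, ca$cols)
  db <- rowSums(dout_mat)
  dcols <- crossprod(W, dout_mat)                   # (C*k, L_out*B)
  # scatter-add back through the im2col gather: one rowsum over gather rows
  dim(dcols) <- c(length(ca$slice_idx), ca$B)
  agg <- rowsum(dcols, ca$slice_idx, reorder = FALSE)
  dxp <- matrix(0, ca$C * ca$Lp, ca$B)
  dxp[as.integer(rownames(agg)), ] <- agg
  dim(dxp) <- c(ca$C, ca$Lp, ca$B)
  dx <- dxp[, ca$Pl + seq_len(ca$L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# Nearest-neighbour upsampling from length L to L_out (L_out <= 2L).
up_fwd <- function(x, L_out) {
  L <- dim(x)[2]
  idx <- ceiling(seq_len(L_out) * L / L_out)
  list(out = x[, idx, , drop = FALSE], idx = idx, L_in = L)
}

up_bwd <- function(dy, idx, L_in) {
  d <- dim(dy)
  dx <- array(0, c(d[1], L_in, d[3]))
  first <- !duplicated(idx)
  dx[, idx[first], ] <- dy[, which(first), , drop = FALSE]
  dup <- which(duplicated(idx))
  if (length(dup)) {
    dx[, idx[dup], ] <- dx[, idx[dup], , drop = FALSE] + dy[, dup, , drop = FALSE]
  }
  dx
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Adam optimizer state over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
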