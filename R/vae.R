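# Variational autoencoder over 8-lead median beats.
#
# Encoder: n_blocks strided convolutional blocks (kernel 5, stride 2, ReLU)
# followed by dense heads for the posterior mean and log-variance.
# Decoder: dense expansion then the symmetrically inverse network
# (nearest-neighbour upsampling + convolution per block, final block
# linear). The latent is a diagonal Gaussian with the usual
# reparameterisation; `encode()` returns the posterior mean, so feature
# extraction is deterministic.

#' VAE configuration
#'
#' @param latent_dim size of the latent representation (default 51).
#' @param n_blocks number of convolutional blocks in the encoder (default 6);
#'   the decoder mirrors them.
#' @param channels integer vector of per-block channel counts (length
#'   `n_blocks`); default ramps from 12 to 32.
#' @param kernel convolution kernel width.
#' @param epochs,batch_size,lr training schedule (Adam).
#' @param kl_weight weight on the KL term at the end of annealing.
#' @param kl_anneal_frac fraction of epochs over which the KL weight ramps
#'   linearly from 0 (guards against posterior collapse on small data).
#' @param seed RNG seed; fixed-seed training is bitwise reproducible.
#' @return an object of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 51, n_blocks = 6, channels = NULL,
                       kernel = 5, epochs = 25, batch_size = 64, lr = 3e-3,
                       kl_weight = 0.05, kl_anneal_frac = 1 / 3, seed = 1) {
  if (latent_dim < 2) stopf("latent_dim must be >= 2")
  if (n_blocks < 1) stopf("n_blocks must be >= 1")
  channels <- channels %||% round(seq(12, 32, length.out = n_blocks))
  if (length(channels) != n_blocks) stopf("channels must have length n_blocks")
  structure(list(latent_dim = as.integer(latent_dim),
                 n_blocks = as.integer(n_blocks),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, kl_weight = kl_weight, kl_anneal_frac = kl_anneal_frac,
                 seed = as.integer(seed)),
            class = "vae_config")
}

beats_to_array <- function(beats) {
  if (is.array(beats) && length(dim(beats)) == 3L) {
    return(list(x = beats, ids = dimnames(beats)[[3]] %||% as.character(seq_len(dim(beats)[3]))))
  }
  if (inherits(beats, "median_beat")) beats <- list(beats)
  stopifnot(is.list(beats), all(vapply(beats, inherits, TRUE, "median_beat")))
  Tn <- ncol(beats[[1]]$beats)
  x <- array(NA_real_, c(8L, Tn, length(beats)))
  for (i in seq_along(beats)) {
    if (ncol(beats[[i]]$beats) != Tn) stopf("beats differ in length")
    x[, , i] <- beats[[i]]$beats
  }
  list(x = x, ids = vapply(beats, function(b) as.character(b$source_id), ""))
}

vae_geometry <- function(input_len, cfg) {
  L <- integer(cfg$n_blocks + 1L)
  L[1] <- as.integer(input_len)
  pads <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    pads[[i]] <- conv_pads(L[i], cfg$kernel, 2L)
    L[i + 1L] <- pads[[i]]$L_out
  }
  dec_pads <- lapply(L[seq_len(cfg$n_blocks)], conv_pads, k = cfg$kernel, stride = 1L)
  list(L = L, enc_pads = pads, dec_pads = dec_pads,
       flat = cfg$channels[cfg$n_blocks] * L[cfg$n_blocks + 1L])
}

vae_init_params <- function(cfg, geo, n_leads = 8L) {
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
  P <- list()
  cin <- c(n_leads, cfg$channels[-cfg$n_blocks])
  for (i in seq_len(cfg$n_blocks)) {
    P[[paste0("eW", i)]] <- he(cfg$channels[i], cin[i] * cfg$kernel)
    P[[paste0("eb", i)]] <- numeric(cfg$channels[i])
  }
  P$mW <- he(cfg$latent_dim, geo$flat) * 0.1
  P$mb <- numeric(cfg$latent_dim)
  P$vW <- he(cfg$latent_dim, geo$flat) * 0.01
  P$vb <- rep(-2, cfg$latent_dim)        # start with small posterior variance
  P$dW <- he(geo$flat, cfg$latent_dim)
  P$db <- numeric(geo$flat)
  dch_in <- rev(cfg$channels)
  dch_out <- c(rev(cfg$channels)[-1], n_leads)
  for (i in seq_len(cfg$n_blocks)) {
    P[[paste0("gW", i)]] <- he(dch_out[i], dch_in[i] * cfg$kernel)
    P[[paste0("gb", i)]] <- numeric(dch_out[i])
  }
  P
}

enc_forward <- function(P, x, cfg, geo, want_cache = FALSE) {
  h <- x
  caches <- if (want_cache) vector("list", cfg$n_blocks) else NULL
  for (i in seq_len(cfg$n_blocks)) {
    cv <- conv_fwd(h, P[[paste0("eW", i)]], P[[paste0("eb", i)]],
                   cfg$kernel, 2L, geo$enc_pads[[i]])
    if (want_cache) caches[[i]] <- list(conv = cv$cache, pre = cv$out)
    h <- relu(cv$out)
  }
  hd <- dim(h)
  hf <- matrix(h, hd[1] * hd[2], hd[3])
  list(mu = P$mW %*% hf + P$mb, lv = P$vW %*% hf + P$vb,
       hf = hf, hdims = hd, caches = caches)
}

enc_backward <- function(P, fwd, dmu, dlv, cfg) {
  G <- list()
  G$mW <- dmu %*% t(fwd$hf); G$mb <- rowSums(dmu)
  G$vW <- dlv %*% t(fwd$hf); G$vb <- rowSums(dlv)
  dh <- array(crossprod(P$mW, dmu) + crossprod(P$vW, dlv), fwd$hdims)
  for (i in rev(seq_len(cfg$n_blocks))) {
    dh <- dh * (fwd$caches[[i]]$pre > 0)
    bk <- conv_bwd(dh, P[[paste0("eW", i)]], fwd$caches[[i]]$conv)
    G[[paste0("eW", i)]] <- bk$dW
    G[[paste0("eb", i)]] <- bk$db
    dh <- bk$dx
  }
  G
}

dec_forward <- function(P, z, cfg, geo, want_cache = FALSE) {
  B <- ncol(z)
  nb <- cfg$n_blocks
  h0_pre <- P$dW %*% z + P$db
  h <- array(relu(h0_pre), c(cfg$channels[nb], geo$L[nb + 1L], B))
  caches <- if (want_cache) vector("list", nb) else NULL
  for (i in seq_len(nb)) {
    target <- geo$L[nb + 1L - i]
    up <- up_fwd(h, target)
    cv <- conv_fwd(up$out, P[[paste0("gW", i)]], P[[paste0("gb", i)]],
                   cfg$kernel, 1L, geo$dec_pads[[nb + 1L - i]])
    if (want_cache) caches[[i]] <- list(up = up, conv = cv$cache, pre = cv$out)
    h <- if (i < nb) relu(cv$out) else cv$out
  }
  list(xhat = h, h0_pre = h0_pre, caches = caches)
}

dec_backward <- function(P, fwd, dxhat, cfg, z) {
  G <- list()
  nb <- cfg$n_blocks
  dh <- dxhat
  for (i in rev(seq_len(nb))) {
    if (i < nb) dh <- dh * (fwd$caches[[i]]$pre > 0)
    bk <- conv_bwd(dh, P[[paste0("gW", i)]], fwd$caches[[i]]$conv)
    G[[paste0("gW", i)]] <- bk$dW
    G[[paste0("gb", i)]] <- bk$db
    dh <- up_bwd(bk$dx, fwd$caches[[i]]$up$idx, fwd$caches[[i]]$up$L_in)
  }
  dh0 <- matrix(dh, length(dh) / dim(dh)[3], dim(dh)[3]) * (fwd$h0_pre > 0)
  G$dW <- dh0 %*% t(z)
  G$db <- rowSums(dh0)
  list(grads = G, dz = crossprod(P$dW, dh0))
}

#' Train the median-beat VAE
#'
#' Inputs are standardized per lead with training-set statistics (stored in
#' the model and re-applied at inference). The loss is per-sample
#' reconstruction sum-of-squares plus a KL term whose weight is annealed
#' linearly from zero over the first `kl_anneal_frac` of epochs.
#'
#' @param beats list of [median_beat()]s (or an `8 x T x N` array).
#' @param cfg a [vae_config()].
#' @param verbose print per-epoch loss.
#' @return an object of class `vae_model`: parameters, config, per-lead
#'   normalization statistics and the per-epoch loss trace. The model is a
#'   plain list and serializes with `saveRDS()`.
#' @export
train_vae <- function(beats, cfg = vae_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "vae_config"))
  ba <- beats_to_array(beats)
  x_all <- ba$x
  N <- dim(x_all)[3]
  if (N < 2 * cfg$batch_size)
    stopf("need at least 2 x batch_size = %d beats, got %d", 2 * cfg$batch_size, N)
  lead_mean <- apply(x_all, 1, mean)
  lead_sd <- pmax(apply(x_all, 1, sd), 1e-6)
  xs <- sweep(sweep(x_all, 1, lead_mean, "-"), 1, lead_sd, "/")
  geo <- vae_geometry(dim(xs)[2], cfg)

  loss_trace <- numeric(cfg$epochs)
  anneal_epochs <- max(1, round(cfg$kl_anneal_frac * cfg$epochs))
  model <- with_seed(cfg$seed, {
    P <- vae_init_params(cfg, geo)
    opt <- adam_init(P)
    for (ep in seq_len(cfg$epochs)) {
      klw <- cfg$kl_weight * min(1, ep / anneal_epochs)
      ord <- sample.int(N)
      ep_loss <- 0
      nb_seen <- 0
      for (start in seq(1, N, by = cfg$batch_size)) {
        idx <- ord[start:min(N, start + cfg$batch_size - 1L)]
        if (length(idx) < 2) next
        xb <- xs[, , idx, drop = FALSE]
        B <- length(idx)
        ef <- enc_forward(P, xb, cfg, geo, want_cache = TRUE)
        eps <- matrix(rnorm(length(ef$mu)), nrow(ef$mu), B)
        sdv <- exp(0.5 * ef$lv)
        z <- ef$mu + sdv * eps
        df <- dec_forward(P, z, cfg, geo, want_cache = TRUE)
        resid <- df$xhat - xb
        loss_rec <- sum(resid^2) / B
        loss_kl <- 0.5 * sum(ef$mu^2 + exp(ef$lv) - 1 - ef$lv) / B
        loss <- loss_rec + klw * loss_kl
        if (!is.finite(loss))
          stopf("non-finite loss at epoch %d (seed %d); lower lr or kl_weight",
                ep, cfg$seed)
        dec_bk <- dec_backward(P, df, 2 * resid / B, cfg, z)
        dz <- dec_bk$dz
        dmu <- dz + klw * ef$mu / B
        dlv <- dz * eps * 0.5 * sdv + klw * 0.5 * (exp(ef$lv) - 1) / B
        G <- c(dec_bk$grads, enc_backward(P, ef, dmu, dlv, cfg))
        upd <- adam_step(P, G[names(P)], opt, lr = cfg$lr)
        P <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + loss * B
        nb_seen <- nb_seen + B
      }
      loss_trace[ep] <- ep_loss / nb_seen
      if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, loss_trace[ep]))
    }
    structure(list(params = P, cfg = cfg, geo = geo,
                   norm = list(mean = lead_mean, sd = lead_sd),
                   input_len = dim(xs)[2], loss_trace = loss_trace),
              class = "vae_model")
  })
  model
}

#' @export
print.vae_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<vae_model> latent %d, %d blocks, %d parameters, %d epochs (final loss %.3f)\n",
              x$cfg$latent_dim, x$cfg$n_blocks, np, x$cfg$epochs,
              tail(x$loss_trace, 1)))
  invisible(x)
}

standardize_beats <- function(model, beats) {
  ba <- beats_to_array(beats)
  if (dim(ba$x)[2] != model$input_len)
    stopf("beat length %d does not match the model's %d", dim(ba$x)[2], model$input_len)
  list(x = sweep(sweep(ba$x, 1, model$norm$mean, "-"), 1, model$norm$sd, "/"),
       ids = ba$ids)
}

#' Encode median beats to latent features
#'
#' Returns the deterministic posterior mean, so repeated calls agree
#' bitwise.
#'
#' @param model a trained [train_vae()] model.
#' @param beats list of [median_beat()]s, a single beat, or an array.
#' @param chunk internal batching size.
#' @return numeric matrix, beats x latent_dim, rownames = source ids.
#' @export
encode <- function(model, beats, chunk = 256L) {
  stopifnot(inherits(model, "vae_model"))
  sb <- standardize_beats(model, beats)
  N <- dim(sb$x)[3]
  out <- matrix(NA_real_, N, model$cfg$latent_dim)
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(N, start + chunk - 1L)
    ef <- enc_forward(model$params, sb$x[, , idx, drop = FALSE], model$cfg, model$geo)
    out[idx, ] <- t(ef$mu)
  }
  rownames(out) <- sb$ids
  colnames(out) <- paste0("z", seq_len(ncol(out)))
  out
}

#' Decode latent vectors to median beats
#'
#' @param model a trained [train_vae()] model.
#' @param z a latent vector, or a matrix with one latent vector per row.
#' @return a [median_beat()] for a single vector, else a list of them.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "vae_model"))
  single <- is.null(dim(z))
  zm <- if (single) matrix(z, ncol = 1) else t(as.matrix(z))
  if (nrow(zm) != model$cfg$latent_dim)
    stopf("latent dimension mismatch: got %d, model has %d", nrow(zm), model$cfg$latent_dim)
  df <- dec_forward(model$params, zm, model$cfg, model$geo)
  xhat <- sweep(sweep(df$xhat, 1, model$norm$sd, "*"), 1, model$norm$mean, "+")
  beats <- lapply(seq_len(dim(xhat)[3]), function(i)
    median_beat(xhat[, , i], fs = 400, fiducial_index = round(model$input_len / 3),
                source_id = sprintf("decoded%03d", i)))
  if (single) beats[[1]] else beats
}

#' Decode a latent traversal
#'
#' Decodes `z` with component `dim` replaced by each value of `grid`, all
#' other components held fixed — the standard visualization of what a
#' latent feature encodes.
#'
#' @param model a trained [train_vae()] model.
#' @param z base latent vector.
#' @param dim latent component to traverse (1-based).
#' @param grid numeric values substituted into component `dim`.
#' @return list of [median_beat()]s, one per grid value.
#' @export
latent_traversal <- function(model, z, dim, grid) {
  stopifnot(inherits(model, "vae_model"))
  if (dim < 1 || dim > model$cfg$latent_dim) stopf("dim out of range")
  zm <- matrix(rep(as.numeric(z), length(grid)), nrow = length(grid), byrow = TRUE)
  zm[, dim] <- grid
  out <- decode(model, zm)
  if (inherits(out, "median_beat")) list(out) else out
}

#' Per-beat reconstruction correlation
#'
#' Pearson correlation between each beat and its VAE reconstruction,
#' computed over all leads and samples of the beat.
#'
#' @param model a trained [train_vae()] model.
#' @param beats list of [median_beat()]s or an array.
#' @return numeric vector of per-beat correlations.
#' @export
reconstruction_correlation <- function(model, beats) {
  sb <- standardize_beats(model, beats)
  N <- dim(sb$x)[3]
  r <- numeric(N)
  for (start in seq(1, N, by = 256L)) {
    idx <- start:min(N, start + 255L)
    ef <- enc_forward(model$params, sb$x[, , idx, drop = FALSE], model$cfg, model$geo)
    df <- dec_forward(model$params, ef$mu, model$cfg, model$geo)
    for (j in seq_along(idx)) {
      r[idx[j]] <- stats::cor(as.vector(sb$x[, , idx[j]]), as.vector(df$xhat[, , j]))
    }
  }
  r
}
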