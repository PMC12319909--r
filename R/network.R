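#' Network architecture configuration
#'
#' Shape contract for the velocity-inversion network: five input channels of
#' length 200 (three demeaned inflow slice signals, cross-sectional areas,
#' and their depths), three 1D convolution stages with increasing channel
#' widths, three transpose-convolution stages with decreasing widths (all
#' kernel 3, padding 1, stride 1, each followed by batch normalization and
#' ReLU), then a flatten and two fully connected layers producing one
#' velocity channel of length 1,000. With unit stride and symmetric padding
#' the transpose convolutions are length-preserving and are realized as
#' convolutions with independent weights; the 200 -> 1,000 upsampling
#' happens in the fully connected head.
#'
#' @param in_channels,in_length Input shape (5 x 200).
#' @param out_length Output velocity length (1,000).
#' @param enc_channels Encoder widths (3 increasing stages).
#' @param dec_channels Decoder widths (3 decreasing stages).
#' @param fc_hidden Hidden width of the first fully connected layer.
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 5L, in_length = 200L,
                           out_length = 1000L,
                           enc_channels = c(16L, 32L, 64L),
                           dec_channels = c(32L, 16L, 8L),
                           fc_hidden = 2000L) {
  stopifnot(length(enc_channels) == 3L, length(dec_channels) == 3L,
            all(enc_channels > 0), all(dec_channels > 0), fc_hidden > 0)
  structure(list(in_channels = as.integer(in_channels),
                 in_length = as.integer(in_length),
                 out_length = as.integer(out_length),
                 enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 fc_hidden = as.integer(fc_hidden)),
            class = "network_config")
}

#' Training configuration
#'
#' @param batch Minibatch size (default 16).
#' @param epochs Training epochs (default 120).
#' @param lr Adam learning rate (default 0.001).
#' @param test_fraction Held-out fraction of the dataset (default 0.10).
#' @param seed RNG seed controlling initialization, the train/test split,
#'   and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch = 16L, epochs = 120L, lr = 1e-3,
                         test_fraction = 0.10, seed = 1L) {
  stopifnot(batch >= 1L, epochs >= 1L, lr > 0,
            test_fraction > 0, test_fraction < 1)
  structure(list(batch = as.integer(batch), epochs = as.integer(epochs),
                 lr = lr, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- tensor helpers (activations stored as (C, L, B) arrays) --------------

im2col3 <- function(x) {
  d <- dim(x)
  im2col3_cpp(x, d[1L], d[2L], d[3L])
}

col2im3 <- function(colmat, cc, l, b) {
  col2im3_cpp(colmat, cc, l, b)
}

conv_forward <- function(x, w, bvec) {
  d <- dim(x)
  col <- im2col3(x)
  y <- w %*% col + bvec
  dim(y) <- c(nrow(w), d[2L], d[3L])
  list(y = y, col = col)
}

conv_backward <- function(dy, cache_col, w, in_c, l, b) {
  dim(dy) <- c(nrow(w), l * b)
  dw <- tcrossprod(dy, cache_col)
  db <- rowSums(dy)
  dcol <- crossprod(w, dy)
  dx <- col2im3(dcol, in_c, l, b)
  list(dx = dx, dw = dw, db = db)
}

bn_forward <- function(x, gamma, beta, running, training, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(x); cc <- d[1L]; n <- d[2L] * d[3L]
  xm <- x; dim(xm) <- c(cc, n)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va * n / max(n - 1L, 1L)
  } else {
    mu <- running$mean
    va <- running$var
    xc <- xm - mu
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- xc * inv_sd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, xhat = xhat, inv_sd = inv_sd, running = running)
}

bn_backward <- function(dy, cache, gamma, d) {
  cc <- d[1L]; n <- d[2L] * d[3L]
  dim(dy) <- c(cc, n)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  dx <- cache$inv_sd / n *
    (n * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

he_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

#' Build the velocity-inversion network
#'
#' Initializes all weights (He initialization, seeded) and batch-norm state.
#'
#' @param cfg A [network_config()].
#' @param seed RNG seed for the initialization.
#' @return An object of class `inflow_net` containing the parameter list,
#'   batch-norm running statistics, and the configuration. The parameter
#'   count is reported by `print()`.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  set.seed(seed)
  chans <- c(cfg$in_channels, cfg$enc_channels, cfg$dec_channels)
  params <- list()
  bn <- list()
  for (i in seq_len(6L)) {
    cin <- chans[i]; cout <- chans[i + 1L]
    params[[paste0("conv", i, "_w")]] <- he_init(cout, 3L * cin)
    params[[paste0("conv", i, "_b")]] <- numeric(cout)
    params[[paste0("bn", i, "_gamma")]] <- rep(1, cout)
    params[[paste0("bn", i, "_beta")]] <- numeric(cout)
    bn[[i]] <- list(mean = numeric(cout), var = rep(1, cout))
  }
  flat <- cfg$dec_channels[3L] * cfg$in_length
  params$fc1_w <- he_init(cfg$fc_hidden, flat)
  params$fc1_b <- numeric(cfg$fc_hidden)
  # small output-head initialization: the regression head starts near the
  # zero predictor, so early optimization is driven by the data rather than
  # by large random outputs (large He-scaled output weights can push the
  # upstream ReLU layer into an unrecoverable all-dead state)
  params$fc2_w <- matrix(stats::rnorm(cfg$out_length * cfg$fc_hidden, 0, 0.01),
                         cfg$out_length, cfg$fc_hidden)
  params$fc2_b <- numeric(cfg$out_length)
  structure(list(params = params, bn = bn, cfg = cfg, seed = seed),
            class = "inflow_net")
}

#' @export
print.inflow_net <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<inflow_net> %d -> conv(%s) -> tconv(%s) -> fc(%d) -> %d; %s parameters\n",
    x$cfg$in_channels, paste(x$cfg$enc_channels, collapse = ","),
    paste(x$cfg$dec_channels, collapse = ","), x$cfg$fc_hidden,
    x$cfg$out_length, format(npar, big.mark = ",")))
  invisible(x)
}

# forward pass; x: (5, 200, B). Returns output (out_length, B) and, when
# training, the caches needed for backprop.
nn_forward <- function(net, x, training = FALSE) {
  p <- net$params
  caches <- vector("list", 6L)
  a <- x
  for (i in seq_len(6L)) {
    cv <- conv_forward(a, p[[paste0("conv", i, "_w")]],
                       p[[paste0("conv", i, "_b")]])
    bnout <- bn_forward(cv$y, p[[paste0("bn", i, "_gamma")]],
                        p[[paste0("bn", i, "_beta")]],
                        net$bn[[i]], training)
    if (training) net$bn[[i]] <- bnout$running
    relu_mask <- bnout$y > 0
    a_next <- bnout$y * relu_mask
    caches[[i]] <- if (training) {
      list(col = cv$col, bn = bnout, mask = relu_mask, dims = dim(cv$y),
           in_c = dim(a)[1L])
    }
    a <- a_next
  }
  d <- dim(a)
  flat <- a; dim(flat) <- c(d[1L] * d[2L], d[3L])
  z1 <- p$fc1_w %*% flat + p$fc1_b
  h1 <- z1 * (z1 > 0)
  out <- p$fc2_w %*% h1 + p$fc2_b
  list(out = out, caches = caches, flat = flat, h1 = h1, z1 = z1,
       conv_out_dim = d, net = net)
}

# backward pass from dOut (out_length, B); returns gradient list matching
# the parameter list.
nn_backward <- function(net, fwd, dout) {
  p <- net$params
  grads <- list()
  grads$fc2_w <- tcrossprod(dout, fwd$h1)
  grads$fc2_b <- rowSums(dout)
  dh1 <- crossprod(p$fc2_w, dout)
  dz1 <- dh1 * (fwd$z1 > 0)
  grads$fc1_w <- tcrossprod(dz1, fwd$flat)
  grads$fc1_b <- rowSums(dz1)
  dflat <- crossprod(p$fc1_w, dz1)
  d <- fwd$conv_out_dim
  da <- dflat; dim(da) <- d
  for (i in 6:1) {
    cache <- fwd$caches[[i]]
    da <- da * cache$mask
    bnb <- bn_backward(da, cache$bn, p[[paste0("bn", i, "_gamma")]],
                       cache$dims)
    grads[[paste0("bn", i, "_gamma")]] <- bnb$dgamma
    grads[[paste0("bn", i, "_beta")]] <- bnb$dbeta
    cb <- conv_backward(bnb$dx, cache$col, p[[paste0("conv", i, "_w")]],
                        cache$in_c, cache$dims[2L], cache$dims[3L])
    grads[[paste0("conv", i, "_w")]] <- cb$dw
    grads[[paste0("conv", i, "_b")]] <- cb$db
    da <- cb$dx
  }
  grads
}

#' Train the velocity-inversion network
#'
#' Splits off `test_fraction` of the samples (by index, seeded), then runs
#' Adam on the mean-squared-error loss over minibatches. Deterministic given
#' the configuration seeds.
#'
#' @param dataset A dataset from [make_training_set()] (fields `inputs`
#'   (5 x 200 x n) and `targets` (out_length x n)).
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print the loss every epoch.
#' @return A list with `net` (trained `inflow_net`), `train_loss` (per-epoch
#'   mean minibatch MSE), `test_mse` (held-out per-timepoint MSE, (cm/s)^2),
#'   and `test_idx` (held-out sample indices).
#' @export
train_inflow_net <- function(dataset, net_cfg = network_config(),
                             train_cfg = train_config(), verbose = FALSE) {
  n <- dim(dataset$inputs)[3L]
  if (n < 100L) stop("need at least 100 samples to train", call. = FALSE)
  set.seed(train_cfg$seed)
  test_idx <- sort(sample.int(n, round(train_cfg$test_fraction * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  net <- build_network(net_cfg, seed = train_cfg$seed)
  opt <- lapply(net$params, function(p) {
    list(m = numeric(length(p)), v = numeric(length(p)))
  })
  step <- 0L
  bsz <- train_cfg$batch
  losses <- numeric(train_cfg$epochs)
  pnames <- names(net$params)
  for (ep in seq_len(train_cfg$epochs)) {
    perm <- sample(train_idx)
    nb <- floor(length(perm) / bsz)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      ids <- perm[((bi - 1L) * bsz + 1L):(bi * bsz)]
      xb <- dataset$inputs[, , ids, drop = FALSE]
      yb <- dataset$targets[, ids, drop = FALSE]
      fwd <- nn_forward(net, xb, training = TRUE)
      net <- fwd$net
      err <- fwd$out - yb
      loss <- mean(err * err)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep, ", batch ", bi,
             call. = FALSE)
      }
      ep_loss <- ep_loss + loss
      dout <- 2 * err / length(err)
      grads <- nn_backward(net, fwd, dout)
      step <- step + 1L
      for (nm in pnames) {
        adam_step_cpp(net$params[[nm]], grads[[nm]],
                      opt[[nm]]$m, opt[[nm]]$v,
                      train_cfg$lr, 0.9, 0.999, 1e-8, step)
      }
    }
    losses[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep,
                                 train_cfg$epochs, losses[ep]))
  }
  # held-out MSE, eval mode, in chunks
  test_mse <- NA_real_
  if (length(test_idx)) {
    se <- 0; cnt <- 0
    for (chunk in split(test_idx, ceiling(seq_along(test_idx) / 64))) {
      xb <- dataset$inputs[, , chunk, drop = FALSE]
      yb <- dataset$targets[, chunk, drop = FALSE]
      out <- nn_forward(net, xb, training = FALSE)$out
      se <- se + sum((out - yb)^2)
      cnt <- cnt + length(yb)
    }
    test_mse <- se / cnt
  }
  list(net = net, train_loss = losses, test_mse = test_mse,
       test_idx = test_idx, train_cfg = train_cfg)
}

#' Predict a velocity time series from inflow signals and anatomy
#'
#' Demeans the three inflow channels, appends the anatomy feature channels,
#' and runs the network in evaluation mode.
#'
#' @param net A trained `inflow_net` (or the list returned by
#'   [train_inflow_net()]).
#' @param inflow 3 x 200 matrix (slices in rows) of inflow signals, one
#'   sample per TR, preprocessed without low-pass filtering.
#' @param profile An [area_profile()] (converted internally to 200-point
#'   area/position channels), or NULL if `inflow` already has 5 rows.
#' @return Numeric velocity series of length `out_length` (cm/s), spanning
#'   the input's wall-clock duration.
#' @export
predict_velocity <- function(net, inflow, profile = NULL) {
  if (!inherits(net, "inflow_net") && !is.null(net$net)) net <- net$net
  cfg <- net$cfg
  inflow <- as.matrix(inflow)
  if (!is.null(profile)) {
    if (nrow(inflow) != 3L || ncol(inflow) != cfg$in_length) {
      stop("inflow must be 3 x ", cfg$in_length, call. = FALSE)
    }
    inflow <- sweep(inflow, 1L, rowMeans(inflow))
    anat <- anatomy_channels(profile, cfg$in_length)
    x <- rbind(inflow, anat$area, anat$position)
  } else {
    if (nrow(inflow) != cfg$in_channels || ncol(inflow) != cfg$in_length) {
      stop("inputs must be ", cfg$in_channels, " x ", cfg$in_length,
           call. = FALSE)
    }
    x <- inflow
    x[1:3, ] <- sweep(x[1:3, , drop = FALSE], 1L,
                      rowMeans(x[1:3, , drop = FALSE]))
  }
  dim(x) <- c(cfg$in_channels, cfg$in_length, 1L)
  as.numeric(nn_forward(net, x, training = FALSE)$out)
}

#' Save / load a network checkpoint
#'
#' The checkpoint carries the parameters, batch-norm statistics, network and
#' training configurations, and seeds; a reloaded network reproduces
#' predictions bit for bit.
#'
#' @param net A trained `inflow_net` (or [train_inflow_net()] result).
#' @param path Checkpoint file path (RDS).
#' @name checkpoint
NULL

#' @rdname checkpoint
#' @export
save_checkpoint <- function(net, path) {
  extra <- NULL
  if (!inherits(net, "inflow_net") && !is.null(net$net)) {
    extra <- net[setdiff(names(net), "net")]
    net <- net$net
  }
  saveRDS(list(params = net$params, bn = net$bn, cfg = net$cfg,
               seed = net$seed, extra = extra), path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(params = obj$params, bn = obj$bn, cfg = obj$cfg,
                 seed = obj$seed),
            class = "inflow_net")
}

#' Aligned mean absolute error between predicted and reference velocity
#'
#' Resamples both series to a common grid, low-pass filters below `lowpass`
#' Hz (zero-phase fifth-order Butterworth), time-shifts by the
#' cross-correlation maximum to correct phase offsets between separately
#' acquired runs, and returns the mean absolute difference over the overlap.
#'
#' @param pred,reference Velocity series in cm/s.
#' @param fs Sampling frequency of `pred` in Hz; `reference` is resampled to
#'   the same grid if its length differs.
#' @param lowpass Cutoff in Hz (default 0.5); NULL to skip.
#' @param max_lag_s Largest alignment shift searched, in seconds.
#' @return Mean absolute error in cm/s.
#' @export
evaluate_prediction <- function(pred, reference, fs, lowpass = 0.5,
                                max_lag_s = 10) {
  pred <- as.numeric(pred)
  reference <- as.numeric(reference)
  if (length(reference) != length(pred)) {
    reference <- stats::approx(seq(0, 1, length.out = length(reference)),
                               reference,
                               xout = seq(0, 1, length.out = length(pred)))$y
  }
  if (stats::sd(pred) == 0 || stats::sd(reference) == 0) {
    stop("constant series: cross-correlation alignment is undefined",
         call. = FALSE)
  }
  if (!is.null(lowpass)) {
    pred <- butter_lowpass(pred, fs, lowpass)
    reference <- butter_lowpass(reference, fs, lowpass)
  }
  max_lag <- min(length(pred) - 2L, max(1L, round(max_lag_s * fs)))
  pa <- pred - mean(pred)
  ra <- reference - mean(reference)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(pa[(1 + l):length(pa)] * ra[1:(length(ra) - l)])
    else sum(pa[1:(length(pa) + l)] * ra[(1 - l):length(ra)])
  }, 0)
  l <- lags[which.max(cc)]
  if (l >= 0) {
    mean(abs(pred[(1 + l):length(pred)] - reference[1:(length(reference) - l)]))
  } else {
    mean(abs(pred[1:(length(pred) + l)] - reference[(1 - l):length(reference)]))
  }
}
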