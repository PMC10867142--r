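# Compact convolutional-recurrent spectrogram classifier: two 3x3 conv
# blocks (ReLU, 2x2 max-pool) collapse the frequency axis, the time axis is
# read by a single-layer GRU, and the final hidden state feeds a softmax.
# Written in base R matrix algebra (im2col convolution, BPTT); gradients are
# verified against finite differences in the test suite.

#' Network configuration for the spectrogram classifier
#'
#' @param input_grid `c(time, frequency)` resolution of the input
#'   spectrograms (after pooling in [prepare_spectrogram_batch()]).
#' @param conv_channels Channels of the two conv blocks.
#' @param gru_units Hidden units of the GRU layer.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Integer seed controlling initialization and batch order.
#' @return List of class `grunet_config`.
#' @export
grunet_config <- function(input_grid = c(200, 64), conv_channels = c(16, 32),
                          gru_units = 64, batch_size = 16,
                          learning_rate = 1e-3, epochs = 200, patience = 20,
                          seed = 1) {
  stopifnot(length(input_grid) == 2, all(input_grid >= 12),
            length(conv_channels) == 2, gru_units >= 1)
  structure(list(input_grid = as.integer(input_grid),
                 conv_channels = as.integer(conv_channels),
                 gru_units = as.integer(gru_units),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "grunet_config")
}

#' Spectrogram batch for the network
#'
#' Computes each call's spectrogram on a reduced `grid` (time x frequency,
#' covering 0 to the view ceiling) and min-max normalizes every call to
#' `[0, 1]` (a constant spectrogram maps to all zeros).
#'
#' @param recs List of [call_recording()]s.
#' @param grid `c(time, frequency)` output resolution.
#' @param view_fmax_hz Upper frequency bound, Hz.
#' @return Numeric array `(calls, time, frequency)`.
#' @export
prepare_spectrogram_batch <- function(recs, grid = c(200, 64),
                                      view_fmax_hz = 5000) {
  if (length(recs) == 0) stop("prepare_spectrogram_batch: empty recording list")
  settings <- spectrogram_settings(n_time_steps = grid[1],
                                   n_freq_steps = grid[2],
                                   view_fmax_hz = view_fmax_hz)
  out <- array(0, dim = c(length(recs), grid[1], grid[2]))
  for (i in seq_along(recs)) {
    s <- compute_spectrogram(recs[[i]], settings)
    v <- s$power_db
    rng <- max(v) - min(v)
    out[i, , ] <- if (rng > 0) (v - min(v)) / rng else 0
  }
  out
}

# ---------------------------------------------------------------------------
# layers

# im2col gather index for valid 3x3 convolution over (t, f) with c channels,
# batch-major flat layout A[b, t, f, c]. Returns matrix (p x 9c) of 0-based
# flat offsets (in units of batch stride).
conv_index <- function(tt, ff, cc) {
  t_out <- tt - 2L; f_out <- ff - 2L
  pos_t <- rep(seq_len(t_out), times = f_out)
  pos_f <- rep(seq_len(f_out), each = t_out)
  idx <- matrix(0L, nrow = t_out * f_out, ncol = 9L * cc)
  j <- 0L
  for (c_i in seq_len(cc)) for (df in 0:2) for (dt in 0:2) {
    j <- j + 1L
    idx[, j] <- (pos_t + dt - 1L) + tt * (pos_f + df - 1L) + tt * ff * (c_i - 1L)
  }
  idx
}

conv_forward <- function(a, w, b_vec, idx) {
  # a: (B, T, F, C); w: (9C x Cout); returns list(out (B,T-2,F-2,Cout), patches)
  d <- dim(a); B <- d[1]
  a_mat <- matrix(a, nrow = B)
  p <- nrow(idx)
  z <- matrix(a_mat[, as.vector(idx) + 1L], nrow = B * p)
  out <- sweep(z %*% w, 2, b_vec, "+")
  list(out = array(out, dim = c(B, d[2] - 2L, d[3] - 2L, ncol(w))),
       patches = z)
}

conv_backward <- function(d_out, patches, w, idx, in_dim) {
  B <- in_dim[1]
  p <- nrow(idx)
  d_mat <- matrix(d_out, nrow = B * p)
  dw <- crossprod(patches, d_mat)
  db <- colSums(d_mat)
  dz <- d_mat %*% t(w)                       # (B*p) x 9C
  da_mat <- matrix(0, nrow = B, ncol = prod(in_dim[-1]))
  dz_b <- matrix(dz, nrow = B)               # B x (p*9C)
  # scatter-add group-wise: within one kernel offset the p target positions
  # are distinct, so each of the 9C groups is a single vectorized accumulate
  for (j in seq_len(ncol(idx))) {
    tgt <- idx[, j] + 1L
    da_mat[, tgt] <- da_mat[, tgt] + dz_b[, (j - 1L) * p + seq_len(p)]
  }
  list(dw = dw, db = db, da = array(da_mat, dim = in_dim))
}

pool_forward <- function(a) {
  d <- dim(a)
  t2 <- d[2] %/% 2L; f2 <- d[3] %/% 2L
  s1 <- a[, seq_len(t2) * 2 - 1, seq_len(f2) * 2 - 1, , drop = FALSE]
  s2 <- a[, seq_len(t2) * 2,     seq_len(f2) * 2 - 1, , drop = FALSE]
  s3 <- a[, seq_len(t2) * 2 - 1, seq_len(f2) * 2,     , drop = FALSE]
  s4 <- a[, seq_len(t2) * 2,     seq_len(f2) * 2,     , drop = FALSE]
  m <- pmax(s1, s2, s3, s4)
  which4 <- ifelse(m == s1, 1L, ifelse(m == s2, 2L, ifelse(m == s3, 3L, 4L)))
  list(out = m, which = which4, in_dim = d)
}

pool_backward <- function(d_out, pf) {
  d <- pf$in_dim
  da <- array(0, dim = d)
  t2 <- d[2] %/% 2L; f2 <- d[3] %/% 2L
  ti <- list(seq_len(t2) * 2 - 1, seq_len(t2) * 2)
  fi <- list(seq_len(f2) * 2 - 1, seq_len(f2) * 2)
  sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (s in 1:4) {
    mask <- (pf$which == s)
    tmp <- da[, ti[[sel[[s]][1]]], fi[[sel[[s]][2]]], , drop = FALSE]
    da[, ti[[sel[[s]][1]]], fi[[sel[[s]][2]]], ] <- tmp + d_out * mask
  }
  da
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_forward <- function(x_seq, p) {
  # x_seq: (B, T, D); returns hidden states and gate activations per step
  d <- dim(x_seq); B <- d[1]; TT <- d[2]
  H <- ncol(p$Uz)
  h <- matrix(0, B, H)
  zs <- rs <- ns <- hs <- vector("list", TT)
  for (t in seq_len(TT)) {
    xt <- matrix(x_seq[, t, ], nrow = B)
    z <- sigmoid(sweep(xt %*% p$Wz + h %*% p$Uz, 2, p$bz, "+"))
    r <- sigmoid(sweep(xt %*% p$Wr + h %*% p$Ur, 2, p$br, "+"))
    n <- tanh(sweep(xt %*% p$Wn + (r * h) %*% p$Un, 2, p$bn, "+"))
    h_new <- (1 - z) * n + z * h
    zs[[t]] <- z; rs[[t]] <- r; ns[[t]] <- n; hs[[t]] <- h_new
    h <- h_new
  }
  list(h_last = h, zs = zs, rs = rs, ns = ns, hs = hs)
}

gru_backward <- function(d_h_last, x_seq, fw, p) {
  d <- dim(x_seq); B <- d[1]; TT <- d[2]; D <- d[3]
  g <- list(Wz = 0 * p$Wz, Wr = 0 * p$Wr, Wn = 0 * p$Wn,
            Uz = 0 * p$Uz, Ur = 0 * p$Ur, Un = 0 * p$Un,
            bz = 0 * p$bz, br = 0 * p$br, bn = 0 * p$bn)
  dx <- array(0, dim = d)
  dh <- d_h_last
  for (t in rev(seq_len(TT))) {
    z <- fw$zs[[t]]; r <- fw$rs[[t]]; n <- fw$ns[[t]]
    h_prev <- if (t == 1) matrix(0, B, ncol(z)) else fw$hs[[t - 1]]
    xt <- matrix(x_seq[, t, ], nrow = B)
    dn <- dh * (1 - z)
    dz <- dh * (h_prev - n)
    dn_pre <- dn * (1 - n^2)
    dz_pre <- dz * z * (1 - z)
    drh <- dn_pre %*% t(p$Un)
    dr <- drh * h_prev
    dr_pre <- dr * r * (1 - r)
    g$Wn <- g$Wn + crossprod(xt, dn_pre)
    g$Un <- g$Un + crossprod(r * h_prev, dn_pre)
    g$bn <- g$bn + colSums(dn_pre)
    g$Wz <- g$Wz + crossprod(xt, dz_pre)
    g$Uz <- g$Uz + crossprod(h_prev, dz_pre)
    g$bz <- g$bz + colSums(dz_pre)
    g$Wr <- g$Wr + crossprod(xt, dr_pre)
    g$Ur <- g$Ur + crossprod(h_prev, dr_pre)
    g$br <- g$br + colSums(dr_pre)
    dx[, t, ] <- dn_pre %*% t(p$Wn) + dz_pre %*% t(p$Wz) + dr_pre %*% t(p$Wr)
    dh <- dh * z + drh * r + dz_pre %*% t(p$Uz) + dr_pre %*% t(p$Ur)
  }
  list(grads = g, dx = dx)
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

init_params <- function(config, n_classes) {
  g <- config$input_grid
  c1 <- config$conv_channels[1]; c2 <- config$conv_channels[2]
  t1 <- (g[1] - 2L) %/% 2L; f1 <- (g[2] - 2L) %/% 2L
  t2 <- (t1 - 2L) %/% 2L; f2 <- (f1 - 2L) %/% 2L
  if (t2 < 1 || f2 < 1) stop("input grid too small for two conv/pool blocks")
  H <- config$gru_units
  D <- f2 * c2
  gl <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
  }
  with_seed(derive_seed(config$seed, "init"), list(
    w1 = gl(9, c1), b1 = rep(0, c1),
    w2 = gl(9 * c1, c2), b2 = rep(0, c2),
    Wz = gl(D, H), Wr = gl(D, H), Wn = gl(D, H),
    Uz = gl(H, H), Ur = gl(H, H), Un = gl(H, H),
    bz = rep(0, H), br = rep(0, H), bn = rep(0, H),
    Wo = gl(H, n_classes), bo = rep(0, n_classes)
  ))
}

net_forward <- function(xb, params, shapes, keep = FALSE) {
  B <- dim(xb)[1]
  a0 <- array(xb, dim = c(B, shapes$g[1], shapes$g[2], 1L))
  c1 <- conv_forward(a0, params$w1, params$b1, shapes$idx1)
  r1 <- pmax(c1$out, 0)
  p1 <- pool_forward(r1)
  c2 <- conv_forward(p1$out, params$w2, params$b2, shapes$idx2)
  r2 <- pmax(c2$out, 0)
  p2 <- pool_forward(r2)
  d2 <- dim(p2$out)
  # collapse frequency x channels into the GRU input per time step
  x_seq <- array(aperm(p2$out, c(1, 2, 3, 4)), dim = c(d2[1], d2[2], d2[3] * d2[4]))
  fw <- gru_forward(x_seq, params)
  logits <- sweep(fw$h_last %*% params$Wo, 2, params$bo, "+")
  probs <- softmax_rows(logits)
  if (!keep) return(list(probs = probs))
  list(probs = probs, a0 = a0, c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
       p2 = p2, x_seq = x_seq, fw = fw)
}

net_backward <- function(cache, y_onehot, params, shapes) {
  B <- nrow(y_onehot)
  d_logits <- (cache$probs - y_onehot) / B
  g <- list()
  g$Wo <- crossprod(cache$fw$h_last, d_logits)
  g$bo <- colSums(d_logits)
  d_h <- d_logits %*% t(params$Wo)
  gb <- gru_backward(d_h, cache$x_seq, cache$fw, params)
  for (nm in names(gb$grads)) g[[nm]] <- gb$grads[[nm]]
  d_p2 <- array(gb$dx, dim = dim(cache$p2$out))
  d_r2 <- pool_backward(d_p2, cache$p2)
  d_c2 <- d_r2 * (cache$c2$out > 0)
  cb2 <- conv_backward(d_c2, cache$c2$patches, params$w2, shapes$idx2,
                       dim(cache$p1$out))
  g$w2 <- cb2$dw; g$b2 <- cb2$db
  d_p1 <- cb2$da
  d_r1 <- pool_backward(d_p1, cache$p1)
  d_c1 <- d_r1 * (cache$c1$out > 0)
  cb1 <- conv_backward(d_c1, cache$c1$patches, params$w1, shapes$idx1,
                       dim(cache$a0))
  g$w1 <- cb1$dw; g$b1 <- cb1$db
  g
}

make_shapes <- function(config) {
  g <- config$input_grid
  c1 <- config$conv_channels[1]
  t1 <- (g[1] - 2L) %/% 2L; f1 <- (g[2] - 2L) %/% 2L
  list(g = g, idx1 = conv_index(g[1], g[2], 1L),
       idx2 = conv_index(t1, f1, c1))
}

adam_step <- function(params, grads, state, lr, t_step) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    mh <- state$m[[nm]] / (1 - b1^t_step)
    vh <- state$v[[nm]] / (1 - b2^t_step)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Train the convolutional-recurrent spectrogram classifier
#'
#' Two 3x3 convolution blocks (ReLU, 2x2 max-pooling) extract local
#' time-frequency features; the pooled map is read as a sequence over time by
#' a single-layer GRU whose final hidden state feeds a softmax classifier.
#' Trained with Adam on cross-entropy, with early stopping on validation
#' accuracy. Fully deterministic given `config$seed`.
#'
#' @param x Array `(calls, time, frequency)` from
#'   [prepare_spectrogram_batch()].
#' @param y Factor of labels (at least two classes present).
#' @param config A [grunet_config()]; its `input_grid` must match `x`.
#' @param validation Optional list `list(x =, y =)` monitored for early
#'   stopping; when NULL, training accuracy is monitored instead.
#' @return Object of class `grunet` with `predict` and `print` methods and a
#'   `history` data.frame (per-epoch loss and accuracies).
#' @export
grunet <- function(x, y, config = grunet_config(), validation = NULL) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("grunet: training labels contain a single class")
  stopifnot(length(dim(x)) == 3, dim(x)[1] == length(y),
            all(dim(x)[2:3] == config$input_grid))
  lev <- levels(y)
  shapes <- make_shapes(config)
  params <- init_params(config, length(lev))
  state <- list(m = lapply(params, function(p) 0 * p),
                v = lapply(params, function(p) 0 * p))
  n <- length(y)
  onehot <- diag(length(lev))[as.integer(y), , drop = FALSE]
  best <- list(metric = -Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_acc = numeric(), val_acc = numeric())
  t_step <- 0L
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      loss <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- x[bi, , , drop = FALSE]
        cache <- net_forward(xb, params, shapes, keep = TRUE)
        loss <- loss - sum(log(pmax(
          cache$probs[cbind(seq_along(bi), as.integer(y[bi]))], 1e-12)))
        grads <- net_backward(cache, onehot[bi, , drop = FALSE], params, shapes)
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, config$learning_rate, t_step)
        params <- upd$params; state <- upd$state
      }
      tr_pred <- predict_grunet_params(params, shapes, lev, x)
      tr_acc <- mean(tr_pred == y)
      val_acc <- if (!is.null(validation)) {
        mean(predict_grunet_params(params, shapes, lev, validation$x) ==
               validation$y)
      } else NA_real_
      metric <- if (is.null(validation)) tr_acc else val_acc
      history <- rbind(history, data.frame(
        epoch = epoch, loss = loss / n, train_acc = tr_acc, val_acc = val_acc))
      if (metric > best$metric + 1e-9) {
        best <- list(metric = metric, params = params, epoch = epoch)
      }
      if (tr_acc >= 1 && (is.null(validation) || epoch - best$epoch >= 5)) break
      if (epoch - best$epoch >= config$patience) break
    }
  })
  structure(list(params = best$params, levels = lev, config = config,
                 shapes = shapes, history = history,
                 best_epoch = best$epoch),
            class = "grunet")
}

predict_grunet_params <- function(params, shapes, lev, x, batch = 64L) {
  n <- dim(x)[1]
  out <- character(n)
  for (start in seq(1, n, by = batch)) {
    bi <- start:min(start + batch - 1L, n)
    p <- net_forward(x[bi, , , drop = FALSE], params, shapes)$probs
    out[bi] <- lev[max.col(p, ties.method = "first")]
  }
  factor(out, levels = lev)
}

#' Predict from a fitted spectrogram classifier
#'
#' @param object A [grunet()] fit.
#' @param newdata Array `(calls, time, frequency)` on the model's grid.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of labels, or a probability matrix.
#' @export
predict.grunet <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(length(dim(newdata)) == 3,
            all(dim(newdata)[2:3] == object$config$input_grid))
  if (type == "class") {
    return(predict_grunet_params(object$params, object$shapes, object$levels,
                                 newdata))
  }
  n <- dim(newdata)[1]
  probs <- matrix(NA_real_, n, length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (start in seq(1, n, by = 64L)) {
    bi <- start:min(start + 63L, n)
    probs[bi, ] <- net_forward(newdata[bi, , , drop = FALSE], object$params,
                               object$shapes)$probs
  }
  probs
}

#' @export
print.grunet <- function(x, ...) {
  cat(sprintf("grunet: conv %d/%d channels -> GRU %d units -> %d classes; trained %d epochs (best %d)\n",
              x$config$conv_channels[1], x$config$conv_channels[2],
              x$config$gru_units, length(x$levels), nrow(x$history),
              x$best_epoch))
  invisible(x)
}

#' Stratified k-fold evaluation of the spectrogram classifier
#'
#' The same stratified protocol and result schema as
#' [evaluate_stratified_kfold()], so explainable and deep models can be
#' tabled side by side. Within each fold, 15% of the training part (stratified)
#' is held out to drive early stopping.
#'
#' @param x Spectrogram array from [prepare_spectrogram_batch()].
#' @param y Factor of labels.
#' @param k Number of folds.
#' @param config A [grunet_config()].
#' @param seed Integer seed.
#' @return An [experiment_result()] with `model = "deep"`.
#' @export
evaluate_grunet <- function(x, y, k = 5, config = grunet_config(), seed = 1) {
  y <- droplevels(factor(y))
  folds <- stratified_folds(y, k, derive_seed(seed, "dl-outer"))
  train_acc <- test_acc <- numeric(k)
  for (i in seq_len(k)) {
    tr <- which(folds != i)
    # stratified validation split inside the training part
    vfolds <- stratified_folds(y[tr], max(2L, min(7L, floor(1 / 0.15))),
                               derive_seed(seed, "dl-val", i))
    vi <- tr[vfolds == 1]
    ti <- tr[vfolds != 1]
    cfg <- config
    cfg$seed <- derive_seed(seed, "dl-fit", i)
    fit <- grunet(x[ti, , , drop = FALSE], y[ti], cfg,
                  validation = list(x = x[vi, , , drop = FALSE], y = y[vi]))
    train_acc[i] <- mean(predict(fit, x[tr, , , drop = FALSE]) == y[tr])
    te <- which(folds == i)
    test_acc[i] <- mean(predict(fit, x[te, , , drop = FALSE]) == y[te])
  }
  experiment_result(train_acc, test_acc, k = k, task = "spectrogram",
                    model = "deep")
}
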