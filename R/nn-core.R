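# Minimal fully-connected network with one hidden layer, trained by Adam
# with inverted dropout and early stopping on a validation split. Kept
# internal: both the power predictor and the candidate classifier wrap it
# with their own losses.

relu <- function(x) pmax(x, 0)

nn_init <- function(n_in, n_hidden, seed = NULL, out_bias = 0,
                    out_sd = sqrt(2 / n_hidden)) {
  if (!is.null(seed)) set.seed(seed)
  list(
    W1 = matrix(stats::rnorm(n_in * n_hidden, sd = sqrt(2 / n_in)), n_in, n_hidden),
    b1 = rep(0, n_hidden),
    W2 = matrix(stats::rnorm(n_hidden, sd = out_sd), n_hidden, 1),
    b2 = out_bias)
}

# forward pass; returns pre-activations for backprop
nn_forward <- function(par, X, dropout_mask = NULL) {
  pre <- sweep(X %*% par$W1, 2, par$b1, `+`)
  H <- relu(pre)
  if (!is.null(dropout_mask)) H <- H * dropout_mask
  out <- drop(H %*% par$W2) + par$b2
  list(pre = pre, H = H, out = out)
}

nn_predict <- function(par, X) nn_forward(par, X)$out

# loss_grad(pred, target) must return list(loss = scalar, dpred = vector)
nn_train <- function(X, y, loss_grad, hidden = 200, dropout = 0.5,
                     batch_size = 1000, lr = 1e-3, max_epochs = 400,
                     patience = 10, val_frac = 0.1, seed = 1,
                     out_bias = 0, out_sd = sqrt(2 / hidden),
                     lr_decays = 0, average_tail = FALSE, verbose = FALSE) {
  set.seed(seed)
  n <- nrow(X)
  n_val <- max(1L, round(val_frac * n))
  if (n <= 2L) n_val <- 0L
  perm <- sample.int(n)
  vi <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  ti <- setdiff(perm, vi)
  Xt <- X[ti, , drop = FALSE]; yt <- y[ti]
  Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
  par <- nn_init(ncol(X), hidden, out_bias = out_bias, out_sd = out_sd)
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  t_adam <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(par = par, val = Inf, epoch = 0L)
  history <- numeric(0)
  bad <- 0L
  final_stage <- lr_decays == 0
  avg <- NULL; avg_n <- 0
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(nrow(Xt))
    for (i0 in seq(1L, nrow(Xt), by = batch_size)) {
      bi <- ord[i0:min(i0 + batch_size - 1L, nrow(Xt))]
      Xb <- Xt[bi, , drop = FALSE]; yb <- yt[bi]
      mask <- if (dropout > 0)
        matrix(stats::rbinom(length(bi) * hidden, 1, 1 - dropout),
               length(bi), hidden) / (1 - dropout)
      else NULL
      fw <- nn_forward(par, Xb, mask)
      lg <- loss_grad(fw$out, yb)
      dout <- matrix(lg$dpred / length(yb), ncol = 1)
      gW2 <- t(fw$H) %*% dout
      gb2 <- sum(dout)
      dH <- dout %*% t(par$W2)
      if (!is.null(mask)) dH <- dH * mask
      dpre <- dH * (fw$pre > 0)
      gW1 <- t(Xb) %*% dpre
      gb1 <- colSums(dpre)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      t_adam <- t_adam + 1
      for (nm in names(par)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^t_adam)
        vhat <- vel[[nm]] / (1 - beta2^t_adam)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    if (average_tail && final_stage) {
      # running weight average over the final annealing stage damps the
      # stochastic wobble that dropout induces near convergence
      avg_n <- avg_n + 1
      if (is.null(avg)) avg <- par
      else for (nm in names(par))
        avg[[nm]] <- avg[[nm]] + (par[[nm]] - avg[[nm]]) / avg_n
    }
    val <- if (length(vi) > 0)
      loss_grad(nn_predict(par, Xv), yv)$loss
    else loss_grad(nn_predict(par, Xt), yt)$loss
    history <- c(history, val)
    if (val < best$val - 1e-12) {
      best <- list(par = par, val = val, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) {
        # on plateau: restore the best weights and anneal the step size a
        # few times before stopping for good
        if (lr_decays > 0) {
          lr_decays <- lr_decays - 1L
          if (lr_decays == 0) final_stage <- TRUE
          lr <- lr / 3
          par <- best$par
          bad <- 0L
        } else break
      }
    }
  }
  out_par <- best$par
  if (average_tail && !is.null(avg)) {
    val_avg <- if (length(vi) > 0)
      loss_grad(nn_predict(avg, Xv), yv)$loss
    else loss_grad(nn_predict(avg, Xt), yt)$loss
    if (val_avg <= best$val) {
      out_par <- avg
      best$val <- val_avg
    }
  }
  if (verbose)
    message(sprintf("stopped after %d epochs; best val loss %.4g at epoch %d",
                    length(history), best$val, best$epoch))
  list(par = out_par, history = history, best_epoch = best$epoch,
       val_loss = best$val)
}
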