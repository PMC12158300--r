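# NFT-vs-resting classification of transition matrices.
#
# The four transition blocks of each A_k are packed into a 4-channel
# 4x4 tensor (smaller blocks zero-padded bottom/right) and classified by
# a small CNN: 2 convolutional layers (2x2 kernels, same padding, 8 then
# 16 channels), 2 max-pool layers (2x2) and 2 fully connected layers
# (hidden 32, output 2), trained with Adam on the softmax cross-entropy.
# Everything is implemented with plain matrix algebra (im2col) because
# the tensors are tiny and no deep-learning runtime is assumed.

POSITIVE_CLASS <- "NFT"

#' Session-level split specification
#'
#' @param ratios train/validation/test fractions (default 0.7/0.1/0.2);
#'   positive, summing to 1.
#' @param seed shuffle seed.
#' @return a `split_spec`.
#' @export
split_spec <- function(ratios = c(train = 0.7, val = 0.1, test = 0.2), seed = 1L) {
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9)
    stopf("split ratios must be positive and sum to 1")
  list(ratios = ratios, seed = as.integer(seed))
}

#' Split session ids into train/validation/test
#'
#' Deterministic given the seed; sizes follow the floor-remainder rule
#' `test = floor(n * r_test)`, `val = floor(n * r_val)`, train the
#' remainder. Every session id lands in exactly one partition, which is
#' what rules out leakage between partitions downstream.
#'
#' @param session_ids character vector (>= 3 unique ids).
#' @param spec a [split_spec()].
#' @return list with `train`, `val`, `test` id vectors.
#' @export
split_sessions <- function(session_ids, spec = split_spec()) {
  ids <- unique(session_ids)
  n <- length(ids)
  if (n < 3) stopf("need at least 3 sessions to split")
  n_test <- floor(n * spec$ratios[[3]])
  n_val <- floor(n * spec$ratios[[2]])
  n_train <- n - n_test - n_val
  if (n_test < 1 || n_val < 1 || n_train < 1)
    stopf("empty partition for n = %d; with ratios %s at least %d sessions are needed",
          n, paste(spec$ratios, collapse = "/"),
          ceiling(1 / min(spec$ratios)))
  set.seed(spec$seed)
  perm <- sample(ids)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

pad_to_4 <- function(m) {
  out <- matrix(0, 4, 4)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

#' Pack transitions into labeled 4x4x4 tensors
#'
#' Each transition matrix becomes one sample: a 4x4x4 array whose four
#' channels hold the mc, loc, mc_loc and mnet blocks, zero-padded
#' bottom/right to 4x4. Packing is lossless: the 43 weights occupy fixed
#' positions.
#'
#' @param x a `pnda_fit`, a `session_chain` with `$transitions`, or a
#'   plain list of [transition_matrix()]s.
#' @param label condition label attached to every sample (taken from the
#'   object when present).
#' @param session_id id attached to every sample.
#' @return list with `tensors` (list of 4x4x4 arrays), `labels`,
#'   `session_ids`.
#' @export
tensorize_transitions <- function(x, label = NULL, session_id = NULL) {
  if (inherits(x, "pnda_fit")) {
    trans <- x$final_transitions
    label <- label %||% x$condition
    session_id <- session_id %||% x$session_id
  } else if (is.list(x) && !is.null(x$transitions)) {
    trans <- x$transitions
    label <- label %||% x$condition
  } else {
    trans <- x
  }
  if (length(trans) == 0) stopf("no transitions to tensorize")
  tensors <- lapply(trans, function(A) {
    stopifnot(inherits(A, "transition_matrix"))
    arr <- array(0, c(4, 4, 4))
    for (i in seq_along(BLOCK_NAMES)) arr[, , i] <- pad_to_4(A[[BLOCK_NAMES[i]]])
    arr
  })
  list(tensors = tensors,
       labels = rep(label %||% NA_character_, length(tensors)),
       session_ids = rep(session_id %||% NA_character_, length(tensors)))
}

#' Recover a transition matrix from its tensor
#'
#' Inverse of the packing in [tensorize_transitions()].
#' @param arr 4x4x4 array.
#' @return a [transition_matrix()].
#' @export
detensorize_transition <- function(arr) {
  stopifnot(identical(dim(arr), c(4L, 4L, 4L)))
  transition_matrix(arr[1:3, 1:3, 1], arr[, , 2], arr[1:3, 1:3, 3], arr[1:3, 1:3, 4])
}

#' CNN architecture and training settings
#'
#' The layer structure is fixed (2 conv + 2 pool + 2 fully connected);
#' the spec only carries the tunable training knobs.
#'
#' @param conv_channels channels after each conv layer (default 8, 16).
#' @param hidden fully connected hidden width (default 32).
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience on validation loss.
#' @return a `cnn_spec`.
#' @export
cnn_spec <- function(conv_channels = c(8L, 16L), hidden = 32L,
                     lr = 0.01, epochs = 150L, batch_size = 64L,
                     patience = 25L) {
  list(conv_channels = as.integer(conv_channels), hidden = as.integer(hidden),
       lr = lr, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), patience = as.integer(patience))
}

# --- tiny CNN plumbing -----------------------------------------------------

# im2col index map for a 2x2 same-padded convolution on an s x s grid
# (padding one row/column bottom-right). Returns a (s*s) x 4 matrix of
# linear indices into the (s+1) x (s+1) padded grid.
conv_idx <- function(s) {
  sp <- s + 1L
  idx <- matrix(0L, s * s, 4L)
  pos <- 0L
  for (c in 1:s) for (r in 1:s) {   # column-major output positions
    pos <- pos + 1L
    idx[pos, ] <- c((c - 1L) * sp + r, (c - 1L) * sp + r + 1L,
                    c * sp + r, c * sp + r + 1L)
  }
  idx
}

# Scatter map: padded linear index for each original position.
pad_idx <- function(s) {
  sp <- s + 1L
  as.vector(outer(1:s, 1:s, function(r, c) (c - 1L) * sp + r))
}

# X: N x (s*s*Cin) matrix, channels contiguous in blocks of s*s
# (column-major within channel). Returns N*(s*s) x (4*Cin) patch matrix.
im2col <- function(X, s, cin, idx) {
  n <- nrow(X)
  ss <- s * s
  sp2 <- (s + 1L)^2
  out <- matrix(0, n * ss, 4L * cin)
  pidx <- pad_idx(s)
  for (ch in seq_len(cin)) {
    padded <- matrix(0, n, sp2)
    padded[, pidx] <- X[, (ch - 1L) * ss + seq_len(ss)]
    for (k in 1:4) out[, (ch - 1L) * 4L + k] <- as.vector(t(padded[, idx[, k]]))
  }
  out
}

# Transpose of im2col: accumulate patch-matrix gradients back onto the
# N x (s*s*Cin) input layout.
col2im <- function(G, s, cin, idx, n) {
  ss <- s * s
  sp2 <- (s + 1L)^2
  pidx <- pad_idx(s)
  out <- matrix(0, n, ss * cin)
  for (ch in seq_len(cin)) {
    padded <- matrix(0, n, sp2)
    for (k in 1:4) {
      g <- matrix(G[, (ch - 1L) * 4L + k], ss, n)  # positions x N
      tg <- t(g)
      for (p in seq_len(ss)) padded[, idx[p, k]] <- padded[, idx[p, k]] + tg[, p]
    }
    out[, (ch - 1L) * ss + seq_len(ss)] <- padded[, pidx]
  }
  out
}

# 2x2 max-pool groups on an s x s grid (column-major), s even.
pool_groups <- function(s) {
  h <- s %/% 2L
  groups <- matrix(0L, h * h, 4L)
  pos <- 0L
  for (c in seq(1, s, by = 2)) for (r in seq(1, s, by = 2)) {
    pos <- pos + 1L
    groups[pos, ] <- c((c - 1L) * s + r, (c - 1L) * s + r + 1L,
                       c * s + r, c * s + r + 1L)
  }
  groups
}

init_cnn <- function(spec, seed) {
  set.seed(seed)
  he <- function(fan_in, nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
  list(W1 = he(4 * 4, 4 * 4, c1), b1 = numeric(c1),
       W2 = he(4 * c1, 4 * c1, c2), b2 = numeric(c2),
       W3 = he(c2, c2, spec$hidden), b3 = numeric(spec$hidden),
       W4 = he(spec$hidden, spec$hidden, 2L), b4 = numeric(2L))
}

# Forward pass. X: N x 64 (4 channels x 16 positions, column-major).
cnn_forward <- function(params, X, spec) {
  n <- nrow(X)
  c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
  i4 <- conv_idx(4L); g4 <- pool_groups(4L)
  i2 <- conv_idx(2L); g2 <- pool_groups(2L)

  M1 <- im2col(X, 4L, 4L, i4)                       # (N*16) x 16
  Z1 <- sweep(M1 %*% params$W1, 2, params$b1, `+`)  # (N*16) x c1
  A1 <- pmax(Z1, 0)
  # pool 4x4 -> 2x2 per channel: operate on N x 16 slices
  P1 <- matrix(0, n, 4L * c1)
  amax1 <- matrix(0L, n, 4L * c1)
  for (ch in seq_len(c1)) {
    a <- matrix(A1[, ch], 16L, n)                   # positions x N
    for (g in 1:4) {
      block <- a[g4[g, ], , drop = FALSE]
      mi <- max.col(t(block), ties.method = "first")
      P1[, (ch - 1L) * 4L + g] <- block[cbind(mi, seq_len(n))]
      amax1[, (ch - 1L) * 4L + g] <- g4[g, mi]
    }
  }
  M2 <- im2col(P1, 2L, c1, i2)                      # (N*4) x (4*c1)
  Z2 <- sweep(M2 %*% params$W2, 2, params$b2, `+`)  # (N*4) x c2
  A2 <- pmax(Z2, 0)
  P2 <- matrix(0, n, c2)
  amax2 <- matrix(0L, n, c2)
  for (ch in seq_len(c2)) {
    a <- matrix(A2[, ch], 4L, n)
    mi <- max.col(t(a), ties.method = "first")
    P2[, ch] <- a[cbind(mi, seq_len(n))]
    amax2[, ch] <- mi
  }
  Z3 <- sweep(P2 %*% params$W3, 2, params$b3, `+`)
  A3 <- pmax(Z3, 0)
  logits <- sweep(A3 %*% params$W4, 2, params$b4, `+`)
  list(M1 = M1, Z1 = Z1, A1 = A1, P1 = P1, amax1 = amax1,
       M2 = M2, Z2 = Z2, A2 = A2, P2 = P2, amax2 = amax2,
       Z3 = Z3, A3 = A3, logits = logits, n = n)
}

softmax <- function(l) {
  e <- exp(l - apply(l, 1, max))
  e / rowSums(e)
}

cnn_backward <- function(params, fw, X, y, spec) {
  n <- fw$n
  c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
  i4 <- conv_idx(4L); i2 <- conv_idx(2L)
  g4 <- pool_groups(4L)
  probs <- softmax(fw$logits)
  dlogits <- probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits / n

  gW4 <- t(fw$A3) %*% dlogits; gb4 <- colSums(dlogits)
  dA3 <- dlogits %*% t(params$W4)
  dZ3 <- dA3 * (fw$Z3 > 0)
  gW3 <- t(fw$P2) %*% dZ3; gb3 <- colSums(dZ3)
  dP2 <- dZ3 %*% t(params$W3)                        # N x c2

  dA2 <- matrix(0, n * 4L, c2)
  for (ch in seq_len(c2)) {
    tmp <- matrix(0, 4L, n)
    tmp[cbind(fw$amax2[, ch], seq_len(n))] <- dP2[, ch]
    dA2[, ch] <- as.vector(tmp)
  }
  dZ2 <- dA2 * (fw$Z2 > 0)
  gW2 <- t(fw$M2) %*% dZ2; gb2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(params$W2)
  dP1 <- col2im(dM2, 2L, c1, i2, n)                  # N x (4*c1)

  dA1 <- matrix(0, n * 16L, c1)
  for (ch in seq_len(c1)) {
    tmp <- matrix(0, 16L, n)
    for (g in 1:4) {
      sel <- cbind(fw$amax1[, (ch - 1L) * 4L + g], seq_len(n))
      tmp[sel] <- tmp[sel] + dP1[, (ch - 1L) * 4L + g]
    }
    dA1[, ch] <- as.vector(tmp)
  }
  dZ1 <- dA1 * (fw$Z1 > 0)
  gW1 <- t(fw$M1) %*% dZ1; gb1 <- colSums(dZ1)

  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

cnn_loss <- function(params, X, y, spec) {
  logits <- cnn_forward(params, X, spec)$logits
  p <- softmax(logits)
  -mean(log(pmax(p[cbind(seq_len(nrow(X)), y)], 1e-12)))
}

tensors_to_matrix <- function(tensors) {
  t(vapply(tensors, function(a) as.vector(a), numeric(64)))
}

labels_to_int <- function(labels) {
  ifelse(labels == POSITIVE_CLASS, 1L, 2L)  # class 1 = NFT (positive)
}

#' Train the transition-tensor CNN
#'
#' Minibatch Adam on softmax cross-entropy with early stopping on the
#' validation loss. Deterministic for a fixed seed (single-threaded
#' matrix algebra).
#'
#' @param train,val tensor sets from [tensorize_transitions()] (lists
#'   with `tensors` and `labels`); both classes must be present in
#'   `train`.
#' @param spec a [cnn_spec()].
#' @param seed integer seed for initialization and batch shuffling.
#' @return a `cnn_model` (parameters, spec, training history).
#' @export
train_classifier <- function(train, val, spec = cnn_spec(), seed = 1L) {
  if (length(unique(train$labels)) < 2)
    stopf("training set must contain both classes")
  X <- tensors_to_matrix(train$tensors)
  y <- labels_to_int(train$labels)
  Xv <- tensors_to_matrix(val$tensors)
  yv <- labels_to_int(val$labels)
  params <- init_cnn(spec, seed)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  n <- nrow(X)
  set.seed(seed + 1L)
  history <- numeric(0)
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample(n)
    for (start in seq(1, n, by = spec$batch_size)) {
      sel <- ord[start:min(start + spec$batch_size - 1, n)]
      fw <- cnn_forward(params, X[sel, , drop = FALSE], spec)
      gr <- cnn_backward(params, fw, X[sel, , drop = FALSE], y[sel], spec)
      t_step <- t_step + 1
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gr[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gr[[nm]]^2
        mh <- m[[nm]] / (1 - beta1^t_step)
        vh <- v[[nm]] / (1 - beta2^t_step)
        params[[nm]] <- params[[nm]] - spec$lr * mh / (sqrt(vh) + eps)
      }
    }
    vloss <- cnn_loss(params, Xv, yv, spec)
    history <- c(history, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(list(params = best$params, spec = spec, seed = seed,
                 val_loss = best$loss, history = history,
                 architecture = "conv2x2x8-pool-conv2x2x16-pool-fc32-fc2"),
            class = "cnn_model")
}

#' Class scores of a tensor set
#'
#' @param model a `cnn_model`.
#' @param tensors list of 4x4x4 arrays.
#' @return numeric vector of NFT-class probabilities.
#' @export
predict_classifier <- function(model, tensors) {
  X <- tensors_to_matrix(tensors)
  softmax(cnn_forward(model$params, X, model$spec)$logits)[, 1]
}

#' Classification metrics from scores and labels
#'
#' NFT is the positive class. Accuracy, F1, TPR and TNR come from the
#' confusion counts at the 0.5 threshold; AUC is the rank statistic
#' (Mann-Whitney) of the scores.
#'
#' @param model a `cnn_model`.
#' @param test tensor set with both classes (single-class sets get an
#'   absent AUC with a warning).
#' @return an `eval_report` list: `accuracy`, `f1_score`, `tpr`, `tnr`,
#'   `auc`, `confusion` (tp, fn, tn, fp), `n`.
#' @export
evaluate_classifier <- function(model, test) {
  scores <- predict_classifier(model, test$tensors)
  eval_from_scores(scores, test$labels)
}

eval_from_scores <- function(scores, labels) {
  pos <- labels == POSITIVE_CLASS
  pred_pos <- scores >= 0.5
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  acc <- (tp + tn) / length(labels)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(tpr) && (prec + tpr) > 0)
    2 * prec * tpr / (prec + tpr) else NA_real_
  auc <- if (any(pos) && any(!pos)) {
    r <- rank(scores)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  } else {
    warnf("single-class test set: AUC is undefined")
    NA_real_
  }
  structure(list(accuracy = acc, f1_score = f1, tpr = tpr, tnr = tnr,
                 auc = auc,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 n = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  F1 %.4f  TPR %.4f  TNR %.4f  AUC %s  (n = %d)\n",
              x$accuracy, x$f1_score, x$tpr, x$tnr,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)), x$n))
  invisible(x)
}

#' K-nearest-neighbour baseline on raw feature vectors
#'
#' Majority vote among the k nearest training points (Euclidean);
#' used as the raw-network baseline against the transition-tensor CNN.
#'
#' @param train_x,test_x numeric matrices (rows = samples).
#' @param train_y labels for `train_x`.
#' @param k neighbours (default 5).
#' @return predicted labels for `test_x`.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 5L) {
  stopifnot(nrow(train_x) >= k)
  t(apply(test_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d)[seq_len(k)]
    tab <- table(train_y[nn])
    names(tab)[which.max(tab)]
  }))[1, ]
}
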