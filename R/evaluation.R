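# Evaluation: confusion-based metrics at the 0.5 operating point, AUROC by
# the rank (Mann-Whitney) statistic with ties counted 1/2, percentile-
# bootstrap confidence intervals, a fixed gated-recurrent baseline, and the
# 0-12 h prediction-horizon sweep.

#' Confusion counts at binary predictions
#' @param labels true labels in \{0, 1\}.
#' @param predicted predicted labels in \{0, 1\}.
#' @return list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(labels, predicted) {
  if (length(labels) != length(predicted))
    stop_config("labels and predictions differ in length")
  stopifnot(all(labels %in% 0:1), all(predicted %in% 0:1))
  list(TP = sum(labels == 1 & predicted == 1),
       TN = sum(labels == 0 & predicted == 0),
       FP = sum(labels == 0 & predicted == 1),
       FN = sum(labels == 1 & predicted == 0))
}

#' Sensitivity TP / (TP + FN)
#' @param counts output of [confusion_counts()].
#' @return fraction in \[0, 1\]; errors when the denominator is zero.
#' @export
sensitivity <- function(counts) {
  if (counts$TP + counts$FN == 0)
    stop_config("sensitivity undefined: no positive labels")
  counts$TP / (counts$TP + counts$FN)
}

#' Specificity TN / (TN + FP)
#' @param counts output of [confusion_counts()].
#' @return fraction in \[0, 1\]; errors when the denominator is zero.
#' @export
specificity <- function(counts) {
  if (counts$TN + counts$FP == 0)
    stop_config("specificity undefined: no negative labels")
  counts$TN / (counts$TN + counts$FP)
}

#' AUROC by the rank statistic
#'
#' Equals the probability that a random positive outscores a random negative,
#' with ties counted 1/2; identical to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels labels in \{0, 1\}, both classes present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_config("AUROC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#' @param scores,labels as in [auroc()].
#' @return data.frame of (fpr, tpr) pairs, non-decreasing, from (0,0) to (1,1).
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  tpr <- c(0, cumsum(labels == 1) / sum(labels == 1))
  fpr <- c(0, cumsum(labels == 0) / sum(labels == 0))
  data.frame(fpr = fpr, tpr = tpr)
}

#' AUROC with a percentile-bootstrap confidence interval
#'
#' Episodes are resampled with replacement `replicates` times; degenerate
#' resamples (one class) are redrawn up to 100 times each. The 2.5/97.5
#' percentiles bound the 95% interval.
#'
#' @param scores,labels as in [auroc()].
#' @param replicates bootstrap replicates (>= 100, default 2000).
#' @param seed RNG seed.
#' @return a `nasga_roc` list: `auroc`, `ci_lower`, `ci_upper`, `replicates`,
#'   `seed`, and the ROC `points`.
#' @export
auroc_ci <- function(scores, labels, replicates = 2000, seed = 1) {
  if (replicates < 100) stop_config("use >= 100 bootstrap replicates")
  point <- auroc(scores, labels)
  set.seed(as.integer(seed))
  n <- length(scores)
  boot <- numeric(replicates)
  for (r in seq_len(replicates)) {
    for (try in 1:100) {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
      if (try == 100) stop_config("could not draw a two-class resample")
    }
    boot[r] <- auroc(scores[idx], labels[idx])
  }
  qs <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(list(auroc = point, ci_lower = min(qs[1], point),
                 ci_upper = max(qs[2], point), replicates = replicates,
                 seed = seed, points = roc_points(scores, labels)),
            class = "nasga_roc")
}

#' @export
print.nasga_roc <- function(x, ...) {
  cat(sprintf("AUROC %.3f (95%% CI %.3f-%.3f, %d bootstrap replicates)\n",
              x$auroc, x$ci_lower, x$ci_upper, x$replicates))
  invisible(x)
}

#' Score a model on the test split
#'
#' @param model a `nasga_child_model` (or any object with a
#'   [predict_scores()] method via `score_fun`).
#' @param episodes split `nasga_episodes`.
#' @param threshold decision threshold on the positive-class score
#'   (default 0.5).
#' @param replicates,seed bootstrap settings.
#' @param score_fun function(model, episodes) -> scores.
#' @return list: `auroc` (a `nasga_roc`), `sensitivity`, `specificity`,
#'   `counts`.
#' @export
evaluate_model <- function(model, episodes, threshold = 0.5,
                           replicates = 2000, seed = 1,
                           score_fun = predict_scores) {
  test <- episode_split(episodes, "test")
  scores <- score_fun(model, test)
  pred <- as.integer(scores >= threshold)
  counts <- confusion_counts(test$label, pred)
  list(auroc = auroc_ci(scores, test$label, replicates, seed),
       sensitivity = sensitivity(counts), specificity = specificity(counts),
       counts = counts)
}

# ---- gated recurrent baseline ----------------------------------------------
# Single-layer GRU classifier with a softmax head, trained under the same
# regime (Adam, cross-entropy, early stopping) and hidden size as the
# searched cells: the comparison anchor for the architecture search.

gru_init <- function(n_features, hidden, seed = NULL) {
  maybe_seed(seed)
  w <- list()
  for (g in c("z", "r", "c")) {
    w[[paste0("U", g)]] <- init_weight(n_features, hidden)
    w[[paste0("W", g)]] <- init_weight(hidden, hidden)
    w[[paste0("b", g)]] <- numeric(hidden)
  }
  w$head_W <- init_weight(hidden, 2)
  w$head_b <- numeric(2)
  w
}

gru_forward <- function(w, X, cache = FALSE) {
  n <- dim(X)[1]; Tt <- dim(X)[2]
  H <- ncol(w$Uz)
  h <- matrix(0, n, H)
  steps <- if (cache) vector("list", Tt) else NULL
  bmat <- function(b) matrix(b, n, length(b), byrow = TRUE)
  sig <- function(x) 1 / (1 + exp(-x))
  for (t in seq_len(Tt)) {
    Xt <- matrix(X[, t, ], n)
    z <- sig(Xt %*% w$Uz + h %*% w$Wz + bmat(w$bz))
    r <- sig(Xt %*% w$Ur + h %*% w$Wr + bmat(w$br))
    cc <- tanh(Xt %*% w$Uc + (r * h) %*% w$Wc + bmat(w$bc))
    h_new <- (1 - z) * h + z * cc
    if (cache) steps[[t]] <- list(Xt = Xt, z = z, r = r, cc = cc, h_prev = h)
    h <- h_new
  }
  logits <- h %*% w$head_W + bmat(w$head_b)
  p <- softmax_rows(logits)
  list(prob = p, h = h, steps = steps)
}

gru_backward <- function(w, X, y, fw) {
  n <- dim(X)[1]; Tt <- dim(X)[2]
  grads <- lapply(w, function(m) array(0, dim = dim(m) %||% length(m)))
  Y <- cbind(1 - y, y)
  dZ <- (fw$prob - Y) / n
  grads$head_W <- crossprod(fw$h, dZ)
  grads$head_b <- colSums(dZ)
  dh <- dZ %*% t(w$head_W)
  for (t in Tt:1) {
    st <- fw$steps[[t]]
    z <- st$z; r <- st$r; cc <- st$cc; hp <- st$h_prev; Xt <- st$Xt
    dz <- dh * (cc - hp)
    dcc <- dh * z
    dhp <- dh * (1 - z)
    dcpre <- dcc * (1 - cc^2)
    grads$Uc <- grads$Uc + crossprod(Xt, dcpre)
    grads$Wc <- grads$Wc + crossprod(r * hp, dcpre)
    grads$bc <- grads$bc + colSums(dcpre)
    drh <- dcpre %*% t(w$Wc)
    dr <- drh * hp
    dhp <- dhp + drh * r
    dzpre <- dz * z * (1 - z)
    grads$Uz <- grads$Uz + crossprod(Xt, dzpre)
    grads$Wz <- grads$Wz + crossprod(hp, dzpre)
    grads$bz <- grads$bz + colSums(dzpre)
    dhp <- dhp + dzpre %*% t(w$Wz)
    drpre <- dr * r * (1 - r)
    grads$Ur <- grads$Ur + crossprod(Xt, drpre)
    grads$Wr <- grads$Wr + crossprod(hp, drpre)
    grads$br <- grads$br + colSums(drpre)
    dhp <- dhp + drpre %*% t(w$Wr)
    dh <- dhp
  }
  grads
}

#' Train and score the fixed gated-recurrent baseline
#'
#' @param episodes preprocessed, split `nasga_episodes`.
#' @param tconfig a [train_config()] (hidden size matched to the searched
#'   cells for a fair comparison).
#' @param replicates,seed bootstrap settings for the reported CI.
#' @return list: `auroc` (a `nasga_roc`), `sensitivity`, `specificity`,
#'   `record` (epochs run, best validation loss), `weights`.
#' @export
baseline_recurrent <- function(episodes, tconfig, replicates = 2000,
                               seed = 1) {
  train <- episode_split(episodes, "train")
  val <- episode_split(episodes, "validation")
  test <- episode_split(episodes, "test")
  if (!n_episodes(train) || !n_episodes(val) || !n_episodes(test))
    stop_config("episodes must carry train/validation/test splits")
  set.seed(as.integer(tconfig$seed))
  w <- gru_init(length(episodes$features), tconfig$hidden)
  opt <- adam_new(w, lr = tconfig$lr)
  n <- n_episodes(train)
  best_loss <- Inf; best_w <- w; stale <- 0L; ep <- 0L
  while (ep < tconfig$max_epochs) {
    ep <- ep + 1L
    ord <- sample.int(n)
    for (start in seq(1, n, by = tconfig$batch_size)) {
      idx <- ord[start:min(start + tconfig$batch_size - 1, n)]
      Xb <- train$x[idx, , , drop = FALSE]
      fw <- gru_forward(w, Xb, cache = TRUE)
      grads <- gru_backward(w, Xb, train$label[idx], fw)
      w <- adam_step(opt, w, grads)
    }
    vp <- gru_forward(w, val$x)$prob
    vloss <- cross_entropy(vp, val$label)
    if (vloss < best_loss - 1e-9) {
      best_loss <- vloss; best_w <- w; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= tconfig$patience) break
    }
  }
  scores <- gru_forward(best_w, test$x)$prob[, 2]
  counts <- confusion_counts(test$label, as.integer(scores >= 0.5))
  list(auroc = auroc_ci(scores, test$label, replicates, seed),
       sensitivity = sensitivity(counts), specificity = specificity(counts),
       record = list(epochs = ep, best_val_loss = best_loss),
       weights = best_w)
}
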