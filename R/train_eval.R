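#' Training configuration
#'
#' Adam with learning rate 1e-3, first-moment decay (beta1, the "momentum"
#' of the optimizer) 0.9, and L2 weight decay 1e-5; mean cross-entropy loss
#' on the softmax outputs. The reference protocol trains for 300 epochs;
#' smaller budgets are routinely sufficient on well-separated cohorts.
#'
#' @param lr learning rate (> 0).
#' @param beta1,beta2 Adam moment decay rates.
#' @param weight_decay L2 penalty coefficient added to the gradient.
#' @param epochs training epochs (>= 1, default 300).
#' @param batch_size minibatch size (default 64).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param checkpoint which parameters the trained model keeps:
#'   `"best_val"` (highest validation accuracy, default) or `"final"`
#'   (last epoch).
#' @param verbose print a progress line every `verbose` epochs (0 = silent).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-5, epochs = 300, batch_size = 64,
                         seed = 1, checkpoint = c("best_val", "final"),
                         verbose = 0) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed,
                 checkpoint = match.arg(checkpoint), verbose = verbose),
            class = "train_config")
}

# Adam state over a single flattened parameter vector (fast in R: one
# vectorized update per batch instead of one per weight array).
adam_init <- function(params) {
  lens <- vapply(params, length, integer(1))
  n <- sum(lens)
  list(m = numeric(n), v = numeric(n), t = 0L, lens = lens,
       dims = lapply(params, dim), names = names(params))
}

flatten_params <- function(params, state) {
  unlist(params[state$names], use.names = FALSE)
}

unflatten_params <- function(theta, state) {
  out <- vector("list", length(state$lens))
  names(out) <- state$names
  at <- 0L
  for (i in seq_along(state$lens)) {
    v <- theta[(at + 1L):(at + state$lens[i])]
    d <- state$dims[[i]]
    out[[i]] <- if (is.null(d)) v else array(v, dim = d)
    at <- at + state$lens[i]
  }
  out
}

adam_update <- function(theta, grads, state, cfg) {
  state$t <- state$t + 1L
  g <- unlist(grads[state$names], use.names = FALSE) + cfg$weight_decay * theta
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * g
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * g * g
  theta <- theta - cfg$lr * (state$m / (1 - cfg$beta1^state$t)) /
    (sqrt(state$v / (1 - cfg$beta2^state$t)) + 1e-8)
  list(theta = theta, state = state)
}

batch_accuracy <- function(probs, y) mean(max.col(probs) - 1L == y)

#' Train a LAFNet-family model on a windowed dataset
#'
#' Minimizes mean cross-entropy on the training split with Adam, recording
#' per-epoch train/validation loss and accuracy; the parameters achieving
#' the best validation accuracy are retained (best-val checkpointing).
#' Deterministic given the configuration seed.
#'
#' @param model a `lafnet_model` from [build_model()], or a [variant_spec()]
#'   (a model is then initialized from the config seed).
#' @param dataset a `windowed_dataset` with non-empty train and val splits,
#'   both containing both classes.
#' @param cfg a [train_config()].
#' @return The trained `lafnet_model` with element `history` (data frame
#'   `epoch, train_loss, train_acc, val_loss, val_acc`) and `best_epoch`.
#' @export
train_model <- function(model, dataset, cfg = train_config()) {
  stopifnot(inherits(dataset, "windowed_dataset"), inherits(cfg, "train_config"))
  tr <- dataset_split(dataset, "train")
  va <- dataset_split(dataset, "val")
  if (length(unique(tr$y)) < 2) stop("training split contains a single class")
  if (inherits(model, "variant_spec")) {
    model <- build_model(model, dim(tr$x)[3], seed = cfg$seed)
  }
  set.seed(cfg$seed)
  n <- dim(tr$x)[1]
  opt <- adam_init(model$params)
  theta <- flatten_params(model$params, opt)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  best <- list(val_acc = -Inf, params = model$params, epoch = 0L)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_acc <- 0; n_seen <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      fw <- model_forward(model, tr$x[idx, , , drop = FALSE], y = tr$y[idx],
                          training = TRUE, grads = TRUE)
      upd <- adam_update(theta, fw$grads, opt, cfg)
      theta <- upd$theta
      opt <- upd$state
      model$params <- unflatten_params(theta, opt)
      ep_loss <- ep_loss + fw$loss * length(idx)
      ep_acc <- ep_acc + batch_accuracy(fw$probs, tr$y[idx]) * length(idx)
      n_seen <- n_seen + length(idx)
    }
    vfw <- model_forward(model, va$x, y = va$y)
    val_acc <- batch_accuracy(vfw$probs, va$y)
    history[epoch, ] <- list(epoch, ep_loss / n_seen, ep_acc / n_seen,
                             vfw$loss, val_acc)
    if (val_acc > best$val_acc) {
      best <- list(val_acc = val_acc, params = model$params, epoch = epoch)
    }
    if (cfg$verbose > 0 && epoch %% cfg$verbose == 0) {
      message(sprintf("epoch %3d  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
                      epoch, ep_loss / n_seen, ep_acc / n_seen, vfw$loss, val_acc))
    }
  }
  if (identical(cfg$checkpoint, "best_val")) {
    model$params <- best$params
    model$best_epoch <- best$epoch
  } else {
    model$best_epoch <- cfg$epochs
  }
  model$history <- history
  model
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; accepts and returns percentages.
#'
#' @param precision,recall percentages (or both proportions).
#' @return F1 on the same scale.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Classification metrics from labels and predictions
#'
#' Accuracy, and precision/recall/F1 for the PD-positive class (label 1),
#' as percentages, plus the 2x2 confusion matrix in counts and as
#' percentages of the total.
#'
#' @param y true labels (0 = healthy, 1 = pd).
#' @param pred predicted labels.
#' @return A `classification_metrics` list: `accuracy`, `precision`,
#'   `recall`, `f1`, `confusion` (counts, actual x predicted),
#'   `confusion_pct`, `n`.
#' @export
classification_metrics <- function(y, pred) {
  stopifnot(length(y) == length(pred))
  y <- as.integer(y); pred <- as.integer(pred)
  tp <- sum(y == 1 & pred == 1); tn <- sum(y == 0 & pred == 0)
  fp <- sum(y == 0 & pred == 1); fn <- sum(y == 1 & pred == 0)
  n <- length(y)
  conf <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                 dimnames = list(actual = c("healthy", "pd"),
                                 predicted = c("healthy", "pd")))
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  structure(list(accuracy = 100 * (tp + tn) / n, precision = precision,
                 recall = recall,
                 f1 = if (is.na(precision) || is.na(recall)) NA_real_
                      else f1_score(precision, recall),
                 confusion = conf, confusion_pct = 100 * conf / n, n = n),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%% (n = %d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$n))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a trained model on one split of a dataset
#'
#' Argmax predictions on the requested split, summarized with
#' [classification_metrics()].
#'
#' @param model a trained `lafnet_model`.
#' @param dataset a `windowed_dataset`.
#' @param split `"test"` (default), `"val"` or `"train"`.
#' @return A `classification_metrics` object with extra element `split`.
#' @export
evaluate_model <- function(model, dataset, split = "test") {
  d <- dataset_split(dataset, split)
  probs <- model_forward(model, d$x)$probs
  m <- classification_metrics(d$y, max.col(probs) - 1L)
  m$split <- split
  m
}

subject_pd_fractions <- function(model, dataset, split) {
  d <- dataset_split(dataset, split)
  pred <- max.col(model_forward(model, d$x)$probs) - 1L
  subj <- unique(d$subject_id)
  data.frame(
    subject_id = subj,
    label = vapply(subj, function(s) d$y[d$subject_id == s][1], integer(1)),
    pd_fraction = vapply(subj, function(s) mean(pred[d$subject_id == s]),
                         numeric(1)))
}

#' Subject-level diagnosis from a subject's window predictions
#'
#' Aggregates window predictions to one diagnosis per held-out subject (the
#' clinically meaningful readout): a subject is called PD when the fraction
#' of its windows predicted PD exceeds a threshold. Because tremor is
#' intermittent, a PD subject's expected fraction is roughly the burst duty
#' rather than 1, so the operating point matters; by default it is
#' calibrated on the validation split (midpoint between the highest healthy
#' and lowest PD validation fraction), never on the evaluated split.
#'
#' @param model a trained `lafnet_model`.
#' @param dataset a `windowed_dataset`.
#' @param split evaluation split (default `"test"`).
#' @param threshold numeric in (0, 1), or `NULL` (default) to calibrate on
#'   the validation split; falls back to 0.5 when validation data cannot
#'   calibrate (missing split or class).
#' @return A `classification_metrics` object over subjects, with elements
#'   `per_subject` (data frame: subject_id, label, pd_fraction, pred) and
#'   `threshold`.
#' @export
evaluate_subjects <- function(model, dataset, split = "test", threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- 0.5
    val <- tryCatch(subject_pd_fractions(model, dataset, "val"),
                    error = function(e) NULL)
    if (!is.null(val) && length(unique(val$label)) == 2) {
      hi_healthy <- max(val$pd_fraction[val$label == 0])
      lo_pd <- min(val$pd_fraction[val$label == 1])
      if (lo_pd > hi_healthy) threshold <- (hi_healthy + lo_pd) / 2
    }
  }
  per <- subject_pd_fractions(model, dataset, split)
  per$pred <- as.integer(per$pd_fraction > threshold)
  m <- classification_metrics(per$label, per$pred)
  m$per_subject <- per
  m$threshold <- threshold
  m$split <- split
  m
}

#' Train and compare the five architecture variants
#'
#' Trains each variant on identical splits and seed and reports test-set
#' metrics in one table (columns: variant, F1, recall, precision, accuracy).
#'
#' @param dataset a `windowed_dataset`.
#' @param specs list of [variant_spec()]s (default [all_variants()]).
#' @param cfg a [train_config()].
#' @return Data frame, one row per variant.
#' @export
compare_variants <- function(dataset, specs = all_variants(),
                             cfg = train_config()) {
  stopifnot(length(specs) >= 2)
  rows <- lapply(specs, function(sp) {
    fit <- train_model(sp, dataset, cfg)
    m <- evaluate_model(fit, dataset, "test")
    data.frame(variant = sp$name, f1 = m$f1, recall = m$recall,
               precision = m$precision, accuracy = m$accuracy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare one architecture across two acquisition conditions
#'
#' Trains and evaluates the same variant independently on two cohorts'
#' datasets (e.g. a high-contrast mid-air cohort vs. a lower-contrast
#' surface-drawing analogue) and returns a two-row table.
#'
#' @param dataset_a,dataset_b `windowed_dataset`s with identical schema.
#' @param spec a [variant_spec()] (default LAFNet).
#' @param cfg a [train_config()].
#' @param names row labels (default `c("A", "B")`).
#' @return Data frame with columns condition, accuracy, precision, recall, f1.
#' @export
compare_tasks <- function(dataset_a, dataset_b, spec = variant_spec("LAFNet"),
                          cfg = train_config(), names = c("A", "B")) {
  one <- function(ds, nm) {
    fit <- train_model(spec, ds, cfg)
    m <- evaluate_model(fit, ds, "test")
    data.frame(condition = nm, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  }
  out <- rbind(one(dataset_a, names[1]), one(dataset_b, names[2]))
  rownames(out) <- NULL
  out
}
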