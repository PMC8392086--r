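# Adam with bias correction; state kept parallel to the flat parameter list
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a branch CNN
#'
#' Minibatch Adam on the binary cross-entropy loss with L2 penalties, early
#' stopping on the validation loss with best-weight restoration, and
#' multiplicative learning-rate reduction when the validation loss
#' plateaus (factor `spec$lr_factor`, floor `1e-6`, plateau patience half
#' the stopping patience).  Fully reproducible for a given `seed`.
#'
#' @param net an untrained (or warm) [build_network()] handle.
#' @param x_train,y_train training sequences (any form accepted by
#'   [predict.m6a_network()]) and binary labels.
#' @param x_val,y_val validation data for early stopping (disjoint from
#'   training).
#' @param seed integer seed covering shuffling and dropout.
#' @param patience epochs without validation improvement before stopping
#'   (default 50); `patience = 0` stops at the first non-improving epoch.
#' @param reduce_lr apply learning-rate reduction on plateau
#'   (default `TRUE`).
#' @param verbose print per-epoch losses.
#' @return The trained `"m6a_network"` with a `$history` element of class
#'   `"training_history"`: data.frame of per-epoch training/validation
#'   losses plus `stopped_epoch` and `best_epoch` attributes.
#' @export
train_network <- function(net, x_train, y_train, x_val, y_val,
                          seed = NULL, patience = 50, reduce_lr = TRUE,
                          verbose = FALSE) {
  stopifnot(inherits(net, "m6a_network"))
  if (length(y_train) == 0L || length(y_val) == 0L)
    stop("training and validation sets must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  spec <- net$spec
  tr_in  <- .model_inputs(net, x_train)
  val_in <- .model_inputs(net, x_val)
  n <- length(y_train)
  lr <- spec$learning_rate
  state <- .adam_init(net$params)
  best_val <- Inf; best_params <- net$params
  best_epoch <- 0L; wait <- 0L; lr_wait <- 0L
  lr_patience <- max(1L, floor(patience / 2))
  hist_tr <- numeric(0); hist_val <- numeric(0)

  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (b0 in seq(1L, n, by = spec$batch_size)) {
      idx <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
      bin <- lapply(tr_in, function(a) a[idx, , , drop = FALSE])
      yb <- y_train[idx]
      fwd <- .nn_forward(net, bin, training = TRUE, keep_cache = TRUE)
      batch_losses <- c(batch_losses, bce_loss(yb, fwd$prob))
      grads <- .nn_backward(net, bin, fwd, yb)
      upd <- .adam_step(net$params, grads, state, lr)
      net$params <- upd$params; state <- upd$state
    }
    val_loss <- bce_loss(y_val, .nn_forward(net, val_in)$prob)
    hist_tr <- c(hist_tr, mean(batch_losses))
    hist_val <- c(hist_val, val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %g",
                      epoch, mean(batch_losses), val_loss, lr))
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_params <- net$params
      best_epoch <- epoch; wait <- 0L; lr_wait <- 0L
    } else {
      wait <- wait + 1L; lr_wait <- lr_wait + 1L
      if (reduce_lr && lr_wait > lr_patience && lr > 1e-6) {
        lr <- max(lr * spec$lr_factor, 1e-6)
        lr_wait <- 0L
      }
      if (wait > patience) break
    }
  }
  net$params <- best_params
  net$history <- structure(
    data.frame(epoch = seq_along(hist_tr), train_loss = hist_tr,
               val_loss = hist_val),
    stopped_epoch = length(hist_tr), best_epoch = best_epoch,
    class = c("training_history", "data.frame"))
  net
}

.as_records <- function(data, labels = NULL) {
  if (is.data.frame(data)) {
    rec <- validate_records(data[, intersect(c("id", "seq", "label"),
                                             names(data)), drop = FALSE])
  } else {
    rec <- data.frame(id = paste0("seq", seq_along(data)),
                      seq = canonicalize_rna(data),
                      label = if (is.null(labels)) NA_integer_ else labels)
    rec <- validate_records(rec)
  }
  if (!is.null(labels)) rec$label <- labels
  rec
}

#' Fit a branch CNN m6A site classifier
#'
#' The main modelling interface.  Encodes the sequences with the three
#' representations (circular dinucleotide, one-hot, NCP), builds the
#' three-branch CNN and trains it with Adam, early stopping on a held-out
#' validation split, and L2 regularization.  Returns a fitted model with
#' the usual methods: [predict.m6a_cnn()], `print`, `summary`, `coef`,
#' `fitted`, `residuals`, `plot` (training curves) and `simulate`.
#'
#' @param data a record `data.frame` (columns `id`, `seq`, `label`) or a
#'   character vector of equal-length odd-length sequences.
#' @param labels binary labels when `data` is a character vector.
#' @param spec a [network_spec()].
#' @param branches active encodings, a subset of
#'   `c("circular", "onehot", "ncp")`.
#' @param arch `"branch"` (feature fusion, default) or `"input_concat"`
#'   (single-branch ablation baseline).
#' @param validation fraction of the data held out for early stopping
#'   (stratified), ignored when `val_data` is given.
#' @param val_data optional explicit validation record `data.frame`.
#' @param seed integer seed (initialization, split, shuffling, dropout).
#' @param patience early-stopping patience in epochs.
#' @param pair_table the [pair_code_table()] used by the circular encoding.
#' @param verbose print per-epoch losses.
#' @return Object of class `"m6a_cnn"`.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(n_pos = 80, n_neg = 80, length = 21, seed = 1)
#' fit <- m6a_cnn(sim$records, spec = network_spec(max_epochs = 15),
#'                seed = 1, patience = 5)
#' summary(fit)
#' }
#' @export
m6a_cnn <- function(data, labels = NULL, spec = network_spec(),
                    branches = c("circular", "onehot", "ncp"),
                    arch = c("branch", "input_concat"), validation = 0.1,
                    val_data = NULL, seed = 1, patience = 50,
                    pair_table = pair_code_table(), verbose = FALSE) {
  arch <- match.arg(arch)
  rec <- .as_records(data, labels)
  if (anyNA(rec$label)) stop("all training records need a 0/1 label")
  L <- nchar(rec$seq[1L])
  set.seed(seed)
  if (is.null(val_data)) {
    idx_val <- unlist(lapply(split(seq_len(nrow(rec)), rec$label),
      function(ix) sample(ix, max(1L, round(validation * length(ix))))))
    train_rec <- rec[-idx_val, , drop = FALSE]
    val_rec <- rec[idx_val, , drop = FALSE]
  } else {
    train_rec <- rec
    val_rec <- .as_records(val_data)
  }
  net <- build_network(spec, L, branches = branches, arch = arch,
                       seed = seed, pair_table = pair_table)
  net <- train_network(net, train_rec, train_rec$label, val_rec,
                       val_rec$label, seed = seed + 1L,
                       patience = patience, verbose = verbose)
  fitted_prob <- .nn_forward(net, .model_inputs(net, train_rec))$prob
  structure(list(network = net, spec = spec, seq_length = L,
                 branches = net$branches, arch = arch,
                 history = net$history, data = train_rec,
                 val_data = val_rec, fitted = fitted_prob,
                 threshold = 0.5, seed = seed, call = match.call()),
            class = "m6a_cnn")
}

#' Predict m6A site probabilities
#'
#' @param object a fitted [m6a_cnn()] model.
#' @param newdata record `data.frame`, character sequences, or encoded
#'   arrays; defaults to the training data.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 calls at the
#'   model threshold.
#' @param ... unused.
#' @return Numeric vector of probabilities or integer class calls.
#' @export
predict.m6a_cnn <- function(object, newdata = NULL,
                            type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  p <- predict(object$network, newdata)
  if (type == "class") as.integer(p >= object$threshold) else p
}

#' @export
print.m6a_cnn <- function(x, ...) {
  cat("Branch CNN m6A site classifier\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat("  architecture: ", x$arch, "; encodings: ",
      paste(x$branches, collapse = ", "), "; ", x$seq_length,
      "-nt windows\n", sep = "")
  h <- x$history
  cat(sprintf("  trained %d epochs (best %d), val loss %.4f\n",
              attr(h, "stopped_epoch"), attr(h, "best_epoch"),
              min(h$val_loss)))
  invisible(x)
}

#' @method summary m6a_cnn
#' @export
summary.m6a_cnn <- function(object, ...) {
  tr <- compute_metrics(object$data$label, object$fitted,
                        object$threshold)
  val <- compute_metrics(object$val_data$label,
                         predict(object, object$val_data))
  out <- structure(list(model = object, train_metrics = tr,
                        val_metrics = val),
                   class = "summary.m6a_cnn")
  out
}

#' @export
print.summary.m6a_cnn <- function(x, ...) {
  print(x$model)
  cat("\nTraining set "); print(x$train_metrics)
  cat("\nValidation set "); print(x$val_metrics)
  invisible(x)
}

#' @method coef m6a_cnn
#' @export
coef.m6a_cnn <- function(object, ...) object$network$params

#' @method fitted m6a_cnn
#' @export
fitted.m6a_cnn <- function(object, ...) object$fitted

#' @method residuals m6a_cnn
#' @export
residuals.m6a_cnn <- function(object, ...) object$data$label - object$fitted

#' @method plot m6a_cnn
#' @export
plot.m6a_cnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = attr(h, "best_epoch"), lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' @method simulate m6a_cnn
#' @export
simulate.m6a_cnn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' k-fold cross-validation of the branch CNN
#'
#' Implements the evaluation protocol: records are split into `k` mutually
#' exclusive folds; in each round one fold tests, the next fold validates
#' (early stopping) and the remaining folds train.  Per-round metrics are
#' averaged arithmetically (with standard deviations) across folds.
#' Per-fold seeds are derived as `seed + round` so folds are independent
#' but the whole run reproduces.
#'
#' @param data record `data.frame` with labels.
#' @param spec a [network_spec()].
#' @param k number of folds, default 10.
#' @param seed master seed.
#' @param branches,arch passed to [build_network()].
#' @param patience early-stopping patience per fold.
#' @param stratified stratify folds by label.
#' @param verbose print fold progress.
#' @return Object of class `"m6a_cv"`: `per_fold` (data.frame of metrics,
#'   one row per fold), `mean` and `sd` (named numeric), plus the fold
#'   plan.
#' @export
cross_validate <- function(data, spec = network_spec(), k = 10, seed = 1,
                           branches = c("circular", "onehot", "ncp"),
                           arch = c("branch", "input_concat"),
                           patience = 50, stratified = TRUE,
                           verbose = FALSE) {
  arch <- match.arg(arch)
  rec <- .as_records(data)
  if (anyNA(rec$label)) stop("cross-validation needs labeled records")
  plan <- make_folds(rec$label, k = k, seed = seed,
                     stratified = stratified)
  per_fold <- vector("list", k)
  for (r in seq_len(k)) {
    ix <- fold_indices(plan, r)
    net <- build_network(spec, nchar(rec$seq[1L]), branches = branches,
                         arch = arch, seed = seed + r)
    net <- train_network(net, rec[ix$train, ], rec$label[ix$train],
                         rec[ix$validation, ], rec$label[ix$validation],
                         seed = seed + r, patience = patience)
    p <- .nn_forward(net, .model_inputs(net, rec[ix$test, ]))$prob
    m <- compute_metrics(rec$label[ix$test], p)
    per_fold[[r]] <- cbind(fold = r, as.data.frame(m))
    if (verbose)
      message(sprintf("fold %2d: accuracy %.3f  auc %.3f",
                      r, m$accuracy, m$auc))
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- setdiff(names(per_fold), "fold")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = apply(per_fold[metric_cols], 2, stats::sd),
                 k = k, seed = seed, arch = arch, branches = branches,
                 plan = plan),
            class = "m6a_cv")
}

#' @export
print.m6a_cv <- function(x, digits = 4, ...) {
  cat(x$k, "-fold cross-validation (", x$arch, " architecture; ",
      paste(x$branches, collapse = ", "), ")\n", sep = "")
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, digits))
  invisible(x)
}

#' Ablation experiments over encodings and fusion strategy
#'
#' Runs the cross-validation protocol with a reduced or rearranged
#' architecture: the full three-branch model (`"three_branch"`), the
#' input-space concatenation baseline (`"input_concat"`), or any subset of
#' the encodings (e.g. `c("onehot", "ncp")`), each encoding keeping its
#' own branch and the concatenated width shrinking to
#' `24 * length(subset)`.
#'
#' @param data labeled record `data.frame`.
#' @param spec a [network_spec()].
#' @param mode `"three_branch"`, `"input_concat"`, or a character subset
#'   of `c("circular", "onehot", "ncp")`.
#' @param ... passed to [cross_validate()] (`k`, `seed`, `patience`, ...).
#' @return An `"m6a_cv"` object with a `mode` element.
#' @export
run_ablation <- function(data, spec = network_spec(),
                         mode = "three_branch", ...) {
  if (identical(mode, "three_branch")) {
    cv <- cross_validate(data, spec, ...)
  } else if (identical(mode, "input_concat")) {
    cv <- cross_validate(data, spec, arch = "input_concat", ...)
  } else if (is.character(mode) && length(mode) >= 1 &&
             all(mode %in% c("circular", "onehot", "ncp"))) {
    cv <- cross_validate(data, spec, branches = mode, ...)
  } else {
    stop("mode must be \"three_branch\", \"input_concat\" or a non-empty ",
         "subset of c(\"circular\", \"onehot\", \"ncp\")")
  }
  cv$mode <- mode
  cv
}

#' Save / load a fitted model as self-describing JSON
#'
#' The checkpoint stores every weight array at full precision together
#' with the network specification, architecture, branch set and pair-code
#' order, so a file round-trips to an identical predictor.
#'
#' @param model a fitted `"m6a_cnn"` or bare `"m6a_network"`.
#' @param path output JSON path.
#' @return `load_m6a_cnn()` returns the restored `"m6a_network"`.
#' @export
save_m6a_cnn <- function(model, path) {
  net <- if (inherits(model, "m6a_cnn")) model$network else model
  stopifnot(inherits(net, "m6a_network"))
  payload <- list(
    spec = unclass(net$spec), seq_length = net$seq_length,
    branches = net$branches, arch = net$arch,
    pair_order = net$pair_table$order,
    params = lapply(net$params, function(p)
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           values = as.numeric(p))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_m6a_cnn
#' @export
load_m6a_cnn <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec,
                  x$spec[setdiff(names(x$spec), "input_widths")])
  net <- build_network(spec, x$seq_length, branches = x$branches,
                       arch = x$arch, seed = 0,
                       pair_table = pair_code_table(x$pair_order))
  for (nm in names(net$params)) {
    p <- x$params[[nm]]
    net$params[[nm]] <- if (length(p$dim) > 1L) array(p$values, p$dim)
                        else as.numeric(p$values)
  }
  net
}
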