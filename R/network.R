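#' Hyperparameter specification of the branch network
#'
#' Describes one branch of the three-branch CNN and the shared training
#' settings.  Every branch applies the same stack: convolution
#' (`conv1_filters` filters of size `conv1_kernel`, stride 1), ReLU, group
#' normalization (`gn_groups` groups), a second convolution
#' (`conv2_filters` filters of size `conv2_kernel`), ReLU, flatten, dropout,
#' and a fully connected layer of `branch_units` features.  The branch
#' features are concatenated (72 hidden features for three branches with
#' the defaults) and fed to a single sigmoid output unit.  L2 penalties are
#' attached to all convolution and dense kernels (`l2_kernel`) and biases
#' (`l2_bias`); group-norm scale/shift parameters are not penalized.
#'
#' @param conv1_filters,conv1_kernel first convolution: filters and size
#'   (defaults 32 and 5).
#' @param conv2_filters,conv2_kernel second convolution: filters and size
#'   (defaults 16 and 3).
#' @param gn_groups group-normalization groups (default 4); must divide
#'   `conv1_filters`.
#' @param dropout dropout rate in `[0, 1)` applied to the flattened branch
#'   features (default 0.5).
#' @param branch_units fully connected features per branch (default 24).
#' @param l2_kernel,l2_bias L2 regularization strengths (defaults `1e-3`,
#'   `1e-4`).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param lr_factor multiplicative learning-rate reduction factor applied
#'   when the validation loss plateaus (default 0.01).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs training epoch cap (default 1000; early stopping
#'   normally ends training much earlier).
#' @param padding convolution padding, `"same"` (default) or `"valid"`.
#' @return Object of class `"network_spec"`.
#' @examples
#' network_spec()
#' @export
network_spec <- function(conv1_filters = 32, conv1_kernel = 5,
                         conv2_filters = 16, conv2_kernel = 3,
                         gn_groups = 4, dropout = 0.5, branch_units = 24,
                         l2_kernel = 1e-3, l2_bias = 1e-4,
                         learning_rate = 1e-3, lr_factor = 0.01,
                         batch_size = 32, max_epochs = 1000,
                         padding = c("same", "valid")) {
  padding <- match.arg(padding)
  spec <- list(conv1_filters = conv1_filters, conv1_kernel = conv1_kernel,
               conv2_filters = conv2_filters, conv2_kernel = conv2_kernel,
               gn_groups = gn_groups, dropout = dropout,
               branch_units = branch_units, l2_kernel = l2_kernel,
               l2_bias = l2_bias, learning_rate = learning_rate,
               lr_factor = lr_factor, batch_size = batch_size,
               max_epochs = max_epochs, padding = padding,
               input_widths = c(circular = 16L, onehot = 4L, ncp = 3L))
  num <- c("conv1_filters", "conv1_kernel", "conv2_filters", "conv2_kernel",
           "gn_groups", "branch_units", "learning_rate", "batch_size",
           "max_epochs")
  if (any(vapply(spec[num], function(v) !is.numeric(v) || v <= 0,
                 logical(1L))))
    stop("network_spec sizes and rates must be strictly positive")
  if (spec$dropout < 0 || spec$dropout >= 1)
    stop("dropout must be in [0, 1)")
  if (spec$conv1_filters %% spec$gn_groups != 0)
    stop("gn_groups (", gn_groups, ") must divide conv1_filters (",
         conv1_filters, ")")
  structure(spec, class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Branch CNN specification\n")
  cat(sprintf("  per branch: conv(%d x %d) -> ReLU -> groupnorm(%d) -> conv(%d x %d) -> ReLU\n",
              x$conv1_filters, x$conv1_kernel, x$gn_groups,
              x$conv2_filters, x$conv2_kernel))
  cat(sprintf("              -> flatten -> dropout(%.2f) -> dense(%d)\n",
              x$dropout, x$branch_units))
  cat(sprintf("  head: concat(3 x %d = %d) -> dense(1, sigmoid)\n",
              x$branch_units, 3 * x$branch_units))
  cat(sprintf("  L2 kernel %g / bias %g; Adam lr %g (plateau factor %g); batch %d; <= %d epochs; %s padding\n",
              x$l2_kernel, x$l2_bias, x$learning_rate, x$lr_factor,
              x$batch_size, x$max_epochs, x$padding))
  invisible(x)
}

## ---- low-level layers (vectorized base R; batch axis first) ----

# im2col view: (N, Lp, C) padded array -> (N*Lout, k*C) matrix whose
# column block j holds the input window at kernel offset j
.im2col <- function(Xp, k, Lout, N, C) {
  Xc <- matrix(0, N * Lout, k * C)
  for (j in seq_len(k)) {
    Xs <- Xp[, j:(j + Lout - 1L), , drop = FALSE]
    dim(Xs) <- c(N * Lout, C)
    Xc[, (j - 1L) * C + seq_len(C)] <- Xs
  }
  Xc
}

# kernel array (k, Cin, F) as the (k*Cin, F) matrix matching .im2col order
.kernel_mat <- function(W) {
  d <- dim(W)
  Wm <- aperm(W, c(2L, 1L, 3L))
  dim(Wm) <- c(d[1L] * d[2L], d[3L])
  Wm
}

# X: (N, L, Cin); W: (k, Cin, F); same/valid padding, stride 1
.conv1d_forward <- function(X, W, b, padding) {
  d <- dim(X); N <- d[1L]; L <- d[2L]; Cin <- d[3L]
  k <- dim(W)[1L]; nf <- dim(W)[3L]
  if (padding == "same") { pad <- (k - 1L) %/% 2L; Lout <- L }
  else { pad <- 0L; Lout <- L - k + 1L }
  if (Lout < 1L) stop("sequence shorter than the convolution kernel")
  if (pad > 0L) {
    Xp <- array(0, c(N, L + 2L * pad, Cin))
    Xp[, pad + seq_len(L), ] <- X
  } else Xp <- X
  Xc <- .im2col(Xp, k, Lout, N, Cin)
  Y <- Xc %*% .kernel_mat(W) + matrix(b, N * Lout, nf, byrow = TRUE)
  dim(Y) <- c(N, Lout, nf)
  list(Y = Y, Xc = Xc, pad = pad, Lout = Lout, L = L)
}

.conv1d_backward <- function(dY, cache, W) {
  N <- dim(dY)[1L]; Lout <- cache$Lout; k <- dim(W)[1L]
  Cin <- dim(W)[2L]; nf <- dim(W)[3L]; L <- cache$L
  dYm <- dY; dim(dYm) <- c(N * Lout, nf)
  dWm <- crossprod(cache$Xc, dYm)        # (k*Cin, F), .im2col column order
  dim(dWm) <- c(Cin, k, nf)
  dW <- aperm(dWm, c(2L, 1L, 3L))
  # input gradient of a stride-1 convolution is itself a convolution of dY
  # with the position-flipped, channel-transposed kernel:
  # dX[s] = sum_j dY[s + pad - j + 1] W_j'  (full padding k - 1 - pad)
  padb <- k - 1L - cache$pad
  if (padb > 0L) {
    dYp <- array(0, c(N, Lout + 2L * padb, nf))
    dYp[, padb + seq_len(Lout), ] <- dY
  } else dYp <- dY
  Wrev <- aperm(W[k:1L, , , drop = FALSE], c(1L, 3L, 2L))  # (k, F, Cin)
  dXm <- .im2col(dYp, k, L, N, nf) %*% .kernel_mat(Wrev)
  dim(dXm) <- c(N, L, Cin)
  list(dX = dXm, dW = dW, db = colSums(dYm))
}

# 0/1 matrix summing (N, M*G) column blocks of width M down to G groups
.group_mask <- function(M, G) {
  mask <- matrix(0, M * G, G)
  mask[cbind(seq_len(M * G), rep(seq_len(G), each = M))] <- 1
  mask
}

# group normalization over (positions x in-group channels) per sample;
# works on the (N, M*G) matrix view, whose memory layout coincides with
# the (N, L, C) array (channels are contiguous within a group)
.gn_forward <- function(X, gamma, beta, groups, eps = 1e-5) {
  d <- dim(X); N <- d[1L]; L <- d[2L]; C <- d[3L]
  M <- L * (C %/% groups)
  B <- X; dim(B) <- c(N, M * groups)
  mask <- .group_mask(M, groups)
  mu  <- (B %*% mask) / M
  v   <- ((B * B) %*% mask) / M - mu * mu
  sdv <- sqrt(v + eps)
  gcol <- rep(seq_len(groups), each = M)
  xhat <- (B - mu[, gcol, drop = FALSE]) / sdv[, gcol, drop = FALSE]
  xm <- xhat; dim(xm) <- c(N * L, C)
  Y <- xm * rep(gamma, each = N * L) + rep(beta, each = N * L)
  dim(Y) <- c(N, L, C)
  list(Y = Y, xhat = xhat, sd = sdv, dims = d, M = M, groups = groups,
       mask = mask, gcol = gcol)
}

.gn_backward <- function(dY, cache, gamma) {
  d <- cache$dims; N <- d[1L]; L <- d[2L]; C <- d[3L]
  M <- cache$M; gcol <- cache$gcol
  dYm <- dY; dim(dYm) <- c(N * L, C)
  xm <- cache$xhat; dim(xm) <- c(N * L, C)
  dgamma <- colSums(dYm * xm)
  dbeta  <- colSums(dYm)
  dxhat <- dYm * rep(gamma, each = N * L)
  dim(dxhat) <- c(N, M * cache$groups)
  xhat <- cache$xhat
  s1 <- dxhat %*% cache$mask
  s2 <- (dxhat * xhat) %*% cache$mask
  dB <- (dxhat - (s1[, gcol, drop = FALSE] +
                    xhat * s2[, gcol, drop = FALSE]) / M) /
    cache$sd[, gcol, drop = FALSE]
  dim(dB) <- d
  list(dX = dB, dgamma = dgamma, dbeta = dbeta)
}

.glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# flattened width of one branch after the two convolutions
.branch_flat_dim <- function(spec, L_in) {
  L_in <- unname(L_in)
  L1 <- if (spec$padding == "same") L_in else L_in - spec$conv1_kernel + 1L
  L2 <- if (spec$padding == "same") L1 else L1 - spec$conv2_kernel + 1L
  c(flat = L2 * spec$conv2_filters, L1 = L1, L2 = L2)
}

.init_branch_params <- function(spec, L_in, C_in, prefix) {
  L_in <- unname(L_in); C_in <- unname(C_in)
  k1 <- spec$conv1_kernel; f1 <- spec$conv1_filters
  k2 <- spec$conv2_kernel; f2 <- spec$conv2_filters
  flat <- .branch_flat_dim(spec, L_in)[["flat"]]
  u <- spec$branch_units
  p <- list(
    W1 = .glorot(c(k1, C_in, f1), k1 * C_in, k1 * f1), b1 = numeric(f1),
    gamma = rep(1, f1), beta = numeric(f1),
    W2 = .glorot(c(k2, f1, f2), k2 * f1, k2 * f2), b2 = numeric(f2),
    Wd = .glorot(c(flat, u), flat, u), bd = numeric(u))
  stats::setNames(p, paste(prefix, names(p), sep = "."))
}

# assemble the per-branch input arrays for a batch of encodings
.branch_inputs <- function(enc, branches, arch, L) {
  if (arch == "input_concat") {
    # align circular rows to per-position width: pair r covers positions
    # 2r-1 and 2r of the ring; repeating each row twice (last row once,
    # via truncation to L) aligns all encodings per position
    circ <- enc$circular[, ceiling(seq_len(L) / 2), , drop = FALSE]
    parts <- list(circular = circ, onehot = enc$onehot, ncp = enc$ncp)
    parts <- parts[branches]
    widths <- vapply(parts, function(a) dim(a)[3L], integer(1L))
    X <- array(0, c(dim(parts[[1L]])[1L], L, sum(widths)))
    off <- 0L
    for (a in parts) {
      X[, , off + seq_len(dim(a)[3L])] <- a
      off <- off + dim(a)[3L]
    }
    list(concat = X)
  } else {
    enc[branches]
  }
}

#' Build a branch CNN model handle
#'
#' Initializes an untrained network for sequences of a fixed odd length.
#' With `arch = "branch"` (the default three-branch fusion architecture)
#' each active encoding feeds its own branch and the learned branch
#' features are concatenated; with `arch = "input_concat"` (the ablation
#' baseline) the raw encodings are concatenated per position — circular
#' rows repeated to sequence length — and fed through a single branch of
#' the same layer stack.
#'
#' @param spec a [network_spec()].
#' @param seq_length odd sequence length the model accepts.
#' @param branches character subset of
#'   `c("circular", "onehot", "ncp")` naming the active encodings.
#' @param arch `"branch"` (feature-space fusion) or `"input_concat"`.
#' @param seed optional integer seed for weight initialization
#'   (uniform Glorot).
#' @param pair_table the [pair_code_table()] used for circular encoding.
#' @return Object of class `"m6a_network"` with queryable `$shapes` and
#'   flat parameter list `$params`.
#' @export
build_network <- function(spec = network_spec(), seq_length,
                          branches = c("circular", "onehot", "ncp"),
                          arch = c("branch", "input_concat"), seed = NULL,
                          pair_table = pair_code_table()) {
  stopifnot(inherits(spec, "network_spec"))
  arch <- match.arg(arch)
  if (seq_length %% 2L == 0L)
    stop("seq_length must be odd (windows are centered on the candidate A)")
  if (length(branches) == 0L ||
      !all(branches %in% c("circular", "onehot", "ncp")))
    stop("branches must be a non-empty subset of ",
         "c(\"circular\", \"onehot\", \"ncp\")")
  branches <- intersect(c("circular", "onehot", "ncp"), branches)
  if (!is.null(seed)) set.seed(seed)
  L  <- as.integer(seq_length)
  Lc <- (L + 1L) %/% 2L
  widths <- spec$input_widths
  if (arch == "input_concat") {
    geom <- list(concat = c(L = L, C = sum(widths[branches])))
  } else {
    lens <- c(circular = Lc, onehot = L, ncp = L)
    geom <- lapply(branches, function(b) c(L = lens[[b]], C = widths[[b]]))
    names(geom) <- branches
  }
  params <- list()
  for (b in names(geom))
    params <- c(params, .init_branch_params(spec, geom[[b]]["L"],
                                            geom[[b]]["C"], b))
  concat_width <- spec$branch_units * length(geom)
  params[["head.Wo"]] <- .glorot(c(concat_width, 1L), concat_width, 1L)
  params[["head.bo"]] <- 0
  shapes <- list(
    inputs = lapply(geom, function(g) unname(g)),
    branch_flat = vapply(geom, function(g)
      .branch_flat_dim(spec, g[["L"]])[["flat"]], numeric(1L)),
    concat_width = concat_width)
  structure(list(spec = spec, seq_length = L, branches = branches,
                 arch = arch, params = params, pair_table = pair_table,
                 shapes = shapes),
            class = "m6a_network")
}

#' @export
print.m6a_network <- function(x, ...) {
  cat("Branch CNN (", x$arch, " architecture) for ", x$seq_length,
      "-nt sequences\n", sep = "")
  cat("  encodings: ", paste(x$branches, collapse = ", "), "\n", sep = "")
  cat("  concatenated hidden width: ", x$shapes$concat_width, "\n", sep = "")
  cat("  parameters: ", sum(vapply(x$params, length, numeric(1L))),
      "\n", sep = "")
  invisible(x)
}

# forward pass over pre-built branch input arrays
# returns probabilities and, if keep_cache, everything backprop needs
.nn_forward <- function(net, inputs, training = FALSE, keep_cache = FALSE) {
  spec <- net$spec; P <- net$params
  zs <- vector("list", length(inputs)); caches <- zs
  for (i in seq_along(inputs)) {
    b <- names(inputs)[i]; X <- inputs[[i]]
    g <- function(nm) P[[paste(b, nm, sep = ".")]]
    c1 <- .conv1d_forward(X, g("W1"), g("b1"), spec$padding)
    a1 <- pmax(c1$Y, 0)
    gn <- .gn_forward(a1, g("gamma"), g("beta"), spec$gn_groups)
    c2 <- .conv1d_forward(gn$Y, g("W2"), g("b2"), spec$padding)
    a2 <- pmax(c2$Y, 0)
    N <- dim(a2)[1L]
    flat <- a2; dim(flat) <- c(N, prod(dim(a2)[2:3]))
    if (training && spec$dropout > 0) {
      mask <- matrix((stats::runif(length(flat)) >= spec$dropout) /
                       (1 - spec$dropout), nrow = N)
      dropped <- flat * mask
    } else { mask <- NULL; dropped <- flat }
    z <- dropped %*% g("Wd") + matrix(g("bd"), N, spec$branch_units,
                                      byrow = TRUE)
    zr <- pmax(z, 0)
    zs[[i]] <- zr
    if (keep_cache)
      caches[[i]] <- list(c1 = c1, a1 = a1, gn = gn, c2 = c2, a2 = a2,
                          flat = flat, mask = mask, dropped = dropped,
                          z = z, zr = zr)
  }
  Z <- do.call(cbind, zs)
  logit <- drop(Z %*% P[["head.Wo"]]) + P[["head.bo"]]
  prob <- 1 / (1 + exp(-logit))
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, Z = Z, caches = stats::setNames(caches, names(inputs)))
}

# gradient of (mean BCE + L2) w.r.t. every parameter
.nn_backward <- function(net, inputs, fwd, labels) {
  spec <- net$spec; P <- net$params
  N <- length(labels)
  grads <- vector("list", length(P)); names(grads) <- names(P)
  dlogit <- matrix((fwd$prob - labels) / N, ncol = 1L)
  grads[["head.Wo"]] <- crossprod(fwd$Z, dlogit) +
    2 * spec$l2_kernel * P[["head.Wo"]]
  grads[["head.bo"]] <- sum(dlogit) + 2 * spec$l2_bias * P[["head.bo"]]
  dZ <- tcrossprod(dlogit, P[["head.Wo"]])
  u <- spec$branch_units
  for (i in seq_along(inputs)) {
    b <- names(inputs)[i]; cc <- fwd$caches[[i]]
    g <- function(nm) P[[paste(b, nm, sep = ".")]]
    dzr <- dZ[, (i - 1L) * u + seq_len(u), drop = FALSE]
    dz <- dzr * (cc$z > 0)
    grads[[paste0(b, ".Wd")]] <- crossprod(cc$dropped, dz) +
      2 * spec$l2_kernel * g("Wd")
    grads[[paste0(b, ".bd")]] <- colSums(dz) + 2 * spec$l2_bias * g("bd")
    dflat <- tcrossprod(dz, g("Wd"))
    if (!is.null(cc$mask)) dflat <- dflat * cc$mask
    da2 <- dflat; dim(da2) <- dim(cc$a2)
    dc2 <- da2 * (cc$c2$Y > 0)
    bw2 <- .conv1d_backward(dc2, cc$c2, g("W2"))
    grads[[paste0(b, ".W2")]] <- bw2$dW + 2 * spec$l2_kernel * g("W2")
    grads[[paste0(b, ".b2")]] <- bw2$db + 2 * spec$l2_bias * g("b2")
    gnb <- .gn_backward(bw2$dX, cc$gn, g("gamma"))
    grads[[paste0(b, ".gamma")]] <- gnb$dgamma
    grads[[paste0(b, ".beta")]]  <- gnb$dbeta
    dc1 <- gnb$dX * (cc$c1$Y > 0)
    bw1 <- .conv1d_backward(dc1, cc$c1, g("W1"))
    grads[[paste0(b, ".W1")]] <- bw1$dW + 2 * spec$l2_kernel * g("W1")
    grads[[paste0(b, ".b1")]] <- bw1$db + 2 * spec$l2_bias * g("b1")
  }
  grads
}

# L2 penalty term of the loss (kernels and biases; not gamma/beta)
.l2_penalty <- function(net) {
  P <- net$params; spec <- net$spec
  nm <- names(P)
  kern <- grepl("\\.(W1|W2|Wd|Wo)$", nm)
  bias <- grepl("\\.(b1|b2|bd|bo)$", nm)
  spec$l2_kernel * sum(vapply(P[kern], function(w) sum(w * w), numeric(1L))) +
    spec$l2_bias  * sum(vapply(P[bias], function(w) sum(w * w), numeric(1L)))
}

# encode raw sequences (or accept pre-encoded arrays) for a network
.model_inputs <- function(net, x) {
  enc <- if (is.list(x) && all(c("circular", "onehot", "ncp") %in% names(x)))
    x
  else {
    seqs <- if (is.data.frame(x)) x$seq else x
    encode_dataset(seqs, net$pair_table)
  }
  inputs <- .branch_inputs(enc, net$branches, net$arch, net$seq_length)
  want <- net$shapes$inputs
  for (b in names(inputs)) {
    got <- dim(inputs[[b]])[2:3]
    if (!identical(as.integer(got), as.integer(want[[b]])))
      stop(sprintf("branch '%s': input shape %s does not match model shape %s",
                   b, paste(got, collapse = "x"),
                   paste(want[[b]], collapse = "x")))
  }
  inputs
}

#' Predict m6A probabilities from a network handle
#'
#' Deterministic inference pass (dropout inactive).  Accepts raw sequences,
#' a record `data.frame`, or pre-encoded arrays from [encode_dataset()].
#'
#' @param object an `"m6a_network"` handle.
#' @param x sequences / records / encoded arrays.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.m6a_network <- function(object, x, ...) {
  inputs <- .model_inputs(object, x)
  .nn_forward(object, inputs)$prob
}
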