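# shared fixtures: all test data is generated in code

rna_bases <- c("A", "C", "G", "U")

random_rna <- function(L, centered = FALSE) {
  s <- sample(rna_bases, L, replace = TRUE)
  if (centered) s[(L + 1) %/% 2] <- "A"
  paste(s, collapse = "")
}

# a deliberately small network so unit tests train in seconds
tiny_spec <- function(max_epochs = 8, ...) {
  network_spec(conv1_filters = 8, conv1_kernel = 3, conv2_filters = 4,
               conv2_kernel = 3, gn_groups = 2, branch_units = 6,
               max_epochs = max_epochs, ...)
}

# quick labeled dataset with a planted motif
quick_sim <- function(n = 60, L = 21, noise = 0, seed = 11) {
  simulate_dataset(n_pos = n / 2, n_neg = n / 2, length = L,
                   noise = noise, seed = seed)
}

# independent brute-force metric oracle (never calls compute_metrics)
oracle_metrics <- function(labels, prob, threshold = 0.5) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(labels)) {
    call <- if (prob[i] >= threshold) 1 else 0
    if (call == 1 && labels[i] == 1) tp <- tp + 1
    if (call == 0 && labels[i] == 0) tn <- tn + 1
    if (call == 1 && labels[i] == 0) fp <- fp + 1
    if (call == 0 && labels[i] == 1) fn <- fn + 1
  }
  pos <- which(labels == 1); neg <- which(labels == 0)
  auc <- NaN
  if (length(pos) > 0 && length(neg) > 0) {
    wins <- 0
    for (i in pos) for (j in neg) {
      if (prob[i] > prob[j]) wins <- wins + 1
      else if (prob[i] == prob[j]) wins <- wins + 0.5
    }
    auc <- wins / (length(pos) * length(neg))
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
       f1 = tp / (tp + (fp + fn) / 2), auc = auc)
}
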