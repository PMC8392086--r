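#' Default planted motif: the canonical m6A consensus
#'
#' A 5-position base-probability table spelling the canonical GGACU
#' consensus (the most common DRACH instance), centered on the methylated
#' adenosine.  Rows are motif positions, columns base probabilities over
#' A, C, G, U.  Degradation of the signal is controlled separately by the
#' `noise` parameter of [simulate_dataset()], which replaces each motif
#' base by a background draw with the given probability.
#'
#' @return 5 x 4 probability matrix.
#' @export
default_motif <- function() {
  m <- rbind(G = c(0, 0, 1, 0), G2 = c(0, 0, 1, 0), A = c(1, 0, 0, 0),
             C = c(0, 1, 0, 0), U = c(0, 0, 0, 1))
  dimnames(m) <- list(c("G", "G", "A", "C", "U"), .base_order)
  m
}

#' Simulate a centered-A labeled sequence dataset with a planted motif
#'
#' Emulates the statistical shape of benchmark m6A datasets: fixed-length
#' windows centered on a candidate adenosine, balanced positive/negative
#' labels.  Positives are background sequences with a degenerate consensus
#' motif implanted around the central A; negatives are motif-free
#' background.  Every sequence (both classes) has `A` forced at the
#' central position, so the only class signal is the motif context — as in
#' real centered benchmark windows.
#'
#' @param n_pos,n_neg numbers of positive and negative sequences.
#' @param length odd sequence length in nt (default 41).
#' @param motif per-position base-probability matrix (rows = motif
#'   positions, columns = A, C, G, U), default [default_motif()].
#' @param motif_offset offset of the motif's central row from the sequence
#'   center (default 0; the motif must fit inside the sequence).
#' @param background base composition of the background, default uniform.
#' @param noise per-position probability that an implanted motif base is
#'   replaced by a background draw (0 = exact consensus, 1 = motif fully
#'   destroyed).
#' @param seed optional integer seed.
#' @return List of class `"sim_dataset"`: `records` (record `data.frame`),
#'   `motif_window` (1-based first/last motif position in the sequence),
#'   `motif`, and the generating parameters.
#' @examples
#' sim <- simulate_dataset(5, 5, length = 41, seed = 7)
#' table(sim$records$label)
#' @export
simulate_dataset <- function(n_pos, n_neg, length = 41,
                             motif = default_motif(), motif_offset = 0,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, U = 0.25),
                             noise = 0.1, seed = NULL) {
  stopifnot(n_pos >= 0, n_neg >= 0, noise >= 0, noise <= 1)
  if (length %% 2 != 1) stop("sequence length must be odd")
  if (abs(sum(background) - 1) > 1e-8)
    stop("background probabilities must sum to 1")
  if (any(abs(rowSums(motif) - 1) > 1e-8))
    stop("each motif row must be a probability distribution")
  w <- nrow(motif)
  centre <- (length + 1L) %/% 2L
  m_centre <- (w + 1L) %/% 2L
  start <- centre + motif_offset - (m_centre - 1L)
  end <- start + w - 1L
  if (start < 1L || end > length)
    stop("motif window [", start, ", ", end,
         "] exceeds the sequence bounds")
  if (!is.null(seed)) set.seed(seed)
  n <- n_pos + n_neg

  draw_bg <- function(k) sample(.base_order, k, replace = TRUE,
                                prob = background)
  chm <- matrix(draw_bg(n * length), nrow = n)
  if (n_pos > 0L) {
    for (j in seq_len(w)) {
      col <- start + j - 1L
      implanted <- sample(.base_order, n_pos, replace = TRUE,
                          prob = motif[j, ])
      noisy <- stats::runif(n_pos) < noise
      implanted[noisy] <- draw_bg(sum(noisy))
      chm[seq_len(n_pos), col] <- implanted
    }
  }
  chm[, centre] <- "A"
  seqs <- apply(chm, 1L, paste, collapse = "")
  records <- data.frame(
    id = c(sprintf("pos%d", seq_len(n_pos)),
           sprintf("neg%d", seq_len(n_neg)))[seq_len(n)],
    seq = seqs,
    label = rep(c(1L, 0L), c(n_pos, n_neg)))
  structure(list(records = records,
                 motif_window = c(start = start, end = end),
                 motif = motif, background = background, noise = noise,
                 length = length, seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic m6A dataset: ", sum(x$records$label == 1L), " positives / ",
      sum(x$records$label == 0L), " negatives, ", x$length, " nt\n",
      sep = "")
  cat("  motif window positions ", x$motif_window["start"], "-",
      x$motif_window["end"], ", noise ", x$noise, "\n", sep = "")
  invisible(x)
}

#' Simulate transcripts and an m6A site table
#'
#' Generates random transcripts with random site positions, a configurable
#' fraction of which is placed in tight clusters (consecutive gaps below
#' the merge radius) so the site-merging and negative-window logic can be
#' exercised without real miCLIP data.
#'
#' @param n_transcripts number of transcripts.
#' @param length_range integer range of transcript lengths.
#' @param sites_per_transcript sites drawn per transcript.
#' @param cluster_fraction fraction of sites emitted as members of tight
#'   clusters (gap `cluster_gap` nt between cluster members).
#' @param cluster_gap within-cluster gap in nt, default 10.
#' @param seed optional integer seed.
#' @return List with `sites` (`data.frame` of `transcript_id`,
#'   `position`, 1-based), `transcript_lengths` (named integer) and
#'   `transcripts` (named character sequences).
#' @export
simulate_site_table <- function(n_transcripts = 5,
                                length_range = c(2000, 5000),
                                sites_per_transcript = 10,
                                cluster_fraction = 0.5, cluster_gap = 10,
                                seed = NULL) {
  stopifnot(n_transcripts > 0, sites_per_transcript > 0,
            cluster_fraction >= 0, cluster_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  txs <- sprintf("tx%d", seq_len(n_transcripts))
  lens <- stats::setNames(
    sample(length_range[1L]:length_range[2L], n_transcripts,
           replace = TRUE), txs)
  rows <- list()
  for (tx in txs) {
    Lt <- lens[[tx]]
    n_clustered <- round(cluster_fraction * sites_per_transcript)
    n_lone <- sites_per_transcript - n_clustered
    # lone sites on a coarse grid > 50 nt apart, clusters appended nearby
    grid <- seq(100L, Lt - 100L, by = 200L)
    lone <- sort(sample(grid, min(n_lone, length(grid))))
    pos <- lone
    while (length(pos) < sites_per_transcript) {
      anchor <- sample(seq(100L, Lt - 200L, by = 1L), 1L)
      run_len <- min(sites_per_transcript - length(pos), 3L)
      pos <- c(pos, anchor + cluster_gap * (0:run_len)[seq_len(run_len)])
    }
    rows[[tx]] <- data.frame(transcript_id = tx,
                             position = sort(unique(pmin(pos, Lt))))
  }
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  transcripts <- vapply(lens, function(Lt)
    paste(sample(.base_order, Lt, replace = TRUE), collapse = ""),
    character(1L))
  list(sites = sites, transcript_lengths = lens,
       transcripts = transcripts)
}
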