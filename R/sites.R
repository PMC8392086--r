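#' Merge clustered m6A sites
#'
#' m6A sites agglomerate; to avoid redundant windows, sites on the same
#' transcript are merged transitively: a maximal run of sites in which
#' consecutive sites are at most `radius` nt apart collapses to its central
#' member (the median-position site; for an even-sized run the lower of the
#' two middle sites).  Single-linkage runs make the result independent of
#' input order, and the output is always a subset of the input rows.
#'
#' Positions are 1-based on the transcript.
#'
#' @param sites `data.frame` with columns `transcript_id`, `position`.
#' @param radius maximal gap (nt) between consecutive sites of a run,
#'   default 50.
#' @return The merged site table (same columns, subset of rows), sorted by
#'   transcript and position.
#' @examples
#' s <- data.frame(transcript_id = "tx1", position = c(100, 120, 400))
#' merge_sites(s)$position  # 100 400
#' @export
merge_sites <- function(sites, radius = 50) {
  stopifnot(all(c("transcript_id", "position") %in% names(sites)))
  if (nrow(sites) == 0L) return(sites)
  sites <- sites[order(sites$transcript_id, sites$position), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(sites)), sites$transcript_id),
    function(idx) {
      pos <- sites$position[idx]
      run_id <- cumsum(c(1, diff(pos) > radius))
      vapply(split(seq_along(pos), run_id), function(run) {
        idx[run[floor((length(run) + 1) / 2)]]  # median member, lower tie
      }, integer(1L))
    }), use.names = FALSE)
  out <- sites[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build positive windows around m6A sites
#'
#' For each (merged) site, draws a fixed-size window that contains the site
#' at a uniformly random offset, subject to the window lying fully inside
#' the transcript, and records the site's offset within the window.  Sites
#' on transcripts shorter than the window are skipped with a warning.
#'
#' Windows are 1-based closed intervals `[start, end]` on the transcript;
#' `site_offset` is the 1-based position of the site within the window.
#'
#' @param sites merged site table (see [merge_sites()]).
#' @param transcript_lengths named integer vector, transcript id to length.
#' @param window odd window size in nt, default 101.
#' @param seed optional integer seed making the offsets reproducible.
#' @return `data.frame` with columns `transcript_id`, `start`, `end`,
#'   `site_pos`, `site_offset`, `label` (= 1).
#' @export
build_positive_windows <- function(sites, transcript_lengths, window = 101,
                                   seed = NULL) {
  stopifnot(window %% 2 == 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", nrow(sites))
  n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    tx <- sites$transcript_id[i]
    p  <- sites$position[i]
    Lt <- transcript_lengths[[tx]]
    if (is.null(Lt) || Lt < window) { n_skipped <- n_skipped + 1L; next }
    lo <- max(1L, p - window + 1L)
    hi <- min(p, Lt - window + 1L)
    start <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
    rows[[i]] <- data.frame(transcript_id = tx, start = start,
                            end = start + window - 1L, site_pos = p,
                            site_offset = p - start + 1L, label = 1L)
  }
  if (n_skipped > 0L)
    warning(n_skipped, " site(s) skipped: transcript shorter than the window")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), site_pos = integer(),
                      site_offset = integer(), label = integer())
  rownames(out) <- NULL
  out
}

# is any site inside [start, end] on transcript tx?
.window_has_site <- function(sites, tx, start, end) {
  pos <- sites$position[sites$transcript_id == tx]
  any(pos >= start & pos <= end)
}

#' Build site-free negative windows near positive windows
#'
#' For each positive window, candidate windows are generated at center
#' offsets of `stride, 2*stride, ..., max_steps*stride` nt on each side and
#' scanned outward.  A candidate is valid if it lies fully inside the
#' transcript and contains no m6A site from the merged table.  The nearest
#' valid candidate on each side is kept, and one of the two is chosen by a
#' fair coin; if only one side yields a candidate it is taken, and if
#' neither does, no negative is emitted for that positive (with a warning).
#'
#' @param positives output of [build_positive_windows()].
#' @param sites merged site table used for the site-exclusion test.
#' @param transcript_lengths named integer vector of transcript lengths.
#' @param window odd window size, default 101.
#' @param stride step between candidate centers in nt, default 10.
#' @param max_steps number of steps scanned per side, default 100.
#' @param seed optional integer seed (side choice is randomized).
#' @return `data.frame` with columns `transcript_id`, `start`, `end`,
#'   `site_pos` (`NA`), `site_offset` (`NA`), `label` (= 0).
#' @export
build_negative_windows <- function(positives, sites, transcript_lengths,
                                   window = 101, stride = 10,
                                   max_steps = 100, seed = NULL) {
  stopifnot(window %% 2 == 1)
  window <- as.integer(window); stride <- as.integer(stride)
  max_steps <- as.integer(max_steps)
  if (!is.null(seed)) set.seed(seed)
  half <- (window - 1L) %/% 2L
  rows <- vector("list", nrow(positives))
  n_failed <- 0L
  for (i in seq_len(nrow(positives))) {
    tx <- positives$transcript_id[i]
    Lt <- transcript_lengths[[tx]]
    centre <- positives$start[i] + half
    found <- c(left = NA_integer_, right = NA_integer_)
    for (side in c(-1L, 1L)) {
      for (s in seq_len(max_steps)) {
        cand <- centre + side * s * stride
        st <- cand - half; en <- cand + half
        if (st < 1L || en > Lt) break  # ran off the transcript
        if (!.window_has_site(sites, tx, st, en)) {
          found[if (side < 0L) "left" else "right"] <- cand
          break
        }
      }
    }
    ok <- !is.na(found)
    if (!any(ok)) { n_failed <- n_failed + 1L; next }
    cand <- if (all(ok)) found[[sample(c("left", "right"), 1L)]]
            else found[[which(ok)]]
    rows[[i]] <- data.frame(transcript_id = tx, start = cand - half,
                            end = cand + half, site_pos = NA_integer_,
                            site_offset = NA_integer_, label = 0L)
  }
  if (n_failed > 0L)
    warning(n_failed, " positive(s) yielded no valid negative window")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), site_pos = integer(),
                      site_offset = integer(), label = integer())
  rownames(out) <- NULL
  out
}

#' Extract window sequences from transcripts
#'
#' Turns window coordinates (from the positive/negative builders) into a
#' labeled record table by substringing the transcript sequences.
#'
#' @param windows `data.frame` of windows (`transcript_id`, `start`, `end`,
#'   `label`).
#' @param transcripts named character vector of transcript sequences.
#' @return Record `data.frame` (`id`, `seq`, `label`); ids are
#'   `transcript:start-end`.
#' @export
window_sequences <- function(windows, transcripts) {
  seqs <- substr(transcripts[windows$transcript_id],
                 windows$start, windows$end)
  data.frame(id = sprintf("%s:%d-%d", windows$transcript_id,
                          windows$start, windows$end),
             seq = canonicalize_rna(unname(seqs)),
             label = windows$label)
}
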