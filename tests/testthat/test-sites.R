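test_that("site merging collapses runs to their central member", {
  s <- data.frame(transcript_id = "tx1", position = c(100, 120, 400))
  expect_equal(merge_sites(s, radius = 50)$position, c(100, 400))
  # single site untouched
  expect_equal(merge_sites(data.frame(transcript_id = "t", position = 500)),
               data.frame(transcript_id = "t", position = 500))
  # gaps of exactly the radius chain into one run; odd run keeps the median
  s <- data.frame(transcript_id = "tx1", position = c(0, 50, 100) + 1)
  expect_equal(merge_sites(s, radius = 50)$position, 51)
  # runs are per transcript and merging ignores input order
  s <- data.frame(transcript_id = c("b", "a", "a", "b"),
                  position = c(10, 200, 210, 30))
  m <- merge_sites(s, radius = 50)
  expect_equal(m$position[m$transcript_id == "a"], 200)
  expect_equal(m$position[m$transcript_id == "b"], 10)
})

test_that("site merging is idempotent on generated tables", {
  for (seed in 1:3) {
    st <- simulate_site_table(n_transcripts = 4, sites_per_transcript = 8,
                              cluster_fraction = 0.5, seed = seed)
    m1 <- merge_sites(st$sites)
    expect_equal(merge_sites(m1), m1)
  }
  # no clusters: merging changes nothing because all gaps exceed the radius
  st <- simulate_site_table(n_transcripts = 3, sites_per_transcript = 5,
                            cluster_fraction = 0, seed = 9)
  gaps <- unlist(lapply(split(st$sites$position, st$sites$transcript_id),
                        diff))
  expect_true(all(gaps > 50))
  expect_equal(merge_sites(st$sites), st$sites)
  # all clustered: merged table is strictly smaller
  st <- simulate_site_table(n_transcripts = 3, sites_per_transcript = 6,
                            cluster_fraction = 1, seed = 10)
  expect_lt(nrow(merge_sites(st$sites)), nrow(st$sites))
})

test_that("positive windows contain their site at a reproducible random offset", {
  lens <- c(tx1 = 10000L, tx2 = 50L)
  sites <- data.frame(transcript_id = c("tx1", "tx2"),
                      position = c(5000L, 10L))
  expect_warning(
    w <- build_positive_windows(sites, lens, window = 101, seed = 4),
    "skipped")
  expect_equal(nrow(w), 1)  # tx2 is shorter than the window
  expect_true(w$start >= 4900 && w$start <= 5000)
  expect_equal(w$end - w$start + 1, 101)
  expect_equal(w$site_offset, w$site_pos - w$start + 1)
  expect_true(w$site_offset >= 1 && w$site_offset <= 101)
  w2 <- suppressWarnings(
    build_positive_windows(sites, lens, window = 101, seed = 4))
  expect_equal(w, w2)  # determinism under the seed
})

test_that("negative windows are site-free and pick the nearest valid side", {
  lens <- c(tx = 20000L)
  # an isolated positive: candidates whose window still covers the site at
  # 5000 are invalid, so the nearest valid centre is 60 nt out on each side
  sites <- data.frame(transcript_id = "tx", position = 5000L)
  pos <- data.frame(transcript_id = "tx", start = 4950L, end = 5050L,
                    site_pos = 5000L, site_offset = 51L, label = 1L)
  centres <- vapply(1:20, function(s) {
    n <- build_negative_windows(pos, sites, lens, seed = s)
    n$start + 50L
  }, integer(1))
  expect_true(all(centres %in% c(4940L, 5060L)))
  expect_true(length(unique(centres)) == 2)  # both sides get chosen

  # left side saturated with sites; the first free right candidate wins
  blocked <- data.frame(
    transcript_id = "tx",
    position = c(5000L, seq(3900L, 4999L, by = 25L), 5010L, 5025L))
  n <- build_negative_windows(pos, blocked, lens, seed = 1)
  # brute-force scan: first candidate centre with no site inside +-50
  cand_ok <- function(centre)
    !any(blocked$position >= centre - 50 & blocked$position <= centre + 50)
  right_first <- Find(cand_ok, 5000L + 10L * (1:100))
  expect_false(any(vapply(5000L - 10L * (1:100),
                          function(c) c - 50 >= 1 && cand_ok(c),
                          logical(1))))
  expect_equal(n$start + 50L, right_first)

  # transcript too short for any candidate: warning, nothing emitted
  expect_warning(
    none <- build_negative_windows(
      data.frame(transcript_id = "s", start = 1L, end = 101L,
                 site_pos = 51L, site_offset = 51L, label = 1L),
      data.frame(transcript_id = "s", position = 51L),
      c(s = 101L)),
    "no valid negative")
  expect_equal(nrow(none), 0)
})

test_that("emitted negatives never overlap a merged site (exhaustive check)", {
  for (seed in 1:3) {
    st <- simulate_site_table(n_transcripts = 4, sites_per_transcript = 10,
                              cluster_fraction = 0.5, seed = seed)
    merged <- merge_sites(st$sites)
    pos <- suppressWarnings(
      build_positive_windows(merged, st$transcript_lengths, seed = seed))
    neg <- suppressWarnings(
      build_negative_windows(pos, merged, st$transcript_lengths,
                             seed = seed))
    for (i in seq_len(nrow(neg))) {
      inside <- merged$transcript_id == neg$transcript_id[i] &
        merged$position >= neg$start[i] & merged$position <= neg$end[i]
      expect_false(any(inside))
      expect_true(neg$start[i] >= 1)
      expect_true(neg$end[i] <= st$transcript_lengths[[neg$transcript_id[i]]])
    }
  }
})

test_that("window sequences extract the right substrings with labels", {
  tx <- c(tx1 = paste(rep("ACGU", 50), collapse = ""))
  w <- data.frame(transcript_id = "tx1", start = 1L, end = 5L,
                  site_pos = 3L, site_offset = 3L, label = 1L)
  rec <- window_sequences(w, tx)
  expect_equal(rec$seq, "ACGUA")
  expect_equal(rec$label, 1L)
  expect_equal(rec$id, "tx1:1-5")
})
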