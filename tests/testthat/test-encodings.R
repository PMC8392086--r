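test_that("canonicalization uppercases, maps T to U and rejects other characters", {
  expect_equal(canonicalize_rna("acgt"), "ACGU")
  expect_equal(canonicalize_rna("ACGU"), "ACGU")
  expect_equal(canonicalize_rna(c("tT", "gg")), c("UU", "GG"))
  expect_error(canonicalize_rna("ACGN"), "position 4")
  expect_error(canonicalize_rna(""), "non-empty")
})

test_that("circular pairing replicates the first base and reads non-overlapping pairs", {
  expect_equal(circular_pairs("A"), "AA")
  expect_equal(circular_pairs("AGU"), c("AG", "UA"))
  # even length: strict mode errors, lenient mode drops the unpaired replicate
  expect_error(circular_pairs("ACGU"), "odd")
  expect_equal(circular_pairs("ACGU", lenient = TRUE), c("AC", "GU"))
})

test_that("circular pair count is (L + 1) / 2 for every odd length", {
  set.seed(5)
  for (L in seq(1, 201, by = 2)) {
    s <- random_rna(L)
    expect_length(circular_pairs(s), (L + 1) / 2)
  }
})

test_that("the pair code table is a bijection over the 16 dinucleotides", {
  tab <- pair_code_table()
  expect_length(tab$order, 16)
  expect_setequal(tab$order,
                  as.vector(outer(rna_bases, rna_bases, paste0)))
  expect_equal(sort(unname(tab$code_of)), 1:16)
  # custom order round-trips; broken orders are rejected
  tab2 <- pair_code_table(rev(tab$order))
  expect_equal(tab2$code_of[["UU"]], 1L)
  expect_error(pair_code_table(rep("AA", 16)), "permutation")
  # enumerating all 16 dinucleotide seeds touches all 16 code indices
  hit <- integer(0)
  for (p in tab$order) {
    s <- paste0(p, substr(p, 1, 1))  # odd-length seed starting with pair p
    hit <- c(hit, which(encode_circular(s, tab)[1, ] == 1))
  }
  expect_setequal(hit, 1:16)
})

test_that("circular encoding is the row-indicator of the pair list", {
  tab <- pair_code_table()
  m <- encode_circular("A", tab)
  expect_equal(dim(m), c(1L, 16L))
  expect_equal(unname(which(m[1, ] == 1)), unname(tab$code_of["AA"]))
  set.seed(7)
  for (L in c(5, 9, 15)) {
    s <- random_rna(L)
    m <- encode_circular(s, tab)
    pairs <- circular_pairs(s)
    expect_equal(unname(rowSums(m)), rep(1, (L + 1) / 2))
    # column sums count pair occurrences (brute-force tally of the list)
    expect_equal(unname(colSums(m)),
                 vapply(tab$order, function(p) sum(pairs == p), numeric(1)),
                 ignore_attr = TRUE)
  }
})

test_that("one-hot and NCP follow the published base tables", {
  expect_equal(unname(encode_onehot("A")), matrix(c(1, 0, 0, 0), 1))
  expect_equal(unname(encode_onehot("ACGU")), diag(4))
  expect_equal(unname(encode_onehot("UUU")),
               matrix(rep(c(0, 0, 0, 1), each = 3), 3))
  expect_equal(unname(encode_ncp("A")), matrix(c(1, 1, 1), 1))
  expect_equal(unname(encode_ncp("G")), matrix(c(1, 0, 0), 1))
  expect_equal(unname(encode_ncp("CU")), rbind(c(0, 0, 1), c(0, 1, 0)))
})

test_that("encodings are mutually consistent and decodable", {
  ncp_of <- rbind(A = c(1, 1, 1), C = c(0, 0, 1),
                  G = c(1, 0, 0), U = c(0, 1, 0))
  set.seed(13)
  for (rep in 1:20) {
    L <- sample(seq(1, 15, by = 2), 1)
    s <- random_rna(L)
    oh <- encode_onehot(s)
    # brute-force decode of the one-hot matrix recovers the sequence
    decoded <- paste(rna_bases[apply(oh, 1, which.max)], collapse = "")
    expect_equal(decoded, s)
    # NCP row i is the property triple of the base one-hot row i indicates
    expect_equal(unname(encode_ncp(s)),
                 unname(ncp_of[rna_bases[apply(oh, 1, which.max)], ,
                               drop = FALSE]))
    # the pair list determines the sequence (up to its replicate closure)
    pairs <- circular_pairs(s)
    rebuilt <- paste(substring(paste(pairs, collapse = ""), 1, L),
                     collapse = "")
    expect_equal(rebuilt, s)
  }
})

test_that("encode_record bundles the three matrices with consistent shapes", {
  for (L in c(41, 51, 101)) {
    enc <- encode_record(random_rna(L))
    expect_equal(dim(enc$circular), c((L + 1) / 2, 16))
    expect_equal(dim(enc$onehot), c(L, 4))
    expect_equal(dim(enc$ncp), c(L, 3))
  }
})

test_that("batch encoding matches the per-record encoders", {
  set.seed(3)
  seqs <- replicate(6, random_rna(15))
  tab <- pair_code_table()
  batch <- encode_dataset(seqs, tab)
  for (i in seq_along(seqs)) {
    one <- encode_record(seqs[i], tab)
    expect_equal(batch$circular[i, , ], unname(one$circular))
    expect_equal(batch$onehot[i, , ], unname(one$onehot))
    expect_equal(batch$ncp[i, , ], unname(one$ncp))
  }
  expect_error(encode_dataset(c("ACA", "ACGUA")), "same length")
  expect_error(encode_dataset("ACGU"), "odd")
})
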