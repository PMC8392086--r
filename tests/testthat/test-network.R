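test_that("the specification enforces its own arithmetic", {
  s <- network_spec()
  expect_equal(s$conv1_filters, 32); expect_equal(s$conv1_kernel, 5)
  expect_equal(s$conv2_filters, 16); expect_equal(s$conv2_kernel, 3)
  expect_equal(s$gn_groups, 4); expect_equal(s$dropout, 0.5)
  expect_equal(s$branch_units, 24)
  expect_error(network_spec(gn_groups = 5), "divide")
  expect_error(network_spec(dropout = 1), "dropout")
  expect_error(network_spec(batch_size = -1), "positive")
})

test_that("the default network has the published layer geometry", {
  net <- build_network(network_spec(), 41, seed = 1)
  expect_equal(net$shapes$concat_width, 72)  # 3 branches x 24 features
  widths <- vapply(net$shapes$inputs, function(g) g[2], numeric(1))
  expect_equal(unname(widths), c(16, 4, 3))
  lens <- vapply(net$shapes$inputs, function(g) g[1], numeric(1))
  expect_equal(unname(lens), c(21, 41, 41))
  # conv1 kernels: kernel size x input width x 32 filters
  expect_equal(dim(net$params[["circular.W1"]]), c(5, 16, 32))
  expect_equal(dim(net$params[["onehot.W1"]]), c(5, 4, 32))
  expect_equal(dim(net$params[["ncp.W1"]]), c(5, 3, 32))
  expect_error(build_network(network_spec(), 40), "odd")
})

test_that("flattened branch sizes follow the declared padding for all dataset lengths", {
  for (L in c(41, 51, 101)) {
    net <- build_network(network_spec(), L, seed = 1)
    expect_equal(unname(net$shapes$branch_flat),
                 c((L + 1) / 2, L, L) * 16)  # same padding: length x 16
    netv <- build_network(network_spec(padding = "valid"), L, seed = 1)
    expect_equal(unname(netv$shapes$branch_flat),
                 (c((L + 1) / 2, L, L) - 4 - 2) * 16)
  }
})

test_that("single-branch and input-concat variants shrink the head accordingly", {
  net1 <- build_network(network_spec(), 41, branches = "onehot", seed = 1)
  expect_equal(net1$shapes$concat_width, 24)
  net2 <- build_network(network_spec(), 41,
                        branches = c("onehot", "ncp"), seed = 1)
  expect_equal(net2$shapes$concat_width, 48)
  netc <- build_network(network_spec(), 41, arch = "input_concat", seed = 1)
  expect_equal(unname(netc$shapes$inputs$concat), c(41, 23))  # 16 + 4 + 3
  expect_equal(netc$shapes$concat_width, 24)
  expect_error(build_network(network_spec(), 41, branches = character(0)))
})

test_that("inference is deterministic, bounded and shape-checked", {
  net <- build_network(tiny_spec(), 21, seed = 2)
  set.seed(1)
  seqs <- replicate(8, random_rna(21))
  p1 <- predict(net, seqs)
  p2 <- predict(net, seqs)
  expect_identical(p1, p2)  # dropout is inference-inactive
  expect_true(all(p1 >= 0 & p1 <= 1))
  # duplicated sample gives identical outputs
  p3 <- predict(net, c(seqs[1], seqs[1]))
  expect_equal(p3[1], p3[2])
  # zero weights: sigmoid(0) = 1/2 everywhere
  net0 <- net
  net0$params <- lapply(net0$params, function(p) p * 0)
  expect_equal(unname(predict(net0, seqs)), rep(0.5, 8))
  # wrong length input names the offending branch
  expect_error(predict(net, replicate(3, random_rna(31))), "branch")
})

test_that("predictions are invariant to a permuted pair-code table", {
  set.seed(4)
  seqs <- replicate(10, random_rna(21))
  tab1 <- pair_code_table()
  perm <- sample(16)
  tab2 <- pair_code_table(tab1$order[perm])
  net1 <- build_network(tiny_spec(), 21, seed = 5, pair_table = tab1)
  net2 <- net1
  net2$pair_table <- tab2
  # permute conv1 input-channel slices to match the permuted code columns
  W <- net1$params[["circular.W1"]]
  net2$params[["circular.W1"]] <- W[, perm, , drop = FALSE]
  expect_equal(predict(net1, seqs), predict(net2, seqs), tolerance = 1e-12)
})

test_that("models round-trip through the JSON checkpoint", {
  net <- build_network(tiny_spec(), 13, seed = 6)
  set.seed(2)
  seqs <- replicate(5, random_rna(13))
  f <- tempfile(fileext = ".json")
  save_m6a_cnn(net, f)
  net2 <- load_m6a_cnn(f)
  expect_equal(predict(net2, seqs), predict(net, seqs), tolerance = 1e-15)
  expect_equal(net2$branches, net$branches)
})
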