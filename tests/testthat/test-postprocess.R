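# Minimal feature tables driving the correction rules: only the
# neighborhood columns matter.
mk_feats <- function(nc, d5 = NULL) {
  n <- length(nc)
  if (is.null(d5)) d5 <- matrix(10, n, 5)
  tibble::tibble(nb_count = nc, nb_dist = d5[, 1], nb_d_mm = d5[, 2],
                 nb_d_mp = d5[, 3], nb_d_pm = d5[, 4], nb_d_pp = d5[, 5])
}

close5 <- function(k) c(rep(1, k), rep(10, 5 - k))  # k distances under 6

test_that("crowded helix labels are corrected by compactness", {
  # neighbor-rich H with little compactness becomes loop ...
  labs <- c("H", "H", "H", "H", "H")
  d5 <- matrix(10, 5, 5)
  d5[4, ] <- close5(2)
  out <- postprocess_labels(labs, mk_feats(c(0, 0, 0, 4, 0), d5))
  expect_equal(as.character(out), c("H", "H", "H", "L", "H"))
  # ... and with high compactness becomes sheet
  d5[4, ] <- close5(3)
  out2 <- postprocess_labels(labs, mk_feats(c(0, 0, 0, 4, 0), d5))
  expect_equal(as.character(out2), c("H", "H", "H", "E", "H"))
})

test_that("loops turn to sheet in dense, compact neighborhoods", {
  labs <- rep("L", 5)
  d5 <- matrix(10, 5, 5)
  d5[4, ] <- close5(3)
  out <- postprocess_labels(labs, mk_feats(c(0, 0, 0, 5, 0), d5))
  expect_equal(as.character(out), c("L", "L", "L", "E", "L"))
  # boundary cases stay: 4 neighbors or only 2 close distances
  d5b <- matrix(10, 5, 5); d5b[4, ] <- close5(2)
  expect_equal(as.character(postprocess_labels(labs, mk_feats(c(0, 0, 0, 5, 0), d5b))),
               labs)
  expect_equal(as.character(postprocess_labels(labs, mk_feats(c(0, 0, 0, 4, 0), d5))),
               labs)
})

test_that("sparse but fully compact loops turn to helix", {
  labs <- rep("L", 5)
  d5 <- matrix(10, 5, 5)
  d5[4, ] <- close5(5)
  out <- postprocess_labels(labs, mk_feats(c(0, 0, 0, 2, 0), d5))
  expect_equal(as.character(out), c("L", "L", "L", "H", "L"))
  # an empty neighbor list has no distance values: the rule must not fire
  out2 <- postprocess_labels(labs, mk_feats(rep(0, 5),
                                            matrix(0, 5, 5)))
  expect_equal(as.character(out2), labs)
})

test_that("isolated residues take the label of a uniform flanking group", {
  out <- postprocess_labels(c("L", "L", "H", "L", "L"), mk_feats(rep(0, 5)))
  expect_equal(as.character(out), rep("L", 5))
  # disagreeing flanks leave the residue alone
  out2 <- postprocess_labels(c("L", "L", "H", "E", "E"), mk_feats(rep(0, 5)))
  expect_equal(as.character(out2), c("L", "L", "H", "E", "E"))
  # flanks of one are not enough
  out3 <- postprocess_labels(c("L", "H", "L"), mk_feats(rep(0, 3)))
  expect_equal(as.character(out3), c("L", "H", "L"))
})

test_that("unresolved labels inherit the nearest resolved label, ties left", {
  out <- postprocess_labels(c("U", "U", "H", "L", "U"), mk_feats(rep(0, 5)))
  expect_equal(as.character(out), c("H", "H", "H", "L", "L"))
  tie <- postprocess_labels(c("H", "U", "L"), mk_feats(rep(0, 3)))
  expect_equal(as.character(tie)[2], "H")
  all_u <- postprocess_labels(rep("U", 3), mk_feats(rep(0, 3)))
  expect_equal(as.character(all_u), rep("U", 3))
})

test_that("each rule fires only on its dedicated fixture", {
  # one run of labels, one flagged residue; nothing else may change
  base_nc <- rep(0, 7)
  d5 <- matrix(10, 7, 5)
  for (rule in 1:3) {
    labs <- if (rule == 1) rep("H", 7) else rep("L", 7)
    nc <- base_nc
    if (rule == 1) { nc[4] <- 3; d5r <- d5; d5r[4, ] <- close5(2) }
    if (rule == 2) { nc[4] <- 5; d5r <- d5; d5r[4, ] <- close5(3) }
    if (rule == 3) { nc[4] <- 2; d5r <- d5; d5r[4, ] <- close5(5) }
    # two adjacent flagged residues, so the isolation rule cannot undo
    # the conversion; everything else must stay put
    nc[5] <- nc[4]; d5r[5, ] <- d5r[4, ]
    out2 <- as.character(postprocess_labels(labs, mk_feats(nc, d5r)))
    expect_equal(which(out2 != labs), c(4L, 5L))
    expect_length(unique(out2[c(4, 5)]), 1L)
  }
})

test_that("post-processing is idempotent on pipeline predictions", {
  corpus <- make_protein_corpus(8, seed = 6)
  model <- train_subspace(corpus[1:6])
  for (tr in corpus[7:8]) {
    feats <- ca_features(tr)
    for (method in c("model1", "model2")) {
      raw <- if (method == "model1") classify_model1(tr, model)
             else classify_model2(tr, model)
      once <- postprocess_labels(raw$label, feats)
      twice <- postprocess_labels(as.character(once), feats)
      expect_equal(as.character(twice), as.character(once))
      expect_true(all(as.character(once) %in% c("H", "E", "L")))
    }
  }
})
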