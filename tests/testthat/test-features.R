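test_that("descriptor validity follows the i-3..i+3 context window", {
  h <- make_helix(13)
  fm <- compute_feature_matrix(h)
  expect_equal(dim(fm), c(39L, 13L))
  fully_valid <- unname(which(colSums(is.na(fm)) == 0))
  expect_equal(fully_valid, 4:10)
  # at i = 3 exactly the elements needing offset -3 are masked
  need_m3 <- vapply(names(catrace:::FEATURE_SPAN),
                    function(nm) catrace:::FEATURE_SPAN[[nm]][1] == -3,
                    logical(1))
  v3 <- fm[seq_len(28), 3]
  expect_true(all(is.na(v3[need_m3])))
  expect_true(all(!is.na(v3[!need_m3])))
  # length-1 trace: only the residue-type code is defined
  one <- ca_trace(matrix(c(0, 0, 0), 1), aa = "TRP")
  v <- compute_feature_vector(one, 1)
  expect_equal(unname(v["aa_code"]), match("TRP", AA3) - 1)
  expect_true(all(is.na(v[setdiff(names(v), "aa_code")])))
})

test_that("columns of the matrix equal per-residue vectors", {
  pr <- make_protein(data.frame(kind = c("helix", "coil"), length = c(8, 6)),
                     jitter_sd = 0.1, seed = 2)
  fm <- compute_feature_matrix(pr)
  for (i in c(1, 5, 9, nrow(pr))) {
    expect_equal(fm[, i], compute_feature_vector(pr, i))
  }
})

test_that("internal-coordinate chains reproduce their generating angles", {
  xyz <- build_from_internal(rep(3.8, 9), rep(91, 8), rep(50, 7))
  tr <- ca_trace(xyz)
  fm <- compute_feature_matrix(tr)
  mid <- 4:7
  for (i in mid) {
    expect_equal(unname(fm[c("ang_c", "ang_m", "ang_p"), i]), rep(91, 3),
                 tolerance = 1e-6)
    expect_equal(unname(fm[paste0("tors_", 1:4), i]), rep(50, 4),
                 tolerance = 1e-6)
    expect_equal(unname(fm[paste0("vt_", 1:4), i]),
                 unname(fm[paste0("vang_", 1:4), i]) + 50, tolerance = 1e-6)
  }
})

test_that("all 39 features are invariant under proper rigid motions", {
  pr <- make_protein(data.frame(kind = c("helix", "coil", "hairpin"),
                                length = c(9, 5, 5)),
                     jitter_sd = 0.1, seed = 11)
  ref <- compute_feature_matrix(pr)
  set.seed(42)
  for (rep in 1:8) {
    rot <- catrace:::random_rotation()
    moved <- catrace:::transform_trace(pr, rot, rnorm(3, sd = 20))
    expect_equal(compute_feature_matrix(moved), ref, tolerance = 1e-6)
  }
})

test_that("reflection negates torsions and leaves unsigned features alone", {
  pr <- make_protein(data.frame(kind = c("helix", "coil"), length = c(9, 6)),
                     jitter_sd = 0.05, seed = 12)
  ref <- compute_feature_matrix(pr)
  mir <- catrace:::transform_trace(pr, diag(c(-1, 1, 1)))
  got <- compute_feature_matrix(mir)
  tors <- paste0("tors_", 1:4)
  vang <- paste0("vang_", 1:4)
  unsigned <- setdiff(feature_names(), c(tors, paste0("vt_", 1:4)))
  expect_equal(got[unsigned, ], ref[unsigned, ], tolerance = 1e-6)
  expect_equal(got[tors, ], -ref[tors, ], tolerance = 1e-6)
  expect_equal(got[paste0("vt_", 1:4), ],
               ref[vang, ] - ref[tors, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("neighborhood block matches the ideal-helix derivation", {
  h <- make_helix(13)
  nf <- neighborhood_features(h, 7)
  expect_equal(nf$neighbors, c(4L, 10L))  # exactly i-3 and i+3
  expect_equal(nf$values[["nb_count"]], 2)
  expect_equal(nf$values[["nb_dist"]], helix_chord(3), tolerance = 1e-9)
  # two-point cloud: second and third singular values vanish
  expect_gt(nf$values[["nb_eig1"]], 0)
  expect_equal(nf$values[["nb_eig2"]], 0, tolerance = 1e-12)
  expect_equal(nf$values[["nb_eig3"]], 0, tolerance = 1e-12)
})

test_that("a straight extended chain has the zero-sentinel block", {
  straight <- ca_trace(cbind(3.8 * (0:9), 0, 0))
  nf <- neighborhood_features(straight, 5)
  expect_equal(unname(nf$values), rep(0, 11))
  expect_equal(nf$neighbors, integer(0))
})

test_that("neighbor lists equal the brute-force double loop everywhere", {
  fixtures <- list(make_helix(12, jitter_sd = 0.1, seed = 1),
                   make_hairpin(7, jitter_sd = 0.1, seed = 2),
                   make_protein(data.frame(kind = c("helix", "coil", "hairpin"),
                                           length = c(8, 5, 6)),
                                jitter_sd = 0.1, seed = 3))
  for (tr in fixtures) {
    for (i in 2:(nrow(tr) - 1)) {
      expect_equal(neighborhood_features(tr, i)$neighbors,
                   brute_neighbors(tr, i) %||% integer(0))
    }
  }
})

test_that("feature TSV round-trips with NA masking", {
  f <- ca_features(make_helix(8))
  txt <- write_features_tsv(f)
  back <- read_features_tsv(txt)
  expect_equal(as.data.frame(back), as.data.frame(f))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
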