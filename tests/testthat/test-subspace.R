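test_that("window bookkeeping matches the closed-form count", {
  for (N in c(12, 13, 16, 20)) {
    h <- make_helix(N)
    w <- build_windows(ca_features(h), window_config(q = 7))
    expect_equal(ncol(w$W$H), max(0L, N - 12L))
  }
  # stride 2 keeps the ceiling of half the windows
  h20 <- make_helix(20)
  w1 <- build_windows(ca_features(h20), window_config(q = 7, z = 1))
  w2 <- build_windows(ca_features(h20), window_config(q = 7, z = 2))
  expect_equal(ncol(w1$W$H), 8L)
  expect_equal(ncol(w2$W$H), ceiling(ncol(w1$W$H) / 2))
})

test_that("windows never span chains and follow the center truth label", {
  a <- make_helix(14)
  b <- make_hairpin(5)
  feats <- dplyr::bind_rows(ca_features(a), ca_features(b))
  w <- build_windows(feats, window_config(q = 3))
  # helix: valid centers 5..10 of 14; hairpin contributes E and L columns
  expect_equal(ncol(w$W$H), 6L)
  expect_gt(ncol(w$W$E), 0L)
  expect_gt(ncol(w$W$L), 0L)
})

test_that("projection_distance equals the least-squares residual", {
  expect_equal(projection_distance(c(1, 2, 2), diag(3)[, 1:2]), 2)
  B <- random_orthonormal(10, 3)
  w_in <- B %*% rnorm(3)
  expect_equal(projection_distance(w_in, B), 0, tolerance = 1e-12)
  set.seed(3)
  for (t in 1:50) {
    B <- random_orthonormal(sample(5:40, 1), sample(1:4, 1))
    w <- rnorm(nrow(B))
    expect_equal(projection_distance(w, B), lsq_residual(w, B),
                 tolerance = 1e-10)
    expect_lte(projection_distance(w, B), sqrt(sum(w^2)) + 1e-12)
  }
  expect_error(projection_distance(rnorm(4), random_orthonormal(5, 2)),
               "incompatible")
})

test_that("principal angles and chordal distance match closed forms", {
  e <- diag(4)
  expect_equal(principal_angles(e[, 1:2], e[, 1:2]), c(0, 0))
  expect_equal(principal_angles(e[, 1, drop = FALSE], e[, 2, drop = FALSE]), 90)
  A <- e[, 1:2]
  B <- cbind(e[, 1], (e[, 2] + e[, 3]) / sqrt(2))
  expect_equal(principal_angles(A, B), c(0, 45), tolerance = 1e-10)
  expect_equal(chordal_distance(A, B), sqrt(0.5), tolerance = 1e-10)
  expect_equal(chordal_distance(e[, 1, drop = FALSE], e[, 2, drop = FALSE]), 1)
  expect_equal(chordal_distance(A, A), 0)
})

test_that("chordal distance is symmetric and basis-invariant", {
  set.seed(5)
  for (t in 1:20) {
    A <- random_orthonormal(12, 3)
    B <- random_orthonormal(12, 2)
    expect_equal(chordal_distance(A, B), chordal_distance(B, A),
                 tolerance = 1e-10)
    # mix the columns of A: same span, same distance
    A2 <- qr.Q(qr(A %*% matrix(rnorm(9), 3)))
    expect_equal(chordal_distance(A2, B), chordal_distance(A, B),
                 tolerance = 1e-10)
  }
})

planted_windows <- function(bases, n_cols = 50, noise = 1e-6) {
  W <- lapply(bases, function(B) {
    B %*% matrix(rnorm(ncol(B) * n_cols), ncol(B)) +
      matrix(rnorm(nrow(B) * n_cols, sd = noise), nrow(B))
  })
  structure(list(W = W, centers = list(), mu = rep(0, 39),
                 sigma = rep(1, 39),
                 cfg = window_config(q = 3, rank_strategy = "gap"),
                 skipped = 0L),
            class = "sse_windows")
}

test_that("fitting recovers planted class subspaces", {
  set.seed(9)
  Q <- random_orthonormal(117, 9)
  bases <- list(H = Q[, 1:3], E = Q[, 4:6], L = Q[, 7:9])
  model <- fit_sse_subspaces(planted_windows(bases))
  expect_equal(unname(model$rank), c(3L, 3L, 3L))
  for (cl in c("H", "E", "L")) {
    expect_lt(chordal_distance(model$basis[[cl]], bases[[cl]]), 1e-3)
  }
  # orthogonal planted subspaces stay orthogonal after fitting
  expect_gt(max(principal_angles(model$basis$H, model$basis$E)), 89.9)
  # all columns identical: rank-1 subspace along the column
  one <- matrix(rep(rnorm(117), 10), 117)
  w1 <- planted_windows(bases)
  w1$W$H <- one
  m1 <- fit_sse_subspaces(w1)
  expect_equal(unname(m1$rank["H"]), 1L)
  expect_lt(chordal_distance(m1$basis$H, one[, 1, drop = FALSE] /
                               sqrt(sum(one[, 1]^2))), 1e-6)
  # an empty class is a hard error naming the class
  w0 <- planted_windows(bases)
  w0$W$E <- w0$W$E[, 0, drop = FALSE]
  expect_error(fit_sse_subspaces(w0), "class E")
})

test_that("argmin ties prefer loop, then sheet", {
  pr <- make_protein(data.frame(kind = c("helix", "coil", "hairpin"),
                                length = c(10, 6, 5)),
                     jitter_sd = 0.1, seed = 6)
  model <- train_subspace(pr)
  model$basis$H <- model$basis$L
  model$basis$E <- model$basis$L
  p <- classify_model1(pr, model)
  expect_true(all(p$label[p$label != "U"] == "L"))
})

test_that("classification is invariant under proper rigid motion", {
  corpus <- make_protein_corpus(6, seed = 3)
  model <- train_subspace(corpus[1:5])
  tr <- corpus[[6]]
  moved <- catrace:::transform_trace(tr, catrace:::random_rotation(),
                                     c(12, -5, 40))
  expect_equal(classify_model1(moved, model)$label,
               classify_model1(tr, model)$label)
})

test_that("model-2 runs with tiny neighborhoods and flags starved chains", {
  corpus <- make_protein_corpus(6, seed = 4)
  model <- train_subspace(corpus[1:5])
  p <- classify_model2(corpus[[6]], model, model2_config(n_local = 2))
  expect_true(all(p$label %in% c("H", "E", "L", "U")))
  expect_true(any(p$label != "U"))
  short <- make_helix(9)
  expect_warning(ps <- classify_model2(short, model),
                 "unresolved")
  expect_true(all(ps$label == "U"))
})

test_that("subspace models survive the JSON round trip", {
  corpus <- make_protein_corpus(6, seed = 5)
  model <- train_subspace(corpus[1:5])
  f <- withr::local_tempfile(fileext = ".json")
  write_sse_model(model, f)
  back <- read_sse_model(f)
  tr <- corpus[[6]]
  p0 <- classify_model1(tr, model)
  p1 <- classify_model1(tr, back)
  expect_equal(p1$label, p0$label)
  expect_equal(p1$d_H, p0$d_H, tolerance = 1e-8)
  # tampered version tag refuses to classify
  bad <- back
  bad$version <- "0"
  expect_error(classify_model1(tr, bad), "mismatch")
})
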