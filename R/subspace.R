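# Union-of-subspaces modeling of secondary structure.  Sliding windows of
# q consecutive residue descriptors are stacked into (q*39)-dimensional
# column vectors; one linear subspace per class (H/E/L) is fitted by SVD
# truncated at the estimated effective rank.  Classification is either by
# orthogonal-projection residual to each class subspace (Model-1) or by
# the Grassmannian chordal distance between a residue-local subspace and
# the class subspaces (Model-2).

SSE_CLASSES <- c("H", "E", "L")
TIE_ORDER <- c("L", "E", "H")  # argmin ties resolve to loop, then sheet

#' Sliding-window configuration
#'
#' @param q Window size in residues (odd, `>= 3`).  Default 3: each
#'   residue's descriptor already encodes its i-3..i+3 context, so a
#'   q-window of descriptors effectively spans `q + 6` residues; wider
#'   windows overrun typical segment lengths and blur class boundaries.
#' @param z Window slide (stride) during training.  Default 1.
#' @param standardize Apply per-feature z-scoring (means/scales estimated
#'   from the training windows) before stacking.  The descriptor mixes
#'   Angstroms and degrees, so this is on by default.
#' @param rank_strategy,tau,min_gap Effective-rank rule for the class
#'   subspaces (see [estimate_rank()]).
#' @return A `window_config` list.
#' @export
window_config <- function(q = 3, z = 1, standardize = TRUE,
                          rank_strategy = "energy", tau = 0.98, min_gap = 10) {
  stopifnot(q >= 3, q %% 2 == 1, z >= 1)
  structure(list(q = as.integer(q), z = as.integer(z),
                 standardize = isTRUE(standardize),
                 rank_strategy = rank_strategy, tau = tau, min_gap = min_gap),
            class = "window_config")
}

#' Build per-class window matrices from labeled descriptor tables
#'
#' Slides a `q`-residue window (stride `z`) along each chain; whenever all
#' `q` member descriptors are fully valid, their standardized values are
#' stacked into one `(q*39)`-vector and appended to the window matrix of
#' the center residue's truth class.  Windows never span chains
#' (`source_id`/`chain` groups).
#'
#' @param features A [ca_features()] tibble (rows from several chains may
#'   be bound together) whose `label` column holds H/E/L truth.
#' @param cfg A [window_config()].
#' @return An `sse_windows` object: per-class matrices `W$H`, `W$E`,
#'   `W$L`, the standardization `mu`/`sigma`, the config, and a count of
#'   skipped (partially invalid) windows.
#' @export
build_windows <- function(features, cfg = window_config()) {
  stopifnot(all(feature_names() %in% names(features)))
  fm_all <- t(as.matrix(features[, feature_names()]))
  valid_col <- colSums(is.na(fm_all)) == 0L
  if (cfg$standardize) {
    mu <- rowMeans(fm_all[, valid_col, drop = FALSE])
    sigma <- apply(fm_all[, valid_col, drop = FALSE], 1, stats::sd)
    sigma[!is.finite(sigma) | sigma < 1e-12] <- 1
  } else {
    mu <- rep(0, 39)
    sigma <- rep(1, 39)
  }
  h <- (cfg$q - 1L) %/% 2L
  cols <- list(H = list(), E = list(), L = list())
  centers <- list(H = list(), E = list(), L = list())
  skipped <- 0L
  grp <- paste(features$source_id, features$chain)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    fm <- (fm_all[, rows, drop = FALSE] - mu) / sigma
    lab <- features$label[rows]
    n <- length(rows)
    for (c in seq(1L, n, by = cfg$z)) {
      if (c - h < 1L || c + h > n) next
      member <- fm[, (c - h):(c + h), drop = FALSE]
      if (anyNA(member)) {
        skipped <- skipped + 1L
        next
      }
      cl <- lab[c]
      if (!cl %in% SSE_CLASSES) next
      cols[[cl]][[length(cols[[cl]]) + 1L]] <- as.numeric(member)
      centers[[cl]][[length(centers[[cl]]) + 1L]] <-
        features$seq_num[rows[c]]
    }
  }
  W <- lapply(cols, function(l) {
    if (!length(l)) matrix(numeric(0), nrow = 39L * cfg$q, ncol = 0)
    else do.call(cbind, l)
  })
  structure(list(W = W, centers = lapply(centers, unlist),
                 mu = mu, sigma = sigma, cfg = cfg, skipped = skipped),
            class = "sse_windows")
}

#' @export
print.sse_windows <- function(x, ...) {
  cat(sprintf("# SSE window matrices (q=%d, z=%d): H=%d E=%d L=%d columns, %d skipped\n",
              x$cfg$q, x$cfg$z, ncol(x$W$H), ncol(x$W$E), ncol(x$W$L),
              x$skipped))
  invisible(x)
}

#' Fit one subspace per secondary-structure class
#'
#' For each class window matrix: SVD, effective-rank estimate, and the
#' span of the leading left singular vectors as the class subspace.
#'
#' @param windows An `sse_windows` object from [build_windows()].
#' @return An `sse_subspace_model` holding per-class orthonormal bases,
#'   ranks, the standardization parameters and the window config.
#' @export
fit_sse_subspaces <- function(windows) {
  stopifnot(inherits(windows, "sse_windows"))
  cfg <- windows$cfg
  basis <- list()
  rank <- integer(0)
  for (cl in SSE_CLASSES) {
    Wc <- windows$W[[cl]]
    if (ncol(Wc) == 0) {
      stop(sprintf("no training windows for class %s", cl), call. = FALSE)
    }
    dec <- svd(Wc)
    r <- estimate_rank(Wc, strategy = cfg$rank_strategy, tau = cfg$tau,
                       min_gap = cfg$min_gap)
    r <- max(1L, min(r, ncol(dec$u)))
    basis[[cl]] <- dec$u[, seq_len(r), drop = FALSE]
    rank[cl] <- r
  }
  structure(list(version = "1", basis = basis, rank = rank,
                 mu = windows$mu, sigma = windows$sigma,
                 q = cfg$q, z = cfg$z, d = 39L,
                 feature_names = feature_names(),
                 rank_strategy = cfg$rank_strategy, tau = cfg$tau,
                 min_gap = cfg$min_gap,
                 n_windows = vapply(windows$W, ncol, integer(1))),
            class = "sse_subspace_model")
}

#' Train the subspace model from labeled traces
#'
#' Convenience wrapper: featurize each trace, pool the windows, fit.
#' @param traces A [ca_trace] or list of them, each with truth in `sse`.
#' @param cfg A [window_config()].
#' @return An `sse_subspace_model`.
#' @export
train_subspace <- function(traces, cfg = window_config()) {
  if (inherits(traces, "ca_trace")) traces <- list(traces)
  feats <- dplyr::bind_rows(lapply(traces, ca_features))
  fit_sse_subspaces(build_windows(feats, cfg))
}

#' @export
print.sse_subspace_model <- function(x, ...) {
  cat(sprintf("# SSE subspace model (q=%d, d=%d): ranks H=%d E=%d L=%d from %d/%d/%d windows\n",
              x$q, x$d, x$rank["H"], x$rank["E"], x$rank["L"],
              x$n_windows["H"], x$n_windows["E"], x$n_windows["L"]))
  invisible(x)
}

#' Orthogonal-projection residual distance
#'
#' `||w - B B' w||`, the Euclidean distance from `w` to the subspace
#' spanned by the orthonormal columns of `basis`.
#' @param w Numeric vector.
#' @param basis Matrix with orthonormal columns, `nrow(basis) == length(w)`.
#' @return Nonnegative scalar.
#' @export
projection_distance <- function(w, basis) {
  basis <- as.matrix(basis)
  if (length(w) != nrow(basis)) {
    stop("w and basis have incompatible dimensions", call. = FALSE)
  }
  r <- w - basis %*% crossprod(basis, w)
  sqrt(sum(r^2))
}

#' Principal angles between two subspaces
#'
#' Angles `theta_k = acos(sigma_k)` where `sigma_k` are the singular
#' values of `A' B` (clipped to `[0, 1]`), ascending, in degrees.
#' @param A,B Matrices with orthonormal columns in the same ambient space.
#' @return Numeric vector of length `min(ncol(A), ncol(B))`.
#' @export
principal_angles <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (!ncol(A) || !ncol(B)) stop("empty basis", call. = FALSE)
  if (nrow(A) != nrow(B)) stop("ambient dimensions differ", call. = FALSE)
  s <- svd(crossprod(A, B), nu = 0, nv = 0)$d
  s <- pmin(1, pmax(0, s))
  sort(acos(s) * RAD2DEG)
}

#' Chordal distance on the Grassmannian
#'
#' `sqrt(sum(sin(theta_j)^2))` over the principal angles -- a metric on
#' subspaces, 0 iff the spans coincide, at most `sqrt(p)`.
#' @inheritParams principal_angles
#' @return Nonnegative scalar.
#' @export
chordal_distance <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (!ncol(A) || !ncol(B)) stop("empty basis", call. = FALSE)
  if (nrow(A) != nrow(B)) stop("ambient dimensions differ", call. = FALSE)
  s <- svd(crossprod(A, B), nu = 0, nv = 0)$d
  s <- pmin(1, pmax(0, s))
  sqrt(sum(1 - s^2))
}

check_model_compat <- function(model) {
  if (!inherits(model, "sse_subspace_model")) {
    stop("not an sse_subspace_model", call. = FALSE)
  }
  if (!identical(model$version, "1") || model$d != 39L ||
      !identical(model$feature_names, feature_names())) {
    stop("model version/feature-layout mismatch; refusing to classify",
         call. = FALSE)
  }
}

# standardized window vectors of every residue with a fully valid window
window_vectors <- function(trace, model) {
  fm <- compute_feature_matrix(trace)
  fm <- (fm - model$mu) / model$sigma
  n <- ncol(fm)
  h <- (model$q - 1L) %/% 2L
  centers <- integer(0)
  cols <- list()
  for (c in seq_len(n)) {
    if (c - h < 1L || c + h > n) next
    member <- fm[, (c - h):(c + h), drop = FALSE]
    if (anyNA(member)) next
    centers <- c(centers, c)
    cols[[length(cols) + 1L]] <- as.numeric(member)
  }
  V <- if (length(cols)) do.call(cbind, cols)
       else matrix(numeric(0), nrow = 39L * model$q, ncol = 0)
  list(V = V, centers = centers)
}

prediction_tibble <- function(trace, labels, dists, method) {
  out <- tibble::tibble(source_id = trace_source_id(trace),
                        chain = trace$chain, seq_num = trace$seq_num,
                        aa = trace$aa)
  if (!is.null(trace$sse)) out$sse <- trace$sse
  out$label <- labels
  out <- dplyr::bind_cols(out, tibble::as_tibble(dists))
  attr(out, "method") <- method
  class(out) <- c("sse_prediction", class(out))
  out
}

#' Classify residues by projection distance to the class subspaces
#'
#' Each residue with a fully valid window is assigned the class whose
#' subspace is closest in orthogonal-projection residual; ties prefer
#' loop, then sheet.  Residues without a valid window (chain ends,
#' breaks) are labeled `"U"` and are resolved by [postprocess_labels()].
#'
#' @param trace A [ca_trace].
#' @param model An `sse_subspace_model`.
#' @return An `sse_prediction` tibble with `label` and the three
#'   distances `d_H`, `d_E`, `d_L`.
#' @export
classify_model1 <- function(trace, model) {
  check_model_compat(model)
  wv <- window_vectors(trace, model)
  n <- nrow(trace)
  labels <- rep("U", n)
  D <- matrix(NA_real_, n, 3, dimnames = list(NULL, paste0("d_", SSE_CLASSES)))
  if (length(wv$centers)) {
    for (cl in SSE_CLASSES) {
      B <- model$basis[[cl]]
      R <- wv$V - B %*% crossprod(B, wv$V)
      D[wv$centers, paste0("d_", cl)] <- sqrt(colSums(R^2))
    }
    labels[wv$centers] <- apply(D[wv$centers, , drop = FALSE], 1, function(d) {
      TIE_ORDER[which.min(d[paste0("d_", TIE_ORDER)])]
    })
  }
  prediction_tibble(trace, labels, D, "model1")
}

#' Local-subspace (Model-2) configuration
#' @param n_local Number of windows per residue-local subspace (the
#'   actual neighborhood is the `2 * floor(n_local / 2) + 1`
#'   sequence-nearest valid windows, centered on the residue).  Default
#'   3: larger neighborhoods mix structure classes near segment
#'   boundaries and degrade the local subspace.
#' @return A `model2_config` list.
#' @export
model2_config <- function(n_local = 3) {
  stopifnot(n_local >= 2)
  structure(list(n_local = as.integer(n_local)), class = "model2_config")
}

#' Classify residues by Grassmannian distance of a local subspace
#'
#' For each residue, the window vectors of its sequence-nearest valid
#' windows form a local matrix whose leading left singular vectors (at
#' the estimated effective rank) span a residue-local subspace; the
#' residue takes the class whose subspace is nearest in chordal
#' distance.
#'
#' @inheritParams classify_model1
#' @param cfg A [model2_config()].
#' @return An `sse_prediction` tibble with `label` and chordal distances
#'   `d_H`, `d_E`, `d_L`.
#' @export
classify_model2 <- function(trace, model, cfg = model2_config()) {
  check_model_compat(model)
  wv <- window_vectors(trace, model)
  n <- nrow(trace)
  labels <- rep("U", n)
  D <- matrix(NA_real_, n, 3, dimnames = list(NULL, paste0("d_", SSE_CLASSES)))
  m <- 2L * (cfg$n_local %/% 2L) + 1L
  if (length(wv$centers) < m) {
    warning(sprintf("fewer than %d valid windows; all residues unresolved", m),
            call. = FALSE)
    return(prediction_tibble(trace, labels, D, "model2"))
  }
  for (idx in seq_along(wv$centers)) {
    i <- wv$centers[idx]
    ord <- order(abs(wv$centers - i), wv$centers)
    sel <- sort(ord[seq_len(m)])
    L <- wv$V[, sel, drop = FALSE]
    r <- estimate_rank(L, strategy = model$rank_strategy, tau = model$tau,
                       min_gap = model$min_gap)
    r <- max(1L, min(r, ncol(L)))
    S_local <- svd(L, nu = r, nv = 0)$u
    d <- vapply(SSE_CLASSES,
                function(cl) chordal_distance(S_local, model$basis[[cl]]),
                numeric(1))
    D[i, ] <- d
    labels[i] <- TIE_ORDER[which.min(d[TIE_ORDER])]
  }
  prediction_tibble(trace, labels, D, "model2")
}

#' Save / load a subspace model as versioned JSON
#'
#' Bases, standardization parameters and the window configuration are
#' stored as plain nested arrays with a format-version tag; loading a
#' file with a different version or descriptor layout refuses to
#' classify.
#' @param model An `sse_subspace_model`.
#' @param path File path.
#' @return `read_sse_model()` returns the model; `write_sse_model()` the
#'   path, invisibly.
#' @export
write_sse_model <- function(model, path) {
  check_model_compat(model)
  payload <- list(version = model$version, q = model$q, z = model$z,
                  d = model$d, feature_names = model$feature_names,
                  rank_strategy = model$rank_strategy, tau = model$tau,
                  min_gap = model$min_gap, mu = model$mu, sigma = model$sigma,
                  rank = as.list(model$rank),
                  n_windows = as.list(model$n_windows),
                  basis = lapply(model$basis, unclass))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sse_model
#' @export
read_sse_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(
    version = p$version, basis = lapply(p$basis, as.matrix),
    rank = vapply(p$rank, as.integer, integer(1)),
    mu = as.numeric(p$mu), sigma = as.numeric(p$sigma),
    q = as.integer(p$q), z = as.integer(p$z), d = as.integer(p$d),
    feature_names = as.character(p$feature_names),
    rank_strategy = p$rank_strategy, tau = p$tau, min_gap = p$min_gap,
    n_windows = vapply(p$n_windows, as.integer, integer(1))),
    class = "sse_subspace_model")
  check_model_compat(model)
  model
}
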