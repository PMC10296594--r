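# Effective-rank estimation and rank-preserving feature-row selection.

#' Effective rank of a matrix
#'
#' Two strategies over the singular spectrum:
#' \describe{
#'   \item{`"energy"`}{smallest `k` with
#'     `sum(sigma[1:k]^2) / sum(sigma^2) >= tau` (default `tau = 0.95`).}
#'   \item{`"gap"`}{index of the largest ratio `sigma[j] / sigma[j+1]`
#'     among the numerically nonzero singular values.  When no ratio
#'     exceeds `min_gap` (i.e. the spectrum has no pronounced gap, as for
#'     the identity), the numerical rank -- the count of singular values
#'     above `1e-12 * sigma[1]` -- is returned instead.}
#' }
#'
#' @param M Numeric matrix (NA entries are not allowed).
#' @param strategy `"energy"` or `"gap"`.
#' @param tau Energy fraction for `"energy"`.
#' @param min_gap Minimum spectral-gap ratio for `"gap"`.
#' @return Integer in `[0, min(dim(M))]`; an all-zero matrix has rank 0.
#' @export
estimate_rank <- function(M, strategy = c("energy", "gap"), tau = 0.95,
                          min_gap = 10) {
  strategy <- match.arg(strategy)
  M <- as.matrix(M)
  if (length(M) == 0) stop("empty matrix", call. = FALSE)
  if (anyNA(M)) stop("estimate_rank() needs a complete matrix", call. = FALSE)
  s <- svd(M, nu = 0, nv = 0)$d
  if (s[1] <= 0) return(0L)
  r0 <- sum(s > 1e-12 * s[1])
  if (strategy == "energy") {
    e <- cumsum(s^2) / sum(s^2)
    return(as.integer(which(e >= tau)[1]))
  }
  if (r0 <= 1L) return(r0)
  ratios <- s[1:(r0 - 1L)] / s[2:r0]
  if (max(ratios) < min_gap) return(r0)
  as.integer(which.max(ratios))
}

#' Select a maximal set of informative descriptor rows
#'
#' Estimates the effective rank `k` of the feature matrix and returns `k`
#' row indices whose submatrix still has effective rank `k` (so the
#' selected features jointly carry the matrix's linear structure and no
#' selected feature is a linear combination of the others).  A
#' pivoted-QR pass proposes the rows; if its submatrix fails the rank
#' condition, seeded random restarts search for one.
#'
#' @param F Numeric feature matrix (features in rows); columns containing
#'   `NA` are dropped before estimation.
#' @param strategy,tau,min_gap Passed to [estimate_rank()].
#' @param seed Seed for the restart randomness (deterministic output).
#' @param max_restarts Restart budget before giving up.
#' @return Sorted integer row indices, length `k`, with attribute
#'   `rank = k`.
#' @export
reduce_features <- function(F, strategy = "gap", tau = 0.95, min_gap = 10,
                            seed = 1L, max_restarts = 200L) {
  F <- as.matrix(F)
  Fv <- F[, colSums(is.na(F)) == 0L, drop = FALSE]
  if (ncol(Fv) == 0) stop("no fully valid columns in F", call. = FALSE)
  k <- estimate_rank(Fv, strategy = strategy, tau = tau, min_gap = min_gap)
  if (k == 0L) stop("feature matrix has effective rank 0", call. = FALSE)
  rank_of <- function(rows) {
    estimate_rank(Fv[rows, , drop = FALSE], strategy = strategy, tau = tau,
                  min_gap = min_gap)
  }
  if (k == nrow(Fv)) {
    rows <- seq_len(nrow(Fv))
    stopifnot(rank_of(rows) == k)
    return(structure(rows, rank = k))
  }
  # pivoted QR of t(F): pivots order rows by how much new span they add
  piv <- qr(t(Fv), LAPACK = TRUE)$pivot
  cand <- sort(piv[seq_len(k)])
  if (rank_of(cand) == k) return(structure(cand, rank = k))
  best <- cand
  best_rank <- rank_of(cand)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (t in seq_len(max_restarts)) {
    rows <- sort(sample(nrow(Fv), k))
    r <- rank_of(rows)
    if (r == k) return(structure(rows, rank = k))
    if (r > best_rank) {
      best <- rows
      best_rank <- r
    }
  }
  rlang::abort(
    sprintf("no %d-row submatrix of effective rank %d found in %d restarts (best: rank %d, rows %s)",
            k, k, max_restarts, best_rank, paste(best, collapse = ",")),
    class = "catrace_reduce_failure", best_rows = best, best_rank = best_rank)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
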