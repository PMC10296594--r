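# Synthetic labeled C-alpha traces: ideal alpha-helices, antiparallel
# beta-hairpins with pairable partners, and random coils, generated from
# internal coordinates (NeRF-style chain extension) so every stage of the
# classifier can be exercised fully offline.  All randomness is seeded.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Build chain coordinates from internal coordinates
#'
#' NeRF-style extension: residue `k` is placed at bond length
#' `bonds[k-1]` from residue `k-1`, with interior angle `angles[k-2]` at
#' residue `k-1` and torsion `torsions[k-3]` over residues
#' `k-3, k-2, k-1, k` (IUPAC sign).  Measuring the built chain reproduces
#' the inputs.
#'
#' @param bonds Bond lengths, Angstroms (`n-1` values, all positive).
#' @param angles Interior angles, degrees (`n-2` values).
#' @param torsions Torsions, degrees (`n-3` values).
#' @return An `n x 3` coordinate matrix.
#' @export
build_from_internal <- function(bonds, angles = numeric(0),
                                torsions = numeric(0)) {
  n <- length(bonds) + 1L
  if (any(bonds <= 0)) stop("bond lengths must be positive", call. = FALSE)
  if (length(angles) != max(0L, n - 2L) || length(torsions) != max(0L, n - 3L)) {
    stop("need n-1 bonds, n-2 angles, n-3 torsions", call. = FALSE)
  }
  xyz <- matrix(0, n, 3)
  if (n >= 2) xyz[2, ] <- c(bonds[1], 0, 0)
  if (n >= 3) {
    th <- angles[1] / RAD2DEG
    xyz[3, ] <- xyz[2, ] + bonds[2] * c(-cos(th), sin(th), 0)
  }
  if (n >= 4) {
    for (k in 4:n) {
      A <- xyz[k - 3, ]; B <- xyz[k - 2, ]; C <- xyz[k - 1, ]
      b <- bonds[k - 1]
      th <- angles[k - 2] / RAD2DEG
      ph <- torsions[k - 3] / RAD2DEG
      bc <- C - B; bc <- bc / vec_norm(bc)
      nrm <- vec_cross(B - A, bc); nrm <- nrm / vec_norm(nrm)
      m <- vec_cross(nrm, bc)
      d <- b * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
      xyz[k, ] <- C + d[1] * bc + d[2] * m + d[3] * nrm
    }
  }
  xyz
}

add_jitter <- function(xyz, jitter_sd) {
  if (jitter_sd > 0) {
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sd), ncol = 3)
  }
  xyz
}

#' Ideal alpha-helix trace
#'
#' C-alpha atoms on a right-handed circular helix: default radius 2.3
#' Angstroms, rise 1.5 Angstroms per residue, 100 degrees of twist per
#' residue, which gives a consecutive C-alpha distance of about 3.83
#' Angstroms and `dist(i, i+3)` of about 5.05 Angstroms.
#'
#' @param n Number of residues (`>= 1`).
#' @param radius,rise,twist Helix parameters (Angstroms, Angstroms/residue,
#'   degrees/residue).
#' @param jitter_sd Isotropic Gaussian coordinate noise, Angstroms.
#' @param seed Seed for the jitter.
#' @return A [ca_trace] with all-`H` truth in `sse`.
#' @export
make_helix <- function(n, radius = 2.3, rise = 1.5, twist = 100,
                       jitter_sd = 0, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  t <- seq_len(n) - 1
  w <- twist / RAD2DEG
  xyz <- cbind(radius * cos(w * t), radius * sin(w * t), rise * t)
  xyz <- with_seed(seed, add_jitter(xyz, jitter_sd))
  ca_trace(xyz, sse = "H", source_id = "synthetic-helix")
}

strand_coords <- function(n) {
  torsions <- 170 * (-1)^(seq_len(max(0, n - 3)) - 1)
  build_from_internal(rep(3.8, n - 1), rep(123, max(0, n - 2)), torsions)
}

#' Extended beta-strand trace
#'
#' Built from internal coordinates (bond 3.8 Angstroms, angle 123
#' degrees, torsions alternating +/-170 degrees), approximating a pleated
#' extended chain.
#' @inheritParams make_helix
#' @return A [ca_trace] with all-`E` truth.
#' @export
make_strand <- function(n, jitter_sd = 0, seed = NULL) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  xyz <- with_seed(seed, add_jitter(strand_coords(n), jitter_sd))
  ca_trace(xyz, sse = "E", source_id = "synthetic-strand")
}

#' Random-coil trace
#'
#' Internal coordinates drawn uniformly (angle in `[85, 140]` degrees,
#' torsion in `[-180, 180]`), rejecting self-intersecting chains (any
#' non-local C-alpha pair closer than 3.5 Angstroms) for up to
#' `retries` draws; the best draw is kept if none passes.
#' @inheritParams make_helix
#' @param retries Self-intersection rejection budget.
#' @return A [ca_trace] with all-`L` truth.
#' @export
make_coil <- function(n, jitter_sd = 0, seed = NULL, retries = 100) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    best_sep <- -Inf
    for (t in seq_len(retries)) {
      xyz <- build_from_internal(rep(3.8, n - 1),
                                 stats::runif(max(0, n - 2), 85, 140),
                                 stats::runif(max(0, n - 3), -180, 180))
      sep <- min_nonlocal_dist(xyz)
      if (sep > best_sep) {
        best <- xyz
        best_sep <- sep
      }
      if (sep >= 3.5) break
    }
    ca_trace(add_jitter(best, jitter_sd), sse = "L",
             source_id = "synthetic-coil")
  })
}

min_nonlocal_dist <- function(xyz) {
  n <- nrow(xyz)
  if (n < 4) return(Inf)
  d <- as.matrix(stats::dist(xyz))
  mask <- abs(row(d) - col(d)) >= 3
  if (!any(mask)) Inf else min(d[mask])
}

# rotate a strand so its principal axis is +x and its pleat lies in z
align_strand <- function(xyz) {
  xyz <- sweep(xyz, 2, xyz[1, ])
  cen <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(cen)$v
  if (det(v) < 0) v[, 3] <- -v[, 3]
  xyz <- xyz %*% v          # principal axis -> x
  if (xyz[nrow(xyz), 1] < 0) xyz[, 1:2] <- -xyz[, 1:2]
  yz <- xyz[, 2:3, drop = FALSE]
  pc <- svd(sweep(yz, 2, colMeans(yz)))$v[, 1]   # dominant off-axis direction
  g <- atan2(pc[1], pc[2])                       # angle from z
  rot <- matrix(c(cos(g), -sin(g), sin(g), cos(g)), 2, 2)
  xyz[, 2:3] <- yz %*% rot
  xyz
}

#' Antiparallel beta-hairpin trace
#'
#' Two registered antiparallel strands of `n_per_strand` residues joined
#' by a two-residue turn.  The second strand is a translated copy of the
#' first (offset `separation` across and `register_offset` along the
#' strand axis) traversed in the reverse direction, so every interior
#' strand residue has a cross-strand partner at
#' `sqrt(separation^2 + register_offset^2)` Angstroms -- inside the
#' 6.31-Angstrom neighborhood cutoff at the default spacing.
#'
#' @param n_per_strand Residues per strand (`>= 3`).
#' @param separation Inter-strand distance, Angstroms.
#' @param register_offset Shift of the second strand along the strand
#'   axis, Angstroms (avoids degenerate exactly-at-the-endpoint
#'   projections).
#' @inheritParams make_helix
#' @return A [ca_trace] of `2 * n_per_strand + 2` residues with truth
#'   `E...E, L, L, E...E`.
#' @export
make_hairpin <- function(n_per_strand, separation = 4.8,
                         register_offset = 0.5, jitter_sd = 0, seed = NULL) {
  n <- n_per_strand
  if (n < 3) stop("n_per_strand must be >= 3", call. = FALSE)
  s1 <- align_strand(strand_coords(n))
  s2 <- sweep(s1, 2, c(register_offset, separation, 0), "+")
  s2 <- s2[rev(seq_len(n)), , drop = FALSE]
  e <- s1[n, ]
  f <- s2[1, ]
  t1 <- e + c(2.2, 0.25 * (f[2] - e[2]), 0.25 * (f[3] - e[3]))
  t2 <- e + c(3.0, 0.75 * (f[2] - e[2]), 0.75 * (f[3] - e[3]))
  xyz <- rbind(s1, t1, t2, s2)
  xyz <- with_seed(seed, add_jitter(xyz, jitter_sd))
  ca_trace(xyz, sse = c(rep("E", n), "L", "L", rep("E", n)),
           source_id = "synthetic-hairpin")
}

segment_builders <- function(kind, len) {
  switch(kind,
         helix = trace_coords(make_helix(len)),
         strand = strand_coords(len),
         coil = trace_coords(make_coil(len)),   # uses current RNG state
         hairpin = trace_coords(make_hairpin(len)),
         stop(sprintf("unknown segment kind '%s'", kind), call. = FALSE))
}

segment_labels <- function(kind, len) {
  switch(kind,
         helix = rep("H", len),
         strand = rep("E", len),
         coil = rep("L", len),
         hairpin = c(rep("E", len), "L", "L", rep("E", len)))
}

#' Assemble a synthetic protein from labeled segments
#'
#' Segments (helix / strand / coil / hairpin) are generated individually
#' and concatenated: each new segment is given a random orientation and
#' attached 3.8 Angstroms from the previous terminus, rejecting joins
#' that fold back sharply or clash with the existing chain.  Truth labels
#' come from the segment kinds.  `length` is residues per segment (per
#' strand, for hairpins, which contribute `2 * length + 2` residues).
#'
#' @param segments A data frame with columns `kind` (helix, strand, coil,
#'   hairpin) and `length`.
#' @param jitter_sd Gaussian coordinate noise applied to the assembled
#'   chain, Angstroms.
#' @param seed Seed fixing all randomness (coil draws, joins, jitter).
#' @return A [ca_trace] with truth labels in `sse`.
#' @export
make_protein <- function(segments, jitter_sd = 0, seed = 1) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("kind", "length") %in% names(segments)))
  with_seed(seed, {
    coords <- NULL
    labels <- character(0)
    for (s in seq_len(nrow(segments))) {
      seg <- segment_builders(segments$kind[s], segments$length[s])
      labels <- c(labels, segment_labels(segments$kind[s], segments$length[s]))
      if (is.null(coords)) {
        coords <- seg
        next
      }
      coords <- attach_segment(coords, seg)
    }
    ca_trace(add_jitter(coords, jitter_sd), sse = labels,
             source_id = "synthetic-protein")
  })
}

attach_segment <- function(coords, seg, tries = 60) {
  n0 <- nrow(coords)
  prev <- coords[n0, ]
  prev_bond <- coords[n0 - 1, ] - prev
  best <- NULL
  best_sep <- -Inf
  for (t in seq_len(tries)) {
    d <- stats::rnorm(3)
    d <- d / vec_norm(d)
    ang <- vector_angle(prev_bond, d)
    if (ang < 85 || ang > 140) next
    rot <- random_rotation()
    t0 <- prev + 3.8 * d
    s2 <- sweep(seg, 2, seg[1, ]) %*% t(rot)
    s2 <- sweep(s2, 2, t0, "+")
    ang2 <- interior_angle(prev, t0, s2[2, ])
    if (ang2 < 70 || ang2 > 160) next
    sep <- min_cross_dist(coords[seq_len(max(1, n0 - 1)), , drop = FALSE],
                          s2[-1, , drop = FALSE])
    if (sep > best_sep) {
      best <- s2
      best_sep <- sep
    }
    if (sep >= 3.2) break
  }
  if (is.null(best)) {
    # no orientation passed the angle screens: extend straight ahead
    t0 <- prev - 3.8 * prev_bond / vec_norm(prev_bond)
    best <- sweep(sweep(seg, 2, seg[1, ]), 2, t0, "+")
  }
  rbind(coords, best)
}

min_cross_dist <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Generate a corpus of synthetic proteins
#'
#' Each protein is helix / coil / hairpin / coil / helix with segment
#' lengths drawn per protein from fixed ranges (helices 8-16 and 6-12,
#' coils 4-8, hairpin strands 5-9 residues), mixing all three structure
#' classes in every chain.
#'
#' @param n Number of proteins.
#' @param seed Master seed; protein `p` uses `seed * 1000 + p`.
#' @param jitter_sd Coordinate noise, Angstroms (default 0.1).
#' @return A list of [ca_trace] objects with truth labels.
#' @export
make_protein_corpus <- function(n, seed = 1, jitter_sd = 0.1) {
  lapply(seq_len(n), function(p) {
    sp <- (seed %% 1e6) * 1000 + p  # derived seeds stay well under 2^31
    lens <- with_seed(sp, c(sample(8:16, 1), sample(4:8, 1), sample(5:9, 1),
                            sample(4:8, 1), sample(6:12, 1)))
    tr <- make_protein(
      data.frame(kind = c("helix", "coil", "hairpin", "coil", "helix"),
                 length = lens),
      jitter_sd = jitter_sd, seed = sp + 500000L)
    attr(tr, "source_id") <- sprintf("synthetic-%03d", p)
    tr
  })
}
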