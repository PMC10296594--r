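# Independent oracles used to freeze expected values: these deliberately
# use different formulations than the package implementation.

# points of an ideal circular helix
helix_points <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  t <- seq_len(n) - 1
  w <- twist * pi / 180
  cbind(radius * cos(w * t), radius * sin(w * t), rise * t)
}

# chord length between residues k apart on the ideal helix (closed form)
helix_chord <- function(k, radius = 2.3, rise = 1.5, twist = 100) {
  w <- twist * pi / 180
  sqrt((2 * radius * sin(k * w / 2))^2 + (k * rise)^2)
}

# interior angle from the three side lengths (law of cosines)
angle_from_sides <- function(a, b, c) {
  acos((a^2 + b^2 - c^2) / (2 * a * b)) * 180 / pi
}

# dihedral via explicit plane normals: unsigned acos plus a separate
# orientation test (different route than the implementation's atan2)
oracle_torsion <- function(p1, p2, p3, p4) {
  n1 <- pracma::cross(p2 - p1, p3 - p2)
  n2 <- pracma::cross(p3 - p2, p4 - p3)
  ang <- acos(min(1, max(-1, sum(n1 * n2) /
                           sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
  s <- sign(sum(pracma::cross(n1, n2) * (p3 - p2)))
  if (s == 0) s <- 1
  s * ang
}

# least-squares residual norm min_x ||w - B x|| via QR
lsq_residual <- function(w, B) {
  fit <- lm.fit(as.matrix(B), w)
  sqrt(sum(fit$residuals^2))
}

# random matrix with orthonormal columns
random_orthonormal <- function(n, k) {
  qr.Q(qr(matrix(rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}

# brute-force double-loop reimplementation of the neighborhood rules
brute_neighbors <- function(trace, i) {
  xyz <- cbind(trace$x, trace$y, trace$z)
  n <- nrow(trace)
  if (i <= 1 || i >= n) return(NULL)
  d <- diff(trace$seq_num)
  step <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  brk <- d != 1L | step <= 2.0 | step >= 4.5
  if (brk[i - 1] || brk[i]) return(NULL)
  cand <- c()
  for (k in seq_len(n)) {
    if (abs(trace$seq_num[k] - trace$seq_num[i]) < 3) next
    if (sqrt(sum((xyz[k, ] - xyz[i, ])^2)) >= 6.31) next
    cand <- c(cand, k)
  }
  keep <- c()
  for (k in cand) {
    others <- setdiff(cand, k)
    if (any(abs(trace$seq_num[others] - trace$seq_num[k]) == 1)) {
      keep <- c(keep, k)
    }
  }
  final <- c()
  a <- xyz[i - 1, ]; b <- xyz[i + 1, ]
  for (k in keep) {
    t <- sum((xyz[k, ] - a) * (b - a)) / sum((b - a)^2)
    foot <- a + t * (b - a)
    if (sqrt(sum((xyz[k, ] - foot)^2)) < 5.81 && t >= 0 && t <= 1) {
      final <- c(final, k)
    }
  }
  sort(final)
}

# one PDB ATOM line with controllable altloc/icode/occupancy
atom_line <- function(serial, resname, chain, seqnum, x, y, z,
                      name = " CA ", altloc = " ", icode = " ", occ = 1) {
  sprintf("ATOM  %5d %4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, name, altloc, resname, chain, seqnum, icode, x, y, z,
          occ, 0)
}
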