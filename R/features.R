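# The 39-dimensional geometric descriptor computed per residue from the
# C-alpha trace alone.  Seven blocks:
#   R (3)  interior pseudo bond angles around residue i
#   E (4)  Euclidean distances to residues i-3, i-2, i+2, i+3
#   D (8)  distances measured on virtual axes through flanking residues
#   V (4)  angles between chords of the trace
#   T (4)  pseudo torsion angles over four consecutive residues
#   M (5)  residue-type code + elementwise V+T sums
#   N (11) neighborhood block (beta-pairing geometry)
# Elements whose supporting residues are missing or span a chain break are
# NA (the validity mask).  Angles in degrees, distances in Angstroms.

# offsets (relative to i) each element needs as a contiguous stretch
FEATURE_SPAN <- list(
  ang_c = c(-1, 1), ang_m = c(-2, 0), ang_p = c(0, 2),
  d_m3 = c(-3, 0), d_m2 = c(-2, 0), d_p2 = c(0, 2), d_p3 = c(0, 3),
  axd_m2_m1 = c(-2, 1), axd_i_p1 = c(-2, 1), axd2_i_p1 = c(-2, 2),
  axd_m1_i = c(-1, 2), axd2_m1_i = c(-3, 1), axd_p1_p2 = c(-1, 2),
  axd_m3_m2 = c(-3, 0), axd_p2_p3 = c(0, 3),
  vang_1 = c(-2, 1), vang_2 = c(-1, 2), vang_3 = c(-3, 0), vang_4 = c(0, 3),
  tors_1 = c(-2, 1), tors_2 = c(-1, 2), tors_3 = c(-3, 0), tors_4 = c(0, 3),
  aa_code = c(0, 0), vt_1 = c(-2, 1), vt_2 = c(-1, 2), vt_3 = c(-3, 0),
  vt_4 = c(0, 3)
)

NBR_NAMES <- c("nb_count", "nb_eig1", "nb_eig2", "nb_eig3", "nb_dist",
               "nb_seqdiff", "nb_d_mm", "nb_d_mp", "nb_d_pm", "nb_d_pp",
               "nb_angle")

# axis table for the D block: axis endpoints (offsets), measured points and
# whether each is projected onto the axis first
AXIS_TABLE <- list(
  axd_m2_m1 = list(axis = c(-2, 1), from = -2, to = -1, pf = FALSE, pt = TRUE),
  axd_i_p1  = list(axis = c(-2, 1), from = 0,  to = 1,  pf = TRUE,  pt = FALSE),
  axd2_i_p1 = list(axis = c(-2, 2), from = 0,  to = 1,  pf = TRUE,  pt = TRUE),
  axd_m1_i  = list(axis = c(-1, 2), from = -1, to = 0,  pf = FALSE, pt = TRUE),
  axd2_m1_i = list(axis = c(-3, 1), from = -1, to = 0,  pf = TRUE,  pt = TRUE),
  axd_p1_p2 = list(axis = c(-1, 2), from = 1,  to = 2,  pf = TRUE,  pt = FALSE),
  axd_m3_m2 = list(axis = c(-3, 0), from = -3, to = -2, pf = FALSE, pt = TRUE),
  axd_p2_p3 = list(axis = c(0, 3),  from = 2,  to = 3,  pf = TRUE,  pt = FALSE)
)

#' Canonical names of the 39 descriptor elements, in order
#' @return Character vector of length 39.
#' @export
feature_names <- function() c(names(FEATURE_SPAN), NBR_NAMES)

NEIGHBOR_CAND_DIST <- 6.31
NEIGHBOR_FINAL_DIST <- 5.81
MIN_SEQ_SEPARATION <- 3L

#' Neighborhood block of the residue descriptor
#'
#' Finds the spatial neighbors of residue `i` that look like beta-pairing
#' partners: residues at least three sequence positions away and closer
#' than 6.31 Angstroms form a candidate list, pruned to candidates that
#' have a sequence-adjacent fellow candidate, and finally filtered to
#' those whose C-alpha lies within 5.81 Angstroms of the segment between
#' residues `i-1` and `i+1` with the perpendicular foot inside the
#' segment.  From the final list the block reports the neighbor count, the
#' singular values of the centered neighbor point cloud, the distance and
#' signed sequence offset to the closest neighbor `j`, four cross
#' distances between the flanks of `i` and `j`, and the angle between the
#' two flank chords.
#'
#' An empty final list yields the all-zero sentinel (still valid); a
#' terminus (no `i-1`/`i+1`) yields an all-`NA` block.
#'
#' @param trace A [ca_trace].
#' @param i Residue row index (1-based).
#' @return A list with `values` (named numeric of length 11) and
#'   `neighbors` (integer row indices of the final list).
#' @export
neighborhood_features <- function(trace, i) {
  n <- nrow(trace)
  brk <- trace_break_after(trace)
  vals <- stats::setNames(rep(NA_real_, 11L), NBR_NAMES)
  if (!trace_contiguous(brk, n, i - 1L, i + 1L)) {
    return(list(values = vals, neighbors = integer(0)))
  }
  xyz <- trace_coords(trace)
  di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
  sep <- abs(trace$seq_num - trace$seq_num[i])
  cand <- which(sep >= MIN_SEQ_SEPARATION & di < NEIGHBOR_CAND_DIST)
  # keep candidates having a sequence-adjacent fellow candidate (one pass)
  if (length(cand)) {
    sn <- trace$seq_num[cand]
    keep <- vapply(seq_along(cand), function(k) {
      any(abs(sn - sn[k]) == 1L)
    }, logical(1))
    cand <- cand[keep]
  }
  final <- integer(0)
  for (k in cand) {
    psd <- point_segment_distance(xyz[k, ], xyz[i - 1L, ], xyz[i + 1L, ])
    if (psd$distance < NEIGHBOR_FINAL_DIST && psd$inside) final <- c(final, k)
  }
  if (!length(final)) {
    vals[] <- 0
    return(list(values = vals, neighbors = integer(0)))
  }
  cloud <- t(xyz[final, , drop = FALSE])            # 3 x n
  cloud <- cloud - rowMeans(cloud)
  sv <- svd(cloud, nu = 0, nv = 0)$d
  sv <- c(sv, 0, 0, 0)[1:3]
  j <- final[which.min(di[final])]
  vals["nb_count"] <- length(final)
  vals[c("nb_eig1", "nb_eig2", "nb_eig3")] <- sv
  vals["nb_dist"] <- di[j]
  vals["nb_seqdiff"] <- trace$seq_num[i] - trace$seq_num[j]
  has_jm <- trace_contiguous(brk, n, j - 1L, j)
  has_jp <- trace_contiguous(brk, n, j, j + 1L)
  ed <- function(a, b) vec_norm(xyz[a, ] - xyz[b, ])
  if (has_jm) {
    vals["nb_d_mm"] <- ed(i - 1L, j - 1L)
    vals["nb_d_pm"] <- ed(i + 1L, j - 1L)
  }
  if (has_jp) {
    vals["nb_d_mp"] <- ed(i - 1L, j + 1L)
    vals["nb_d_pp"] <- ed(i + 1L, j + 1L)
  }
  if (has_jm && has_jp) {
    vals["nb_angle"] <- vector_angle(xyz[i + 1L, ] - xyz[i - 1L, ],
                                     xyz[j + 1L, ] - xyz[j - 1L, ])
  }
  list(values = vals, neighbors = sort(final))
}

#' Descriptor of one residue
#'
#' The 39 elements in canonical order (see [feature_names()]); elements
#' whose supporting residues are missing or span a chain break are `NA`.
#'
#' @param trace A [ca_trace].
#' @param i Residue row index (1-based).
#' @return Named numeric vector of length 39.
#' @export
compute_feature_vector <- function(trace, i) {
  compute_feature_matrix(trace)[, i]
}

feature_vector_impl <- function(trace, i, xyz, brk) {
  n <- nrow(trace)
  p <- function(off) xyz[i + off, ]
  ok <- function(name) {
    sp <- FEATURE_SPAN[[name]]
    trace_contiguous(brk, n, i + sp[1], i + sp[2])
  }
  safe <- function(name, expr) {
    if (!ok(name)) return(NA_real_)
    tryCatch(expr, catrace_invalid_geometry = function(e) NA_real_)
  }
  v <- stats::setNames(rep(NA_real_, 28L), names(FEATURE_SPAN))
  v["ang_c"] <- safe("ang_c", interior_angle(p(-1), p(0), p(1)))
  v["ang_m"] <- safe("ang_m", interior_angle(p(-2), p(-1), p(0)))
  v["ang_p"] <- safe("ang_p", interior_angle(p(0), p(1), p(2)))
  v["d_m3"] <- safe("d_m3", vec_norm(p(-3) - p(0)))
  v["d_m2"] <- safe("d_m2", vec_norm(p(-2) - p(0)))
  v["d_p2"] <- safe("d_p2", vec_norm(p(2) - p(0)))
  v["d_p3"] <- safe("d_p3", vec_norm(p(3) - p(0)))
  for (nm in names(AXIS_TABLE)) {
    ax <- AXIS_TABLE[[nm]]
    v[nm] <- safe(nm, axis_distance(p(ax$axis[1]), p(ax$axis[2]),
                                    p(ax$from), p(ax$to), ax$pf, ax$pt))
  }
  v["vang_1"] <- safe("vang_1", vector_angle(p(0) - p(-2), p(1) - p(-1)))
  v["vang_2"] <- safe("vang_2", vector_angle(p(1) - p(-1), p(2) - p(0)))
  v["vang_3"] <- safe("vang_3", vector_angle(p(-1) - p(-3), p(0) - p(-2)))
  v["vang_4"] <- safe("vang_4", vector_angle(p(2) - p(0), p(3) - p(1)))
  v["tors_1"] <- safe("tors_1", torsion_angle(p(-2), p(-1), p(0), p(1)))
  v["tors_2"] <- safe("tors_2", torsion_angle(p(-1), p(0), p(1), p(2)))
  v["tors_3"] <- safe("tors_3", torsion_angle(p(-3), p(-2), p(-1), p(0)))
  v["tors_4"] <- safe("tors_4", torsion_angle(p(0), p(1), p(2), p(3)))
  v["aa_code"] <- match(trace$aa[i], AA3) - 1
  for (k in 1:4) {
    v[paste0("vt_", k)] <- v[paste0("vang_", k)] + v[paste0("tors_", k)]
  }
  c(v, neighborhood_features(trace, i)$values)
}

#' Descriptor matrix of a whole trace
#'
#' @param trace A [ca_trace].
#' @return A 39 x N numeric matrix, one column per residue, rows named by
#'   [feature_names()]; `NA` marks masked elements.
#' @export
compute_feature_matrix <- function(trace) {
  xyz <- trace_coords(trace)
  brk <- trace_break_after(trace)
  m <- vapply(seq_len(nrow(trace)),
              function(i) feature_vector_impl(trace, i, xyz, brk),
              numeric(39L))
  rownames(m) <- feature_names()
  colnames(m) <- as.character(trace$seq_num)
  m
}

#' Tidy per-residue descriptor table
#'
#' @param trace A [ca_trace] (an `sse` column, if present, is carried
#'   through as the `label` column).
#' @return A tibble with `source_id`, `chain`, `seq_num`, `aa`, `label`
#'   and the 39 descriptor columns.
#' @export
ca_features <- function(trace) {
  m <- compute_feature_matrix(trace)
  out <- tibble::tibble(source_id = trace_source_id(trace),
                        chain = trace$chain, seq_num = trace$seq_num,
                        aa = trace$aa,
                        label = trace$sse %||% NA_character_)
  dplyr::bind_cols(out, tibble::as_tibble(t(m)))
}

#' Write / read the descriptor table as TSV
#'
#' Masked entries are serialized as `NA`.
#' @param features Tibble from [ca_features()].
#' @param path Output file; `NULL` returns text.
#' @return TSV text (invisibly when written to a file).
#' @export
write_features_tsv <- function(features, path = NULL) {
  txt <- readr::format_tsv(features)
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  invisible(txt)
}

#' @rdname write_features_tsv
#' @param x Path or TSV text.
#' @export
read_features_tsv <- function(x) {
  readr::read_tsv(if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) x else I(x),
                  col_types = readr::cols(
                    source_id = readr::col_character(),
                    chain = readr::col_character(),
                    aa = readr::col_character(),
                    label = readr::col_character(),
                    .default = readr::col_double()))
}

# 39 x N matrix from a ca_features() tibble (inverse of ca_features layout)
features_to_matrix <- function(features) {
  m <- t(as.matrix(features[, feature_names()]))
  colnames(m) <- as.character(features$seq_num)
  m
}
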