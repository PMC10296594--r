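# Rule-based correction of predicted labels using the neighborhood block
# of the descriptor.  The five "close distances" of a residue are
# nb_dist plus the four flank cross distances; a residue with an empty
# neighbor list has no distance values, so its close count is zero.

#' Post-processing configuration
#'
#' Thresholds for the correction rules, in the order they are applied:
#' \enumerate{
#'   \item H with `neighbor_count > helix_fix_min_neighbors`: relabeled L
#'     when fewer than 3 of its 5 neighborhood distances are below
#'     `dist_threshold`, otherwise E (high compactness marks a strand).
#'   \item L with `neighbor_count > loop_to_sheet_min_neighbors` and more
#'     than `loop_to_sheet_min_close` close distances: relabeled E.
#'   \item L with `neighbor_count < loop_to_helix_max_neighbors` and
#'     exactly `loop_to_helix_close_count` close distances: relabeled H.
#'   \item Unresolved (`U`) labels inherit the nearest resolved label
#'     (ties go left), so the smoothing below sees final labels.
#'   \item Isolated residues (run of length 1 with at least `flank`
#'     same-labeled residues on each side, both sides agreeing): flipped
#'     to the flanking label.
#' }
#'
#' @param dist_threshold Closeness cutoff, Angstroms (strict `<`).
#' @param helix_fix_min_neighbors,loop_to_sheet_min_neighbors,
#'   loop_to_helix_max_neighbors,loop_to_sheet_min_close,
#'   loop_to_helix_close_count Neighbor/close-count thresholds as above.
#' @param flank Residues required on each side for isolation.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(dist_threshold = 6,
                               helix_fix_min_neighbors = 2,
                               loop_to_sheet_min_neighbors = 4,
                               loop_to_sheet_min_close = 2,
                               loop_to_helix_max_neighbors = 3,
                               loop_to_helix_close_count = 5,
                               flank = 2) {
  stopifnot(dist_threshold > 0)
  structure(list(dist_threshold = dist_threshold,
                 helix_fix_min_neighbors = helix_fix_min_neighbors,
                 loop_to_sheet_min_neighbors = loop_to_sheet_min_neighbors,
                 loop_to_sheet_min_close = loop_to_sheet_min_close,
                 loop_to_helix_max_neighbors = loop_to_helix_max_neighbors,
                 loop_to_helix_close_count = loop_to_helix_close_count,
                 flank = as.integer(flank)),
            class = "postprocess_config")
}

#' Apply the label-correction rules
#'
#' @param labels Character labels over `c("H","E","L","U")` (a vector or
#'   an `sse_prediction` tibble, whose `label` column is used and
#'   replaced).
#' @param features The matching [ca_features()] tibble (only the
#'   neighborhood columns are used).
#' @param cfg A [postprocess_config()].
#' @return Corrected labels, same shape as `labels`.
#' @export
postprocess_labels <- function(labels, features, cfg = postprocess_config()) {
  tab <- NULL
  if (is.data.frame(labels)) {
    tab <- labels
    labels <- tab$label
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  nc <- features$nb_count
  close <- close_distance_count(features, cfg$dist_threshold)
  n <- length(labels)

  for (i in seq_len(n)) {
    if (is.na(nc[i])) next
    if (labels[i] == "H" && nc[i] > cfg$helix_fix_min_neighbors) {
      labels[i] <- if (close[i] < 3) "L" else "E"
    } else if (labels[i] == "L" && nc[i] > cfg$loop_to_sheet_min_neighbors &&
               close[i] > cfg$loop_to_sheet_min_close) {
      labels[i] <- "E"
    } else if (labels[i] == "L" && nc[i] < cfg$loop_to_helix_max_neighbors &&
               close[i] == cfg$loop_to_helix_close_count) {
      labels[i] <- "H"
    }
  }

  if (any(labels == "U") && any(labels != "U")) {
    resolved <- which(labels != "U")
    for (i in which(labels == "U")) {
      labels[i] <- labels[resolved[which.min(abs(resolved - i))]]
    }
  }

  f <- cfg$flank
  for (i in seq_len(n)) {
    if (i - f < 1L || i + f > n) next
    left <- labels[(i - f):(i - 1L)]
    right <- labels[(i + 1L):(i + f)]
    grp <- left[1]
    if (grp != "U" && grp != labels[i] &&
        all(left == grp) && all(right == grp)) {
      labels[i] <- grp
    }
  }

  if (!is.null(tab)) {
    tab$label <- labels
    attr(tab, "method") <- paste0(attr(tab, "method") %||% "labels",
                                  "+postprocessed")
    return(tab)
  }
  new_labels(labels, "postprocessed")
}

# number of the 5 neighborhood distances strictly below the threshold;
# an empty neighbor list (nb_count == 0) has no distance values
close_distance_count <- function(features, threshold) {
  d5 <- as.matrix(features[, c("nb_dist", "nb_d_mm", "nb_d_mp",
                               "nb_d_pm", "nb_d_pp")])
  cnt <- rowSums(d5 < threshold, na.rm = TRUE)
  cnt[!is.na(features$nb_count) & features$nb_count == 0] <- 0
  cnt
}
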