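# The ca_trace container: a tibble with one row per residue of a single
# protein chain, carrying the C-alpha coordinate and residue metadata.
# Columns: chain, seq_num, aa (3-letter code), x, y, z, and optionally a
# truth label column `sse` (H/E/L).  Attributes: source_id, has_break.

#' Standard amino acids, alphabetical by 3-letter code
#'
#' The residue-type feature encodes the amino acid as its 0-based index in
#' this vector.
#' @export
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Construct a C-alpha trace
#'
#' Builds the per-residue tibble used throughout the package from raw
#' coordinates.  Consecutive C-alpha distances outside `(2.0, 4.5)`
#' Angstroms, or gaps in `seq_num`, mark the trace as containing a chain
#' break (descriptor elements spanning a break are masked downstream).
#'
#' @param xyz Numeric matrix, one row per residue, 3 columns.
#' @param seq_num Integer residue sequence numbers, strictly increasing.
#'   Default `1:n`.
#' @param aa 3-letter amino-acid codes (recycled if length 1).
#' @param chain Chain identifier (single character).
#' @param source_id Identifier stored as an attribute and echoed in
#'   prediction tables.
#' @param sse Optional per-residue truth labels over `c("H","E","L")`.
#' @return A `ca_trace` tibble.
#' @export
ca_trace <- function(xyz, seq_num = NULL, aa = "ALA", chain = "A",
                     source_id = "trace", sse = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L)
  n <- nrow(xyz)
  if (n < 1L) stop("a ca_trace needs at least one residue", call. = FALSE)
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (is.null(seq_num)) seq_num <- seq_len(n)
  seq_num <- as.integer(seq_num)
  if (any(diff(seq_num) <= 0L)) {
    stop("seq_num must be strictly increasing", call. = FALSE)
  }
  aa <- rep_len(as.character(aa), n)
  bad <- setdiff(unique(aa), AA3)
  if (length(bad)) {
    stop(sprintf("non-standard amino acid code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(chain = as.character(chain), seq_num = seq_num,
                        aa = aa, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  if (!is.null(sse)) {
    sse <- rep_len(as.character(sse), n)
    stopifnot(all(sse %in% c("H", "E", "L")))
    out$sse <- sse
  }
  new_ca_trace(out, source_id = source_id)
}

new_ca_trace <- function(df, source_id = "trace") {
  df <- tibble::as_tibble(df)
  attr(df, "source_id") <- source_id
  attr(df, "has_break") <- any(trace_break_after(df))
  class(df) <- c("ca_trace", class(df))
  df
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("# C-alpha trace `%s`: %d residues (chain %s)%s\n",
              trace_source_id(x), nrow(x), x$chain[1],
              if (isTRUE(attr(x, "has_break"))) ", contains break(s)" else ""))
  NextMethod()
}

trace_source_id <- function(trace) {
  attr(trace, "source_id") %||% "trace"
}

trace_coords <- function(trace) {
  m <- cbind(trace$x, trace$y, trace$z)
  rownames(m) <- NULL
  m
}

# Logical vector of length n-1: is there a break between row i and i+1?
# A break is a seq_num gap or a consecutive C-alpha distance outside
# (2.0, 4.5) Angstroms.
trace_break_after <- function(trace) {
  n <- nrow(trace)
  if (n < 2L) return(logical(0))
  xyz <- cbind(trace$x, trace$y, trace$z)
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  gap <- diff(trace$seq_num) != 1L
  gap | d <= 2.0 | d >= 4.5
}

# Rows lo..hi form a contiguous stretch (all inside the chain, no break).
trace_contiguous <- function(breaks_after, n, lo, hi) {
  if (lo < 1L || hi > n) return(FALSE)
  if (hi == lo) return(TRUE)
  !any(breaks_after[lo:(hi - 1L)])
}

# Apply a rigid (or improper, if rotation has det -1) motion to a trace.
transform_trace <- function(trace, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- trace_coords(trace) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  trace$x <- xyz[, 1]
  trace$y <- xyz[, 2]
  trace$z <- xyz[, 3]
  trace
}

`%||%` <- function(a, b) if (is.null(a)) b else a
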