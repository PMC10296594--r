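# PDB input/output restricted to what a C-alpha-only classifier needs:
# ATOM records (CA atoms of one chain, first MODEL only), HELIX/SHEET
# records as 3-state ground truth, and a per-residue prediction TSV.
# Column positions follow wwPDB format v3.3.

reject <- function(reason, detail) {
  rlang::abort(sprintf("%s: %s", reason, detail),
               class = "catrace_rejection", reason = reason)
}

pdb_lines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    pdb <- readLines(pdb, warn = FALSE)
  } else if (length(pdb) == 1L) {
    pdb <- strsplit(pdb, "\n", fixed = TRUE)[[1]]
  }
  # first MODEL only
  endmdl <- which(startsWith(pdb, "ENDMDL"))
  if (length(endmdl)) pdb <- pdb[seq_len(endmdl[1] - 1L)]
  pdb
}

pad80 <- function(x) formatC(x, width = -80)

#' Read the C-alpha trace of one chain from a PDB file
#'
#' Parses ATOM records of the requested chain (first model only; HETATM
#' ignored) and returns one row per residue that has a CA atom.  Alternate
#' locations are resolved by keeping altLoc `' '` or `'A'`; failing that the
#' highest-occupancy CA wins (ties: first encountered).
#'
#' Chains are rejected -- with a reason code in the condition -- when they
#' contain insertion codes (`"insertion-code"`), non-standard amino acids
#' (`"unknown-residue"`), or a residue with atoms but no CA
#' (`"missing-CA"`); a missing chain raises `"missing-chain"`.  With
#' `lenient = TRUE` the offending residues are skipped with a warning
#' instead (the resulting trace is flagged as containing breaks).
#'
#' @param pdb Path to a PDB file, or PDB-format text.
#' @param chain Chain identifier (single character).
#' @param lenient Downgrade per-residue rejections to skips.
#' @return A [ca_trace] tibble.
#' @export
read_ca_trace <- function(pdb, chain = "A", lenient = FALSE) {
  lines <- pdb_lines(pdb)
  atoms <- lines[startsWith(lines, "ATOM")]
  atoms <- pad80(atoms)
  if (!length(atoms)) reject("missing-chain", "no ATOM records in input")
  ch <- substr(atoms, 22, 22)
  atoms <- atoms[ch == chain]
  if (!length(atoms)) {
    reject("missing-chain", sprintf("no ATOM records for chain '%s'", chain))
  }
  rec <- tibble::tibble(
    name    = substr(atoms, 13, 16),
    altloc  = substr(atoms, 17, 17),
    resname = trimws(substr(atoms, 18, 20)),
    seq_num = as.integer(substr(atoms, 23, 26)),
    icode   = substr(atoms, 27, 27),
    x = as.numeric(substr(atoms, 31, 38)),
    y = as.numeric(substr(atoms, 39, 46)),
    z = as.numeric(substr(atoms, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(atoms, 55, 60)))
  )
  rec$occ[is.na(rec$occ)] <- 1

  drop_or_reject <- function(reason, detail, rows) {
    if (!lenient) reject(reason, detail)
    warning(sprintf("skipping residue(s) [%s]: %s", reason, detail),
            call. = FALSE)
    rows
  }

  drop_seq <- integer(0)
  if (any(rec$icode != " ")) {
    bad <- unique(rec$seq_num[rec$icode != " "])
    drop_seq <- c(drop_seq, drop_or_reject(
      "insertion-code",
      sprintf("insertion code at residue(s) %s", paste(bad, collapse = ",")),
      bad))
  }
  if (any(!rec$resname %in% AA3)) {
    bad <- unique(rec$seq_num[!rec$resname %in% AA3])
    drop_seq <- c(drop_seq, drop_or_reject(
      "unknown-residue",
      sprintf("non-standard residue(s) at %s", paste(bad, collapse = ",")),
      bad))
  }
  rec <- rec[!rec$seq_num %in% drop_seq, , drop = FALSE]

  seq_nums <- unique(rec$seq_num)
  has_ca <- vapply(seq_nums, function(s) {
    any(rec$name == " CA " & rec$seq_num == s)
  }, logical(1))
  if (any(!has_ca)) {
    bad <- seq_nums[!has_ca]
    drop_seq <- drop_or_reject(
      "missing-CA",
      sprintf("no CA atom for residue(s) %s", paste(bad, collapse = ",")),
      bad)
    rec <- rec[!rec$seq_num %in% drop_seq, , drop = FALSE]
    seq_nums <- setdiff(seq_nums, drop_seq)
  }
  if (!length(seq_nums)) reject("missing-CA", "no usable residues remain")

  rows <- lapply(sort(seq_nums), function(s) {
    cas <- rec[rec$name == " CA " & rec$seq_num == s, , drop = FALSE]
    pref <- cas$altloc %in% c(" ", "A")
    pick <- if (any(pref)) which(pref)[1] else which.max(cas$occ)
    cas[pick, c("seq_num", "resname", "x", "y", "z")]
  })
  df <- dplyr::bind_rows(rows)
  ca_trace(cbind(df$x, df$y, df$z), seq_num = df$seq_num, aa = df$resname,
           chain = chain, source_id = paste0("pdb:", chain))
}

#' Read 3-state truth labels from HELIX/SHEET records
#'
#' Residues covered by a HELIX record become `H`, by a SHEET record `E`,
#' all others `L`.  Any helix class (including 3-10 and pi) maps to `H`.
#' Where HELIX and SHEET overlap, HELIX wins (with a message).
#'
#' @param pdb Path to a PDB file, or PDB-format text (the same file the
#'   trace was parsed from).
#' @param trace The [ca_trace] the labels align with.
#' @param require_records Reject (reason `"missing-sse"`) when the file has
#'   no HELIX/SHEET records at all, mirroring corpus-cleaning practice.
#'   Default `FALSE`: such files yield all-loop truth.
#' @return Character vector of labels over `c("H","E","L")`, one per
#'   residue, with attribute `provenance = "truth"`.
#' @export
read_sse_labels <- function(pdb, trace, require_records = FALSE) {
  lines <- pdb_lines(pdb)
  helix <- pad80(lines[startsWith(lines, "HELIX")])
  sheet <- pad80(lines[startsWith(lines, "SHEET")])
  if (require_records && !length(helix) && !length(sheet)) {
    reject("missing-sse", "no HELIX/SHEET records in input")
  }
  chain <- trace$chain[1]
  labels <- rep("L", nrow(trace))

  fill <- function(labels, init_ch, init, end_ch, end, code) {
    for (k in seq_along(init)) {
      if (init_ch[k] != chain || end_ch[k] != chain) next
      lo <- init[k]; hi <- end[k]
      covered <- trace$seq_num >= lo & trace$seq_num <= hi
      span <- trace$seq_num[covered]
      if (!all(lo:hi %in% span)) {
        stop(sprintf("%s record %d-%d references residues absent from the trace",
                     if (code == "H") "HELIX" else "SHEET", lo, hi),
             call. = FALSE)
      }
      if (code == "H" && any(labels[covered] == "E")) {
        message("HELIX/SHEET overlap: HELIX takes precedence")
      }
      labels[covered] <- code
    }
    labels
  }
  if (length(sheet)) {
    labels <- fill(labels,
                   substr(sheet, 22, 22), as.integer(substr(sheet, 23, 26)),
                   substr(sheet, 33, 33), as.integer(substr(sheet, 34, 37)), "E")
  }
  if (length(helix)) {
    labels <- fill(labels,
                   substr(helix, 20, 20), as.integer(substr(helix, 22, 25)),
                   substr(helix, 32, 32), as.integer(substr(helix, 34, 37)), "H")
  }
  new_labels(labels, "truth")
}

new_labels <- function(x, provenance) {
  structure(as.character(x), provenance = provenance)
}

#' Read one chain and its truth labels together
#'
#' Convenience wrapper around [read_ca_trace()] and [read_sse_labels()]
#' that returns the trace with the truth in an `sse` column.
#' @inheritParams read_ca_trace
#' @inheritParams read_sse_labels
#' @return A [ca_trace] tibble with an `sse` column.
#' @export
read_pdb_chain <- function(pdb, chain = "A", lenient = FALSE,
                           require_records = FALSE) {
  trace <- read_ca_trace(pdb, chain, lenient = lenient)
  trace$sse <- as.character(read_sse_labels(pdb, trace,
                                            require_records = require_records))
  trace
}

#' Write per-residue predictions as TSV
#'
#' One row per residue: `source_id`, `chain`, `seq_num`, `aa`, `label`,
#' with a header line.
#'
#' @param trace A [ca_trace].
#' @param labels Character labels aligned with the trace.
#' @param path Output file; `NULL` returns the TSV text instead.
#' @return The TSV text (invisibly when written to a file).
#' @export
write_predictions <- function(trace, labels, path = NULL) {
  labels <- as.character(labels)
  if (length(labels) != nrow(trace)) {
    stop("labels and trace have different lengths", call. = FALSE)
  }
  tab <- tibble::tibble(source_id = trace_source_id(trace),
                        chain = trace$chain, seq_num = trace$seq_num,
                        aa = trace$aa, label = labels)
  txt <- readr::format_tsv(tab)
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  invisible(txt)
}

#' Read a prediction TSV written by [write_predictions()]
#' @param x Path or TSV text.
#' @return A tibble with columns `source_id`, `chain`, `seq_num`, `aa`,
#'   `label`.
#' @export
read_predictions <- function(x) {
  readr::read_tsv(if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) x else I(x),
                  col_types = readr::cols(
                    source_id = readr::col_character(),
                    chain = readr::col_character(),
                    seq_num = readr::col_integer(),
                    aa = readr::col_character(),
                    label = readr::col_character()))
}

#' Write a minimal C-alpha-only PDB file
#'
#' Emits ATOM records for the CA atoms plus HELIX/SHEET records derived
#' from the label runs, so generated fixtures can be consumed by the
#' package's own reader (and by other tools that accept CA-only files).
#'
#' @param trace A [ca_trace]; its `sse` column (or `labels`) provides the
#'   secondary-structure records.
#' @param path Output file; `NULL` returns the text.
#' @param labels Optional labels overriding `trace$sse`.
#' @return PDB text (invisibly when written to a file).
#' @export
write_ca_pdb <- function(trace, path = NULL, labels = NULL) {
  labels <- as.character(labels %||% trace$sse %||% rep("L", nrow(trace)))
  stopifnot(length(labels) == nrow(trace))
  chain <- trace$chain[1]
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hdr <- character(0)
  hser <- 0L; sser <- 0L
  for (k in seq_along(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (runs$values[k] == "H") {
      hser <- hser + 1L
      hdr <- c(hdr, sprintf(
        "HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d %2d%30s %5d",
        hser, sprintf("H%02d", hser), trace$aa[i0], chain, trace$seq_num[i0],
        trace$aa[i1], chain, trace$seq_num[i1], 1L, "", i1 - i0 + 1L))
    } else if (runs$values[k] == "E") {
      sser <- sser + 1L
      hdr <- c(hdr, sprintf(
        "SHEET  %3d %3s%2d %3s %1s%4d  %3s %1s%4d %2d",
        sser, sprintf("S%02d", sser), 1L, trace$aa[i0], chain,
        trace$seq_num[i0], trace$aa[i1], chain, trace$seq_num[i1], 0L))
    }
  }
  atoms <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(trace)), trace$aa, chain, trace$seq_num,
    trace$x, trace$y, trace$z, 1, 0)
  txt <- paste(c(hdr, atoms, "END"), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}
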