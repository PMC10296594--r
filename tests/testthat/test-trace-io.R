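simple_pdb <- function(extra = character(0), header = character(0)) {
  paste(c(header,
          atom_line(1, "ALA", "A", 1, 0, 0, 0),
          atom_line(2, "GLY", "A", 2, 3.8, 0, 0),
          extra,
          atom_line(4, "VAL", "A", 3, 7.6, 0, 0),
          "END"), collapse = "\n")
}

test_that("read_ca_trace parses CA atoms in residue order", {
  tr <- read_ca_trace(simple_pdb(), "A")
  expect_s3_class(tr, "ca_trace")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$seq_num, 1:3)
  expect_equal(tr$aa, c("ALA", "GLY", "VAL"))
  expect_equal(tr$x, c(0, 3.8, 7.6))
})

test_that("alternate locations keep altloc ' '/'A', else highest occupancy", {
  txt <- simple_pdb(extra = atom_line(3, "GLY", "A", 2, 9, 9, 9,
                                      altloc = "B", occ = 0.7))
  tr <- read_ca_trace(txt, "A")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$x[2], 3.8)  # altloc 'B' copy ignored

  # neither blank nor 'A': occupancy decides
  txt2 <- paste(c(atom_line(1, "ALA", "A", 1, 0, 0, 0),
                  atom_line(2, "GLY", "A", 2, 1, 1, 1, altloc = "B", occ = 0.3),
                  atom_line(3, "GLY", "A", 2, 2, 2, 2, altloc = "C", occ = 0.6),
                  atom_line(4, "VAL", "A", 3, 7.6, 0, 0)), collapse = "\n")
  tr2 <- read_ca_trace(txt2, "A")
  expect_equal(tr2$x[2], 2)
})

test_that("rejection reasons mirror the corpus-cleaning rules", {
  # residue 2 present but without a CA atom
  no_ca <- paste(c(atom_line(1, "ALA", "A", 1, 0, 0, 0),
                   atom_line(2, "GLY", "A", 2, 3.8, 0, 0, name = " N  "),
                   atom_line(3, "VAL", "A", 3, 7.6, 0, 0)), collapse = "\n")
  err <- tryCatch(read_ca_trace(no_ca, "A"), catrace_rejection = function(e) e)
  expect_equal(err$reason, "missing-CA")

  ins <- simple_pdb(extra = atom_line(3, "SER", "A", 2, 5, 0, 0, icode = "A"))
  expect_equal(tryCatch(read_ca_trace(ins, "A"),
                        catrace_rejection = function(e) e)$reason,
               "insertion-code")

  unk <- paste(c(atom_line(1, "ALA", "A", 1, 0, 0, 0),
                 atom_line(2, "MSE", "A", 2, 3.8, 0, 0),
                 atom_line(3, "VAL", "A", 3, 7.6, 0, 0)), collapse = "\n")
  expect_equal(tryCatch(read_ca_trace(unk, "A"),
                        catrace_rejection = function(e) e)$reason,
               "unknown-residue")

  expect_equal(tryCatch(read_ca_trace(simple_pdb(), "B"),
                        catrace_rejection = function(e) e)$reason,
               "missing-chain")

  no_sse <- read_ca_trace(simple_pdb(), "A")
  expect_equal(tryCatch(read_sse_labels(simple_pdb(), no_sse,
                                        require_records = TRUE),
                        catrace_rejection = function(e) e)$reason,
               "missing-sse")
})

test_that("lenient mode skips offending residues with a warning", {
  unk <- paste(c(atom_line(1, "ALA", "A", 1, 0, 0, 0),
                 atom_line(2, "MSE", "A", 2, 3.8, 0, 0),
                 atom_line(3, "VAL", "A", 3, 7.6, 0, 0)), collapse = "\n")
  expect_warning(tr <- read_ca_trace(unk, "A", lenient = TRUE),
                 "unknown-residue")
  expect_equal(tr$seq_num, c(1L, 3L))
  expect_true(attr(tr, "has_break"))
})

test_that("HELIX/SHEET records fill 3-state labels with HELIX precedence", {
  helix6 <- make_helix(6)
  body <- vapply(seq_len(6), function(i) {
    atom_line(i, "ALA", "A", i, helix6$x[i], helix6$y[i], helix6$z[i])
  }, character(1))
  hrec <- sprintf("HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d %2d%30s %5d",
                  1L, "H1", "ALA", "A", 2L, "ALA", "A", 5L, 1L, "", 4L)
  srec <- sprintf("SHEET  %3d %3s%2d %3s %1s%4d  %3s %1s%4d %2d",
                  1L, "S1", 1L, "ALA", "A", 4L, "ALA", "A", 6L, 0L)
  txt <- paste(c(hrec, body), collapse = "\n")
  tr <- read_ca_trace(txt, "A")
  expect_equal(as.character(read_sse_labels(txt, tr)),
               c("L", "H", "H", "H", "H", "L"))

  expect_equal(as.character(read_sse_labels(paste(body, collapse = "\n"), tr)),
               rep("L", 6))

  txt2 <- paste(c(hrec, srec, body), collapse = "\n")
  expect_message(lab <- read_sse_labels(txt2, tr), "HELIX takes precedence")
  expect_equal(as.character(lab), c("L", "H", "H", "H", "H", "E"))

  bad <- sprintf("HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d %2d%30s %5d",
                 1L, "H1", "ALA", "A", 5L, "ALA", "A", 9L, 1L, "", 5L)
  expect_error(read_sse_labels(paste(c(bad, body), collapse = "\n"), tr),
               "absent from the trace")
})

test_that("prediction TSV round-trips", {
  tr <- make_helix(4)
  txt <- write_predictions(tr, c("H", "H", "L", "E"))
  expect_equal(length(strsplit(txt, "\n")[[1]]), 5)  # header + 4 rows
  back <- read_predictions(txt)
  expect_equal(back$label, c("H", "H", "L", "E"))
  expect_equal(back$seq_num, 1:4)
  # idempotence through a file
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(tr, c("H", "H", "L", "E"), f)
  again <- read_predictions(f)
  expect_equal(again, back)
  expect_error(write_predictions(tr, c("H", "L")), "different lengths")
})

test_that("generated PDB files round-trip through the reader", {
  pr <- make_protein(data.frame(kind = c("helix", "coil", "hairpin"),
                                length = c(10, 5, 6)), seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(pr, f)
  back <- read_pdb_chain(f, "A")
  expect_equal(back$sse, pr$sse)
  expect_equal(back$seq_num, pr$seq_num)
  expect_equal(cbind(back$x, back$y, back$z),
               round(cbind(pr$x, pr$y, pr$z), 3))
})
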