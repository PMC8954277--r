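test_that("parse_structure keeps heavy atoms in file order and drops H/HETATM", {
  s <- parse_structure(tiny_pdb_lines())
  expect_s3_class(s, "protein_structure")
  expect_equal(nrow(s$atoms), 7)            # 8 ATOM minus 1 hydrogen
  expect_false("H" %in% s$atoms$element)
  expect_false("HOH" %in% s$atoms$residue_name)
  expect_true(all(s$atoms$element %in% c("C", "N", "O", "S")))
  expect_equal(s$sequence, "GA")
  expect_equal(s$atoms$residue_ordinal, c(1, 1, 1, 1, 2, 2, 2))
  # file order preserved: atom names appear as written
  expect_equal(s$atoms$atom_name, c("N", "CA", "C", "O", "N", "CA", "CB"))
})

test_that("parse_structure fails on input without ATOM records", {
  expect_error(parse_structure(c("HEADER    EMPTY", "END")), "ATOM")
  expect_error(parse_structure(""), "ATOM")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA AGLY A   1       1.458   0.000   0.000  0.60 12.00           C",
    "ATOM      3  CA BGLY A   1       1.458   0.500   0.000  0.40 12.00           C",
    "END")
  s <- parse_structure(lines)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$y[s$atoms$atom_name == "CA"], 0)   # altloc A kept
  # occupancy tie resolves to the first record in file order
  lines_tie <- sub("  0.60", "  0.40", lines)
  s2 <- parse_structure(lines_tie)
  expect_equal(s2$atoms$y[s2$atoms$atom_name == "CA"], 0)
})

test_that("unknown residues are retained and flagged in the sequence", {
  lines <- c(
    "ATOM      1  N   XYZ A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  XYZ A   1       1.458   0.000   0.000  1.00 12.00           C",
    "END")
  expect_warning(s <- parse_structure(lines), "unknown")
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$sequence, "X")
})

test_that("PSSM parsing reads raw scores and validates dimensions", {
  seq3 <- "ARN"
  txt <- generate_pssm(seq3, conservation = 1, seed = 5)
  p <- read_pssm(txt, 3)
  expect_equal(dim(p), c(3, 20))
  expect_equal(colnames(p), bios2net:::aa_order)
  # diagonal dominance at full conservation
  expect_true(all(p[cbind(1:3, 1:3)] > apply(p[, -(1:3)], 1, max)))
  expect_error(read_pssm(txt, 4), "expected sequence length")
  bad <- sub("^    2 R", "    2 R oops", txt[grep("^    2 R", txt)[1]])
  txt_bad <- txt
  txt_bad[grep("^    2 R", txt)[1]] <- bad
  expect_error(read_pssm(txt_bad, 3), "line")
})

test_that("missing PSSM sentinel yields a flagged zero matrix", {
  p <- read_pssm(NULL, 5)
  expect_equal(dim(p), c(5, 20))
  expect_true(all(p == 0))
  expect_true(attr(p, "synthetic_zero"))
})

test_that("point-cloud TSV round-trips and rejects malformed files", {
  cl <- random_cloud(17, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_point_cloud(cl, f)
  back <- read_point_cloud(f)
  expect_equal(back$points, cl$points, tolerance = 1e-6,
               ignore_attr = TRUE)
  # 52 columns -> error
  lines <- readLines(f)
  broken <- vapply(lines, function(l)
    sub("\t[^\t]*$", "", l), "", USE.NAMES = FALSE)
  f2 <- tempfile(); writeLines(broken, f2)
  expect_error(read_point_cloud(f2), "53")
  # permuted header -> error (order is part of the format)
  hdr <- strsplit(lines[1], "\t")[[1]]
  lines[1] <- paste(rev(hdr), collapse = "\t")
  f3 <- tempfile(); writeLines(lines, f3)
  expect_error(read_point_cloud(f3), "order")
})

test_that("only the first model of a multi-model file is used", {
  model1 <- c(
    "MODEL        1",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 12.00           C",
    "ENDMDL")
  model2 <- c(
    "MODEL        2",
    "ATOM      1  N   GLY A   1       9.000   9.000   9.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       9.458   9.000   9.000  1.00 12.00           C",
    "ENDMDL")
  s <- parse_structure(c(model1, model2, "END"))
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[1], 0)          # model-1 coordinates, not model-2
})
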