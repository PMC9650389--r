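test_that("fixed-column PDB records parse with all nine semantic fields", {
  s <- parse_structure(sample_pdb_lines(), label = "snippet")
  expect_s3_class(s, "mep_structure")
  expect_equal(nrow(s), 3)
  expect_equal(s$record_type, c("ATOM", "ATOM", "HETATM"))
  expect_equal(s$atom_name, c("N", "CA", "O"))
  expect_equal(s$residue_name, c("ALA", "ALA", "HOH"))
  expect_equal(s$chain_id, c("A", "A", "B"))
  expect_equal(s$residue_number, c(1L, 1L, 2L))
  expect_equal(s$x, c(11.104, 11.639, 1.000))
  expect_equal(s$z, c(-6.504, -5.147, 3.000))
})

test_that("occupancy/B-factor/element columns do not affect coordinates", {
  full <- "ATOM      1  CA  GLY A   7       1.500  -2.250   3.125  1.00 20.00           C"
  bare <- "ATOM      1  CA  GLY A   7       1.500  -2.250   3.125"
  a <- parse_structure(full, label = "a")
  b <- parse_structure(bare, label = "b")
  expect_equal(coords(a), coords(b))
})

test_that("HETATM records are retained with their record type", {
  s <- parse_structure(sample_pdb_lines())
  expect_true("HETATM" %in% s$record_type)
})

test_that("alternate locations other than blank/A are dropped", {
  lines <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000",
    "ATOM      3  CA  GLY A   2       2.000   0.000   0.000")
  s <- parse_structure(lines)
  expect_equal(nrow(s), 2)
  expect_false(9 %in% s$x)
})

test_that("unparseable coordinate records and empty files are errors", {
  expect_error(parse_structure("ATOM      1  CA  ALA A   1      xx.xxx   0.0   0.0"),
               "line 1")
  expect_error(parse_structure(c("REMARK nothing", "END")), "no coordinate")
})

test_that("parse -> write -> parse round-trips coordinates and fields", {
  set.seed(42)
  s <- generate_toy_complex(motif_spec(rnorm(9), jitter = 0.3), seed = 3,
                            label = "rt")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- parse_structure(f, label = "rt")
  expect_equal(coords(s2), coords(s), tolerance = 1e-8)
  for (col in c("record_type", "serial", "atom_name", "residue_name",
                "chain_id", "residue_number")) {
    expect_equal(s2[[col]], s[[col]])
  }
})

test_that("preprocessing strips to nine fields, idempotently, in order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(sample_pdb_lines(), f)
  out1 <- withr::local_tempfile()
  preprocess_structure_file(f, out1)
  lines <- readLines(out1)
  expect_equal(length(lines), 3)
  expect_true(all(lengths(strsplit(trimws(lines), "\\s+")) == 9))
  # order preserved
  expect_equal(sapply(strsplit(lines, "\\s+"), `[`, 2), c("1", "2", "3"))
  # idempotent
  out2 <- withr::local_tempfile()
  preprocess_structure_file(out1, out2)
  expect_identical(readLines(out2), lines)
})

test_that("preprocessing a file with no coordinate records fails", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK a", "REMARK b"), f)
  expect_error(preprocess_structure_file(f), "no coordinate")
})

test_that("nine-field dialect parses identically to its fixed-column source", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(sample_pdb_lines(), f)
  clean <- withr::local_tempfile()
  preprocess_structure_file(f, clean)
  a <- parse_structure(f, label = "x")
  b <- parse_structure(clean, label = "x")
  expect_equal(coords(a), coords(b), tolerance = 1e-9)
  expect_equal(a$chain_id, b$chain_id)
})

test_that("formal charge model puts +1 on the lysine side-chain nitrogen", {
  lines <- c(
    "ATOM      1  CA  LYS A   5       0.000   0.000   0.000",
    "ATOM      2  NZ  LYS A   5       1.000   1.000   1.000")
  s <- assign_charges_radii(parse_structure(lines), add_termini = FALSE)
  expect_equal(s$charge[s$atom_name == "NZ"], 1)
  expect_equal(s$charge[s$atom_name == "CA"], 0)
  expect_equal(s$radius[s$atom_name == "NZ"], 1.55)
  expect_equal(s$radius[s$atom_name == "CA"], 1.7)
})

test_that("a backbone-only alanine stays neutral without termini charges", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000",
    "ATOM      4  O   ALA A   1       1.400   2.450   0.000")
  s <- assign_charges_radii(parse_structure(lines), add_termini = FALSE)
  expect_equal(total_charge(s), 0)
  s2 <- assign_charges_radii(parse_structure(lines), add_termini = TRUE)
  expect_equal(total_charge(s2), 1)  # zwitterionic N-terminus, no OXT here
})

test_that("registered pseudo-atom types take their table charge everywhere", {
  extra <- tibble::tibble(residue_name = "PSX", atom_name = "CA",
                          charge = -0.5, radius = 1.7)
  lines <- c(
    "ATOM      1  CA  PSX Z   1       0.000   0.000   0.000",
    "ATOM      2  CA  PSX Z   2       3.800   0.000   0.000")
  s <- assign_charges_radii(parse_structure(lines),
                            default_charge_model(extra = extra),
                            add_termini = FALSE)
  expect_equal(s$charge, c(-0.5, -0.5))
})

test_that("assignment conserves the table total and keeps atom order", {
  lines <- c(
    "ATOM      1  OD1 ASP A   1       0.000   0.000   0.000",
    "ATOM      2  OD2 ASP A   1       1.000   0.000   0.000",
    "ATOM      3  NZ  LYS A   2       5.000   0.000   0.000")
  s0 <- parse_structure(lines)
  s <- assign_charges_radii(s0, add_termini = FALSE)
  expect_equal(s$serial, s0$serial)
  expect_equal(total_charge(s), -0.5 - 0.5 + 1)
})

test_that("unknown residues error under the strict policy and pass as zero", {
  lines <- "ATOM      1  XQ  ZZZ A   1       0.000   0.000   0.000"
  s <- parse_structure(lines)
  expect_error(
    assign_charges_radii(s, default_charge_model(unknown = "error"),
                         add_termini = FALSE),
    "ZZZ")
  s2 <- assign_charges_radii(s, default_charge_model(unknown = "zero"),
                             add_termini = FALSE)
  expect_equal(s2$charge, 0)
})

test_that("peptide chain detection picks the shortest 8-11 residue chain", {
  s <- reference_structure()
  expect_equal(peptide_chain(s), "C")
  expect_equal(peptide_chain(s, override = "A"), "A")
  expect_error(peptide_chain(s, override = "Z"), "not present")
  one_chain <- parse_structure(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000")
  expect_error(peptide_chain(one_chain), "no peptide chain")
})
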