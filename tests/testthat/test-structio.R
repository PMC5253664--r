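test_that("a PDB fixture reads with the expected residues and atoms", {
  path <- writeGagPdb()
  s <- readStructure(path)
  expect_s4_class(s, "ProteinStructure")
  expect_equal(length(s), 13)
  sq <- residueSequence(s)
  expect_equal(sq$code, c("G", "A", "G"))
  expect_equal(sq$resno, 1:3)
})

test_that("model selection picks the requested model only", {
  m1 <- gagPdbLines()
  m2 <- sub("^ATOM(.{24})(.{8})", "ATOM\\1\\2", m1)  # same template
  shift <- function(lines, dz) {
    vapply(lines, function(l) {
      if (!startsWith(l, "ATOM")) return(l)
      z <- as.numeric(substr(l, 47, 54))
      paste0(substr(l, 1, 46), sprintf("%8.3f", z + dz), substr(l, 55, nchar(l)))
    }, "", USE.NAMES = FALSE)
  }
  path <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", setdiff(m1, c("TER", "END")), "ENDMDL",
               "MODEL     2", setdiff(shift(m1, 10), c("TER", "END")),
               "ENDMDL", "END"), path)
  s1 <- readStructure(path, modelIndex = 1)
  s2 <- readStructure(path, modelIndex = 2)
  expect_equal(length(s2), length(s1))
  expect_equal(atoms(s2)$z, atoms(s1)$z + 10, tolerance = 1e-9)
  expect_error(readStructure(path, modelIndex = 3), "out of range")
})

test_that("alternate locations resolve to the highest occupancy", {
  lines <- gagPdbLines()
  # replace the ALA CB with two altlocs: A occ 0.6 at x=3.6, B occ 0.4 at x=9.9
  cbIdx <- grep(" CB ", lines)
  lines <- append(lines[-cbIdx],
                  c(pdbAtomLine(90, "CB", "ALA", "A", 2, 3.6, 3.7, 1.2,
                                occ = 0.6, alt = "A"),
                    pdbAtomLine(91, "CB", "ALA", "A", 2, 9.9, 3.7, 1.2,
                                occ = 0.4, alt = "B")),
                  after = cbIdx - 1)
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- readStructure(path)
  cb <- atoms(s)[atoms(s)$name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 3.6, tolerance = 1e-9)
})

test_that("waters, hetero atoms and hydrogens are excluded", {
  lines <- gagPdbLines()
  lines <- append(lines, c(
    pdbAtomLine(95, "O", "HOH", "A", 50, 20, 20, 20, record = "HETATM"),
    pdbAtomLine(96, "ZN", "ZN", "A", 51, 25, 25, 25, elem = "ZN",
                record = "HETATM"),
    pdbAtomLine(97, "H", "GLY", "A", 1, 0.5, -0.5, 0, elem = "H")),
    after = length(lines) - 2)
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- readStructure(path)
  expect_equal(length(s), 13)
  expect_false(any(atoms(s)$element == "H"))
  sH <- readStructure(path, includeHydrogens = TRUE)
  expect_equal(length(sH), 14)
})

test_that("table reading is schema-checked, order- and dialect-tolerant", {
  tab <- makeRatesTable(10, timesMs = c(0, 5, 15))
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  got <- readTable(path, ratesTableSchema())
  expect_equal(nrow(got), 3)
  expect_type(got$time_ms, "double")

  # column order permutation
  path2 <- tempfile(fileext = ".csv")
  write.csv(tab[, rev(names(tab))], path2, row.names = FALSE)
  got2 <- readTable(path2, ratesTableSchema())
  expect_equal(sort(got2$time_ms), sort(got$time_ms))

  # tab-delimited + CRLF line endings
  path3 <- tempfile(fileext = ".tsv")
  txt <- paste(capture.output(write.table(tab, sep = "\t", row.names = FALSE,
                                          quote = FALSE)), collapse = "\r\n")
  writeLines(txt, path3, sep = "")
  got3 <- readTable(path3, ratesTableSchema())
  expect_equal(got3$area_unmod, got$area_unmod)

  # extra unknown column tolerated with a warning
  tab$rt_min <- 12.5
  path4 <- tempfile(fileext = ".csv")
  write.csv(tab, path4, row.names = FALSE)
  expect_warning(readTable(path4, ratesTableSchema()), "unknown column")

  # missing required column is a named schema error
  tab$time_ms <- NULL
  path5 <- tempfile(fileext = ".csv")
  write.csv(tab, path5, row.names = FALSE)
  expect_error(readTable(path5, ratesTableSchema()), "time_ms")

  # non-numeric cell in a numeric column is a row-level error
  tab2 <- makeRatesTable(10, timesMs = c(0, 5, 15))
  tab2$area_mod <- as.character(tab2$area_mod)
  tab2$area_mod[2] <- "n/a"
  path6 <- tempfile(fileext = ".csv")
  write.csv(tab2, path6, row.names = FALSE)
  expect_error(readTable(path6, ratesTableSchema()), "area_mod.*row")
})

test_that("B-factor annotation writes values, sentinels and clamps", {
  s <- readStructure(writeGagPdb())
  path <- tempfile(fileext = ".pdb")
  writeAnnotatedStructure(s, c("A:2" = 1.5), path)
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  b <- as.numeric(substr(lines, 61, 66))
  resno <- as.integer(substr(lines, 23, 26))
  expect_true(all(b[resno == 2] == 1.5))
  expect_true(all(b[resno != 2] == 0))

  # empty map: all sentinel
  writeAnnotatedStructure(s, setNames(numeric(), character()), path)
  b2 <- as.numeric(substr(grep("^ATOM", readLines(path), value = TRUE), 61, 66))
  expect_true(all(b2 == 0))

  # out-of-field-range value clamps with a warning
  expect_warning(writeAnnotatedStructure(s, c("A:2" = 12345), path), "clamp")
  b3 <- as.numeric(substr(grep("^ATOM", readLines(path), value = TRUE), 61, 66))
  expect_equal(max(b3), 999.99)

  # unknown residue key errors
  expect_error(writeAnnotatedStructure(s, c("B:9" = 1), path), "not present")
})

test_that("read-write round trip preserves atoms to PDB precision", {
  s <- makeFixtureStructure("helix", 12, seed = 2)
  path <- tempfile(fileext = ".pdb")
  writeAnnotatedStructure(s, c("A:3" = 2.25), path)
  s2 <- readStructure(path)
  expect_equal(length(s2), length(s))
  a1 <- atoms(s); a2 <- atoms(s2)
  ord <- function(a) a[order(a$resno, a$name), ]
  a1 <- ord(a1); a2 <- ord(a2)
  expect_equal(a2$name, a1$name)
  expect_equal(a2$x, a1$x, tolerance = 5e-4)
  expect_equal(a2$y, a1$y, tolerance = 5e-4)
  expect_equal(a2$z, a1$z, tolerance = 5e-4)
})

test_that("site identifiers parse singles and adjacent pairs only", {
  p <- parseSite(c("A:17", "B:17-18"))
  expect_equal(p$ambiguous, c(FALSE, TRUE))
  expect_equal(p$resno[[2]], c(17L, 18L))
  expect_error(parseSite("A:17-19"), "adjacent")
  expect_error(parseSite("17"), "malformed")
})
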