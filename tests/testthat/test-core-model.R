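test_that("component references require a single versioned accession", {
  cr <- component_ref("AC000001.1", 150000, "clone")
  expect_s3_class(cr, "component_ref")
  expect_error(component_ref("AC000001", 100), "version suffix")
  expect_error(component_ref("AC.1.1", 100), "version suffix")
  expect_error(component_ref("", 100), "non-empty")
  expect_error(component_ref("AC1.1", 0), ">= 1")
})

test_that("gap specs carry kind, linkage, and the unknown-size convention", {
  g <- gap_spec(NA, "clone", linkage = FALSE)
  expect_true(is.na(g$gap_length))
  expect_identical(unknown_gap_length(), 100L)
  expect_error(gap_spec(0), ">= 1")
})

test_that("AGP validation reports perfect tilings as clean", {
  rows <- agp(agp_component_row("chrT", 1, 100, 1, "A.1", 1, 100),
              agp_component_row("chrT", 101, 200, 2, "B.1", 1, 100))
  expect_identical(nrow(validate_agp_object(rows)), 0L)
  expect_true(is_valid(validate_agp_object(rows)))
})

test_that("AGP validation finds holes, overlaps, and length mismatches", {
  hole <- agp(agp_component_row("chrT", 1, 100, 1, "A.1", 1, 100),
              agp_component_row("chrT", 103, 200, 2, "B.1", 1, 98))
  r <- validate_agp_object(hole)
  expect_identical(sum(r$rule == "coordinate-hole"), 1L)
  expect_match(r$detail[r$rule == "coordinate-hole"], "101-102")

  mism <- agp(agp_component_row("chrT", 1, 100, 1, "A.1", 1, 99))
  expect_identical(sum(validate_agp_object(mism)$rule == "length-mismatch"), 1L)

  over <- agp(agp_component_row("chrT", 1, 100, 1, "A.1", 1, 100),
              agp_component_row("chrT", 90, 189, 2, "B.1", 1, 100))
  expect_identical(sum(validate_agp_object(over)$rule == "coordinate-overlap"), 1L)

  parts <- agp(agp_component_row("chrT", 1, 100, 2, "A.1", 1, 100))
  expect_identical(sum(validate_agp_object(parts)$rule == "part-numbers"), 1L)
})

test_that("a contig-rank object never holds gap rows", {
  rows <- agp(agp_component_row("ctg", 1, 100, 1, "A.1", 1, 100),
              agp_gap_row("ctg", 101, 200, 2, 100))
  expect_error(assembled_object("ctg", "contig", rows), "no gap rows")
  expect_s3_class(assembled_object("ctg", "scaffold", rows), "assembled_object")
})

test_that("assembly validation enforces the unit structure", {
  t <- toy_assembly(11)
  expect_true(is_valid(validate_assembly(t$asm)))

  # a second primary unit is a violation
  bad <- t$asm
  bad$units$P2 <- assembly_unit("P2", "primary")
  expect_false(is_valid(validate_assembly(bad)))
  expect_true("one-primary-unit" %in% validate_assembly(bad)$rule)

  # an alt member with no placement
  altrows <- agp_component_row("alt1", 1, 100, 1, "Z.1", 1, 100)
  alt <- assembled_object("alt1", "scaffold", altrows)
  a2 <- t$asm
  a2$units$ALT <- assembly_unit("ALT", "alt-loci", list(alt1 = alt))
  r <- validate_assembly(a2)
  expect_true("missing-placement" %in% r$rule)

  # two alt placements overlapping on the chromosome within one unit
  alt2 <- assembled_object("alt2", "scaffold",
                           agp_component_row("alt2", 1, 100, 1, "Y.1", 1, 100))
  a3 <- t$asm
  a3$units$ALT <- assembly_unit("ALT", "alt-loci", list(alt1 = alt, alt2 = alt2))
  a3$placements$alt1 <- placement("alt1", "chr1",
    data.frame(alt_start = 1, alt_stop = 100, parent_start = 100, parent_stop = 199))
  a3$placements$alt2 <- placement("alt2", "chr1",
    data.frame(alt_start = 1, alt_stop = 100, parent_start = 150, parent_stop = 249))
  expect_true("alt-overlap" %in% validate_assembly(a3)$rule)
})

test_that("oversized alternate loci draw a warning finding, not an error", {
  t <- toy_assembly(12)
  big <- assembled_object("altbig", "scaffold",
                          agp_component_row("altbig", 1, 6e6, 1, "BIG.1", 1, 6e6))
  a <- t$asm
  a$units$ALT <- assembly_unit("ALT", "alt-loci", list(altbig = big))
  a$placements$altbig <- placement("altbig", "chr1",
    data.frame(alt_start = 1, alt_stop = 100, parent_start = 1, parent_stop = 100))
  r <- validate_assembly(a)
  expect_true("alt-locus-size" %in% r$rule)
  expect_identical(r$severity[r$rule == "alt-locus-size"], "warning")
  expect_true(is_valid(r))
})

test_that("scaffold classification covers all five statuses and is total", {
  t <- toy_assembly(13)
  asm <- t$asm
  sc_unloc <- assembled_object("scU", "scaffold",
                               agp_component_row("scU", 1, 50, 1, "U.1", 1, 50),
                               chromosome = "chr1")
  sc_unpl <- assembled_object("scV", "scaffold",
                              agp_component_row("scV", 1, 50, 1, "V.1", 1, 50))
  asm$units$PRIMARY$members$scU <- sc_unloc
  asm$units$PRIMARY$members$scV <- sc_unpl
  alt <- assembled_object("altA", "scaffold",
                          agp_component_row("altA", 1, 50, 1, "W.1", 1, 50))
  asm$units$ALT <- assembly_unit("ALT", "alt-loci", list(altA = alt))
  pat <- assembled_object("fixA", "scaffold",
                          agp_component_row("fixA", 1, 50, 1, "X.1", 1, 50))
  asm$units$PATCHES <- assembly_unit("PATCHES", "patches", list(fixA = pat))

  expect_identical(classify_scaffold("chr1", asm)$status, "placed")
  expect_identical(classify_scaffold("scU", asm)$status, "unlocalized")
  expect_identical(classify_scaffold("scU", asm)$chromosome, "chr1")
  expect_identical(classify_scaffold("scV", asm)$status, "unplaced")
  expect_true(is.na(classify_scaffold("scV", asm)$chromosome))
  expect_identical(classify_scaffold("altA", asm)$status, "alt")
  expect_identical(classify_scaffold("fixA", asm)$status, "patch")
  expect_error(classify_scaffold("nope", asm), "not found")

  # a scaffold referenced as a component of a chromosome AGP is placed
  chr2rows <- agp(agp_component_row("chr2", 1, 50, 1, "scW", 1, 50))
  scW <- assembled_object("scW", "scaffold",
                          agp_component_row("scW", 1, 50, 1, "W2.1", 1, 50))
  asm$units$PRIMARY$members$chr2 <- assembled_object("chr2", "chromosome", chr2rows)
  asm$units$PRIMARY$members$scW <- scW
  expect_identical(classify_scaffold("scW", asm)$status, "placed")
  expect_identical(classify_scaffold("scW", asm)$chromosome, "chr2")
})

test_that("release versions format and step as expected", {
  v <- release_version(1, 0)
  expect_identical(format(v), "v1")
  expect_identical(format(release_version(37, 4)), "v37.p4")
})
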