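test_that("minor releases accumulate patches without touching primary sequences", {
  set.seed(41)
  t <- toy_assembly(41, n = 3, comp_len = 1000)
  before <- t$asm$sequences[["chr1"]]
  p1 <- random_patch(t$asm, kind = "FIX", id = "fix1")
  a1 <- minor_release(t$asm, list(p1$patch))
  expect_identical(format(a1$version), "v1.p1")
  expect_identical(names(a1$patches), "fix1")
  expect_identical(a1$sequences[["chr1"]], before)

  p2 <- random_patch(a1, kind = "NOVEL", id = "nov1", occupied = p1$span)
  a2 <- minor_release(a1, list(p2$patch))
  expect_identical(format(a2$version), "v1.p2")
  # cumulative: the PATCHES unit holds both patches
  pu <- Filter(function(u) u$kind == "patches", a2$units)[[1]]
  expect_setequal(names(pu$members), c("fix1", "nov1"))
  expect_identical(a2$sequences[["chr1"]], before)
  expect_true(is_valid(validate_assembly(a2)))
})

test_that("a new patch overlapping an active patch is rejected", {
  set.seed(42)
  t <- toy_assembly(42, n = 3, comp_len = 1000)
  p1 <- random_patch(t$asm, kind = "FIX", id = "fix1")
  a1 <- minor_release(t$asm, list(p1$patch))
  clash <- p1$patch
  clash$scaffold$name <- "fix2"
  clash$placement$alt_name <- "fix2"
  expect_error(minor_release(a1, list(clash)), "overlaps active patch")
})

test_that("the release decision embodies the printed thresholds", {
  expect_true(release_decision(100, 0))
  expect_false(release_decision(99, 1.0))
  expect_true(release_decision(0, 1.5))
  expect_false(release_decision(0, 0))
  # monotone in both arguments
  for (n in c(0, 50, 99, 100, 150)) {
    for (pct in c(0, 0.5, 1, 1.01, 5)) {
      if (release_decision(n, pct)) {
        expect_true(release_decision(n + 1, pct))
        expect_true(release_decision(n, min(100, pct + 1)))
      }
    }
  }
})

test_that("euchromatin-affected percentage is a union over non-gap primary bases", {
  t <- toy_assembly(43)
  expect_identical(pct_euchromatin_affected(t$asm), 0)

  # one patch covering 10 bp of a 1000 bp gapless chromosome: 1.0 percent
  set.seed(43)
  chrseq <- rand_dna(1000)
  chr <- assembled_object("chrE", "chromosome",
                          agp_component_row("chrE", 1, 1000, 1, "E.1", 1, 1000))
  asm <- assembly("e", units = list(P = assembly_unit("P", "primary", list(chrE = chr))),
                  sequences = c(chrE = chrseq))
  mkfix <- function(id, s, e) {
    len <- e - s + 1L
    sc <- assembled_object(id, "scaffold",
                           agp_component_row(id, 1, len, 1, paste0(toupper(id), ".1"), 1, len))
    genome_patch(sc, "FIX", substr(chrseq, s, e), region(paste0("R", id), "chrE", s, e),
                 placement(id, "chrE", data.frame(alt_start = 1, alt_stop = len,
                                                  parent_start = s, parent_stop = e)))
  }
  asm$patches$f1 <- mkfix("f1", 101, 110)
  expect_identical(pct_euchromatin_affected(asm), 1.0)

  # overlapping spans are counted once (union oracle: per-base coverage)
  asm$patches$f2 <- mkfix("f2", 106, 115)
  cov <- rep(FALSE, 1000); cov[101:110] <- TRUE; cov[106:115] <- TRUE
  expect_identical(pct_euchromatin_affected(asm), 100 * sum(cov) / 1000)

  # gap bases count in neither numerator nor denominator
  chr_g <- assembled_object("chrE", "chromosome",
                            agp(agp_component_row("chrE", 1, 500, 1, "E.1", 1, 500),
                                agp_gap_row("chrE", 501, 600, 2, 100),
                                agp_component_row("chrE", 601, 1000, 3, "E.1b", 1, 400)))
  asm$units$P$members$chrE <- chr_g
  expect_identical(pct_euchromatin_affected(asm), 100 * sum(cov) / 900)
})

test_that("a major release splices FIX patches and the remap oracle agrees", {
  set.seed(44)
  t <- toy_assembly(44, n = 3, comp_len = 1000)
  old <- t$asm$sequences[["chr1"]]
  # FIX patch replacing 100 bp at 501-600 with 150 bp (flankless placement)
  newcore <- rand_dna(150)
  sc <- assembled_object("fixA", "scaffold",
                         agp_component_row("fixA", 1, 210, 1, "FIXA.1", 1, 210))
  pseq <- paste0(substr(old, 471, 500), newcore, substr(old, 601, 630))
  pl <- placement("fixA", "chr1",
                  data.frame(alt_start = c(1, 181), alt_stop = c(30, 210),
                             parent_start = c(471, 601), parent_stop = c(500, 630)))
  p <- genome_patch(sc, "FIX", pseq, region("RA", "chr1", 471, 630), pl)
  a1 <- minor_release(t$asm, list(p))
  a2 <- major_release(a1, force = TRUE)
  expect_identical(format(a2$version), "v2")

  # per-base splice oracle: old prefix + placed patch span + old suffix
  expected <- paste0(substr(old, 1, 470), pseq, substr(old, 631, nchar(old)))
  expect_identical(a2$sequences[["chr1"]], expected)
  expect_identical(nchar(expected), nchar(old) + 50L)

  remap <- a2$remap$chr1
  # positions after the splice shift by +50; before it, unchanged
  expect_identical(remap_position(remap, 100, "old_to_new")$position, 100L)
  expect_identical(remap_position(remap, 700, "old_to_new")$position, 750L)
  expect_false(remap_position(remap, 550, "old_to_new")$mapped)
  # round trip over every mappable old coordinate
  for (i in seq_len(nrow(remap))) {
    pos <- remap$old_start[i]:remap$old_end[i]
    fwd <- pos + remap$offset[i]
    back <- vapply(fwd, function(x) remap_position(remap, x, "new_to_old")$position,
                   integer(1))
    expect_identical(back, pos)
  }
  # FIX retired, PATCHES unit empty
  expect_identical(a2$patches$fixA$state, "retired-into-major")
  pu <- Filter(function(u) u$kind == "patches", a2$units)[[1]]
  expect_length(pu$members, 0L)
  # the rebuilt chromosome AGP reproduces the spliced sequence
  comps2 <- c(t$components, FIXA.1 = pseq)
  pu2 <- Filter(function(u) u$kind == "primary", a2$units)[[1]]
  expect_identical(build_object_sequence(pu2$members$chr1$agp, comps2), expected)
})

test_that("NOVEL patches are promoted; conflicting ones get separate alt units", {
  set.seed(45)
  t <- toy_assembly(45, n = 3, comp_len = 1000)
  p1 <- random_patch(t$asm, kind = "NOVEL", id = "novA")
  a1 <- minor_release(t$asm, list(p1$patch))
  a2 <- major_release(a1, force = TRUE)
  alt_units <- Filter(function(u) u$kind == "alt-loci", a2$units)
  expect_length(alt_units, 1L)
  expect_identical(names(alt_units[[1]]$members), "novA")
  expect_identical(a2$patches$novA$state, "promoted-to-alt")
  pu <- Filter(function(u) u$kind == "patches", a2$units)[[1]]
  expect_length(pu$members, 0L)

  # two NOVEL patches over the same primary span cannot share one alt unit;
  # release them through two successive minor releases of sibling assemblies
  pA <- p1$patch
  pB <- p1$patch
  pB$scaffold$name <- "novB"
  pB$placement$alt_name <- "novB"
  pB$region$region_name <- "REG_novB"
  aX <- minor_release(t$asm, list(pA))
  # bypass the live-overlap guard: promotion itself must separate them
  aX$patches$novB <- pB
  aX$placements$novB <- pB$placement
  puX <- which(vapply(aX$units, `[[`, character(1), "kind") == "patches")
  aX$units[[puX]]$members$novB <- pB$scaffold
  aY <- major_release(aX, force = TRUE)
  alt_units <- Filter(function(u) u$kind == "alt-loci", aY$units)
  expect_length(alt_units, 2L)
  homes <- sort(unname(vapply(alt_units, function(u) names(u$members), character(1))))
  expect_identical(homes, c("novA", "novB"))
})

test_that("overlapping FIX placements block a major release", {
  set.seed(46)
  t <- toy_assembly(46, n = 3, comp_len = 1000)
  p1 <- random_patch(t$asm, kind = "FIX", id = "fixA")
  a1 <- minor_release(t$asm, list(p1$patch))
  clash <- p1$patch
  clash$scaffold$name <- "fixB"
  clash$placement$alt_name <- "fixB"
  a1$patches$fixB <- clash
  a1$placements$fixB <- clash$placement
  pu <- which(vapply(a1$units, `[[`, character(1), "kind") == "patches")
  a1$units[[pu]]$members$fixB <- clash$scaffold
  expect_error(major_release(a1, force = TRUE), "overlapping placements")
})

test_that("a major release without cause requires force", {
  set.seed(47)
  t <- toy_assembly(47, n = 3, comp_len = 1000)
  p1 <- random_patch(t$asm, kind = "NOVEL", id = "novA")
  a1 <- minor_release(t$asm, list(p1$patch))
  expect_error(major_release(a1), "release criteria not met")
  expect_message(major_release(a1, force = TRUE), "forced")
})

test_that("issue lifecycle: open, resolve once, summarize by type", {
  iss <- issue_tracker()
  iss <- open_issue(iss, "HG-1", "clone-problem", "chr1", 1, 10)
  iss <- open_issue(iss, "HG-2", "clone-problem", "chr1", 20, 30)
  iss <- open_issue(iss, "HG-3", "clone-problem", "chr2", 1, 10)
  iss <- open_issue(iss, "HG-4", "gap", "chr2", 50, 99)
  iss <- open_issue(iss, "HG-5", "gap", "chr3", 5, 6)
  iss <- open_issue(iss, "HG-6", "variation", "chr3", 7, 9)
  v <- release_version(1, 1)
  for (id in c("HG-1", "HG-2", "HG-3", "HG-4", "HG-5")) {
    iss <- resolve_issue(iss, id, v)
  }
  s <- summarize_issues(iss)
  expect_identical(s$count[s$type == "clone-problem"], 3L)
  expect_identical(s$count[s$type == "gap"], 2L)
  expect_identical(s$count[s$type == "variation"], 0L)
  expect_identical(sum(s$count), 5L)

  expect_error(resolve_issue(iss, "HG-1", v), "already resolved")
  expect_error(resolve_issue(iss, "HG-99", v), "no such issue")
  expect_error(open_issue(iss, "HG-7", "typo-problem", "chr1", 1, 2), "unknown issue type")
  expect_identical(sum(summarize_issues(issue_tracker())$count), 0L)
})
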