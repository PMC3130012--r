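Package: refasm
Title: Reference Genome Assembly Model with Alternate Loci and Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the clone-based reference assembly model used by modern
    genome reference curation: tiling-path (TPF) to AGP construction with
    switch points chosen inside verified component overlaps, sequence building
    from AGP instructions, assembly units with alternate loci and patch
    scaffolds, alignment-based chromosome context (placements) and coordinate
    liftover, coordinate-stable minor releases with a FIX/NOVEL patch
    lifecycle, curation-issue tracking, and a synthetic-region generator that
    demonstrates why alternate loci improve placement of allele-specific
    sequencing reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
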