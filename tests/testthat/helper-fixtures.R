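# Shared fixtures and independent oracles used across the suite.

# small single-chromosome assembly built from generated components
toy_assembly <- function(seed, n = 2L, comp_len = 800L, overlap = 100L,
                         object = "chr1") {
  g <- gen_components(seed, n = n, length = comp_len, overlap_len = overlap,
                      error_rate = 0, object = object)
  a <- tpf_to_agp(g$tpf, g$components)
  chr <- assembled_object(object, "chromosome", as.data.frame(a))
  s <- build_object_sequence(a, g$components)
  asm <- assembly("toy",
                  units = list(PRIMARY = assembly_unit("PRIMARY", "primary",
                                                       stats::setNames(list(chr), object))),
                  sequences = stats::setNames(s, object))
  list(asm = asm, components = g$components, truth = g$truth)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# random patch against chromosome `chr`: replaces a parent span (flanks
# included in the placement) with new sequence of a possibly different length;
# caller manages RNG state and overlap avoidance via `occupied`
random_patch <- function(asm, chr = "chr1", kind = "FIX", id, occupied = NULL,
                         flank = 30L) {
  chrseq <- asm$sequences[[chr]]
  L <- nchar(chrseq)
  repeat {
    core_len <- sample(40:150, 1L)
    s <- sample(seq(flank + 1L, L - core_len - flank), 1L)
    e <- s + core_len - 1L
    ps <- s - flank; pe <- e + flank
    ok <- TRUE
    if (!is.null(occupied) && nrow(occupied)) {
      ok <- all(pe < occupied$start | ps > occupied$stop)
    }
    if (ok) break
  }
  new_len <- sample(40:250, 1L)
  newseq <- rand_dna(new_len)
  pseq <- paste0(substr(chrseq, ps, s - 1L), newseq, substr(chrseq, e + 1L, pe))
  alt_len <- nchar(pseq)
  prow <- agp_component_row(id, 1L, alt_len, 1L, paste0(toupper(id), ".1"), 1L, alt_len)
  psc <- assembled_object(id, "scaffold", prow)
  pl <- placement(id, chr,
                  data.frame(alt_start = c(1L, alt_len - flank + 1L),
                             alt_stop = c(flank, alt_len),
                             parent_start = c(ps, e + 1L),
                             parent_stop = c(s - 1L, pe)))
  reg <- region(paste0("REG_", id), chr, ps, pe)
  list(patch = genome_patch(psc, kind, pseq, reg, pl),
       span = data.frame(start = ps, stop = pe))
}

# random placement with indels, built directly from a block walk
random_placement <- function(n_blocks = NULL) {
  if (is.null(n_blocks)) n_blocks <- sample(1:6, 1L)
  alt_pos <- sample(1:20, 1L); par_pos <- sample(1:20, 1L)
  blocks <- list()
  for (i in seq_len(n_blocks)) {
    len <- sample(5:80, 1L)
    blocks[[i]] <- data.frame(alt_start = alt_pos, alt_stop = alt_pos + len - 1L,
                              parent_start = par_pos, parent_stop = par_pos + len - 1L)
    alt_pos <- alt_pos + len; par_pos <- par_pos + len
    gap_kind <- sample(c("ins", "del", "both"), 1L)
    if (gap_kind %in% c("ins", "both")) alt_pos <- alt_pos + sample(1:40, 1L)
    if (gap_kind %in% c("del", "both")) par_pos <- par_pos + sample(1:40, 1L)
  }
  placement("altX", "chrX", do.call(rbind, blocks))
}

# per-base liftover oracle: dense alt->parent map filled block by block
placement_map_oracle <- function(pl) {
  m <- rep(NA_integer_, pl$alt_stop)
  b <- pl$blocks
  for (i in seq_len(nrow(b))) {
    m[b$alt_start[i]:b$alt_stop[i]] <- b$parent_start[i]:b$parent_stop[i]
  }
  m
}

# per-base provenance oracle for an AGP object: rebuilds the sequence row by
# row from component coordinates and checks single coverage of every base
agp_provenance_rebuild <- function(rows, comps) {
  rows <- as.data.frame(rows)
  L <- max(rows$object_end)
  covered <- integer(L)
  out <- character(L)
  for (i in seq_len(nrow(rows))) {
    span <- rows$object_beg[i]:rows$object_end[i]
    covered[span] <- covered[span] + 1L
    if (rows$component_type[i] %in% c("N", "U")) {
      out[span] <- "N"
    } else {
      cpos <- rows$component_beg[i]:rows$component_end[i]
      piece <- substring(comps[[rows$component_id[i]]], cpos, cpos)
      if (rows$orientation[i] == "-") {
        piece <- rev(chartr("ACGTN", "TGCAN", piece))
      }
      out[span] <- piece
    }
  }
  stopifnot(all(covered == 1L))
  paste(out, collapse = "")
}

# brute-force global alignment (linear gap penalty): number of aligned
# (non-gap on both axes) columns in an optimal path, ties preferring diagonal
nw_aligned_columns <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  na <- length(A); nb <- length(B)
  S <- matrix(0L, na + 1L, nb + 1L)
  M <- matrix(0L, na + 1L, nb + 1L)
  S[, 1L] <- gap * 0:na
  S[1L, ] <- gap * 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    diag <- S[i, j] + if (A[i] == B[j]) match else mismatch
    up <- S[i, j + 1L] + gap
    left <- S[i + 1L, j] + gap
    best <- max(diag, up, left)
    S[i + 1L, j + 1L] <- best
    M[i + 1L, j + 1L] <- if (best == diag) M[i, j] + 1L
      else if (best == up) M[i, j + 1L] else M[i + 1L, j]
  }
  M[na + 1L, nb + 1L]
}

# hand-built 1 kb insertion fixture: primary = FL+FR (500+500), alternate
# carries a 50 bp insert between the flanks; anchors overlap middle clone
# by 50 bp on each side
insertion_fixture <- function(seed = 42L) {
  set.seed(seed)
  fl <- rand_dna(500L); fr <- rand_dna(500L); ins <- rand_dna(50L)
  comps <- c(FLA.1 = fl, FRA.1 = fr,
             MIDI.1 = paste0(substr(fl, 451, 500), ins, substr(fr, 1, 50)),
             MIDD.1 = paste0(substr(fl, 451, 500), substr(fr, 1, 50)))
  del_tpf <- tpf(rbind(tpf_component("FLA.1", "chrF"),
                       tpf_component("MIDD.1", "chrF"),
                       tpf_component("FRA.1", "chrF")))
  ins_tpf <- tpf(rbind(tpf_component("FLA.1", "altF"),
                       tpf_component("MIDI.1", "altF"),
                       tpf_component("FRA.1", "altF")))
  agp_p <- tpf_to_agp(del_tpf, comps)
  agp_a <- tpf_to_agp(ins_tpf, comps)
  list(components = comps, agp_primary = agp_p, agp_alt = agp_a,
       primary_seq = build_object_sequence(agp_p, comps),
       alt_seq = build_object_sequence(agp_a, comps),
       insert_span_alt = c(501L, 550L))
}
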