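# Synthetic fixtures and the read-placement demonstration: clone-like
# components tiling a hidden truth sequence, a dual-haplotype region in
# which an insertion path and a deletion path share flanking anchor
# components, simulated reads, and a minimal best-placement read aligner
# used to show that carrying the insertion path as an alternate locus
# prevents misplacement of insertion-specific reads.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each position with probability p (always to a different base)
mutate_bases <- function(seq, positions) {
  if (!length(positions)) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  for (i in positions) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate overlapping clone-like components tiling a hidden truth sequence
#'
#' Components tile a random truth sequence with fixed-length dovetail
#' overlaps. Substitution errors at rate \code{error_rate} are introduced
#' into each component's copy of its prefix overlap, emulating clone-to-clone
#' disagreement within verified overlaps. Pure function of its seed.
#'
#' @param seed Integer seed.
#' @param n Number of components (>= 1).
#' @param length Component length in bp.
#' @param overlap_len Dovetail overlap length (< length).
#' @param error_rate Per-base substitution rate within overlaps, in [0, 0.05].
#' @param object Object name used in the tiling path.
#' @return List with \code{truth}, \code{components} (named sequences),
#'   \code{tpf}, and \code{accessions}.
#' @export
gen_components <- function(seed, n = 3L, length = 1000L, overlap_len = 100L,
                           error_rate = 0, object = "chrS") {
  stopifnot(n >= 1L, overlap_len < length, error_rate >= 0, error_rate <= 0.05)
  with_seed(seed, {
    step <- length - overlap_len
    truth_len <- n * length - (n - 1L) * overlap_len
    truth <- random_dna(truth_len)
    acc <- sprintf("SYN%03d.1", seq_len(n))
    comps <- character(n)
    for (i in seq_len(n)) {
      s <- (i - 1L) * step + 1L
      comp <- substr(truth, s, s + length - 1L)
      if (i > 1L && error_rate > 0) {
        pos <- which(stats::runif(overlap_len) < error_rate)
        comp <- mutate_bases(comp, pos)
      }
      comps[i] <- comp
    }
    names(comps) <- acc
    path <- tpf(do.call(rbind, lapply(acc, tpf_component, object = object)))
    list(truth = truth, components = comps, tpf = path, accessions = acc)
  })
}

#' Generate a dual-haplotype region: insertion path vs deletion path
#'
#' Emulates a structurally variant locus with two tiling paths through shared
#' flanking anchor components: the deletion haplotype is left flank + right
#' flank; the insertion haplotype additionally carries \code{insert_len} of
#' unique sequence between them. Each path has its own middle clone spanning
#' the junction; the two anchor clones appear in both paths.
#'
#' @param seed Integer seed.
#' @param flank_len Length of each flank (bp).
#' @param insert_len Length of the insertion-specific sequence (>= 200 bp).
#' @param anchor_overlap Dovetail overlap between each anchor and the middle
#'   clone (bp).
#' @return List with \code{components}, \code{insertion_tpf},
#'   \code{deletion_tpf}, \code{anchors}, the two haplotype sequences, and
#'   \code{insert_span} (span of the unique insert on the insertion
#'   haplotype).
#' @export
gen_variant_region <- function(seed, flank_len = 5000L, insert_len = 2000L,
                               anchor_overlap = 500L) {
  stopifnot(insert_len >= 200L, anchor_overlap < flank_len)
  with_seed(seed, {
    fl <- random_dna(flank_len)
    fr <- random_dna(flank_len)
    ins <- random_dna(insert_len)
    ov <- as.integer(anchor_overlap)
    del_mid <- paste0(substr(fl, flank_len - ov + 1L, flank_len), substr(fr, 1L, ov))
    ins_mid <- paste0(substr(fl, flank_len - ov + 1L, flank_len), ins,
                      substr(fr, 1L, ov))
    comps <- c(ANCL.1 = fl, ANCR.1 = fr, DELM.1 = del_mid, INSM.1 = ins_mid)
    deletion_tpf <- tpf(rbind(tpf_component("ANCL.1", "chrP"),
                              tpf_component("DELM.1", "chrP"),
                              tpf_component("ANCR.1", "chrP")))
    insertion_tpf <- tpf(rbind(tpf_component("ANCL.1", "alt_ins"),
                               tpf_component("INSM.1", "alt_ins"),
                               tpf_component("ANCR.1", "alt_ins")))
    list(components = comps,
         insertion_tpf = insertion_tpf, deletion_tpf = deletion_tpf,
         anchors = c("ANCL.1", "ANCR.1"),
         insertion_hap = paste0(fl, ins, fr),
         deletion_hap = paste0(fl, fr),
         insert_span = c(flank_len + 1L, flank_len + insert_len),
         flank_len = as.integer(flank_len), insert_len = as.integer(insert_len))
  })
}

#' Build the with-alt and without-alt assemblies for a variant region
#'
#' The deletion path becomes the primary chromosome; the insertion path is
#' carried as an alternate locus (placed by anchored alignment) in the
#' with-alt assembly and dropped entirely in the without-alt assembly.
#'
#' @param reg Output of \code{\link{gen_variant_region}}.
#' @return List with \code{with_alt} and \code{without_alt}
#'   \code{assembly} objects.
#' @export
variant_assemblies <- function(reg) {
  agp_p <- tpf_to_agp(reg$deletion_tpf, reg$components)
  agp_a <- tpf_to_agp(reg$insertion_tpf, reg$components)
  chr <- assembled_object("chrP", "chromosome", as.data.frame(agp_p))
  alt <- assembled_object("alt_ins", "scaffold", as.data.frame(agp_a))
  seq_p <- build_object_sequence(agp_p, reg$components)
  seq_a <- build_object_sequence(agp_a, reg$components)
  pl <- anchor_align(agp_a, agp_p, reg$components)
  with_alt <- assembly(
    "synthetic_with_alt",
    units = list(PRIMARY = assembly_unit("PRIMARY", "primary", list(chrP = chr)),
                 ALT_1 = assembly_unit("ALT_1", "alt-loci", list(alt_ins = alt))),
    sequences = c(chrP = seq_p, alt_ins = seq_a),
    placements = list(alt_ins = pl))
  without_alt <- assembly(
    "synthetic_without_alt",
    units = list(PRIMARY = assembly_unit("PRIMARY", "primary", list(chrP = chr))),
    sequences = c(chrP = seq_p))
  list(with_alt = with_alt, without_alt = without_alt)
}

#' Simulate uniformly placed reads with substitution errors
#'
#' @param seed Integer seed.
#' @param haplotype_seq Sequence reads are drawn from.
#' @param n_reads Number of reads.
#' @param read_len Read length (bp).
#' @param error_rate Per-base substitution error rate.
#' @return Data frame with read_id, seq, truth_start, truth_end.
#' @export
simulate_reads <- function(seed, haplotype_seq, n_reads, read_len = 100L,
                           error_rate = 0.01) {
  L <- nchar(haplotype_seq)
  stopifnot(read_len <= L, error_rate >= 0, error_rate < 1)
  with_seed(seed, {
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    seqs <- substring(haplotype_seq, starts, starts + read_len - 1L)
    if (error_rate > 0) {
      for (i in seq_len(n_reads)) {
        pos <- which(stats::runif(read_len) < error_rate)
        if (length(pos)) seqs[i] <- mutate_bases(seqs[i], pos)
      }
    }
    data.frame(read_id = sprintf("read%05d", seq_len(n_reads)), seq = seqs,
               truth_start = starts, truth_end = starts + read_len - 1L,
               stringsAsFactors = FALSE)
  })
}

# k-mer index of a set of target sequences: per target, a list mapping each
# k-mer to its start positions
build_kmer_index <- function(targets, k) {
  lapply(targets, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(list())
    km <- substring(s, 1:n, k:(n + k - 1L))
    split(1:n, km)
  })
}

count_mismatches <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Align reads to a set of target sequences (best single placement)
#'
#' A deliberately minimal aligner: exact k-mer seeds looked up in an index of
#' the targets, ungapped evaluation of each candidate placement, and the best
#' (fewest mismatches) placement reported; ties are broken by target order
#' then leftmost position, and reads whose best identity is below
#' \code{min_identity} are reported unaligned. No mapping quality is
#' produced.
#'
#' @param reads Data frame with read_id and seq (e.g.
#'   \code{\link{simulate_reads}} output).
#' @param targets Named character vector of target sequences.
#' @param k Seed length.
#' @param min_identity Minimum identity to call a read aligned.
#' @return Data frame with read_id, target, position, mismatches, aligned.
#' @export
align_reads <- function(reads, targets, k = 15L, min_identity = 0.9) {
  idx <- build_kmer_index(targets, k)
  tnames <- names(targets)
  tlens <- nchar(targets)
  n <- nrow(reads)
  out_target <- character(n); out_pos <- integer(n)
  out_mm <- integer(n); out_aligned <- logical(n)
  for (r in seq_len(n)) {
    rd <- reads$seq[r]
    rl <- nchar(rd)
    seed_pos <- unique(pmax(1L, c(1L, (rl - k) %/% 2L + 1L, rl - k + 1L)))
    best_mm <- rl + 1L; best_t <- NA_character_; best_p <- NA_integer_
    for (ti in seq_along(tnames)) {
      cand <- integer(0)
      for (sp in seed_pos) {
        hits <- idx[[ti]][[substr(rd, sp, sp + k - 1L)]]
        if (!is.null(hits)) cand <- c(cand, hits - sp + 1L)
      }
      cand <- sort(unique(cand[cand >= 1L & cand + rl - 1L <= tlens[ti]]))
      for (p in cand) {
        mm <- count_mismatches(rd, substr(targets[[ti]], p, p + rl - 1L))
        if (mm < best_mm) { best_mm <- mm; best_t <- tnames[ti]; best_p <- p }
      }
    }
    ok <- !is.na(best_t) && (1 - best_mm / rl) >= min_identity
    out_target[r] <- if (ok) best_t else NA_character_
    out_pos[r] <- if (ok) best_p else NA_integer_
    out_mm[r] <- if (ok) best_mm else NA_integer_
    out_aligned[r] <- ok
  }
  data.frame(read_id = reads$read_id, target = out_target, position = out_pos,
             mismatches = out_mm, aligned = out_aligned, stringsAsFactors = FALSE)
}

# implied coordinate of an alignment on the alternate-scaffold axis:
# identity for hits on the alt scaffold, liftover for hits on the chromosome
implied_alt_coord <- function(aln, alt_name, pl) {
  n <- nrow(aln)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!aln$aligned[i]) next
    if (identical(aln$target[i], alt_name)) {
      out[i] <- aln$position[i]
    } else if (identical(aln$target[i], pl$parent_name)) {
      pos <- aln$position[i]
      if (pos >= pl$parent_start && pos <= pl$parent_stop) {
        lv <- liftover(pl, pos, "primary_to_alt")
        if (lv$mapped) out[i] <- lv$position
      } else if (pos < pl$parent_start) {
        out[i] <- pos - pl$parent_start + pl$alt_start
      } else {
        out[i] <- pos - pl$parent_stop + pl$alt_stop
      }
    }
  }
  out
}

#' Do alternate loci rescue allele-specific reads?
#'
#' Aligns reads simulated from the insertion haplotype against an assembly
#' that carries the insertion path as an alternate locus and against one
#' that does not. A read is alt-specific when its truth span overlaps the
#' insertion-only sequence (the spans the placement reports as
#' insertion-in-alt). For each assembly the alt-specific reads are counted
#' as correctly placed (aligned position implies their true coordinate on
#' the insertion haplotype), misplaced, or unaligned.
#'
#' @param reads \code{\link{simulate_reads}} output (truth positions
#'   required) from the insertion haplotype.
#' @param with_alt,without_alt The two assemblies from
#'   \code{\link{variant_assemblies}}.
#' @param k,min_identity Aligner parameters (see \code{\link{align_reads}}).
#' @return List with \code{report} (counts per assembly), \code{n_alt_specific},
#'   \code{flank_agreement} (fraction of non-alt-specific reads with the
#'   same implied placement in both assemblies), and the per-read table.
#' @export
evaluate_alt_awareness <- function(reads, with_alt, without_alt,
                                   k = 15L, min_identity = 0.9) {
  if (!all(c("truth_start", "truth_end") %in% names(reads))) {
    stop("reads carry no truth positions; use simulate_reads()", call. = FALSE)
  }
  alt_units <- Filter(function(u) u$kind == "alt-loci", with_alt$units)
  if (!length(alt_units) || !length(alt_units[[1L]]$members)) {
    stop("with_alt assembly has no alternate locus", call. = FALSE)
  }
  alt_name <- names(alt_units[[1L]]$members)[1L]
  pl <- with_alt$placements[[alt_name]]
  ins <- diff_blocks(pl)
  ins <- ins[ins$kind == "insertion-in-alt", , drop = FALSE]
  alt_specific <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(ins))) {
    alt_specific <- alt_specific |
      (reads$truth_start <= ins$alt_stop[i] & reads$truth_end >= ins$alt_start[i])
  }
  aln_with <- align_reads(reads, with_alt$sequences, k, min_identity)
  aln_without <- align_reads(reads, without_alt$sequences, k, min_identity)
  coord_with <- implied_alt_coord(aln_with, alt_name, pl)
  coord_without <- implied_alt_coord(aln_without, alt_name, pl)
  classify <- function(aln, coord) {
    ifelse(!aln$aligned, "unaligned",
           ifelse(!is.na(coord) & coord == reads$truth_start, "correct", "misplaced"))
  }
  cls_with <- classify(aln_with, coord_with)
  cls_without <- classify(aln_without, coord_without)
  count <- function(cls) {
    c(correct = sum(cls[alt_specific] == "correct"),
      misplaced = sum(cls[alt_specific] == "misplaced"),
      unaligned = sum(cls[alt_specific] == "unaligned"))
  }
  cw <- count(cls_with); cwo <- count(cls_without)
  report <- data.frame(assembly = c("with_alt", "without_alt"),
                       correct = c(cw["correct"], cwo["correct"]),
                       misplaced = c(cw["misplaced"], cwo["misplaced"]),
                       unaligned = c(cw["unaligned"], cwo["unaligned"]),
                       row.names = NULL, stringsAsFactors = FALSE)
  flank <- !alt_specific
  agreement <- if (any(flank)) {
    same <- (is.na(coord_with[flank]) & is.na(coord_without[flank])) |
      (!is.na(coord_with[flank]) & !is.na(coord_without[flank]) &
         coord_with[flank] == coord_without[flank])
    mean(same)
  } else NA_real_
  list(report = report, n_alt_specific = sum(alt_specific),
       flank_agreement = agreement,
       per_read = data.frame(read_id = reads$read_id, alt_specific = alt_specific,
                             class_with = cls_with, class_without = cls_without,
                             stringsAsFactors = FALSE))
}
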