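# Building assembled sequences from tiling paths: dovetail overlap detection
# between adjacent components, switch-point selection inside the verified
# overlap, TPF -> AGP conversion (no duplicated overlap sequence), and
# rendering object sequences from AGP instructions.

#' Reverse complement
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 1-based positions at which two equal-length strings differ
seq_mismatch_positions <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  which(ra != rb)
}

#' Find the dovetail overlap between two adjacent components
#'
#' Searches for a suffix(left)/prefix(right) overlap of at least
#' \code{min_len} bp using exact k-mer seeds from the right sequence's prefix
#' looked up in the left sequence, then scoring each implied dovetail by
#' ungapped identity. Returns the highest-identity qualifying overlap
#' (ties broken toward the longer overlap), or \code{NULL} when none reaches
#' \code{min_identity}.
#'
#' @param left_seq,right_seq Component sequences in tiling-path orientation.
#' @param min_len Minimum overlap length (>= 20).
#' @param min_identity Minimum fractional identity over the overlap, in
#'   (0.9, 1].
#' @param left_name,right_name Component accessions carried into the result.
#' @return An \code{overlap_call} (left_span, right_span, length, identity,
#'   mismatch offsets within the overlap) or \code{NULL}.
#' @export
find_overlap <- function(left_seq, right_seq, min_len = 20L, min_identity = 0.97,
                         left_name = "left", right_name = "right") {
  stopifnot(min_len >= 20L, min_identity > 0.9, min_identity <= 1)
  nl <- nchar(left_seq); nr <- nchar(right_seq)
  max_l <- min(nl, nr)
  if (max_l < min_len) return(NULL)
  k <- min(20L, min_len)
  seed_starts <- seq(1L, max(1L, max_l - k + 1L), by = k)
  cand <- integer(0)
  for (q in seed_starts) {
    seed <- substr(right_seq, q, q + k - 1L)
    if (nchar(seed) < k) next
    hits <- gregexpr(seed, left_seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    L <- nl - hits + q           # implied dovetail length
    cand <- c(cand, L[L >= min_len & L <= max_l])
  }
  score <- function(lengths) {
    best <- NULL
    for (L in lengths) {
      mm <- seq_mismatch_positions(substr(left_seq, nl - L + 1L, nl),
                                   substr(right_seq, 1L, L))
      ident <- (L - length(mm)) / L
      if (ident >= min_identity &&
          (is.null(best) || ident > best$identity + 1e-12)) {
        best <- structure(list(left_component = left_name, right_component = right_name,
                               left_span = c(nl - L + 1L, nl), right_span = c(1L, L),
                               length = L, identity = ident,
                               mismatch_offsets = mm),
                          class = "overlap_call")
      }
    }
    best
  }
  best <- score(sort(unique(cand), decreasing = TRUE))
  if (is.null(best)) {
    # every seed window may carry a substitution; fall back to scanning all
    # dovetail lengths (desk-scale sequences keep this cheap)
    best <- score(max_l:min_len)
  }
  best
}

#' @export
print.overlap_call <- function(x, ...) {
  cat(sprintf("<overlap_call> %s[%d-%d] / %s[%d-%d], %d bp, identity %.4f\n",
              x$left_component, x$left_span[1], x$left_span[2],
              x$right_component, x$right_span[1], x$right_span[2],
              x$length, x$identity))
  invisible(x)
}

#' Select a switch point inside a verified overlap
#'
#' The switch point is placed at the midpoint of the longest exact-match run
#' inside the overlap; when several runs tie, the leftmost wins. This is a
#' deterministic, reproducible rule; the midpoint keeps the switch as far as
#' possible from the nearest disagreement.
#'
#' @param overlap An \code{overlap_call} from \code{\link{find_overlap}}.
#' @return A \code{switch_point}: the last base taken from the left component
#'   (\code{position_in_from}) and the corresponding base of the right
#'   component (\code{position_in_to}), in each component's own coordinates
#'   (tiling-path orientation).
#' @export
select_switch_point <- function(overlap) {
  stopifnot(inherits(overlap, "overlap_call"))
  L <- overlap$length
  mm <- overlap$mismatch_offsets
  bounds <- c(0L, mm, L + 1L)
  run_start <- bounds[-length(bounds)] + 1L
  run_end <- bounds[-1L] - 1L
  keep <- run_end >= run_start
  run_start <- run_start[keep]; run_end <- run_end[keep]
  if (!length(run_start)) stop("overlap has no exact-match run", call. = FALSE)
  len <- run_end - run_start + 1L
  i <- which.max(len)              # which.max takes the leftmost maximum
  m <- (run_start[i] + run_end[i]) %/% 2L
  switch_point(overlap$left_component, overlap$right_component,
               position_in_from = overlap$left_span[1L] + m - 1L,
               position_in_to = overlap$right_span[1L] + m - 1L)
}

# safe lookup in a named character vector or list
get_seq <- function(seqs, accession) {
  if (!accession %in% names(seqs)) return(NULL)
  seqs[[accession]]
}

oriented_seq <- function(seqs, accession, orientation) {
  s <- get_seq(seqs, accession)
  if (is.null(s)) stop("missing component sequence: ", accession, call. = FALSE)
  if (orientation == "-") revcomp(s) else s
}

# map a span in oriented coordinates back to component coordinates
oriented_to_component <- function(s, e, len, orientation) {
  if (orientation == "+") c(s, e) else c(len - e + 1L, len - s + 1L)
}

#' Build an AGP object from a tiling path
#'
#' Walks the tiling path, detects the dovetail overlap between each pair of
#' adjacent components (adjacent means not separated by a gap row), selects a
#' switch point inside each overlap, and emits AGP component rows whose
#' object spans abut exactly at the switch points, so no overlap sequence is
#' duplicated. Gap rows pass through; unknown-size gaps are rendered at the
#' conventional 100 bp as type \code{"U"}.
#'
#' Overlap detection runs on the oriented sequences; AGP component spans are
#' reported in each component's own coordinates.
#'
#' @param path A \code{tpf} (may contain several objects).
#' @param component_seqs Named character vector of component sequences.
#' @param min_len,min_identity Overlap acceptance thresholds (see
#'   \code{\link{find_overlap}}); they are logged in the AGP header comment.
#' @return An \code{agp} data frame covering every object in the path, with
#'   the chosen \code{switch_point}s in the \code{"switch_points"} attribute.
#' @export
tpf_to_agp <- function(path, component_seqs, min_len = 20L, min_identity = 0.97) {
  path <- as.data.frame(path)
  all_rows <- list()
  all_switches <- list()
  for (obj in unique(path$object)) {
    p <- path[path$object == obj, , drop = FALSE]
    n <- nrow(p)
    comp_idx <- which(p$row_type == "component")
    for (acc in p$accession[comp_idx]) {
      if (is.null(get_seq(component_seqs, acc))) {
        stop("missing component sequence: ", acc, call. = FALSE)
      }
    }
    oseqs <- lapply(comp_idx, function(i) oriented_seq(component_seqs, p$accession[i], p$orientation[i]))
    names(oseqs) <- p$accession[comp_idx]
    lens <- vapply(oseqs, nchar, integer(1))
    left_trim <- stats::setNames(integer(length(comp_idx)), p$accession[comp_idx])
    right_trim <- left_trim
    # adjacent component pairs (no gap row between them) must overlap
    for (i in seq_len(n - 1L)) {
      if (p$row_type[i] == "component" && p$row_type[i + 1L] == "component") {
        a <- p$accession[i]; b <- p$accession[i + 1L]
        ov <- find_overlap(oseqs[[a]], oseqs[[b]], min_len, min_identity,
                           left_name = a, right_name = b)
        if (is.null(ov)) {
          stop("adjacent components ", a, " and ", b, " in '", obj,
               "' have no qualifying overlap; insert a gap row between them",
               call. = FALSE)
        }
        sp <- select_switch_point(ov)
        m <- sp$position_in_to - ov$right_span[1L] + 1L   # bases of overlap kept from left
        right_trim[a] <- lens[a] - (ov$left_span[1L] + m - 1L)
        left_trim[b] <- m
        # record the switch point in component coordinates
        from_cc <- oriented_to_component(sp$position_in_from, sp$position_in_from,
                                         lens[a], p$orientation[i])[1L]
        to_cc <- oriented_to_component(sp$position_in_to, sp$position_in_to,
                                       lens[b], p$orientation[i + 1L])[1L]
        all_switches[[length(all_switches) + 1L]] <-
          switch_point(a, b, from_cc, to_cc)
      }
    }
    rows <- list()
    pos <- 0L; part <- 0L
    for (i in seq_len(n)) {
      part <- part + 1L
      if (p$row_type[i] == "gap") {
        gl <- p$gap_length[i]
        known <- !is.na(gl)
        if (!known) gl <- unknown_gap_length()
        rows[[part]] <- agp_gap_row(obj, pos + 1L, pos + gl, part,
                                    gap_length = gl, gap_type = p$gap_type[i],
                                    linkage = TRUE, known = known)
        pos <- pos + gl
      } else {
        acc <- p$accession[i]
        s <- 1L + left_trim[acc]
        e <- lens[acc] - right_trim[acc]
        if (e < s) {
          stop("component ", acc, " fully consumed by flanking overlaps", call. = FALSE)
        }
        cc <- oriented_to_component(s, e, lens[acc], p$orientation[i])
        span <- e - s + 1L
        rows[[part]] <- agp_component_row(obj, pos + 1L, pos + span, part,
                                          component_id = acc,
                                          component_beg = cc[1L], component_end = cc[2L],
                                          orientation = p$orientation[i])
        pos <- pos + span
      }
    }
    all_rows <- c(all_rows, rows)
  }
  out <- do.call(agp, all_rows)
  attr(out, "comments") <- sprintf("# overlap min_len=%d min_identity=%.3f",
                                   as.integer(min_len), min_identity)
  attr(out, "switch_points") <- all_switches
  out
}

#' Render the sequence of one AGP object
#'
#' Component rows contribute the stated component span (reverse-complemented
#' for \code{"-"} rows); gap rows contribute runs of \code{N}.
#'
#' @param rows \code{agp} data frame for a single object.
#' @param component_seqs Named character vector of component sequences.
#' @return The object sequence as a single string.
#' @export
build_object_sequence <- function(rows, component_seqs) {
  rows <- as.data.frame(rows)
  if (length(unique(rows$object)) != 1L) {
    stop("build_object_sequence expects a single object; see build_assembly_sequences",
         call. = FALSE)
  }
  rows <- rows[order(rows$object_beg), , drop = FALSE]
  pieces <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$component_type %in% c("N", "U")) {
      pieces[i] <- strrep("N", r$object_end - r$object_beg + 1L)
    } else {
      s <- get_seq(component_seqs, r$component_id)
      if (is.null(s)) stop("missing component sequence: ", r$component_id, call. = FALSE)
      if (r$component_end > nchar(s) || r$component_beg < 1L) {
        stop("component span ", r$component_beg, "-", r$component_end,
             " outside component ", r$component_id, " (length ", nchar(s), ")",
             call. = FALSE)
      }
      piece <- substr(s, r$component_beg, r$component_end)
      if (r$orientation == "-") piece <- revcomp(piece)
      pieces[i] <- piece
    }
  }
  paste(pieces, collapse = "")
}

#' Render sequences for every object in an AGP table
#'
#' @param x \code{agp} data frame (possibly several objects).
#' @param component_seqs Named character vector of component sequences.
#' @return Named character vector of object sequences.
#' @export
build_assembly_sequences <- function(x, component_seqs) {
  x <- as.data.frame(x)
  objs <- unique(x$object)
  stats::setNames(
    vapply(objs, function(o) build_object_sequence(x[x$object == o, ], component_seqs),
           character(1)),
    objs)
}

#' Per-unit assembly statistics
#'
#' @param asm An \code{assembly}.
#' @return Data frame with one row per unit: objects, total bp, gap row
#'   count, gap bp. Totals are additive over units.
#' @export
assembly_stats <- function(asm) {
  rows <- lapply(asm$units, function(u) {
    gap_count <- 0L; gap_bp <- 0L; total_bp <- 0L
    for (m in u$members) {
      g <- is_gap_row(m$agp)
      gap_count <- gap_count + sum(g)
      gap_bp <- gap_bp + sum(m$agp$object_end[g] - m$agp$object_beg[g] + 1L)
      total_bp <- total_bp + m$length
    }
    data.frame(unit = u$name, kind = u$kind, objects = length(u$members),
               total_bp = total_bp, gap_count = gap_count, gap_bp = gap_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
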