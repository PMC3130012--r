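# Chromosome context for alternate loci and patches. An alternate scaffold
# gets no chromosome coordinates of its own; instead it is aligned to the
# primary chromosome through the anchor components shared by both tiling
# paths, and the alignment's gapless blocks become the placement used for
# coordinate liftover.

# object-coordinate span occupied by component positions [s, e] in an AGP row
component_span_to_object <- function(row, s, e) {
  if (row$orientation == "+") {
    c(row$object_beg + (s - row$component_beg),
      row$object_beg + (e - row$component_beg))
  } else {
    c(row$object_beg + (row$component_end - e),
      row$object_beg + (row$component_end - s))
  }
}

anchor_blocks <- function(alt_rows, primary_rows) {
  alt_comp <- alt_rows[!is_gap_row(alt_rows), , drop = FALSE]
  pri_comp <- primary_rows[!is_gap_row(primary_rows), , drop = FALSE]
  shared <- intersect(alt_comp$component_id, pri_comp$component_id)
  blocks <- list()
  for (acc in shared) {
    a <- alt_comp[alt_comp$component_id == acc, ][1L, ]
    p <- pri_comp[pri_comp$component_id == acc, ][1L, ]
    if (a$orientation != p$orientation) next   # inverted use: not an anchor
    s <- max(a$component_beg, p$component_beg)
    e <- min(a$component_end, p$component_end)
    if (e < s) next
    aspan <- component_span_to_object(a, s, e)
    pspan <- component_span_to_object(p, s, e)
    blocks[[length(blocks) + 1L]] <-
      data.frame(alt_start = aspan[1L], alt_stop = aspan[2L],
                 parent_start = pspan[1L], parent_stop = pspan[2L])
  }
  if (!length(blocks)) return(NULL)
  out <- do.call(rbind, blocks)
  out[order(out$alt_start), , drop = FALSE]
}

# global alignment of two segments, decomposed into gapless blocks with
# absolute 1-based coordinates (alt_off/par_off are the positions *before*
# the first base of each segment)
align_segment_blocks <- function(alt_seg, par_seg, alt_off, par_off,
                                 match = 1, mismatch = -1,
                                 gap_opening = 5, gap_extension = 1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(alt_seg), subject = Biostrings::DNAString(par_seg),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_opening, gapExtension = gap_extension)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  state <- ifelse(ap != "-" & as != "-", "M", ifelse(as == "-", "I", "D"))
  r <- rle(state)
  api <- cumsum(ap != "-")   # alt position after each column
  asi <- cumsum(as != "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] != "M") next
    blocks[[length(blocks) + 1L]] <- data.frame(
      alt_start = alt_off + api[starts[i]],
      alt_stop = alt_off + api[ends[i]],
      parent_start = par_off + asi[starts[i]],
      parent_stop = par_off + asi[ends[i]])
  }
  if (length(blocks)) do.call(rbind, blocks) else NULL
}

merge_abutting_blocks <- function(blocks) {
  blocks <- blocks[order(blocks$alt_start), , drop = FALSE]
  out <- blocks[1L, , drop = FALSE]
  if (nrow(blocks) > 1L) for (i in 2:nrow(blocks)) {
    j <- nrow(out)
    if (blocks$alt_start[i] == out$alt_stop[j] + 1L &&
        blocks$parent_start[i] == out$parent_stop[j] + 1L) {
      out$alt_stop[j] <- blocks$alt_stop[i]
      out$parent_stop[j] <- blocks$parent_stop[i]
    } else {
      out <- rbind(out, blocks[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Place an alternate scaffold on its chromosome by anchored alignment
#'
#' Components shared between the alternate and the primary tiling path (the
#' anchor clones) define exact aligned blocks. Each inter-anchor segment pair
#' is then globally aligned (match +1, mismatch -1, gap open -5, gap extend
#' -1) and split into gapless blocks. Leading/trailing segments outside the
#' outermost anchors are aligned the same way when both sides have sequence.
#'
#' @param alt_rows AGP rows of the alternate scaffold (single object).
#' @param primary_rows AGP rows of the primary chromosome (single object).
#' @param component_seqs Named character vector of component sequences.
#' @return A \code{placement} of the alternate scaffold onto the chromosome.
#'   Fails with an unplaceable error when the two paths share no anchor
#'   component (the scaffold then stays unlocalized/unplaced).
#' @export
anchor_align <- function(alt_rows, primary_rows, component_seqs) {
  alt_rows <- as.data.frame(alt_rows)
  primary_rows <- as.data.frame(primary_rows)
  alt_name <- alt_rows$object[1L]
  parent_name <- primary_rows$object[1L]
  anchors <- anchor_blocks(alt_rows, primary_rows)
  if (is.null(anchors)) {
    stop("unplaceable: '", alt_name, "' and '", parent_name,
         "' share no anchor component", call. = FALSE)
  }
  if (is.unsorted(anchors$parent_start, strictly = TRUE) && nrow(anchors) > 1L) {
    stop("anchor components are ordered differently on the two paths", call. = FALSE)
  }
  alt_seq <- build_object_sequence(alt_rows, component_seqs)
  par_seq <- build_object_sequence(primary_rows, component_seqs)
  blocks <- anchors
  segs <- list()
  # inter-anchor segments
  if (nrow(anchors) > 1L) for (i in seq_len(nrow(anchors) - 1L)) {
    segs[[length(segs) + 1L]] <- c(anchors$alt_stop[i], anchors$alt_start[i + 1L],
                                   anchors$parent_stop[i], anchors$parent_start[i + 1L])
  }
  # flanks outside the outermost anchors
  segs[[length(segs) + 1L]] <- c(0L, anchors$alt_start[1L],
                                 0L, anchors$parent_start[1L])
  segs[[length(segs) + 1L]] <- c(anchors$alt_stop[nrow(anchors)], nchar(alt_seq) + 1L,
                                 anchors$parent_stop[nrow(anchors)], nchar(par_seq) + 1L)
  for (s in segs) {
    a0 <- s[1L]; a1 <- s[2L]; p0 <- s[3L]; p1 <- s[4L]
    if (a1 - a0 > 1L && p1 - p0 > 1L) {
      alt_seg <- substr(alt_seq, a0 + 1L, a1 - 1L)
      par_seg <- substr(par_seq, p0 + 1L, p1 - 1L)
      nb <- align_segment_blocks(alt_seg, par_seg, a0, p0)
      if (!is.null(nb)) blocks <- rbind(blocks, nb)
    }
  }
  placement(alt_name, parent_name, merge_abutting_blocks(blocks))
}

#' Lift a position across a placement
#'
#' Positions inside an aligned block map by exact offset; positions that fall
#' between blocks (inside an indel) do not map, and the nearest flanking
#' mapped positions on the target axis are reported instead so callers can
#' choose their own rounding convention. Liftover is a partial bijection:
#' mapping a mappable position there and back is the identity.
#'
#' @param pl A \code{placement}.
#' @param position 1-based position on the source axis.
#' @param direction \code{"alt_to_primary"} or \code{"primary_to_alt"}.
#' @return A list with \code{mapped} (logical), \code{position} (when
#'   mapped), and \code{flank_lower}/\code{flank_upper} (nearest mapped
#'   target positions, when not).
#' @export
liftover <- function(pl, position, direction = c("alt_to_primary", "primary_to_alt")) {
  direction <- match.arg(direction)
  b <- pl$blocks
  if (direction == "alt_to_primary") {
    src_start <- b$alt_start; src_stop <- b$alt_stop
    dst_start <- b$parent_start; dst_stop <- b$parent_stop
    lo <- pl$alt_start; hi <- pl$alt_stop
  } else {
    src_start <- b$parent_start; src_stop <- b$parent_stop
    dst_start <- b$alt_start; dst_stop <- b$alt_stop
    lo <- pl$parent_start; hi <- pl$parent_stop
  }
  position <- as.integer(position)
  if (position < lo || position > hi) {
    stop("position ", position, " outside placement span ", lo, "-", hi, call. = FALSE)
  }
  i <- which(src_start <= position & position <= src_stop)
  if (length(i) == 1L) {
    return(list(mapped = TRUE, position = dst_start[i] + (position - src_start[i]),
                flank_lower = NA_integer_, flank_upper = NA_integer_))
  }
  before <- which(src_stop < position)
  after <- which(src_start > position)
  list(mapped = FALSE, position = NA_integer_,
       flank_lower = if (length(before)) dst_stop[max(before)] else NA_integer_,
       flank_upper = if (length(after)) dst_start[min(after)] else NA_integer_)
}

#' Classify the indels implied by a placement
#'
#' The gaps between consecutive aligned blocks are classified by which axis
#' advances: sequence present only on the alternate scaffold is an
#' insertion-in-alt; sequence present only on the chromosome is a
#' deletion-in-alt. A gap where both axes advance yields one record of each
#' kind.
#'
#' @param pl A \code{placement}.
#' @return Data frame with columns kind, alt_start, alt_stop, parent_start,
#'   parent_stop, length. For an insertion the parent span gives the two
#'   flanking mapped chromosome positions; for a deletion the alt span gives
#'   the flanking scaffold positions.
#' @export
diff_blocks <- function(pl) {
  b <- pl$blocks
  out <- data.frame(kind = character(), alt_start = integer(), alt_stop = integer(),
                    parent_start = integer(), parent_stop = integer(),
                    length = integer(), stringsAsFactors = FALSE)
  if (nrow(b) < 2L) return(out)
  for (i in seq_len(nrow(b) - 1L)) {
    ga <- b$alt_start[i + 1L] - b$alt_stop[i] - 1L
    gp <- b$parent_start[i + 1L] - b$parent_stop[i] - 1L
    if (ga > 0L) {
      out <- rbind(out, data.frame(
        kind = "insertion-in-alt",
        alt_start = b$alt_stop[i] + 1L, alt_stop = b$alt_start[i + 1L] - 1L,
        parent_start = b$parent_stop[i], parent_stop = b$parent_start[i + 1L],
        length = ga, stringsAsFactors = FALSE))
    }
    if (gp > 0L) {
      out <- rbind(out, data.frame(
        kind = "deletion-in-alt",
        alt_start = b$alt_stop[i], alt_stop = b$alt_start[i + 1L],
        parent_start = b$parent_stop[i] + 1L, parent_stop = b$parent_start[i + 1L] - 1L,
        length = gp, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
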