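# Readers and writers for the model's file formats: 9-column AGP, GRC-style
# TPF, FASTA (via Biostrings), the placement TSV that carries alignment-based
# chromosome context, and the curation-issue table. All round-trips are
# lossless for canonical input: lines end in "\n", fields are tab-separated,
# comment lines start with "#" and are kept at the top of the file.

read_lines_norm <- function(path) {
  x <- readLines(path, warn = FALSE)
  # strip carriage returns and trailing spaces; keep tabs, which delimit a
  # trailing empty field (canonical AGP gap rows end in one)
  sub("[ \r]+$", "", x)
}

split_fields <- function(line) {
  # keep trailing empty fields (strsplit drops them)
  f <- strsplit(paste0(line, "\x01"), "\t", fixed = TRUE)[[1L]]
  f[length(f)] <- sub("\x01$", "", f[length(f)])
  f
}

parse_int <- function(x, what, lineno) {
  v <- suppressWarnings(as.integer(x))
  if (any(is.na(v)) || any(as.character(v) != x)) {
    stop(sprintf("line %d: non-integer %s: '%s'", lineno, what, x), call. = FALSE)
  }
  v
}

# ---- AGP -------------------------------------------------------------------

#' Read an AGP file
#'
#' Parses a 9-column tab-separated AGP file. Component codes W/F/A/D/O/P are
#' all treated as component rows; N and U are gap rows. Comment lines
#' (\code{#...}) are preserved in the \code{"comments"} attribute and
#' re-emitted at the top of the file by \code{\link{write_agp}}.
#'
#' @param path File path.
#' @return An \code{agp} data frame (one row per AGP line, possibly several
#'   objects).
#' @export
read_agp <- function(path) {
  lines <- read_lines_norm(path)
  comments <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    lineno <- which(lines == body[i])[1L]
    f <- split_fields(body[i])
    if (length(f) != 9L) {
      stop(sprintf("line %d: expected 9 AGP columns, found %d", lineno, length(f)),
           call. = FALSE)
    }
    kind <- f[5L]
    beg <- parse_int(f[2L], "object_beg", lineno)
    end <- parse_int(f[3L], "object_end", lineno)
    part <- parse_int(f[4L], "part_number", lineno)
    if (kind %in% c("W", "F", "A", "D", "O", "P")) {
      rows[[i]] <- agp_component_row(
        object = f[1L], object_beg = beg, object_end = end, part_number = part,
        component_id = f[6L],
        component_beg = parse_int(f[7L], "component_beg", lineno),
        component_end = parse_int(f[8L], "component_end", lineno),
        orientation = f[9L], component_type = kind)
    } else if (kind %in% c("N", "U")) {
      gt <- f[7L]
      if (!gt %in% c("contig", "clone", "scaffold-break")) gt <- "scaffold-break"
      rows[[i]] <- agp_gap_row(
        object = f[1L], object_beg = beg, object_end = end, part_number = part,
        gap_length = parse_int(f[6L], "gap_length", lineno),
        gap_type = gt, linkage = identical(f[8L], "yes"), known = kind == "N")
    } else {
      stop(sprintf("line %d: unknown AGP row kind '%s'", lineno, kind), call. = FALSE)
    }
  }
  out <- do.call(agp, rows)
  attr(out, "comments") <- comments
  out
}

#' Write an AGP file
#'
#' @param x An \code{agp} data frame.
#' @param path File path.
#' @return Invisibly, \code{path}.
#' @export
write_agp <- function(x, path) {
  x <- as.data.frame(x)
  lines <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    lines[i] <- if (r$component_type %in% c("N", "U")) {
      paste(r$object, r$object_beg, r$object_end, r$part_number,
            r$component_type, r$gap_length, r$gap_type,
            if (isTRUE(r$linkage)) "yes" else "no", "", sep = "\t")
    } else {
      paste(r$object, r$object_beg, r$object_end, r$part_number,
            r$component_type, r$component_id, r$component_beg,
            r$component_end, r$orientation, sep = "\t")
    }
  }
  comments <- attr(x, "comments")
  writeLines(c(comments, lines), path, sep = "\n")
  invisible(path)
}

# ---- TPF -------------------------------------------------------------------

#' Construct a tiling path
#'
#' A TPF gives the ordered component accessions used to build one object.
#' Gap rows mark places where adjacent components do not overlap.
#'
#' @param rows Data frame with columns row_type ("component"/"gap"),
#'   accession, object, orientation, gap_type, gap_length.
#' @return A \code{tpf} data frame.
#' @export
tpf <- function(rows) {
  need <- c("row_type", "accession", "object", "orientation", "gap_type", "gap_length")
  stopifnot(all(need %in% names(rows)))
  rows <- as.data.frame(rows)[, need]
  for (obj in unique(rows$object)) {
    acc <- rows$accession[rows$row_type == "component" & rows$object == obj]
    if (anyDuplicated(acc)) {
      stop("component appears more than once in tiling path '", obj, "': ",
           paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
    }
  }
  rownames(rows) <- NULL
  structure(rows, class = c("tpf", "data.frame"))
}

#' Construct one tiling-path component row
#' @param accession Versioned component accession.
#' @param object Object the path builds.
#' @param orientation \code{"+"} or \code{"-"}.
#' @return One-row data frame suitable for \code{\link{tpf}}.
#' @export
tpf_component <- function(accession, object, orientation = "+") {
  data.frame(row_type = "component", accession = accession, object = object,
             orientation = orientation, gap_type = NA_character_,
             gap_length = NA_integer_, stringsAsFactors = FALSE)
}

#' Construct one tiling-path gap row
#' @param object Object the path builds.
#' @param gap_type Gap kind.
#' @param gap_length Length in bp, or \code{NA} when unknown.
#' @return One-row data frame suitable for \code{\link{tpf}}.
#' @export
tpf_gap <- function(object, gap_type = "contig", gap_length = NA) {
  data.frame(row_type = "gap", accession = NA_character_, object = object,
             orientation = NA_character_, gap_type = gap_type,
             gap_length = as.integer(gap_length), stringsAsFactors = FALSE)
}

#' Read a tiling path file
#'
#' Component rows are \code{accession<TAB>object<TAB>orientation}; gap rows
#' are \code{GAP<TAB>kind<TAB>length} with \code{na} for unknown length. A
#' gap row belongs to the object of the preceding component row.
#'
#' @param path File path.
#' @return A \code{tpf} data frame.
#' @export
read_tpf <- function(path) {
  lines <- read_lines_norm(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- vector("list", length(body))
  current_object <- NA_character_
  for (i in seq_along(body)) {
    f <- split_fields(body[i])
    if (identical(f[1L], "GAP")) {
      if (length(f) < 2L) stop(sprintf("line %d: GAP row needs a kind", i), call. = FALSE)
      if (is.na(current_object)) stop(sprintf("line %d: GAP row before any component", i), call. = FALSE)
      gl <- if (length(f) >= 3L && !identical(f[3L], "na")) parse_int(f[3L], "gap length", i) else NA_integer_
      gt <- if (f[2L] %in% c("contig", "clone", "scaffold-break")) f[2L] else "scaffold-break"
      rows[[i]] <- tpf_gap(current_object, gt, gl)
    } else {
      if (length(f) < 2L) stop(sprintf("line %d: expected accession and object", i), call. = FALSE)
      ori <- if (length(f) >= 3L && nzchar(f[3L])) normalize_orientation(f[3L]) else "+"
      current_object <- f[2L]
      rows[[i]] <- tpf_component(f[1L], f[2L], ori)
    }
  }
  tpf(do.call(rbind, rows))
}

#' Write a tiling path file
#'
#' @param x A \code{tpf} data frame.
#' @param path File path.
#' @return Invisibly, \code{path}.
#' @export
write_tpf <- function(x, path) {
  x <- as.data.frame(x)
  lines <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    lines[i] <- if (x$row_type[i] == "gap") {
      paste("GAP", x$gap_type[i],
            if (is.na(x$gap_length[i])) "na" else x$gap_length[i], sep = "\t")
    } else {
      paste(x$accession[i], x$object[i], x$orientation[i], sep = "\t")
    }
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file
#'
#' @param path File path.
#' @return Named character vector of uppercase sequences. Duplicate names are
#'   an error.
#' @export
read_fasta <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(stats::setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA sequence name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(toupper(as.character(set)), nm)
}

#' Write a FASTA file (60-column canonical form)
#'
#' @param seqs Named character vector.
#' @param path File path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA sequence name", call. = FALSE)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# ---- placements ------------------------------------------------------------

#' Placement record: alignment of an alternate locus or patch onto a chromosome
#'
#' A placement gives a scaffold its chromosome context by alignment rather
#' than coordinates: a list of gapless aligned blocks between the scaffold
#' ("alt") axis and the primary chromosome ("parent") axis. Blocks are sorted
#' and non-overlapping on both axes and each block has equal length on both.
#'
#' @param alt_name Scaffold name.
#' @param parent_name Primary chromosome name.
#' @param blocks Data frame with columns alt_start, alt_stop, parent_start,
#'   parent_stop (1-based inclusive).
#' @param orientation Placement orientation (\code{"+"} only, currently).
#' @param alt_start,alt_stop,parent_start,parent_stop Overall spans; default
#'   to the hull of the blocks.
#' @return An object of class \code{placement}.
#' @export
placement <- function(alt_name, parent_name, blocks, orientation = "+",
                      alt_start = NULL, alt_stop = NULL,
                      parent_start = NULL, parent_stop = NULL) {
  blocks <- as.data.frame(blocks)
  need <- c("alt_start", "alt_stop", "parent_start", "parent_stop")
  stopifnot(all(need %in% names(blocks)), nrow(blocks) >= 1L)
  blocks[] <- lapply(blocks[need], as.integer)
  alen <- blocks$alt_stop - blocks$alt_start
  plen <- blocks$parent_stop - blocks$parent_start
  if (any(alen < 0L) || any(plen < 0L)) stop("malformed placement block span", call. = FALSE)
  if (any(alen != plen)) {
    stop("placement block lengths differ between alt and parent axes", call. = FALSE)
  }
  if (is.unsorted(blocks$alt_start, strictly = TRUE) ||
      is.unsorted(blocks$parent_start, strictly = TRUE)) {
    stop("placement blocks must be sorted on both axes", call. = FALSE)
  }
  n <- nrow(blocks)
  if (n > 1L) {
    if (any(blocks$alt_start[-1L] <= blocks$alt_stop[-n]) ||
        any(blocks$parent_start[-1L] <= blocks$parent_stop[-n])) {
      stop("placement blocks overlap", call. = FALSE)
    }
  }
  structure(list(
    alt_name = alt_name, parent_name = parent_name,
    alt_start = as.integer(alt_start %||% min(blocks$alt_start)),
    alt_stop = as.integer(alt_stop %||% max(blocks$alt_stop)),
    parent_start = as.integer(parent_start %||% min(blocks$parent_start)),
    parent_stop = as.integer(parent_stop %||% max(blocks$parent_stop)),
    orientation = orientation, blocks = blocks),
    class = "placement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement> %s:%d-%d -> %s:%d-%d (%s), %d block(s)\n",
              x$alt_name, x$alt_start, x$alt_stop,
              x$parent_name, x$parent_start, x$parent_stop,
              x$orientation, nrow(x$blocks)))
  invisible(x)
}

format_blocks <- function(blocks) {
  paste(sprintf("%d-%d:%d-%d", blocks$alt_start, blocks$alt_stop,
                blocks$parent_start, blocks$parent_stop), collapse = ";")
}

parse_blocks <- function(s, lineno) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+):([0-9]+)-([0-9]+)$", parts))
  if (any(vapply(m, length, integer(1)) != 5L)) {
    stop(sprintf("line %d: malformed block list '%s'", lineno, s), call. = FALSE)
  }
  v <- t(vapply(m, function(g) as.integer(g[-1L]), integer(4)))
  data.frame(alt_start = v[, 1L], alt_stop = v[, 2L],
             parent_start = v[, 3L], parent_stop = v[, 4L])
}

#' Read a placement TSV
#'
#' Columns: alt_name, alt_start, alt_stop, parent_name, parent_start,
#' parent_stop, orientation, block list
#' (\code{altStart-altStop:parentStart-parentStop;...}). Placement
#' invariants (sorted, non-overlapping, equal-length blocks) are enforced on
#' read.
#'
#' @param path File path.
#' @return A list of \code{placement}s, named by scaffold.
#' @export
read_placements <- function(path) {
  lines <- read_lines_norm(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  for (i in seq_along(body)) {
    f <- split_fields(body[i])
    if (length(f) != 8L) {
      stop(sprintf("line %d: expected 8 placement columns, found %d", i, length(f)),
           call. = FALSE)
    }
    pl <- placement(alt_name = f[1L], parent_name = f[4L],
                    blocks = parse_blocks(f[8L], i), orientation = f[7L],
                    alt_start = parse_int(f[2L], "alt_start", i),
                    alt_stop = parse_int(f[3L], "alt_stop", i),
                    parent_start = parse_int(f[5L], "parent_start", i),
                    parent_stop = parse_int(f[6L], "parent_stop", i))
    out[[pl$alt_name]] <- pl
  }
  out
}

#' Write a placement TSV
#'
#' @param placements List of \code{placement}s.
#' @param path File path.
#' @param header Optional comment lines (without "#") recording provenance,
#'   e.g. alignment parameters.
#' @return Invisibly, \code{path}.
#' @export
write_placements <- function(placements, path, header = NULL) {
  lines <- vapply(placements, function(p) {
    paste(p$alt_name, p$alt_start, p$alt_stop, p$parent_name,
          p$parent_start, p$parent_stop, p$orientation,
          format_blocks(p$blocks), sep = "\t")
  }, character(1))
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# ---- issues ----------------------------------------------------------------

issue_types <- function() {
  c("clone-problem", "path-problem", "grc-housekeeping", "missing-sequence",
    "variation", "gap", "unknown")
}

#' Read the curation-issue table
#'
#' Tab-separated columns: id, type, status, chromosome, start, stop,
#' resolution release (\code{na} when unresolved).
#'
#' @param path File path.
#' @return An \code{issue_table} data frame.
#' @export
read_issues <- function(path) {
  lines <- read_lines_norm(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- lapply(seq_along(body), function(i) {
    f <- split_fields(body[i])
    if (length(f) != 7L) {
      stop(sprintf("line %d: expected 7 issue columns, found %d", i, length(f)),
           call. = FALSE)
    }
    if (!f[2L] %in% issue_types()) {
      stop(sprintf("line %d: unknown issue type '%s'", i, f[2L]), call. = FALSE)
    }
    data.frame(id = f[1L], type = f[2L], status = f[3L], chromosome = f[4L],
               start = parse_int(f[5L], "start", i),
               stop = parse_int(f[6L], "stop", i),
               resolution_release = if (identical(f[7L], "na")) NA_character_ else f[7L],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), type = character(), status = character(),
               chromosome = character(), start = integer(), stop = integer(),
               resolution_release = character(), stringsAsFactors = FALSE)
  structure(out, class = c("issue_table", "data.frame"))
}

#' Write the curation-issue table
#'
#' @param issues An \code{issue_table} data frame.
#' @param path File path.
#' @return Invisibly, \code{path}.
#' @export
write_issues <- function(issues, path) {
  issues <- as.data.frame(issues)
  lines <- vapply(seq_len(nrow(issues)), function(i) {
    r <- issues[i, ]
    paste(r$id, r$type, r$status, r$chromosome, r$start, r$stop,
          if (is.na(r$resolution_release)) "na" else r$resolution_release,
          sep = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
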