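# The release state machine: cumulative minor releases that add FIX/NOVEL
# patch scaffolds without touching primary coordinates, and major releases
# that splice FIX patches into the chromosomes, promote NOVEL patches to
# alternate-loci units, and emit an old<->new coordinate remap table.
# Also the curation-issue tracker.

#' Genome patch
#'
#' A patch is a scaffold released between major assemblies. A FIX patch
#' corrects an assembly error and is rolled into the chromosome (and
#' retired) at the next major release; a NOVEL patch adds a new alternate
#' locus and is promoted to an alternate-loci unit instead. Patches give
#' users timely access to improvements without disrupting the chromosome
#' coordinate system.
#'
#' @param scaffold The patch \code{assembled_object}.
#' @param kind \code{"FIX"} or \code{"NOVEL"}.
#' @param sequence Built scaffold sequence.
#' @param region The \code{assembly_region} the patch updates.
#' @param placement \code{placement} of the scaffold on its chromosome.
#' @param introduced_in \code{release_version} (set by
#'   \code{\link{minor_release}}).
#' @return An object of class \code{genome_patch}.
#' @export
genome_patch <- function(scaffold, kind = c("FIX", "NOVEL"), sequence,
                         region, placement, introduced_in = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(scaffold, "assembled_object"), inherits(placement, "placement"))
  structure(list(scaffold = scaffold, kind = kind, sequence = sequence,
                 region = region, placement = placement,
                 introduced_in = introduced_in, state = "active"),
            class = "genome_patch")
}

active_patches <- function(asm, kind = NULL) {
  ps <- Filter(function(p) p$state == "active", asm$patches)
  if (!is.null(kind)) ps <- Filter(function(p) p$kind == kind, ps)
  ps
}

spans_overlap <- function(a_start, a_stop, b_start, b_stop) {
  a_start <= b_stop && b_start <= a_stop
}

#' Apply a minor release: add patches without moving a single coordinate
#'
#' Minor releases are cumulative: the PATCHES unit after the release holds
#' every previously active patch plus the new ones. The primary-unit
#' sequences are asserted bit-identical before and after (the
#' coordinate-stability contract).
#'
#' @param asm An \code{assembly}.
#' @param new_patches List of \code{genome_patch}es, each with a valid
#'   placement. A new patch must not overlap any active patch on the
#'   primary chromosome.
#' @return The assembly at the next patch version.
#' @export
minor_release <- function(asm, new_patches) {
  primary_before <- primary_sequences(asm)
  placements_before <- asm$placements
  next_version <- release_version(asm$version$major, asm$version$patch + 1L)
  pu_idx <- which(vapply(asm$units, `[[`, character(1), "kind") == "patches")
  if (!length(pu_idx)) {
    asm$units[["PATCHES"]] <- assembly_unit("PATCHES", "patches")
    pu_idx <- which(names(asm$units) == "PATCHES")
  }
  for (p in new_patches) {
    stopifnot(inherits(p, "genome_patch"))
    if (is.null(p$placement)) stop("patch ", p$scaffold$name, " has no placement", call. = FALSE)
    for (q in active_patches(asm)) {
      if (identical(q$placement$parent_name, p$placement$parent_name) &&
          spans_overlap(p$placement$parent_start, p$placement$parent_stop,
                        q$placement$parent_start, q$placement$parent_stop)) {
        stop("patch ", p$scaffold$name, " overlaps active patch ",
             q$scaffold$name, " on ", p$placement$parent_name, call. = FALSE)
      }
    }
    p$introduced_in <- next_version
    asm$patches[[p$scaffold$name]] <- p
    asm$units[[pu_idx]]$members[[p$scaffold$name]] <- p$scaffold
    asm$placements[[p$scaffold$name]] <- p$placement
    asm$sequences[[p$scaffold$name]] <- p$sequence
    rn <- p$region$region_name
    if (is.null(asm$regions[[rn]])) {
      asm$regions[[rn]] <- p$region
    }
    asm$regions[[rn]]$linked <- rbind(
      asm$regions[[rn]]$linked,
      data.frame(scaffold = p$scaffold$name,
                 role = if (p$kind == "FIX") "fix-patch" else "novel-patch",
                 stringsAsFactors = FALSE))
  }
  asm$version <- next_version
  if (!identical(primary_sequences(asm), primary_before)) {
    stop("coordinate-stability violation: primary sequences changed in a minor release",
         call. = FALSE)
  }
  for (nm in names(placements_before)) {
    if (!identical(asm$placements[[nm]], placements_before[[nm]])) {
      stop("coordinate-stability violation: existing placement changed in a minor release",
           call. = FALSE)
    }
  }
  asm
}

primary_sequences <- function(asm) {
  pu <- primary_unit(asm)
  nm <- names(pu$members)
  asm$sequences[nm[nm %in% names(asm$sequences)]]
}

#' Should the next major release happen?
#'
#' Major updates are made infrequently: only once at least
#' \code{fix_threshold} FIX patches have accumulated, or more than
#' \code{pct_threshold} percent of the euchromatic sequence is affected.
#'
#' @param n_fix_patches Number of active FIX patches (>= 0).
#' @param pct_euchromatin_affected Percentage in [0, 100].
#' @param fix_threshold Patch-count threshold (default 100).
#' @param pct_threshold Percentage threshold (default 1; the comparison is
#'   strict).
#' @return \code{TRUE} iff \code{n_fix_patches >= fix_threshold} or
#'   \code{pct_euchromatin_affected > pct_threshold}.
#' @export
release_decision <- function(n_fix_patches, pct_euchromatin_affected,
                             fix_threshold = 100L, pct_threshold = 1) {
  stopifnot(n_fix_patches >= 0,
            pct_euchromatin_affected >= 0, pct_euchromatin_affected <= 100)
  n_fix_patches >= fix_threshold || pct_euchromatin_affected > pct_threshold
}

#' Percentage of euchromatic sequence affected by active FIX patches
#'
#' Euchromatic sequence is operationalized as the non-gap sequence of the
#' primary unit. The numerator is the union (counted once) of the FIX-patch
#' placement spans intersected with non-gap positions.
#'
#' @param asm An \code{assembly}.
#' @return Percentage in [0, 100].
#' @export
pct_euchromatin_affected <- function(asm) {
  pu <- primary_unit(asm)
  total <- 0; affected <- 0
  fix <- active_patches(asm, "FIX")
  for (m in pu$members) {
    gap <- is_gap_row(m$agp)
    nongap <- rep(TRUE, m$length)
    for (i in which(gap)) nongap[m$agp$object_beg[i]:m$agp$object_end[i]] <- FALSE
    total <- total + sum(nongap)
    cov <- rep(FALSE, m$length)
    for (p in fix) {
      if (identical(p$placement$parent_name, m$name)) {
        s <- max(1L, p$placement$parent_start)
        e <- min(m$length, p$placement$parent_stop)
        if (e >= s) cov[s:e] <- TRUE
      }
    }
    affected <- affected + sum(cov & nongap)
  }
  if (total == 0) return(0)
  100 * affected / total
}

# clip an object's AGP rows to [lo, hi] (object coordinates), preserving
# component coordinates; returns rows with object coords still absolute
clip_agp_to_span <- function(rows, lo, hi) {
  keep <- rows$object_end >= lo & rows$object_beg <= hi
  rows <- rows[keep, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    cut_l <- max(0L, lo - rows$object_beg[i])
    cut_r <- max(0L, rows$object_end[i] - hi)
    if (cut_l == 0L && cut_r == 0L) next
    if (rows$component_type[i] %in% c("N", "U")) {
      rows$gap_length[i] <- rows$gap_length[i] - cut_l - cut_r
    } else if (rows$orientation[i] == "+") {
      rows$component_beg[i] <- rows$component_beg[i] + cut_l
      rows$component_end[i] <- rows$component_end[i] - cut_r
    } else {
      rows$component_beg[i] <- rows$component_beg[i] + cut_r
      rows$component_end[i] <- rows$component_end[i] - cut_l
    }
    rows$object_beg[i] <- rows$object_beg[i] + cut_l
    rows$object_end[i] <- rows$object_end[i] - cut_r
  }
  rows
}

shift_rows <- function(rows, delta, new_object = NULL) {
  rows$object_beg <- rows$object_beg + as.integer(delta)
  rows$object_end <- rows$object_end + as.integer(delta)
  if (!is.null(new_object)) rows$object <- new_object
  rows
}

remap_block <- function(remap, s, e) {
  i <- which(remap$old_start <= s & e <= remap$old_end)
  if (length(i) != 1L) return(NULL)
  c(s + remap$offset[i], e + remap$offset[i])
}

remap_placement <- function(pl, remap_tables) {
  remap <- remap_tables[[pl$parent_name]]
  if (is.null(remap)) return(pl)
  b <- pl$blocks
  for (i in seq_len(nrow(b))) {
    nb <- remap_block(remap, b$parent_start[i], b$parent_stop[i])
    if (is.null(nb)) {
      stop("placement of ", pl$alt_name,
           " overlaps a spliced region; curation required", call. = FALSE)
    }
    b$parent_start[i] <- nb[1L]; b$parent_stop[i] <- nb[2L]
  }
  placement(pl$alt_name, pl$parent_name, b, pl$orientation)
}

#' Lift a position across a major-release remap table
#'
#' @param remap Remap table for one chromosome (columns old_start, old_end,
#'   new_start, new_end, offset).
#' @param position 1-based position.
#' @param direction \code{"old_to_new"} or \code{"new_to_old"}.
#' @return List with \code{mapped} and \code{position}; positions inside a
#'   replaced span do not map.
#' @export
remap_position <- function(remap, position, direction = c("old_to_new", "new_to_old")) {
  direction <- match.arg(direction)
  position <- as.integer(position)
  if (direction == "old_to_new") {
    i <- which(remap$old_start <= position & position <= remap$old_end)
    if (length(i) == 1L) {
      return(list(mapped = TRUE, position = position + as.integer(remap$offset[i])))
    }
  } else {
    i <- which(remap$new_start <= position & position <= remap$new_end)
    if (length(i) == 1L) {
      return(list(mapped = TRUE, position = position - as.integer(remap$offset[i])))
    }
  }
  list(mapped = FALSE, position = NA_integer_)
}

#' Apply a major release
#'
#' FIX patches are spliced into their chromosomes at their placements
#' (replacing the placed primary span with the placed scaffold span) and
#' retired; NOVEL patches are promoted into an alternate-loci unit whose
#' existing members they do not overlap, with a new unit created when every
#' existing unit conflicts. FIX splicing happens first so that promoted
#' NOVEL placements (and existing alternate-locus placements) can be
#' remapped onto post-splice coordinates. The PATCHES unit is emptied, the
#' major version increments, and the old<->new coordinate remap table is
#' stored in the returned assembly's \code{$remap}.
#'
#' @param asm An \code{assembly}.
#' @param force Apply even when \code{\link{release_decision}} says no
#'   (logged via \code{message}).
#' @return The assembly at the next major version.
#' @export
major_release <- function(asm, force = FALSE) {
  fix <- active_patches(asm, "FIX")
  novel <- active_patches(asm, "NOVEL")
  pct <- pct_euchromatin_affected(asm)
  if (!release_decision(length(fix), pct)) {
    if (!force) {
      stop("release criteria not met (", length(fix), " FIX patches, ",
           sprintf("%.3f", pct), "% euchromatin affected); use force = TRUE",
           call. = FALSE)
    }
    message("major release forced with ", length(fix), " FIX patches and ",
            sprintf("%.3f", pct), "% euchromatin affected")
  }
  pu_idx <- which(vapply(asm$units, `[[`, character(1), "kind") == "primary")
  pu <- asm$units[[pu_idx]]
  remap_tables <- list()
  # ---- splice FIX patches, chromosome by chromosome
  by_chr <- split(fix, vapply(fix, function(p) p$placement$parent_name, character(1)))
  for (chr in names(by_chr)) {
    ps <- by_chr[[chr]]
    starts <- vapply(ps, function(p) p$placement$parent_start, integer(1))
    ps <- ps[order(starts)]
    for (i in seq_len(length(ps) - 1L)) {
      if (ps[[i + 1L]]$placement$parent_start <= ps[[i]]$placement$parent_stop) {
        stop("FIX patches ", ps[[i]]$scaffold$name, " and ",
             ps[[i + 1L]]$scaffold$name,
             " have overlapping placements on ", chr, "; curation required",
             call. = FALSE)
      }
    }
    old_seq <- asm$sequences[[chr]]
    old_len <- nchar(old_seq)
    old_member <- pu$members[[chr]]
    new_pieces <- character(0); new_rows <- list()
    remap <- data.frame(old_start = integer(), old_end = integer(),
                        new_start = integer(), new_end = integer(),
                        offset = integer())
    cursor_old <- 1L; cursor_new <- 0L
    for (p in ps) {
      s <- p$placement$parent_start; e <- p$placement$parent_stop
      as_ <- p$placement$alt_start; ae <- p$placement$alt_stop
      if (cursor_old <= s - 1L) {
        seg_len <- s - cursor_old
        new_pieces <- c(new_pieces, substr(old_seq, cursor_old, s - 1L))
        new_rows[[length(new_rows) + 1L]] <-
          shift_rows(clip_agp_to_span(old_member$agp, cursor_old, s - 1L),
                     cursor_new - (cursor_old - 1L))
        remap <- rbind(remap, data.frame(
          old_start = cursor_old, old_end = s - 1L,
          new_start = cursor_new + 1L, new_end = cursor_new + seg_len,
          offset = cursor_new + 1L - cursor_old))
        cursor_new <- cursor_new + seg_len
      }
      patch_piece <- substr(p$sequence, as_, ae)
      new_pieces <- c(new_pieces, patch_piece)
      new_rows[[length(new_rows) + 1L]] <-
        shift_rows(clip_agp_to_span(p$scaffold$agp, as_, ae),
                   cursor_new - (as_ - 1L), new_object = chr)
      cursor_new <- cursor_new + nchar(patch_piece)
      cursor_old <- e + 1L
    }
    if (cursor_old <= old_len) {
      seg_len <- old_len - cursor_old + 1L
      new_pieces <- c(new_pieces, substr(old_seq, cursor_old, old_len))
      new_rows[[length(new_rows) + 1L]] <-
        shift_rows(clip_agp_to_span(old_member$agp, cursor_old, old_len),
                   cursor_new - (cursor_old - 1L))
      remap <- rbind(remap, data.frame(
        old_start = cursor_old, old_end = old_len,
        new_start = cursor_new + 1L, new_end = cursor_new + seg_len,
        offset = cursor_new + 1L - cursor_old))
    }
    new_seq <- paste(new_pieces, collapse = "")
    rows <- do.call(rbind, new_rows)
    rows$part_number <- seq_len(nrow(rows))
    rownames(rows) <- NULL
    rows <- structure(rows, class = c("agp", "data.frame"))
    pu$members[[chr]] <- assembled_object(chr, "chromosome", rows,
                                          chromosome = old_member$chromosome)
    asm$sequences[[chr]] <- new_seq
    remap_tables[[chr]] <- remap
  }
  asm$units[[pu_idx]] <- pu
  # ---- remap surviving placements onto post-splice coordinates
  fix_names <- vapply(fix, function(p) p$scaffold$name, character(1))
  for (nm in names(asm$placements)) {
    if (nm %in% fix_names) next
    asm$placements[[nm]] <- remap_placement(asm$placements[[nm]], remap_tables)
  }
  # ---- promote NOVEL patches into non-conflicting alt-loci units
  unit_kinds <- vapply(asm$units, `[[`, character(1), "kind")
  for (p in novel) {
    pl <- asm$placements[[p$scaffold$name]]
    placed <- FALSE
    for (ui in which(unit_kinds == "alt-loci")) {
      conflict <- FALSE
      for (other in names(asm$units[[ui]]$members)) {
        q <- asm$placements[[other]]
        if (!is.null(q) && identical(q$parent_name, pl$parent_name) &&
            spans_overlap(pl$parent_start, pl$parent_stop,
                          q$parent_start, q$parent_stop)) {
          conflict <- TRUE; break
        }
      }
      if (!conflict) {
        asm$units[[ui]]$members[[p$scaffold$name]] <- p$scaffold
        placed <- TRUE; break
      }
    }
    if (!placed) {
      k <- sum(unit_kinds == "alt-loci") + 1L
      nm <- paste0("ALT_", k)
      while (nm %in% names(asm$units)) { k <- k + 1L; nm <- paste0("ALT_", k) }
      asm$units[[nm]] <- assembly_unit(nm, "alt-loci",
                                       members = stats::setNames(list(p$scaffold),
                                                                 p$scaffold$name))
      unit_kinds <- vapply(asm$units, `[[`, character(1), "kind")
    }
    asm$patches[[p$scaffold$name]]$state <- "promoted-to-alt"
  }
  # ---- retire FIX patches and empty the PATCHES unit
  for (nm in fix_names) {
    asm$patches[[nm]]$state <- "retired-into-major"
    asm$placements[[nm]] <- NULL
    asm$sequences <- asm$sequences[names(asm$sequences) != nm]
  }
  ppu_idx <- which(unit_kinds == "patches")
  for (ui in ppu_idx) asm$units[[ui]]$members <- list()
  asm$version <- release_version(asm$version$major + 1L, 0L)
  asm$remap <- remap_tables
  asm
}

# ---- issue tracking --------------------------------------------------------

#' Create an empty curation-issue tracker
#' @return An \code{issue_table} data frame.
#' @export
issue_tracker <- function() {
  structure(data.frame(id = character(), type = character(), status = character(),
                       chromosome = character(), start = integer(), stop = integer(),
                       resolution_release = character(), stringsAsFactors = FALSE),
            class = c("issue_table", "data.frame"))
}

#' Open a curation issue
#'
#' @param issues An \code{issue_table}.
#' @param id Issue identifier (unique).
#' @param type One of the issue taxonomy: clone-problem, path-problem,
#'   grc-housekeeping, missing-sequence, variation, gap, unknown.
#' @param chromosome,start,stop Affected region.
#' @return The updated \code{issue_table}.
#' @export
open_issue <- function(issues, id, type, chromosome, start, stop) {
  if (!type %in% issue_types()) {
    stop("unknown issue type '", type, "'; must be one of: ",
         paste(issue_types(), collapse = ", "), call. = FALSE)
  }
  if (id %in% issues$id) stop("issue id already exists: ", id, call. = FALSE)
  row <- data.frame(id = id, type = type, status = "open", chromosome = chromosome,
                    start = as.integer(start), stop = as.integer(stop),
                    resolution_release = NA_character_, stringsAsFactors = FALSE)
  structure(rbind(as.data.frame(issues), row),
            class = c("issue_table", "data.frame"))
}

#' Resolve a curation issue
#'
#' @param issues An \code{issue_table}.
#' @param id Issue identifier.
#' @param release The \code{release_version} (or its formatted string) in
#'   which the issue is resolved.
#' @return The updated \code{issue_table}.
#' @export
resolve_issue <- function(issues, id, release) {
  i <- which(issues$id == id)
  if (!length(i)) stop("no such issue: ", id, call. = FALSE)
  if (issues$status[i] == "resolved") stop("issue already resolved: ", id, call. = FALSE)
  issues$status[i] <- "resolved"
  issues$resolution_release[i] <-
    if (inherits(release, "release_version")) format(release) else as.character(release)
  issues
}

#' Summarize resolved issues by type and resolution release
#'
#' @param issues An \code{issue_table}.
#' @return Data frame with columns resolution_release, type, count, one row
#'   per type per release in which issues were resolved (all seven types are
#'   reported per release, zeros included). The counts sum to the number of
#'   resolved issues.
#' @export
summarize_issues <- function(issues) {
  res <- issues[issues$status == "resolved", , drop = FALSE]
  types <- issue_types()
  if (!nrow(res)) {
    return(data.frame(resolution_release = NA_character_, type = types,
                      count = 0L, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(unique(res$resolution_release), function(rel) {
    sub <- res[res$resolution_release == rel, ]
    data.frame(resolution_release = rel, type = types,
               count = as.integer(table(factor(sub$type, levels = types))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
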