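# Core domain types for the clone-based reference assembly model:
# components, tiling paths, AGP objects, assembly units, regions, and
# release versions, plus the structural validators that enforce the
# model's invariants.

#' Component reference
#'
#' A component is the basic genomic-level sequence from which assemblies are
#' built: typically a clone insert, a WGS contig, or a PCR fragment.
#' Components are identified by a versioned accession (e.g. \code{"AC000001.1"}).
#'
#' @param accession Versioned accession string; must contain exactly one
#'   \code{.<version>} suffix.
#' @param length Component length in bp (>= 1).
#' @param source_kind One of \code{"clone"}, \code{"wgs"}, \code{"pcr"}.
#' @return An object of class \code{component_ref}.
#' @export
component_ref <- function(accession, length, source_kind = c("clone", "wgs", "pcr")) {
  source_kind <- match.arg(source_kind)
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession)) {
    stop("accession must be a non-empty string", call. = FALSE)
  }
  if (!grepl("^[^.]+\\.[0-9]+$", accession)) {
    stop("accession must carry exactly one version suffix (e.g. 'AC000001.1'): ",
         accession, call. = FALSE)
  }
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("component length must be >= 1", call. = FALSE)
  structure(list(accession = accession, length = length, source_kind = source_kind),
            class = "component_ref")
}

#' Gap specification
#'
#' @param gap_length Gap length in bp, or \code{NA} for a gap of unknown size.
#'   Unknown-size gaps are rendered with a fixed conventional length of 100 bp
#'   of \code{N} (see \code{\link{unknown_gap_length}}).
#' @param gap_kind One of \code{"contig"}, \code{"clone"}, \code{"scaffold-break"}.
#' @param linkage Is there linkage evidence across the gap?
#' @return An object of class \code{gap_spec}.
#' @export
gap_spec <- function(gap_length = NA, gap_kind = c("contig", "clone", "scaffold-break"),
                     linkage = TRUE) {
  gap_kind <- match.arg(gap_kind)
  if (!is.na(gap_length)) {
    gap_length <- as.integer(gap_length)
    if (is.na(gap_length) || gap_length < 1L) stop("gap_length must be >= 1 or NA", call. = FALSE)
  } else {
    gap_length <- NA_integer_
  }
  structure(list(gap_length = gap_length, gap_kind = gap_kind,
                 linkage = isTRUE(linkage)),
            class = "gap_spec")
}

#' Conventional rendering length for gaps of unknown size
#'
#' AGP convention for "U" gaps: 100 bp of N.
#' @return Integer scalar, 100.
#' @export
unknown_gap_length <- function() 100L

#' Switch point between two adjacent components
#'
#' The base at which contig sequence generation stops using one component and
#' switches to the next. Both positions are 1-based coordinates inside the
#' verified overlap between the two components.
#'
#' @param from_component,to_component Accessions of the two components.
#' @param position_in_from,position_in_to 1-based positions of the switch
#'   point in each component's own coordinates.
#' @return An object of class \code{switch_point}.
#' @export
switch_point <- function(from_component, to_component, position_in_from, position_in_to) {
  structure(list(from_component = from_component, to_component = to_component,
                 position_in_from = as.integer(position_in_from),
                 position_in_to = as.integer(position_in_to)),
            class = "switch_point")
}

#' Release version
#'
#' Assemblies are versioned as major releases with cumulative minor (patch)
#' releases: patch number 0 is the major release itself and each minor release
#' increments it by one.
#'
#' @param major Major release number (>= 1).
#' @param patch Patch number (>= 0).
#' @return An object of class \code{release_version}.
#' @export
release_version <- function(major = 1L, patch = 0L) {
  major <- as.integer(major); patch <- as.integer(patch)
  stopifnot(major >= 1L, patch >= 0L)
  structure(list(major = major, patch = patch), class = "release_version")
}

#' @export
format.release_version <- function(x, ...) {
  if (x$patch == 0L) paste0("v", x$major) else paste0("v", x$major, ".p", x$patch)
}

#' @export
print.release_version <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

# ---- AGP rows --------------------------------------------------------------

agp_columns <- c("object", "object_beg", "object_end", "part_number",
                 "component_type", "component_id", "component_beg",
                 "component_end", "orientation", "gap_length", "gap_type",
                 "linkage")

empty_agp <- function() {
  structure(data.frame(object = character(), object_beg = integer(),
                       object_end = integer(), part_number = integer(),
                       component_type = character(), component_id = character(),
                       component_beg = integer(), component_end = integer(),
                       orientation = character(), gap_length = integer(),
                       gap_type = character(), linkage = logical(),
                       stringsAsFactors = FALSE),
            class = c("agp", "data.frame"))
}

#' Construct an AGP component row
#'
#' @param object Name of the assembled object this row belongs to.
#' @param object_beg,object_end 1-based inclusive span on the object.
#' @param part_number Row number within the object, consecutive from 1.
#' @param component_id Versioned component accession.
#' @param component_beg,component_end 1-based inclusive span on the component.
#' @param orientation \code{"+"} or \code{"-"}.
#' @param component_type AGP component code (W/F/A/D/O/P); all are treated
#'   uniformly as components.
#' @return One-row \code{agp} data frame.
#' @export
agp_component_row <- function(object, object_beg, object_end, part_number,
                              component_id, component_beg, component_end,
                              orientation = "+", component_type = "W") {
  orientation <- normalize_orientation(orientation)
  structure(data.frame(object = object, object_beg = as.integer(object_beg),
                       object_end = as.integer(object_end),
                       part_number = as.integer(part_number),
                       component_type = component_type,
                       component_id = component_id,
                       component_beg = as.integer(component_beg),
                       component_end = as.integer(component_end),
                       orientation = orientation,
                       gap_length = NA_integer_, gap_type = NA_character_,
                       linkage = NA, stringsAsFactors = FALSE),
            class = c("agp", "data.frame"))
}

#' Construct an AGP gap row
#'
#' @inheritParams agp_component_row
#' @param gap_length Gap length in bp; unknown-size gaps carry the
#'   conventional 100 bp (component_type \code{"U"}).
#' @param gap_type Gap kind: \code{"contig"}, \code{"clone"} or
#'   \code{"scaffold-break"}.
#' @param linkage Linkage evidence across the gap.
#' @param known Is the gap size known (\code{"N"}) or conventional (\code{"U"})?
#' @return One-row \code{agp} data frame.
#' @export
agp_gap_row <- function(object, object_beg, object_end, part_number,
                        gap_length, gap_type = "contig", linkage = TRUE,
                        known = TRUE) {
  structure(data.frame(object = object, object_beg = as.integer(object_beg),
                       object_end = as.integer(object_end),
                       part_number = as.integer(part_number),
                       component_type = if (known) "N" else "U",
                       component_id = NA_character_,
                       component_beg = NA_integer_, component_end = NA_integer_,
                       orientation = NA_character_,
                       gap_length = as.integer(gap_length),
                       gap_type = gap_type, linkage = isTRUE(linkage),
                       stringsAsFactors = FALSE),
            class = c("agp", "data.frame"))
}

#' Bind AGP rows into one AGP table
#' @param ... \code{agp} data frames (rows) to combine.
#' @return An \code{agp} data frame.
#' @export
agp <- function(...) {
  out <- do.call(rbind, lapply(list(...), function(x) {
    stopifnot(is.data.frame(x))
    as.data.frame(x)[, agp_columns]
  }))
  rownames(out) <- NULL
  structure(out, class = c("agp", "data.frame"))
}

is_gap_row <- function(rows) rows$component_type %in% c("N", "U")

# "?" and "na" orientations occur in the wild; mapped to "+" with a warning.
normalize_orientation <- function(x) {
  bad <- x %in% c("?", "na", "0")
  if (any(bad)) {
    warning("orientation '", paste(unique(x[bad]), collapse = "','"),
            "' mapped to '+'", call. = FALSE)
    x[bad] <- "+"
  }
  if (!all(x %in% c("+", "-"))) {
    stop("orientation must be '+' or '-'", call. = FALSE)
  }
  x
}

# ---- assembled objects, units, assemblies ---------------------------------

#' Assembled object (contig, scaffold, or chromosome)
#'
#' Wraps the AGP rows describing one assembled sequence. A contig-rank object
#' must contain no gap rows; a scaffold is an ordered, oriented set of contigs
#' separated by gap rows.
#'
#' @param name Object name (must match the AGP rows' object column).
#' @param rank One of \code{"contig"}, \code{"scaffold"}, \code{"chromosome"}.
#' @param rows \code{agp} data frame for this object.
#' @param chromosome Optional chromosome association (for unlocalized
#'   scaffolds and for chromosome-rank objects).
#' @return An object of class \code{assembled_object}.
#' @export
assembled_object <- function(name, rank = c("contig", "scaffold", "chromosome"),
                             rows, chromosome = NA_character_) {
  rank <- match.arg(rank)
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("assembled object needs at least one AGP row", call. = FALSE)
  if (!all(rows$object == name)) stop("AGP rows belong to a different object", call. = FALSE)
  if (rank == "contig" && any(is_gap_row(rows))) {
    stop("a contig must contain no gap rows", call. = FALSE)
  }
  structure(list(name = name, rank = rank,
                 agp = structure(rows, class = c("agp", "data.frame")),
                 length = max(rows$object_end),
                 chromosome = chromosome),
            class = "assembled_object")
}

#' @export
print.assembled_object <- function(x, ...) {
  cat(sprintf("<assembled_object> %s (%s), %d bp, %d AGP rows\n",
              x$name, x$rank, x$length, nrow(x$agp)))
  invisible(x)
}

#' Assembly unit
#'
#' A container of assembled objects: the primary unit (the non-redundant
#' haploid genome), an alternate-loci unit, or the PATCHES unit.
#'
#' @param name Unit name.
#' @param kind One of \code{"primary"}, \code{"alt-loci"}, \code{"patches"}.
#' @param members List of \code{assembled_object}s.
#' @return An object of class \code{assembly_unit}.
#' @export
assembly_unit <- function(name, kind = c("primary", "alt-loci", "patches"),
                          members = list()) {
  kind <- match.arg(kind)
  if (length(members) && is.null(names(members))) {
    names(members) <- vapply(members, function(m) m$name, character(1))
  }
  structure(list(name = name, kind = kind, members = members),
            class = "assembly_unit")
}

#' Region with linked extra-chromosomal sequences
#'
#' A named span on a primary chromosome that points to the extra-chromosomal
#' sequences representing it: alternate loci, FIX patches, or NOVEL patches.
#' One region may link sequences in several roles simultaneously.
#'
#' @param region_name Region name.
#' @param chromosome Primary chromosome name.
#' @param primary_start,primary_stop 1-based inclusive span on the chromosome.
#' @param linked Data frame with columns \code{scaffold} and \code{role}
#'   (role in \code{"alt-locus"}, \code{"fix-patch"}, \code{"novel-patch"}).
#' @return An object of class \code{assembly_region}.
#' @export
region <- function(region_name, chromosome, primary_start, primary_stop,
                   linked = data.frame(scaffold = character(), role = character())) {
  stopifnot(primary_stop >= primary_start)
  if (nrow(linked) && !all(linked$role %in% c("alt-locus", "fix-patch", "novel-patch"))) {
    stop("region roles must be alt-locus, fix-patch or novel-patch", call. = FALSE)
  }
  structure(list(region_name = region_name, chromosome = chromosome,
                 primary_start = as.integer(primary_start),
                 primary_stop = as.integer(primary_stop),
                 linked = linked),
            class = "assembly_region")
}

#' Assembly: a versioned set of assembly units
#'
#' @param name Assembly name.
#' @param units Named list of \code{assembly_unit}s (exactly one primary).
#' @param sequences Named character vector of built object sequences.
#' @param placements Named list of \code{placement}s, keyed by scaffold name.
#' @param regions Named list of \code{assembly_region}s.
#' @param patches Named list of \code{genome_patch}es, keyed by scaffold name.
#' @param version \code{release_version}.
#' @return An object of class \code{assembly}.
#' @export
assembly <- function(name, units, sequences = character(),
                     placements = list(), regions = list(),
                     patches = list(), version = release_version()) {
  if (is.null(names(units))) names(units) <- vapply(units, `[[`, character(1), "name")
  structure(list(name = name, version = version, units = units,
                 sequences = sequences, placements = placements,
                 regions = regions, patches = patches, remap = NULL),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %s %s: %d unit(s), %d placement(s), %d active patch(es)\n",
              x$name, format(x$version), length(x$units), length(x$placements),
              length(x$patches)))
  for (u in x$units) {
    cat(sprintf("  unit %-12s (%s): %d member(s)\n", u$name, u$kind, length(u$members)))
  }
  invisible(x)
}

primary_unit <- function(asm) {
  kinds <- vapply(asm$units, `[[`, character(1), "kind")
  idx <- which(kinds == "primary")
  if (length(idx) != 1L) stop("assembly must have exactly one primary unit", call. = FALSE)
  asm$units[[idx]]
}

patches_unit <- function(asm) {
  kinds <- vapply(asm$units, `[[`, character(1), "kind")
  idx <- which(kinds == "patches")
  if (length(idx) == 0L) return(NULL)
  asm$units[[idx[1L]]]
}

find_member <- function(asm, name) {
  for (u in asm$units) {
    if (name %in% names(u$members)) return(list(unit = u, member = u$members[[name]]))
  }
  NULL
}

# ---- validation ------------------------------------------------------------

new_report <- function() {
  structure(data.frame(rule = character(), object = character(),
                       detail = character(), severity = character(),
                       stringsAsFactors = FALSE),
            class = c("validation_report", "data.frame"))
}

add_finding <- function(report, rule, object, detail, severity = "error") {
  row <- data.frame(rule = rule, object = object, detail = detail,
                    severity = severity, stringsAsFactors = FALSE)
  structure(rbind(as.data.frame(report), row),
            class = c("validation_report", "data.frame"))
}

#' Is a validation report clean?
#'
#' @param report A \code{validation_report}.
#' @return \code{TRUE} when the report carries no error-severity findings
#'   (warnings, e.g. the 5 Mb alternate-locus size advisory, do not
#'   invalidate).
#' @export
is_valid <- function(report) {
  !any(report$severity == "error")
}

#' Validate the AGP rows of one assembled object
#'
#' Checks the AGP tiling invariants: all rows name the same object, part
#' numbers are consecutive from 1, spans are well formed, component spans
#' match their object spans, and adjacent rows tile the object with no
#' coordinate holes or overlaps. Violations are reported as data, never as
#' exceptions: the report lists every violated invariant and is empty iff the
#' object is valid.
#'
#' @param rows \code{agp} data frame for a single object.
#' @return A \code{validation_report} data frame with columns rule, object,
#'   detail, severity.
#' @export
validate_agp_object <- function(rows) {
  report <- new_report()
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) {
    return(add_finding(report, "non-empty", NA_character_, "no AGP rows"))
  }
  obj <- rows$object[1L]
  if (length(unique(rows$object)) != 1L) {
    report <- add_finding(report, "single-object", obj,
                          paste("rows name several objects:",
                                paste(unique(rows$object), collapse = ", ")))
  }
  if (!identical(as.integer(rows$part_number), seq_len(nrow(rows)))) {
    report <- add_finding(report, "part-numbers", obj,
                          "part numbers are not consecutive from 1")
  }
  bad_span <- which(rows$object_end < rows$object_beg)
  for (i in bad_span) {
    report <- add_finding(report, "span", obj,
                          sprintf("row %d: object_end < object_beg", i))
  }
  comp <- which(!is_gap_row(rows))
  for (i in comp) {
    ospan <- rows$object_end[i] - rows$object_beg[i]
    cspan <- rows$component_end[i] - rows$component_beg[i]
    if (is.na(cspan) || cspan != ospan) {
      report <- add_finding(report, "length-mismatch", obj,
                            sprintf("row %d: object span %d bp != component span %s bp",
                                    i, ospan + 1L,
                                    if (is.na(cspan)) "NA" else cspan + 1L))
    }
  }
  # tiling: rows sorted by object_beg must abut exactly, starting at 1
  ord <- order(rows$object_beg)
  beg <- rows$object_beg[ord]; end <- rows$object_end[ord]
  if (beg[1L] != 1L) {
    report <- add_finding(report, "tiling", obj,
                          sprintf("object does not start at 1 (starts at %d)", beg[1L]))
  }
  if (length(beg) > 1L) {
    for (i in seq_len(length(beg) - 1L)) {
      nxt <- beg[i + 1L]; prev_end <- end[i]
      if (nxt > prev_end + 1L) {
        report <- add_finding(report, "coordinate-hole", obj,
                              sprintf("hole at %d-%d", prev_end + 1L, nxt - 1L))
      } else if (nxt <= prev_end) {
        report <- add_finding(report, "coordinate-overlap", obj,
                              sprintf("rows overlap at %d-%d", nxt, prev_end))
      }
    }
  }
  report
}

#' Validate an assembly's structural invariants
#'
#' Checks that the assembly has exactly one primary unit; that every member
#' of an alternate-loci or PATCHES unit has a placement; that placements
#' within one alternate-loci unit do not overlap each other on the primary
#' chromosome; that unlocalized members carry a chromosome and unplaced
#' members none; that every FIX/NOVEL patch lives in the PATCHES unit; and
#' that each member's AGP rows are themselves valid. Alternate loci over
#' 5 Mb draw a warning-severity finding, never an error (there is no hard
#' size limit).
#'
#' @param asm An \code{assembly}.
#' @return A \code{validation_report}.
#' @export
validate_assembly <- function(asm) {
  report <- new_report()
  kinds <- vapply(asm$units, `[[`, character(1), "kind")
  if (sum(kinds == "primary") != 1L) {
    report <- add_finding(report, "one-primary-unit", asm$name,
                          sprintf("%d primary units", sum(kinds == "primary")))
  }
  for (u in asm$units) {
    for (m in u$members) {
      sub <- validate_agp_object(m$agp)
      if (nrow(sub)) report <- structure(rbind(as.data.frame(report), as.data.frame(sub)),
                                         class = c("validation_report", "data.frame"))
      if (m$rank == "contig" && any(is_gap_row(m$agp))) {
        report <- add_finding(report, "contig-gapless", m$name,
                              "contig-rank object contains gap rows")
      }
    }
    if (u$kind %in% c("alt-loci", "patches")) {
      for (m in u$members) {
        if (is.null(asm$placements[[m$name]])) {
          report <- add_finding(report, "missing-placement", m$name,
                                sprintf("%s member has no placement", u$kind))
        }
        if (u$kind == "alt-loci" && m$length > 5e6) {
          report <- add_finding(report, "alt-locus-size", m$name,
                                sprintf("alternate locus is %d bp (> 5 Mb advisory)", m$length),
                                severity = "warning")
        }
      }
      if (u$kind == "alt-loci" && length(u$members) > 1L) {
        pl <- Filter(Negate(is.null), asm$placements[names(u$members)])
        if (length(pl) > 1L) {
          for (i in seq_len(length(pl) - 1L)) for (j in seq((i + 1L), length(pl))) {
            a <- pl[[i]]; b <- pl[[j]]
            if (identical(a$parent_name, b$parent_name) &&
                a$parent_start <= b$parent_stop && b$parent_start <= a$parent_stop) {
              report <- add_finding(report, "alt-overlap", u$name,
                                    sprintf("placements of %s and %s overlap on %s",
                                            a$alt_name, b$alt_name, a$parent_name))
            }
          }
        }
      }
    }
    if (u$kind == "primary") {
      for (m in u$members) {
        if (m$rank == "scaffold") {
          st <- classify_scaffold(m$name, asm)
          if (st$status == "unlocalized" && is.na(st$chromosome)) {
            report <- add_finding(report, "unlocalized-chromosome", m$name,
                                  "unlocalized scaffold lacks a chromosome")
          }
        }
      }
    }
  }
  # every patch scaffold must sit in the PATCHES unit
  pu <- patches_unit(asm)
  for (p in asm$patches) {
    if (p$state == "active" &&
        (is.null(pu) || !(p$scaffold$name %in% names(pu$members)))) {
      report <- add_finding(report, "patch-unit", p$scaffold$name,
                            "active patch is not a member of the PATCHES unit")
    }
  }
  report
}

#' Classify a scaffold's placement status
#'
#' @param name Scaffold (assembled object) name.
#' @param asm The \code{assembly} it belongs to.
#' @return An object of class \code{scaffold_status} with fields
#'   \code{status} (placed / unlocalized / unplaced / alt / patch) and
#'   \code{chromosome} (or \code{NA}).
#' @export
classify_scaffold <- function(name, asm) {
  hit <- find_member(asm, name)
  if (is.null(hit)) stop("scaffold not found in assembly: ", name, call. = FALSE)
  u <- hit$unit; m <- hit$member
  status <- if (u$kind == "patches") {
    list(status = "patch",
         chromosome = if (!is.null(asm$placements[[name]])) asm$placements[[name]]$parent_name else NA_character_)
  } else if (u$kind == "alt-loci") {
    list(status = "alt",
         chromosome = if (!is.null(asm$placements[[name]])) asm$placements[[name]]$parent_name else NA_character_)
  } else if (m$rank == "chromosome") {
    list(status = "placed", chromosome = m$name)
  } else {
    # scaffold in the primary unit: placed when a chromosome AGP uses it
    host <- NA_character_
    for (mm in u$members) {
      if (mm$rank == "chromosome" && name %in% mm$agp$component_id) host <- mm$name
    }
    if (!is.na(host)) {
      list(status = "placed", chromosome = host)
    } else if (!is.na(m$chromosome)) {
      list(status = "unlocalized", chromosome = m$chromosome)
    } else {
      list(status = "unplaced", chromosome = NA_character_)
    }
  }
  structure(status, class = "scaffold_status")
}
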