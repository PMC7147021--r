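#' Construct an annotated protein sequence
#'
#' An annotated sequence couples an amino-acid string with a per-residue
#' label track marking each residue as hinge-bending (`H`) or intradomain
#' (`D`). Annotated sequences of this kind, derived from pairs of protein
#' conformers, are the basic data of hinge-region sequence analysis.
#'
#' @param id Character identifier, e.g. `"1GGG_A"`.
#' @param residues Character string over the 23-letter residue alphabet
#'   (20 standard amino acids plus the ambiguity codes `B`, `X`, `Z`).
#'   The terminus dummy `-` never appears inside a sequence.
#' @param labels Character string of the same length over `{H, D}`.
#' @return An object of class `"annot_seq"`: a list with elements `id`,
#'   `residues` and `labels`.
#' @examples
#' s <- annotated_sequence("q", "ACDEF", "DDHDD")
#' nchar(s$residues)
#' @export
annotated_sequence <- function(id, residues, labels) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L,
            is.character(labels), length(labels) == 1L)
  if (nchar(residues) != nchar(labels)) {
    stop("record '", id, "': length mismatch between residues (",
         nchar(residues), ") and labels (", nchar(labels), ")")
  }
  res_ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!res_ch %in% RESIDUE_ALPHABET)
  if (length(bad) > 0L) {
    stop("record '", id, "': illegal residue character '", res_ch[bad[1L]],
         "' at position ", bad[1L])
  }
  lab_ch <- strsplit(labels, "", fixed = TRUE)[[1]]
  badl <- which(!lab_ch %in% c("H", "D"))
  if (length(badl) > 0L) {
    stop("record '", id, "': illegal label character '", lab_ch[badl[1L]],
         "' at position ", badl[1L])
  }
  structure(list(id = id, residues = residues, labels = labels),
            class = "annot_seq")
}

#' @export
print.annot_seq <- function(x, ...) {
  cat("<annot_seq> ", x$id, " (", nchar(x$residues), " residues, ",
      sum(strsplit(x$labels, "")[[1]] == "H"), " hinge)\n", sep = "")
  invisible(x)
}

#' Read annotated sequences from a two-track FASTA-like file
#'
#' The format is FASTA-like with one extra track per record:
#' `>id`, a residue line, then a label line over `{H, D}` of equal length.
#' Multi-line tracks are supported provided residues and labels are wrapped
#' identically; in practice each track is written on a single line (see
#' [write_annotated_fasta()]). Residue lines and label lines are
#' distinguished by content, so records may wrap both tracks in parallel.
#'
#' @param path Path to the file.
#' @return A list of [annotated_sequence()] objects (empty list for an
#'   empty file).
#' @export
read_annotated_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("parse error: file does not start with a '>' header")
  starts <- which(hdr)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[i]])
    id <- sub("\\s.*$", "", id)
    body <- lines[seq.int(starts[i] + 1L, length.out = ends[i] - starts[i])]
    if (length(body) < 2L) {
      stop("parse error in record '", id, "': expected a residue line and ",
           "a label line")
    }
    if (length(body) %% 2L != 0L) {
      stop("parse error in record '", id, "': odd number of track lines")
    }
    half <- length(body) / 2L
    residues <- paste(body[seq_len(half)], collapse = "")
    labels <- paste(body[half + seq_len(half)], collapse = "")
    out[[i]] <- annotated_sequence(id, residues, labels)
  }
  out
}

#' Write annotated sequences in the two-track format
#'
#' Inverse of [read_annotated_fasta()]: each record is written as three
#' lines (`>id`, residues, labels) with no wrapping, so reading the file
#' back round-trips bit-exactly.
#'
#' @param seqs List of [annotated_sequence()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotated_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) {
    c(paste0(">", s$id), s$residues, s$labels)
  }))
  if (is.null(lines)) lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read plain (unannotated) FASTA query sequences
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A named character vector of sequences.
#' @export
read_query_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Maximal runs of hinge labels
#'
#' A bending region is a maximal run of consecutive `H` labels; this
#' connects per-residue labels to per-movement bending-region counts.
#'
#' @param labels Label string over `{H, D}`, or an `annot_seq`.
#' @return A data frame with columns `start`, `end` (1-based, inclusive)
#'   and `length`, one row per bending region.
#' @export
bending_regions <- function(labels) {
  if (inherits(labels, "annot_seq")) labels <- labels$labels
  r <- rle(strsplit(labels, "", fixed = TRUE)[[1]] == "H")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Selection criteria for domain movements
#'
#' Bundles the thresholds used to retain only clear, well-defined domain
#' movements: an exact number of dynamic domains, a minimum domain size, a
#' minimum interdomain rotation angle, a maximum intradomain backbone RMSD,
#' and caps on the number and length of bending regions. All bounds are
#' inclusive. The defaults are the strict selection used for the
#' high-confidence group; `group_criteria("group2")` gives the more
#' permissive set.
#'
#' @param n_domains Required number of dynamic domains (exact).
#' @param min_domain_residues Minimum number of residues in any domain.
#' @param min_rotation_angle Minimum interdomain rotation angle, degrees.
#' @param max_intradomain_rmsd Maximum intradomain backbone RMSD, Angstrom.
#' @param max_bending_regions Maximum number of bending regions.
#' @param max_bending_region_residues Maximum residues in a bending region.
#' @return An object of class `"filter_criteria"`.
#' @export
filter_criteria <- function(n_domains = 2,
                            min_domain_residues = 80,
                            min_rotation_angle = 20,
                            max_intradomain_rmsd = 2.5,
                            max_bending_regions = 3,
                            max_bending_region_residues = 10) {
  vals <- c(n_domains, min_domain_residues, min_rotation_angle,
            max_intradomain_rmsd, max_bending_regions,
            max_bending_region_residues)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all criteria bounds must be positive and finite")
  }
  structure(list(n_domains = n_domains,
                 min_domain_residues = min_domain_residues,
                 min_rotation_angle = min_rotation_angle,
                 max_intradomain_rmsd = max_intradomain_rmsd,
                 max_bending_regions = max_bending_regions,
                 max_bending_region_residues = max_bending_region_residues),
            class = "filter_criteria")
}

#' @rdname filter_criteria
#' @param group `"group1"` (strict) or `"group2"` (permissive).
#' @export
group_criteria <- function(group = c("group1", "group2")) {
  group <- match.arg(group)
  if (group == "group1") {
    filter_criteria()
  } else {
    filter_criteria(n_domains = 2, min_domain_residues = 80,
                    min_rotation_angle = 15, max_intradomain_rmsd = 3.0,
                    max_bending_regions = 5,
                    max_bending_region_residues = 15)
  }
}

movement_fields <- c("id", "n_domains", "min_domain_residues",
                     "rotation_angle_deg", "intradomain_rmsd_A",
                     "n_bending_regions", "max_bending_region_residues")

#' Filter domain-movement records by selection criteria
#'
#' A record passes iff its number of domains equals the criterion exactly
#' and every other field lies within the inclusive bound: domain size and
#' rotation angle at or above their minima, intradomain RMSD, number of
#' bending regions and bending-region length at or below their maxima.
#' Input order is preserved; the operation is idempotent.
#'
#' @param records Data frame of movement metadata with columns
#'   `id`, `n_domains`, `min_domain_residues`, `rotation_angle_deg`,
#'   `intradomain_rmsd_A`, `n_bending_regions`,
#'   `max_bending_region_residues`.
#' @param criteria A [filter_criteria()] object.
#' @return The subset of `records` passing all criteria.
#' @export
filter_movements <- function(records, criteria) {
  stopifnot(inherits(criteria, "filter_criteria"), is.data.frame(records))
  missing_cols <- setdiff(movement_fields, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing field(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) return(records)
  for (f in movement_fields) {
    bad <- which(is.na(records[[f]]))
    if (length(bad) > 0L) {
      stop("record '", records$id[bad[1L]], "': missing value in field '",
           f, "'")
    }
  }
  keep <- records$n_domains == criteria$n_domains &
    records$min_domain_residues >= criteria$min_domain_residues &
    records$rotation_angle_deg >= criteria$min_rotation_angle &
    records$intradomain_rmsd_A <= criteria$max_intradomain_rmsd &
    records$n_bending_regions <= criteria$max_bending_regions &
    records$max_bending_region_residues <= criteria$max_bending_region_residues
  records[keep, , drop = FALSE]
}

#' Read or write a movement-metadata table
#'
#' Headered tab-separated table with the columns listed in
#' [filter_movements()].
#'
#' @param path File path.
#' @return `read_movement_table` returns a data frame.
#' @export
read_movement_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(movement_fields, names(df))
  if (length(missing_cols) > 0L) {
    stop("movement table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' @rdname read_movement_table
#' @param records Data frame of movement metadata.
#' @export
write_movement_table <- function(records, path) {
  utils::write.table(records[, movement_fields], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy redundancy reduction by pairwise sequence identity
#'
#' Removes redundant sequences so that no retained pair reaches the
#' identity threshold. Sequences are considered longest-first (stable for
#' ties); a sequence is kept iff its identity to every already-kept
#' sequence is below the threshold. This is a deliberately simple greedy
#' clustering with a pluggable identity function; it honours the same
#' contract as word-filter-based tools such as CD-Hit without reproducing
#' their heuristics.
#'
#' @param seqs List of `annot_seq` objects.
#' @param identity_threshold Percent identity in `(0, 100]`; default 90.
#' @param identity_fn Function of two residue strings returning percent
#'   identity; defaults to [pairwise_identity()].
#' @return The retained subset, in decreasing length order.
#' @export
greedy_identity_filter <- function(seqs, identity_threshold = 90,
                                   identity_fn = pairwise_identity) {
  stopifnot(identity_threshold > 0, identity_threshold <= 100)
  if (length(seqs) == 0L) return(seqs)
  ord <- order(-vapply(seqs, function(s) nchar(s$residues), integer(1)))
  kept <- list()
  for (i in ord) {
    cand <- seqs[[i]]
    redundant <- FALSE
    for (k in kept) {
      if (identity_fn(cand$residues, k$residues) >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept[[length(kept) + 1L]] <- cand
  }
  kept
}

#' Overall hinge-residue proportion of a dataset
#'
#' @param seqs Non-empty list of `annot_seq` objects.
#' @return Total `H` labels divided by total labels, in `[0, 1]`.
#' @export
hinge_fraction <- function(seqs) {
  if (length(seqs) == 0L) stop("empty dataset")
  lab <- paste(vapply(seqs, `[[`, character(1), "labels"), collapse = "")
  ch <- strsplit(lab, "", fixed = TRUE)[[1]]
  sum(ch == "H") / length(ch)
}
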