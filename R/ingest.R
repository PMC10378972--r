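# Triplet-alignment ingestion: aligned multi-FASTA reading, validation and
# the locus-level filters (CDS gap count, intergenic length).

ROLE_ORDER <- c("ingroup1", "ingroup2", "outgroup")

#' Construct and validate a triplet alignment
#'
#' The unit of analysis is one aligned locus from three taxa: two ingroup
#' genomes from the same family and one outgroup, in that order. Sequences
#' are uppercased; characters outside `A,C,G,T,-` are either masked to `N`
#' (and the affected columns are later skipped during site extraction) or
#' rejected.
#'
#' @param seqs character vector of exactly three aligned sequences, in the
#'   order ingroup1, ingroup2, outgroup.
#' @param locus_id locus identifier.
#' @param locus_type `"CDS"` (protein coding, read in frame) or `"NC"`
#'   (noncoding/intergenic).
#' @param frame_offset for CDS loci, the 1-based alignment column of codon
#'   position 1 minus one (i.e. 0 when the alignment starts in frame).
#' @param ambiguous `"mask"` (default) replaces ambiguity codes with `N`;
#'   `"reject"` raises an error on any character outside `A,C,G,T,-`.
#' @return an object of class `triplet_alignment`: a list with elements
#'   `locus_id`, `locus_type`, `seqs` (length-3 character vector named by
#'   role), `length` (alignment columns) and `frame_offset`.
#' @export
triplet_alignment <- function(seqs, locus_id = "locus", locus_type = c("NC", "CDS"),
                              frame_offset = 0L, ambiguous = c("mask", "reject")) {
  locus_type <- match.arg(locus_type)
  ambiguous <- match.arg(ambiguous)
  if (length(seqs) != 3L)
    stop("a triplet alignment needs exactly 3 sequences, got ", length(seqs))
  seqs <- toupper(as.character(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences must have identical lengths, got ",
         paste(widths, collapse = ", "))
  if (any(grepl("[^ACGT-]", seqs))) {
    if (ambiguous == "reject")
      stop("sequences contain characters outside {A,C,G,T,-}")
    seqs <- gsub("[^ACGT-]", "N", seqs)
  }
  frame_offset <- as.integer(frame_offset)
  if (is.na(frame_offset) || frame_offset < 0L)
    stop("frame_offset must be a nonnegative integer")
  if (locus_type == "CDS" && (widths[1] - frame_offset) < 3L)
    stop("CDS locus '", locus_id, "' has no usable codon after frame_offset")
  names(seqs) <- ROLE_ORDER
  structure(list(locus_id = as.character(locus_id), locus_type = locus_type,
                 seqs = seqs, length = widths[1],
                 frame_offset = frame_offset),
            class = "triplet_alignment")
}

#' @export
print.triplet_alignment <- function(x, ...) {
  cat(sprintf("triplet_alignment '%s' (%s): %d columns, frame_offset %d\n",
              x$locus_id, x$locus_type, x$length, x$frame_offset))
  invisible(x)
}

#' Read one aligned triplet locus from multi-FASTA
#'
#' The file must contain exactly three aligned records. Record order is taken
#' as ingroup1, ingroup2, outgroup unless every header carries an explicit
#' `role=ingroup1|ingroup2|outgroup` tag, in which case the tags decide the
#' roles regardless of record order.
#'
#' @param path path to an aligned multi-FASTA file.
#' @param locus_type,frame_offset,ambiguous see [triplet_alignment()].
#' @param locus_id defaults to the file name without extension.
#' @return a [triplet_alignment()].
#' @export
read_triplet_fasta <- function(path, locus_type = c("NC", "CDS"),
                               frame_offset = 0L, locus_id = NULL,
                               ambiguous = c("mask", "reject")) {
  locus_type <- match.arg(locus_type)
  if (is.null(locus_id))
    locus_id <- sub("\\.(fa|fasta|fna)$", "", basename(path), ignore.case = TRUE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 3L)
    stop("'", path, "': expected 3 FASTA records, found ", length(recs))
  seqs <- as.character(recs)
  tags <- regmatches(names(recs),
                     regexpr("role=(ingroup1|ingroup2|outgroup)", names(recs)))
  if (length(tags) == 3L) {
    roles <- sub("role=", "", tags)
    if (anyDuplicated(roles))
      stop("'", path, "': duplicated role tags in FASTA headers")
    seqs <- seqs[match(ROLE_ORDER, roles)]
  }
  triplet_alignment(unname(seqs), locus_id = locus_id, locus_type = locus_type,
                    frame_offset = frame_offset, ambiguous = ambiguous)
}

#' Apply the locus-level exclusion filters
#'
#' CDS alignments are excluded when more than 30 gap characters in total were
#' introduced across the three sequences; intergenic alignments shorter than
#' 70 columns are excluded.
#'
#' @param aln a [triplet_alignment()].
#' @param max_cds_gaps maximum total gap characters tolerated in a CDS
#'   alignment (inclusive).
#' @param min_nc_length minimum intergenic alignment length (inclusive).
#' @return a one-row data frame (a "filter report") with columns `locus_id`,
#'   `kept` and `reason` (`ok`, `cds_gap_excess` or `nc_too_short`).
#' @export
filter_locus <- function(aln, max_cds_gaps = 30L, min_nc_length = 70L) {
  stopifnot(inherits(aln, "triplet_alignment"))
  n_gaps <- sum(vapply(aln$seqs,
                       function(s) lengths(regmatches(s, gregexpr("-", s, fixed = TRUE))),
                       integer(1)))
  if (aln$locus_type == "CDS" && n_gaps > max_cds_gaps) {
    kept <- FALSE; reason <- "cds_gap_excess"
  } else if (aln$locus_type == "NC" && aln$length < min_nc_length) {
    kept <- FALSE; reason <- "nc_too_short"
  } else {
    kept <- TRUE; reason <- "ok"
  }
  data.frame(locus_id = aln$locus_id, locus_type = aln$locus_type,
             length = aln$length, n_gaps = n_gaps,
             kept = kept, reason = reason, stringsAsFactors = FALSE)
}

#' Read a batch manifest
#'
#' A manifest is a TSV with header and columns `locus_id`, `path`,
#' `locus_type` (`CDS`/`NC`) and optionally `frame_offset` (default 0) and
#' `triplet_id`. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest file path.
#' @return data frame of manifest rows with resolved paths.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "path", "locus_type")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.null(m$frame_offset)) m$frame_offset <- 0L
  m$frame_offset[is.na(m$frame_offset)] <- 0L
  if (is.null(m$triplet_id)) m$triplet_id <- NA_character_
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}
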