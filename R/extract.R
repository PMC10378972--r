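# Site extraction: outgroup-parsimony polarization of alignment columns and
# emission of site observations with their tetranucleotide contexts.

# 3 x L character matrix of the aligned sequences
seq_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
}

#' Polarize aligned bases by outgroup parsimony
#'
#' Given the two ingroup bases and the outgroup base at one column, infer the
#' ancestral and derived states: if all three agree the site is conserved
#' (ancestral == derived); if the ingroups differ and the outgroup matches
#' exactly one of them, the matching state is ancestral and the other
#' derived. Columns where the ingroups agree but differ from the outgroup
#' (a change on the deeper lineage) or where all three states differ cannot
#' be assigned to an ingroup branch and are discarded, as is any column with
#' a gap or ambiguity code.
#'
#' @param ingroup1,ingroup2,outgroup character vectors of single bases
#'   (recycled to common length).
#' @return data frame with columns `ancestral`, `derived` (NA when
#'   discarded) and `status` (`conserved`, `substitution` or `discard`).
#' @export
#' @examples
#' polarize("A", "G", "A")  # ancestral A, derived G
#' polarize("A", "A", "G")  # discard
polarize <- function(ingroup1, ingroup2, outgroup) {
  n <- max(length(ingroup1), length(ingroup2), length(outgroup))
  a <- rep_len(toupper(ingroup1), n)
  b <- rep_len(toupper(ingroup2), n)
  o <- rep_len(toupper(outgroup), n)
  valid <- a %in% BASES & b %in% BASES & o %in% BASES
  anc <- rep(NA_character_, n)
  der <- rep(NA_character_, n)
  status <- rep("discard", n)

  cons <- valid & a == b & b == o
  anc[cons] <- a[cons]; der[cons] <- a[cons]; status[cons] <- "conserved"

  s1 <- valid & a != b & o == a          # ingroup2 carries the derived state
  anc[s1] <- a[s1]; der[s1] <- b[s1]; status[s1] <- "substitution"
  s2 <- valid & a != b & o == b          # ingroup1 carries the derived state
  anc[s2] <- b[s2]; der[s2] <- a[s2]; status[s2] <- "substitution"

  data.frame(ancestral = anc, derived = der, status = status,
             stringsAsFactors = FALSE)
}

empty_observations <- function() {
  data.frame(locus_id = character(), column = integer(),
             site_class = character(), context = character(),
             ancestral = character(), derived = character(),
             stringsAsFactors = FALSE)
}

skip_counts <- function(...) {
  v <- c(...)
  storage.mode(v) <- "integer"
  v
}

#' Extract polarized noncoding site observations
#'
#' Walks every alignment column of a noncoding locus. A column is emitted
#' when (a) its four context columns (two on each side) are gap-free,
#' unambiguous and identical across the three sequences, and (b) outgroup
#' parsimony can polarize the focal column (see [polarize()]). The context is
#' read from the shared flanking bases. Columns closer than two positions to
#' either alignment end have no full context and are skipped.
#'
#' @param aln a noncoding [triplet_alignment()] that passed the locus
#'   filters.
#' @return data frame of site observations with columns `locus_id`, `column`
#'   (1-based alignment column of the focal site), `site_class` (`"NC"`),
#'   `context` (4-base string `L2 L1 R1 R2`), `ancestral`, `derived`, plus a
#'   `"skips"` attribute tallying skipped columns by reason (`edge`,
#'   `context_ineligible`, `focal_invalid`, `polarize_discard`).
#' @export
extract_nc_sites <- function(aln) {
  stopifnot(inherits(aln, "triplet_alignment"))
  if (aln$locus_type != "NC")
    stop("extract_nc_sites expects a noncoding locus")
  L <- aln$length
  if (L < 5L) {
    out <- empty_observations()
    attr(out, "skips") <- skip_counts(edge = L, context_ineligible = 0,
                                      focal_invalid = 0, polarize_discard = 0)
    return(out)
  }
  m <- seq_matrix(aln)
  valid <- matrix(m %in% BASES, nrow = 3L)
  col_valid <- valid[1L, ] & valid[2L, ] & valid[3L, ]
  col_shared <- col_valid & m[1L, ] == m[2L, ] & m[2L, ] == m[3L, ]

  centers <- 3:(L - 2L)
  ctx_ok <- col_shared[centers - 2L] & col_shared[centers - 1L] &
    col_shared[centers + 1L] & col_shared[centers + 2L]
  focal_ok <- col_valid[centers]
  eligible <- centers[ctx_ok & focal_ok]

  pol <- polarize(m[1L, eligible], m[2L, eligible], m[3L, eligible])
  keep <- pol$status != "discard"
  cols <- eligible[keep]
  out <- data.frame(locus_id = rep(aln$locus_id, length(cols)),
                    column = cols, site_class = rep("NC", length(cols)),
                    context = paste0(m[1L, cols - 2L], m[1L, cols - 1L],
                                     m[1L, cols + 1L], m[1L, cols + 2L]),
                    ancestral = pol$ancestral[keep],
                    derived = pol$derived[keep],
                    stringsAsFactors = FALSE)
  attr(out, "skips") <- skip_counts(
    edge = 4L,
    context_ineligible = sum(!ctx_ok),
    focal_invalid = sum(ctx_ok & !focal_ok),
    polarize_discard = sum(!keep))
  out
}

#' Extract polarized fourfold-degenerate site observations
#'
#' Reads a CDS alignment codon by codon in the declared frame. A codon's
#' third position is emitted when the codon's first two bases are identical
#' across the three sequences and form a fourfold-degenerate prefix
#' ([FFD_PREFIXES]), the first two bases of the next codon (the downstream
#' context) are likewise identical, and all five positions of the window are
#' gap-free and unambiguous in every sequence. The context is
#' `(codon pos 1, codon pos 2, next codon pos 1, next codon pos 2)`; the
#' last codon of a CDS has no downstream context and is skipped. The three
#' third-position bases are polarized with [polarize()].
#'
#' @param aln a CDS [triplet_alignment()] that passed the locus filters.
#' @return data frame of site observations as in [extract_nc_sites()], with
#'   `site_class` `"FFD"`; skip reasons are `window_invalid` (gap/ambiguity
#'   or non-shared codon prefix / downstream context), `not_ffd_prefix` and
#'   `polarize_discard`.
#' @export
extract_ffd_sites <- function(aln) {
  stopifnot(inherits(aln, "triplet_alignment"))
  if (aln$locus_type != "CDS")
    stop("extract_ffd_sites expects a CDS locus")
  L <- aln$length
  starts <- seq.int(aln$frame_offset + 1L, L, by = 3L)
  starts <- starts[starts + 4L <= L]   # need next codon's first two columns
  if (length(starts) == 0L) {
    out <- empty_observations()
    attr(out, "skips") <- skip_counts(window_invalid = 0, not_ffd_prefix = 0,
                                      polarize_discard = 0)
    return(out)
  }
  m <- seq_matrix(aln)
  valid <- matrix(m %in% BASES, nrow = 3L)
  col_valid <- valid[1L, ] & valid[2L, ] & valid[3L, ]
  col_shared <- col_valid & m[1L, ] == m[2L, ] & m[2L, ] == m[3L, ]

  # window = codon (s, s+1, s+2) plus next codon's first two bases (s+3, s+4)
  window_ok <- col_shared[starts] & col_shared[starts + 1L] &
    col_valid[starts + 2L] & col_shared[starts + 3L] & col_shared[starts + 4L]
  prefix <- paste0(m[1L, starts], m[1L, starts + 1L])
  ffd <- window_ok & prefix %in% FFD_PREFIXES
  third <- starts[ffd] + 2L

  pol <- polarize(m[1L, third], m[2L, third], m[3L, third])
  keep <- pol$status != "discard"
  cols <- third[keep]
  out <- data.frame(locus_id = rep(aln$locus_id, length(cols)),
                    column = cols, site_class = rep("FFD", length(cols)),
                    context = paste0(m[1L, cols - 2L], m[1L, cols - 1L],
                                     m[1L, cols + 1L], m[1L, cols + 2L]),
                    ancestral = pol$ancestral[keep],
                    derived = pol$derived[keep],
                    stringsAsFactors = FALSE)
  attr(out, "skips") <- skip_counts(
    window_invalid = sum(!window_ok),
    not_ffd_prefix = sum(window_ok) - sum(ffd),
    polarize_discard = sum(!keep))
  out
}

#' Extract site observations from any locus
#'
#' Dispatches to [extract_nc_sites()] or [extract_ffd_sites()] on
#' `locus_type`.
#'
#' @param aln a [triplet_alignment()].
#' @return data frame of site observations (see [extract_nc_sites()]).
#' @export
extract_sites <- function(aln) {
  if (aln$locus_type == "NC") extract_nc_sites(aln) else extract_ffd_sites(aln)
}
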