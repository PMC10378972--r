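# Tetranucleotide contexts: enumeration, complementary folding geometry, ATI.

#' Nucleotide alphabet used throughout the package
#'
#' Bases are always ordered `A, C, G, T`; count-matrix rows and columns use
#' this order.
#' @export
BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Fourfold-degenerate codon prefixes
#'
#' The eight two-base codon prefixes for which all four third-position bases
#' encode the same amino acid under the standard (and plastid, NCBI table 11)
#' genetic code: Leu (CTN), Val (GTN), Ser (TCN), Pro (CCN), Thr (ACN),
#' Ala (GCN), Arg (CGN), Gly (GGN).
#' @export
FFD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Reverse complement of a tetranucleotide context
#'
#' A context is the string `L2 L1 R1 R2` of the two bases on each side of a
#' focal site (`L1`/`R1` immediately adjacent). Reading the opposite strand
#' maps the context to `comp(R2) comp(R1) comp(L1) comp(L2)`, i.e. the
#' reverse complement of the 4-mer.
#'
#' @param context character vector of 4-base context strings over `A,C,G,T`.
#' @return character vector of reverse-complement contexts.
#' @export
#' @examples
#' revcomp_context("AATT")  # "AATT" (self-complementary)
#' revcomp_context("CTAG")
revcomp_context <- function(context) {
  comp <- chartr("ACGT", "TGCA", context)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""),
         character(1))
}

#' Canonical representative of a complementary context pair
#'
#' Strand symmetry makes a context and its reverse complement equivalent;
#' the canonical form is the lexicographically smaller of the two under
#' `A < C < G < T`, giving a deterministic, order-independent key for folded
#' matrices.
#'
#' @inheritParams revcomp_context
#' @return character vector of canonical context strings.
#' @export
canonical_context <- function(context) {
  rc <- revcomp_context(context)
  ifelse(context <= rc, context, rc)
}

is_self_complementary <- function(context) {
  context == revcomp_context(context)
}

#' Enumerate the valid tetranucleotide contexts for a site class
#'
#' Noncoding (NC) sites can sit in any of the 4^4 = 256 contexts. A
#' fourfold-degenerate (FFD) third codon position has its left context fixed
#' to the codon's first two bases, so only the 8 fourfold-degenerate prefixes
#' times 16 right pairs = 128 contexts can occur.
#'
#' @param site_class `"NC"` or `"FFD"`.
#' @return sorted character vector of context strings (256 for NC, 128 for
#'   FFD).
#' @export
#' @examples
#' length(enumerate_contexts("NC"))   # 256
#' length(enumerate_contexts("FFD"))  # 128
enumerate_contexts <- function(site_class = c("NC", "FFD")) {
  site_class <- match.arg(site_class)
  g <- expand.grid(L2 = BASES, L1 = BASES, R1 = BASES, R2 = BASES,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ctx <- sort(paste0(g$L2, g$L1, g$R1, g$R2))
  if (site_class == "FFD") ctx <- ctx[substr(ctx, 1, 2) %in% FFD_PREFIXES]
  ctx
}

#' AT Index of a context
#'
#' Weighted A+T count of the four context bases, with the bases immediately
#' flanking the focal site weighted more heavily than the outer pair. With
#' the default weights (3 for `L1`/`R1`, 2 for `L2`/`R2`) the index ranges
#' over 0..10; contexts with ATI > 9 are called A+T-rich and contexts with
#' ATI < 5 G+C-rich.
#'
#' @inheritParams revcomp_context
#' @param inner_weight,outer_weight weights for the adjacent (`L1`,`R1`) and
#'   outer (`L2`,`R2`) context bases.
#' @return integer vector of ATI values.
#' @export
#' @examples
#' ati("ATAT")  # 10, A+T-rich
#' ati("GCCG")  # 0, G+C-rich
ati <- function(context, inner_weight = 3, outer_weight = 2) {
  is_at <- function(b) b == "A" | b == "T"
  outer_weight * (is_at(substr(context, 1, 1)) + is_at(substr(context, 4, 4))) +
    inner_weight * (is_at(substr(context, 2, 2)) + is_at(substr(context, 3, 3)))
}

#' Classify a context by AT Index
#'
#' @param ati_value numeric vector of ATI values (see [ati()]).
#' @param at_rich_above contexts with ATI strictly above this are `AT_rich`.
#' @param gc_rich_below contexts with ATI strictly below this are `GC_rich`.
#' @return character vector with values `"AT_rich"`, `"GC_rich"` or `"mid"`.
#' @export
at_class <- function(ati_value, at_rich_above = 9, gc_rich_below = 5) {
  ifelse(ati_value > at_rich_above, "AT_rich",
         ifelse(ati_value < gc_rich_below, "GC_rich", "mid"))
}
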