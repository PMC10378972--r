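# Per-context 4x4 count matrices: accumulation, complementary folding,
# long-form serialization.

zero_matrix <- function() {
  matrix(0L, 4L, 4L, dimnames = list(ancestral = BASES, derived = BASES))
}

#' Number of substitutions in a count matrix
#'
#' Sum of the off-diagonal entries; the diagonal holds conserved sites.
#'
#' @param M 4x4 count matrix (rows ancestral, columns derived, order
#'   `A,C,G,T`).
#' @return integer count.
#' @export
n_subs <- function(M) sum(M) - sum(diag(M))

#' Accumulate site observations into per-context count matrices
#'
#' Every observation increments exactly one cell `M[ancestral, derived]` of
#' the 4x4 matrix of its (unfolded) context; conserved sites fill the
#' diagonal. Matrices for enumerated-but-unobserved contexts are
#' materialized as all-zero, so downstream reporting can distinguish absent
#' data from an unenumerated context.
#'
#' @param observations data frame of site observations as produced by
#'   [extract_sites()] (columns `site_class`, `context`, `ancestral`,
#'   `derived` required).
#' @return named list with one element per site class present (`"FFD"`,
#'   `"NC"`); each element is a named list of 4x4 integer count matrices
#'   keyed by (unfolded) context string, covering the full
#'   [enumerate_contexts()] set for that class.
#' @export
accumulate <- function(observations) {
  stopifnot(all(c("site_class", "context", "ancestral", "derived") %in%
                  names(observations)))
  out <- list()
  for (cls in intersect(c("FFD", "NC"), unique(observations$site_class))) {
    obs <- observations[observations$site_class == cls, , drop = FALSE]
    levels <- enumerate_contexts(cls)
    if (!all(obs$context %in% levels))
      stop("observations contain contexts outside the ", cls, " context set: ",
           paste(utils::head(setdiff(obs$context, levels)), collapse = ", "))
    tab <- table(factor(obs$context, levels = levels),
                 factor(obs$ancestral, levels = BASES),
                 factor(obs$derived, levels = BASES))
    mats <- lapply(seq_along(levels), function(i) {
      M <- matrix(as.integer(tab[i, , ]), 4L, 4L,
                  dimnames = list(ancestral = BASES, derived = BASES))
      M
    })
    names(mats) <- levels
    out[[cls]] <- mats
  }
  out
}

#' Complement transform of a count matrix
#'
#' Reading the opposite strand maps an `A -> D` change to
#' `comp(A) -> comp(D)`; on the fixed base order `A,C,G,T` the complement is
#' index reversal, so the transform reverses both matrix dimensions.
#'
#' @inheritParams n_subs
#' @return transformed matrix.
#' @export
complement_transform <- function(M) {
  M2 <- M[4:1, 4:1]
  dimnames(M2) <- list(ancestral = BASES, derived = BASES)
  M2
}

#' Fold complementary context matrices together
#'
#' Under strand symmetry a context and its reverse complement describe the
#' same process seen from opposite strands, so their count matrices are
#' combined: the matrix of a non-canonical context is complement-transformed
#' and added into its canonical partner ([canonical_context()]). The 16
#' self-complementary contexts are stored once with their own complement
#' transform added to themselves (doubling their totals but leaving all
#' rates and stationary vectors unchanged), so that every folded matrix
#' satisfies `M == complement_transform(M)` when both strand readings are
#' present.
#'
#' @param matrices named list of 4x4 count matrices keyed by context (one
#'   site class, as one element of [accumulate()]'s result).
#' @return named list of folded matrices keyed by canonical context, sorted.
#' @export
fold_complements <- function(matrices) {
  keys <- names(matrices)
  canon <- sort(unique(canonical_context(keys)))
  out <- stats::setNames(replicate(length(canon), zero_matrix(),
                                   simplify = FALSE), canon)
  for (ctx in keys) {
    M <- matrices[[ctx]]
    can <- canonical_context(ctx)
    if (ctx != can) {
      out[[can]] <- out[[can]] + complement_transform(M)
    } else if (is_self_complementary(ctx)) {
      out[[can]] <- out[[can]] + M + complement_transform(M)
    } else {
      out[[can]] <- out[[can]] + M
    }
  }
  out
}

#' Serialize count matrices to long form
#'
#' @param matrices named list of 4x4 count matrices keyed by context.
#' @param site_class site-class label recorded in each row.
#' @return data frame with columns `site_class`, `context`, `ancestral`,
#'   `derived`, `count` (16 rows per context).
#' @export
matrices_to_df <- function(matrices, site_class) {
  ctx <- names(matrices)
  data.frame(site_class = rep(site_class, 16L * length(ctx)),
             context = rep(ctx, each = 16L),
             ancestral = rep(rep(BASES, times = 4L), times = length(ctx)),
             derived = rep(rep(BASES, each = 4L), times = length(ctx)),
             count = unlist(lapply(matrices, as.vector), use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Rebuild count matrices from long form
#'
#' Inverse of [matrices_to_df()] for one site class.
#'
#' @param df long-form data frame (columns `context`, `ancestral`,
#'   `derived`, `count`; a `site_class` column, if present, must be
#'   constant).
#' @return named list of 4x4 count matrices keyed by context.
#' @export
df_to_matrices <- function(df) {
  if (!is.null(df$site_class) && length(unique(df$site_class)) > 1L)
    stop("df_to_matrices expects a single site class; split the data frame")
  split_df <- split(df, df$context)
  lapply(split_df, function(d) {
    M <- zero_matrix()
    M[cbind(match(d$ancestral, BASES), match(d$derived, BASES))] <-
      as.integer(d$count)
    M
  })
}
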