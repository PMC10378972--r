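# Shared fixtures and independent oracles for the test suite.

make_aln <- function(s1, s2, s3, locus_type = "NC", frame_offset = 0,
                     locus_id = "t", ...) {
  triplet_alignment(c(s1, s2, s3), locus_id = locus_id,
                    locus_type = locus_type, frame_offset = frame_offset, ...)
}

write_triplet_fa <- function(seqs, path, headers = NULL) {
  if (is.null(headers)) headers <- paste0("rec", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

revcomp_seq <- function(s) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

# random aligned triplet with controllable divergence, gaps and ambiguities
random_triplet <- function(len, p_div = 0.05, p_gap = 0, p_amb = 0,
                           locus_type = "NC", frame_offset = 0) {
  mutate <- function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(len) < p_div
    v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    v[runif(len) < p_gap] <- "-"
    v[runif(len) < p_amb] <- "N"
    paste(v, collapse = "")
  }
  root <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                       prob = c(.32, .18, .18, .32)), collapse = "")
  make_aln(mutate(root), mutate(root), mutate(root),
           locus_type = locus_type, frame_offset = frame_offset)
}

# Independent fourfold-degenerate prefix set, derived from the genetic code
ffd_prefixes_oracle <- function() {
  gc <- Biostrings::GENETIC_CODE
  prefixes <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                    1, paste, collapse = "")
  prefixes[vapply(prefixes, function(p) {
    length(unique(gc[paste0(p, c("A", "C", "G", "T"))])) == 1L
  }, logical(1))]
}

# Naive per-column re-scan of an alignment; an independent implementation of
# the site-extraction rules used as a brute-force oracle.
naive_extract <- function(aln) {
  bases <- c("A", "C", "G", "T")
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  L <- ncol(m)
  shared_base <- function(j) {
    v <- m[, j]
    if (all(v %in% bases) && length(unique(v)) == 1L) v[1] else NA_character_
  }
  pol <- function(a, b, o) {
    if (!all(c(a, b, o) %in% bases)) return(NULL)
    if (a == b && b == o) return(c(a, a))
    if (a != b && o == a) return(c(a, b))
    if (a != b && o == b) return(c(b, a))
    NULL
  }
  rows <- list()
  emit <- function(j, cls, ctx, ad) {
    rows[[length(rows) + 1L]] <<- data.frame(
      locus_id = aln$locus_id, column = j, site_class = cls, context = ctx,
      ancestral = ad[1], derived = ad[2], stringsAsFactors = FALSE)
  }
  if (aln$locus_type == "NC") {
    for (j in seq_len(L)) {
      if (j < 3L || j > L - 2L) next
      ctx <- vapply(c(j - 2L, j - 1L, j + 1L, j + 2L), shared_base, "")
      if (anyNA(ctx)) next
      ad <- pol(m[1, j], m[2, j], m[3, j])
      if (is.null(ad)) next
      emit(j, "NC", paste(ctx, collapse = ""), ad)
    }
  } else {
    ffd <- ffd_prefixes_oracle()
    s <- aln$frame_offset + 1L
    while (s + 4L <= L) {
      win <- vapply(c(s, s + 1L, s + 3L, s + 4L), shared_base, "")
      third_ok <- all(m[, s + 2L] %in% bases)
      if (!anyNA(win) && third_ok &&
          paste0(win[1], win[2]) %in% ffd) {
        ad <- pol(m[1, s + 2L], m[2, s + 2L], m[3, s + 2L])
        if (!is.null(ad))
          emit(s + 2L, "FFD", paste(win, collapse = ""), ad)
      }
      s <- s + 3L
    }
  }
  if (length(rows) == 0L) return(ctxsub:::empty_observations())
  do.call(rbind, rows)
}

# Power-iteration oracle for the stationary vector of a transition matrix
power_iteration_pi <- function(P, steps = 2000L) {
  v <- rep(0.25, 4)
  for (i in seq_len(steps)) v <- as.vector(v %*% P)
  v / sum(v)
}

# Quadrature oracle for the binomial point-null Bayes factor
bf_binom_quadrature <- function(k, n) {
  m1 <- stats::integrate(function(p) stats::dbinom(k, n, p), 0, 1)$value
  m1 / stats::dbinom(k, n, 0.5)
}

# Analytic stationary vector of a continuous-time generator with the given
# off-diagonal rates (solves pi Q = 0, sum pi = 1)
ctmc_stationary <- function(rates) {
  Q <- rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 4))
  qr.solve(A, c(0, 0, 0, 0, 1))
}
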