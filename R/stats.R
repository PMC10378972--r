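# Per-context substitution statistics: rates, ts/tv, stationary vectors,
# bootstrap uncertainty, CpG odds ratios, FFD-vs-NC comparisons.

TS_PAIRS <- cbind(from = c(1L, 3L, 2L, 4L), to = c(3L, 1L, 4L, 2L))  # A<->G, C<->T

#' Per-row and overall substitution rates of a count matrix
#'
#' The rate of substitution from base `b` within a context is the sum of the
#' off-diagonal entries of row `b` divided by the row total; the overall
#' rate is the total off-diagonal count divided by the matrix total. Rows
#' with zero total have no data and their rate is `NA` (missing, not 0), as
#' is the overall rate of an all-zero matrix.
#'
#' @param M 4x4 count matrix (rows ancestral, columns derived, order
#'   `A,C,G,T`).
#' @return list with `rate_from` (named numeric, one entry per base) and
#'   `rate_overall`.
#' @export
row_rates <- function(M) {
  rt <- rowSums(M)
  off <- rt - diag(M)
  rate_from <- ifelse(rt > 0, off / rt, NA_real_)
  names(rate_from) <- BASES
  total <- sum(rt)
  list(rate_from = rate_from,
       rate_overall = if (total > 0) sum(off) / total else NA_real_)
}

#' Transition and transversion rates of a count matrix
#'
#' Transitions are the four purine-purine / pyrimidine-pyrimidine cells
#' (`A<->G`, `C<->T`); the remaining eight off-diagonal cells are
#' transversions. Each count is divided by the matrix total. `ts_tv` is
#' their ratio, with `tv_undefined = TRUE` (and `ts_tv = NA`) when no
#' transversion was observed.
#'
#' @inheritParams row_rates
#' @return list with `ts_rate`, `tv_rate`, `ts_tv`, `tv_undefined`.
#' @export
ts_tv_rates <- function(M) {
  total <- sum(M)
  if (total <= 0)
    return(list(ts_rate = NA_real_, tv_rate = NA_real_, ts_tv = NA_real_,
                tv_undefined = TRUE))
  ts <- sum(M[TS_PAIRS])
  tv <- n_subs(M) - ts
  list(ts_rate = ts / total, tv_rate = tv / total,
       ts_tv = if (tv > 0) ts / tv else NA_real_,
       tv_undefined = tv == 0)
}

# TRUE iff the support graph of P (plus self-loops) is strongly connected;
# for a 4-state chain reachability within 4 steps is conclusive.
is_irreducible <- function(P) {
  A <- (P > 0) | diag(4) > 0
  R <- A
  R <- (R %*% R) > 0
  R <- (R %*% R) > 0
  all(R)
}

#' Stationary vector of a count matrix's empirical transition matrix
#'
#' Row-normalizing a count matrix (conserved sites included on the diagonal)
#' gives the empirical one-step Markov transition matrix `P`; its stationary
#' vector `pi` (the unique probability vector with `pi %*% P == pi` for an
#' irreducible chain) is the equilibrium base composition toward which a
#' site evolving under this context-conserved process converges. Computed by
#' left eigen-decomposition and normalized to sum 1.
#'
#' @inheritParams row_rates
#' @param tol residual tolerance for `max |pi P - pi|`.
#' @return list with `pi` (named numeric over `A,C,G,T`, or `NA`s when
#'   flagged), `eq_AT = pi[A] + pi[T]`, and `flag` (`"ok"`, `"zero_row"`,
#'   `"reducible"`, `"no_convergence"`).
#' @export
stationary_vector <- function(M, tol = 1e-9) {
  bad <- function(flag) list(pi = stats::setNames(rep(NA_real_, 4L), BASES),
                             eq_AT = NA_real_, flag = flag)
  rt <- rowSums(M)
  if (any(rt <= 0)) return(bad("zero_row"))
  P <- M / rt
  if (!is_irreducible(P)) return(bad("reducible"))
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  pi <- v / sum(v)
  pi[abs(pi) < 1e-14] <- 0
  if (any(pi < 0) || max(abs(pi %*% P - pi)) > tol) return(bad("no_convergence"))
  names(pi) <- BASES
  list(pi = pi, eq_AT = pi[["A"]] + pi[["T"]], flag = "ok")
}

#' Bootstrap the equilibrium A+T content of a count matrix
#'
#' Each resample keeps every row's diagonal (conserved count) and its
#' off-diagonal total, redrawing the row's substitutions with replacement
#' from the observed off-diagonal cells (a multinomial with probabilities
#' proportional to those cells). The A+T content of the stationary vector is
#' computed for each resampled matrix; the mean and standard deviation over
#' `n_boot` resamples estimate the sampling uncertainty of the point
#' `eq_AT`. Resamples whose chain is reducible are dropped (`n_ok` reports
#' how many were used).
#'
#' @inheritParams row_rates
#' @param n_boot number of resamples (the reference analysis uses 1000).
#' @param seed integer seed; identical seeds give identical results.
#' @return list with `boot_mean_AT`, `boot_sd_AT`, `n_ok`.
#' @export
bootstrap_eq_at <- function(M, n_boot = 1000L, seed = 1L) {
  if (!is.numeric(n_boot) || n_boot < 1L)
    stop("n_boot must be a positive integer")
  rt <- rowSums(M)
  if (any(rt <= 0) || stationary_vector(M)$flag != "ok")
    stop("bootstrap_eq_at requires a matrix with a valid stationary vector")
  offdiag <- lapply(1:4, function(r) {
    cells <- setdiff(1:4, r)
    list(cells = cells, n = sum(M[r, cells]), p = M[r, cells])
  })
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(n_boot), function(i) {
    B <- M
    for (r in 1:4) {
      od <- offdiag[[r]]
      if (od$n > 0)
        B[r, od$cells] <- as.vector(stats::rmultinom(1L, od$n, od$p))
    }
    stationary_vector(B)$eq_AT
  }, numeric(1))
  ok <- !is.na(vals)
  list(boot_mean_AT = mean(vals[ok]),
       boot_sd_AT = if (sum(ok) > 1L) stats::sd(vals[ok]) else 0,
       n_ok = sum(ok))
}

#' Odds ratio of a 2x2 count table
#'
#' For counts `a, b` (focal / other changes in the focal dinucleotide
#' context) and `c, d` (the same in all other contexts), the odds ratio is
#' `(a/b) / (c/d)`. `NA` when any of `b`, `c`, `d` is zero.
#'
#' @param a,b,c,d nonnegative counts.
#' @return numeric odds ratio (vectorized).
#' @export
#' @examples
#' cpg_odds_ratio(5606, 12488, 11685, 32153)  # 1.24 to two decimals
cpg_odds_ratio <- function(a, b, c, d) {
  ifelse(b > 0 & c > 0 & d > 0, (a / b) / (c / d), NA_real_)
}

#' CpG-effect contingency tables from folded context matrices
#'
#' Aggregates substitution counts over contexts by the identity of the
#' immediate neighbor of the focal base, yielding the two strand-complementary
#' readings of the CpG dinucleotide: substitutions from `G` split by whether
#' the 5' neighbor (`L1`) is `C` (`CG` vs `DG`, D = not C), with the focal
#' transition `G->A` against the other changes `G->B` (B = not A); and
#' substitutions from `C` split by whether the 3' neighbor (`R1`) is `G`
#' (`CG` vs `CH`, H = not G), with `C->T` against `C->V` (V = not T). Outer
#' context bases are marginalized by summation. An elevated odds ratio for
#' the `CG` rows is the classic signature of deamination of methylated
#' cytosine.
#'
#' @param matrices named list of folded count matrices keyed by canonical
#'   context (one site class; see [fold_complements()]).
#' @param site_class label recorded in the output.
#' @return data frame with one row per reading (`G>A` and `C>T`): counts
#'   `focal_cpg`, `other_cpg`, `focal_noncpg`, `other_noncpg` and `OR`.
#' @export
cpg_tables <- function(matrices, site_class) {
  ctx <- names(matrices)
  arr <- vapply(matrices, identity, matrix(0, 4, 4))   # 4 x 4 x n
  sum_over <- function(sel, from, to) sum(arr[from, to, sel])
  iA <- 1L; iC <- 2L; iG <- 3L; iT <- 4L

  l1_is_c <- substr(ctx, 2, 2) == "C"
  r1_is_g <- substr(ctx, 3, 3) == "G"

  rows <- rbind(
    data.frame(site_class = site_class, reading = "G>A",
               focal_cpg = sum_over(l1_is_c, iG, iA),
               other_cpg = sum_over(l1_is_c, iG, iC) + sum_over(l1_is_c, iG, iT),
               focal_noncpg = sum_over(!l1_is_c, iG, iA),
               other_noncpg = sum_over(!l1_is_c, iG, iC) + sum_over(!l1_is_c, iG, iT),
               stringsAsFactors = FALSE),
    data.frame(site_class = site_class, reading = "C>T",
               focal_cpg = sum_over(r1_is_g, iC, iT),
               other_cpg = sum_over(r1_is_g, iC, iA) + sum_over(r1_is_g, iC, iG),
               focal_noncpg = sum_over(!r1_is_g, iC, iT),
               other_noncpg = sum_over(!r1_is_g, iC, iA) + sum_over(!r1_is_g, iC, iG),
               stringsAsFactors = FALSE))
  rows$OR <- cpg_odds_ratio(rows$focal_cpg, rows$other_cpg,
                            rows$focal_noncpg, rows$other_noncpg)
  rows
}

#' Bayes factor for a binomial count against the point null p = 0.5
#'
#' Marginal likelihood of `k` successes in `n` trials under a uniform
#' Beta(1,1) prior on the success probability, divided by the likelihood at
#' the point null `p = 0.5` (a Savage-Dickey-style BF10). Closed form:
#' `(1/(n+1)) / (choose(n,k) 0.5^n)`.
#'
#' @param k,n successes and trials.
#' @return BF10 (numeric).
#' @export
bf_binom <- function(k, n) {
  exp(-log(n + 1) - (lchoose(n, k) + n * log(0.5)))
}

#' Compare a per-context statistic between two site classes
#'
#' For contexts shared between two named statistic vectors (e.g. equilibrium
#' A+T of FFD vs NC matrices), reports the least-squares r-squared, the
#' percentage of contexts where `x` strictly exceeds `y`, and the Bayes
#' factor ([bf_binom()]) for that success count against an even split.
#'
#' @param x,y named numeric vectors keyed by context; only finite values of
#'   shared names are used.
#' @param log10_scale compare on log10 scale (for rate-like statistics).
#' @return list with `n`, `r2`, `pct_x_gt_y`, `bayes_factor`; all `NA` when
#'   fewer than 3 shared contexts remain.
#' @export
compare_sets <- function(x, y, log10_scale = FALSE) {
  shared <- intersect(names(x), names(y))
  xv <- unname(x[shared]); yv <- unname(y[shared])
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L)
    return(list(n = length(xv), r2 = NA_real_, pct_x_gt_y = NA_real_,
                bayes_factor = NA_real_))
  if (log10_scale) { xv <- log10(xv); yv <- log10(yv) }
  k <- sum(xv > yv)
  n <- length(xv)
  r2 <- if (stats::sd(xv) > 0 && stats::sd(yv) > 0)
    stats::cor(xv, yv)^2 else NA_real_
  list(n = n, r2 = r2, pct_x_gt_y = 100 * k / n, bayes_factor = bf_binom(k, n))
}

#' Per-context statistics table for a folded matrix set
#'
#' One row per canonical context: counts, overall and per-base rates,
#' transition/transversion rates and their ratio, the AT Index and its
#' class, the stationary vector and its A+T content, bootstrap mean/sd of
#' equilibrium A+T, and a `reportable` flag for contexts with at least
#' `min_subs` substitutions (the reporting filter used for figures and
#' summaries; all contexts are retained in the table).
#'
#' @param matrices named list of folded count matrices (one site class).
#' @param site_class `"FFD"` or `"NC"`.
#' @param n_boot bootstrap resamples per context (0 skips the bootstrap).
#' @param seed master seed; each context uses a stream derived
#'   deterministically from `(seed, site_class, context)` so results do not
#'   depend on iteration order.
#' @param min_subs reporting threshold on the substitution count.
#' @param at_rich_above,gc_rich_below ATI class thresholds (see
#'   [at_class()]).
#' @return data frame, one row per context.
#' @export
context_stats <- function(matrices, site_class, n_boot = 1000L, seed = 1L,
                          min_subs = 25L, at_rich_above = 9, gc_rich_below = 5) {
  ctx <- names(matrices)
  rows <- lapply(ctx, function(cc) {
    M <- matrices[[cc]]
    rr <- row_rates(M)
    tt <- ts_tv_rates(M)
    sv <- stationary_vector(M)
    boot_mean <- boot_sd <- NA_real_
    if (n_boot > 0 && sv$flag == "ok" && n_subs(M) > 0) {
      b <- bootstrap_eq_at(M, n_boot = n_boot,
                           seed = derive_seed(seed, site_class, cc))
      boot_mean <- b$boot_mean_AT; boot_sd <- b$boot_sd_AT
    }
    a <- ati(cc)
    data.frame(site_class = site_class, context = cc,
               n_total = sum(M), n_subs = n_subs(M),
               rate_overall = rr$rate_overall,
               rate_from_A = rr$rate_from[["A"]], rate_from_C = rr$rate_from[["C"]],
               rate_from_G = rr$rate_from[["G"]], rate_from_T = rr$rate_from[["T"]],
               ts_rate = tt$ts_rate, tv_rate = tt$tv_rate, ts_tv = tt$ts_tv,
               ati = a, at_class = at_class(a, at_rich_above, gc_rich_below),
               pi_A = sv$pi[["A"]], pi_C = sv$pi[["C"]],
               pi_G = sv$pi[["G"]], pi_T = sv$pi[["T"]],
               eq_AT = sv$eq_AT, stationary_flag = sv$flag,
               boot_mean_AT = boot_mean, boot_sd_AT = boot_sd,
               reportable = n_subs(M) >= min_subs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
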