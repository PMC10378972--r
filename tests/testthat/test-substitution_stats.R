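mat <- function(v) matrix(v, 4, 4, byrow = TRUE,
                          dimnames = list(ancestral = BASES, derived = BASES))

test_that("row and overall rates follow the off-diagonal / total definition", {
  M <- mat(c(90, 4, 3, 3,
             0, 10, 0, 0,
             0, 0, 10, 0,
             0, 0, 0, 10))
  rr <- row_rates(M)
  expect_equal(rr$rate_from[["A"]], 0.10)
  expect_equal(rr$rate_overall, 10 / 130)

  # diagonal-only matrix: overall rate 0
  expect_equal(row_rates(diag(c(5, 5, 5, 5)))$rate_overall, 0)

  # off-diagonal sum 25 in a total of 1000
  M2 <- mat(c(250, 25, 0, 0,
              0, 250, 0, 0,
              0, 0, 225, 0,
              0, 0, 0, 250))
  expect_equal(row_rates(M2)$rate_overall, 0.025)

  # all-zero matrix: rates are missing, not 0
  z <- row_rates(mat(rep(0, 16)))
  expect_true(all(is.na(z$rate_from)))
  expect_true(is.na(z$rate_overall))

  # a zero-total row is missing while other rows are reported
  M3 <- mat(c(9, 1, 0, 0,  0, 0, 0, 0,  0, 0, 8, 2,  0, 0, 0, 10))
  expect_true(is.na(row_rates(M3)$rate_from[["C"]]))
  expect_equal(row_rates(M3)$rate_from[["G"]], 0.2)
})

test_that("ts/tv classification, ratio, and the undefined-tv flag", {
  # only A->G counts: no transversions, ratio undefined
  Monly <- mat(rep(0, 16)); Monly["A", "G"] <- 5; Monly["A", "A"] <- 95
  tt <- ts_tv_rates(Monly)
  expect_equal(tt$tv_rate, 0)
  expect_true(tt$tv_undefined)
  expect_true(is.na(tt$ts_tv))

  # equal counts in all 12 off-diagonal cells: 4 ts cells vs 8 tv cells
  Meq <- mat(rep(3, 16))
  expect_equal(ts_tv_rates(Meq)$ts_tv, 0.5)

  # brute-force cell classification oracle on random matrices,
  # plus the exact identities ts + tv = overall and weighted row rates
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  set.seed(61)
  for (i in 1:8) {
    M <- mat(rpois(16, 20))
    ts_oracle <- 0; tv_oracle <- 0
    for (a in BASES) for (d in BASES) {
      if (a == d) next
      if (purine[a] == purine[d]) ts_oracle <- ts_oracle + M[a, d]
      else tv_oracle <- tv_oracle + M[a, d]
    }
    tt <- ts_tv_rates(M)
    expect_equal(tt$ts_rate, ts_oracle / sum(M))
    expect_equal(tt$tv_rate, tv_oracle / sum(M))
    rr <- row_rates(M)
    expect_equal(tt$ts_rate + tt$tv_rate, rr$rate_overall)
    rt <- rowSums(M)
    expect_equal(sum(rr$rate_from * rt / sum(rt)), rr$rate_overall)
  }
})

test_that("AT Index weights the inner flanks 3 and outer flanks 2", {
  expect_equal(ati("ATAT"), 10)
  expect_equal(at_class(ati("ATAT")), "AT_rich")
  expect_equal(ati("GCCG"), 0)
  expect_equal(at_class(ati("GCCG")), "GC_rich")
  expect_equal(ati("ACGT"), 4)      # 2 + 0 + 0 + 2
  expect_equal(at_class(ati("ACGT")), "GC_rich")
  expect_equal(at_class(7), "mid")
})

test_that("stationary vectors solve pi P = pi and match independent oracles", {
  # uniform off-diagonal transition probabilities: doubly stochastic
  Mu <- mat(rep(2, 16)); diag(Mu) <- 94
  svu <- stationary_vector(Mu)
  expect_equal(svu$flag, "ok")
  expect_equal(unname(svu$pi), rep(0.25, 4), tolerance = 1e-12)

  # fixture cross-checked against a power-iteration oracle
  M <- mat(c(98, 0, 2, 0,
             5, 90, 0, 5,
             5, 0, 90, 5,
             0, 2, 0, 98))
  sv <- stationary_vector(M)
  expect_equal(sv$flag, "ok")
  P <- M / rowSums(M)
  expect_lt(max(abs(sv$pi %*% P - sv$pi)), 1e-9)
  expect_equal(unname(sv$pi), power_iteration_pi(P), tolerance = 1e-8)

  # detailed-balance construction: for M = diag(w) %*% S with symmetric S,
  # row normalization cancels w and P = S / rowSums(S) satisfies detailed
  # balance with pi proportional to rowSums(S) — closed-form ground truth
  w <- c(4, 1, 2, 3)
  S <- mat(c(80, 2, 3, 5, 2, 70, 4, 6, 3, 4, 60, 7, 5, 6, 7, 50))
  Mdb <- diag(w) %*% S
  dimnames(Mdb) <- dimnames(S)
  pi_truth <- unname(rowSums(S) / sum(S))
  expect_equal(unname(stationary_vector(Mdb)$pi), pi_truth, tolerance = 1e-9)

  # a zero-total row flags the context instead of fabricating a vector
  Mz <- mat(rep(1, 16)); Mz["C", ] <- 0
  expect_equal(stationary_vector(Mz)$flag, "zero_row")
  expect_true(is.na(stationary_vector(Mz)$eq_AT))

  # an absorbing state makes the chain reducible
  Mr <- mat(rep(1, 16)); Mr["A", ] <- c(10, 0, 0, 0)
  expect_equal(stationary_vector(Mr)$flag, "reducible")
})

test_that("equilibrium A+T is invariant under the complement transform", {
  set.seed(67)
  for (i in 1:6) {
    M <- mat(rpois(16, 15)) + diag(rpois(4, 200))
    sv1 <- stationary_vector(M)
    sv2 <- stationary_vector(complement_transform(M))
    expect_equal(sv1$eq_AT, sv2$eq_AT, tolerance = 1e-9)
  }
})

test_that("bootstrap of equilibrium A+T is seeded, degenerate-safe and convergent", {
  # single off-diagonal cell per row, arranged as an irreducible cycle
  M <- mat(rep(0, 16)); diag(M) <- 100
  M["A", "C"] <- 20; M["C", "G"] <- 15; M["G", "T"] <- 25; M["T", "A"] <- 10
  # every row's off-diagonal mass in one cell: resamples never vary
  bdeg <- bootstrap_eq_at(M, n_boot = 50, seed = 5)
  expect_equal(bdeg$boot_sd_AT, 0)
  expect_equal(bdeg$boot_mean_AT, stationary_vector(M)$eq_AT)

  # determinism: same seed, same result; different seed differs
  set.seed(71)
  Mw <- mat(rpois(16, 40)) + diag(rpois(4, 400))
  b1 <- bootstrap_eq_at(Mw, n_boot = 100, seed = 9)
  b2 <- bootstrap_eq_at(Mw, n_boot = 100, seed = 9)
  expect_identical(b1, b2)
  b3 <- bootstrap_eq_at(Mw, n_boot = 100, seed = 10)
  expect_false(identical(b1$boot_mean_AT, b3$boot_mean_AT))

  # convergence: with >= 100 substitutions per row the bootstrap mean
  # approaches the point estimate at large n_boot
  Mb <- mat(rpois(16, 50)) + diag(rep(500, 4))
  bb <- bootstrap_eq_at(Mb, n_boot = 10000, seed = 13)
  expect_lt(abs(bb$boot_mean_AT - stationary_vector(Mb)$eq_AT), 0.01)

  expect_error(bootstrap_eq_at(Mw, n_boot = 0), "positive")
})

test_that("CpG odds ratios reproduce the published values and basic identities", {
  # published gymnosperm counts, both site classes and strand readings
  pub <- published_cpg_counts()
  expect_equal(round(pub$OR[pub$site_class == "FFD" & pub$reading == "G>A"], 2), 1.24)
  expect_equal(round(pub$OR[pub$site_class == "FFD" & pub$reading == "C>T"], 2), 1.22)
  expect_equal(round(pub$OR[pub$site_class == "NC" & pub$reading == "G>A"], 2), 1.24)
  expect_equal(round(pub$OR[pub$site_class == "NC" & pub$reading == "C>T"], 2), 1.23)

  expect_equal(cpg_odds_ratio(10, 20, 5, 10), 1)
  expect_equal(cpg_odds_ratio(2, 1, 1, 2), 4)
  expect_true(is.na(cpg_odds_ratio(2, 0, 1, 2)))
  # invariance under scaling any row of the 2x2 table
  expect_equal(cpg_odds_ratio(30, 10, 7, 11),
               cpg_odds_ratio(3 * 30, 3 * 10, 7, 11))
  expect_equal(cpg_odds_ratio(30, 10, 7, 11),
               cpg_odds_ratio(30, 10, 5 * 7, 5 * 11))
})

test_that("CpG tables aggregate folded matrices by the immediate neighbor", {
  z <- mat(rep(0, 16))
  cg <- z; cg["C", "T"] <- 8; cg["C", "A"] <- 2; cg["G", "A"] <- 5; cg["G", "T"] <- 1
  ch <- z; ch["C", "T"] <- 3; ch["C", "G"] <- 3; ch["G", "A"] <- 4; ch["G", "C"] <- 2
  mats <- list(ACGA = cg,   # R1 = G (CpG for C focal), L1 = C (CpG for G focal)
               ATCA = ch)   # R1 = C, L1 = T: non-CpG on both readings
  tab <- cpg_tables(mats, "NC")
  ct <- tab[tab$reading == "C>T", ]
  expect_equal(ct$focal_cpg, 8); expect_equal(ct$other_cpg, 2)
  expect_equal(ct$focal_noncpg, 3); expect_equal(ct$other_noncpg, 3)
  expect_equal(ct$OR, (8 / 2) / (3 / 3))
  ga <- tab[tab$reading == "G>A", ]
  expect_equal(ga$focal_cpg, 5); expect_equal(ga$other_cpg, 1)
  expect_equal(ga$focal_noncpg, 4); expect_equal(ga$other_noncpg, 2)
})

test_that("set comparison: r-squared, strict-majority percentage and Bayes factor", {
  x <- setNames(c(1, 2, 3, 4, 5), paste0("c", 1:5))
  same <- compare_sets(x, x)
  expect_equal(same$r2, 1)
  expect_equal(same$pct_x_gt_y, 0)   # no strict inequalities

  # independent white noise: r2 near zero
  set.seed(83)
  n <- 2000
  xr <- setNames(rnorm(n), paste0("c", 1:n))
  yr <- setNames(rnorm(n), paste0("c", 1:n))
  expect_lt(compare_sets(xr, yr)$r2, 0.01)

  # Bayes factor against quadrature oracle
  expect_equal(bf_binom(5, 10), bf_binom_quadrature(5, 10), tolerance = 1e-6)
  expect_equal(bf_binom(76, 136), bf_binom_quadrature(76, 136), tolerance = 1e-6)
  expect_equal(compare_sets(x, setNames(c(0, 3, 2, 5, 4), names(x)))$bayes_factor,
               bf_binom(3, 5))

  # fewer than 3 shared contexts: missing result
  few <- compare_sets(x[1:2], x[1:2] * 2)
  expect_true(is.na(few$r2))
  expect_equal(few$n, 2)
})
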