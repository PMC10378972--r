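test_that("zero branch lengths give identical sequences and only diagonal counts", {
  scn <- sim_scenario(seed = 3, n_loci = 2, locus_length = 500,
                      t_in1 = 0, t_in2 = 0, t_out = 0)
  sim <- simulate_triplet(scn)
  expect_equal(nrow(sim$truth), 0L)
  for (aln in sim$alignments)
    expect_equal(unname(aln$seqs[1]), unname(aln$seqs[2]))
  obs <- do.call(rbind, lapply(sim$alignments, extract_sites))
  expect_true(all(obs$ancestral == obs$derived))
  mats <- accumulate(obs)$NC
  expect_equal(sum(vapply(mats, n_subs, numeric(1))), 0)

  # zero-divergence recovery: no false polarizations, sensitivity undefined
  rec <- recovery_report(sim$truth, obs)
  expect_equal(rec$n_true_single, 0L)
  expect_true(is.na(rec$polarization_sensitivity))
  expect_equal(rec$n_inferred_subs, 0L)
})

test_that("the simulator is deterministic under a fixed seed", {
  scn <- sim_scenario(seed = 17, n_loci = 1, locus_length = 2000)
  s1 <- simulate_triplet(scn)
  s2 <- simulate_triplet(scn)
  expect_identical(s1$alignments[[1]]$seqs, s2$alignments[[1]]$seqs)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_triplet(sim_scenario(seed = 18, n_loci = 1, locus_length = 2000))
  expect_false(identical(s1$alignments[[1]]$seqs, s3$alignments[[1]]$seqs))
})

test_that("CDS roots are codon-structured without stop codons", {
  scn <- sim_scenario(seed = 5, n_loci = 3, locus_length = 902,
                      locus_type = "CDS", t_in1 = 0, t_in2 = 0, t_out = 0)
  sim <- simulate_triplet(scn)
  for (aln in sim$alignments) {
    expect_equal(aln$length %% 3L, 0L)
    codons <- substring(aln$seqs[1], seq(1, aln$length, 3), seq(3, aln$length, 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("an invalid rate model is rejected before simulation", {
  bad <- function(ctx) matrix(-1, 4, 4)
  expect_error(rate_model(bad))
  scn <- sim_scenario(seed = 1, n_loci = 1, locus_length = 100)
  scn$model$convention <- "discrete"
  expect_error(simulate_triplet(scn), "ctmc")
})

test_that("a context-independent model shows no rate heterogeneity across contexts", {
  scn <- sim_scenario(seed = 101, n_loci = 2, locus_length = 12000,
                      model = hky_model(kappa = 2),
                      t_in1 = 0.015, t_in2 = 0.015, t_out = 0.015)
  sim <- simulate_triplet(scn)
  obs <- do.call(rbind, lapply(sim$alignments, extract_sites))
  folded <- fold_complements(accumulate(obs)$NC)
  counts <- t(vapply(folded, function(M) c(subs = n_subs(M),
                                           cons = sum(diag(M))),
                     numeric(2)))
  counts <- counts[rowSums(counts) >= 50, ]
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("a 5x transition bias is recovered as ts:tv near 2.5", {
  # every off-diagonal ts cell gets rate 5r, every tv cell r, so the expected
  # count ratio is (4*5)/(8*1) = 2.5 in every context
  scn <- sim_scenario(seed = 107, n_loci = 2, locus_length = 15000,
                      model = hky_model(kappa = 5, pi = rep(0.25, 4)),
                      t_in1 = 0.02, t_in2 = 0.02, t_out = 0.02)
  sim <- simulate_triplet(scn)
  obs <- do.call(rbind, lapply(sim$alignments, extract_sites))
  folded <- fold_complements(accumulate(obs)$NC)
  pooled <- Reduce(`+`, folded)
  tt <- ts_tv_rates(pooled)
  expect_lt(abs(tt$ts_tv - 2.5) / 2.5, 0.2)
})

test_that("a pure CpG multiplier yields exactly that expected odds ratio", {
  # with a context-independent kappa the only context effect is the CpG
  # multiplier, so the model-implied odds ratio equals it exactly
  pure <- default_context_model(cpg_mult = 1.23, kappa_range = c(2, 2))
  exp_tab <- expected_cpg_tables(pure)
  expect_equal(exp_tab$OR, c(1.23, 1.23), tolerance = 1e-12)
  none <- default_context_model(cpg_mult = 1, kappa_range = c(2, 2))
  expect_equal(expected_cpg_tables(none)$OR, c(1, 1), tolerance = 1e-12)
})

test_that("inferred CpG odds ratios match the generator's analytic expectation", {
  model <- default_context_model()
  expected <- expected_cpg_tables(model)$OR   # ATI-kappa confound included
  sim <- simulate_triplet(sim_scenario(seed = 149, n_loci = 6,
                                       locus_length = 50000, model = model,
                                       t_in1 = 0.03, t_in2 = 0.03,
                                       t_out = 0.03))
  obs <- do.call(rbind, lapply(sim$alignments, extract_sites))
  tab <- cpg_tables(fold_complements(accumulate(obs)$NC), "NC")
  expect_equal(tab$OR, expected, tolerance = 0.25)
})

test_that("long-run single-site occupancy matches the analytic stationary vector", {
  model <- default_context_model()
  # force one context by evolving a single site between immutable A flanks
  ctx <- "AAAA"
  rates <- model$Q[ctx, , ]
  pi_truth <- ctmc_stationary(rates)
  full <- c(1L, 1L, 2L, 1L, 1L)   # flanks AA [C] AA
  set.seed(211)
  res <- ctxsub:::evolve_branch(full, t_branch = 4000, model)
  ev <- res$events
  # time-weighted occupancy from the event log
  times <- c(0, ev$time, 4000)
  states <- c(2L, ev$to)
  occ <- tapply(diff(times), factor(states, levels = 1:4), sum)
  occ[is.na(occ)] <- 0
  occ <- occ / sum(occ)
  expect_lt(max(abs(occ - pi_truth)), 0.04)
})

test_that("a mislabeled outgroup degrades recovery (negative control)", {
  scn <- sim_scenario(seed = 131, n_loci = 2, locus_length = 8000,
                      t_in1 = 0.01, t_in2 = 0.01, t_out = 0.04)
  sim <- simulate_triplet(scn)
  obs_ok <- do.call(rbind, lapply(sim$alignments, extract_sites))
  rec_ok <- recovery_report(sim$truth, obs_ok)

  swapped <- lapply(sim$alignments, function(aln) {
    make_aln(aln$seqs[["outgroup"]], aln$seqs[["ingroup2"]],
             aln$seqs[["ingroup1"]], locus_id = aln$locus_id)
  })
  obs_bad <- do.call(rbind, lapply(swapped, extract_sites))
  rec_bad <- recovery_report(sim$truth, obs_bad)

  expect_gt(rec_ok$polarization_sensitivity, 0.9)
  expect_gt(rec_bad$false_polarization_rate, rec_ok$false_polarization_rate)
  expect_lt(rec_bad$detection_rate, rec_ok$detection_rate)
})

test_that("inferred per-context equilibrium tracks the generator's stationary vectors", {
  # contrast model: A+T-rich contexts evolve toward high A+T, G+C-rich
  # contexts toward low A+T, so the analytic stationary A+T varies widely
  contrast <- rate_model(function(ctx) {
    at <- 0.25 + 0.05 * ati(ctx)    # target A+T from 0.25 to 0.75
    p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
    m <- outer(rep(1, 4), p)
    diag(m) <- 0
    m
  })
  scn <- sim_scenario(seed = 139, n_loci = 2, locus_length = 40000,
                      model = contrast, t_in1 = 0.03, t_in2 = 0.03,
                      t_out = 0.03)
  sim <- simulate_triplet(scn)
  obs <- do.call(rbind, lapply(sim$alignments, extract_sites))
  folded <- fold_complements(accumulate(obs)$NC)

  # the generator's stationary A+T depends only on the ATI here, so pooling
  # the folded matrices by ATI removes estimator noise without touching the
  # signal; the inferred equilibrium must track the analytic one tightly
  grp <- ati(names(folded))
  levels <- sort(unique(grp))
  pooled <- lapply(levels, function(g) Reduce(`+`, folded[grp == g]))
  eq <- vapply(pooled, function(M) stationary_vector(M)$eq_AT, numeric(1))
  analytic <- vapply(levels, function(g) {
    ctx <- names(folded)[grp == g][1]
    pi <- ctmc_stationary(contrast$Q[ctx, , ])
    pi[1] + pi[4]
  }, numeric(1))
  keep <- vapply(pooled, n_subs, numeric(1)) >= 50 & !is.na(eq)
  expect_gte(sum(keep), 8)
  expect_gt(cor(eq[keep], analytic[keep])^2, 0.9)

  # and the noisier per-context estimates must still correlate positively
  st <- context_stats(folded, "NC", n_boot = 0)
  st <- st[st$n_subs >= 20 & st$stationary_flag == "ok", ]
  per_ctx_truth <- 0.25 + 0.05 * ati(st$context)
  expect_gt(nrow(st), 20)
  expect_gt(cor(st$eq_AT, per_ctx_truth), 0.4)
})
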