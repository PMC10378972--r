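# Synthetic triplet data: continuous-time sequence evolution with
# tetranucleotide-context-dependent rates, plus ground-truth event logs and
# parameter-recovery metrics.

context_index <- function(b_l2, b_l1, b_r1, b_r2) {
  ((b_l2 - 1L) * 64L + (b_l1 - 1L) * 16L + (b_r1 - 1L) * 4L + (b_r2 - 1L)) + 1L
}

all_context_strings <- function() {
  g <- expand.grid(R2 = BASES, R1 = BASES, L1 = BASES, L2 = BASES,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  paste0(g$L2, g$L1, g$R1, g$R2)   # index order matches context_index()
}

#' Build a context-dependent rate model
#'
#' A rate model is a `256 x 4 x 4` array `Q[context, from, to]` of
#' continuous-time substitution rates (off-diagonal; the diagonal is zero
#' and ignored), indexed by tetranucleotide context. `builder(context)` is
#' called once per context string and must return a 4x4 matrix of
#' nonnegative rates in base order `A,C,G,T`. The whole array is rescaled so
#' that the mean leaving rate over all (context, base) pairs is
#' `mean_rate`, making branch lengths interpretable as expected
#' substitutions per site under a uniform composition.
#'
#' @param builder function of one context string returning a 4x4 rate
#'   matrix.
#' @param mean_rate target mean leaving rate (default 1).
#' @return a `rate_model` object: list with `Q` (the array), `leave`
#'   (`256 x 4` leaving rates) and `convention = "ctmc"`.
#' @export
rate_model <- function(builder, mean_rate = 1) {
  ctx <- all_context_strings()
  Q <- array(0, dim = c(256L, 4L, 4L),
             dimnames = list(context = ctx, from = BASES, to = BASES))
  for (i in seq_along(ctx)) {
    m <- builder(ctx[i])
    stopifnot(is.matrix(m), all(dim(m) == 4L), all(m[row(m) != col(m)] >= 0))
    diag(m) <- 0
    Q[i, , ] <- m
  }
  leave <- apply(Q, c(1, 2), sum)
  scale <- mean_rate / mean(leave)
  Q <- Q * scale
  leave <- leave * scale
  structure(list(Q = Q, leave = leave, convention = "ctmc"),
            class = "rate_model")
}

#' Context-independent HKY-style rate model
#'
#' Rates `q(i -> j) = pi[j] * kappa` for transitions and `pi[j]` for
#' transversions, identical in every context; useful as a null model for
#' heterogeneity tests.
#'
#' @param kappa transition/transversion rate multiplier.
#' @param pi target composition (order `A,C,G,T`; default plastome-like
#'   A+T-rich).
#' @inheritParams rate_model
#' @return a [rate_model()].
#' @export
hky_model <- function(kappa = 2, pi = c(0.32, 0.18, 0.18, 0.32),
                      mean_rate = 1) {
  pi <- pi / sum(pi)
  is_ts <- matrix(FALSE, 4, 4); is_ts[TS_PAIRS] <- TRUE
  base_m <- outer(rep(1, 4), pi) * ifelse(is_ts, kappa, 1)
  diag(base_m) <- 0
  rate_model(function(ctx) base_m, mean_rate = mean_rate)
}

#' Default context-dependent rate model
#'
#' Emulates the qualitative context effects reported for plastome DNA: an
#' HKY-style rate skeleton with plastome-like composition, a
#' transition/transversion multiplier that decreases with the AT Index of
#' the context (G+C-rich contexts get ts:tv above 1, A+T-rich contexts
#' below 1), and a CpG multiplier that raises the deamination-like
#' transitions `C -> T` (when the 3' neighbor is G) and `G -> A` (when the
#' 5' neighbor is C).
#'
#' @param pi composition (order `A,C,G,T`).
#' @param cpg_mult multiplier on the CpG transitions (default 1.23, i.e. a
#'   ~23% excess).
#' @param kappa_range range of the context-dependent transition multiplier,
#'   mapped linearly onto ATI 10..0.
#' @inheritParams rate_model
#' @return a [rate_model()].
#' @export
default_context_model <- function(pi = c(0.32, 0.18, 0.18, 0.32),
                                  cpg_mult = 1.23, kappa_range = c(0.8, 3),
                                  mean_rate = 1) {
  pi <- pi / sum(pi)
  is_ts <- matrix(FALSE, 4, 4); is_ts[TS_PAIRS] <- TRUE
  rate_model(function(ctx) {
    kappa <- kappa_range[2] - (kappa_range[2] - kappa_range[1]) * ati(ctx) / 10
    m <- outer(rep(1, 4), pi) * ifelse(is_ts, kappa, 1)
    dimnames(m) <- list(BASES, BASES)
    if (substr(ctx, 3, 3) == "G") m["C", "T"] <- m["C", "T"] * cpg_mult
    if (substr(ctx, 2, 2) == "C") m["G", "A"] <- m["G", "A"] * cpg_mult
    diag(m) <- 0
    m
  }, mean_rate = mean_rate)
}

#' Expected CpG contingency tables of a rate model
#'
#' Analytic counterpart of [cpg_tables()] for a generator: with sites
#' distributed over contexts by an independent-base composition, the
#' expected substitution flux from base `b` to `d` in context `c` is
#' `P(c) * comp[b] * Q[c, b, d]` per unit branch length. Folding these flux
#' matrices and aggregating them like observed counts gives the odds ratios
#' the model implies, including any confounding between a CpG multiplier
#' and other context effects (e.g. an ATI-dependent ts:tv also elevates
#' transitions next to G/C neighbors).
#'
#' @param model a [rate_model()].
#' @param composition base frequencies used for both the context
#'   distribution and the ancestral base (order `A,C,G,T`).
#' @param contexts contexts over which sites are distributed (default all
#'   256; pass `enumerate_contexts("FFD")` for the fourfold-degenerate
#'   class, whose restricted prefix set mixes the context effects
#'   differently).
#' @return data frame as [cpg_tables()] (site_class `"model"`).
#' @export
expected_cpg_tables <- function(model, composition = c(0.32, 0.18, 0.18, 0.32),
                                contexts = NULL) {
  stopifnot(inherits(model, "rate_model"))
  comp <- composition / sum(composition)
  ctx_all <- dimnames(model$Q)$context
  if (is.null(contexts)) contexts <- ctx_all
  stopifnot(all(contexts %in% ctx_all))
  flux <- lapply(contexts, function(cc) {
    w <- prod(comp[match(strsplit(cc, "")[[1]], BASES)])
    m <- w * diag(comp) %*% model$Q[match(cc, ctx_all), , ]
    dimnames(m) <- list(ancestral = BASES, derived = BASES)
    m
  })
  names(flux) <- contexts
  cpg_tables(fold_complements(flux), "model")
}

#' Define a simulation scenario
#'
#' A scenario fixes everything the simulator needs: the number and length of
#' loci, the site class (codon-structured CDS or unstructured NC), the three
#' branch lengths of the triplet's star tree (ingroup1, ingroup2, outgroup,
#' all measured from their common ancestor in expected substitutions per
#' site), the context-dependent rate model, and the root composition.
#'
#' @param seed integer seed.
#' @param n_loci number of loci to simulate.
#' @param locus_length alignment length per locus (rounded down to a
#'   multiple of 3 for CDS).
#' @param locus_type `"NC"` or `"CDS"`.
#' @param t_in1,t_in2,t_out branch lengths (>= 0).
#' @param model a [rate_model()] (default [default_context_model()]).
#' @param root_composition base frequencies at the root (order `A,C,G,T`).
#' @return a `sim_scenario` object.
#' @export
sim_scenario <- function(seed = 1L, n_loci = 10L, locus_length = 10000L,
                         locus_type = c("NC", "CDS"),
                         t_in1 = 0.01, t_in2 = 0.01, t_out = 0.01,
                         model = default_context_model(),
                         root_composition = c(0.32, 0.18, 0.18, 0.32)) {
  locus_type <- match.arg(locus_type)
  stopifnot(inherits(model, "rate_model"),
            t_in1 >= 0, t_in2 >= 0, t_out >= 0,
            n_loci >= 1, locus_length >= 5)
  if (locus_type == "CDS") locus_length <- 3L * (locus_length %/% 3L)
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 locus_type = locus_type,
                 branch_lengths = c(in1 = t_in1, in2 = t_in2, out = t_out),
                 model = model,
                 root_composition = root_composition / sum(root_composition)),
            class = "sim_scenario")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Root sequence as integer codes 1..4; CDS roots are concatenated codons
# with stops rejected by resampling.
draw_root <- function(n, locus_type, comp) {
  s <- sample.int(4L, n, replace = TRUE, prob = comp)
  if (locus_type == "CDS") {
    starts <- seq.int(1L, n - 2L, by = 3L)
    repeat {
      codons <- paste0(BASES[s[starts]], BASES[s[starts + 1L]], BASES[s[starts + 2L]])
      bad <- which(codons %in% STOP_CODONS)
      if (length(bad) == 0L) break
      for (b in bad)
        s[starts[b] + 0:2] <- sample.int(4L, 3L, replace = TRUE, prob = comp)
    }
  }
  s
}

# Evolve one sequence along one branch under the scenario's rate model via
# thinning (uniformization): candidate events arrive as a Poisson process at
# the maximal per-site rate and are accepted with probability
# actual_rate / max_rate given the current state, which is exact for a
# neighbor-dependent process because contexts are re-read at each candidate.
# `full` carries two fixed, immutable flanking bases on each end so terminal
# sites have defined contexts.
evolve_branch <- function(full, t_branch, model) {
  n <- length(full) - 4L
  events <- list(site = integer(), time = numeric(),
                 from = integer(), to = integer(), context = integer())
  if (t_branch > 0 && n > 0) {
    rmax <- max(model$leave)
    n_cand <- stats::rpois(1L, rmax * n * t_branch)
    if (n_cand > 0) {
      times <- sort(stats::runif(n_cand, 0, t_branch))
      sites <- sample.int(n, n_cand, replace = TRUE) + 2L
      u <- stats::runif(n_cand)
      ne <- 0L
      ev_site <- integer(n_cand); ev_time <- numeric(n_cand)
      ev_from <- integer(n_cand); ev_to <- integer(n_cand)
      ev_ctx <- integer(n_cand)
      for (k in seq_len(n_cand)) {
        i <- sites[k]
        ci <- context_index(full[i - 2L], full[i - 1L], full[i + 1L], full[i + 2L])
        b <- full[i]
        if (u[k] < model$leave[ci, b] / rmax) {
          p <- model$Q[ci, b, ]
          to <- sample.int(4L, 1L, prob = p)
          ne <- ne + 1L
          ev_site[ne] <- i - 2L; ev_time[ne] <- times[k]
          ev_from[ne] <- b; ev_to[ne] <- to; ev_ctx[ne] <- ci
          full[i] <- to
        }
      }
      idx <- seq_len(ne)
      events <- list(site = ev_site[idx], time = ev_time[idx],
                     from = ev_from[idx], to = ev_to[idx],
                     context = ev_ctx[idx])
    }
  }
  list(seq = full, events = events)
}

#' Simulate aligned triplets with a ground-truth substitution log
#'
#' For each locus, a root sequence is drawn from the scenario's composition
#' (codon-structured without stop codons for CDS), then evolved
#' independently along the three branches of a star tree (ingroup1,
#' ingroup2, outgroup) under the context-dependent rate model; contexts are
#' re-read after every substitution so neighboring sites co-evolve. No
#' indels are generated, so the three sequences are an alignment by
#' construction. Every accepted substitution is logged with its site, time,
#' states and the context at the moment of the event.
#'
#' @param scn a [sim_scenario()].
#' @return list with `alignments` (list of [triplet_alignment()]) and
#'   `truth` (data frame: `locus_id`, `branch`, `site` (1-based column),
#'   `time`, `from`, `to`, `context`).
#' @export
simulate_triplet <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (!identical(scn$model$convention, "ctmc"))
    stop("rate model must use the continuous-time ('ctmc') convention")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scn$seed)
  ctx_strings <- all_context_strings()
  alignments <- vector("list", scn$n_loci)
  truth <- vector("list", scn$n_loci)
  for (l in seq_len(scn$n_loci)) {
    locus_id <- sprintf("sim%03d", l)
    root <- draw_root(scn$locus_length, scn$locus_type, scn$root_composition)
    flanks <- sample.int(4L, 4L, replace = TRUE, prob = scn$root_composition)
    full0 <- c(flanks[1:2], root, flanks[3:4])
    branches <- names(scn$branch_lengths)
    seqs <- character(3)
    logs <- vector("list", 3)
    for (j in 1:3) {
      res <- evolve_branch(full0, scn$branch_lengths[[j]], scn$model)
      seqs[j] <- paste(BASES[res$seq[3:(scn$locus_length + 2L)]], collapse = "")
      ev <- res$events
      logs[[j]] <- data.frame(
        locus_id = rep(locus_id, length(ev$site)),
        branch = rep(branches[j], length(ev$site)),
        site = ev$site, time = ev$time,
        from = BASES[ev$from], to = BASES[ev$to],
        context = ctx_strings[ev$context],
        stringsAsFactors = FALSE)
    }
    alignments[[l]] <- triplet_alignment(seqs, locus_id = locus_id,
                                         locus_type = scn$locus_type)
    truth[[l]] <- do.call(rbind, logs)
  }
  list(alignments = alignments, truth = do.call(rbind, truth))
}

#' Write a simulated dataset in the ingest format
#'
#' Writes one aligned multi-FASTA per locus (headers carry
#' `role=ingroup1|ingroup2|outgroup` tags), a batch manifest TSV
#' ([read_manifest()] format) and the ground-truth event log TSV.
#'
#' @param sim result of [simulate_triplet()].
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(sim$alignments, function(aln) {
    fa <- file.path(dir, paste0(aln$locus_id, ".fasta"))
    recs <- Biostrings::DNAStringSet(unname(aln$seqs))
    names(recs) <- paste0(aln$locus_id, "_", ROLE_ORDER, " role=", ROLE_ORDER)
    Biostrings::writeXStringSet(recs, fa)
    data.frame(locus_id = aln$locus_id, path = basename(fa),
               locus_type = aln$locus_type, frame_offset = aln$frame_offset,
               triplet_id = "sim", stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.tsv")
  write_tsv(do.call(rbind, rows), manifest)
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(manifest)
}

#' Parameter-recovery metrics for a simulated run
#'
#' Compares the pipeline's inferred site observations against the ground
#' truth. A true event is "cleanly detectable" when it lies on an ingroup
#' branch and is the only event at its (locus, site) across all three
#' branches — at low divergence this covers almost all events.
#' `detection_rate` is the fraction of cleanly detectable events recovered
#' with the correct ancestral/derived states (misses include columns
#' skipped because a neighboring event broke context conservation);
#' `polarization_sensitivity` restricts the denominator to cleanly
#' detectable events whose column was emitted at all, isolating the
#' polarization step itself from context-eligibility losses.
#' `false_polarization_rate` is the fraction of inferred substitutions that
#' do not match a cleanly detectable true event.
#'
#' @param truth ground-truth event log from [simulate_triplet()].
#' @param observations site observations from [extract_sites()] /
#'   [run_pipeline()] over the simulated alignments.
#' @return list with `n_true_single`, `n_inferred_subs`, `detection_rate`,
#'   `polarization_sensitivity`, `false_polarization_rate`, and
#'   `per_context` (data frame of true vs inferred substitution counts per
#'   unfolded context).
#' @export
recovery_report <- function(truth, observations) {
  key <- function(l, s) paste(l, s, sep = "#")
  ev_key <- key(truth$locus_id, truth$site)
  multi <- ev_key %in% ev_key[duplicated(ev_key)]
  clean <- truth[!multi & truth$branch %in% c("in1", "in2"), , drop = FALSE]

  subs <- observations[observations$ancestral != observations$derived, , drop = FALSE]
  obs_all_key <- key(observations$locus_id, observations$column)
  sub_key <- key(subs$locus_id, subs$column)
  clean_key <- key(clean$locus_id, clean$site)

  m <- match(clean_key, sub_key)
  correct <- !is.na(m) & subs$ancestral[m] == clean$from &
    subs$derived[m] == clean$to
  correct[is.na(correct)] <- FALSE

  n_clean <- nrow(clean)
  emitted <- clean_key %in% obs_all_key
  detection_rate <- if (n_clean > 0) mean(correct) else NA_real_
  pol_sens <- if (any(emitted)) mean(correct[emitted]) else NA_real_
  false_rate <- if (nrow(subs) > 0)
    mean(!(sub_key %in% clean_key[correct])) else NA_real_

  count_by_ctx <- function(ctx, col_name) {
    if (length(ctx) == 0L) {
      d <- data.frame(context = character(), n = integer())
    } else {
      d <- as.data.frame(table(context = ctx), stringsAsFactors = FALSE)
      names(d)[2] <- "n"
    }
    names(d)[2] <- col_name
    d
  }
  per_context <- merge(count_by_ctx(clean$context, "true_subs"),
                       count_by_ctx(subs$context, "inferred_subs"),
                       by = "context", all = TRUE)
  per_context[is.na(per_context)] <- 0

  list(n_true_single = n_clean, n_inferred_subs = nrow(subs),
       detection_rate = detection_rate,
       polarization_sensitivity = pol_sens,
       false_polarization_rate = false_rate,
       per_context = per_context)
}
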