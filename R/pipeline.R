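# End-to-end orchestration: manifest -> filters -> site observations ->
# folded matrices -> per-context statistics, CpG tables and summaries.

#' Build and validate a pipeline configuration
#'
#' Defaults reproduce the reference analysis settings: 1000 bootstrap
#' resamples, a 25-substitution reporting threshold, and ATI class
#' thresholds of >9 (A+T-rich) and <5 (G+C-rich).
#'
#' @param manifest path to a batch manifest ([read_manifest()]).
#' @param out_dir output directory.
#' @param seed master seed for all stochastic steps (bootstrap streams are
#'   derived per context with [derive_seed()]).
#' @param n_boot bootstrap resamples per context (must be >= 1; use
#'   `n_boot = NULL` to skip the bootstrap entirely).
#' @param min_subs_report reporting threshold on per-context substitution
#'   counts.
#' @param at_rich_above,gc_rich_below ATI classification thresholds.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `run_config` object (list).
#' @export
run_config <- function(manifest, out_dir, seed = 1L, n_boot = 1000L,
                       min_subs_report = 25L, at_rich_above = 9,
                       gc_rich_below = 5, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (!is.null(n_boot) && (!is.numeric(n_boot) || n_boot < 1))
    stop("n_boot must be a positive integer (or NULL to skip the bootstrap)")
  cfg <- list(manifest = manifest, out_dir = out_dir, seed = as.integer(seed),
              n_boot = if (is.null(n_boot)) 0L else as.integer(n_boot),
              min_subs_report = as.integer(min_subs_report),
              at_rich_above = at_rich_above, gc_rich_below = gc_rich_below,
              log_level = log_level)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  # out_dir excluded so reruns into different directories stay comparable
  keys <- setdiff(names(cfg), "out_dir")
  txt <- paste(keys, vapply(cfg[keys], function(x) paste(format(x), collapse = ","),
                            character(1)),
               sep = "=", collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full context-dependent substitution pipeline
#'
#' Reads every locus in the manifest, applies the locus filters, extracts
#' and polarizes FFD/NC sites, accumulates and folds the per-context count
#' matrices, and computes per-context statistics, CpG contingency tables and
#' the FFD-vs-NC comparisons. All tables are written as TSV under the
#' configured output directory together with a JSON summary that echoes the
#' configuration (with hash and seed) and stage-by-stage counts. Outputs are
#' deterministic: the same configuration and seed produce byte-identical
#' files.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the in-memory results (`filter_report`,
#'   `observations`, `matrices` (folded, per class), `stats`, `cpg`,
#'   `comparison`, `summary`) and `paths` of the written files.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (cfg$log_level == "info") message(sprintf(...))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- read_manifest(cfg$manifest)
  say("read manifest: %d loci", nrow(manifest))

  alns <- list(); reports <- list(); skips <- list(); obs <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    aln <- read_triplet_fasta(row$path, locus_type = row$locus_type,
                              frame_offset = row$frame_offset,
                              locus_id = row$locus_id)
    rep_i <- filter_locus(aln)
    reports[[i]] <- rep_i
    if (rep_i$kept) {
      o <- extract_sites(aln)
      obs[[length(obs) + 1L]] <- o
      skips[[length(skips) + 1L]] <-
        data.frame(locus_id = aln$locus_id, reason = names(attr(o, "skips")),
                   n = as.integer(attr(o, "skips")), stringsAsFactors = FALSE)
    }
  }
  filter_report <- do.call(rbind, reports)
  if (!any(filter_report$kept))
    stop("no locus passed the filters; nothing to analyze")
  observations <- do.call(rbind, obs)
  skip_log <- do.call(rbind, skips)
  say("kept %d/%d loci; %d site observations",
      sum(filter_report$kept), nrow(filter_report), nrow(observations))

  unfolded <- accumulate(observations)
  folded <- lapply(unfolded, fold_complements)

  stats_tabs <- list(); cpg_tabs <- list()
  for (cls in names(folded)) {
    stats_tabs[[cls]] <- context_stats(
      folded[[cls]], cls, n_boot = cfg$n_boot, seed = cfg$seed,
      min_subs = cfg$min_subs_report, at_rich_above = cfg$at_rich_above,
      gc_rich_below = cfg$gc_rich_below)
    cpg_tabs[[cls]] <- cpg_tables(folded[[cls]], cls)
    say("%s: %d canonical contexts, %d reportable", cls,
        nrow(stats_tabs[[cls]]), sum(stats_tabs[[cls]]$reportable))
  }
  stats_all <- do.call(rbind, unname(stats_tabs))
  cpg_all <- do.call(rbind, unname(cpg_tabs))

  comparison <- NULL
  if (all(c("FFD", "NC") %in% names(stats_tabs))) {
    pick <- function(cls, col) {
      d <- stats_tabs[[cls]]
      d <- d[d$reportable & d$stationary_flag == "ok", ]
      stats::setNames(d[[col]], canonical_context(d$context))
    }
    comparison <- list(
      rate_overall = compare_sets(pick("FFD", "rate_overall"),
                                  pick("NC", "rate_overall")),
      eq_AT = compare_sets(pick("FFD", "eq_AT"), pick("NC", "eq_AT")))
  }

  paths <- list(
    filter_report = write_tsv(filter_report, file.path(cfg$out_dir, "filtered.tsv")),
    sites = write_tsv(observations, file.path(cfg$out_dir, "sites.tsv")),
    skip_log = write_tsv(skip_log, file.path(cfg$out_dir, "skips.tsv")),
    matrices = write_tsv(
      do.call(rbind, lapply(names(folded),
                            function(cls) matrices_to_df(folded[[cls]], cls))),
      file.path(cfg$out_dir, "matrices.tsv")),
    stats = write_tsv(stats_all, file.path(cfg$out_dir, "context_stats.tsv")),
    cpg = write_tsv(cpg_all, file.path(cfg$out_dir, "cpg_tables.tsv")))

  summary <- list(
    config = c(cfg[setdiff(names(cfg), "out_dir")],
               list(config_hash = config_hash(cfg))),
    metadata = list(
      bootstrap = "row-wise multinomial redraw of off-diagonal counts",
      bayes_factor = "binomial point-null (p=0.5) vs Beta(1,1), BF10",
      folding = paste("canonical = lexicographic min of {context, revcomp};",
                      "self-complementary contexts store the sum with their",
                      "own complement transform (totals doubled)")),
    counts = list(
      loci_in = nrow(filter_report), loci_kept = sum(filter_report$kept),
      observations = nrow(observations),
      skips = stats::setNames(as.list(tapply(skip_log$n, skip_log$reason, sum)),
                              sort(unique(skip_log$reason)))),
    comparison = comparison)
  summary_path <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$summary <- summary_path

  invisible(list(filter_report = filter_report, observations = observations,
                 matrices = folded, stats = stats_tabs, cpg = cpg_tabs,
                 comparison = comparison, summary = summary, paths = paths))
}

#' Published CpG substitution counts for gymnosperm plastomes
#'
#' The aggregated CpG contingency counts published for the 17
#' gymnosperm-plastome triplet dataset (FFD and NC site classes, both
#' strand readings), shipped as a plain-text table. Odds ratios are always
#' recomputed from the counts with [cpg_odds_ratio()].
#'
#' @return data frame with columns `site_class`, `reading`, `focal_cpg`,
#'   `other_cpg`, `focal_noncpg`, `other_noncpg` and recomputed `OR`.
#' @export
#' @examples
#' published_cpg_counts()
published_cpg_counts <- function() {
  path <- system.file("extdata", "gymnosperm_cpg_counts.tsv", package = "ctxsub")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$OR <- cpg_odds_ratio(d$focal_cpg, d$other_cpg, d$focal_noncpg, d$other_noncpg)
  d
}
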