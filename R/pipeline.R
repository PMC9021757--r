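# Orchestration: evaluate every requested marker set (single loci and
# concatenated combinations) under all four criteria and render reports.

#' Evaluation configuration
#'
#' @param loci Character vector of locus names to evaluate singly; defaults
#'   at run time to every locus in the dataset.
#' @param combinations `"all"` (every subset of size >= 2 of `loci`; 11
#'   combinations for four loci), a list of character vectors, or `NULL`
#'   for single loci only.
#' @param bootstrap_B Bootstrap replicates for NJ support (default 1000).
#' @param support_threshold Bootstrap percentage a clade must exceed for a
#'   species to count as discriminated (default 50; 60 is a common stricter
#'   preset).
#' @param bcm_quantile Quantile of intraspecific distances used as the
#'   best-close-match threshold (default 0.95).
#' @param methods Subset of `c("njtree", "bestmatch", "bestclosematch",
#'   "tophit")`.
#' @param singleton_policy Singleton handling for tree-based discrimination
#'   (see [species_discrimination()]).
#' @param seed Integer global seed; all stage seeds derive from it.
#' @return An `eval_config` list.
#' @export
eval_config <- function(loci = NULL, combinations = "all", bootstrap_B = 1000,
                        support_threshold = 50, bcm_quantile = 0.95,
                        methods = c("njtree", "bestmatch", "bestclosematch", "tophit"),
                        singleton_policy = "exclude", seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) == 0) bg_validation_error("at least one method required")
  stopifnot(bootstrap_B >= 1, bcm_quantile > 0, bcm_quantile <= 1)
  structure(list(loci = loci, combinations = combinations,
                 bootstrap_B = as.integer(bootstrap_B),
                 support_threshold = support_threshold,
                 bcm_quantile = bcm_quantile, methods = methods,
                 singleton_policy = singleton_policy, seed = as.integer(seed)),
            class = "eval_config")
}

#' Enumerate multi-locus marker combinations
#'
#' All subsets of size at least 2 of the given locus names; four loci give
#' the 11 combinations evaluated alongside the 4 single loci.
#'
#' @param loci Character vector of locus names (length >= 2).
#' @return A list of character vectors.
#' @export
all_combinations <- function(loci) {
  combos <- list()
  for (k in 2:length(loci))
    combos <- c(combos, utils::combn(loci, k, simplify = FALSE))
  combos
}

subset_alignment <- function(aln, ids) {
  locus_alignment(aln$locus_name, aln$seqs[names(aln$seqs) %in% ids],
                  partition = aln$partition)
}

# Iteratively drop the sample with the most invalid pairs until the matrix
# is fully valid (needed before NJ). Returns kept labels and a log line.
prune_invalid <- function(dm) {
  valid <- dm$valid
  keep <- seq_along(dm$labels)
  dropped <- character()
  repeat {
    bad <- rowSums(!valid[keep, keep, drop = FALSE])
    if (all(bad == 0)) break
    worst <- keep[which.max(bad)]
    dropped <- c(dropped, dm$labels[worst])
    keep <- setdiff(keep, worst)
    if (length(keep) < 3) break
  }
  list(labels = dm$labels[keep], dropped = dropped)
}

evaluate_marker_set <- function(ds, aln, cfg) {
  name <- aln$locus_name
  log <- character()
  idx <- match(names(aln$seqs), ds$samples$sample_id)
  ingroup_ids <- names(aln$seqs)[!ds$samples$is_outgroup[idx]]
  if (length(ingroup_ids) < 3) {
    return(list(name = name, skipped = TRUE,
                log = sprintf("%s: skipped, fewer than 3 ingroup samples", name)))
  }
  stats <- locus_stats(aln)
  dm <- suppressWarnings(k2p_distance_matrix(aln))
  n_invalid <- sum(!dm$valid[upper.tri(dm$valid)])
  if (n_invalid > 0)
    log <- c(log, sprintf("%s: %d invalid distance pair(s) excluded", name, n_invalid))
  gp <- partition_distances(dm, ds$samples)
  gap <- tryCatch(gap_statistics(gp), barcodegap_error = function(e) {
    log <<- c(log, sprintf("%s: gap statistics unavailable (%s)",
                           name, conditionMessage(e)))
    NULL
  })
  methods <- list()
  if ("njtree" %in% cfg$methods) {
    pr <- prune_invalid(dm)
    if (length(pr$dropped))
      log <- c(log, sprintf("%s: dropped from tree for invalid distances: %s",
                            name, paste(pr$dropped, collapse = ", ")))
    if (length(pr$labels) >= 3) {
      tree <- bootstrap_support(subset_alignment(aln, pr$labels),
                                B = cfg$bootstrap_B,
                                seed = derive_seed(cfg$seed, paste0("bootstrap:", name)))
      disc <- species_discrimination(tree, ds$samples,
                                     threshold = cfg$support_threshold,
                                     singleton_policy = cfg$singleton_policy)
      if (attr(tree, "n_discarded") > 0)
        log <- c(log, sprintf("%s: %d bootstrap replicate(s) discarded",
                              name, attr(tree, "n_discarded")))
      methods$njtree <- list(report = disc, tree_newick = ape::write.tree(tree))
    } else {
      log <- c(log, sprintf("%s: NJ skipped, fewer than 3 analyzable samples", name))
    }
  }
  if ("bestmatch" %in% cfg$methods)
    methods$bestmatch <- best_match(dm, ds$samples)
  bcm_threshold <- NA_real_
  if ("bestclosematch" %in% cfg$methods) {
    if (nrow(gp$intra) > 0) {
      bcm_threshold <- intraspecific_threshold(gp, cfg$bcm_quantile)
      methods$bestclosematch <- best_close_match(dm, ds$samples, bcm_threshold)
    } else {
      log <- c(log, sprintf("%s: best close match skipped, no intraspecific distances", name))
    }
  }
  if ("tophit" %in% cfg$methods)
    methods$tophit <- top_hit_discrimination(aln, ds$samples)
  list(name = name, skipped = FALSE, n_samples = length(aln$seqs),
       n_ingroup = length(ingroup_ids), stats = stats, gap = gap,
       gap_profile = gp, bcm_threshold = bcm_threshold,
       methods = methods, log = log)
}

#' Run the full four-criteria evaluation
#'
#' For every single locus and every requested combination: sequence
#' characteristics, K2P distance matrix, barcoding-gap profile, and each
#' selected discrimination/identification method. Marker sets whose sample
#' intersection leaves fewer than 3 ingroup samples are skipped with a
#' logged reason. Fully deterministic for a fixed configuration seed.
#'
#' @param ds A [barcode_dataset].
#' @param cfg An [eval_config].
#' @return An `evaluation_summary`: per-marker-set results, the
#'   configuration, and an exclusion log.
#' @export
run_evaluation <- function(ds, cfg) {
  stopifnot(inherits(ds, "barcode_dataset"), inherits(cfg, "eval_config"))
  loci <- cfg$loci %||% names(ds$loci)
  missing <- setdiff(loci, names(ds$loci))
  if (length(missing))
    bg_validation_error(sprintf("unknown loci: %s", paste(missing, collapse = ", ")))
  combos <- if (identical(cfg$combinations, "all")) {
    if (length(loci) >= 2) all_combinations(loci) else list()
  } else if (is.null(cfg$combinations)) list() else cfg$combinations
  results <- list()
  log <- character()
  for (nm in loci) {
    r <- evaluate_marker_set(ds, ds$loci[[nm]], cfg)
    log <- c(log, r$log)
    results[[r$name]] <- r
  }
  for (combo in combos) {
    aln <- tryCatch(concatenate_loci(ds, combo), barcodegap_error = function(e) {
      log <<- c(log, sprintf("%s: skipped (%s)", paste(combo, collapse = "+"),
                             conditionMessage(e)))
      NULL
    })
    if (is.null(aln)) next
    r <- evaluate_marker_set(ds, aln, cfg)
    log <- c(log, r$log)
    results[[r$name]] <- r
  }
  structure(list(marker_sets = results, config = cfg, log = log),
            class = "evaluation_summary")
}

#' Format a success rate the way barcode surveys report them
#'
#' @param n Numerator (successes).
#' @param N Denominator (evaluated).
#' @return A string like `"84.85% (28/33)"`.
#' @export
format_rate <- function(n, N) {
  if (is.na(N) || N == 0) return("NA (0/0)")
  sprintf("%.2f%% (%d/%d)", 100 * n / N, n, N)
}

rate_entry <- function(n, N) {
  list(percent = if (N > 0) 100 * n / N else NA, n = n, N = N,
       formatted = format_rate(n, N))
}

# Plain-list view of a summary, suitable for JSON serialization.
summary_as_list <- function(summary) {
  cfg <- summary$config
  sets <- lapply(summary$marker_sets, function(r) {
    if (isTRUE(r$skipped)) return(list(name = r$name, skipped = TRUE))
    out <- list(name = r$name, skipped = FALSE, n_samples = r$n_samples,
                n_ingroup = r$n_ingroup,
                stats = unclass(r$stats))
    if (!is.null(r$gap))
      out$gap <- list(intra_mean = r$gap$intra_mean,
                      intra_range = r$gap$intra_range,
                      inter_mean = r$gap$inter_mean,
                      inter_range = r$gap$inter_range,
                      gap = r$gap$gap,
                      overlap_fraction = r$gap$overlap_fraction)
    out$bcm_threshold <- r$bcm_threshold
    m <- list()
    if (!is.null(r$methods$njtree)) {
      rep <- r$methods$njtree$report
      m$njtree <- c(rate_entry(rep$n_success, rep$n_evaluated),
                    list(statuses = as.list(table(rep$per_species$status))))
    }
    for (nm in c("bestmatch", "bestclosematch")) {
      if (is.null(r$methods[[nm]])) next
      rep <- r$methods[[nm]]
      m[[nm]] <- c(rate_entry(rep$counts$success, rep$n_queries),
                   list(counts = rep$counts,
                        species_level_rate = rep$species_level_rate))
    }
    if (!is.null(r$methods$tophit)) {
      rep <- r$methods$tophit
      m$tophit <- rate_entry(rep$n_success, rep$n_evaluated)
    }
    out$methods <- m
    out
  })
  list(config = unclass(cfg), marker_sets = unname(sets), log = summary$log)
}

#' Render tabular reports for an evaluation
#'
#' Writes `table1.tsv` (per-marker-set sequence characteristics),
#' `table2.tsv` (per-method discrimination rates as `"xx.xx% (n/N)"`),
#' per-marker-set gap histograms and per-query tables, newick trees, and a
#' machine-readable `summary.json`. Re-rendering the same summary over the
#' same directory reproduces the files byte for byte.
#'
#' @param summary An `evaluation_summary` from [run_evaluation()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(summary, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  wtsv <- function(df, f) {
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, f)
  }
  active <- Filter(function(r) !isTRUE(r$skipped), summary$marker_sets)
  t1 <- do.call(rbind, lapply(active, function(r) {
    df <- as.data.frame(r$stats)
    df$locus <- r$name
    if (!is.null(r$gap)) {
      df$mean_inter_pct <- sprintf("%.2f (%.2f-%.2f)", r$gap$inter_mean,
                                   r$gap$inter_range[1], r$gap$inter_range[2])
      df$mean_intra_pct <- sprintf("%.2f (%.2f-%.2f)", r$gap$intra_mean,
                                   r$gap$intra_range[1], r$gap$intra_range[2])
    } else {
      df$mean_inter_pct <- NA; df$mean_intra_pct <- NA
    }
    df
  }))
  wtsv(t1, file.path(outdir, "table1.tsv"))
  rows <- list()
  for (r in active) {
    if (!is.null(r$methods$njtree)) {
      rep <- r$methods$njtree$report
      rows[[length(rows) + 1]] <- data.frame(
        marker_set = r$name, method = "njtree",
        rate = format_rate(rep$n_success, rep$n_evaluated),
        percent = round(rep$rate, 2), n = rep$n_success, N = rep$n_evaluated)
    }
    for (nm in c("bestmatch", "bestclosematch")) {
      rep <- r$methods[[nm]]
      if (is.null(rep)) next
      rows[[length(rows) + 1]] <- data.frame(
        marker_set = r$name, method = nm,
        rate = format_rate(rep$counts$success, rep$n_queries),
        percent = round(rep$success_rate, 2),
        n = rep$counts$success, N = rep$n_queries)
    }
    if (!is.null(r$methods$tophit)) {
      rep <- r$methods$tophit
      rows[[length(rows) + 1]] <- data.frame(
        marker_set = r$name, method = "tophit",
        rate = format_rate(rep$n_success, rep$n_evaluated),
        percent = round(rep$rate, 2), n = rep$n_success, N = rep$n_evaluated)
    }
  }
  wtsv(do.call(rbind, rows), file.path(outdir, "table2.tsv"))
  for (r in active) {
    safe <- gsub("[^A-Za-z0-9_+-]", "_", r$name)
    if (!is.null(r$gap))
      wtsv(r$gap$histogram, file.path(outdir, sprintf("gap_%s.tsv", safe)))
    if (!is.null(r$methods$njtree)) {
      tf <- file.path(outdir, sprintf("tree_%s.nwk", safe))
      writeLines(r$methods$njtree$tree_newick, tf)
      written <- c(written, tf)
      wtsv(r$methods$njtree$report$per_species,
           file.path(outdir, sprintf("species_%s.tsv", safe)))
    }
    for (nm in c("bestmatch", "bestclosematch"))
      if (!is.null(r$methods[[nm]]))
        wtsv(r$methods[[nm]]$per_query,
             file.path(outdir, sprintf("queries_%s_%s.tsv", safe, nm)))
    if (!is.null(r$methods$tophit))
      wtsv(r$methods$tophit$per_species,
           file.path(outdir, sprintf("tophit_%s.tsv", safe)))
  }
  jf <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary_as_list(summary), jf, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", na = "null")
  written <- c(written, jf)
  invisible(written)
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("<evaluation_summary> %d marker set(s), seed %d\n",
              length(x$marker_sets), x$config$seed))
  for (r in x$marker_sets) {
    if (isTRUE(r$skipped)) { cat(sprintf("  %s: skipped\n", r$name)); next }
    parts <- character()
    if (!is.null(r$methods$njtree)) {
      rep <- r$methods$njtree$report
      parts <- c(parts, sprintf("NJ %s", format_rate(rep$n_success, rep$n_evaluated)))
    }
    if (!is.null(r$methods$bestmatch))
      parts <- c(parts, sprintf("BM %s", format_rate(
        r$methods$bestmatch$counts$success, r$methods$bestmatch$n_queries)))
    if (!is.null(r$methods$bestclosematch))
      parts <- c(parts, sprintf("BCM %s", format_rate(
        r$methods$bestclosematch$counts$success, r$methods$bestclosematch$n_queries)))
    if (!is.null(r$methods$tophit))
      parts <- c(parts, sprintf("TopHit %s", format_rate(
        r$methods$tophit$n_success, r$methods$tophit$n_evaluated)))
    cat(sprintf("  %s: %s\n", r$name, paste(parts, collapse = ", ")))
  }
  invisible(x)
}
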