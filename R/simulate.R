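# Synthetic multi-locus barcode datasets with controlled divergence
# structure: a shared species tree, a two-parameter (kappa) substitution
# process, star-shaped intraspecific variation, optional indel blocks,
# twin species with identical sequences, and per-(species, locus) dropout.

#' Describe a simulated locus
#'
#' @param name Locus name.
#' @param length Alignment length in bp (>= 100).
#' @param kappa Transition/transversion rate ratio (> 0). 4 is a typical
#'   value for plant barcode loci.
#' @param gc_target Root-sequence GC content in percent, in (0, 100).
#'   Distinguishes loci such as ITS (high GC) from psbA-trnH (low GC).
#' @param indel_rate Per-site probability that a gap block starts in a
#'   species lineage (0 disables indels).
#' @param indel_length Integer range `c(min, max)` of gap-block lengths.
#' @return A `locus_spec` list.
#' @export
locus_spec <- function(name, length, kappa = 4, gc_target = 50,
                       indel_rate = 0, indel_length = c(3, 15)) {
  stopifnot(length >= 100, kappa > 0, gc_target > 0, gc_target < 100,
            indel_rate >= 0, indel_rate <= 1, length(indel_length) == 2,
            indel_length[1] >= 1, indel_length[2] >= indel_length[1])
  structure(list(name = name, length = as.integer(length), kappa = kappa,
                 gc_target = gc_target, indel_rate = indel_rate,
                 indel_length = as.integer(indel_length)),
            class = "locus_spec")
}

#' Simulation parameters for a multi-locus barcode dataset
#'
#' @param n_species Number of ingroup species (>= 2).
#' @param individuals_per_species Integer range `c(min, max)` (or a single
#'   count) of individuals sampled per species.
#' @param loci List of [locus_spec] objects.
#' @param intra_depth Star depth within species: each individual sits
#'   `intra_depth` substitutions/site from its species ancestor, so the
#'   expected intraspecific pairwise divergence is `2 * intra_depth`.
#' @param inter_depth Root-to-tip depth of the species tree in
#'   substitutions/site.
#' @param twin_pairs Number of species pairs forced to identical sequences
#'   (emulating species that barcodes cannot separate).
#' @param missing_locus_rate Probability that a species fails a locus
#'   entirely (emulating PCR failure).
#' @param n_outgroups Number of outgroup samples (attached outside the
#'   ingroup at three times its depth); 0 for none.
#' @param seed Integer seed (mandatory); all downstream stages derive their
#'   seeds from it.
#' @param require_gap Validate `intra_depth < inter_depth` (the gap-positive
#'   regime); set `FALSE` to simulate overlapping regimes.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_species, individuals_per_species, loci,
                       intra_depth, inter_depth, twin_pairs = 0,
                       missing_locus_rate = 0, n_outgroups = 0, seed,
                       require_gap = TRUE) {
  if (length(individuals_per_species) == 1)
    individuals_per_species <- rep(individuals_per_species, 2)
  stopifnot(n_species >= 2, individuals_per_species[1] >= 1,
            individuals_per_species[2] >= individuals_per_species[1],
            intra_depth >= 0, inter_depth > 0,
            missing_locus_rate >= 0, missing_locus_rate <= 1,
            n_outgroups >= 0, is.numeric(seed))
  if (require_gap && intra_depth >= inter_depth)
    bg_validation_error("intra_depth must be < inter_depth (set require_gap = FALSE to override)")
  if (twin_pairs > n_species / 2)
    bg_validation_error("twin_pairs cannot exceed n_species / 2")
  if (!length(loci) || !all(vapply(loci, inherits, logical(1), "locus_spec")))
    bg_validation_error("'loci' must be a non-empty list of locus_spec objects")
  names(loci) <- vapply(loci, `[[`, "", "name")
  structure(list(n_species = as.integer(n_species),
                 individuals_per_species = as.integer(individuals_per_species),
                 loci = loci, intra_depth = intra_depth,
                 inter_depth = inter_depth, twin_pairs = as.integer(twin_pairs),
                 missing_locus_rate = missing_locus_rate,
                 n_outgroups = as.integer(n_outgroups),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a species tree
#'
#' A random coalescent-shaped ingroup topology (ultrametric, with the
#' branching order of a coalescent draw) whose internal node heights are
#' re-spaced evenly between `min_split_frac * inter_depth` and
#' `inter_depth`. The floor guarantees that every pair of species diverges
#' by at least `2 * min_split_frac * inter_depth` substitutions/site, which
#' is the regime the evaluation pipeline assumes (intraspecific variation
#' well below any interspecific divergence); raw coalescent heights would
#' occasionally place sister species arbitrarily close together. Outgroup
#' tips, when requested, are attached outside the ingroup at three times
#' its depth.
#'
#' @param n_species Number of ingroup species (>= 2).
#' @param inter_depth Root-to-tip depth (substitutions/site).
#' @param seed Integer seed; identical seeds give identical newick output.
#' @param n_outgroups Number of outgroup leaves (default 0).
#' @param min_split_frac Shallowest split height as a fraction of
#'   `inter_depth` (default 0.15).
#' @return A rooted `phylo` tree with ingroup tips `Species_01`, ... and
#'   outgroup tips `Outgroup_01`, ....
#' @export
simulate_species_tree <- function(n_species, inter_depth, seed, n_outgroups = 0,
                                  min_split_frac = 0.15) {
  stopifnot(n_species >= 2, inter_depth > 0,
            min_split_frac > 0, min_split_frac <= 1)
  set.seed(seed)
  tr <- ape::rcoal(n_species, tip.label = sprintf("Species_%02d", seq_len(n_species)))
  if (n_species > 2) {
    ages <- ape::branching.times(tr)  # named by internal node number
    new_ages <- seq(min_split_frac * inter_depth, inter_depth,
                    length.out = length(ages))[rank(ages, ties.method = "first")]
    names(new_ages) <- names(ages)
    ntip <- n_species
    age_of <- function(nd) if (nd <= ntip) 0 else new_ages[[as.character(nd)]]
    tr$edge.length <- vapply(seq_len(nrow(tr$edge)), function(e)
      age_of(tr$edge[e, 1]) - age_of(tr$edge[e, 2]), numeric(1))
  } else {
    tr$edge.length <- rep(inter_depth, 2)
  }
  if (n_outgroups == 0) return(tr)
  inner <- sub(";$", "", ape::write.tree(tr))
  og <- if (n_outgroups == 1) {
    sprintf("Outgroup_01:%s", fmt_num(3 * inter_depth))
  } else {
    sprintf("(%s):%s",
            paste(sprintf("Outgroup_%02d:%s", seq_len(n_outgroups),
                          fmt_num(inter_depth)), collapse = ","),
            fmt_num(2 * inter_depth))
  }
  ape::read.tree(text = sprintf("(%s:%s,%s);", inner, fmt_num(2 * inter_depth), og))
}

# K80 transition probabilities for one branch of length d (expected
# substitutions/site), rate ratio kappa. Returns c(p_same, p_ts, p_tv_each).
k80_branch_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv   = 0.25 - 0.25 * e1)
}

# Evolve an encoded sequence (1=A,2=C,3=G,4=T) along one branch.
evolve_branch <- function(seq, d, kappa) {
  if (d <= 0) return(seq)
  p <- k80_branch_probs(d, kappa)
  ts_partner <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  u <- stats::runif(length(seq))
  out <- seq
  sel_ts <- u >= p[1] & u < p[1] + p[2]
  sel_tv1 <- u >= p[1] + p[2] & u < p[1] + p[2] + p[3]
  sel_tv2 <- u >= p[1] + p[2] + p[3]
  out[sel_ts] <- ts_partner[seq[sel_ts]]
  out[sel_tv1] <- tv1[seq[sel_tv1]]
  out[sel_tv2] <- tv2[seq[sel_tv2]]
  out
}

#' Evolve sequences for one locus down a species tree
#'
#' Draws a root sequence at the target GC content, evolves it along every
#' branch under a two-parameter (kappa) Markov substitution process, then
#' spawns each species' individuals on a star whose arms are `intra_depth`
#' long, so the expected divergence between two conspecific individuals is
#' `2 * intra_depth`. Gap blocks are then inserted
#' per species lineage at the locus's indel rate, as aligned gap columns
#' shared by all individuals of the species (no realignment is needed).
#'
#' @param tree A species tree from [simulate_species_tree()].
#' @param spec A [locus_spec].
#' @param individuals Named integer vector: individuals per species (names
#'   are tip labels of `tree`; missing names default to 1).
#' @param intra_depth Star arm length (substitutions/site); pairwise
#'   intraspecific divergence has expectation `2 * intra_depth`.
#' @param seed Integer seed.
#' @return A [locus_alignment]; sample ids are `<species>_<k>`.
#' @export
evolve_sequences <- function(tree, spec, individuals, intra_depth, seed) {
  set.seed(seed)
  ntip <- length(tree$tip.label)
  L <- spec$length
  gc <- spec$gc_target / 100
  node_seq <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  node_seq[[root]] <- sample.int(4L, L, replace = TRUE,
                                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  ord <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    node_seq[[ch]] <- evolve_branch(node_seq[[p]], ord$edge.length[e], spec$kappa)
  }
  counts <- stats::setNames(rep(1L, ntip), tree$tip.label)
  counts[names(individuals)] <- individuals
  rows <- list()
  for (i in seq_len(ntip)) {
    species <- tree$tip.label[i]
    for (k in seq_len(counts[[species]])) {
      s <- evolve_branch(node_seq[[i]], intra_depth, spec$kappa)
      rows[[paste0(species, "_", k)]] <- s
    }
  }
  mat <- do.call(rbind, rows)
  chars <- matrix(c("A", "C", "G", "T")[mat], nrow = nrow(mat))
  # indel blocks: per species lineage, whole aligned gap columns
  if (spec$indel_rate > 0) {
    species_of_row <- sub("_[0-9]+$", "", names(rows))
    for (species in tree$tip.label) {
      n_events <- stats::rbinom(1, L, spec$indel_rate)
      if (n_events == 0) next
      starts <- sample.int(L, n_events, replace = TRUE)
      lrng <- seq(spec$indel_length[1], spec$indel_length[2])
      lens <- if (length(lrng) == 1) rep(lrng, n_events) else
        sample(lrng, n_events, replace = TRUE)
      for (v in seq_len(n_events)) {
        cols <- starts[v]:min(starts[v] + lens[v] - 1L, L)
        chars[species_of_row == species, cols] <- "-"
      }
    }
  }
  seqs <- apply(chars, 1, paste, collapse = "")
  names(seqs) <- names(rows)
  locus_alignment(spec$name, seqs)
}

#' Build a complete synthetic barcode dataset
#'
#' Assembles all loci from one shared species tree, forces `twin_pairs`
#' species pairs to verbatim-identical sequences across every locus (the
#' second species of a pair receives copies of the first's sequences), and
#' applies per-(species, locus) dropout. A truth record (true tree, twin
#' list, dropout list, per-species sample counts) accompanies the dataset
#' so downstream assertions can be made against the generating process.
#'
#' @param params A [sim_params] object.
#' @return A list with `dataset` (a [barcode_dataset]) and `truth`.
#' @export
build_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  seed <- params$seed
  tree <- simulate_species_tree(params$n_species, params$inter_depth,
                                derive_seed(seed, "tree"), params$n_outgroups)
  species <- sprintf("Species_%02d", seq_len(params$n_species))
  set.seed(derive_seed(seed, "individuals"))
  rng <- seq(params$individuals_per_species[1], params$individuals_per_species[2])
  counts <- stats::setNames(
    if (length(rng) == 1) rep(rng, params$n_species) else
      sample(rng, params$n_species, replace = TRUE),
    species)
  if (params$n_outgroups > 0) {
    og <- sprintf("Outgroup_%02d", seq_len(params$n_outgroups))
    counts <- c(counts, stats::setNames(rep(1L, params$n_outgroups), og))
  }
  loci <- list()
  for (spec in params$loci)
    loci[[spec$name]] <- evolve_sequences(
      tree, spec, counts, params$intra_depth,
      derive_seed(seed, paste0("locus:", spec$name)))
  # twin pairs: copy the source species' rows onto the twin, recycled
  twins <- data.frame(source = character(), twin = character(),
                      stringsAsFactors = FALSE)
  if (params$twin_pairs > 0) {
    set.seed(derive_seed(seed, "twins"))
    chosen <- sample(species, 2 * params$twin_pairs)
    for (p in seq_len(params$twin_pairs)) {
      src <- chosen[2 * p - 1]; twin <- chosen[2 * p]
      twins <- rbind(twins, data.frame(source = src, twin = twin,
                                       stringsAsFactors = FALSE))
      for (nm in names(loci)) {
        seqs <- loci[[nm]]$seqs
        src_rows <- paste0(src, "_", seq_len(counts[[src]]))
        twin_rows <- paste0(twin, "_", seq_len(counts[[twin]]))
        seqs[twin_rows] <- seqs[src_rows][
          ((seq_along(twin_rows) - 1L) %% length(src_rows)) + 1L]
        loci[[nm]] <- locus_alignment(nm, seqs, partition = loci[[nm]]$partition)
      }
    }
  }
  # per-(species, locus) dropout emulating PCR failure
  missing <- data.frame(species = character(), locus = character(),
                        stringsAsFactors = FALSE)
  if (params$missing_locus_rate > 0) {
    set.seed(derive_seed(seed, "missing"))
    for (nm in names(loci)) {
      for (s in species) {
        if (stats::runif(1) < params$missing_locus_rate) {
          keep <- !startsWith(names(loci[[nm]]$seqs), paste0(s, "_"))
          if (sum(keep) < 3) next  # keep the locus analyzable
          loci[[nm]] <- locus_alignment(nm, loci[[nm]]$seqs[keep])
          missing <- rbind(missing, data.frame(species = s, locus = nm,
                                               stringsAsFactors = FALSE))
        }
      }
    }
  }
  sample_id <- unlist(lapply(names(counts), function(s)
    paste0(s, "_", seq_len(counts[[s]]))), use.names = FALSE)
  samples <- data.frame(
    sample_id = sample_id,
    species = sub("_[0-9]+$", "", sample_id),
    is_outgroup = startsWith(sample_id, "Outgroup"),
    stringsAsFactors = FALSE)
  truth <- list(tree = ape::write.tree(tree),
                counts = as.list(counts), twins = twins, missing = missing,
                params = unclass(params)[setdiff(names(params), "loci")])
  list(dataset = barcode_dataset(samples, loci), truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' One aligned FASTA per locus (headers `species|sample_id|[outgroup]`),
#' the true species tree as newick, and the truth record as JSON.
#'
#' @param result A list from [build_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(result$dataset$loci)) {
    f <- file.path(dir, paste0(nm, ".fasta"))
    write_aligned_fasta(result$dataset$loci[[nm]], f, result$dataset$samples)
    files <- c(files, f)
  }
  tf <- file.path(dir, "true_tree.nwk")
  writeLines(result$truth$tree, tf)
  jf <- file.path(dir, "truth.json")
  jsonlite::write_json(result$truth[c("counts", "twins", "missing", "params")],
                       jf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, tf, jf))
}
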