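# Neighbour joining, bootstrap support, and monophyly-based species
# discrimination.

# Resolve a k2p_matrix or plain labeled matrix into (labels, D), requiring
# every pairwise entry to be valid.
resolve_matrix <- function(dm) {
  if (inherits(dm, "k2p_matrix")) {
    bad <- which(!dm$valid & upper.tri(dm$valid), arr.ind = TRUE)
    if (nrow(bad))
      bg_validation_error(sprintf(
        "invalid distance entries: %s",
        paste(sprintf("%s-%s", dm$labels[bad[, 1]], dm$labels[bad[, 2]]),
              collapse = ", ")))
    list(labels = dm$labels, D = dm$d)
  } else {
    D <- as.matrix(dm)
    if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
    if (anyNA(D)) bg_validation_error("distance matrix contains NA entries")
    list(labels = rownames(D), D = D)
  }
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic neighbour joining: at each step the pair minimizing the
#' rate-corrected criterion `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)` is joined,
#' with the usual branch-length and distance updates. Ties in the criterion
#' are broken deterministically by the lexicographically smallest pair of
#' cluster labels (each cluster labeled by its smallest member tip).
#' Negative branch-length estimates are clamped to zero with the deficit
#' transferred to the sister edge, preserving the joined pair's path length.
#'
#' @param dm A `k2p_matrix` (all entries must be valid) or a labeled
#'   symmetric numeric matrix, with at least 3 rows.
#' @return An unrooted `phylo` tree (basal trifurcation) with branch lengths
#'   in substitutions per site.
#' @export
nj_tree <- function(dm) {
  r <- resolve_matrix(dm)
  labels <- r$labels; D <- r$D
  n <- length(labels)
  if (n < 3) bg_validation_error("neighbour joining requires at least 3 samples")
  nwk <- labels
  key <- labels
  while (length(nwk) > 3) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    mn <- min(Q)
    cand <- which(Q == mn & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      k1 <- pmin(key[cand[, 1]], key[cand[, 2]])
      k2 <- pmax(key[cand[, 1]], key[cand[, 2]])
      cand <- cand[order(k1, k2)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt_num(bi), nwk[j], fmt_num(bj))
    new_key <- min(key[i], key[j])
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
  }
  # resolve the final three clusters around a central node (three-point rule)
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  x1 <- max(x1, 0); x2 <- max(x2, 0); x3 <- max(x3, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt_num(x1),
                 nwk[2], fmt_num(x2), nwk[3], fmt_num(x3))
  ape::read.tree(text = txt)
}

# Descendant tip labels for every node; list indexed by node number.
node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

bipartition_key <- function(tips, all_tips) {
  ref <- min(all_tips)
  side <- if (ref %in% tips) sort(setdiff(all_tips, tips)) else sort(tips)
  paste(side, collapse = "\r")
}

# Non-trivial bipartition keys of a tree, named by internal node number.
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- node_tipsets(tree)
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  keys <- vapply(internal_children,
                 function(nd) bipartition_key(sets[[nd]], tree$tip.label), "")
  names(keys) <- internal_children
  keys[vapply(internal_children, function(nd) {
    k <- length(sets[[nd]]); k >= 2 && k <= ntip - 2
  }, logical(1))]
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `B` times (within each locus block when the
#' alignment carries a concatenation partition), rebuilds the NJ tree for
#' each pseudo-alignment, and scores each internal edge of the original tree
#' by the percentage of replicate trees containing the same bipartition.
#' Replicates whose distance matrix has undefined entries are discarded; if
#' more than 10% of replicates are discarded the analysis aborts.
#'
#' @param aln A [locus_alignment] whose K2P matrix is fully valid.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; identical seeds give identical supports.
#' @param partition Optional partition data frame (`locus`, `start`, `end`);
#'   defaults to the alignment's own `partition` field.
#' @return The original NJ `phylo` tree with node labels set to support
#'   percentages and a numeric per-node `support` attribute. The attribute
#'   `n_discarded` records discarded replicates.
#' @export
bootstrap_support <- function(aln, B, seed, partition = NULL) {
  stopifnot(B >= 1)
  partition <- partition %||% aln$partition
  dm <- k2p_distance_matrix(aln)
  tree <- nj_tree(dm)
  orig_keys <- tree_bipartitions(tree)
  counts <- integer(length(orig_keys))
  names(counts) <- orig_keys
  spans <- if (is.null(partition)) list(seq_len(aln$aligned_length)) else
    lapply(seq_len(nrow(partition)),
           function(i) seq(partition$start[i], partition$end[i]))
  enc <- encode_alignment(aln)
  n_discarded <- 0L
  n_used <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    cols <- unlist(lapply(spans, function(s) s[sample.int(length(s), replace = TRUE)]))
    rep_dm <- k2p_from_encoded(enc[, cols, drop = FALSE])
    if (any(!rep_dm$valid)) { n_discarded <- n_discarded + 1L; next }
    rep_tree <- nj_tree(rep_dm$d)
    rep_keys <- tree_bipartitions(rep_tree)
    hit <- names(counts) %in% rep_keys
    counts[hit] <- counts[hit] + 1L
    n_used <- n_used + 1L
  }
  if (n_discarded > 0.10 * B)
    bg_analysis_error(sprintf(
      "%d of %d bootstrap replicates had undefined distances", n_discarded, B))
  ntip <- length(tree$tip.label)
  support <- rep(NA_real_, ntip + tree$Nnode)
  if (n_used > 0)
    support[as.integer(names(orig_keys))] <- 100 * counts[orig_keys] / n_used
  tree$node.label <- ifelse(is.na(support[(ntip + 1):(ntip + tree$Nnode)]), "",
                            fmt_num(support[(ntip + 1):(ntip + tree$Nnode)]))
  attr(tree, "support") <- support
  attr(tree, "n_discarded") <- n_discarded
  tree
}

# K2P matrix directly from an encoded integer matrix (bootstrap fast path).
k2p_from_encoded <- function(enc) {
  ind <- lapply(1:4, function(b) (enc == b) * 1)
  valid <- (enc > 0L) * 1
  n_sites <- tcrossprod(valid)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  ts <- tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]]) +
        tcrossprod(ind[[2]], ind[[4]]) + tcrossprod(ind[[4]], ind[[2]])
  tv <- n_sites - matches - ts
  P <- ifelse(n_sites > 0, ts / n_sites, NA_real_)
  Q <- ifelse(n_sites > 0, tv / n_sites, NA_real_)
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  ok <- n_sites > 0 & a1 > 0 & a2 > 0
  d <- matrix(NA_real_, nrow(enc), nrow(enc))
  d[ok] <- -0.5 * log(a1[ok]) - 0.25 * log(a2[ok])
  diag(d) <- 0
  diag(ok) <- TRUE
  dimnames(d) <- list(rownames(enc), rownames(enc))
  list(d = d, valid = ok)
}

# Numeric per-node support vector from a tree (attribute or node labels).
support_by_node <- function(tree) {
  sup <- attr(tree, "support")
  ntip <- length(tree$tip.label)
  if (is.null(sup)) {
    sup <- rep(NA_real_, ntip + tree$Nnode)
    if (!is.null(tree$node.label))
      sup[(ntip + 1):(ntip + tree$Nnode)] <-
        suppressWarnings(as.numeric(tree$node.label))
  }
  sup
}

#' Species discrimination by monophyly with bootstrap support
#'
#' A species with two or more individuals is discriminated when some edge of
#' the tree separates exactly its individuals from all other leaves (when
#' outgroup samples are present, the species-side of the edge must be free
#' of outgroups, which is monophyly on the outgroup-rooted tree) and that
#' edge's bootstrap support exceeds `threshold`. Species represented by one
#' individual are vacuously monophyletic and are handled by
#' `singleton_policy`. Edges without a support value (e.g. a tree built
#' without bootstrapping) do not veto an otherwise monophyletic species.
#'
#' @param tree A `phylo` tree, typically from [bootstrap_support()].
#' @param samples Sample table covering every tip.
#' @param threshold Support threshold in percent; success requires support
#'   strictly above it. Default 50; 60 is a common stricter preset.
#' @param singleton_policy `"exclude"` (default) leaves singletons out of
#'   the denominator, `"fail"` counts them as failures, `"succeed"` as
#'   automatic successes.
#' @return An object of class `discrimination_report`: `per_species` data
#'   frame (`species`, `n_individuals`, `status`, `support`), `n_success`,
#'   `n_evaluated` and `rate` (percent).
#' @export
species_discrimination <- function(tree, samples, threshold = 50,
                                   singleton_policy = c("exclude", "fail", "succeed")) {
  singleton_policy <- match.arg(singleton_policy)
  idx <- match(tree$tip.label, samples$sample_id)
  if (anyNA(idx))
    bg_validation_error(sprintf("tips with no sample record: %s",
      paste(tree$tip.label[is.na(idx)], collapse = ", ")))
  sp <- samples$species[idx]
  outgroup_tips <- tree$tip.label[samples$is_outgroup[idx]]
  ingroup_species <- sort(unique(sp[!samples$is_outgroup[idx]]))
  all_tips <- tree$tip.label
  ntip <- length(all_tips)
  sets <- node_tipsets(tree)
  sup <- support_by_node(tree)
  # candidate clade sides: each edge contributes its child tip set and the
  # complement; with outgroups present a valid side must contain none
  side_list <- list(); side_support <- numeric(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    s1 <- sets[[ch]]
    s2 <- sort(setdiff(all_tips, s1))
    esup <- if (ch > ntip) sup[ch] else 100  # pendant edges are trivially present
    if (length(s1) <= 1 || length(s2) <= 1) esup <- 100
    side_list <- c(side_list, list(s1, s2))
    side_support <- c(side_support, esup, esup)
  }
  per <- lapply(ingroup_species, function(s) {
    tips <- sort(tree$tip.label[sp == s & !samples$is_outgroup[idx]])
    if (length(tips) == 0)
      return(data.frame(species = s, n_individuals = 0L, status = "absent",
                        support = NA_real_, stringsAsFactors = FALSE))
    if (length(tips) == 1)
      return(data.frame(species = s, n_individuals = 1L, status = "singleton",
                        support = NA_real_, stringsAsFactors = FALSE))
    best <- NA_real_; mono <- FALSE
    for (k in seq_along(side_list)) {
      side <- side_list[[k]]
      if (length(side) != length(tips) || !all(side == tips)) next
      if (length(outgroup_tips) && any(outgroup_tips %in% side)) next
      mono <- TRUE
      cand <- side_support[k]
      if (is.na(best) || (!is.na(cand) && cand > best)) best <- cand
    }
    status <- if (!mono) "non-monophyletic"
      else if (is.na(best) || best > threshold) "monophyletic-with-support"
      else "monophyletic-low-support"
    data.frame(species = s, n_individuals = length(tips), status = status,
               support = best, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  multi <- per$status %in% c("monophyletic-with-support",
                             "monophyletic-low-support", "non-monophyletic")
  singles <- per$status == "singleton"
  n_success <- sum(per$status == "monophyletic-with-support")
  n_eval <- sum(multi)
  if (singleton_policy == "fail") n_eval <- n_eval + sum(singles)
  if (singleton_policy == "succeed") {
    n_eval <- n_eval + sum(singles)
    n_success <- n_success + sum(singles)
  }
  structure(list(per_species = per, n_success = n_success,
                 n_evaluated = n_eval,
                 rate = if (n_eval > 0) 100 * n_success / n_eval else NA_real_,
                 threshold = threshold, singleton_policy = singleton_policy),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> %d/%d species discriminated (%.2f%%), support > %g%%, singletons: %s\n",
              x$n_success, x$n_evaluated, x$rate, x$threshold, x$singleton_policy))
  invisible(x)
}
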