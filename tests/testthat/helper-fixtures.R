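# Shared fixture builders and independent oracles.

make_aln <- function(seqs, name = "L") locus_alignment(name, seqs)

samples_table <- function(ids, species, outgroup = rep(FALSE, length(ids))) {
  data.frame(sample_id = ids, species = species, is_outgroup = outgroup,
             stringsAsFactors = FALSE)
}

# Random aligned sequences with optional gaps and ambiguity codes.
rand_seqs <- function(n, len, p_gap = 0, p_amb = 0, prefix = "s") {
  pool <- c("A", "C", "G", "T")
  amb <- c("R", "Y", "N", "W")
  out <- vapply(seq_len(n), function(i) {
    ch <- sample(pool, len, replace = TRUE)
    if (p_gap > 0) ch[stats::runif(len) < p_gap] <- "-"
    if (p_amb > 0) {
      hit <- stats::runif(len) < p_amb
      ch[hit] <- sample(amb, sum(hit), replace = TRUE)
    }
    paste(ch, collapse = "")
  }, "")
  names(out) <- paste0(prefix, seq_len(n))
  out
}

# Independent K2P oracle: character-by-character recount plus the closed
# form, no shared code with the package implementation.
k2p_oracle <- function(s1, s2) {
  c1 <- strsplit(toupper(s1), "")[[1]]
  c2 <- strsplit(toupper(s2), "")[[1]]
  purines <- c("A", "G"); pyrimidines <- c("C", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(c1)) {
    a <- c1[k]; b <- c2[k]
    if (!(a %in% c(purines, pyrimidines)) || !(b %in% c(purines, pyrimidines)))
      next
    n <- n + 1L
    if (a == b) next
    same_class <- (a %in% purines && b %in% purines) ||
      (a %in% pyrimidines && b %in% pyrimidines)
    if (same_class) ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0) return(list(distance = NA_real_, n_sites = 0L))
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    return(list(distance = NA_real_, n_sites = n))
  list(distance = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
       n_sites = n)
}

# Random unrooted binary tree with comfortably long branches; its patristic
# distances form an additive matrix.
rand_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1)
  tr
}

# Unordered set of non-trivial bipartitions, each canonicalized to the side
# not containing the alphabetically first tip.
biparts_of <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- character()
  for (cl in pp) {
    side <- sort(attr(pp, "labels")[cl])
    if (length(side) < 2 || length(side) > length(tips) - 2) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(side, collapse = "|"))
  }
  sort(unique(out))
}

# Small synthetic dataset used by several identification tests.
small_sim <- function(seed, n_species = 10, ind = c(2, 3), twin_pairs = 0,
                      intra = 0.003, inter = 0.1, L = 600) {
  p <- sim_params(n_species, ind,
                  list(locus_spec("L1", L, kappa = 4, gc_target = 50)),
                  intra_depth = intra, inter_depth = inter,
                  twin_pairs = twin_pairs, seed = seed)
  build_dataset(p)
}
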