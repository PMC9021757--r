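# Kimura two-parameter distances, intra/inter partitioning, barcoding gap.

# Encode aligned strings as integers: A=1, C=2, G=3, T=4; everything else
# (gaps, N, ambiguity codes) = 0 and is excluded pairwise from comparisons.
encode_alignment <- function(aln) {
  m <- seq_matrix(aln)
  enc <- matrix(match(m, UNAMBIGUOUS, nomatch = 0L), nrow = nrow(m))
  rownames(enc) <- rownames(m)
  enc
}

k2p_from_counts <- function(n_ts, n_tv, n_sites) {
  if (n_sites == 0) return(NA_real_)
  P <- n_ts / n_sites
  Q <- n_tv / n_sites
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Compares only columns where both sequences carry an unambiguous base
#' (pairwise deletion of gaps, `N` and ambiguity codes). With `P` the
#' proportion of transitions (A<->G, C<->T) and `Q` the proportion of
#' transversions among the compared sites, the distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` substitutions per site.
#' The distance is undefined (`NA`) when no sites are comparable or either
#' logarithm argument is non-positive (saturation).
#'
#' @param seq1,seq2 Aligned sequences of equal length (character strings or
#'   single-character vectors).
#' @return A list with `distance` (`NA` when undefined) and `n_sites`, the
#'   number of compared columns.
#' @export
k2p_distance <- function(seq1, seq2) {
  c1 <- if (length(seq1) == 1) strsplit(toupper(seq1), "")[[1]] else toupper(seq1)
  c2 <- if (length(seq2) == 1) strsplit(toupper(seq2), "")[[1]] else toupper(seq2)
  if (length(c1) != length(c2))
    bg_validation_error("sequences have unequal aligned lengths")
  e1 <- match(c1, UNAMBIGUOUS, nomatch = 0L)
  e2 <- match(c2, UNAMBIGUOUS, nomatch = 0L)
  keep <- e1 > 0L & e2 > 0L
  e1 <- e1[keep]; e2 <- e2[keep]
  n <- length(e1)
  # transitions are A<->G (1,3) and C<->T (2,4): codes differ by 2
  diff <- e1 != e2
  n_ts <- sum(diff & abs(e1 - e2) == 2L)
  n_tv <- sum(diff) - n_ts
  list(distance = k2p_from_counts(n_ts, n_tv, n), n_sites = n)
}

#' All-pairs K2P distance matrix for a locus alignment
#'
#' Computes every pairwise K2P distance under pairwise deletion. Pairs whose
#' distance is undefined (no comparable sites or saturated) are flagged in
#' the validity mask and excluded from all downstream summaries.
#'
#' @param aln A [locus_alignment] with at least 2 rows.
#' @return An object of class `k2p_matrix` with fields `labels`, `d`
#'   (symmetric numeric matrix, proportion scale, `NA` where invalid),
#'   `valid` (symmetric logical) and `n_sites` (symmetric integer matrix of
#'   compared-column counts).
#' @export
k2p_distance_matrix <- function(aln) {
  if (length(aln$seqs) < 2)
    bg_validation_error("need at least 2 sequences for a distance matrix")
  enc <- encode_alignment(aln)
  labels <- rownames(enc)
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
  dimnames(d) <- dimnames(ok) <- dimnames(n_sites) <- list(labels, labels)
  n_invalid <- sum(!ok[upper.tri(ok)])
  if (n_invalid > 0)
    warning(sprintf("%d pair(s) have undefined K2P distance and were flagged invalid",
                    n_invalid), call. = FALSE)
  structure(list(labels = labels, d = d, valid = ok,
                 n_sites = matrix(as.integer(n_sites), nrow(enc),
                                  dimnames = list(labels, labels))),
            class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<k2p_matrix> %d samples, %d/%d valid pairs\n", n,
              sum(x$valid[upper.tri(x$valid)]), n * (n - 1) / 2))
  invisible(x)
}

#' Write / read a K2P matrix as a square tab-delimited file
#'
#' @param dm A `k2p_matrix`.
#' @param path Output path. Invalid entries are written as `NA`.
#' @export
write_distance_tsv <- function(dm, path) {
  m <- dm$d
  m[!dm$valid] <- NA
  df <- data.frame(sample_id = dm$labels, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @param path Path to a file written by [write_distance_tsv()].
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labels <- df[[1]]
  d <- as.matrix(df[, -1, drop = FALSE])
  dimnames(d) <- list(labels, labels)
  valid <- !is.na(d)
  diag(valid) <- TRUE
  structure(list(labels = labels, d = d, valid = valid,
                 n_sites = matrix(NA_integer_, length(labels), length(labels),
                                  dimnames = list(labels, labels))),
            class = "k2p_matrix")
}

#' Partition pairwise distances into intra- and inter-specific sets
#'
#' Every valid pairwise distance between two ingroup samples lands in
#' exactly one of the two sets: `intra` when the samples are conspecific,
#' `inter` otherwise. Outgroup samples are excluded. Species represented by
#' a single individual contribute no intraspecific distances.
#'
#' @param dm A `k2p_matrix`.
#' @param samples Sample table covering every matrix label.
#' @return An object of class `gap_profile` with data frames `intra`
#'   (`species`, `distance`) and `inter` (`species1`, `species2`,
#'   `distance`), plus `per_species_max_intra` and `per_species_min_inter`
#'   named vectors. Distances stay on the proportion scale.
#' @export
partition_distances <- function(dm, samples) {
  idx <- match(dm$labels, samples$sample_id)
  if (anyNA(idx))
    bg_validation_error(sprintf("labels with no sample record: %s",
      paste(dm$labels[is.na(idx)], collapse = ", ")))
  ingroup <- which(!samples$is_outgroup[idx])
  sp <- samples$species[idx]
  pairs <- which(upper.tri(dm$d), arr.ind = TRUE)
  keep <- pairs[, 1] %in% ingroup & pairs[, 2] %in% ingroup &
    dm$valid[pairs]
  pairs <- pairs[keep, , drop = FALSE]
  sp1 <- sp[pairs[, 1]]; sp2 <- sp[pairs[, 2]]
  dval <- dm$d[pairs]
  same <- sp1 == sp2
  intra <- data.frame(species = sp1[same], distance = dval[same],
                      stringsAsFactors = FALSE)
  lo <- pmin(sp1[!same], sp2[!same]); hi <- pmax(sp1[!same], sp2[!same])
  inter <- data.frame(species1 = lo, species2 = hi, distance = dval[!same],
                      stringsAsFactors = FALSE)
  max_intra <- if (nrow(intra)) tapply(intra$distance, intra$species, max) else NULL
  min_inter <- NULL
  if (nrow(inter)) {
    both <- rbind(data.frame(species = inter$species1, distance = inter$distance),
                  data.frame(species = inter$species2, distance = inter$distance))
    min_inter <- tapply(both$distance, both$species, min)
  }
  structure(list(intra = intra, inter = inter,
                 per_species_max_intra = max_intra,
                 per_species_min_inter = min_inter),
            class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  cat(sprintf("<gap_profile> %d intraspecific, %d interspecific distances\n",
              nrow(x$intra), nrow(x$inter)))
  invisible(x)
}

#' Barcoding-gap summary statistics
#'
#' Summarizes the separation between intra- and inter-specific distance
#' distributions: means and ranges (percent scale), a shared-bin histogram,
#' the global gap indicator `min(inter) - max(intra)` and the overlap
#' fraction, i.e. the proportion of intraspecific distances at or above the
#' smallest interspecific distance. A positive gap indicator with zero
#' overlap is the ideal barcode.
#'
#' @param gp A `gap_profile` with at least one distance in each set.
#' @param bin_width Histogram bin width in percent (default 0.5).
#' @return A list with `intra_mean`, `intra_range`, `inter_mean`,
#'   `inter_range` (all percent), `gap` (percent), `overlap_fraction`, and
#'   `histogram` (data frame: `bin_start`, `bin_end`, `n_intra`, `n_inter`).
#' @export
gap_statistics <- function(gp, bin_width = 0.5) {
  if (nrow(gp$intra) == 0)
    bg_validation_error("no intraspecific distances available")
  if (nrow(gp$inter) == 0)
    bg_validation_error("no interspecific distances available")
  intra <- gp$intra$distance * 100
  inter <- gp$inter$distance * 100
  top <- max(intra, inter, bin_width)
  edges <- seq(0, ceiling(top / bin_width) * bin_width + bin_width, by = bin_width)
  hist_counts <- function(x) {
    idx <- pmin(findInterval(x, edges, rightmost.closed = TRUE), length(edges) - 1L)
    tabulate(idx, nbins = length(edges) - 1L)
  }
  histogram <- data.frame(bin_start = utils::head(edges, -1),
                          bin_end = edges[-1],
                          n_intra = hist_counts(intra),
                          n_inter = hist_counts(inter))
  list(intra_mean = mean(intra), intra_range = range(intra),
       inter_mean = mean(inter), inter_range = range(inter),
       gap = min(inter) - max(intra),
       overlap_fraction = mean(intra >= min(inter)),
       histogram = histogram)
}
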