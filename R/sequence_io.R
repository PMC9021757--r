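# Reading, validating and characterizing aligned multi-locus barcode data.

ALLOWED_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-")
UNAMBIGUOUS <- c("A", "C", "G", "T")

#' Construct a locus alignment
#'
#' An aligned set of sequences for one barcoding locus. Rows are keyed by
#' sample id; every row must have the same number of columns. The alphabet is
#' A/C/G/T, the IUPAC ambiguity codes, `N` and the gap character `-`.
#'
#' @param locus_name Name of the locus (e.g. `"ITS"`).
#' @param seqs Named character vector of aligned sequences (names are sample
#'   ids). Lower-case input is folded to upper case.
#' @param partition Optional data frame with columns `locus`, `start`, `end`
#'   (1-based inclusive column spans) recording constituent loci of a
#'   concatenated alignment; used for partitioned bootstrap resampling.
#' @return An object of class `locus_alignment` with fields `locus_name`,
#'   `seqs`, `aligned_length` and `partition`.
#' @export
locus_alignment <- function(locus_name, seqs, partition = NULL) {
  if (!is.character(seqs) || is.null(names(seqs)) || any(names(seqs) == ""))
    bg_validation_error("'seqs' must be a named character vector")
  if (anyDuplicated(names(seqs)))
    bg_validation_error(sprintf(
      "duplicate sample id(s): %s",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    bg_alignment_error(sprintf(
      "unequal aligned lengths: %s", paste(unique(lens), collapse = ", ")))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% ALLOWED_CHARS)
    if (length(bad))
      bg_validation_error(sprintf(
        "illegal character '%s' in record '%s' at column %d",
        chars[bad[1]], names(seqs)[i], bad[1]))
    if (all(chars == "-"))
      bg_validation_error(sprintf("record '%s' is entirely gaps", names(seqs)[i]))
  }
  structure(
    list(locus_name = locus_name, seqs = seqs,
         aligned_length = unname(lens[1]), partition = partition),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d sequences x %d columns\n",
              x$locus_name, length(x$seqs), x$aligned_length))
  if (!is.null(x$partition))
    cat("  partition:", paste(sprintf("%s[%d-%d]", x$partition$locus,
        x$partition$start, x$partition$end), collapse = " "), "\n")
  invisible(x)
}

# Character matrix view (rows = samples, cols = alignment columns).
seq_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}

#' Read an aligned FASTA file
#'
#' Headers follow the convention `Species_binomial|sample_id|[outgroup]`:
#' the first `|`-delimited field is the species binomial, the second the
#' unique sample id, and an optional third field equal to `outgroup` flags
#' the sample as an outgroup. A header with a single field is taken as both
#' species and sample id.
#'
#' @param path Path to an aligned multi-FASTA file.
#' @param locus_name Locus name to attach to the alignment.
#' @return A list with `alignment` (a [locus_alignment]) and `samples`
#'   (a data frame with columns `sample_id`, `species`, `is_outgroup`).
#' @export
read_aligned_fasta <- function(path, locus_name) {
  if (!file.exists(path)) bg_error(sprintf("file not found: %s", path), "io_error")
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- as.character(ss)
  parts <- strsplit(headers, "|", fixed = TRUE)
  species <- vapply(parts, `[`, "", 1)
  sample_id <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1], "")
  is_outgroup <- vapply(parts, function(p)
    length(p) >= 3 && tolower(trimws(p[3])) == "outgroup", logical(1))
  if (any(species == "")) bg_validation_error("empty species field in FASTA header")
  if (anyDuplicated(sample_id))
    bg_validation_error(sprintf("duplicate sample_id in %s: %s", path,
      paste(unique(sample_id[duplicated(sample_id)]), collapse = ", ")))
  names(seqs) <- sample_id
  aln <- locus_alignment(locus_name, seqs)
  samples <- data.frame(sample_id = sample_id, species = species,
                        is_outgroup = is_outgroup, stringsAsFactors = FALSE)
  list(alignment = aln, samples = samples)
}

#' Write a locus alignment as FASTA
#'
#' @param aln A [locus_alignment].
#' @param path Output path.
#' @param samples Optional sample table; when given, headers are rebuilt as
#'   `species|sample_id|outgroup`, otherwise headers are the sample ids.
#' @export
write_aligned_fasta <- function(aln, path, samples = NULL) {
  headers <- names(aln$seqs)
  if (!is.null(samples)) {
    idx <- match(headers, samples$sample_id)
    if (anyNA(idx)) bg_validation_error("sample table does not cover all rows")
    headers <- ifelse(samples$is_outgroup[idx],
                      paste(samples$species[idx], headers, "outgroup", sep = "|"),
                      paste(samples$species[idx], headers, sep = "|"))
  }
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Assemble a multi-locus barcode dataset
#'
#' @param samples Data frame with columns `sample_id`, `species`,
#'   `is_outgroup`; every row key of every locus must appear here. A sample
#'   may be absent from a locus (e.g. a PCR failure).
#' @param loci Named list of [locus_alignment] objects (names are locus names).
#' @return An object of class `barcode_dataset`.
#' @export
barcode_dataset <- function(samples, loci) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "species", "is_outgroup") %in% names(samples)))
  if (anyDuplicated(samples$sample_id))
    bg_validation_error("duplicate sample_id in sample table")
  if (any(!nzchar(samples$species)))
    bg_validation_error("empty species name in sample table")
  if (is.null(names(loci)) || any(names(loci) == ""))
    bg_validation_error("'loci' must be a named list")
  for (nm in names(loci)) {
    aln <- loci[[nm]]
    if (!inherits(aln, "locus_alignment"))
      bg_validation_error(sprintf("locus '%s' is not a locus_alignment", nm))
    missing <- setdiff(names(aln$seqs), samples$sample_id)
    if (length(missing))
      bg_validation_error(sprintf(
        "locus '%s' has rows with no sample record: %s",
        nm, paste(missing, collapse = ", ")))
  }
  structure(list(samples = samples, loci = loci), class = "barcode_dataset")
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat(sprintf("<barcode_dataset> %d samples, %d species (%d outgroup), %d loci\n",
              nrow(x$samples), length(unique(x$samples$species[!x$samples$is_outgroup])),
              sum(x$samples$is_outgroup), length(x$loci)))
  for (nm in names(x$loci))
    cat(sprintf("  %s: %d sequences x %d bp\n", nm,
                length(x$loci[[nm]]$seqs), x$loci[[nm]]$aligned_length))
  invisible(x)
}

#' Read a multi-locus dataset from per-locus FASTA files
#'
#' @param paths Named character vector of FASTA paths; names are locus names.
#' @return A [barcode_dataset]. Sample metadata from all files are merged and
#'   must agree on species and outgroup status.
#' @export
read_barcode_dataset <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    bg_validation_error("'paths' must be named by locus")
  loci <- list(); tabs <- list()
  for (nm in names(paths)) {
    r <- read_aligned_fasta(paths[[nm]], nm)
    loci[[nm]] <- r$alignment
    tabs[[nm]] <- r$samples
  }
  samples <- unique(do.call(rbind, tabs))
  if (anyDuplicated(samples$sample_id))
    bg_validation_error("conflicting metadata for the same sample_id across loci")
  rownames(samples) <- NULL
  barcode_dataset(samples, loci)
}

#' Sequence characteristics of a locus alignment
#'
#' Computes the per-locus summary used to characterize candidate barcodes:
#' number of sequences, ungapped length range, aligned length, GC content
#' range, and counts of variable and parsimony-informative sites.
#'
#' GC content per row is (G+C)/(A+C+G+T) over unambiguous, ungapped
#' characters. A column is variable if at least two distinct unambiguous
#' states occur; it is parsimony-informative if at least two states each
#' occur in at least two rows. Gaps, `N` and ambiguity codes never count as
#' states.
#'
#' @param aln A [locus_alignment] with at least 2 rows.
#' @return An object of class `locus_stats` (a list; see fields in source),
#'   coercible to a one-row data frame with [as.data.frame()].
#' @export
locus_stats <- function(aln) {
  if (length(aln$seqs) < 2)
    bg_validation_error("locus_stats requires at least 2 sequences")
  m <- seq_matrix(aln)
  ungapped <- rowSums(m != "-")
  acgt <- matrix(m %in% UNAMBIGUOUS, nrow = nrow(m))
  gc <- rowSums(matrix(m %in% c("G", "C"), nrow = nrow(m))) / rowSums(acgt) * 100
  n_var <- 0L; n_pi <- 0L
  for (j in seq_len(ncol(m))) {
    states <- m[acgt[, j], j]
    tab <- table(states)
    if (length(tab) >= 2) {
      n_var <- n_var + 1L
      if (sum(tab >= 2) >= 2) n_pi <- n_pi + 1L
    }
  }
  structure(list(
    locus_name = aln$locus_name,
    n_sequences = length(aln$seqs),
    ungapped_length_min = min(ungapped),
    ungapped_length_max = max(ungapped),
    aligned_length = aln$aligned_length,
    gc_min = min(gc), gc_max = max(gc),
    n_variable_sites = n_var,
    n_parsimony_informative_sites = n_pi
  ), class = "locus_stats")
}

#' @export
as.data.frame.locus_stats <- function(x, ...) {
  data.frame(locus = x$locus_name, n_sequences = x$n_sequences,
             ungapped_min = x$ungapped_length_min,
             ungapped_max = x$ungapped_length_max,
             aligned_length = x$aligned_length,
             gc_min = round(x$gc_min, 1), gc_max = round(x$gc_max, 1),
             n_variable_sites = x$n_variable_sites,
             n_parsimony_informative = x$n_parsimony_informative_sites,
             stringsAsFactors = FALSE)
}

#' @export
print.locus_stats <- function(x, ...) {
  cat(sprintf(
    "<locus_stats> %s: n=%d, aligned %d bp (ungapped %d-%d), GC %.1f-%.1f%%, %d variable / %d parsimony-informative sites\n",
    x$locus_name, x$n_sequences, x$aligned_length, x$ungapped_length_min,
    x$ungapped_length_max, x$gc_min, x$gc_max, x$n_variable_sites,
    x$n_parsimony_informative_sites))
  invisible(x)
}

#' Concatenate loci for combination analyses
#'
#' Rows are restricted to samples present in every named locus (samples
#' missing any constituent locus are dropped, which shrinks the species
#' denominator downstream, as happens with real PCR failures). The per-locus
#' column spans are recorded in the result's `partition` field so the
#' bootstrap can resample within locus blocks.
#'
#' @param ds A [barcode_dataset].
#' @param loci Character vector of at least 2 locus names, in concatenation
#'   order.
#' @return A [locus_alignment] named by joining the locus names with `+`.
#' @export
concatenate_loci <- function(ds, loci) {
  if (length(loci) < 2) bg_validation_error("need at least 2 loci to concatenate")
  missing <- setdiff(loci, names(ds$loci))
  if (length(missing))
    bg_validation_error(sprintf("unknown loci: %s", paste(missing, collapse = ", ")))
  common <- Reduce(intersect, lapply(ds$loci[loci], function(a) names(a$seqs)))
  # preserve dataset sample order
  common <- ds$samples$sample_id[ds$samples$sample_id %in% common]
  if (length(common) == 0)
    bg_validation_error("no sample is present in all requested loci")
  pieces <- lapply(ds$loci[loci], function(a) a$seqs[common])
  cat_seqs <- do.call(paste0, pieces)
  names(cat_seqs) <- common
  lens <- vapply(ds$loci[loci], function(a) a$aligned_length, integer(1))
  ends <- cumsum(lens)
  partition <- data.frame(locus = loci, start = c(1L, utils::head(ends, -1) + 1L),
                          end = ends, stringsAsFactors = FALSE)
  locus_alignment(paste(loci, collapse = "+"), cat_seqs, partition = partition)
}
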