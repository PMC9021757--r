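# Distance-based identification: best match, best close match with an
# intraspecific-distance threshold, and leave-one-out top-hit discrimination.

new_identification_report <- function(per_query) {
  if (is.null(per_query))
    per_query <- data.frame(query = character(), species = character(),
                            nearest = character(), nearest_distance = numeric(),
                            status = character(), is_singleton = logical(),
                            stringsAsFactors = FALSE)
  counts <- table(factor(per_query$status,
                         levels = c("success", "ambiguous", "failure", "unidentified")))
  n_query <- nrow(per_query)
  success_rate <- if (n_query > 0) 100 * counts[["success"]] / n_query else NA_real_
  sp_ok <- tapply(per_query$status == "success", per_query$species, all)
  species_level_rate <- if (length(sp_ok)) 100 * mean(sp_ok) else NA_real_
  structure(list(per_query = per_query, counts = as.list(counts),
                 n_queries = n_query, success_rate = success_rate,
                 species_level_rate = species_level_rate),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("<identification_report> %d queries: %d success, %d ambiguous, %d failure, %d unidentified (success %.2f%%)\n",
              x$n_queries, x$counts$success, x$counts$ambiguous,
              x$counts$failure, x$counts$unidentified, x$success_rate))
  invisible(x)
}

match_queries <- function(dm, samples, threshold = Inf) {
  idx <- match(dm$labels, samples$sample_id)
  if (anyNA(idx))
    bg_validation_error(sprintf("labels with no sample record: %s",
      paste(dm$labels[is.na(idx)], collapse = ", ")))
  ingroup <- which(!samples$is_outgroup[idx])
  if (length(ingroup) < 2)
    bg_validation_error("need at least 2 ingroup samples")
  sp <- samples$species[idx]
  singleton_sp <- names(which(table(sp[ingroup]) == 1))
  out <- vector("list", length(ingroup))
  for (k in seq_along(ingroup)) {
    i <- ingroup[k]
    others <- setdiff(ingroup, i)
    valid_others <- others[dm$valid[i, others]]
    if (length(valid_others) == 0) next  # excluded: no valid neighbour
    dvec <- dm$d[i, valid_others]
    m <- min(dvec)
    if (m > threshold) {
      out[[k]] <- data.frame(
        query = dm$labels[i], species = sp[i], nearest = "",
        nearest_distance = m, status = "unidentified",
        is_singleton = sp[i] %in% singleton_sp, stringsAsFactors = FALSE)
      next
    }
    nn <- valid_others[dvec == m]  # exact ties: identical stored distances
    nn_sp <- unique(sp[nn])
    status <- if (length(nn_sp) > 1) "ambiguous"
      else if (nn_sp == sp[i]) "success" else "failure"
    out[[k]] <- data.frame(
      query = dm$labels[i], species = sp[i],
      nearest = paste(dm$labels[nn], collapse = ","),
      nearest_distance = m, status = status,
      is_singleton = sp[i] %in% singleton_sp, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Best-match identification
#'
#' Leave-one-out nearest-neighbour identification: each ingroup sample is
#' queried against all other ingroup samples and its minimum-distance
#' neighbour set (including exact ties) determines the outcome. All
#' neighbours conspecific with the query: success; all heterospecific:
#' failure; a mix of species among tied neighbours: ambiguous. A singleton
#' species' query can never succeed (no conspecific exists); singletons are
#' flagged in `per_query$is_singleton` so either denominator convention can
#' be audited. Queries with no valid neighbour are excluded.
#'
#' @param dm A `k2p_matrix`.
#' @param samples Sample table; outgroup samples are excluded.
#' @return An `identification_report`: `per_query` data frame, status
#'   `counts`, `success_rate` (percent of queries) and `species_level_rate`
#'   (percent of species whose every query succeeds).
#' @export
best_match <- function(dm, samples) {
  per_query <- match_queries(dm, samples, threshold = Inf)
  new_identification_report(per_query)
}

#' Intraspecific distance threshold
#'
#' The distance below which a given fraction (default 95%) of all
#' intraspecific distances lie, computed by linear interpolation between
#' order statistics. Used by [best_close_match()] to reject queries with no
#' close barcode match.
#'
#' @param gp A `gap_profile` with a non-empty intraspecific set.
#' @param quantile Fraction in (0, 1]; default 0.95.
#' @return The threshold on the proportion scale.
#' @export
intraspecific_threshold <- function(gp, quantile = 0.95) {
  if (nrow(gp$intra) == 0)
    bg_validation_error("no intraspecific distances to set a threshold from")
  stopifnot(quantile > 0, quantile <= 1)
  x <- sort(gp$intra$distance)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * quantile + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

#' Best-close-match identification
#'
#' As [best_match()], except that a query whose nearest valid neighbour lies
#' farther than `threshold` is classified `unidentified` instead of being
#' matched. With `threshold = Inf` the report is identical to best match.
#'
#' @param dm A `k2p_matrix`.
#' @param samples Sample table; outgroup samples are excluded.
#' @param threshold Non-negative distance threshold (proportion scale),
#'   typically from [intraspecific_threshold()].
#' @return An `identification_report`.
#' @export
best_close_match <- function(dm, samples, threshold) {
  stopifnot(threshold >= 0)
  per_query <- match_queries(dm, samples, threshold = threshold)
  new_identification_report(per_query)
}

# Percent-identity similarity matrix over mutually unambiguous columns.
percent_identity_matrix <- function(aln) {
  enc <- encode_alignment(aln)
  ind <- lapply(1:4, function(b) (enc == b) * 1)
  valid <- (enc > 0L) * 1
  n_sites <- tcrossprod(valid)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  s <- ifelse(n_sites > 0, 100 * matches / n_sites, NA_real_)
  dimnames(s) <- list(rownames(enc), rownames(enc))
  s
}

#' Leave-one-out top-hit species discrimination
#'
#' A self-contained analogue of querying a local sequence database: each
#' ingroup sample is scored against every other ingroup sample (default
#' scorer: percent identity over mutually unambiguous columns of the
#' alignment) and its top hits are the samples attaining the maximum score.
#' A species is discriminated only when every one of its members' top hits
#' are exclusively conspecific; any heterospecific sequence among a
#' member's top hits fails the species.
#'
#' @param aln A [locus_alignment].
#' @param samples Sample table; outgroup samples are excluded.
#' @param scorer Optional function `(locus_alignment) -> similarity matrix`
#'   (higher is better, `NA` for unscorable pairs); defaults to percent
#'   identity.
#' @return A list with `per_species` data frame (`species`,
#'   `n_individuals`, `success`), `n_success`, `n_evaluated` and `rate`
#'   (percent of species).
#' @export
top_hit_discrimination <- function(aln, samples, scorer = NULL) {
  scorer <- scorer %||% percent_identity_matrix
  sim <- scorer(aln)
  labels <- rownames(sim)
  idx <- match(labels, samples$sample_id)
  if (anyNA(idx))
    bg_validation_error(sprintf("rows with no sample record: %s",
      paste(labels[is.na(idx)], collapse = ", ")))
  ingroup <- which(!samples$is_outgroup[idx])
  if (length(ingroup) < 2)
    bg_validation_error("need at least 2 ingroup samples")
  sp <- samples$species[idx]
  member_ok <- logical(length(ingroup))
  for (k in seq_along(ingroup)) {
    i <- ingroup[k]
    others <- setdiff(ingroup, i)
    svec <- sim[i, others]
    others <- others[!is.na(svec)]; svec <- svec[!is.na(svec)]
    if (length(svec) == 0) { member_ok[k] <- NA; next }
    top <- others[svec == max(svec)]
    member_ok[k] <- all(sp[top] == sp[i])
  }
  species <- sort(unique(sp[ingroup]))
  per <- data.frame(species = species,
                    n_individuals = as.integer(table(sp[ingroup])[species]),
                    success = vapply(species, function(s)
                      isTRUE(all(member_ok[sp[ingroup] == s])), logical(1)),
                    stringsAsFactors = FALSE)
  n_eval <- nrow(per)
  n_success <- sum(per$success)
  list(per_species = per, n_success = n_success, n_evaluated = n_eval,
       rate = if (n_eval > 0) 100 * n_success / n_eval else NA_real_)
}
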