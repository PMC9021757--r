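# Internal helpers: error classes, derived seeds, small utilities.

#' @keywords internal
"_PACKAGE"

# Signal a classed condition so callers can distinguish user errors
# (validation, alignment) from analysis failures (e.g. too many discarded
# bootstrap replicates) and I/O problems.
bg_error <- function(msg, class) {
  stop(structure(
    class = c(paste0("barcodegap_", class), "barcodegap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

bg_validation_error <- function(msg) bg_error(msg, "validation_error")
bg_alignment_error  <- function(msg) bg_error(msg, "alignment_error")
bg_analysis_error   <- function(msg) bg_error(msg, "analysis_error")

#' Derive a stage-specific seed from a global seed
#'
#' One global seed drives the whole pipeline; each stage (per locus, per
#' bootstrap, ...) receives a seed deterministically derived from the global
#' seed and the stage name, so any stage can be re-run in isolation.
#'
#' @param seed Integer global seed.
#' @param stage Character stage identifier (e.g. `"bootstrap:ITS"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic number formatting for newick output and reports.
fmt_num <- function(x) sprintf("%.15g", x)
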