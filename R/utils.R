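#' dropscreen: pooled shRNA dropout screen analysis
#'
#' Simulation, quantification, depletion scoring, differential expression,
#' set integration and enrichment for barcode dropout screens of drug
#' resistance.
#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

abort_validation <- function(msg, class = "dropscreen_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_parameter <- function(msg) {
  abort_validation(msg, class = "dropscreen_parameter_error")
}

abort_io <- function(msg) {
  abort_validation(msg, class = "dropscreen_io_error")
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

## Seeded evaluation that leaves the caller's RNG state untouched.
with_seed <- function(seed, code) {
  if (!is_count(seed)) abort_parameter("seed must be a single integer")
  withr::with_seed(as.integer(seed), code)
}

## Hamming distance between equal-length strings; NA on length mismatch.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

## Case-normalized gene symbols used for all set operations.
normalize_symbols <- function(x) {
  unique(toupper(trimws(as.character(x))))
}

geometric_mean <- function(x) exp(mean(log(x)))
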