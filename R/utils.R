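#' Canonicalize gene symbols
#'
#' One documented canonicalization used everywhere genes are compared:
#' uppercase and strip surrounding whitespace. All set operations (enrichment,
#' cross-study alignment, marker overlap) pass symbols through this first.
#'
#' @param x character vector of gene symbols
#' @return character vector of canonical symbols
#' @export
canonical_gene <- function(x) {
  toupper(trimws(as.character(x)))
}

# Fixed module label palette, assigned by decreasing module size. Mirrors the
# conventional coexpression-network color order; "grey" is reserved for
# unassigned genes and never appears here.
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}

module_labels_for <- function(n) {
  pal <- module_palette()
  if (n <= length(pal)) return(pal[seq_len(n)])
  c(pal, paste0("module", seq.int(length(pal) + 1L, n)))
}

#' Derive a deterministic substream seed
#'
#' All randomness in the package flows from a single user seed; independent
#' stages draw from substreams derived by hashing the stage tag into the seed.
#' Kept below 2^31 so the result is a valid R integer seed.
#'
#' @param seed integer master seed
#' @param tag character tag naming the consumer (e.g. "study", "permutation")
#' @return integer seed for `set.seed()`
#' @export
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
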