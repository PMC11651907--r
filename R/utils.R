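# internal helpers shared across modules

# single string key per pair; \r cannot occur in node ids read from
# whitespace/comma-separated files
pair_key <- function(i, j) paste(i, j, sep = "\r")

# canonical (unordered) orientation of a pair: lexicographically smaller
# id first; node ids are opaque strings throughout
orient_pairs <- function(i, j) {
  swap <- i > j
  list(i = ifelse(swap, j, i), j = ifelse(swap, i, j))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

stop_ <- function(...) stop(..., call. = FALSE)
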