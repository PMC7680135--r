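## Internal helpers shared across modules.

#' Canonicalize unordered document pairs
#'
#' Returns a two-column data.table (i, j) with i < j lexicographically, so an
#' unordered pair has a single canonical representation suitable for keyed
#' joins.
#'
#' @param a,b character vectors of equal length.
#' @return data.table with columns `i`, `j`.
#' @keywords internal
#' @noRd
pair_key <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- a > b
  i <- ifelse(swap, b, a)
  j <- ifelse(swap, a, b)
  data.table(i = i, j = j)
}

## Deterministic ordering used before any summation so totals are
## reproducible bit-for-bit on a given platform.
order_pairs <- function(dt) {
  setorderv(dt, c("i", "j"))
  dt
}

## Dense re-labelling of cluster ids to 1..K preserving first-appearance
## order of sorted original labels.
dense_ids <- function(x) {
  ux <- sort(unique(x))
  match(x, ux)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_litmap <- function(...) stop(..., call. = FALSE)

## Split a semicolon-delimited field into a character vector (TSV list
## columns); empty string -> character(0).
split_list_field <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

join_list_field <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}
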