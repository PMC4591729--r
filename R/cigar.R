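#' Parse a CIGAR string into operations
#' @param cigar A single CIGAR string, e.g. `"10M3I90M"`.
#' @return A list with `op` (character) and `len` (integer) vectors.
#' @noRd
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || identical(cigar, "*"))
    validation_error("malformed CIGAR: '", cigar, "'")
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar))
    validation_error("malformed CIGAR: '", cigar, "'")
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
cigar_query_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])

#' Project a reference interval onto read coordinates
#'
#' Given an aligned read's CIGAR and mapping position, returns the smallest
#' read-coordinate interval whose aligned reference footprint contains the
#' reference interval `[start, end]`.  Insertions between covered reference
#' bases are included; deletions inside the interval contribute zero read
#' bases (a fully deleted interval projects to an empty interval with
#' `end < start`).  The interval is *not covered* — and `NULL` is returned —
#' when any part of it lies outside the read's aligned span, including
#' soft/hard-clipped ends and reference skips (`N`).
#'
#' @param cigar CIGAR string of the alignment.
#' @param pos 1-based leftmost mapping position (SAM `POS`).
#' @param start,end 1-based inclusive reference interval to project.
#' @return Integer vector `c(read_start, read_end)` (1-based inclusive) or
#'   `NULL` when the interval is not covered.
#' @examples
#' project_ref_interval("100M", 1, 11, 20)     # c(11, 20)
#' project_ref_interval("10M3I90M", 1, 6, 15)  # c(6, 18)
#' project_ref_interval("50M", 101, 141, 160)  # NULL
#' @export
project_ref_interval <- function(cigar, pos, start, end) {
  if (end < start) validation_error("end must be >= start")
  ops <- parse_cigar(cigar)
  a <- start - 1L; b <- end          # 0-based half-open [a, b)
  r <- pos - 1L; q <- 0L
  qa <- NA_integer_; qb <- NA_integer_
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; l <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      if (a >= r && a < r + l) qa <- q + (a - r)
      if (b - 1L >= r && b - 1L < r + l) qb <- q + (b - 1L - r) + 1L
      r <- r + l; q <- q + l
    } else if (op == "D") {
      if (a >= r && a < r + l) qa <- q
      if (b - 1L >= r && b - 1L < r + l) qb <- q
      r <- r + l
    } else if (op == "N") {
      if (max(a, r) < min(b, r + l)) return(NULL)
      r <- r + l
    } else if (op %in% c("I", "S")) {
      q <- q + l
    }                                 # H, P consume nothing
  }
  if (is.na(qa) || is.na(qb)) return(NULL)
  c(qa + 1L, qb)                      # 1-based inclusive; empty when qb < qa + 1
}
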