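#' Detect perfect SSRs in reference sequences
#'
#' Scans DNA sequences for maximal perfect tandem runs of 1-6 nt motifs and
#' returns them as an [ssr_catalog()].  Only the shortest period of a run is
#' reported (an `(AT)8` run is never also reported as `(ATAT)4`), runs are
#' broken at `N`, and each run is reported once, anchored at its left edge
#' with the motif read verbatim from that phase.  Reported loci consist of
#' whole repeat units only (`length_nt == motif length x repeat count`); a
#' trailing partial unit does not extend the annotated interval.
#'
#' @param sequences Named character vector of DNA sequences, or a
#'   `Biostrings::DNAStringSet`.  Unnamed sequences are named `seq1`, ...
#' @param min_repeats Integer vector of length 6: the minimum number of
#'   repeat units for motif lengths 1..6.  Defaults to the common MISA
#'   thresholds `c(10, 6, 5, 5, 5, 5)`.  Values must be >= 2.
#' @return An [ssr_catalog()] of perfect loci (`ssr_type` `p1`..`p6`).
#' @examples
#' find_perfect_ssrs(c(chr1 = "TTTTTGATGATGATGATGATGATCCCC"),
#'                   min_repeats = c(10, 6, 5, 5, 5, 5))
#' @export
find_perfect_ssrs <- function(sequences, min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (!is.character(sequences))
    validation_error("sequences must be a character vector or DNAStringSet")
  if (length(min_repeats) != 6L || any(min_repeats < 2))
    validation_error("min_repeats must give a minimum count (>= 2) for motif lengths 1..6")
  if (is.null(names(sequences)) && length(sequences))
    names(sequences) <- paste0("seq", seq_along(sequences))

  hits <- list()
  for (sid in names(sequences)) {
    s <- toupper(sequences[[sid]])
    n <- nchar(s)
    if (n == 0L) next
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ok <- ch %in% DNA_BASES
    for (k in 1:6) {
      if (n < k * min_repeats[k]) next
      idx <- seq_len(n - k)
      m <- ch[idx] == ch[idx + k] & ok[idx] & ok[idx + k]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        i0 <- starts[j]                      # run left edge
        reg_len <- r$lengths[j] + k          # maximal period-k region length
        count <- reg_len %/% k
        if (count < min_repeats[k]) next
        motif <- substr(s, i0, i0 + k - 1L)
        if (!is_primitive_motif(motif)) next
        hits[[length(hits) + 1L]] <- data.frame(
          seq_id = sid, ssr_type = paste0("p", k), motif = motif,
          repeat_count = count, start = i0, end = i0 + count * k - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(ssr_catalog(NULL))
  df <- do.call(rbind, hits)
  # a locus is keyed by (seq_id, start); if two periods ever coincide at the
  # same start, keep the shortest
  df <- df[order(df$seq_id, df$start, nchar(df$motif)), , drop = FALSE]
  df <- df[!duplicated(paste(df$seq_id, df$start)), , drop = FALSE]
  df$length_nt <- df$end - df$start + 1L
  ssr_catalog(df)
}

#' Is a motif primitive (not itself a repeat of a shorter unit)?
#' @noRd
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (strrep(substr(motif, 1L, d), k %/% d) == motif) return(FALSE)
  }
  TRUE
}
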