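#' All rotations of a motif
#' @noRd
motif_rotations <- function(motif) {
  k <- nchar(motif)
  unique(substring(strrep(motif, 2L), seq_len(k), seq_len(k) + k - 1L))
}

#' Maximal repeat run covering an anchor position
#'
#' Finds the maximal perfect tandem run (of any rotation of `motif`) in
#' `seq` that covers the 1-based position `anchor`, and counts its whole
#' repeat units.  The run extent includes a trailing partial unit (bases
#' continuing the period), so bases immediately beyond `start`/`end` break
#' the repeat phase by construction.
#'
#' @return list(count, start, end); count 0 (NA bounds) when no full motif
#'   unit covers the anchor.
#' @noRd
repeat_run <- function(seq, anchor, motif) {
  n <- nchar(seq); k <- nchar(motif)
  if (anchor < 1L || anchor > n) validation_error("anchor outside the read")
  best <- list(count = 0L, start = NA_integer_, end = NA_integer_)
  if (n < k) return(best)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ok <- ch %in% DNA_BASES
  rots <- motif_rotations(toupper(motif))
  s <- paste(ch, collapse = "")

  if (n - k >= 1L) {
    idx <- seq_len(n - k)
    m <- ch[idx] == ch[idx + k] & ok[idx] & ok[idx + k]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts[j]; j1 <- ends[j] + k
      if (anchor < i0 || anchor > j1) next
      if (j1 - i0 + 1L < k) next
      if (!(substr(s, i0, i0 + k - 1L) %in% rots)) next
      count <- (j1 - i0 + 1L) %/% k
      if (count > best$count || (count == best$count && !is.na(best$start) && i0 < best$start))
        best <- list(count = count, start = i0, end = j1)
    }
  }
  if (best$count == 0L) {
    # isolated single unit: no period-k self-match, but one full motif copy
    for (w in max(1L, anchor - k + 1L):min(anchor, n - k + 1L)) {
      if (substr(s, w, w + k - 1L) %in% rots) {
        best <- list(count = 1L, start = w, end = w + k - 1L)
        break
      }
    }
  }
  best
}

#' Count repeat units in a read at an anchored position
#'
#' Returns the number of whole motif copies in the maximal perfect tandem
#' run — of any rotation of `motif` — that covers position `anchor` of the
#' read sequence.  Counting is done on the read itself, not on a reference
#' projection, so reads carrying insertion or deletion alleles report the
#' allele actually present in the read.  Returns 0 when no full motif unit
#' covers the anchor.
#'
#' @param seq Read sequence (character scalar).
#' @param anchor 1-based position inside the read, typically the midpoint of
#'   the projected SSR interval (see [project_ref_interval()]).
#' @param motif Repeat motif, 1-6 nt over A/C/G/T.
#' @return Integer count of whole repeat units.
#' @examples
#' count_repeat_units("TTGATGATGATGATGATGATCC", 10, "GAT")  # 6
#' @export
count_repeat_units <- function(seq, anchor, motif) {
  repeat_run(seq, anchor, motif)$count
}
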