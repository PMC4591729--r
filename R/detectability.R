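#' Detectability limits of SSR alleles for a given read length
#'
#' A read can only measure an SSR allele unambiguously when it covers the
#' whole repeat run plus at least one full motif of non-repeat sequence on
#' each side.  For reads of length `read_len` and a motif of `motif_len`
#' nucleotides this caps the measurable run at `read_len - 2 * motif_len`
#' nucleotides, i.e. `floor((read_len - 2 * motif_len) / motif_len)` whole
#' repeat units.  With 100-nt reads, dinucleotide runs are detectable up to
#' 96 nt (48 units) and hexanucleotide runs up to 88 nt (14 units).
#'
#' @param read_len Read length in nucleotides; must exceed `2 * motif_len`.
#' @param motif_len Motif (repeat unit) length in nucleotides, 1-6.
#' @return Integer vector: the maximum measurable run length in nucleotides
#'   (`max_detectable_ssr_length`) or in whole repeat units
#'   (`max_detectable_repeats`).
#' @examples
#' max_detectable_ssr_length(100, 2)  # 96
#' max_detectable_repeats(100, 6)     # 14
#' @export
max_detectable_ssr_length <- function(read_len, motif_len) {
  check_detectability_args(read_len, motif_len)
  as.integer(read_len - 2L * motif_len)
}

#' @rdname max_detectable_ssr_length
#' @export
max_detectable_repeats <- function(read_len, motif_len) {
  check_detectability_args(read_len, motif_len)
  as.integer((read_len - 2L * motif_len) %/% motif_len)
}

check_detectability_args <- function(read_len, motif_len) {
  if (!is.numeric(read_len) || !is.numeric(motif_len))
    validation_error("read_len and motif_len must be numeric")
  if (any(motif_len < 1L) || any(motif_len > 6L) || any(motif_len != floor(motif_len)))
    validation_error("motif_len must be an integer in 1..6")
  if (any(read_len <= 2 * motif_len))
    validation_error("read_len must exceed 2 * motif_len")
  invisible(TRUE)
}
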