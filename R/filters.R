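#' Read-filtering parameters for spanning-read selection
#'
#' @param flank_len Number of read bases required beyond the repeat run on
#'   each side.  `NULL` (default) means one full motif length per locus,
#'   which makes the filter agree with the detectability arithmetic of
#'   [max_detectable_ssr_length()]; set `flank_len = 1` for the permissive
#'   "one or more nucleotides" reading.
#' @param multimap_policy How to recognise multi-mapped reads: `"tag"`
#'   (default) uses the secondary/supplementary flags, a hit-count tag
#'   (`NH`) greater than 1, or a secondary alignment score (`XS`) reaching
#'   the primary score (`AS`) — the output of bowtie2-style aligners;
#'   `"mapq"` treats any read with `MAPQ < min_mapq` as multi-mapped.
#' @param min_mapq Minimum mapping quality under the `"mapq"` policy.
#' @param require_flank_break Require the base adjacent to the repeat run on
#'   each side to break the repeat phase *inside* the read (rejecting runs
#'   that touch a read edge, where the allele length is uncertain).
#' @return A list of class `ssr_filter_params`.
#' @export
filter_params <- function(flank_len = NULL,
                          multimap_policy = c("tag", "mapq"),
                          min_mapq = 10L,
                          require_flank_break = TRUE) {
  multimap_policy <- match.arg(multimap_policy)
  if (!is.null(flank_len) && (!is.numeric(flank_len) || flank_len < 1))
    validation_error("flank_len must be >= 1 (or NULL for one motif length)")
  structure(list(flank_len = if (is.null(flank_len)) NULL else as.integer(flank_len),
                 multimap_policy = multimap_policy,
                 min_mapq = as.integer(min_mapq),
                 require_flank_break = isTRUE(require_flank_break)),
            class = "ssr_filter_params")
}

#' Is an alignment record multi-mapped?
#'
#' Under the `"tag"` policy a read is multi-mapped when its secondary
#' (0x100) or supplementary (0x800) flag is set, when a hit-count tag (`NH`)
#' exceeds 1, or when the secondary alignment score (`XS`) reaches the
#' primary alignment score (`AS`) — i.e. the read has at least one other
#' placement as good as the reported one.  Under the `"mapq"` policy a read
#' is multi-mapped when `MAPQ < min_mapq`.
#'
#' @param read A list with elements `flag`, `mapq` and optionally `NH`,
#'   `AS`, `XS` (missing tags are `NA`/absent).
#' @param params [filter_params()].
#' @return Logical scalar.
#' @export
is_multimapped <- function(read, params = filter_params()) {
  flag <- read$flag %||% 0L
  if (bitwAnd(flag, 0x100L) > 0L || bitwAnd(flag, 0x800L) > 0L) return(TRUE)
  if (params$multimap_policy == "mapq") {
    mq <- read$mapq %||% NA_integer_
    return(!is.na(mq) && mq < params$min_mapq)
  }
  nh <- read$NH %||% NA_integer_
  if (!is.na(nh) && nh > 1L) return(TRUE)
  as <- read$AS %||% NA_integer_
  xs <- read$XS %||% NA_integer_
  if (!is.na(as) && !is.na(xs) && xs >= as) return(TRUE)
  FALSE
}

#' Does a read span an SSR locus with clean flanks?
#'
#' The spanning test behind read retrieval: a read is accepted for a locus
#' iff (a) its aligned footprint covers the whole reference interval of the
#' locus (soft/hard clips and reference skips do not cover; internal
#' deletions do), and (b) the maximal repeat run in the *read* sequence at
#' the locus lies entirely inside the read with at least `flank_len` bases
#' beyond the run on both sides.  Runs touching a read edge are rejected as
#' border-uncertain: the allele could extend beyond the read.
#'
#' @param read A list with `pos` (1-based mapping position), `cigar`, and
#'   `seq` (read bases, reference orientation as stored in SAM).
#' @param locus One catalog row (list or single-row data frame) with
#'   `start`, `end`, `motif`.
#' @param params [filter_params()].
#' @return A list: `accept` (logical), `reason` (`NA`, `"partial_span"` or
#'   `"border_uncertain"`), `count` (repeat units measured in the read),
#'   `run` (read-coordinate extent of the run).
#' @export
passes_span_and_flank <- function(read, locus, params = filter_params()) {
  reject <- function(reason) list(accept = FALSE, reason = reason,
                                  count = NA_integer_, run = NULL)
  proj <- project_ref_interval(read$cigar, read$pos, locus$start, locus$end)
  if (is.null(proj) || proj[2L] < proj[1L]) return(reject("partial_span"))
  anchor <- proj[1L] + (proj[2L] - proj[1L]) %/% 2L
  rr <- repeat_run(read$seq, anchor, locus$motif)
  if (rr$count == 0L) return(reject("border_uncertain"))
  k <- nchar(locus$motif)
  flank <- params$flank_len %||% k
  n <- nchar(read$seq)
  if (params$require_flank_break && (rr$start < 2L || rr$end > n - 1L))
    return(reject("border_uncertain"))
  if (rr$start - flank < 1L || rr$end + flank > n)
    return(reject("border_uncertain"))
  list(accept = TRUE, reason = NA_character_, count = rr$count,
       run = c(rr$start, rr$end))
}

#' Resolve a mate pair accepted at the same locus
#'
#' Both mates of a proper pair can individually span a locus.  When their
#' aligned reference intervals overlap and they report the same repeat
#' count, they measure the same molecule once: one observation is kept.
#' When they overlap but disagree, the pair is internally inconsistent and
#' both are discarded.  Mates that do not overlap each other yet both claim
#' to span the same repeat indicate a misalignment and are both discarded.
#'
#' @param mate_a,mate_b Lists with `ref_start`, `ref_end` (1-based aligned
#'   reference span) and `count` (repeat units), e.g. as produced by
#'   [passes_span_and_flank()] plus alignment coordinates.
#' @return A list: `action` (`"keep_one"` or `"discard_both"`), `keep` (the
#'   retained observation or `NULL`), `reason` (`NA` or `"mate_conflict"`).
#' @export
resolve_mate_pair <- function(mate_a, mate_b) {
  overlaps <- mate_a$ref_start <= mate_b$ref_end && mate_b$ref_start <= mate_a$ref_end
  if (!overlaps)
    return(list(action = "discard_both", keep = NULL, reason = "mate_conflict"))
  if (mate_a$count != mate_b$count)
    return(list(action = "discard_both", keep = NULL, reason = "mate_conflict"))
  first <- if (isTRUE(mate_b$is_first_mate) && !isTRUE(mate_a$is_first_mate))
    mate_b else mate_a
  list(action = "keep_one", keep = first, reason = NA_character_)
}
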