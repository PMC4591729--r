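#' Open a SAM/BAM file for random access
#'
#' SAM input is converted to BAM; unindexed BAM is coordinate-sorted and
#' indexed into a temporary copy.  Returns an `Rsamtools::BamFile`.
#' @noRd
open_alignments <- function(path) {
  if (!file.exists(path))
    validation_error("alignment file '", path, "' does not exist")
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  idx <- paste0(bam, ".bai")
  if (!file.exists(idx)) {
    sorted <- Rsamtools::sortBam(bam, tempfile())
    idx <- Rsamtools::indexBam(sorted)
    bam <- sorted
  }
  Rsamtools::BamFile(bam, index = idx)
}

DISCARD_REASONS <- c("partial_span", "border_uncertain", "multimapped",
                     "mate_conflict", "mate_duplicate", "unmapped_or_secondary")

#' Collect spanning reads and count repeat units per locus
#'
#' The read-retrieval stage.  For every genotypable locus in the catalog,
#' fetches the reads overlapping it from one genotype's alignment file and
#' applies, in order: the unmapped/secondary/supplementary filter, the
#' multi-mapper filter ([is_multimapped()]), the span-and-flank filter
#' ([passes_span_and_flank()]) and mate-pair resolution
#' ([resolve_mate_pair()]).  Repeat units of the surviving observations are
#' counted in read space and aggregated into a histogram per locus.
#'
#' @param alignments Path to a SAM or BAM file (coordinate-sorted or
#'   sortable) for one genotype.  Reference names must match the catalog.
#' @param catalog An [ssr_catalog()].
#' @param params [filter_params()].
#' @param genotype_id Identifier recorded with the table.
#' @param fasta_dir If non-`NULL`, a directory into which one FASTA file of
#'   accepted reads per locus is written (headers carry the read id and its
#'   repeat count).
#' @return A data frame of class `repeat_count_table` with columns `locus`,
#'   `seq_id`, `start`, `end`, `motif`, `ssr_type`, `repeat_count`,
#'   `n_reads`, ordered by catalog position then ascending repeat count.
#'   Attributes: `genotype_id`; `discards`, a per-locus data frame of
#'   fetched/accepted/discard-reason tallies satisfying
#'   `fetched == accepted + sum(reasons)`.
#' @export
collect_spanning_reads <- function(alignments, catalog,
                                   params = filter_params(),
                                   genotype_id = "G1", fasta_dir = NULL) {
  g <- catalog[catalog$genotypable, , drop = FALSE]
  empty <- empty_count_table(genotype_id)
  if (nrow(g) == 0L) return(empty)

  bf <- open_alignments(alignments)
  targets <- Rsamtools::scanBamHeader(bf)$targets
  missing_seq <- setdiff(unique(g$seq_id), names(targets))
  if (length(missing_seq))
    validation_error("reference sequence(s) absent from alignment header: ",
                     paste(missing_seq, collapse = ", "))

  which <- GenomicRanges::GRanges(g$seq_id, IRanges::IRanges(g$start, g$end))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("NH", "AS", "XS"), which = which)
  fetched <- Rsamtools::scanBam(bf, param = param)

  rows <- list(); disc <- list(); fasta <- list()
  for (i in seq_len(nrow(g))) {
    locus <- as.list(g[i, ])
    key <- locus_key(g[i, , drop = FALSE])
    res <- locus_observations(fetched[[i]], locus, params)
    tally <- res$tally
    obs <- res$obs
    if (nrow(obs)) {
      hist <- table(obs$count)
      counts <- as.integer(names(hist))
      ord <- order(counts)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = key, seq_id = locus$seq_id, start = locus$start,
        end = locus$end, motif = locus$motif, ssr_type = locus$ssr_type,
        repeat_count = counts[ord], n_reads = as.integer(hist)[ord],
        stringsAsFactors = FALSE)
    }
    disc[[i]] <- data.frame(locus = key, fetched = res$fetched,
                            accepted = nrow(obs),
                            as.list(tally), stringsAsFactors = FALSE)
    if (!is.null(fasta_dir)) fasta[[key]] <- obs
  }

  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "genotype_id") <- genotype_id
  attr(out, "discards") <- do.call(rbind, disc)
  class(out) <- c("repeat_count_table", "data.frame")
  if (!is.null(fasta_dir)) write_locus_fasta(fasta, fasta_dir)
  out
}

empty_count_table <- function(genotype_id) {
  out <- data.frame(locus = character(), seq_id = character(),
                    start = integer(), end = integer(), motif = character(),
                    ssr_type = character(), repeat_count = integer(),
                    n_reads = integer(), stringsAsFactors = FALSE)
  attr(out, "genotype_id") <- genotype_id
  attr(out, "discards") <- cbind(
    data.frame(locus = character(), fetched = integer(), accepted = integer()),
    stats::setNames(as.data.frame(matrix(integer(), 0, length(DISCARD_REASONS))),
                    DISCARD_REASONS))
  class(out) <- c("repeat_count_table", "data.frame")
  out
}

#' Filter one locus's fetched records down to accepted observations
#' @noRd
locus_observations <- function(recs, locus, params) {
  tally <- stats::setNames(integer(length(DISCARD_REASONS)), DISCARD_REASONS)
  n <- length(recs$qname)
  keep <- list()
  for (j in seq_len(n)) {
    flag <- recs$flag[j]
    if (bitwAnd(flag, 0x4L) > 0L || bitwAnd(flag, 0x100L) > 0L ||
        bitwAnd(flag, 0x800L) > 0L || is.na(recs$cigar[j]) ||
        is.na(recs$pos[j])) {
      tally[["unmapped_or_secondary"]] <- tally[["unmapped_or_secondary"]] + 1L
      next
    }
    read <- list(qname = recs$qname[j], flag = flag, pos = recs$pos[j],
                 mapq = recs$mapq[j], cigar = recs$cigar[j],
                 seq = as.character(recs$seq[j]),
                 NH = tag_value(recs, "NH", j), AS = tag_value(recs, "AS", j),
                 XS = tag_value(recs, "XS", j))
    if (is_multimapped(read, params)) {
      tally[["multimapped"]] <- tally[["multimapped"]] + 1L
      next
    }
    verdict <- passes_span_and_flank(read, locus, params)
    if (!verdict$accept) {
      tally[[verdict$reason]] <- tally[[verdict$reason]] + 1L
      next
    }
    keep[[length(keep) + 1L]] <- data.frame(
      qname = read$qname, count = verdict$count, ref_start = read$pos,
      ref_end = read$pos + cigar_ref_len(parse_cigar(read$cigar)) - 1L,
      is_first_mate = bitwAnd(flag, 0x40L) > 0L,
      seq = read$seq, stringsAsFactors = FALSE)
  }
  obs <- if (length(keep)) do.call(rbind, keep) else
    data.frame(qname = character(), count = integer(), ref_start = integer(),
               ref_end = integer(), is_first_mate = logical(),
               seq = character(), stringsAsFactors = FALSE)

  # mate-pair resolution among accepted observations
  if (nrow(obs)) {
    drop <- logical(nrow(obs))
    for (qn in unique(obs$qname[duplicated(obs$qname)])) {
      idx <- which(obs$qname == qn)
      if (length(idx) != 2L) {            # defensive: >2 primary records
        drop[idx] <- TRUE
        tally[["mate_conflict"]] <- tally[["mate_conflict"]] + length(idx)
        next
      }
      res <- resolve_mate_pair(as.list(obs[idx[1L], ]), as.list(obs[idx[2L], ]))
      if (res$action == "keep_one") {
        keep_a <- !(obs$is_first_mate[idx[2L]] && !obs$is_first_mate[idx[1L]])
        drop[if (keep_a) idx[2L] else idx[1L]] <- TRUE
        tally[["mate_duplicate"]] <- tally[["mate_duplicate"]] + 1L
      } else {
        drop[idx] <- TRUE
        tally[["mate_conflict"]] <- tally[["mate_conflict"]] + 2L
      }
    }
    obs <- obs[!drop, , drop = FALSE]
  }
  obs <- obs[order(obs$count, obs$qname), , drop = FALSE]
  list(obs = obs, tally = tally, fetched = n)
}

tag_value <- function(recs, tag, j) {
  v <- recs$tag[[tag]]
  if (is.null(v) || length(v) < j) NA_integer_ else v[j]
}

write_locus_fasta <- function(fasta, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(fasta)) {
    obs <- fasta[[key]]
    file <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", key), ".fasta"))
    lines <- character(0)
    if (nrow(obs))
      lines <- as.vector(rbind(sprintf(">%s repeat_count=%d", obs$qname, obs$count),
                               obs$seq))
    writeLines(lines, file)
  }
  invisible(dir)
}

#' Write / read a per-genotype repeat-count table
#'
#' The 3-column tab-delimited interchange format of the read-retrieval
#' stage: locus key (`"seq_id:start-end(motif)"`), number of repeat units,
#' number of supporting reads.
#'
#' @param x A `repeat_count_table` (or any data frame with `locus`,
#'   `repeat_count`, `n_reads`).
#' @param file Output path (`write_counts`) or input path (`read_counts`).
#' @return `read_counts` returns a data frame with columns `locus`,
#'   `repeat_count`, `n_reads` and a `genotype_id` attribute.
#' @export
write_counts <- function(x, file) {
  df <- data.frame(locus = x$locus, repeat_count = x$repeat_count,
                   n_reads = x$n_reads)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @param genotype_id Genotype identifier to attach; defaults to the file
#'   name without extension.
#' @rdname write_counts
#' @export
read_counts <- function(file, genotype_id = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("locus", "repeat_count", "n_reads")
  if (!all(need %in% names(df)))
    validation_error("'", file, "' is not a 3-column repeat-count table")
  attr(df, "genotype_id") <- genotype_id %||%
    tools::file_path_sans_ext(basename(file))
  df
}

#' Write the per-locus discard summary of a count table
#' @param x A `repeat_count_table`.
#' @param file Output path.
#' @export
write_discards <- function(x, file) {
  utils::write.table(attr(x, "discards"), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @export
print.repeat_count_table <- function(x, ...) {
  d <- attr(x, "discards")
  cat(sprintf("Repeat-count table for genotype '%s': %d loci with accepted reads, %d reads accepted / %d fetched\n",
              attr(x, "genotype_id") %||% "?", length(unique(x$locus)),
              sum(x$n_reads), if (is.null(d)) NA_integer_ else sum(d$fetched)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 12L))
  invisible(x)
}
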