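#' Call SSR alleles from a repeat-count histogram
#'
#' The polymorphism-finding stage's per-locus, per-genotype decision rule,
#' governed by two thresholds: `min_reads` (`t`), the minimum total number
#' of spanning reads for the locus to be analysed at all, and `min_percent`
#' (`p`), the minimum percentage of spanning reads an allele — notably the
#' minor allele of a heterozygote — must reach to be reported.  Both
#' boundaries are inclusive: a locus with exactly `t` reads is analysed, and
#' an allele at exactly `p`% is reported.  Defaults are `t = 10`, `p = 30`,
#' so e.g. a 7:3 split over 10 reads is called heterozygous.  For polyploids
#' `p` can be lowered to admit three or more alleles.  When `p > 50` no bin
#' may qualify; the major allele is then still reported, so a covered locus
#' always yields a call.
#'
#' @param histogram Named integer vector (names are repeat-unit counts,
#'   values supporting-read counts), or a data frame with `repeat_count` and
#'   `n_reads` columns (e.g. rows of a `repeat_count_table`).
#' @param min_reads Threshold `t` (default 10).
#' @param min_percent Threshold `p` in percent (default 30).
#' @return A list of class `allele_call`: `status` (`"called"` or
#'   `"insufficient_coverage"`), `alleles` (repeat counts, support
#'   descending, ties broken toward the larger count), `supports`,
#'   `total_reads`, `zygosity` (`"homozygous"`, `"heterozygous"`,
#'   `"multi-allelic"` or `"n/a"`).
#' @examples
#' call_alleles(c(`6` = 7, `5` = 3))   # heterozygous, alleles 6 and 5
#' call_alleles(c(`8` = 20, `7` = 5))  # homozygous 8: 5/25 = 20% < 30%
#' @export
call_alleles <- function(histogram, min_reads = 10, min_percent = 30) {
  if (min_reads < 1) validation_error("min_reads (t) must be >= 1")
  if (min_percent <= 0 || min_percent > 100)
    validation_error("min_percent (p) must be in (0, 100]")
  if (is.data.frame(histogram)) {
    counts <- as.integer(histogram$repeat_count)
    support <- as.integer(histogram$n_reads)
  } else {
    counts <- as.integer(names(histogram))
    support <- as.integer(histogram)
  }
  if (anyDuplicated(counts))
    validation_error("histogram has duplicate repeat_count bins")
  total <- sum(support)
  if (length(counts) == 0L || total < min_reads) {
    return(structure(list(status = "insufficient_coverage",
                          alleles = integer(0), supports = integer(0),
                          total_reads = as.integer(total), zygosity = "n/a"),
                     class = "allele_call"))
  }
  # inclusive boundary: support/total * 100 >= p, compared in integer space
  sel <- support * 100 >= min_percent * total - 1e-9
  if (!any(sel)) {
    major <- order(-support, -counts)[1L]
    sel <- seq_along(counts) == major
  }
  counts <- counts[sel]; support <- support[sel]
  ord <- order(-support, -counts)
  counts <- counts[ord]; support <- support[ord]
  zyg <- switch(min(length(counts), 3L), "homozygous", "heterozygous",
                "multi-allelic")
  structure(list(status = "called", alleles = counts, supports = support,
                 total_reads = as.integer(total), zygosity = zyg),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  if (x$status == "insufficient_coverage") {
    cat(sprintf("allele call: insufficient coverage (%d reads)\n", x$total_reads))
  } else {
    cat(sprintf("allele call: %s, alleles %s (support %s of %d reads)\n",
                x$zygosity, paste(x$alleles, collapse = "; "),
                paste(x$supports, collapse = "; "), x$total_reads))
  }
  invisible(x)
}

format_allele_call <- function(call) {
  if (call$status != "called") "NA" else paste(call$alleles, collapse = "; ")
}

#' Join per-genotype count tables and flag polymorphic loci
#'
#' Performs a full outer join of the per-genotype repeat-count tables over
#' all genotypable catalog loci (the in-memory equivalent of the relational
#' join of the comparative stage), calls alleles per locus and genotype with
#' [call_alleles()], and classifies each locus: `polymorphic` when at least
#' two genotypes are called and their allele sets differ, `monomorphic` when
#' at least two are called and all sets agree, `not_comparable` otherwise.
#' Insufficient coverage is encoded as `"NA"` rather than a dropped row, so
#' the output has one row per catalog locus.  Loci present in a count table
#' but absent from the catalog are retained with `ssr_type` `"unknown"`
#' under a warning.
#'
#' @param tables Named list (names = unique genotype ids) of
#'   `repeat_count_table`s or data frames read with [read_counts()].  At
#'   least two genotypes are required.
#' @param catalog An [ssr_catalog()].
#' @param min_reads,min_percent Thresholds passed to [call_alleles()].
#' @return A data frame of class `ssr_poly_table`: `locus`, `ssr_type`, one
#'   allele-string column per genotype (major allele first, e.g. `"6; 5"`),
#'   `verdict`.  Rows follow catalog order; columns follow genotype input
#'   order.
#' @export
join_genotypes <- function(tables, catalog, min_reads = 10, min_percent = 30) {
  ids <- names(tables)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(seq_along(tables), function(i)
      attr(tables[[i]], "genotype_id") %||% "", character(1))
  if (any(!nzchar(ids)))
    validation_error("every count table needs a genotype id (name the list)")
  if (anyDuplicated(ids))
    validation_error("duplicate genotype id: ", ids[duplicated(ids)][1L])
  if (length(tables) < 2L)
    validation_error("comparison requires at least two genotypes")

  keys <- locus_key(catalog)
  types <- catalog$ssr_type
  genotypable <- catalog$genotypable

  extra <- setdiff(unique(unlist(lapply(tables, function(t) t$locus))), keys)
  if (length(extra)) {
    warning("loci absent from the catalog retained with ssr_type 'unknown': ",
            paste(extra, collapse = ", "))
    keys <- c(keys, extra)
    types <- c(types, rep("unknown", length(extra)))
    genotypable <- c(genotypable, rep(TRUE, length(extra)))
  }

  cells <- matrix("NA", nrow = length(keys), ncol = length(ids),
                  dimnames = list(NULL, ids))
  verdict <- rep("not_comparable", length(keys))
  for (r in seq_along(keys)) {
    if (!genotypable[r]) next
    sets <- list()
    for (gi in seq_along(ids)) {
      t <- tables[[gi]]
      sub <- t[t$locus == keys[r], , drop = FALSE]
      call <- call_alleles(sub[, c("repeat_count", "n_reads")],
                           min_reads = min_reads, min_percent = min_percent)
      cells[r, gi] <- format_allele_call(call)
      if (call$status == "called")
        sets[[length(sets) + 1L]] <- sort(call$alleles)
    }
    if (length(sets) >= 2L) {
      same <- all(vapply(sets[-1L], identical, logical(1), y = sets[[1L]]))
      verdict[r] <- if (same) "monomorphic" else "polymorphic"
    }
  }
  out <- data.frame(locus = keys, ssr_type = types, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (gi in seq_along(ids)) out[[ids[gi]]] <- cells[, gi]
  out$verdict <- verdict
  attr(out, "genotypes") <- ids
  attr(out, "params") <- list(min_reads = min_reads, min_percent = min_percent)
  class(out) <- c("ssr_poly_table", "data.frame")
  out
}

#' Write / read the final polymorphism table
#'
#' Tab-delimited: locus key, SSR type, one allele-string column per
#' genotype, verdict.  `read_calls_table(write_calls_table(x))` recovers the
#' allele strings.
#'
#' @param x An `ssr_poly_table` from [join_genotypes()].
#' @param file Output path, or `NULL` to return the lines.
#' @return `write_calls_table`: the lines (invisibly when written);
#'   `read_calls_table`: the table as a data frame.
#' @export
write_calls_table <- function(x, file = NULL) {
  header <- paste(c("locus", "ssr_type", attr(x, "genotypes"), "verdict"),
                  collapse = "\t")
  rows <- apply(as.data.frame(x), 1L, paste, collapse = "\t")
  lines <- c(header, unname(rows))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' @rdname write_calls_table
#' @export
read_calls_table <- function(file) {
  if (is.character(file) && length(file) > 1L) {
    con <- textConnection(file)
    on.exit(close(con))
    df <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = character(0))
  } else {
    df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = character(0))
  }
  df[] <- lapply(df, as.character)
  attr(df, "genotypes") <- setdiff(names(df), c("locus", "ssr_type", "verdict"))
  class(df) <- c("ssr_poly_table", "data.frame")
  df
}

#' @export
print.ssr_poly_table <- function(x, ...) {
  cat(sprintf("SSR polymorphism table: %d loci x %d genotypes (t >= %s, p >= %s%%)\n",
              nrow(x), length(attr(x, "genotypes")),
              attr(x, "params")$min_reads %||% "?",
              attr(x, "params")$min_percent %||% "?"))
  print.data.frame(head(as.data.frame(x), 15L))
  if (nrow(x) > 15L) cat(sprintf("... and %d more loci\n", nrow(x) - 15L))
  invisible(x)
}

#' @method summary ssr_poly_table
#' @export
summary.ssr_poly_table <- function(object, ...) {
  tab <- table(factor(object$verdict,
                      levels = c("polymorphic", "monomorphic", "not_comparable")))
  cat("Verdicts:\n")
  print(tab)
  invisible(tab)
}
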