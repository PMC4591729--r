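#' Construct an SSR catalog
#'
#' An `ssr_catalog` is a data frame of microsatellite loci, one row per
#' locus, keyed by `(seq_id, start)` and sorted by reference then position.
#' Coordinates are 1-based inclusive, the convention of MISA-like tables
#' (`end - start + 1 == length_nt`).  Perfect loci of type `p1`..`p6` are
#' genotypable; compound loci (type starting with `c`) are retained so that
#' output row counts match the input catalog, but flagged non-genotypable.
#'
#' @param loci A data frame with columns `seq_id`, `ssr_type`, `start`,
#'   `end`, and either `motif` + `repeat_count` (perfect loci) or `ssr`
#'   (the raw SSR descriptor, required for compound loci).  Optional:
#'   `ssr_index`, `length_nt`.
#' @return A data frame of class `ssr_catalog` with columns `seq_id`,
#'   `ssr_index`, `ssr_type`, `ssr`, `motif`, `repeat_count`, `length_nt`,
#'   `start`, `end`, `genotypable`.
#' @seealso [read_misa()], [write_misa()], [find_perfect_ssrs()]
#' @export
ssr_catalog <- function(loci) {
  if (is.null(loci) || nrow(loci) == 0L) {
    out <- data.frame(seq_id = character(), ssr_index = integer(),
                      ssr_type = character(), ssr = character(),
                      motif = character(), repeat_count = integer(),
                      length_nt = integer(), start = integer(), end = integer(),
                      genotypable = logical(), stringsAsFactors = FALSE)
    class(out) <- c("ssr_catalog", "data.frame")
    return(out)
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("seq_id", "ssr_type", "start", "end")
  miss <- setdiff(need, names(loci))
  if (length(miss))
    validation_error("catalog is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(loci$motif)) loci$motif <- NA_character_
  if (is.null(loci$repeat_count)) loci$repeat_count <- NA_integer_
  loci$start <- as.integer(loci$start)
  loci$end <- as.integer(loci$end)
  loci$repeat_count <- as.integer(loci$repeat_count)
  if (is.null(loci$length_nt)) loci$length_nt <- loci$end - loci$start + 1L
  loci$length_nt <- as.integer(loci$length_nt)

  perfect <- grepl("^p[1-6]$", loci$ssr_type)
  if (is.null(loci$ssr)) loci$ssr <- NA_character_
  loci$ssr <- ifelse(perfect & !is.na(loci$motif),
                     sprintf("(%s)%d", loci$motif, loci$repeat_count),
                     loci$ssr)

  for (i in seq_len(nrow(loci))) {
    row_id <- sprintf("row %d (%s:%d)", i, loci$seq_id[i], loci$start[i])
    if (is.na(loci$start[i]) || loci$start[i] < 1L)
      validation_error(row_id, ": start must be >= 1")
    if (loci$length_nt[i] != loci$end[i] - loci$start[i] + 1L)
      validation_error(row_id, ": length ", loci$length_nt[i],
                       " != end - start + 1 = ", loci$end[i] - loci$start[i] + 1L)
    if (perfect[i]) {
      m <- loci$motif[i]
      if (is.na(m) || !grepl("^[ACGT]{1,6}$", m))
        validation_error(row_id, ": motif '", m, "' is not a 1-6 nt A/C/G/T string")
      if (is.na(loci$repeat_count[i]) || loci$repeat_count[i] < 1L)
        validation_error(row_id, ": repeat_count must be >= 1")
      if (loci$length_nt[i] != nchar(m) * loci$repeat_count[i])
        validation_error(row_id, ": length ", loci$length_nt[i],
                         " != motif length x repeat count")
    }
  }
  key <- paste(loci$seq_id, loci$start)
  if (anyDuplicated(key))
    validation_error("duplicate (seq_id, start) key: ", key[duplicated(key)][1L])

  ord <- order(loci$seq_id, loci$start)
  loci <- loci[ord, , drop = FALSE]
  if (is.null(loci$ssr_index)) loci$ssr_index <- NA_integer_
  loci$ssr_index <- as.integer(loci$ssr_index)
  if (anyNA(loci$ssr_index))
    loci$ssr_index <- stats::ave(seq_len(nrow(loci)), loci$seq_id,
                                 FUN = seq_along)
  loci$genotypable <- perfect[ord]
  out <- loci[, c("seq_id", "ssr_index", "ssr_type", "ssr", "motif",
                  "repeat_count", "length_nt", "start", "end", "genotypable")]
  rownames(out) <- NULL
  class(out) <- c("ssr_catalog", "data.frame")
  out
}

#' Locus keys for catalog rows
#'
#' The canonical locus identifier used throughout the package:
#' `"seq_id:start-end(motif)"`.
#' @param x An `ssr_catalog` or any data frame with `seq_id`, `start`,
#'   `end`, `motif` columns.
#' @return Character vector of keys, one per row.
#' @export
locus_key <- function(x) {
  motif <- ifelse(is.na(x$motif), x$ssr_type, x$motif)
  sprintf("%s:%d-%d(%s)", x$seq_id, x$start, x$end, motif)
}

#' Read a MISA-like SSR table
#'
#' Parses the 7-column tab-delimited dialect of MISA output: sequence ID,
#' SSR number, SSR type (`p1`..`p6` for perfect, `c`/`c*` for compound),
#' SSR descriptor such as `"(GAT)6"`, size in nt, start, end (1-based
#' inclusive).  A single header line is tolerated.  Rows whose size does not
#' equal `end - start + 1`, or whose motif contains non-A/C/G/T characters,
#' raise a validation error naming the offending line.
#'
#' @param file Path to a file, or a character vector of lines.
#' @return An [ssr_catalog()].
#' @examples
#' cat <- read_misa(c("TR11073\t1\tp3\t(GAT)6\t18\t389\t406"))
#' cat$motif        # "GAT"
#' cat$repeat_count # 6
#' @export
read_misa <- function(file) {
  lines <- misa_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(ssr_catalog(NULL))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1L]]
  has_header <- length(first) >= 7L &&
    (is.na(suppressWarnings(as.integer(first[[6L]]))) ||
     is.na(suppressWarnings(as.integer(first[[7L]]))))
  if (has_header) {
    fields <- fields[-1L]
    lines <- lines[-1L]
  }
  if (!length(fields)) return(ssr_catalog(NULL))

  n <- length(fields)
  seq_id <- character(n); ssr_index <- integer(n); ssr_type <- character(n)
  ssr <- character(n); motif <- character(n); repeat_count <- integer(n)
  size <- integer(n); start <- integer(n); end <- integer(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    lineno <- i + as.integer(has_header)
    if (length(f) < 7L)
      validation_error("line ", lineno, ": expected >= 7 tab-separated columns, got ",
                       length(f))
    seq_id[i] <- f[[1L]]
    ssr_index[i] <- suppressWarnings(as.integer(f[[2L]]))
    ssr_type[i] <- f[[3L]]
    ssr[i] <- f[[4L]]
    size[i] <- parse_misa_int(f[[5L]], lineno, "size")
    start[i] <- parse_misa_int(f[[6L]], lineno, "start")
    end[i] <- parse_misa_int(f[[7L]], lineno, "end")
    if (grepl("^p[1-6]$", ssr_type[i])) {
      m <- regmatches(ssr[i], regexec("^\\(([A-Za-z]+)\\)([0-9]+)$", ssr[i]))[[1L]]
      if (length(m) != 3L)
        validation_error("line ", lineno, ": cannot parse SSR descriptor '",
                         ssr[i], "'")
      if (!grepl("^[ACGT]+$", m[[2L]]))
        validation_error("line ", lineno, ": motif '", m[[2L]],
                         "' contains non-ACGT characters")
      motif[i] <- m[[2L]]
      repeat_count[i] <- as.integer(m[[3L]])
    } else {
      motif[i] <- NA_character_
      repeat_count[i] <- NA_integer_
    }
    if (size[i] != end[i] - start[i] + 1L)
      validation_error("line ", lineno, ": size ", size[i],
                       " != end - start + 1 = ", end[i] - start[i] + 1L)
  }
  ssr_catalog(data.frame(seq_id = seq_id, ssr_index = ssr_index,
                         ssr_type = ssr_type, ssr = ssr, motif = motif,
                         repeat_count = repeat_count, length_nt = size,
                         start = start, end = end, stringsAsFactors = FALSE))
}

misa_lines <- function(file) {
  if (is.character(file) && length(file) == 1L && !grepl("\t|\n", file)) {
    if (!file.exists(file)) validation_error("cannot read '", file, "': no such file")
    return(readLines(file, warn = FALSE))
  }
  unlist(strsplit(as.character(file), "\n", fixed = TRUE))
}

parse_misa_int <- function(x, lineno, what) {
  v <- suppressWarnings(as.integer(x))
  if (is.na(v))
    validation_error("line ", lineno, ": ", what, " '", x, "' is not an integer")
  v
}

#' Write a MISA-like SSR table
#'
#' Emits the same 7-column dialect accepted by [read_misa()], preceded by a
#' header line, in catalog order.  `read_misa(write_misa(x))` reproduces `x`.
#'
#' @param catalog An [ssr_catalog()].
#' @param file Output path, or `NULL` to return the lines visibly.
#' @return The lines (invisibly when written to a file).
#' @export
write_misa <- function(catalog, file = NULL) {
  header <- paste("ID", "SSR nr.", "SSR type", "SSR", "size", "start", "end",
                  sep = "\t")
  rows <- character(0)
  if (nrow(catalog) > 0L)
    rows <- sprintf("%s\t%d\t%s\t%s\t%d\t%d\t%d",
                    catalog$seq_id, catalog$ssr_index, catalog$ssr_type,
                    catalog$ssr, catalog$length_nt, catalog$start, catalog$end)
  lines <- c(header, rows)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' @export
print.ssr_catalog <- function(x, ...) {
  cat(sprintf("SSR catalog: %d loci (%d genotypable) on %d reference sequence(s)\n",
              nrow(x), sum(x$genotypable), length(unique(x$seq_id))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more loci\n", nrow(x) - 10L))
  invisible(x)
}
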