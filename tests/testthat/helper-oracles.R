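# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: SSR detection compares whole units left to right, repeat
# counting enumerates all tandem windows, and projection expands the
# alignment base by base.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

rotations_of <- function(motif) {
  k <- nchar(motif)
  unique(substring(strrep(motif, 2L), seq_len(k), seq_len(k) + k - 1L))
}

primitive_motif <- function(motif) {
  k <- nchar(motif)
  divs <- seq_len(max(k - 1L, 0L))
  divs <- divs[k %% divs == 0L]
  !any(vapply(divs, function(d) strrep(substr(motif, 1, d), k / d) == motif,
              logical(1)))
}

# enumerate maximal perfect runs by direct unit comparison at every start
oracle_find_ssrs <- function(seq, min_repeats = c(10, 6, 5, 5, 5, 5),
                             seq_id = "seq1") {
  s <- toupper(seq)
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hits <- list()
  for (k in 1:6) {
    for (i in seq_len(max(n - k * min_repeats[k] + 1L, 0L))) {
      motif <- substr(s, i, i + k - 1L)
      if (!grepl("^[ACGT]+$", motif) || !primitive_motif(motif)) next
      # leftmost: the preceding base must not continue the period
      if (i > 1L && ch[i - 1L] == ch[i + k - 1L] &&
          ch[i - 1L] %in% c("A", "C", "G", "T")) next
      cnt <- 1L
      while (i + (cnt + 1L) * k - 1L <= n &&
             substr(s, i + cnt * k, i + (cnt + 1L) * k - 1L) == motif)
        cnt <- cnt + 1L
      if (cnt < min_repeats[k]) next
      hits[[length(hits) + 1L]] <- data.frame(
        seq_id = seq_id, motif = motif, repeat_count = cnt, start = i,
        end = i + cnt * k - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(seq_id = character(), motif = character(),
                      repeat_count = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, hits)
  df <- df[order(df$start, nchar(df$motif)), , drop = FALSE]
  df <- df[!duplicated(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# largest c over all whole-unit windows [i, i + c*k - 1] covering the anchor
oracle_count_units <- function(seq, anchor, motif) {
  s <- toupper(seq)
  n <- nchar(s)
  k <- nchar(motif)
  rots <- rotations_of(toupper(motif))
  best <- 0L
  for (i in seq_len(anchor)) {
    max_c <- (n - i + 1L) %/% k
    if (max_c < 1L) next
    for (r in rots) {
      big <- strrep(r, max_c)
      c <- 0L
      while (c < max_c && substr(s, i + c * k, i + (c + 1L) * k - 1L) ==
             substr(big, c * k + 1L, (c + 1L) * k)) c <- c + 1L
      if (c >= 1L && i + c * k - 1L >= anchor) best <- max(best, c)
    }
  }
  best
}

# per-base expansion of the alignment; returns 1-based inclusive read
# interval, NULL when not covered
oracle_project <- function(cigar, pos, start, end) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  op <- substr(toks, nchar(toks), nchar(toks))
  len <- as.integer(substr(toks, 1, nchar(toks) - 1))
  refpos <- integer(0); type <- character(0); qidx <- integer(0)
  r <- pos; q <- 1L
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      refpos <- c(refpos, r:(r + len[i] - 1L))
      type <- c(type, rep("M", len[i]))
      qidx <- c(qidx, q:(q + len[i] - 1L))
      r <- r + len[i]; q <- q + len[i]
    } else if (op[i] == "D") {
      refpos <- c(refpos, r:(r + len[i] - 1L))
      type <- c(type, rep("D", len[i]))
      qidx <- c(qidx, rep(q, len[i]))
      r <- r + len[i]
    } else if (op[i] == "N") {
      refpos <- c(refpos, r:(r + len[i] - 1L))
      type <- c(type, rep("N", len[i]))
      qidx <- c(qidx, rep(NA_integer_, len[i]))
      r <- r + len[i]
    } else if (op[i] %in% c("I", "S")) {
      q <- q + len[i]
    }
  }
  want <- start:end
  hit <- match(want, refpos)
  if (anyNA(hit)) return(NULL)
  if (any(type[hit] == "N")) return(NULL)
  first <- hit[1]; last <- hit[length(hit)]
  qa <- qidx[first]
  qb <- if (type[last] == "M") qidx[last] else qidx[last] - 1L
  c(qa, qb)
}

expect_same_loci <- function(found, expected) {
  cols <- c("motif", "repeat_count", "start", "end")
  expect_equal(as.data.frame(found)[, cols],
               as.data.frame(expected)[, cols],
               ignore_attr = TRUE)
}
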