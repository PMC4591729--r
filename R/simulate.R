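#' Simulation parameters for read generation
#'
#' @param read_len Read length in nt (>= 20).
#' @param coverage Fold coverage (per reference base) for the random and
#'   paired modes; ignored when `tiling = TRUE`.
#' @param error_rate Per-base substitution probability in `[0, 0.1)`.
#' @param paired Emit proper mate pairs instead of single-end reads.
#' @param fragment_mean,fragment_sd Fragment length distribution (nt) for
#'   paired mode.
#' @param tiling Deterministic mode: one read starting at every haplotype
#'   position (coverage equals the read length), with haplotypes assigned by
#'   a balanced low-discrepancy cycle over the allele fractions so any
#'   window of start positions realises the planted fractions to within one
#'   read.  Used for exact-recovery and boundary experiments.
#' @param seed Integer seed; every stochastic choice derives from it.
#' @return A list of class `ssr_sim_config`.
#' @export
sim_config <- function(read_len = 100L, coverage = 30, error_rate = 0,
                       paired = FALSE, fragment_mean = 300, fragment_sd = 30,
                       tiling = FALSE, seed = 1L) {
  if (read_len < 20L) validation_error("read_len must be >= 20")
  if (coverage <= 0) validation_error("coverage must be > 0")
  if (error_rate < 0 || error_rate >= 0.1)
    validation_error("error_rate must be in [0, 0.1)")
  structure(list(read_len = as.integer(read_len), coverage = coverage,
                 error_rate = error_rate, paired = isTRUE(paired),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 tiling = isTRUE(tiling), seed = as.integer(seed)),
            class = "ssr_sim_config")
}

#' Evaluate code under a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulate reference sequences with planted perfect SSRs
#'
#' Builds one or more reference sequences carrying perfect repeat runs at
#' known positions, surrounded by repeat-free random background, and returns
#' them together with the truth catalog.  Background is rejection-sampled:
#' the bases adjacent to each run are chosen to break the repeat phase, and
#' a candidate sequence is kept only when [find_perfect_ssrs()] recovers
#' exactly the planted catalog, so no accidental repeat abuts or shadows a
#' planted locus.  Deterministic under `seed`.
#'
#' @param loci Data frame with columns `motif` and `repeat_count`, one row
#'   per planted locus; optional `seq_id` groups several loci onto one
#'   sequence (default: one sequence per locus, named `SEQ1`, ...).  Loci
#'   sharing a sequence are placed in row order, separated by `margin` nt.
#' @param margin Non-repeat margin (nt) before, between and after loci; keep
#'   it at or above the read length so every read spans at most one locus.
#' @param seed Integer seed.
#' @param min_repeats Detection thresholds used for the truth cross-check,
#'   as in [find_perfect_ssrs()].  Planted counts below the threshold for
#'   their motif length are infeasible and raise an error.
#' @return A list of class `ssr_reference`: `sequences` (named character),
#'   `catalog` (the truth [ssr_catalog()]).
#' @export
simulate_reference <- function(loci, margin = 110L, seed = 1L,
                               min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (!all(c("motif", "repeat_count") %in% names(loci)))
    validation_error("loci needs 'motif' and 'repeat_count' columns")
  if (is.null(loci$seq_id)) loci$seq_id <- paste0("SEQ", seq_len(nrow(loci)))
  loci$repeat_count <- as.integer(loci$repeat_count)
  if (margin < 10L) validation_error("margin must be >= 10")
  for (i in seq_len(nrow(loci))) {
    m <- toupper(loci$motif[i]); k <- nchar(m)
    if (!grepl("^[ACGT]{1,6}$", m) || !is_primitive_motif(m))
      validation_error("locus ", i, ": motif '", m,
                       "' must be a primitive 1-6 nt A/C/G/T motif")
    if (loci$repeat_count[i] < min_repeats[k])
      validation_error("locus ", i, ": infeasible placement - repeat_count ",
                       loci$repeat_count[i], " is below the detection minimum ",
                       min_repeats[k], " for ", k, "-nt motifs")
    loci$motif[i] <- m
  }

  with_seed(seed, {
    seq_ids <- unique(loci$seq_id)
    sequences <- character(0)
    truth <- list()
    for (sid in seq_ids) {
      rows <- loci[loci$seq_id == sid, , drop = FALSE]
      lens <- nchar(rows$motif) * rows$repeat_count
      starts <- integer(nrow(rows))
      cur <- as.integer(margin) + 1L
      for (i in seq_len(nrow(rows))) {
        starts[i] <- cur
        cur <- cur + as.integer(lens[i]) + as.integer(margin)
      }
      total_len <- cur - 1L
      truth_rows <- data.frame(seq_id = sid, ssr_type = paste0("p", nchar(rows$motif)),
                               motif = rows$motif, repeat_count = rows$repeat_count,
                               start = starts, end = starts + lens - 1L,
                               stringsAsFactors = FALSE)
      truth[[sid]] <- truth_rows
      sequences[[sid]] <- build_background(truth_rows, total_len, min_repeats)
    }
    catalog <- ssr_catalog(do.call(rbind, truth))
    check <- find_perfect_ssrs(sequences, min_repeats)
    if (!identical(as.data.frame(check)[, c("seq_id", "motif", "repeat_count", "start", "end")],
                   as.data.frame(catalog)[, c("seq_id", "motif", "repeat_count", "start", "end")]))
      stop("internal error: truth catalog not recovered from simulated reference")
    structure(list(sequences = sequences, catalog = catalog),
              class = "ssr_reference")
  })
}

#' Rejection-sample one background sequence around planted runs
#' @noRd
build_background <- function(truth_rows, total_len, min_repeats) {
  runs <- strrep(truth_rows$motif, truth_rows$repeat_count)
  for (attempt in 1:200) {
    ch <- sample(DNA_BASES, total_len, replace = TRUE)
    for (i in seq_len(nrow(truth_rows))) {
      s <- truth_rows$start[i]; e <- truth_rows$end[i]
      m <- truth_rows$motif[i]; k <- nchar(m)
      ch[s:e] <- strsplit(runs[i], "", fixed = TRUE)[[1L]]
      # phase-breaking neighbours: left must not extend the period, right
      # must not start another unit
      last <- substr(m, k, k); first <- substr(m, 1L, 1L)
      ch[s - 1L] <- sample(setdiff(DNA_BASES, last), 1L)
      ch[e + 1L] <- sample(setdiff(DNA_BASES, first), 1L)
    }
    seqc <- paste(ch, collapse = "")
    found <- find_perfect_ssrs(stats::setNames(seqc, truth_rows$seq_id[1L]),
                               min_repeats)
    ok <- nrow(found) == nrow(truth_rows) &&
      identical(found$start, truth_rows$start) &&
      identical(found$end, truth_rows$end) &&
      identical(found$motif, truth_rows$motif)
    if (ok) return(seqc)
  }
  stop("could not build a repeat-free background after 200 attempts")
}

#' Write simulated reference sequences as FASTA
#' @param reference An `ssr_reference` from [simulate_reference()].
#' @param file Output FASTA path.
#' @export
write_reference_fasta <- function(reference, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference$sequences), file)
  invisible(file)
}

#' Simulate one genotype's aligned reads over a simulated reference
#'
#' Draws reads from genotype haplotypes (the reference with each planted run
#' replaced by the allele's run) and emits them as a coordinate-sorted SAM
#' file with CIGAR strings encoding the allele length difference as a single
#' insertion or deletion left-aligned at the run's left edge, the SAM
#' convention for repeat indels.  Per-base substitution errors are applied
#' after CIGAR assignment.  Alleles longer than
#' [max_detectable_ssr_length()] allows are accepted but flagged: they yield
#' zero spanning reads by construction.
#'
#' @param reference An `ssr_reference` from [simulate_reference()].
#' @param alleles Allele sets per locus, in truth-catalog row order: a
#'   numeric vector (one homozygous allele per locus), or a list with one
#'   element per locus, each either a numeric vector of repeat counts
#'   (equal fractions) or `list(counts =, fractions =)`.  All loci on the
#'   same sequence must have the same number of haplotypes and fractions.
#' @param config A [sim_config()].
#' @param genotype_id Genotype label used in read names.
#' @param sam Output SAM path (default: a temp file).
#' @param fastq Optional FASTQ path for the raw reads.
#' @return A list of class `ssr_sim_reads`: `sam`, `n_reads`, `truth`
#'   (normalised allele sets keyed by locus), `flagged` (locus keys whose
#'   allele exceeds the detectability limit).
#' @export
simulate_genotype_reads <- function(reference, alleles, config = sim_config(),
                                    genotype_id = "G1", sam = NULL,
                                    fastq = NULL) {
  catalog <- reference$catalog
  truth <- normalize_alleles(alleles, catalog)
  L <- config$read_len
  sam <- sam %||% tempfile(fileext = ".sam")

  flagged <- character(0)
  for (i in seq_len(nrow(catalog))) {
    k <- nchar(catalog$motif[i])
    if (any(truth[[i]]$counts * k > max_detectable_ssr_length(L, k)))
      flagged <- c(flagged, locus_key(catalog[i, , drop = FALSE]))
  }

  records <- with_seed(config$seed, {
    recs <- list()
    for (sid in names(reference$sequences)) {
      refseq <- reference$sequences[[sid]]
      rows_idx <- which(catalog$seq_id == sid)
      hap <- build_haplotypes(refseq, catalog[rows_idx, , drop = FALSE],
                              truth[rows_idx])
      recs[[sid]] <- emit_reads(hap, sid, nchar(refseq), config, genotype_id)
    }
    do.call(rbind, recs)
  })
  if (is.null(records)) records <- empty_sam_records()
  ord <- order(match(records$rname, names(reference$sequences)), records$pos,
               records$qname)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL

  targets <- stats::setNames(nchar(reference$sequences), names(reference$sequences))
  write_sam(records, targets, sam)
  if (!is.null(fastq)) write_sim_fastq(records, fastq)
  structure(list(sam = sam, n_reads = nrow(records), truth = truth,
                 flagged = flagged, genotype_id = genotype_id,
                 records = records),
            class = "ssr_sim_reads")
}

normalize_alleles <- function(alleles, catalog) {
  n <- nrow(catalog)
  if (is.numeric(alleles)) alleles <- as.list(alleles)
  if (!is.list(alleles) || length(alleles) != n)
    validation_error("alleles must give one allele set per catalog locus (", n, ")")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- alleles[[i]]
    if (is.numeric(a)) a <- list(counts = a, fractions = rep(1 / length(a), length(a)))
    if (!all(c("counts", "fractions") %in% names(a)) ||
        length(a$counts) != length(a$fractions))
      validation_error("allele set ", i, ": need matching counts and fractions")
    if (any(a$counts < 1L))
      validation_error("allele set ", i, ": repeat counts must be >= 1")
    if (abs(sum(a$fractions) - 1) > 1e-6)
      validation_error("allele set ", i, ": fractions must sum to 1")
    out[[i]] <- list(counts = as.integer(a$counts), fractions = a$fractions)
  }
  names(out) <- locus_key(catalog)
  # all loci on one sequence share the haplotype structure
  for (sid in unique(catalog$seq_id)) {
    idx <- which(catalog$seq_id == sid)
    H <- vapply(out[idx], function(x) length(x$counts), integer(1))
    if (length(unique(H)) != 1L)
      validation_error("loci on '", sid, "' must have the same number of alleles")
    fr <- lapply(out[idx], `[[`, "fractions")
    if (!all(vapply(fr[-1], function(f) isTRUE(all.equal(f, fr[[1L]])), logical(1))))
      validation_error("loci on '", sid, "' must share allele fractions")
  }
  out
}

#' Build haplotype sequences and haplotype->reference alignment chains
#'
#' A chain is a data frame of ops: M consumes haplotype and reference, I
#' haplotype only, D reference only.  Indels sit at the run's left edge.
#' @noRd
build_haplotypes <- function(refseq, loci, truth) {
  H <- length(truth[[1L]]$counts)
  fractions <- truth[[1L]]$fractions
  haps <- vector("list", H)
  for (h in seq_len(H)) {
    pieces <- character(0); ops <- character(0); lens <- integer(0)
    cur <- 1L
    for (i in seq_len(nrow(loci))) {
      s <- loci$start[i]; e <- loci$end[i]
      k <- nchar(loci$motif[i]); c_ref <- loci$repeat_count[i]
      c_a <- truth[[i]]$counts[h]
      pre <- s - cur
      if (pre > 0L) {
        pieces <- c(pieces, substr(refseq, cur, s - 1L))
        ops <- c(ops, "M"); lens <- c(lens, pre)
      }
      run <- substr(strrep(loci$motif[i], c_a), 1L, c_a * k)
      pieces <- c(pieces, run)
      if (c_a > c_ref) {
        ops <- c(ops, "I", "M"); lens <- c(lens, (c_a - c_ref) * k, c_ref * k)
      } else if (c_a < c_ref) {
        ops <- c(ops, "D", "M"); lens <- c(lens, (c_ref - c_a) * k, c_a * k)
      } else {
        ops <- c(ops, "M"); lens <- c(lens, c_ref * k)
      }
      cur <- e + 1L
    }
    if (cur <= nchar(refseq)) {
      pieces <- c(pieces, substr(refseq, cur, nchar(refseq)))
      ops <- c(ops, "M"); lens <- c(lens, nchar(refseq) - cur + 1L)
    }
    chain <- merge_chain(ops, lens)
    haps[[h]] <- list(seq = paste(pieces, collapse = ""), chain = chain)
  }
  list(haps = haps, fractions = fractions)
}

merge_chain <- function(ops, lens) {
  keep_op <- character(0); keep_len <- integer(0)
  for (i in seq_along(ops)) {
    if (length(keep_op) && keep_op[length(keep_op)] == ops[i]) {
      keep_len[length(keep_len)] <- keep_len[length(keep_len)] + lens[i]
    } else {
      keep_op <- c(keep_op, ops[i]); keep_len <- c(keep_len, lens[i])
    }
  }
  data.frame(op = keep_op, len = keep_len, stringsAsFactors = FALSE)
}

#' CIGAR and POS of a read covering haplotype interval [s0, s0+L-1]
#' @noRd
chain_read_alignment <- function(chain, s0, L) {
  hc <- 0L; rc <- 0L
  pos <- NA_integer_
  ops <- character(0); lens <- integer(0)
  lo <- s0; hi <- s0 + L - 1L
  for (i in seq_len(nrow(chain))) {
    op <- chain$op[i]; l <- chain$len[i]
    if (op == "M" || op == "I") {
      a <- max(hc + 1L, lo); b <- min(hc + l, hi)
      if (b >= a) {
        if (op == "M" && is.na(pos)) pos <- rc + (a - hc)
        ops <- c(ops, op); lens <- c(lens, b - a + 1L)
      }
      hc <- hc + l
      if (op == "M") rc <- rc + l
    } else {                            # D: between hap bases hc and hc+1
      if (hc >= lo && hc <= hi - 1L) {
        ops <- c(ops, "D"); lens <- c(lens, l)
      }
      rc <- rc + l
    }
    if (hc >= hi) break
  }
  if (is.na(pos)) return(NULL)
  # clips: leading/trailing insertions have no reference anchor
  if (length(ops) && ops[1L] == "I") ops[1L] <- "S"
  if (length(ops) && ops[length(ops)] == "I") ops[length(ops)] <- "S"
  # drop flanking deletions (they only shift the mapping position)
  while (length(ops) && ops[1L] == "D") {
    pos <- pos  # pos already anchored at first M
    ops <- ops[-1L]; lens <- lens[-1L]
  }
  while (length(ops) && ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  m <- merge_chain(ops, lens)
  list(pos = pos, cigar = paste0(m$len, m$op, collapse = ""))
}

#' Balanced low-discrepancy haplotype assignment
#' @noRd
haplotype_cycle <- function(fractions, n) {
  H <- length(fractions)
  cnt <- numeric(H)
  out <- integer(n)
  for (m in seq_len(n)) {
    deficit <- fractions * m - cnt
    h <- which.max(deficit)
    cnt[h] <- cnt[h] + 1
    out[m] <- h
  }
  out
}

apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < error_rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

emit_reads <- function(hap, sid, ref_len, config, genotype_id) {
  L <- config$read_len
  haps <- hap$haps; fractions <- hap$fractions
  hap_lens <- vapply(haps, function(h) nchar(h$seq), integer(1))
  recs <- list()
  add <- function(qname, flag, pos, cigar, seq, rnext = "*", pnext = 0L, tlen = 0L) {
    recs[[length(recs) + 1L]] <<- data.frame(
      qname = qname, flag = flag, rname = sid, pos = pos, mapq = 42L,
      cigar = cigar, rnext = rnext, pnext = pnext, tlen = tlen, seq = seq,
      stringsAsFactors = FALSE)
  }
  single <- function(h, s0, qname) {
    if (s0 < 1L || s0 + L - 1L > hap_lens[h]) return(invisible(NULL))
    aln <- chain_read_alignment(haps[[h]]$chain, s0, L)
    if (is.null(aln)) return(invisible(NULL))
    seq <- apply_errors(substr(haps[[h]]$seq, s0, s0 + L - 1L), config$error_rate)
    add(qname, 0L, aln$pos, aln$cigar, seq)
  }

  if (config$tiling) {
    n_pos <- max(hap_lens) - L + 1L
    if (n_pos < 1L) validation_error("read_len exceeds haplotype length")
    hs <- haplotype_cycle(fractions, n_pos)
    for (p in seq_len(n_pos))
      single(hs[p], p, sprintf("%s_%s_t%06d", genotype_id, sid, p))
  } else if (!config$paired) {
    n_reads <- max(1L, as.integer(round(config$coverage * ref_len / L)))
    for (r in seq_len(n_reads)) {
      h <- sample.int(length(haps), 1L, prob = fractions)
      if (hap_lens[h] < L) next
      s0 <- sample.int(hap_lens[h] - L + 1L, 1L)
      single(h, s0, sprintf("%s_%s_r%06d", genotype_id, sid, r))
    }
  } else {
    n_pairs <- max(1L, as.integer(round(config$coverage * ref_len / (2L * L))))
    for (r in seq_len(n_pairs)) {
      h <- sample.int(length(haps), 1L, prob = fractions)
      f <- as.integer(round(rnorm(1L, config$fragment_mean, config$fragment_sd)))
      f <- max(L, min(f, hap_lens[h]))
      if (hap_lens[h] < f) next
      s0 <- sample.int(hap_lens[h] - f + 1L, 1L)
      s2 <- s0 + f - L
      a1 <- chain_read_alignment(haps[[h]]$chain, s0, L)
      a2 <- chain_read_alignment(haps[[h]]$chain, s2, L)
      if (is.null(a1) || is.null(a2)) next
      qn <- sprintf("%s_%s_p%06d", genotype_id, sid, r)
      q1 <- apply_errors(substr(haps[[h]]$seq, s0, s0 + L - 1L), config$error_rate)
      q2 <- apply_errors(substr(haps[[h]]$seq, s2, s2 + L - 1L), config$error_rate)
      span <- a2$pos + cigar_ref_len(parse_cigar(a2$cigar)) - a1$pos
      add(qn, 99L, a1$pos, a1$cigar, q1, "=", a2$pos, span)
      add(qn, 147L, a2$pos, a2$cigar, q2, "=", a1$pos, -span)
    }
  }
  if (!length(recs)) return(NULL)
  do.call(rbind, recs)
}

empty_sam_records <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             rnext = character(), pnext = integer(), tlen = integer(),
             seq = character(), stringsAsFactors = FALSE)
}

#' Write alignment records as a coordinate-sorted SAM file
#'
#' @param records Data frame with SAM columns `qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, and optional
#'   tag columns `NH`, `AS`, `XS` (integer; `NA` omits the tag).
#' @param targets Named integer vector of reference lengths (`@SQ` lines).
#' @param file Output path.
#' @export
write_sam <- function(records, targets, file) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(targets), as.integer(targets)))
  body <- character(0)
  if (nrow(records)) {
    qual <- vapply(nchar(records$seq), function(n) strrep("I", n), character(1))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                    records$qname, records$flag, records$rname, records$pos,
                    records$mapq, records$cigar,
                    records$rnext %||% rep("*", nrow(records)),
                    records$pnext %||% rep(0L, nrow(records)),
                    records$tlen %||% rep(0L, nrow(records)),
                    records$seq, qual)
    for (tag in c("NH", "AS", "XS")) {
      if (!is.null(records[[tag]])) {
        extra <- ifelse(is.na(records[[tag]]), "",
                        sprintf("\t%s:i:%d", tag, records[[tag]]))
        body <- paste0(body, extra)
      }
    }
  }
  writeLines(c(header, body), file)
  invisible(file)
}

write_sim_fastq <- function(records, file) {
  lines <- as.vector(rbind(paste0("@", records$qname),
                           records$seq,
                           "+",
                           vapply(nchar(records$seq),
                                  function(n) strrep("I", n), character(1))))
  writeLines(lines, file)
  invisible(file)
}

#' @export
print.ssr_sim_reads <- function(x, ...) {
  cat(sprintf("Simulated reads for genotype '%s': %d records -> %s\n",
              x$genotype_id, x$n_reads, x$sam))
  if (length(x$flagged))
    cat("alleles beyond the detectability limit at:",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
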