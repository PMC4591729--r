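# Shared fixture: one reference with a (GAT)6 locus, reads written as SAM
# through the package's SAM emitter and read back through Rsamtools.

make_catalog <- function() {
  ssr_catalog(data.frame(seq_id = "chr", ssr_type = "p3", motif = "GAT",
                         repeat_count = 6L, start = 51L, end = 68L))
}

sam_record <- function(qname, pos, seq, flag = 0L, cigar = paste0(nchar(seq), "M"),
                       mapq = 42L, NH = NA_integer_, AS = NA_integer_,
                       XS = NA_integer_) {
  data.frame(qname = qname, flag = flag, rname = "chr", pos = pos, mapq = mapq,
             cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L, seq = seq,
             NH = NH, AS = AS, XS = XS, stringsAsFactors = FALSE)
}

with_fixture_reads <- function(records, targets = c(chr = 250L)) {
  sam <- tempfile(fileext = ".sam")
  records <- records[order(records$pos), , drop = FALSE]
  write_sam(records, targets, sam)
  sam
}

fixture_seq <- local({
  set.seed(31)
  repeat {
    bg <- random_dna(250)
    s <- paste0(substr(bg, 1, 47), "TCC", strrep("GAT", 6), "CCA",
                substr(bg, 74, 250))
    if (nrow(oracle_find_ssrs(s, c(10, 6, 5, 5, 5, 5))) == 1L) break
  }
  s
})
span_read <- function(qname, pos, len = 100L, ...)
  sam_record(qname, pos, substr(fixture_seq, pos, pos + len - 1L), ...)

test_that("clean spanning reads produce a single-allele histogram with conserved tallies", {
  recs <- do.call(rbind, lapply(1:12, function(i)
    span_read(sprintf("r%02d", i), pos = i * 4L)))
  # one partial (starts inside the run), one border case, one multimapped
  recs <- rbind(recs,
                span_read("partial", 60L),
                span_read("border", 51L),
                span_read("multi", 10L, NH = 3L))
  tab <- collect_spanning_reads(with_fixture_reads(recs), make_catalog())
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$repeat_count, 6L)
  # border/partial classification depends on where each extra read falls
  d <- attr(tab, "discards")
  expect_equal(d$fetched, d$accepted + d$partial_span + d$border_uncertain +
                 d$multimapped + d$mate_conflict + d$mate_duplicate +
                 d$unmapped_or_secondary)
  expect_equal(d$multimapped, 1L)
  expect_equal(tab$n_reads, d$accepted)
})

test_that("equally scoring secondary placements are filtered as multi-mapped", {
  recs <- rbind(span_read("uniq", 10L, AS = -5L, XS = -20L),
                span_read("dup", 14L, AS = -5L, XS = -5L))
  tab <- collect_spanning_reads(with_fixture_reads(recs), make_catalog())
  d <- attr(tab, "discards")
  expect_equal(d$multimapped, 1L)
  expect_equal(d$accepted, 1L)
})

test_that("overlapping concordant mates are deduplicated, conflicting mates dropped", {
  concordant <- rbind(span_read("pairA", 10L, flag = 99L),
                      span_read("pairA", 40L, flag = 147L))
  tab <- collect_spanning_reads(with_fixture_reads(concordant), make_catalog())
  expect_equal(tab$n_reads, 1L)
  expect_equal(attr(tab, "discards")$mate_duplicate, 1L)

  # a chimeric mate carrying 5 units instead of 6
  alt <- paste0(substr(fixture_seq, 30, 50), strrep("GAT", 5),
                substr(fixture_seq, 69, 250))
  chimeric <- rbind(span_read("pairB", 10L, flag = 99L),
                    sam_record("pairB", 30L, substr(alt, 1, 100),
                               flag = 147L, cigar = "21M3D79M"))
  tab <- collect_spanning_reads(with_fixture_reads(chimeric), make_catalog())
  expect_equal(nrow(tab), 0L)
  expect_equal(attr(tab, "discards")$mate_conflict, 2L)
})

test_that("read order does not change the table", {
  set.seed(13)
  recs <- do.call(rbind, lapply(1:20, function(i)
    span_read(sprintf("r%02d", i), pos = sample(2:50, 1))))
  t1 <- collect_spanning_reads(with_fixture_reads(recs), make_catalog())
  t2 <- collect_spanning_reads(with_fixture_reads(recs[sample.int(nrow(recs)), ]),
                               make_catalog())
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_equal(attr(t1, "discards"), attr(t2, "discards"))
})

test_that("the accepted-read FASTA matches the count table", {
  recs <- do.call(rbind, lapply(1:8, function(i)
    span_read(sprintf("r%02d", i), pos = i * 5L)))
  dir <- tempfile()
  tab <- collect_spanning_reads(with_fixture_reads(recs), make_catalog(),
                                fasta_dir = dir)
  files <- list.files(dir, full.names = TRUE)
  expect_length(files, 1L)
  fa <- Biostrings::readDNAStringSet(files)
  expect_length(fa, sum(tab$n_reads))
  expect_true(all(grepl("repeat_count=6", names(fa))))
})

test_that("empty alignments and absent loci give empty results, not errors", {
  sam <- with_fixture_reads(span_read("r1", 10L)[0, ])
  tab <- collect_spanning_reads(sam, make_catalog())
  expect_equal(nrow(tab), 0L)
  expect_equal(attr(tab, "discards")$fetched, 0L)
})

test_that("a catalog sequence missing from the alignment header is an error", {
  sam <- with_fixture_reads(span_read("r1", 10L))
  bad <- ssr_catalog(data.frame(seq_id = "chrZ", ssr_type = "p3", motif = "GAT",
                                repeat_count = 6L, start = 51L, end = 68L))
  expect_error(collect_spanning_reads(sam, bad), "chrZ")
})
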