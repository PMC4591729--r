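test_that("the planted truth catalog is recovered by detection and is seed-stable", {
  loci <- data.frame(motif = c("GAT", "A"), repeat_count = c(8L, 13L))
  ref <- simulate_reference(loci, margin = 110, seed = 7)
  found <- find_perfect_ssrs(ref$sequences)
  expect_equal(as.data.frame(found)[, c("seq_id", "motif", "repeat_count", "start", "end")],
               as.data.frame(ref$catalog)[, c("seq_id", "motif", "repeat_count", "start", "end")])
  # byte-identical under the same seed
  ref2 <- simulate_reference(loci, margin = 110, seed = 7)
  expect_identical(ref$sequences, ref2$sequences)
  # and the reads too
  s1 <- simulate_genotype_reads(ref, c(8L, 13L), sim_config(seed = 5))
  s2 <- simulate_genotype_reads(ref, c(8L, 13L), sim_config(seed = 5))
  expect_identical(readLines(s1$sam), readLines(s2$sam))
})

test_that("multiple loci per sequence are laid out as specified", {
  # nine haploid sequences carrying eight homopolymer loci each
  loci <- do.call(rbind, lapply(1:9, function(g)
    data.frame(seq_id = sprintf("CP%02d", g),
               motif = rep(c("T", "A"), 4),
               repeat_count = rep(c(12L, 14L, 11L, 13L), 2))))
  ref <- simulate_reference(loci, margin = 60, seed = 3)
  expect_equal(nrow(ref$catalog), 72L)
  expect_equal(length(ref$sequences), 9L)
  expect_equal(as.data.frame(find_perfect_ssrs(ref$sequences))$start,
               ref$catalog$start)
})

test_that("infeasible plantings are rejected", {
  expect_error(simulate_reference(data.frame(motif = "GAT", repeat_count = 3L)),
               "infeasible")
  expect_error(simulate_reference(data.frame(motif = "ATAT", repeat_count = 8L)),
               "primitive")
})

test_that("emitted SAM is valid and internally consistent", {
  ref <- simulate_reference(data.frame(motif = "AG", repeat_count = 10L), seed = 2)
  sim <- simulate_genotype_reads(ref, list(c(10L, 9L)),
                                 sim_config(coverage = 20, seed = 2))
  # a strict SAM parser accepts it
  bam <- Rsamtools::asBam(sim$sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  expect_true(file.exists(bam))
  # CIGAR query widths equal sequence lengths
  for (i in seq_len(nrow(sim$records))) {
    ops <- ssrpoly:::parse_cigar(sim$records$cigar[i])
    expect_equal(ssrpoly:::cigar_query_len(ops), nchar(sim$records$seq[i]))
  }
  # coordinate sorted
  expect_true(!is.unsorted(sim$records$pos))
})

test_that("error-free homozygous reads all carry the planted allele", {
  ref <- simulate_reference(data.frame(motif = "GAT", repeat_count = 8L), seed = 11)
  sim <- simulate_genotype_reads(ref, 6L, sim_config(coverage = 30, seed = 4))
  tab <- collect_spanning_reads(sim$sam, ref$catalog)
  expect_equal(tab$repeat_count, 6L)   # read-space count, not the reference 8
  expect_gt(tab$n_reads, 0L)
})

test_that("a 50/50 heterozygote splits spanning reads near evenly", {
  ref <- simulate_reference(data.frame(motif = "TC", repeat_count = 7L), seed = 21)
  sim <- simulate_genotype_reads(ref, list(c(7L, 6L)),
                                 sim_config(coverage = 60, seed = 22))
  tab <- collect_spanning_reads(sim$sam, ref$catalog)
  expect_setequal(tab$repeat_count, c(6L, 7L))
  frac <- tab$n_reads / sum(tab$n_reads)
  # binomial tolerance at this depth
  expect_true(all(frac > 0.3 & frac < 0.7))
})

test_that("paired mode emits proper overlapping pairs that deduplicate", {
  ref <- simulate_reference(data.frame(motif = "GAT", repeat_count = 7L), seed = 8)
  sim <- simulate_genotype_reads(ref, 7L,
                                 sim_config(coverage = 40, paired = TRUE,
                                            fragment_mean = 150, fragment_sd = 5,
                                            seed = 9))
  expect_true(all(sim$records$flag %in% c(99L, 147L)))
  tab <- collect_spanning_reads(sim$sam, ref$catalog)
  d <- attr(tab, "discards")
  expect_gt(d$mate_duplicate, 0L)      # overlapping concordant mates collapse
  expect_equal(d$fetched, d$accepted + d$partial_span + d$border_uncertain +
                 d$multimapped + d$mate_conflict + d$mate_duplicate +
                 d$unmapped_or_secondary)
  expect_equal(tab$repeat_count, 7L)
})

test_that("oversized alleles are flagged at generation time", {
  ref <- simulate_reference(data.frame(motif = "AC", repeat_count = 48L),
                            margin = 120, seed = 13)
  sim <- simulate_genotype_reads(ref, 49L, sim_config(seed = 13, tiling = TRUE))
  expect_length(sim$flagged, 1L)
})
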