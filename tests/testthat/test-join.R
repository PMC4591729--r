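two_locus_catalog <- function() {
  ssr_catalog(data.frame(seq_id = c("TRa", "TRb"), ssr_type = c("p3", "p2"),
                         motif = c("GAT", "TC"), repeat_count = c(6L, 7L),
                         start = c(100L, 40L), end = c(117L, 53L)))
}

count_tbl <- function(key, counts) {
  data.frame(locus = rep(key, length(counts)),
             repeat_count = as.integer(names(counts)),
             n_reads = as.integer(counts), stringsAsFactors = FALSE)
}

test_that("allele sets that differ across called genotypes are polymorphic", {
  cat <- two_locus_catalog()
  keyA <- locus_key(cat)[1L]
  g1 <- count_tbl(keyA, c(`6` = 12))
  g2 <- count_tbl(keyA, c(`6` = 8, `5` = 4))
  out <- join_genotypes(list(G1 = g1, G2 = g2), cat)
  expect_equal(nrow(out), 2L)              # one row per catalog locus
  rowA <- out[out$locus == keyA, ]
  expect_equal(rowA$G1, "6")
  expect_equal(rowA$G2, "6; 5")
  expect_equal(rowA$verdict, "polymorphic")
  # the uncovered locus is NA everywhere and not comparable
  rowB <- out[out$locus != keyA, ]
  expect_equal(unname(unlist(rowB[, c("G1", "G2")])), c("NA", "NA"))
  expect_equal(rowB$verdict, "not_comparable")
})

test_that("identical called allele sets are monomorphic", {
  cat <- two_locus_catalog()
  keyA <- locus_key(cat)[1L]
  out <- join_genotypes(list(G1 = count_tbl(keyA, c(`6` = 12)),
                             G2 = count_tbl(keyA, c(`6` = 30))), cat)
  expect_equal(out$verdict[out$locus == keyA], "monomorphic")
})

test_that("a single called genotype cannot be compared", {
  cat <- two_locus_catalog()
  keyA <- locus_key(cat)[1L]
  out <- join_genotypes(list(G1 = count_tbl(keyA, c(`6` = 12)),
                             G2 = count_tbl(keyA, c(`6` = 5))), cat)
  rowA <- out[out$locus == keyA, ]
  expect_equal(rowA$G1, "6")
  expect_equal(rowA$G2, "NA")
  expect_equal(rowA$verdict, "not_comparable")
})

test_that("heterozygous cells order the major allele first", {
  cat <- two_locus_catalog()
  keyA <- locus_key(cat)[1L]
  out <- join_genotypes(list(G1 = count_tbl(keyA, c(`5` = 8, `6` = 4)),
                             G2 = count_tbl(keyA, c(`6` = 12))), cat)
  expect_equal(out[out$locus == keyA, "G1"], "5; 6")
})

test_that("duplicate genotype ids and too few genotypes are rejected", {
  cat <- two_locus_catalog()
  t1 <- count_tbl(locus_key(cat)[1L], c(`6` = 12))
  expect_error(join_genotypes(list(G1 = t1, G1 = t1), cat), "duplicate")
  expect_error(join_genotypes(list(G1 = t1), cat), "two genotypes")
})

test_that("count-table loci missing from the catalog are kept with a warning", {
  cat <- two_locus_catalog()
  t1 <- count_tbl("TRx:9-20(AG)", c(`6` = 12))
  t2 <- count_tbl("TRx:9-20(AG)", c(`5` = 12))
  expect_warning(out <- join_genotypes(list(G1 = t1, G2 = t2), cat), "unknown")
  row <- out[out$locus == "TRx:9-20(AG)", ]
  expect_equal(row$ssr_type, "unknown")
  expect_equal(row$verdict, "polymorphic")
})

test_that("compound catalog rows appear as non-genotyped rows", {
  cat <- ssr_catalog(data.frame(seq_id = c("TRa", "TRa"),
                                ssr_type = c("p3", "c"),
                                motif = c("GAT", NA), ssr = c(NA, "(GA)6nn(CT)5"),
                                repeat_count = c(6L, NA),
                                start = c(100L, 300L), end = c(117L, 324L)))
  keyA <- locus_key(cat)[1L]
  out <- join_genotypes(list(G1 = count_tbl(keyA, c(`6` = 12)),
                             G2 = count_tbl(keyA, c(`6` = 15))), cat)
  expect_equal(nrow(out), 2L)
  expect_equal(out$verdict[out$ssr_type == "c"], "not_comparable")
})

test_that("the calls table round-trips through its text form", {
  cat <- two_locus_catalog()
  keyA <- locus_key(cat)[1L]
  out <- join_genotypes(list(G1 = count_tbl(keyA, c(`6` = 8, `5` = 4)),
                             G2 = count_tbl(keyA, c(`6` = 12))), cat)
  tmp <- tempfile(fileext = ".tsv")
  write_calls_table(out, tmp)
  back <- read_calls_table(tmp)
  expect_equal(back$locus, out$locus)
  expect_equal(back$G1, out$G1)
  expect_equal(back$G2, out$G2)
  expect_equal(back$verdict, out$verdict)
  expect_equal(attr(back, "genotypes"), c("G1", "G2"))
})
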