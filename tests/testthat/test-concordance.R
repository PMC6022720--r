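test_that("the finer-resolution equivalence rule matches haplogroup nesting", {
  tr <- default_tree()
  # one method at broader resolution: concordant
  expect_true(is_concordant("A2", "A2x", tr))
  expect_true(is_concordant("H", "H", tr))
  # distinct branches: discordant
  expect_false(is_concordant("L0", "L1", tr))
  expect_false(is_concordant("J", "T", tr))
  # tree-aware nesting, including two-letter clades
  expect_true(is_concordant("JT", "J", tr))
  expect_true(is_concordant("L3", "L3e", tr))
  # string fallback for labels outside the reduced tree: the extra character
  # must continue the letter/number alternation
  expect_true(is_concordant("A2x", "A2x1", tr))
  expect_false(is_concordant("QQ", "Q", tr))
  # case-insensitive
  expect_true(is_concordant("a2", "A2X", tr))
  expect_error(is_concordant("", "H", tr), "non-empty")
})

test_that("is_concordant is symmetric", {
  tr <- default_tree()
  labels <- c("H", "HV", "JT", "J", "T", "L0", "L3", "L3e", "A2", "A2x",
              "B2a", "U", "K", "X2a")
  for (a in labels) {
    for (b in labels) {
      expect_identical(is_concordant(a, b, tr), is_concordant(b, a, tr))
    }
  }
})

test_that("concordance_table excludes unclassified and hand-counts correctly", {
  tr <- default_tree()
  a <- c(s1 = "H", s2 = "unclassified", s3 = "L0")
  b <- c(s1 = "H", s2 = "H", s3 = "L1")
  rep <- concordance_table(a, b, tr)
  expect_identical(rep$n_excluded_unclassified, 1L)
  expect_identical(rep$n_compared, 2L)
  expect_identical(rep$n_concordant, 1L)
  expect_equal(rep$percent_concordant, 50.0)
  expect_identical(rep$discordant$sample_id, "s3")
  # report invariants
  expect_identical(rep$n_compared,
                   rep$n_shared - rep$n_excluded_unclassified)
  expect_equal(rep$percent_concordant,
               100 * rep$n_concordant / rep$n_compared)

  # identical call sets -> 100%
  expect_equal(concordance_table(a[c(1, 3)], a[c(1, 3)],
                                 tr)$percent_concordant, 100.0)
  # the finer-resolution rule applies inside the table
  expect_equal(concordance_table(c(s1 = "A2"), c(s1 = "A2x"),
                                 tr)$percent_concordant, 100.0)

  # relabeling sample ids leaves the percentage unchanged
  a2 <- a; names(a2) <- c("x9", "x2", "x7")
  b2 <- b; names(b2) <- c("x9", "x2", "x7")
  expect_equal(concordance_table(a2, b2, tr)$percent_concordant,
               rep$percent_concordant)

  expect_error(concordance_table(c(s1 = "H"), c(s9 = "H"), tr),
               "share no sample")
  expect_error(concordance_table(c(s1 = "unclassified"),
                                 c(s1 = "H"), tr),
               "no comparable samples")
})

test_that("haplogroup frequencies exclude offspring and aggregate lineages", {
  tr <- default_tree()
  # two trios, mothers H and A2, fathers U and C; children excluded
  fam <- data.frame(
    fid = rep(c("F1", "F2"), each = 3),
    iid = c("m1", "f1", "c1", "m2", "f2", "c2"),
    pat = c("0", "0", "f1", "0", "0", "f2"),
    mat = c("0", "0", "m1", "0", "0", "m2"),
    sex = c("2", "1", "1", "2", "1", "2"),
    pheno = "-9", stringsAsFactors = FALSE)
  results <- data.frame(
    sample_id = fam$iid,
    haplogroup = c("H", "U", "H", "A2", "C", "A2"),
    path = "", status = "classified", n_missing_required = 0L,
    stringsAsFactors = FALSE)

  freq <- haplogroup_frequencies(results, fam, tr, founders_only = TRUE)
  expect_identical(sum(freq$haplogroup$count), 4L)
  expect_setequal(freq$haplogroup$haplogroup, c("H", "A2", "U", "C"))
  expect_true(all(freq$haplogroup$frequency == 0.25))
  expect_equal(sum(freq$haplogroup$frequency), 1, tolerance = 1e-9)

  # lineage aggregation sums member-label frequencies exactly
  lin <- freq$lineage
  expect_equal(lin$frequency[lin$lineage == "European"], 0.5)
  expect_equal(lin$frequency[lin$lineage == "NativeAmerican_Asian"], 0.5)
  expect_equal(sum(lin$frequency), 1, tolerance = 1e-9)

  # founders_only = FALSE counts everyone
  all_in <- haplogroup_frequencies(results, fam, tr, founders_only = FALSE)
  expect_identical(sum(all_in$haplogroup$count), 6L)
  expect_equal(all_in$haplogroup$frequency[
    all_in$haplogroup$haplogroup == "H"], 2 / 6)

  # unclassified samples leave the denominator
  results$status[1] <- "unclassified"
  results$haplogroup[1] <- ""
  f2 <- haplogroup_frequencies(results, fam, tr)
  expect_identical(sum(f2$haplogroup$count), 3L)

  # degenerate: everything unclassified
  results$status <- "unclassified"
  results$haplogroup <- ""
  expect_warning(f3 <- haplogroup_frequencies(results, fam, tr),
                 "no classified")
  expect_identical(nrow(f3$haplogroup), 0L)

  expect_error(
    haplogroup_frequencies(
      data.frame(sample_id = "ghost", haplogroup = "H", path = "",
                 status = "classified", n_missing_required = 0L),
      fam, tr),
    "absent from the pedigree")
})

test_that("simulated trios feed the founder-only frequency pipeline", {
  tr <- default_tree()
  sim <- simulate_dataset(tr, 90, n_trios = 30, seed = 17)
  g <- simulated_genotypes(sim)
  res <- suppressMessages(classify_dataset(tr, g))
  freq <- haplogroup_frequencies(res, g$fam, tr, founders_only = TRUE)
  # 90 samples minus 30 offspring
  expect_identical(sum(freq$haplogroup$count), 60L)
  expect_equal(sum(freq$haplogroup$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(freq$lineage$frequency), 1, tolerance = 1e-9)
  # lineage counts are exact sums of their member haplogroup counts
  for (l in freq$lineage$lineage) {
    expect_identical(
      freq$lineage$count[freq$lineage$lineage == l],
      sum(freq$haplogroup$count[freq$haplogroup$lineage == l]))
  }
})

test_that("call-set CSVs round-trip through read_callset", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,haplogroup", "s1,H", "s2,A2x", "s3,unclassified"),
             path)
  cs <- read_callset(path)
  expect_identical(as.character(cs), c("H", "A2x", "unclassified"))
  expect_identical(names(cs), c("s1", "s2", "s3"))
  expect_error(read_callset(tempfile()), "not found")
})
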