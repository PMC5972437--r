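siteDf <- function(fpkm, spacer_len = 20L, nuclease = "SpCas9",
                   editing_pct = 50) {
  k <- length(fpkm)
  data.frame(site_id = sprintf("s%02d", seq_len(k)),
             nuclease = rep_len(nuclease, k),
             spacer_len = rep_len(spacer_len, k), fpkm = fpkm,
             editing_pct = rep_len(editing_pct, k),
             assay = rep_len("deep_seq", k))
}

test_that("expression split is strict-below / at-or-above the threshold", {
  df <- siteDf(c(0, 10, 24.9, 25, 25.1, 300))
  sp <- splitByExpression(df)
  expect_equal(sp$low$fpkm, c(0, 10, 24.9))
  expect_equal(sp$high$fpkm, c(25, 25.1, 300))
  expect_equal(nrow(sp$low) + nrow(sp$high), nrow(df))
  # custom threshold
  sp2 <- splitByExpression(df, threshold = 10)
  expect_equal(sp2$low$fpkm, 0)
  # empty input stays a valid empty partition
  sp0 <- splitByExpression(siteDf(numeric()))
  expect_equal(nrow(sp0$low), 0L)
  expect_equal(nrow(sp0$high), 0L)
  # missing values are dropped with a warning
  expect_warning(spNA <- splitByExpression(siteDf(c(5, NA, 50))), "missing")
  expect_equal(nrow(spNA$low) + nrow(spNA$high), 2L)
})

test_that("optimal-length filtering follows per-enzyme ranges", {
  df <- siteDf(rep(50, 10), spacer_len = 16:25)
  expect_equal(filterOptimalLengths(df, "SpCas9")$spacer_len, 17:22)
  expect_equal(filterOptimalLengths(df, "SaCas9")$spacer_len, 21:25)
  expect_equal(filterOptimalLengths(df, "NmCas9")$spacer_len, 19:25)
  expect_equal(filterOptimalLengths(df, "AsCpf1")$spacer_len, 19:25)
  expect_equal(filterOptimalLengths(df, "LbCpf1")$spacer_len, 19:25)
  # boundary cases called out explicitly
  expect_false(23L %in% filterOptimalLengths(df, "SpCas9")$spacer_len)
  expect_true(21L %in% filterOptimalLengths(df, "SaCas9")$spacer_len)
  expect_false(18L %in% filterOptimalLengths(df, "LbCpf1")$spacer_len)
  expect_error(filterOptimalLengths(df, "NoSuchCas"), "unknown nuclease")
})

test_that("rank-sum comparisons reproduce known exact p-values", {
  # clean separation of two n=3 groups: two-sided exact p = 2/choose(6,3)
  r <- compareGroups(c(1, 2, 3), c(10, 11, 12), "wilcoxon_rank_sum")
  expect_equal(r$p.value, 0.1)
  # identical tied groups carry no evidence
  r2 <- compareGroups(c(5, 5, 5), c(5, 5, 5), "wilcoxon_rank_sum")
  expect_equal(r2$p.value, 1)
  expect_error(compareGroups(1, c(1, 2), "wilcoxon_rank_sum"))
})

test_that("exact rank-sum p-values match exhaustive enumeration", {
  set.seed(77)
  for (rep in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(1000, n1 + n2)           # distinct -> no ties
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    got <- compareGroups(a, b, "wilcoxon_rank_sum")$p.value
    expect_equal(got, rankSumEnumP(a, b),
                 label = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
  }
})

test_that("t and KS tests run and degenerate t input errors", {
  a <- c(10, 12, 14, 11); b <- c(20, 22, 24, 21)
  rt <- compareGroups(a, b, "t_test")
  expect_lt(rt$p.value, 0.01)
  expect_match(rt$method, "Welch")
  rk <- compareGroups(a, b, "ks_test")
  expect_true(rk$p.value >= 0 && rk$p.value <= 1)
  expect_error(compareGroups(c(3, 3, 3), c(7, 7, 7), "t_test"), "degenerate")
  # one constant group is fine for Welch
  expect_s3_class(compareGroups(c(3, 3, 3), c(7, 8, 9), "t_test"), "htest")
})

test_that("the t-test holds its nominal type I error under the null", {
  set.seed(2024)
  reps <- 400
  p <- vapply(seq_len(reps), function(i)
    compareGroups(rnorm(10), rnorm(10), "t_test")$p.value, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / reps))
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03), "BH"),
               p.adjust(c(0.01, 0.02, 0.03), "BH"))
})

test_that("the recommender covers every goal/specificity/donor combination", {
  grid <- expand.grid(goal = c("knockout", "precise_edit"),
                      spec = c(FALSE, TRUE),
                      donor = c("none", "ssODN", "plasmid"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rec <- if (g$goal == "precise_edit" && g$donor == "none") {
      expect_warning(
        r <- recommendSystem(g$goal, g$spec, g$donor), "falling back")
      r
    } else recommendSystem(g$goal, g$spec, g$donor)
    expect_s4_class(rec, "Recommendation")
    expect_gte(length(rec@rationale), 1L)
    expect_true(all(nzchar(rec@rationale)))
    expect_true(all(rec@nucleases %in% listNucleases()))
  }
})

test_that("recommendations encode the published selection rules", {
  expect_setequal(recommendSystem("knockout", FALSE)@nucleases,
                  c("SpCas9", "LbCpf1"))
  kSpec <- recommendSystem("knockout", TRUE)
  expect_equal(kSpec@nucleases[1], "AsCpf1")
  expect_true("SaCas9" %in% kSpec@nucleases)
  ss <- recommendSystem("precise_edit", donor = "ssODN")
  expect_setequal(ss@nucleases, c("SpCas9", "LbCpf1"))
  expect_equal(ss@donorAdvice$SpCas9$strand, "T")
  expect_equal(ss@donorAdvice$SpCas9$armPamProximal, 37L)
  expect_equal(ss@donorAdvice$SpCas9$armPamDistal, 77L)
  expect_equal(ss@donorAdvice$LbCpf1$strand, "NT")
  expect_equal(ss@donorAdvice$LbCpf1$armPamProximal, 77L)
  expect_equal(recommendSystem("precise_edit", donor = "plasmid")@nucleases,
               "SpCas9")
  # purity: repeated calls are identical
  expect_identical(recommendSystem("knockout", TRUE),
                   recommendSystem("knockout", TRUE))
})

test_that("site results are read with validation", {
  f <- tempfile(fileext = ".tsv")
  write.table(siteDf(c(10, 80)), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  df <- readSiteResults(f)
  expect_equal(nrow(df), 2L)
  bad <- siteDf(c(10, 80)); bad$editing_pct <- c(50, 120)
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSiteResults(f), "editing_pct")
  write.table(siteDf(10)[, -4], f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readSiteResults(f), "missing column")
})
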