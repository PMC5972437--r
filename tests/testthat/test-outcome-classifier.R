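makeTestExperiment <- function(seed = 7L) {
  loc <- testLocus(seed = seed)
  site <- loc$site
  ip <- insertionPointBetweenCuts(site, site)
  ampliconExperiment(loc$ref, site, windowSize = 40L,
                     insertionPoint0 = ip, insertSeq = "TCTAGA")
}

test_that("a perfect read aligns as a full match", {
  exp <- makeTestExperiment()
  ref <- exp@referenceSeq
  a <- alignRead(ref, ref)
  expect_equal(a$cigar, paste0(nchar(ref), "M"))
  expect_equal(a$identity, 1.0)
  expect_equal(nrow(a$events), 0L)
})

test_that("a clean 3-nt deletion yields one 3D event at the left-aligned position", {
  set.seed(41)
  ref <- randomDnaStr(120)
  read <- paste0(substr(ref, 1, 60), substr(ref, 64, 120))
  a <- alignRead(read, ref)
  expect_match(a$cigar, "3D")
  expect_equal(nrow(a$events), 1L)
  expect_equal(a$events$type, "D")
  expect_equal(a$events$len, 3L)
  # the event must be at its 5'-most equivalent placement
  p <- a$events$pos0
  expect_true(p == 0 ||
                substr(ref, p, p) != substr(ref, p + 3L, p + 3L))
  # and the score is DP-optimal
  expect_equal(a$score, nwScoreOracle(read, ref))
})

test_that("alignment scores equal the textbook DP oracle on random pairs", {
  set.seed(101)
  for (rep in 1:120) {
    a <- randomDnaStr(sample(30:60, 1))
    b <- randomDnaStr(sample(30:60, 1))
    got <- alignRead(a, b)$score
    expect_equal(got, nwScoreOracle(a, b), label = sprintf("pair %d", rep))
  }
})

test_that("NHEJ labels honour the spacer window and the longest-event rule", {
  win <- c(40L, 120L)
  mkev <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(type = r[[1]], pos0 = as.integer(r[[2]]),
                 len = as.integer(r[[3]]), seq = strrep("A", r[[3]]))))
  }
  none <- data.frame(type = character(), pos0 = integer(), len = integer(),
                     seq = character())
  expect_equal(classifyNhej(none, win), "Match")
  expect_equal(classifyNhej(mkev(list("I", 80, 1)), win), "Insertion")
  expect_equal(classifyNhej(mkev(list("D", 80, 5)), win), "Deletion")
  # a 5-nt deletion 50 bp outside the window does not count
  expect_equal(classifyNhej(mkev(list("D", 170, 5)), win), "Match")
  # deletions overlapping the window edge do count
  expect_equal(classifyNhej(mkev(list("D", 38, 4)), win), "Deletion")
  # both events: longest wins; ties go to Deletion
  expect_equal(classifyNhej(mkev(list("I", 60, 4), list("D", 80, 2)), win),
               "Insertion")
  expect_equal(classifyNhej(mkev(list("I", 60, 2), list("D", 80, 4)), win),
               "Deletion")
  expect_equal(classifyNhej(mkev(list("I", 60, 3), list("D", 80, 3)), win),
               "Deletion")
})

test_that("HDR labels require the restriction site within the window segment", {
  exp <- makeTestExperiment()
  modRef <- exp@modifiedReferenceSeq
  # read identical to the modified reference -> Correct
  out <- classifyReads(modRef, exp, "hdr")
  expect_equal(out$hdr_label, "Correct")
  # unedited read lacks the site -> No
  out <- classifyReads(exp@referenceSeq, exp, "hdr")
  expect_equal(out$hdr_label, "No")
  # site present plus a 2-nt deletion in the window -> Wrong
  mw <- modWindow0(exp)
  delAt <- mw[1] + 5L
  read <- paste0(substr(modRef, 1, delAt), substr(modRef, delAt + 3L,
                                                  nchar(modRef)))
  out <- classifyReads(read, exp, "hdr")
  expect_equal(out$nhej_label, "Deletion")
  expect_equal(out$hdr_label, "Wrong")
  # the site elsewhere in the read but not at the locus does not rescue a
  # read that lost it in the window
  naked <- sub("TCTAGA", "", modRef, fixed = TRUE)
  readFar <- paste0("TCTAGA", substr(naked, 7L, nchar(naked)))
  out <- classifyReads(readFar, exp, "hdr")
  expect_equal(out$hdr_label, "No")
  expect_error(classifyHdr("ACGT", "Match",
                           ampliconExperiment(strrep("A", 100), c(30, 50))),
               "modified reference")
})

test_that("substitution-only reads are Match and low-identity reads Unaligned", {
  exp <- makeTestExperiment()
  ref <- exp@referenceSeq
  sub <- ref
  substr(sub, 70, 70) <- if (substr(ref, 70, 70) == "A") "C" else "A"
  out <- classifyReads(sub, exp, "nhej")
  expect_equal(out$nhej_label, "Match")
  junk <- randomDnaStr(nchar(ref))
  out <- classifyReads(junk, exp, "nhej")
  expect_equal(out$nhej_label, "Unaligned")
})

test_that("summaries conserve counts and compute percentages on aligned reads", {
  lab <- c(rep("Insertion", 20), rep("Deletion", 10), rep("Match", 70))
  s <- summarizeOutcomes(S4Vectors::DataFrame(nhej_label = lab))
  expect_equal(s@indelPct, 30.0)
  expect_equal(s@nInsertion + s@nDeletion + s@nMatch, s@nAligned)
  s0 <- summarizeOutcomes(S4Vectors::DataFrame(
    nhej_label = rep("Match", 5)))
  expect_equal(s0@indelPct, 0.0)
  expect_warning(
    sNA <- summarizeOutcomes(S4Vectors::DataFrame(
      nhej_label = rep("Unaligned", 3))),
    "zero aligned")
  expect_true(is.na(sNA@indelPct))
})

test_that("classification is exhaustive and window-monotone on simulated reads", {
  cfg <- simConfig(seed = 404L, nReads = 300L)
  fx <- makeLocusFixture(cfg)
  sim <- simulateReads(fx)
  out <- classifyReads(sim$reads, fx$experiment, "nhej")
  tab <- table(factor(out$nhej_label,
                      levels = c("Insertion", "Deletion", "Match",
                                 "Unaligned")))
  expect_equal(sum(tab[c("Insertion", "Deletion", "Match")]),
               sum(out$nhej_label != "Unaligned"))
  # enlarging the window never decreases the indel count
  widths <- c(10L, 20L, 40L, 60L)
  counts <- vapply(widths, function(w) {
    e <- fx$experiment
    e@windowSize <- w
    o <- classifyReads(sim$reads, e, "nhej")
    sum(o$nhej_label %in% c("Insertion", "Deletion"))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("programmed indel fractions are recovered within binomial error", {
  cfg <- simConfig(seed = 555L, nReads = 2000L,
                   fractions = c(wt = 0.7, indel = 0.3, hdr_correct = 0,
                                 hdr_wrong = 0))
  fx <- makeLocusFixture(cfg)
  sim <- simulateReads(fx)
  out <- classifyReads(sim$reads, fx$experiment, "nhej")
  s <- summarizeOutcomes(out)
  pTruth <- mean(sim$truth$category == "indel")
  pHat <- (s@nInsertion + s@nDeletion) / s@nAligned
  tol <- 3 * sqrt(pTruth * (1 - pTruth) / s@nAligned)
  expect_lt(abs(pHat - pTruth), max(tol, 1e-12))
})

test_that("per-read outcomes and JSON summary are written faithfully", {
  cfg <- simConfig(seed = 31L, nReads = 50L)
  fx <- makeLocusFixture(cfg)
  sim <- simulateReads(fx)
  out <- classifyReads(sim$reads, fx$experiment, "hdr")
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  writeOutcomes(out, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 50L)
  sum <- jsonlite::read_json(js)
  expect_equal(sum$n_total, 50L)
  expect_equal(sum$n_hdr_correct + sum$n_hdr_wrong + sum$n_hdr_no,
               sum$n_aligned)
})
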