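test_that("configuration validation catches bad parameters", {
  expect_error(simConfig(), "mandatory")
  expect_error(simConfig(1, fractions = c(wt = 0.5, indel = 0.5,
                                          hdr_correct = 0.2,
                                          hdr_wrong = -0.2)),
               "sum to 1")
  expect_error(simConfig(1, errorRate = 0.5), "errorRate")
  expect_error(simConfig(1, referenceLength = 50), "too small")
  cfg <- simConfig(seed = 1L)
  expect_s3_class(cfg, "SimConfig")
  expect_equal(cfg$nReads, 10000L)
  expect_equal(sum(cfg$fractions), 1)
})

test_that("the fixture embeds exactly one validated site, deterministically", {
  cfg <- simConfig(seed = 11L)
  fx <- makeLocusFixture(cfg)
  expect_s4_class(fx$site, "GRanges")
  expect_length(fx$site, 1L)
  expect_equal(as.character(GenomicRanges::strand(fx$site)), "+")
  ref <- as.character(fx$reference[[1]])
  expect_equal(nchar(ref), 240L)
  # rescanning the emitted reference finds the same single site
  again <- scanMatchedSites(ref, cfg$combo)
  expect_length(again, 1L)
  expect_equal(GenomicRanges::start(again), GenomicRanges::start(fx$site))
  # PAMs re-validate against the raw sequence
  s0 <- GenomicRanges::start(fx$site) - 1L
  e0 <- GenomicRanges::end(fx$site)
  expect_true(matchesPam(substr(ref, s0 - 3L, s0), "TTTN"))
  expect_true(matchesPam(substr(ref, e0 + 1L, e0 + 6L), "NGGRRT"))
  # byte-identical under the same seed
  fx2 <- makeLocusFixture(simConfig(seed = 11L))
  expect_identical(as.character(fx2$reference[[1]]), ref)
  expect_identical(fx2$donor@oligoSeq, fx$donor@oligoSeq)
  # the experiment's modified reference carries the insert at the junction
  exp <- fx$experiment
  ip <- exp@insertionPoint0
  expect_equal(substr(exp@modifiedReferenceSeq, ip + 1L, ip + 6L), "TCTAGA")
  expect_equal(nchar(exp@modifiedReferenceSeq), 246L)
  # the insert sits between the two cleavage positions
  cut <- cas9CutSite(fx$site, fx$cas9Nuclease)
  nick <- unname(cpf1CutSites(fx$site, fx$cpf1Nuclease)["non_target"])
  expect_true(ip >= min(cut, nick) && ip <= max(cut, nick))
})

test_that("spacer lengths outside the combo range are rejected", {
  expect_error(makeLocusFixture(simConfig(seed = 2L, spacerLen = 16L)),
               "range")
  fxLong <- makeLocusFixture(simConfig(seed = 2L, combo = "cpf1_nm_long",
                                       spacerLen = 24L))
  expect_equal(GenomicRanges::width(fxLong$site), 24L)
})

test_that("simulated reads honour the configured mixture and are reproducible", {
  cfg <- simConfig(seed = 21L, nReads = 500L)
  fx <- makeLocusFixture(cfg)
  sim <- simulateReads(fx)
  expect_equal(sum(sim$counts), 500L)
  expect_length(sim$reads, 500L)
  expect_equal(sort(names(sim$counts)),
               sort(c("wt", "indel", "hdr_correct", "hdr_wrong")))
  # truth table is one row per read, consistent with the realized counts
  expect_equal(nrow(sim$truth), 500L)
  expect_equal(sort(as.vector(table(sim$truth$category))),
               sort(as.vector(sim$counts[sim$counts > 0])))
  # indel lengths only for indel-bearing categories, within truncation
  hasIndel <- sim$truth$category %in% c("indel", "hdr_wrong")
  expect_true(all(!is.na(sim$truth$indel_len[hasIndel])))
  expect_true(all(is.na(sim$truth$indel_len[!hasIndel])))
  expect_true(all(sim$truth$indel_len[hasIndel] >= 1L &
                    sim$truth$indel_len[hasIndel] <= cfg$maxIndelLen))
  # same seed, same bytes
  sim2 <- simulateReads(makeLocusFixture(simConfig(seed = 21L,
                                                   nReads = 500L)))
  expect_identical(as.character(sim$reads), as.character(sim2$reads))
  expect_identical(as.data.frame(sim$truth), as.data.frame(sim2$truth))
  # a different seed changes the reads
  sim3 <- simulateReads(fx, simConfig(seed = 22L, nReads = 500L))
  expect_false(identical(as.character(sim$reads), as.character(sim3$reads)))
})

test_that("pure wild-type and pure correct-HDR mixtures classify as such", {
  cfgWt <- simConfig(seed = 31L, nReads = 120L, errorRate = 0,
                     fractions = c(wt = 1, indel = 0, hdr_correct = 0,
                                   hdr_wrong = 0))
  fx <- makeLocusFixture(cfgWt)
  simWt <- simulateReads(fx)
  outWt <- classifyReads(simWt$reads, fx$experiment, "nhej")
  expect_true(all(outWt$nhej_label == "Match"))
  expect_equal(summarizeOutcomes(outWt)@indelPct, 0)

  cfgHdr <- simConfig(seed = 31L, nReads = 120L, errorRate = 0,
                      fractions = c(wt = 0, indel = 0, hdr_correct = 1,
                                    hdr_wrong = 0))
  simHdr <- simulateReads(fx, cfgHdr)
  outHdr <- classifyReads(simHdr$reads, fx$experiment, "hdr")
  expect_true(all(outHdr$hdr_label == "Correct"))
  expect_equal(summarizeOutcomes(outHdr)@hdrCorrectPct, 100)
})

test_that("noise-free reads classify exactly as their generating category", {
  cfg <- simConfig(seed = 47L, nReads = 200L, errorRate = 0)
  fx <- makeLocusFixture(cfg)
  sim <- simulateReads(fx)
  mix <- estimateOutcomeMixture(sim$reads, fx$experiment)
  truthCounts <- table(factor(sim$truth$category,
                              levels = names(mix$counts)))
  expect_equal(unname(mix$counts), as.vector(truthCounts))
  expect_equal(mix$n, 200L)
  # per-read agreement, not just marginal counts
  expect_equal(mix$perRead$category, sim$truth$category)
})

test_that("wrong-HDR reads always retain an intact recognition site", {
  cfg <- simConfig(seed = 53L, nReads = 400L, errorRate = 0,
                   fractions = c(wt = 0, indel = 0, hdr_correct = 0,
                                 hdr_wrong = 1))
  fx <- makeLocusFixture(cfg)
  sim <- simulateReads(fx)
  expect_true(all(grepl("TCTAGA", as.character(sim$reads), fixed = TRUE)))
  out <- classifyReads(sim$reads, fx$experiment, "hdr")
  expect_true(all(out$hdr_label == "Wrong"))
})

test_that("FASTQ export round-trips reads and qualities", {
  cfg <- simConfig(seed = 61L, nReads = 40L)
  fx <- makeLocusFixture(cfg)
  sim <- simulateReads(fx)
  fq <- tempfile(fileext = ".fastq")
  truthTsv <- tempfile(fileext = ".tsv")
  writeSimulatedFastq(sim, fq, truthTsv)
  expect_equal(length(readLines(fq)), 4L * 40L)
  back <- readAmpliconFastq(fq)
  expect_length(back, 40L)
  expect_identical(as.character(back), as.character(sim$reads))
  expect_identical(names(back), names(sim$reads))
  truth <- utils::read.delim(truthTsv)
  expect_equal(truth$read_id, names(sim$reads))
})
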