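#' Simulation configuration
#'
#' Parameters for the synthetic amplicon experiment: a random background
#' sequence with one embedded matched target site, and a read mixture of
#' wild-type, indel-bearing, correctly HDR-edited (restriction site
#' inserted) and erroneously HDR-edited (site plus an extra indel)
#' molecules with per-base substitution sequencing errors.
#'
#' The defaults emulate a deep-sequenced HDR editing experiment: 10,000
#' reads mixing 60% wild-type, 30% indel, 7% correct and 3% wrong
#' incorporation at a 0.1% substitution error rate.
#'
#' @param seed Integer RNG seed (mandatory; all randomness derives from it).
#' @param referenceLength Reference amplicon length in nt.
#' @param combo Matched-site combo for [scanMatchedSites()].
#' @param spacerLen Embedded spacer length in nt.
#' @param nReads Number of simulated reads.
#' @param fractions Named numeric `(wt, indel, hdr_correct, hdr_wrong)`
#'   summing to 1.
#' @param indelGeomProb Geometric success probability for indel lengths
#'   (length = 1 + Geom(p), truncated at `maxIndelLen`).
#' @param maxIndelLen Indel length truncation (default 25 nt).
#' @param insFraction Probability that a sampled indel is an insertion.
#' @param errorRate Per-base substitution error rate, in [0, 0.05].
#' @param readLength Read length; NA (default) emits full-length amplicon
#'   reads.
#' @param insertSeq Donor insert / recognition sequence (XbaI TCTAGA).
#' @param windowSize Classification window half-width in bp.
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(seed,
                      referenceLength = 240L,
                      combo = "cpf1_sp_sa",
                      spacerLen = 20L,
                      nReads = 10000L,
                      fractions = c(wt = 0.6, indel = 0.3,
                                    hdr_correct = 0.07, hdr_wrong = 0.03),
                      indelGeomProb = 0.3,
                      maxIndelLen = 25L,
                      insFraction = 0.5,
                      errorRate = 0.001,
                      readLength = NA_integer_,
                      insertSeq = "TCTAGA",
                      windowSize = 40L) {
  if (missing(seed) || is.na(seed)) stop("'seed' is mandatory")
  stopifnot(length(fractions) == 4L,
            all(names(fractions) == c("wt", "indel", "hdr_correct",
                                      "hdr_wrong")))
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must be >= 0 and sum to 1")
  if (errorRate < 0 || errorRate > 0.05)
    stop("'errorRate' must lie in [0, 0.05]")
  pat3 <- .COMBOS[[combo]]$pat3
  minLen <- spacerLen + 4L + nchar(pat3) + 2L * windowSize
  if (referenceLength < minLen)
    stop(sprintf("referenceLength %d too small to embed the site (need >= %d)",
                 referenceLength, minLen))
  structure(list(seed = as.integer(seed),
                 referenceLength = as.integer(referenceLength),
                 combo = combo, spacerLen = as.integer(spacerLen),
                 nReads = as.integer(nReads), fractions = fractions,
                 indelGeomProb = indelGeomProb,
                 maxIndelLen = as.integer(maxIndelLen),
                 insFraction = insFraction, errorRate = errorRate,
                 readLength = as.integer(readLength),
                 insertSeq = toupper(insertSeq),
                 windowSize = as.integer(windowSize)),
            class = "SimConfig")
}

.randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Build a synthetic locus fixture
#'
#' Generates a random background amplicon with exactly one embedded matched
#' target site of the requested combo (re-drawing the background until the
#' scanner reports a single site and the recognition sequence is absent
#' from the unedited amplicon, so the restriction readout stays
#' identifiable), the corresponding donor-modified
#' reference (insert placed between the Cas9 cut and the Cpf1 non-target
#' nick), a symmetric 47/47 NT ssODN donor, and the ready-to-use
#' [AmpliconExperiment-class]. Deterministic under the config seed.
#'
#' @param config A [simConfig()].
#' @param maxAttempts Background re-draws before giving up.
#' @return A list of class `"LocusFixture"`: `reference` (named
#'   [Biostrings::DNAStringSet]), `site` (GRanges), `experiment`,
#'   `donor`, `cas9Nuclease`, `cpf1Nuclease`, `config`.
#' @export
makeLocusFixture <- function(config, maxAttempts = 100L) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  cdef <- .COMBOS[[config$combo]]
  pat3 <- cdef$pat3
  L <- config$spacerLen
  if (L < cdef$lenRange[1] || L > cdef$lenRange[2])
    stop(sprintf("spacerLen %d outside combo '%s' range [%d, %d]", L,
                 config$combo, cdef$lenRange[1], cdef$lenRange[2]))
  n <- config$referenceLength
  spacerStart0 <- as.integer((n - L) %/% 2)
  casStart0 <- spacerStart0 - 4L
  for (attempt in seq_len(maxAttempts)) {
    cassette <- paste0("TTT", sample(c("A", "C", "G", "T"), 1L),
                       .randomDna(L), realizeIupac(pat3))
    bg <- .randomDna(n)
    ref <- paste0(substr(bg, 1L, casStart0),
                  cassette,
                  substr(bg, casStart0 + nchar(cassette) + 1L, n))
    sites <- scanMatchedSites(ref, config$combo, c(17L, 25L),
                              seqId = "synthetic_locus")
    if (length(sites) == 1L &&
        as.character(strand(sites)) == "+" &&
        start(sites) == spacerStart0 + 1L &&
        !grepl(config$insertSeq, ref, fixed = TRUE)) break
    if (attempt == maxAttempts)
      stop("could not embed a unique matched site; increase maxAttempts")
  }
  cas9Name <- intersect(c("SpCas9", "SaCas9", "NmCas9"), cdef$compatible)[1]
  cpf1Name <- "LbCpf1"
  ip <- insertionPointBetweenCuts(sites, sites,
                                  nucleaseProfile(cas9Name),
                                  nucleaseProfile(cpf1Name))
  experiment <- ampliconExperiment(ref, sites, config$windowSize,
                                   insertionPoint0 = ip,
                                   insertSeq = config$insertSeq)
  donor <- designSsodn(ref, ip, config$insertSeq, 47L, 47L, "NT",
                       targetStrand = "-", locusId = "synthetic_locus")
  refSet <- Biostrings::DNAStringSet(ref)
  names(refSet) <- "synthetic_locus"
  structure(list(reference = refSet, site = sites, experiment = experiment,
                 donor = donor, cas9Nuclease = cas9Name,
                 cpf1Nuclease = cpf1Name, config = config),
            class = "LocusFixture")
}

# Sample one indel into `template`. posChoices are candidate 0-based
# positions (inter-base for insertions, first-deleted-base for deletions);
# forbidden is an optional 0-based half-open interval deletions must not
# overlap and insertions must not split.
.sampleIndel <- function(template, posChoices, config, forbidden = NULL) {
  n <- nchar(template)
  isIns <- stats::runif(1) < config$insFraction
  len <- min(stats::rgeom(1, config$indelGeomProb) + 1L, config$maxIndelLen)
  if (isIns) {
    ok <- posChoices
    if (!is.null(forbidden) && forbidden[2] - forbidden[1] > 1)
      ok <- ok[ok <= forbidden[1] | ok >= forbidden[2]]
    pos0 <- if (length(ok) == 1L) ok else sample(ok, 1L)
    ins <- .randomDna(len)
    seqOut <- paste0(substr(template, 1L, pos0), ins,
                     substr(template, pos0 + 1L, n))
    list(seq = seqOut, type = "Insertion", len = len, pos0 = pos0)
  } else {
    ok <- posChoices[posChoices + len <= n]
    if (!is.null(forbidden))
      ok <- ok[ok + len <= forbidden[1] | ok >= forbidden[2]]
    if (!length(ok)) {           # fall back to a 1-nt deletion
      len <- 1L
      ok <- posChoices[posChoices + 1L <= n]
      if (!is.null(forbidden))
        ok <- ok[ok + 1L <= forbidden[1] | ok >= forbidden[2]]
    }
    pos0 <- if (length(ok) == 1L) ok else sample(ok, 1L)
    seqOut <- paste0(substr(template, 1L, pos0),
                     substr(template, pos0 + len + 1L, n))
    list(seq = seqOut, type = "Deletion", len = len, pos0 = pos0)
  }
}

.applySubstitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in hit) {
      alt <- setdiff(bases, ch[i])
      ch[i] <- if (length(alt)) sample(alt, 1L) else ch[i]
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate amplicon reads with ground truth
#'
#' Draws per-category read counts from a seeded multinomial over the
#' configured fractions, builds each read from its category template
#' (wild-type = reference; indel = reference with one indel intersecting
#' the spacer, placed near the Cas9 cut; correct HDR = modified reference;
#' wrong HDR = modified reference with one extra indel in the window that
#' leaves the recognition site intact), applies substitution sequencing
#' errors, and records per-read truth labels in the classifier's
#' vocabularies. Deterministic under `config$seed` (a distinct stream,
#' seed + 1, from the fixture's).
#'
#' @param fixture A [makeLocusFixture()] result.
#' @param config The [simConfig()] (defaults to the fixture's).
#' @return A list of class `"SimReads"`: `reads` (named
#'   [Biostrings::DNAStringSet]), `qualities` (constant Phred+33 Q30
#'   [Biostrings::BStringSet]), `truth` ([S4Vectors::DataFrame]: read_id,
#'   category, nhej_label, hdr_label, indel_type, indel_len), `counts`
#'   (realized category counts, summing to `nReads`).
#' @export
simulateReads <- function(fixture, config = fixture$config) {
  stopifnot(inherits(fixture, "LocusFixture"), inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  exp <- fixture$experiment
  ref <- exp@referenceSeq
  modRef <- exp@modifiedReferenceSeq
  insLen <- nchar(exp@insertSeq)
  ip <- exp@insertionPoint0
  cut0 <- cas9CutSite(fixture$site, nucleaseProfile(fixture$cas9Nuclease))
  # indel positions: near the cut but strictly inside the spacer
  indelPos <- max(exp@spacerStart0 + 1L, cut0 - 5L):
    min(exp@spacerEnd0 - 1L, cut0 + 5L)
  mw <- modWindow0(exp)
  # wrong-HDR indels model imperfect junction repair: keep them near the
  # insert and clear of the window edges so left-aligned events cannot
  # slide out of the classification window
  wrongPos <- max(mw[1] + 1L, ip - config$maxIndelLen):
    min(mw[2] - 1L, ip + insLen + config$maxIndelLen)
  siteIv <- c(ip, ip + insLen)    # recognition interval, modified coords

  counts <- as.vector(stats::rmultinom(1L, config$nReads, config$fractions))
  names(counts) <- names(config$fractions)
  cats <- rep(names(counts), counts)

  seqs <- character(length(cats))
  indelType <- rep(NA_character_, length(cats))
  indelLen <- rep(NA_integer_, length(cats))
  for (i in seq_along(cats)) {
    seqs[i] <- switch(cats[i],
      wt = ref,
      hdr_correct = modRef,
      indel = {
        ev <- .sampleIndel(ref, indelPos, config)
        indelType[i] <- ev$type; indelLen[i] <- ev$len; ev$seq
      },
      hdr_wrong = {
        ev <- .sampleIndel(modRef, wrongPos, config, forbidden = siteIv)
        indelType[i] <- ev$type; indelLen[i] <- ev$len; ev$seq
      })
  }
  seqs <- .applySubstitutions(seqs, config$errorRate)
  if (!is.na(config$readLength)) {
    mid <- (exp@spacerStart0 + exp@spacerEnd0) %/% 2L
    seqs <- vapply(seqs, function(s) {
      n <- nchar(s)
      if (n <= config$readLength) return(s)
      st <- min(max(0L, mid - config$readLength %/% 2L),
                n - config$readLength)
      substr(s, st + 1L, st + config$readLength)
    }, character(1), USE.NAMES = FALSE)
  }
  ord <- sample(length(cats))
  seqs <- seqs[ord]; cats <- cats[ord]
  indelType <- indelType[ord]; indelLen <- indelLen[ord]
  ids <- sprintf("read_%05d", seq_along(cats))
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- ids
  quals <- Biostrings::BStringSet(strrep("?", nchar(seqs)))  # Phred+33 Q30
  names(quals) <- ids
  nhejTruth <- ifelse(cats == "indel", indelType, "Match")
  nhejTruth[cats == "hdr_wrong"] <- indelType[cats == "hdr_wrong"]
  hdrTruth <- c(wt = "No", indel = "No", hdr_correct = "Correct",
                hdr_wrong = "Wrong")[cats]
  truth <- S4Vectors::DataFrame(read_id = ids, category = cats,
                                nhej_label = unname(nhejTruth),
                                hdr_label = unname(hdrTruth),
                                indel_type = indelType,
                                indel_len = indelLen)
  structure(list(reads = reads, qualities = quals, truth = truth,
                 counts = counts),
            class = "SimReads")
}

#' Write simulated reads as FASTQ (plus truth TSV)
#'
#' @param sim A [simulateReads()] result.
#' @param fastqPath Output FASTQ path.
#' @param truthPath Optional TSV path for the per-read truth table.
#' @return (Invisibly) `fastqPath`.
#' @export
writeSimulatedFastq <- function(sim, fastqPath, truthPath = NULL) {
  stopifnot(inherits(sim, "SimReads"))
  Biostrings::writeXStringSet(sim$reads, fastqPath, format = "fastq",
                              qualities = sim$qualities)
  if (!is.null(truthPath))
    utils::write.table(as.data.frame(sim$truth), truthPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(fastqPath)
}

#' Read amplicon reads from a FASTQ file
#'
#' @param path FASTQ path. Base qualities are read but not used by the
#'   classifier (no quality-aware step exists in the outcome scheme); they
#'   are retained in the returned object for inspection.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
readAmpliconFastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # the reader always notes that FASTQ carries no metadata columns;
      # nothing is lost, so silence that message only
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
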