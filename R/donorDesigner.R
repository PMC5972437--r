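#' Insertion point between the Cas9 and Cpf1 cleavage positions
#'
#' For a matched locus cut by both a Cas9 (blunt cut) and a Cpf1 (staggered
#' cut; its annotated cleavage position is the non-target-strand nick), the
#' donor insert is placed between the two cleavage positions: at their
#' midpoint, rounded toward the Cas9 cut when the midpoint is not an
#' integer. Coincident cuts return that coordinate.
#'
#' @param cas9Site,cpf1Site One-row [GenomicRanges::GRanges] spacer
#'   intervals on the same sequence (e.g. the same matched site from
#'   [scanMatchedSites()], or a seed-overlapping pair).
#' @param cas9Profile,cpf1Profile Profiles of the two enzymes.
#' @return 0-based inter-base insertion coordinate.
#' @export
insertionPointBetweenCuts <- function(cas9Site, cpf1Site,
                                      cas9Profile = nucleaseProfile("SpCas9"),
                                      cpf1Profile = nucleaseProfile("LbCpf1")) {
  if (as.character(GenomicRanges::seqnames(cas9Site)) !=
      as.character(GenomicRanges::seqnames(cpf1Site)))
    stop("cas9Site and cpf1Site are on different sequences")
  a <- cas9CutSite(cas9Site, cas9Profile)
  b <- unname(cpf1CutSites(cpf1Site, cpf1Profile)["non_target"])
  if (a == b) return(as.integer(a))
  mid <- (a + b) / 2
  # round toward the Cas9 cut on half-integer midpoints
  as.integer(if (mid == floor(mid)) mid else if (a < b) floor(mid) else
    ceiling(mid))
}

.refAsChar <- function(reference) {
  if (is(reference, "DNAStringSet")) {
    stopifnot(length(reference) == 1L)
    toupper(as.character(reference[[1]]))
  } else if (is(reference, "DNAString")) {
    toupper(as.character(reference))
  } else {
    stopifnot(is.character(reference), length(reference) == 1L)
    toupper(reference)
  }
}

#' Design an ssODN donor template
#'
#' Builds a single-stranded oligo: `arm5` reference bases upstream of the
#' insertion point + insert + `arm3` reference bases downstream, then
#' reverse-complements the whole oligo if needed so that the emitted
#' sequence has the requested strand identity. "T" emits the target-strand
#' sequence (the strand the guide RNA base-pairs with), "NT" the
#' non-target-strand sequence; which reference strand is the target strand
#' is given by `targetStrand`.
#'
#' Arm arguments are counted on the reference plus strand (upstream /
#' downstream of the insertion point); the stored `arm5`/`arm3` slots are
#' re-labelled to the emitted oligo's own 5'->3' orientation, so the NT
#' design of a locus is `reverseComplement(T design)` with swapped arms.
#'
#' @param reference Reference sequence (character, DNAString or length-1
#'   DNAStringSet).
#' @param insertionPoint0 0-based inter-base insertion coordinate.
#' @param insertSeq Insert (plus-strand orientation), e.g. XbaI "TCTAGA".
#' @param arm5,arm3 Homology-arm lengths (nt) upstream/downstream of the
#'   insertion point on the plus strand.
#' @param strandIdentity "NT" or "T".
#' @param targetStrand Which reference strand ("+" or "-") is the target
#'   strand. For a plus-strand protospacer the target strand is "-".
#' @param locusId Locus label recorded in the design.
#' @param anchorNuclease Optional enzyme name the PAM-proximal/distal arm
#'   labels refer to.
#' @return A [DonorDesign-class].
#' @examples
#' ref <- strrep("ACGT", 60)
#' d <- designSsodn(ref, 120, "TCTAGA", 47, 47, "NT")
#' nchar(d@oligoSeq)  # 100
#' @export
designSsodn <- function(reference, insertionPoint0, insertSeq, arm5, arm3,
                        strandIdentity = c("NT", "T"), targetStrand = "-",
                        locusId = "locus", anchorNuclease = "") {
  strandIdentity <- match.arg(strandIdentity)
  stopifnot(targetStrand %in% c("+", "-"), arm5 >= 1L, arm3 >= 1L)
  s <- .refAsChar(reference)
  n <- nchar(s)
  ip <- as.integer(insertionPoint0)
  if (ip - arm5 < 0L)
    stop(sprintf("5' arm exceeds reference start by %d nt", arm5 - ip))
  if (ip + arm3 > n)
    stop(sprintf("3' arm exceeds reference end by %d nt", ip + arm3 - n))
  up <- substr(s, ip - arm5 + 1L, ip)
  down <- substr(s, ip + 1L, ip + arm3)
  plusOligo <- paste0(up, toupper(insertSeq), down)
  # the plus-strand oligo has identity T iff the plus strand is the target
  plusIdentity <- if (targetStrand == "+") "T" else "NT"
  if (strandIdentity == plusIdentity) {
    oligo <- plusOligo; a5 <- arm5; a3 <- arm3
  } else {
    oligo <- revComp(plusOligo); a5 <- arm3; a3 <- arm5
  }
  new("DonorDesign", locusId = locusId, insertSeq = toupper(insertSeq),
      insertionPoint0 = ip, arm5 = as.integer(a5), arm3 = as.integer(a3),
      strandIdentity = strandIdentity, anchorNuclease = anchorNuclease,
      oligoSeq = oligo)
}

#' Evidence-based recommended ssODN design for a nuclease
#'
#' Returns the donor architecture found to maximise HDR for each supported
#' enzyme: for SpCas9 an asymmetric target-strand (T) ssODN with the long
#' arm on the PAM-distal side (37/77); for the Cpf1 nucleases an asymmetric
#' non-target-strand (NT) ssODN with the long arm on the PAM-proximal side.
#' The insert is placed at the enzyme's own cleavage position (blunt cut
#' for Cas9, non-target-strand nick for Cpf1). SaCas9 and NmCas9 have no
#' supported recommendation (they showed little ssODN-mediated HDR in the
#' underlying screen) and raise an error.
#'
#' @param nuclease "SpCas9", "AsCpf1" or "LbCpf1" (name or profile).
#' @param site One-row [GenomicRanges::GRanges] spacer interval.
#' @param insertSeq Insert sequence, e.g. XbaI "TCTAGA".
#' @param reference Reference sequence the site lies on.
#' @param armShort,armLong Short/long arm lengths (defaults 37/77 nt).
#' @param locusId Locus label.
#' @return A [DonorDesign-class] with `anchorNuclease` set.
#' @export
recommendedDesign <- function(nuclease, site, insertSeq, reference,
                              armShort = 37L, armLong = 77L,
                              locusId = "locus") {
  profile <- nucleaseProfile(nuclease)
  if (profile@name %in% c("SaCas9", "NmCas9"))
    stop(sprintf("no recommendation in source study for %s ssODN donors",
                 profile@name))
  st <- as.character(strand(site))
  if (profile@pamSide == "three_prime") {
    ip <- cas9CutSite(site, profile)
    identity <- "T"
    # PAM is 3' of the protospacer: genomically right for "+" sites. The
    # long arm goes PAM-distal.
    pamRight <- st == "+"
    arms <- if (pamRight) c(armLong, armShort) else c(armShort, armLong)
  } else {
    ip <- unname(cpf1CutSites(site, profile)["non_target"])
    identity <- "NT"
    # PAM is 5' of the protospacer: genomically left for "+" sites. The
    # long arm goes PAM-proximal.
    pamLeft <- st == "+"
    arms <- if (pamLeft) c(armLong, armShort) else c(armShort, armLong)
  }
  targetStrand <- if (st == "+") "-" else "+"
  designSsodn(reference, ip, insertSeq, arm5 = arms[1], arm3 = arms[2],
              strandIdentity = identity, targetStrand = targetStrand,
              locusId = locusId, anchorNuclease = profile@name)
}

#' In-silico restriction digest
#'
#' Predicts RFLP fragment lengths by cutting an amplicon at every exact,
#' non-overlapping occurrence of a recognition sequence. The cut falls
#' `cutOffset` nt into the recognition site (default 1, the XbaI T^CTAGA
#' convention); fragment lengths always sum to the amplicon length.
#'
#' @param amplicon Amplicon sequence (character or DNAString).
#' @param recognitionSeq Recognition sequence (>= 4 nt).
#' @param cutOffset Cut position within the recognition site, 0-based.
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @examples
#' inSilicoDigest(paste0(strrep("A", 40), "TCTAGA", strrep("G", 54)),
#'                "TCTAGA")
#' @export
inSilicoDigest <- function(amplicon, recognitionSeq, cutOffset = 1L) {
  s <- .refAsChar(amplicon)
  rec <- toupper(recognitionSeq)
  stopifnot(nchar(rec) >= 4L, cutOffset >= 0L, cutOffset <= nchar(rec))
  n <- nchar(s)
  m <- Biostrings::matchPattern(rec, Biostrings::DNAString(s))
  starts0 <- BiocGenerics::start(m) - 1L
  # keep non-overlapping occurrences, leftmost-greedy
  keep <- integer()
  lastEnd <- 0L
  for (st in starts0) {
    if (st >= lastEnd) { keep <- c(keep, st); lastEnd <- st + nchar(rec) }
  }
  cuts <- keep + cutOffset
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  as.integer(diff(c(0L, cuts, n)))
}

#' Write donor designs as FASTA plus a TSV manifest
#'
#' @param designs A list of [DonorDesign-class] objects.
#' @param fastaPath,tsvPath Output paths (`tsvPath` defaults to `fastaPath`
#'   with a `.tsv` extension).
#' @return (Invisibly) `fastaPath`.
#' @export
writeDonorFasta <- function(designs, fastaPath,
                            tsvPath = sub("\\.[^.]*$", ".tsv", fastaPath)) {
  if (is(designs, "DonorDesign")) designs <- list(designs)
  nm <- vapply(designs, function(d)
    sprintf("%s_%s_%d-%d", d@locusId, d@strandIdentity, d@arm5, d@arm3),
    character(1))
  seqs <- Biostrings::DNAStringSet(vapply(designs, slot, character(1),
                                          "oligoSeq"))
  names(seqs) <- nm
  Biostrings::writeXStringSet(seqs, fastaPath)
  man <- data.frame(
    name = nm,
    locus = vapply(designs, slot, character(1), "locusId"),
    strand_identity = vapply(designs, slot, character(1), "strandIdentity"),
    arm5 = vapply(designs, slot, integer(1), "arm5"),
    arm3 = vapply(designs, slot, integer(1), "arm3"),
    insert = vapply(designs, slot, character(1), "insertSeq"),
    length = vapply(designs, function(d) nchar(d@oligoSeq), integer(1)))
  utils::write.table(man, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fastaPath)
}
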