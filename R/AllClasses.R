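#' @import methods
NULL

#' NucleaseProfile: PAM grammar and cut-site model of a Cas nuclease
#'
#' Describes everything the package needs to know about one programmable
#' nuclease: its PAM pattern (IUPAC), which side of the protospacer the PAM
#' sits on, the PAM-proximal seed length, the cut-site model (a blunt
#' double-strand cut at a fixed offset from the PAM for Cas9-family enzymes,
#' or a staggered pair of per-strand nicks for Cpf1/Cas12a-family enzymes)
#' and the spacer-length range over which the enzyme is considered optimally
#' active.
#'
#' Cut offsets are expressed in nucleotides from the PAM boundary on the
#' protospacer side: a blunt offset of 3 places the cut 3 bp 5' of the first
#' PAM base (Cas9 convention); staggered offsets of 18/23 place the
#' non-target-strand nick 18 nt and the target-strand nick 23 nt 3' of the
#' last PAM base (Cpf1 convention), leaving a 5' overhang.
#'
#' @slot name Enzyme identifier, e.g. "SpCas9".
#' @slot pamPattern IUPAC pattern string, e.g. "NGG" or "TTTN".
#' @slot pamSide Either "three_prime" (PAM 3' of the protospacer, Cas9) or
#'   "five_prime" (PAM 5' of the protospacer, Cpf1).
#' @slot seedLen PAM-proximal seed length in nt (7 for all built-ins).
#' @slot cutType "blunt" or "staggered".
#' @slot cutOffset Blunt cut offset in bp from the PAM boundary (NA for
#'   staggered profiles).
#' @slot nonTargetOffset,targetOffset Staggered nick offsets in nt 3' of the
#'   PAM for the non-target and target strand (NA for blunt profiles).
#' @slot optimalSpacerMin,optimalSpacerMax Inclusive optimal spacer-length
#'   bounds in nt; `optimalSpacerMax = NA` means unbounded above.
#'
#' @seealso [nucleaseProfile()], [registerNuclease()], [cas9CutSite()],
#'   [cpf1CutSites()]
#' @export
setClass("NucleaseProfile",
  representation(
    name = "character",
    pamPattern = "character",
    pamSide = "character",
    seedLen = "integer",
    cutType = "character",
    cutOffset = "integer",
    nonTargetOffset = "integer",
    targetOffset = "integer",
    optimalSpacerMin = "integer",
    optimalSpacerMax = "integer"
  )
)

setValidity("NucleaseProfile", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  pat <- object@pamPattern
  if (length(pat) != 1L || !nzchar(pat)) {
    msg <- c(msg, "'pamPattern' must be a single non-empty string")
  } else if (!all(strsplit(pat, "")[[1]] %in% names(IUPAC_SETS))) {
    msg <- c(msg, sprintf("'pamPattern' (%s) contains non-IUPAC characters", pat))
  }
  if (!object@pamSide %in% c("three_prime", "five_prime"))
    msg <- c(msg, "'pamSide' must be 'three_prime' or 'five_prime'")
  if (is.na(object@seedLen) || object@seedLen < 1L)
    msg <- c(msg, "'seedLen' must be >= 1")
  if (!object@cutType %in% c("blunt", "staggered"))
    msg <- c(msg, "'cutType' must be 'blunt' or 'staggered'")
  if (object@cutType == "blunt" && is.na(object@cutOffset))
    msg <- c(msg, "blunt profiles need a 'cutOffset'")
  if (object@cutType == "staggered" &&
      (is.na(object@nonTargetOffset) || is.na(object@targetOffset)))
    msg <- c(msg, "staggered profiles need 'nonTargetOffset' and 'targetOffset'")
  if (!is.na(object@optimalSpacerMax) &&
      object@optimalSpacerMin > object@optimalSpacerMax)
    msg <- c(msg, "'optimalSpacerMin' must be <= 'optimalSpacerMax'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NucleaseProfile", function(object) {
  side <- if (object@pamSide == "three_prime") "3' of protospacer" else
    "5' of protospacer"
  cut <- if (object@cutType == "blunt") {
    sprintf("blunt, %d bp from PAM", object@cutOffset)
  } else {
    sprintf("staggered, nicks %d/%d nt from PAM (5' overhang %d nt)",
            object@nonTargetOffset, object@targetOffset,
            object@targetOffset - object@nonTargetOffset)
  }
  upper <- if (is.na(object@optimalSpacerMax)) "" else object@optimalSpacerMax
  cat("NucleaseProfile:", object@name, "\n",
      "  PAM: ", object@pamPattern, " (", side, ")\n",
      "  seed: PAM-proximal ", object@seedLen, " nt\n",
      "  cut: ", cut, "\n",
      "  optimal spacer length: ", object@optimalSpacerMin, "-", upper,
      " nt\n", sep = "")
})

#' DonorDesign: an ssODN repair template
#'
#' A single-stranded oligodeoxynucleotide donor built around an insertion
#' point in a reference locus: 5' homology arm, insert (typically a
#' restriction-site sequence such as XbaI TCTAGA), 3' homology arm. The
#' oligo can be emitted as either the target-strand sequence ("T", the
#' strand the guide RNA base-pairs with) or the non-target-strand sequence
#' ("NT"); arm lengths are recorded relative to the emitted oligo's own
#' 5'->3' orientation, so the NT design of a locus is the exact reverse
#' complement of the T design with the arm labels swapped.
#'
#' @slot locusId Locus/sequence identifier.
#' @slot insertSeq Insert sequence (plus-strand reference orientation).
#' @slot insertionPoint0 0-based inter-base insertion coordinate on the
#'   plus strand of the reference.
#' @slot arm5,arm3 Homology-arm lengths (nt) on the emitted oligo's 5' and
#'   3' sides.
#' @slot strandIdentity "NT" or "T".
#' @slot anchorNuclease Enzyme whose PAM defines "PAM-proximal/distal" arm
#'   labels for this design ("" when not applicable).
#' @slot oligoSeq The emitted single-stranded oligo sequence.
#'
#' @seealso [designSsodn()], [recommendedDesign()]
#' @export
setClass("DonorDesign",
  representation(
    locusId = "character",
    insertSeq = "character",
    insertionPoint0 = "integer",
    arm5 = "integer",
    arm3 = "integer",
    strandIdentity = "character",
    anchorNuclease = "character",
    oligoSeq = "character"
  )
)

setValidity("DonorDesign", function(object) {
  msg <- character()
  if (!object@strandIdentity %in% c("NT", "T"))
    msg <- c(msg, "'strandIdentity' must be 'NT' or 'T'")
  if (object@arm5 < 1L || object@arm3 < 1L)
    msg <- c(msg, "homology arms must be >= 1 nt")
  total <- object@arm5 + nchar(object@insertSeq) + object@arm3
  if (nchar(object@oligoSeq) != total)
    msg <- c(msg, sprintf(
      "oligo length (%d) != arm5 + insert + arm3 (%d)",
      nchar(object@oligoSeq), total))
  if (length(msg)) msg else TRUE
})

setMethod("show", "DonorDesign", function(object) {
  cat("DonorDesign (", object@strandIdentity, " strand) at ", object@locusId,
      "\n  arms: ", object@arm5, "/", object@arm3, " nt, insert ",
      object@insertSeq, " (", nchar(object@insertSeq), " nt), total ",
      nchar(object@oligoSeq), " nt\n",
      "  insertion point (plus strand, inter-base): ",
      object@insertionPoint0, "\n", sep = "")
  if (nzchar(object@anchorNuclease))
    cat("  arm labels anchored to:", object@anchorNuclease, "\n")
  cat("  oligo: ", substr(object@oligoSeq, 1, 60),
      if (nchar(object@oligoSeq) > 60) "..." else "", "\n", sep = "")
})

#' AmpliconExperiment: reference context for read classification
#'
#' Bundles the reference amplicon, the protospacer interval, the
#' classification window (spacer +/- `windowSize` bp, clipped to the
#' reference) and, for HDR experiments, the modified reference carrying the
#' donor insert together with the restriction-site recognition sequence
#' whose presence defines HDR incorporation.
#'
#' All coordinates are 0-based half-open on the reference plus strand.
#'
#' @slot referenceSeq Unedited reference amplicon (plus strand).
#' @slot spacerStart0,spacerEnd0 Protospacer interval, 0-based half-open.
#' @slot windowSize Window extension in bp on each side of the spacer
#'   (default 40).
#' @slot insertionPoint0 Insertion point of the donor insert (NA when no
#'   HDR mode is configured).
#' @slot insertSeq Donor insert sequence ("" when absent).
#' @slot recognitionSeq Restriction-site recognition sequence scored for
#'   HDR incorporation ("" when absent).
#' @slot modifiedReferenceSeq Reference with the insert applied ("" when
#'   absent).
#'
#' @seealso [ampliconExperiment()], [classifyReads()]
#' @export
setClass("AmpliconExperiment",
  representation(
    referenceSeq = "character",
    spacerStart0 = "integer",
    spacerEnd0 = "integer",
    windowSize = "integer",
    insertionPoint0 = "integer",
    insertSeq = "character",
    recognitionSeq = "character",
    modifiedReferenceSeq = "character"
  )
)

setValidity("AmpliconExperiment", function(object) {
  msg <- character()
  n <- nchar(object@referenceSeq)
  if (n < 1L) msg <- c(msg, "empty reference sequence")
  if (object@spacerStart0 < 0L || object@spacerEnd0 > n ||
      object@spacerStart0 >= object@spacerEnd0)
    msg <- c(msg, "spacer interval must be non-empty and within the reference")
  if (object@windowSize < 0L) msg <- c(msg, "'windowSize' must be >= 0")
  if (nzchar(object@modifiedReferenceSeq)) {
    ip <- object@insertionPoint0
    if (is.na(ip) || !nzchar(object@insertSeq)) {
      msg <- c(msg, "modified reference requires insertionPoint0 and insertSeq")
    } else {
      expect <- paste0(substr(object@referenceSeq, 1L, ip), object@insertSeq,
                       substr(object@referenceSeq, ip + 1L, n))
      if (object@modifiedReferenceSeq != expect)
        msg <- c(msg,
          "modified reference must differ from the reference only by the insert at insertionPoint0")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AmpliconExperiment", function(object) {
  w <- refWindow0(object)
  cat("AmpliconExperiment\n",
      "  reference: ", nchar(object@referenceSeq), " bp; spacer [",
      object@spacerStart0, ",", object@spacerEnd0, "); window [",
      w[1], ",", w[2], ")\n", sep = "")
  if (nzchar(object@modifiedReferenceSeq))
    cat("  HDR mode: insert ", object@insertSeq, " at ",
        object@insertionPoint0, "; recognition ", object@recognitionSeq,
        "\n", sep = "")
})

#' EditingSummary: per-experiment editing-outcome tallies
#'
#' Read counts per NHEJ category (Insertion / Deletion / Match, scored
#' within the spacer window) and, when HDR classification was run, per HDR
#' category (Correct / Wrong / No incorporation), with the derived indel and
#' correct-incorporation percentages. Percentages use aligned reads as the
#' denominator; unaligned reads are counted in `nTotal` only.
#'
#' @slot nTotal,nAligned Total and aligned read counts.
#' @slot nInsertion,nDeletion,nMatch NHEJ category counts.
#' @slot indelPct 100 * (insertions + deletions) / aligned.
#' @slot nHdrCorrect,nHdrWrong,nHdrNo HDR category counts (NA outside HDR
#'   mode).
#' @slot hdrCorrectPct 100 * correct / aligned (NA outside HDR mode).
#'
#' @seealso [summarizeOutcomes()]
#' @export
setClass("EditingSummary",
  representation(
    nTotal = "integer", nAligned = "integer",
    nInsertion = "integer", nDeletion = "integer", nMatch = "integer",
    indelPct = "numeric",
    nHdrCorrect = "integer", nHdrWrong = "integer", nHdrNo = "integer",
    hdrCorrectPct = "numeric"
  )
)

setValidity("EditingSummary", function(object) {
  msg <- character()
  if (object@nInsertion + object@nDeletion + object@nMatch != object@nAligned)
    msg <- c(msg, "NHEJ category counts must sum to nAligned")
  if (!is.na(object@nHdrCorrect) &&
      object@nHdrCorrect + object@nHdrWrong + object@nHdrNo != object@nAligned)
    msg <- c(msg, "HDR category counts must sum to nAligned")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EditingSummary", function(object) {
  cat("EditingSummary: ", object@nAligned, "/", object@nTotal,
      " reads aligned\n",
      "  NHEJ: ", object@nInsertion, " Insertion, ", object@nDeletion,
      " Deletion, ", object@nMatch, " Match; indel% = ",
      formatC(object@indelPct, digits = 3, format = "fg"), "\n", sep = "")
  if (!is.na(object@nHdrCorrect))
    cat("  HDR:  ", object@nHdrCorrect, " Correct, ", object@nHdrWrong,
        " Wrong, ", object@nHdrNo, " No; correct% = ",
        formatC(object@hdrCorrectPct, digits = 3, format = "fg"), "\n",
        sep = "")
})

#' Recommendation: a nuclease/donor recommendation
#'
#' Output of the guideline rule engine: an ordered set of recommended
#' nucleases for an editing goal, optional donor-design advice per enzyme,
#' and the evidence rationale behind each branch.
#'
#' @slot goal "knockout" or "precise_edit".
#' @slot specificityCritical Whether off-target tolerance drove the choice.
#' @slot donor Donor type considered: "none", "ssODN" or "plasmid".
#' @slot nucleases Recommended enzymes, in preference order.
#' @slot donorAdvice Named list (per enzyme) of donor parameters, or empty.
#' @slot rationale Character vector of evidence statements (always >= 1).
#'
#' @seealso [recommendSystem()]
#' @export
setClass("Recommendation",
  representation(
    goal = "character",
    specificityCritical = "logical",
    donor = "character",
    nucleases = "character",
    donorAdvice = "list",
    rationale = "character"
  )
)

setValidity("Recommendation", function(object) {
  if (length(object@rationale) < 1L)
    "every recommendation must carry at least one rationale" else TRUE
})

setMethod("show", "Recommendation", function(object) {
  cat("Recommendation (goal: ", object@goal,
      if (object@specificityCritical) ", specificity-critical" else "",
      if (object@donor != "none") paste0(", donor: ", object@donor) else "",
      ")\n  nucleases: ", paste(object@nucleases, collapse = ", "), "\n",
      sep = "")
  if (length(object@donorAdvice))
    for (nm in names(object@donorAdvice)) {
      a <- object@donorAdvice[[nm]]
      cat("  donor for ", nm, ": ", a$strand, " strand, PAM-proximal arm ",
          a$armPamProximal, " nt / PAM-distal arm ", a$armPamDistal,
          " nt\n", sep = "")
    }
  cat("  rationale:\n")
  for (r in object@rationale) cat("   - ", r, "\n", sep = "")
})
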