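#' Construct an AmpliconExperiment
#'
#' @param reference Reference amplicon (character, DNAString or length-1
#'   DNAStringSet).
#' @param spacer Either a numeric `c(start0, end0)` 0-based half-open
#'   interval or a one-row [GenomicRanges::GRanges] spacer.
#' @param windowSize Classification window extension on each side of the
#'   spacer in bp (default 40); the window is clipped to the reference.
#' @param insertionPoint0,insertSeq Donor insert position/sequence; both
#'   given switch the experiment into HDR mode and build the modified
#'   reference.
#' @param recognitionSeq Restriction-site sequence scored for HDR
#'   incorporation (defaults to `insertSeq`).
#' @return An [AmpliconExperiment-class].
#' @export
ampliconExperiment <- function(reference, spacer, windowSize = 40L,
                               insertionPoint0 = NA_integer_,
                               insertSeq = "", recognitionSeq = insertSeq) {
  ref <- .refAsChar(reference)
  if (is(spacer, "GRanges")) {
    s0 <- .site0(spacer)
    spacer <- c(s0$start0, s0$end0)
  }
  hdr <- !is.na(insertionPoint0) && nzchar(insertSeq)
  modRef <- if (hdr) {
    paste0(substr(ref, 1L, insertionPoint0), toupper(insertSeq),
           substr(ref, insertionPoint0 + 1L, nchar(ref)))
  } else ""
  new("AmpliconExperiment",
      referenceSeq = ref,
      spacerStart0 = as.integer(spacer[1]), spacerEnd0 = as.integer(spacer[2]),
      windowSize = as.integer(windowSize),
      insertionPoint0 = as.integer(insertionPoint0),
      insertSeq = toupper(insertSeq),
      recognitionSeq = toupper(recognitionSeq),
      modifiedReferenceSeq = modRef)
}

#' Classification window on the unedited reference
#'
#' @param experiment An [AmpliconExperiment-class].
#' @param windowSize Optional override of the experiment's window size.
#' @return `c(start0, end0)`, 0-based half-open, clipped to the reference.
#' @export
refWindow0 <- function(experiment, windowSize = experiment@windowSize) {
  c(max(0L, experiment@spacerStart0 - windowSize),
    min(nchar(experiment@referenceSeq), experiment@spacerEnd0 + windowSize))
}

#' Classification window on the modified (donor-edited) reference
#'
#' Same window as [refWindow0()] but in modified-reference coordinates: the
#' right edge is shifted by the insert length (the insert always lies
#' between the two cleavage positions, inside the window).
#'
#' @inheritParams refWindow0
#' @return `c(start0, end0)` on the modified reference.
#' @export
modWindow0 <- function(experiment, windowSize = experiment@windowSize) {
  if (!nzchar(experiment@modifiedReferenceSeq))
    stop("experiment has no modified reference (HDR mode not configured)")
  w <- refWindow0(experiment, windowSize)
  ins <- nchar(experiment@insertSeq)
  c(w[1], min(nchar(experiment@modifiedReferenceSeq), w[2] + ins))
}

#' Default alignment scoring parameters
#'
#' Match +2, mismatch -2, gap open -6, gap extend -1 (a length-k gap costs
#' 6 + k).
#'
#' @return Named list of scores.
#' @export
defaultAlignScores <- function() {
  list(match = 2, mismatch = -2, gapOpen = -6, gapExtend = -1)
}

# Left-align one indel event against the reference (VCF-style
# normalisation): an event may shift left while the reference base before
# it equals the last base of the event's sequence. `floor0` bounds the
# shift (end of the previous event, or alignment start).
.leftAlignEvent <- function(type, pos0, seq, ref, floor0) {
  len <- nchar(seq)
  repeat {
    if (pos0 <= floor0) break
    prevBase <- substr(ref, pos0, pos0)          # ref base at pos0-1 (0-based)
    lastBase <- substr(seq, len, len)
    if (prevBase != lastBase) break
    seq <- paste0(prevBase, substr(seq, 1L, len - 1L))
    pos0 <- pos0 - 1L
  }
  list(pos0 = pos0, seq = seq)
}

# Per-read walk over the compact alignment representation: the internal
# insertion/deletion runs (alignment-column coordinates, as reported by
# Biostrings::indel()), the aligned-region bounds on read and reference,
# and the match count. Avoids materialising gapped alignment strings,
# which dominates runtime at amplicon depth. Returns events
# (left-aligned), identity, CIGAR and the read segment aligned to the
# reference window [ws, we).
.walkCompact <- function(readStr, ref, cols, insS, insW, delS, delW,
                         subjStart, subjEnd, patStart, patEnd, nMatch,
                         type, ws, we) {
  readLen <- nchar(readStr)
  refLen <- nchar(ref)
  # internal runs over alignment columns 1..cols
  evS <- c(insS, delS); evW <- c(insW, delW)
  evT <- c(rep("I", length(insS)), rep("D", length(delS)))
  o <- order(evS); evS <- evS[o]; evW <- evW[o]; evT <- evT[o]
  runT <- character(0); runW <- integer(0)
  pos <- 1L
  for (k in seq_along(evS)) {
    if (evS[k] > pos) { runT <- c(runT, "M"); runW <- c(runW, evS[k] - pos) }
    runT <- c(runT, evT[k]); runW <- c(runW, evW[k])
    pos <- evS[k] + evW[k]
  }
  if (pos <= cols) { runT <- c(runT, "M"); runW <- c(runW, cols - pos + 1L) }
  if (type == "global") {
    # terminal gaps are excluded from the column count and indel ranges
    # but are genuine scored events in full-global mode
    leadI <- patStart - 1L; trailI <- readLen - patEnd
    leadD <- subjStart - 1L; trailD <- refLen - subjEnd
    if (leadD > 0L) { runT <- c("D", runT); runW <- c(leadD, runW) }
    if (leadI > 0L) { runT <- c("I", runT); runW <- c(leadI, runW) }
    if (trailD > 0L) { runT <- c(runT, "D"); runW <- c(runW, trailD) }
    if (trailI > 0L) { runT <- c(runT, "I"); runW <- c(runW, trailI) }
    refC <- 0L
  } else {
    refC <- subjStart - 1L
  }
  # merge any adjacent same-type runs (possible at terminal joins)
  if (length(runT) > 1L) {
    same <- c(FALSE, runT[-1L] == runT[-length(runT)])
    if (any(same)) {
      grp <- cumsum(!same)
      runW <- as.integer(tapply(runW, grp, sum))
      runT <- runT[!same]
    }
  }

  readC <- 0L
  floor0 <- refC
  events <- list()
  segR1 <- NA_integer_; segR2 <- NA_integer_
  for (k in seq_along(runT)) {
    w <- runW[k]
    if (runT[k] == "M") {
      if (!is.null(ws)) {
        lo <- max(refC, ws); hi <- min(refC + w, we)
        if (lo < hi) {
          if (is.na(segR1)) segR1 <- readC + (lo - refC) + 1L
          segR2 <- readC + (hi - refC)
        }
      }
      refC <- refC + w; readC <- readC + w
    } else if (runT[k] == "I") {
      evSeq <- substr(readStr, readC + 1L, readC + w)
      la <- .leftAlignEvent("I", refC, evSeq, ref, floor0)
      events[[length(events) + 1L]] <- data.frame(
        type = "I", pos0 = la$pos0, len = w, seq = la$seq,
        stringsAsFactors = FALSE)
      floor0 <- la$pos0
      readC <- readC + w
    } else {
      evSeq <- substr(ref, refC + 1L, refC + w)
      la <- .leftAlignEvent("D", refC, evSeq, ref, floor0)
      events[[length(events) + 1L]] <- data.frame(
        type = "D", pos0 = la$pos0, len = w, seq = la$seq,
        stringsAsFactors = FALSE)
      floor0 <- la$pos0 + w
      refC <- refC + w
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), pos0 = integer(), len = integer(),
               seq = character(), stringsAsFactors = FALSE)
  segment <- if (!is.na(segR1)) substr(readStr, segR1, segR2) else ""
  list(events = events, identity = nMatch / sum(runW),
       cigar = paste0(runW, runT, collapse = ""), segment = segment)
}

#' Align amplicon reads to a reference
#'
#' Global (Needleman-Wunsch) or semi-global alignment of reads against a
#' short amplicon reference with affine gap penalties, via
#' [Biostrings::pairwiseAlignment()]. Indels are reported left-aligned
#' (shifted to their 5'-most equivalent position) so CIGARs are
#' deterministic across equivalent gap placements.
#'
#' @param reads [Biostrings::DNAStringSet] (or character vector) of reads.
#' @param reference Reference sequence.
#' @param scores Named list as from [defaultAlignScores()].
#' @param type `"global"` (both sequences end-to-end, the Needleman-Wunsch
#'   model) or `"global-local"` (read global, reference flanks free; for
#'   reads shorter than the amplicon).
#' @param window Optional `c(start0, end0)` reference window for which the
#'   aligned read segment is extracted (used by HDR classification).
#' @return A list with `table` (a [S4Vectors::DataFrame]: read_id, score,
#'   identity, cigar, offset0, segment) and `events` (per-read data.frames
#'   of indel events: type I/D, 0-based ref position, length, sequence).
#' @export
alignReads <- function(reads, reference, scores = defaultAlignScores(),
                       type = c("global", "global-local"), window = NULL) {
  type <- match.arg(type)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  ref <- .refAsChar(reference)
  ids <- if (!is.null(names(reads))) names(reads) else
    paste0("read", seq_along(reads))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scores$match, mismatch = scores$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    reads, Biostrings::DNAString(ref), type = type,
    substitutionMatrix = submat,
    gapOpening = -scores$gapOpen, gapExtension = -scores$gapExtend)
  cols <- Biostrings::nchar(aln)
  nMatch <- Biostrings::nmatch(aln)
  idl <- Biostrings::indel(aln)
  insAll <- Biostrings::insertion(idl)
  delAll <- Biostrings::deletion(idl)
  insS <- as.list(BiocGenerics::start(insAll))
  insW <- as.list(BiocGenerics::width(insAll))
  delS <- as.list(BiocGenerics::start(delAll))
  delW <- as.list(BiocGenerics::width(delAll))
  subjStart <- BiocGenerics::start(Biostrings::subject(aln))
  subjEnd <- BiocGenerics::end(Biostrings::subject(aln))
  patStart <- BiocGenerics::start(Biostrings::pattern(aln))
  patEnd <- BiocGenerics::end(Biostrings::pattern(aln))
  off0 <- subjStart - 1L
  scoreVec <- BiocGenerics::score(aln)
  readStrs <- as.character(reads)
  ws <- if (is.null(window)) NULL else window[1]
  we <- if (is.null(window)) NULL else window[2]
  walks <- lapply(seq_along(reads), function(i)
    .walkCompact(readStrs[i], ref, cols[i], insS[[i]], insW[[i]],
                 delS[[i]], delW[[i]], subjStart[i], subjEnd[i],
                 patStart[i], patEnd[i], nMatch[i], type, ws, we))
  tab <- S4Vectors::DataFrame(
    read_id = ids,
    score = scoreVec,
    identity = vapply(walks, `[[`, numeric(1), "identity"),
    cigar = vapply(walks, `[[`, character(1), "cigar"),
    offset0 = off0,
    segment = vapply(walks, `[[`, character(1), "segment"))
  list(table = tab, events = lapply(walks, `[[`, "events"))
}

#' Align a single read
#'
#' Convenience wrapper around [alignReads()] for one read.
#'
#' @inheritParams alignReads
#' @param read A single read (character or DNAString).
#' @param minReadLen Minimum read length (default 30); shorter reads error.
#' @return A list: `cigar`, `score`, `identity`, `offset0`, `events`.
#' @export
alignRead <- function(read, reference, scores = defaultAlignScores(),
                      type = c("global", "global-local"), minReadLen = 30L) {
  read <- as.character(read)
  if (nchar(read) < minReadLen)
    stop(sprintf("read length %d below minimum %d", nchar(read), minReadLen))
  res <- alignReads(read, reference, scores, type)
  tab <- res$table
  list(cigar = tab$cigar[1], score = tab$score[1],
       identity = tab$identity[1], offset0 = tab$offset0[1],
       events = res$events[[1]])
}

# Does an event intersect the window [ws, we)? Deletions by interval
# overlap; insertions by their inter-base point (window-inclusive).
.eventsInWindow <- function(events, ws, we) {
  if (!nrow(events)) return(events[0, ])
  del <- events$type == "D"
  keep <- logical(nrow(events))
  keep[del] <- events$pos0[del] < we & (events$pos0[del] + events$len[del]) > ws
  keep[!del] <- events$pos0[!del] >= ws & events$pos0[!del] <= we
  events[keep, , drop = FALSE]
}

#' NHEJ classification of one aligned read
#'
#' Labels a read by its indel events within the spacer window: any
#' insertion and no deletion -> "Insertion"; any deletion and no insertion
#' -> "Deletion"; neither (substitution-only reads included) -> "Match";
#' both -> the longest event wins, ties going to "Deletion".
#'
#' @param events Event data.frame for the read (from [alignReads()]),
#'   in the coordinates of the reference that defines `window0`.
#' @param window0 `c(start0, end0)` classification window.
#' @return One of "Insertion", "Deletion", "Match".
#' @export
classifyNhej <- function(events, window0) {
  ev <- .eventsInWindow(events, window0[1], window0[2])
  hasI <- any(ev$type == "I"); hasD <- any(ev$type == "D")
  if (hasI && hasD) {
    maxI <- max(ev$len[ev$type == "I"]); maxD <- max(ev$len[ev$type == "D"])
    if (maxI > maxD) "Insertion" else "Deletion"
  } else if (hasI) "Insertion" else if (hasD) "Deletion" else "Match"
}

#' HDR classification of one read aligned to the modified reference
#'
#' The restriction site is "present" when the recognition sequence occurs
#' exactly within the read segment aligned to the spacer window of the
#' modified reference (not genome-wide in the read, anchoring the call to
#' the edit locus). Present and NHEJ-Match -> "Correct"; present with an
#' indel -> "Wrong"; absent -> "No".
#'
#' @param windowSegment Read bases aligned to the modified-reference
#'   window (column `segment` of [alignReads()] run with `window =`
#'   [modWindow0()]).
#' @param nhejLabel The read's NHEJ label against the modified reference.
#' @param experiment An HDR-mode [AmpliconExperiment-class].
#' @return One of "Correct", "Wrong", "No".
#' @export
classifyHdr <- function(windowSegment, nhejLabel, experiment) {
  if (!nzchar(experiment@recognitionSeq) ||
      !nzchar(experiment@modifiedReferenceSeq))
    stop("HDR classification requires a modified reference and recognitionSeq")
  present <- grepl(experiment@recognitionSeq, windowSegment, fixed = TRUE)
  if (!present) "No" else if (nhejLabel == "Match") "Correct" else "Wrong"
}

#' Classify a set of amplicon reads
#'
#' Aligns reads to the experiment's reference ("nhej" mode) or modified
#' reference ("hdr" mode) and labels each read. Reads failing the identity
#' threshold (or shorter than `minReadLen`) are labelled "Unaligned" and
#' excluded from percentage denominators downstream.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector.
#' @param experiment An [AmpliconExperiment-class].
#' @param mode `"nhej"` (align to the unedited reference) or `"hdr"`
#'   (align to the modified reference and additionally score restriction-
#'   site incorporation).
#' @param scores,type Passed to [alignReads()].
#' @param minIdentity Minimum alignment identity over the aligned span
#'   (default 0.75).
#' @param minReadLen Reads shorter than this are "Unaligned" (default 30).
#' @return A [S4Vectors::DataFrame] with columns `read_id`, `nhej_label`
#'   ("Insertion"/"Deletion"/"Match"/"Unaligned"), `hdr_label`
#'   ("Correct"/"Wrong"/"No" or NA), `identity`, `score`, `cigar`.
#' @export
classifyReads <- function(reads, experiment, mode = c("nhej", "hdr"),
                          scores = defaultAlignScores(),
                          type = c("global", "global-local"),
                          minIdentity = 0.75, minReadLen = 30L) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (mode == "hdr") {
    if (!nzchar(experiment@modifiedReferenceSeq))
      stop("HDR mode requires an experiment with a modified reference")
    ref <- experiment@modifiedReferenceSeq
    win <- modWindow0(experiment)
  } else {
    ref <- experiment@referenceSeq
    win <- refWindow0(experiment)
  }
  res <- alignReads(reads, ref, scores, type, window = win)
  tab <- res$table
  tooShort <- Biostrings::width(reads) < minReadLen
  aligned <- !tooShort & tab$identity >= minIdentity
  nhej <- rep("Unaligned", length(reads))
  nhej[aligned] <- vapply(which(aligned), function(i)
    classifyNhej(res$events[[i]], win), character(1))
  hdr <- rep(NA_character_, length(reads))
  if (mode == "hdr")
    hdr[aligned] <- vapply(which(aligned), function(i)
      classifyHdr(tab$segment[i], nhej[i], experiment), character(1))
  S4Vectors::DataFrame(read_id = tab$read_id, nhej_label = nhej,
                       hdr_label = hdr, identity = tab$identity,
                       score = tab$score, cigar = tab$cigar)
}

#' Summarise per-read outcomes into editing percentages
#'
#' @param outcomes Output of [classifyReads()] (any object with
#'   `nhej_label` and optionally `hdr_label` columns).
#' @return An [EditingSummary-class]. With zero aligned reads the
#'   percentages are NA and a warning is raised.
#' @export
summarizeOutcomes <- function(outcomes) {
  stopifnot(length(outcomes$nhej_label) > 0L)
  nhej <- outcomes$nhej_label
  nTotal <- length(nhej)
  aligned <- nhej != "Unaligned"
  nAligned <- sum(aligned)
  nI <- sum(nhej == "Insertion"); nD <- sum(nhej == "Deletion")
  nM <- sum(nhej == "Match")
  indelPct <- if (nAligned == 0L) {
    warning("zero aligned reads; percentages are NA")
    NA_real_
  } else 100 * (nI + nD) / nAligned
  hdr <- outcomes$hdr_label
  hasHdr <- !is.null(hdr) && any(!is.na(hdr))
  if (hasHdr) {
    nC <- sum(hdr == "Correct", na.rm = TRUE)
    nW <- sum(hdr == "Wrong", na.rm = TRUE)
    nN <- sum(hdr == "No", na.rm = TRUE)
    hdrPct <- if (nAligned == 0L) NA_real_ else 100 * nC / nAligned
  } else {
    nC <- NA_integer_; nW <- NA_integer_; nN <- NA_integer_
    hdrPct <- NA_real_
  }
  new("EditingSummary", nTotal = nTotal, nAligned = nAligned,
      nInsertion = nI, nDeletion = nD, nMatch = nM, indelPct = indelPct,
      nHdrCorrect = nC, nHdrWrong = nW, nHdrNo = nN, hdrCorrectPct = hdrPct)
}

#' Estimate the four-way outcome mixture of an HDR experiment
#'
#' Classifies every read against both references and combines the labels
#' into the four molecular categories an HDR amplicon experiment mixes:
#' HDR-label "Correct" -> `hdr_correct`; "Wrong" -> `hdr_wrong`; "No" with
#' an indel against the unedited reference -> `indel`; "No" and Match
#' against the unedited reference -> `wt`. Reads unaligned in either pass
#' are excluded.
#'
#' @inheritParams classifyReads
#' @return A list: `counts` (named integer), `proportions` (of classified
#'   reads), `n` (classified reads), `perRead` (a [S4Vectors::DataFrame]
#'   with both label sets and the combined `category`).
#' @export
estimateOutcomeMixture <- function(reads, experiment,
                                   scores = defaultAlignScores(),
                                   type = c("global", "global-local"),
                                   minIdentity = 0.75, minReadLen = 30L) {
  type <- match.arg(type)
  nhejOut <- classifyReads(reads, experiment, "nhej", scores, type,
                           minIdentity, minReadLen)
  hdrOut <- classifyReads(reads, experiment, "hdr", scores, type,
                          minIdentity, minReadLen)
  ok <- nhejOut$nhej_label != "Unaligned" & hdrOut$nhej_label != "Unaligned"
  category <- rep(NA_character_, length(ok))
  category[ok & hdrOut$hdr_label == "Correct"] <- "hdr_correct"
  category[ok & hdrOut$hdr_label == "Wrong"] <- "hdr_wrong"
  noSite <- ok & hdrOut$hdr_label == "No"
  category[noSite & nhejOut$nhej_label %in% c("Insertion", "Deletion")] <-
    "indel"
  category[noSite & nhejOut$nhej_label == "Match"] <- "wt"
  lev <- c("wt", "indel", "hdr_correct", "hdr_wrong")
  counts <- table(factor(category, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  n <- sum(counts)
  list(counts = counts,
       proportions = if (n > 0) counts / n else counts * NA_real_,
       n = n,
       perRead = S4Vectors::DataFrame(read_id = nhejOut$read_id,
                                      nhej_vs_reference = nhejOut$nhej_label,
                                      nhej_vs_modified = hdrOut$nhej_label,
                                      hdr_label = hdrOut$hdr_label,
                                      category = category))
}

#' Write per-read outcomes and a JSON summary
#'
#' @param outcomes Output of [classifyReads()].
#' @param tsvPath Per-read TSV path.
#' @param jsonPath Optional JSON summary path.
#' @return (Invisibly) `tsvPath`.
#' @export
writeOutcomes <- function(outcomes, tsvPath, jsonPath = NULL) {
  utils::write.table(as.data.frame(outcomes), tsvPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath)) {
    s <- summarizeOutcomes(outcomes)
    jsonlite::write_json(list(
      n_total = s@nTotal, n_aligned = s@nAligned,
      n_insertion = s@nInsertion, n_deletion = s@nDeletion,
      n_match = s@nMatch, indel_pct = s@indelPct,
      n_hdr_correct = s@nHdrCorrect, n_hdr_wrong = s@nHdrWrong,
      n_hdr_no = s@nHdrNo, hdr_correct_pct = s@hdrCorrectPct),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsvPath)
}
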