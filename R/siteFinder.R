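#' @importFrom GenomicRanges GRanges strand start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

# Combined-PAM combos: 5' flank always TTTN (AsCpf1/LbCpf1); the 3' flank
# pattern folds the Cas9-family requirement(s) on top of SpCas9's NGG.
.COMBOS <- list(
  cpf1_sp_sa = list(pat3 = "NGGRRT",
                    compatible = c("SpCas9", "SaCas9", "AsCpf1", "LbCpf1"),
                    lenRange = c(17L, 25L)),
  cpf1_sp_nm = list(pat3 = "NGGNGATT",
                    compatible = c("SpCas9", "NmCas9", "AsCpf1", "LbCpf1"),
                    lenRange = c(17L, 25L)),
  cpf1_nm_long = list(pat3 = "NNNNGATT",
                      compatible = c("NmCas9", "AsCpf1", "LbCpf1"),
                      lenRange = c(24L, 25L))
)
.PAT5 <- "TTTN"

.asPlainSeq <- function(sequence) {
  # Accept character, DNAString, or a length-1 DNAStringSet (FASTA record).
  if (is(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    id <- if (!is.null(names(sequence))) names(sequence)[1] else "seq1"
    return(list(seq = toupper(as.character(sequence[[1]])), id = id))
  }
  if (is(sequence, "DNAString"))
    return(list(seq = toupper(as.character(sequence)), id = "seq1"))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  id <- if (!is.null(names(sequence))) names(sequence) else "seq1"
  list(seq = toupper(sequence), id = id)
}

# Scan one strand-oriented sequence for windows pat5 + spacer(L) + pat3.
# Returns a data.frame of window start0 (0-based, full window incl. flanks)
# and spacer length; excludes any window containing an ambiguous base.
.scanOneStrand <- function(s, pat5, pat3, lens) {
  n <- nchar(s)
  p5 <- nchar(pat5); p3 <- nchar(pat3)
  hits <- list()
  for (L in lens) {
    total <- p5 + L + p3
    if (n < total) next
    starts <- seq_len(n - total + 1L)       # 1-based window starts
    w5 <- substring(s, starts, starts + p5 - 1L)
    ok <- iupacMatchMany(w5, pat5)
    if (!any(ok)) next
    idx <- starts[ok]
    w3 <- substring(s, idx + p5 + L, idx + p5 + L + p3 - 1L)
    ok3 <- iupacMatchMany(w3, pat3)
    idx <- idx[ok3]
    if (!length(idx)) next
    # reject windows containing N anywhere (spacer or flanks)
    win <- substring(s, idx, idx + total - 1L)
    idx <- idx[!grepl("N", win, fixed = TRUE)]
    if (length(idx))
      hits[[length(hits) + 1L]] <- data.frame(winStart0 = idx - 1L, len = L)
  }
  if (!length(hits)) data.frame(winStart0 = integer(), len = integer())
  else do.call(rbind, hits)
}

#' Scan a sequence for multi-nuclease matched target sites
#'
#' Finds every window, on both strands, whose 5' flank matches the Cpf1 PAM
#' TTTN and whose 3' flank matches a combined Cas9-family pattern, so the
#' same protospacer can be targeted by several nucleases at once:
#' \describe{
#'   \item{`cpf1_sp_sa`}{3' flank NGGRRT; compatible with SpCas9, SaCas9,
#'     AsCpf1, LbCpf1.}
#'   \item{`cpf1_sp_nm`}{3' flank NGGNGATT; compatible with SpCas9, NmCas9,
#'     AsCpf1, LbCpf1.}
#'   \item{`cpf1_nm_long`}{3' flank NNNNGATT with 24-25 nt spacers;
#'     compatible with NmCas9, AsCpf1, LbCpf1.}
#' }
#' Windows containing ambiguous (N) bases are never reported. Hits of
#' different spacer lengths at the same locus are all kept, deduplicated by
#' (start, end, strand).
#'
#' @param sequence A character string, [Biostrings::DNAString] or length-1
#'   [Biostrings::DNAStringSet] (one FASTA record).
#' @param combo One of `"cpf1_sp_sa"`, `"cpf1_sp_nm"`, `"cpf1_nm_long"`.
#' @param spacerLenRange Inclusive spacer-length range to scan, within
#'   17-25 nt (intersected with 24-25 for `cpf1_nm_long`).
#' @param seqId Sequence name override (defaults to the FASTA name).
#' @return A [GenomicRanges::GRanges] over the spacer intervals (1-based,
#'   forward-strand coordinates; `strand` gives the protospacer strand),
#'   sorted by (start, strand), with metadata columns `spacer_seq`
#'   (protospacer-strand sequence), `combo`, `compatible` (CharacterList),
#'   `pam5_seq`/`pam3_seq` (flank sequences in protospacer orientation) and
#'   the 0-based forward-strand flank intervals `pam5_start0`, `pam5_end0`,
#'   `pam3_start0`, `pam3_end0` (pam5 = TTTN side, pam3 = Cas9 side, both in
#'   protospacer orientation).
#' @examples
#' s <- paste0(strrep("C", 10), "TTTA", strrep("AC", 10), "A", "AGGAAT",
#'             strrep("C", 10))
#' scanMatchedSites(s, "cpf1_sp_sa", c(21, 21))
#' @export
scanMatchedSites <- function(sequence, combo = c("cpf1_sp_sa", "cpf1_sp_nm",
                                                 "cpf1_nm_long"),
                             spacerLenRange = c(17L, 25L), seqId = NULL) {
  combo <- match.arg(combo)
  cdef <- .COMBOS[[combo]]
  rec <- .asPlainSeq(sequence)
  if (!is.null(seqId)) rec$id <- seqId
  s <- rec$seq
  emptyHit <- GRanges()
  if (!nzchar(s) || grepl("[^ACGTN]", s)) {
    warning("empty or invalid sequence; returning no sites")
    return(emptyHit)
  }
  stopifnot(spacerLenRange[1] >= 17L, spacerLenRange[2] <= 25L,
            spacerLenRange[1] <= spacerLenRange[2])
  lo <- max(spacerLenRange[1], cdef$lenRange[1])
  hi <- min(spacerLenRange[2], cdef$lenRange[2])
  if (lo > hi) return(emptyHit)
  lens <- lo:hi
  p5 <- nchar(.PAT5); p3 <- nchar(cdef$pat3)
  n <- nchar(s)

  build <- function(df, strand, src) {
    if (!nrow(df)) return(NULL)
    if (strand == "+") {
      spacerStart0 <- df$winStart0 + p5
    } else {
      # mirror revcomp coordinates back to forward strand
      spacerStart0 <- n - (df$winStart0 + p5 + df$len)
    }
    spacerEnd0 <- spacerStart0 + df$len
    if (strand == "+") {
      pam5 <- cbind(spacerStart0 - p5, spacerStart0)
      pam3 <- cbind(spacerEnd0, spacerEnd0 + p3)
    } else {
      pam5 <- cbind(spacerEnd0, spacerEnd0 + p5)
      pam3 <- cbind(spacerStart0 - p3, spacerStart0)
    }
    fwdSpacer <- substring(s, spacerStart0 + 1L, spacerEnd0)
    fwd5 <- substring(s, pam5[, 1] + 1L, pam5[, 2])
    fwd3 <- substring(s, pam3[, 1] + 1L, pam3[, 2])
    if (strand == "-") {
      spacerSeq <- revComp(fwdSpacer); pam5Seq <- revComp(fwd5)
      pam3Seq <- revComp(fwd3)
    } else {
      spacerSeq <- fwdSpacer; pam5Seq <- fwd5; pam3Seq <- fwd3
    }
    gr <- GRanges(rec$id, IRanges(spacerStart0 + 1L, spacerEnd0),
                  strand = strand)
    mcols(gr) <- DataFrame(
      spacer_seq = spacerSeq, combo = combo,
      compatible = IRanges::CharacterList(
        rep(list(cdef$compatible), length(gr))),
      pam5_seq = pam5Seq, pam3_seq = pam3Seq,
      pam5_start0 = pam5[, 1], pam5_end0 = pam5[, 2],
      pam3_start0 = pam3[, 1], pam3_end0 = pam3[, 2])
    gr
  }

  fwd <- build(.scanOneStrand(s, .PAT5, cdef$pat3, lens), "+", s)
  rev <- build(.scanOneStrand(revComp(s), .PAT5, cdef$pat3, lens), "-", s)
  out <- c(GRanges(), fwd, rev)
  if (!length(out)) return(out)
  key <- paste(start(out), end(out), strand(out))
  out <- out[!duplicated(key)]
  out[order(start(out), end(out), as.character(strand(out)))]
}

#' Scan a sequence for single-nuclease target sites
#'
#' Finds every protospacer + PAM occurrence for one nuclease on both
#' strands (PAM 3' of the spacer for Cas9-family profiles, 5' for
#' Cpf1-family).
#'
#' @inheritParams scanMatchedSites
#' @param profile Nuclease name or [NucleaseProfile-class].
#' @return A [GenomicRanges::GRanges] over spacer intervals with metadata
#'   columns `nuclease`, `spacer_seq`, `pam_seq` and the 0-based
#'   forward-strand PAM interval `pam_start0`/`pam_end0`.
#' @export
scanSites <- function(sequence, profile, spacerLenRange = c(17L, 25L),
                      seqId = NULL) {
  profile <- nucleaseProfile(profile)
  rec <- .asPlainSeq(sequence)
  if (!is.null(seqId)) rec$id <- seqId
  s <- rec$seq
  if (!nzchar(s) || grepl("[^ACGTN]", s)) {
    warning("empty or invalid sequence; returning no sites")
    return(GRanges())
  }
  lens <- spacerLenRange[1]:spacerLenRange[2]
  n <- nchar(s)
  threePrime <- profile@pamSide == "three_prime"
  pat5 <- if (threePrime) "" else profile@pamPattern
  pat3 <- if (threePrime) profile@pamPattern else ""
  p5 <- nchar(pat5); p3 <- nchar(pat3)

  scanStrand <- function(str) {
    hits <- list()
    for (L in lens) {
      total <- p5 + L + p3
      if (n < total) next
      starts <- seq_len(n - total + 1L)
      ok <- rep(TRUE, length(starts))
      if (p5 > 0)
        ok <- iupacMatchMany(substring(str, starts, starts + p5 - 1L), pat5)
      idx <- starts[ok]
      if (p3 > 0 && length(idx)) {
        w3 <- substring(str, idx + p5 + L, idx + p5 + L + p3 - 1L)
        idx <- idx[iupacMatchMany(w3, pat3)]
      }
      if (length(idx)) {
        win <- substring(str, idx, idx + total - 1L)
        idx <- idx[!grepl("N", win, fixed = TRUE)]
      }
      if (length(idx))
        hits[[length(hits) + 1L]] <- data.frame(winStart0 = idx - 1L, len = L)
    }
    if (!length(hits)) data.frame(winStart0 = integer(), len = integer())
    else do.call(rbind, hits)
  }

  build <- function(df, strand) {
    if (!nrow(df)) return(NULL)
    if (strand == "+") {
      spacerStart0 <- df$winStart0 + p5
    } else {
      spacerStart0 <- n - (df$winStart0 + p5 + df$len)
    }
    spacerEnd0 <- spacerStart0 + df$len
    pamLen <- p5 + p3
    if (threePrime) {
      pam <- if (strand == "+") cbind(spacerEnd0, spacerEnd0 + pamLen) else
        cbind(spacerStart0 - pamLen, spacerStart0)
    } else {
      pam <- if (strand == "+") cbind(spacerStart0 - pamLen, spacerStart0) else
        cbind(spacerEnd0, spacerEnd0 + pamLen)
    }
    fwdSpacer <- substring(s, spacerStart0 + 1L, spacerEnd0)
    fwdPam <- substring(s, pam[, 1] + 1L, pam[, 2])
    spacerSeq <- if (strand == "-") revComp(fwdSpacer) else fwdSpacer
    pamSeq <- if (strand == "-") revComp(fwdPam) else fwdPam
    gr <- GRanges(rec$id, IRanges(spacerStart0 + 1L, spacerEnd0),
                  strand = strand)
    mcols(gr) <- DataFrame(nuclease = profile@name, spacer_seq = spacerSeq,
                           pam_seq = pamSeq, pam_start0 = pam[, 1],
                           pam_end0 = pam[, 2])
    gr
  }

  out <- c(GRanges(), build(scanStrand(s), "+"),
           build(scanStrand(revComp(s)), "-"))
  if (!length(out)) return(out)
  key <- paste(start(out), end(out), strand(out))
  out <- out[!duplicated(key)]
  out[order(start(out), end(out), as.character(strand(out)))]
}

# Seed interval of a site, 0-based half-open forward-strand coordinates:
# the PAM-proximal seedLen nt of the spacer.
.seedInterval0 <- function(site, profile) {
  s <- .site0(site)
  k <- profile@seedLen
  if (profile@pamSide == "three_prime") {
    if (s$strand == "+") c(s$end0 - k, s$end0) else c(s$start0, s$start0 + k)
  } else {
    if (s$strand == "+") c(s$start0, s$start0 + k) else
      c(s$end0 - k, s$end0)
  }
}

#' Find Cas9/Cpf1 site pairs with overlapping seed regions
#'
#' Scans a sequence independently for Cas9-family and Cpf1-family sites and
#' reports every pair whose PAM-proximal seed regions (seed length taken
#' from each profile, 7 nt for built-ins) intersect as genomic intervals.
#' Such pairs let both enzyme families attack the same critical bases even
#' though their PAMs sit on opposite sides of the protospacer.
#'
#' @inheritParams scanMatchedSites
#' @param cas9Profile,cpf1Profile Profiles (or names) of the two enzymes.
#' @param minOverlap Minimum seed-interval overlap in nt (default 1).
#' @param spacerLenRange Spacer lengths to scan for both enzymes.
#' @return A [S4Vectors::DataFrame] with columns `cas9_site` and `cpf1_site`
#'   (each a [GenomicRanges::GRanges]) and `overlap_start0`, `overlap_end0`,
#'   `overlap_len` describing the seed intersection (0-based half-open).
#' @export
findOverlappingSeedPairs <- function(sequence,
                                     cas9Profile = nucleaseProfile("SpCas9"),
                                     cpf1Profile = nucleaseProfile("LbCpf1"),
                                     minOverlap = 1L,
                                     spacerLenRange = c(17L, 25L),
                                     seqId = NULL) {
  cas9Profile <- nucleaseProfile(cas9Profile)
  cpf1Profile <- nucleaseProfile(cpf1Profile)
  stopifnot(cas9Profile@pamSide == "three_prime",
            cpf1Profile@pamSide == "five_prime", minOverlap >= 1L)
  cas9 <- scanSites(sequence, cas9Profile, spacerLenRange, seqId)
  cpf1 <- scanSites(sequence, cpf1Profile, spacerLenRange, seqId)
  empty <- DataFrame(cas9_site = GRanges(), cpf1_site = GRanges(),
                     overlap_start0 = integer(), overlap_end0 = integer(),
                     overlap_len = integer())
  if (!length(cas9) || !length(cpf1)) return(empty)
  seedA <- t(vapply(seq_along(cas9), function(i)
    .seedInterval0(cas9[i], cas9Profile), numeric(2)))
  seedB <- t(vapply(seq_along(cpf1), function(i)
    .seedInterval0(cpf1[i], cpf1Profile), numeric(2)))
  ov <- IRanges::findOverlaps(IRanges(seedA[, 1] + 1L, seedA[, 2]),
                              IRanges(seedB[, 1] + 1L, seedB[, 2]),
                              minoverlap = minOverlap)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  os <- pmax(seedA[qi, 1], seedB[si, 1])
  oe <- pmin(seedA[qi, 2], seedB[si, 2])
  DataFrame(cas9_site = cas9[qi], cpf1_site = cpf1[si],
            overlap_start0 = as.integer(os), overlap_end0 = as.integer(oe),
            overlap_len = as.integer(oe - os))
}

#' Write scanned sites as BED-like TSV with a JSON sidecar
#'
#' Writes a BED6-compatible TSV (0-based half-open spacer intervals, score
#' column 0) and a JSON sidecar listing each site's compatible nucleases
#' and PAM sequences.
#'
#' @param sites Output of [scanMatchedSites()].
#' @param bedPath,jsonPath Output file paths (`jsonPath` defaults to
#'   `bedPath` with a `.json` extension).
#' @return (Invisibly) `bedPath`.
#' @export
writeSitesBed <- function(sites, bedPath,
                          jsonPath = sub("\\.[^.]*$", ".json", bedPath)) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    chromStart = start(sites) - 1L,
    chromEnd = end(sites),
    name = paste0("site", seq_along(sites)),
    score = 0L,
    strand = as.character(strand(sites)))
  utils::write.table(df, bedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- lapply(seq_along(sites), function(i) list(
    name = paste0("site", i),
    spacer_seq = mcols(sites)$spacer_seq[i],
    combo = mcols(sites)$combo[i],
    compatible = as.character(mcols(sites)$compatible[[i]]),
    pam5_seq = mcols(sites)$pam5_seq[i],
    pam3_seq = mcols(sites)$pam3_seq[i]))
  jsonlite::write_json(side, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(bedPath)
}
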