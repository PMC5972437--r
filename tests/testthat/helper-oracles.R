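# Independent oracles used to validate the package's fast paths.

# --- textbook Needleman-Wunsch / Gotoh affine-gap DP score ------------------
# Global alignment score with match/mismatch scores and a length-k gap
# costing open + k * ext. Row-vectorised dynamic programme; gap states
# follow the standard Gotoh recursion (gaps open from the match state).
nwScoreOracle <- function(a, b, match = 2, mismatch = -2, open = 6, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e18
  # row i of M/Ix/Iy over j = 0..m
  Mprev <- c(0, rep(NEG, m))
  Ixprev <- rep(NEG, m + 1L)               # gap in b (consumes a)
  Iyprev <- c(NEG, -(open + ext * seq_len(m)))  # gap in a (consumes b)
  for (i in seq_len(n)) {
    s <- ifelse(y == x[i], match, mismatch)
    prevBest <- pmax(Mprev, Ixprev, Iyprev)
    Mrow <- c(NEG, prevBest[1:m] + s)
    Ixrow <- pmax(Mprev - (open + ext), Ixprev - ext)
    Ixrow[1] <- -(open + ext * i)
    # Iy within the row: best M[i, k] + ext*k for k < j, then close the gap
    best <- cummax(Mrow + ext * (0:m))
    Iyrow <- c(NEG, best[1:m]) - open - ext * (0:m)
    Mprev <- Mrow; Ixprev <- Ixrow; Iyprev <- Iyrow
  }
  max(Mprev[m + 1L], Ixprev[m + 1L], Iyprev[m + 1L])
}

randomDnaStr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

# --- IUPAC expansion oracle -------------------------------------------------
# Enumerates the concrete ACGT strings a pattern stands for.
iupacExpandOracle <- function(pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  chars <- strsplit(pattern, "")[[1]]
  grid <- do.call(expand.grid, c(lapply(chars, function(p) sets[[p]]),
                                 stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

allWindows <- function(len) {
  grid <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), len),
                                 stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

# --- regex-based matched-site scanner oracle --------------------------------
# Finds matched sites via perl lookahead regexes (overlap-aware), an
# entirely different mechanism from the package's position-wise scan.
iupacToRegex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(pattern, "")[[1]]], collapse = "")
}

scanOracle <- function(s, combo, lenRange = c(17L, 25L)) {
  pat3 <- switch(combo, cpf1_sp_sa = "NGGRRT", cpf1_sp_nm = "NGGNGATT",
                 cpf1_nm_long = "NNNNGATT")
  lens <- switch(combo, cpf1_nm_long = max(lenRange[1], 24L):
                   min(lenRange[2], 25L),
                 lenRange[1]:lenRange[2])
  r5 <- iupacToRegex("TTTN"); r3 <- iupacToRegex(pat3)
  n <- nchar(s)
  revs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  out <- list()
  for (L in lens) {
    rx <- sprintf("(?=%s[ACGT]{%d}%s)", r5, L, r3)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") s else revs
      m <- gregexpr(rx, subj, perl = TRUE)[[1]]
      if (m[1] == -1) next
      win0 <- as.integer(m) - 1L
      sp0 <- if (strand == "+") win0 + 4L else n - (win0 + 4L + L)
      out[[length(out) + 1L]] <- data.frame(start0 = sp0, end0 = sp0 + L,
                                            strand = strand)
    }
  }
  if (!length(out))
    return(data.frame(start0 = integer(), end0 = integer(),
                      strand = character()))
  df <- unique(do.call(rbind, out))
  df[order(df$start0, df$end0, df$strand), , drop = FALSE]
}

sitesToDf <- function(gr) {
  if (!length(gr))
    return(data.frame(start0 = integer(), end0 = integer(),
                      strand = character()))
  df <- data.frame(start0 = GenomicRanges::start(gr) - 1L,
                   end0 = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)))
  df[order(df$start0, df$end0, df$strand), , drop = FALSE]
}

# --- exhaustive Wilcoxon rank-sum enumeration -------------------------------
# Two-sided exact p-value by enumerating every assignment of the pooled
# ranks to group A (assumes no ties), with R's doubling rule.
rankSumEnumP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  ws <- apply(idx, 2, function(k) sum(r[k])) - n1 * (n1 + 1) / 2
  pLo <- mean(ws <= wObs)
  pHi <- mean(ws >= wObs)
  min(1, 2 * min(pLo, pHi))
}

# A deterministic matched-site cassette embedded in fixed flanks, for tests
# that need a known locus without the simulator.
testLocus <- function(spacerLen = 20L, flank = 60L, seed = 7L) {
  set.seed(seed)
  repeat {
    ref <- paste0(randomDnaStr(flank), "TTTA", randomDnaStr(spacerLen),
                  "TGGAATAC", randomDnaStr(flank))
    sites <- scanMatchedSites(ref, "cpf1_sp_sa")
    if (length(sites) == 1L &&
        as.character(GenomicRanges::strand(sites)) == "+" &&
        !grepl("TCTAGA", ref, fixed = TRUE))
      return(list(ref = ref, site = sites))
  }
}
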