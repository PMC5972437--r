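#' Split per-site results into low/high expression groups
#'
#' Partitions site-level editing results at an FPKM expression threshold:
#' strictly below goes to the low group, at-or-above to the high group
#' (default threshold 25, chosen to split a typical screen into two groups
#' of roughly equal size). Rows with missing FPKM are dropped with a
#' warning.
#'
#' @param results data.frame with at least an `fpkm` column (site-level
#'   results also carry `site_id`, `nuclease`, `spacer_len`, `editing_pct`,
#'   `assay`).
#' @param threshold FPKM threshold (default 25).
#' @return `list(low = ..., high = ...)` of data.frames partitioning the
#'   non-missing rows.
#' @export
splitByExpression <- function(results, threshold = 25) {
  stopifnot(is.data.frame(results), "fpkm" %in% names(results))
  miss <- is.na(results$fpkm)
  if (any(miss))
    warning(sprintf("%d result(s) with missing fpkm excluded", sum(miss)))
  kept <- results[!miss, , drop = FALSE]
  list(low = kept[kept$fpkm < threshold, , drop = FALSE],
       high = kept[kept$fpkm >= threshold, , drop = FALSE])
}

#' Filter results to a nuclease's optimal spacer lengths
#'
#' Retains rows whose `spacer_len` lies in the enzyme's optimal range
#' (SpCas9 17-22 nt inclusive; SaCas9 >= 21 nt; NmCas9, AsCpf1 and LbCpf1
#' >= 19 nt for the built-in profiles).
#'
#' @param results data.frame with a `spacer_len` column.
#' @param nuclease Enzyme name or [NucleaseProfile-class].
#' @return The retained rows.
#' @export
filterOptimalLengths <- function(results, nuclease) {
  stopifnot(is.data.frame(results), "spacer_len" %in% names(results))
  profile <- nucleaseProfile(nuclease)
  lo <- profile@optimalSpacerMin
  hi <- profile@optimalSpacerMax
  keep <- results$spacer_len >= lo &
    (is.na(hi) | results$spacer_len <= hi)
  results[keep, , drop = FALSE]
}

#' Two-sample comparison test
#'
#' The comparison statistics used for site-level editing efficiencies:
#' Wilcoxon rank-sum (exact null distribution when the combined sample size
#' is <= `exactMaxN` and there are no ties, normal approximation with tie
#' correction otherwise), Welch/paired t-test, or two-sample
#' Kolmogorov-Smirnov. Two-sided throughout.
#'
#' @param a,b Numeric vectors (each n >= 2; t-test needs n >= 3 per group).
#' @param test One of "wilcoxon_rank_sum", "t_test", "ks_test".
#' @param paired Paired test (rank-sum becomes signed-rank; t-test paired).
#' @param exactMaxN Combined-n cutoff for the exact rank-sum distribution
#'   (default 20).
#' @param correction Optional p-value adjustment method for callers running
#'   many tests (see [stats::p.adjust()]); applied downstream, recorded
#'   here for the method label only. Default "none": raw p-values.
#' @return The `htest` object (statistic + p.value).
#' @export
compareGroups <- function(a, b, test = c("wilcoxon_rank_sum", "t_test",
                                         "ks_test"),
                          paired = FALSE, exactMaxN = 20L,
                          correction = "none") {
  test <- match.arg(test)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (test == "wilcoxon_rank_sum") {
    if (length(unique(c(a, b))) == 1L) {
      # every pooled value tied: the rank statistic is degenerate (the
      # normal approximation divides by a zero variance), but the data
      # carry no evidence against the null, so report p = 1
      res <- structure(
        list(statistic = c(W = length(a) * length(b) / 2),
             p.value = 1,
             alternative = "two.sided",
             method = "Wilcoxon rank sum test (all values tied)",
             data.name = "a and b"),
        class = "htest")
      return(res)
    }
    exact <- (length(a) + length(b)) <= exactMaxN
    suppressWarnings(
      stats::wilcox.test(a, b, paired = paired, exact = exact,
                         correct = TRUE, alternative = "two.sided"))
  } else if (test == "t_test") {
    stopifnot(length(a) >= 3L, length(b) >= 3L)
    if (stats::var(a) == 0 && stats::var(b) == 0)
      stop("degenerate input: both groups have zero variance")
    stats::t.test(a, b, paired = paired, var.equal = FALSE,
                  alternative = "two.sided")
  } else {
    suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  }
}

#' Adjust a vector of p-values
#'
#' Raw p-values are reported by default across the package; this helper
#' applies Benjamini-Hochberg (or any [stats::p.adjust()] method) when a
#' caller runs many comparisons.
#'
#' @param p Numeric vector of p-values.
#' @param method Adjustment method (default "BH").
#' @return Adjusted p-values.
#' @export
adjustPvalues <- function(p, method = "BH") stats::p.adjust(p, method)

#' Nuclease/donor selection rule engine
#'
#' Deterministic encoding of the selection guidelines distilled from the
#' multi-nuclease comparison:
#' \itemize{
#'   \item knockout, specificity not critical: SpCas9 or LbCpf1 (comparable
#'     indel frequencies in lowly and highly expressed genes).
#'   \item knockout, specificity critical: AsCpf1 first (lowest tolerance
#'     of single spacer-target mismatches), or SaCas9 with a >= 21-nt
#'     spacer.
#'   \item precise edit with an ssODN donor: SpCas9 with an asymmetric
#'     37/77 target-strand donor (long arm PAM-distal); LbCpf1 with a
#'     non-target-strand donor whose PAM-proximal arm is extended.
#'   \item precise edit with a linearized-plasmid donor: SpCas9 performs
#'     favorably against the Cpf1 enzymes.
#' }
#' Unknown combinations (e.g. a precise edit with no donor) fall back to
#' the knockout defaults with a warning. The function is pure: identical
#' inputs give identical outputs, and every output carries at least one
#' rationale statement.
#'
#' @param goal "knockout" or "precise_edit".
#' @param specificityCritical Is off-target activity a primary concern?
#' @param donor Donor type: "none", "ssODN" or "plasmid".
#' @return A [Recommendation-class].
#' @examples
#' recommendSystem("knockout", specificityCritical = TRUE)
#' recommendSystem("precise_edit", donor = "ssODN")
#' @export
recommendSystem <- function(goal = c("knockout", "precise_edit"),
                            specificityCritical = FALSE,
                            donor = c("none", "ssODN", "plasmid")) {
  goal <- match.arg(goal)
  donor <- match.arg(donor)
  mk <- function(nucleases, donorAdvice, rationale)
    new("Recommendation", goal = goal,
        specificityCritical = specificityCritical, donor = donor,
        nucleases = nucleases, donorAdvice = donorAdvice,
        rationale = rationale)
  knockoutDefault <- function(rationaleExtra = character()) {
    if (specificityCritical) {
      mk(c("AsCpf1", "SaCas9"), list(), c(rationaleExtra,
        "AsCpf1 shows the lowest tolerance of single mismatches between spacer and target, at the cost of overall cleavage efficiency",
        "SaCas9 is an alternative for specificity-sensitive targets because it requires longer spacers (at least 21 nt) for activity"))
    } else {
      mk(c("SpCas9", "LbCpf1"), list(), c(rationaleExtra,
        "SpCas9 and LbCpf1 generate indels at comparable frequencies in both lowly and highly expressed genes when spacers of optimal length are used"))
    }
  }
  if (goal == "knockout") return(knockoutDefault())
  if (donor == "ssODN") {
    advice <- list(
      SpCas9 = list(strand = "T", armPamProximal = 37L, armPamDistal = 77L),
      LbCpf1 = list(strand = "NT", armPamProximal = 77L, armPamDistal = 37L))
    return(mk(c("SpCas9", "LbCpf1"), advice, c(
      "for ssODN-mediated HDR, SpCas9 prefers target-strand donors and is most efficient with the asymmetric 37/77 T design (long arm PAM-distal)",
      "the Cpf1 nucleases prefer non-target-strand donors; extending the PAM-proximal arm of the NT ssODN increases LbCpf1 HDR frequency")))
  }
  if (donor == "plasmid") {
    return(mk("SpCas9", list(), c(
      "with linearized double-stranded plasmid donors SpCas9 performs favorably against the Cpf1 enzymes in knockin efficiency")))
  }
  warning("no donor specified for a precise edit; falling back to knockout defaults")
  knockoutDefault(
    "precise editing requires a repair template; knockout guidance returned instead")
}

#' Read site-level results from a TSV
#'
#' Expects columns `site_id`, `nuclease`, `spacer_len`, `fpkm`,
#' `editing_pct`, `assay` (deep_seq / t7e1 / rflp).
#'
#' @param path TSV file path.
#' @return data.frame of site results.
#' @export
readSiteResults <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "nuclease", "spacer_len", "fpkm", "editing_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$editing_pct < 0 | df$editing_pct > 100, na.rm = TRUE))
    stop("editing_pct must lie in [0, 100]")
  if (any(df$fpkm < 0, na.rm = TRUE)) stop("fpkm must be >= 0")
  df
}
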