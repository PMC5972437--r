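# Profile registry. Populated from inst/extdata/nucleases.yaml at load time;
# users may add profiles with registerNuclease().
.profileRegistry <- new.env(parent = emptyenv())

.profileFromSpec <- function(name, spec) {
  cut <- spec$cut
  blunt <- identical(cut$type, "blunt")
  maxLen <- spec$optimal_spacer$max
  new("NucleaseProfile",
      name = name,
      pamPattern = toupper(spec$pam_pattern),
      pamSide = spec$pam_side,
      seedLen = as.integer(spec$seed_len),
      cutType = cut$type,
      cutOffset = if (blunt) as.integer(cut$offset) else NA_integer_,
      nonTargetOffset = if (blunt) NA_integer_ else
        as.integer(cut$non_target_offset),
      targetOffset = if (blunt) NA_integer_ else as.integer(cut$target_offset),
      optimalSpacerMin = as.integer(spec$optimal_spacer$min),
      optimalSpacerMax = if (is.null(maxLen)) NA_integer_ else
        as.integer(maxLen))
}

#' Load nuclease profiles from a YAML config
#'
#' Reads a config with the same schema as the package's built-in
#' `nucleases.yaml` and registers every profile it defines, replacing any
#' existing profile of the same name.
#'
#' @param path Path to a YAML file with a top-level `nucleases:` map.
#' @return (Invisibly) the registered [NucleaseProfile-class] objects.
#' @export
loadNucleaseConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$nucleases))
    stop("config has no 'nucleases' section: ", path)
  profs <- lapply(names(cfg$nucleases), function(nm)
    .profileFromSpec(nm, cfg$nucleases[[nm]]))
  for (p in profs) registerNuclease(p)
  invisible(profs)
}

#' Register a nuclease profile
#'
#' @param profile A validated [NucleaseProfile-class].
#' @return (Invisibly) the profile.
#' @export
registerNuclease <- function(profile) {
  stopifnot(is(profile, "NucleaseProfile"))
  validObject(profile)
  assign(profile@name, profile, envir = .profileRegistry)
  invisible(profile)
}

#' Look up a registered nuclease profile
#'
#' @param name Enzyme name, e.g. "SpCas9". A [NucleaseProfile-class] is
#'   passed through unchanged.
#' @return The [NucleaseProfile-class].
#' @export
nucleaseProfile <- function(name) {
  if (is(name, "NucleaseProfile")) return(name)
  if (!exists(name, envir = .profileRegistry))
    stop(sprintf("unknown nuclease '%s'; registered: %s", name,
                 paste(listNucleases(), collapse = ", ")))
  get(name, envir = .profileRegistry)
}

#' List registered nuclease names
#' @return Character vector of enzyme names.
#' @export
listNucleases <- function() sort(ls(envir = .profileRegistry))

.onLoad <- function(libname, pkgname) {
  cfg <- system.file("extdata", "nucleases.yaml", package = pkgname,
                     mustWork = TRUE)
  loadNucleaseConfig(cfg)
}

# --- cut-site coordinate models --------------------------------------------
#
# All coordinates are 0-based half-open on the forward strand; cut sites are
# inter-base integers (coordinate x = the gap between base x-1 and base x).

.site0 <- function(site) {
  # Extract 0-based half-open spacer interval + strand from a one-row GRanges.
  stopifnot(is(site, "GRanges"), length(site) == 1L)
  list(start0 = GenomicRanges::start(site) - 1L,
       end0 = GenomicRanges::end(site),
       strand = as.character(GenomicRanges::strand(site)))
}

#' Blunt Cas9 cut-site coordinate
#'
#' Cas9-family nucleases cut bluntly 3 bp 5' of the first PAM base (within
#' the protospacer, on its PAM-proximal side). For a plus-strand site with
#' spacer \[s,e) the cut falls at inter-base coordinate `e - offset`; minus
#' strand sites are mirrored (`s + offset`).
#'
#' @param site One-row [GenomicRanges::GRanges] spanning the spacer (1-based,
#'   as produced by [scanMatchedSites()] / [scanSites()]).
#' @param profile A `pamSide == "three_prime"` [NucleaseProfile-class].
#' @return 0-based inter-base cut coordinate on the forward strand.
#' @export
cas9CutSite <- function(site, profile = nucleaseProfile("SpCas9")) {
  profile <- nucleaseProfile(profile)
  if (profile@pamSide != "three_prime")
    stop(sprintf("'%s' is a 5'-PAM (Cpf1-family) profile; use cpf1CutSites()",
                 profile@name))
  s <- .site0(site)
  off <- profile@cutOffset
  if (s$strand == "-") s$start0 + off else s$end0 - off
}

#' Staggered Cpf1 nick coordinates
#'
#' Cpf1/Cas12a-family nucleases cut distal to their 5' PAM with a staggered
#' cut: the non-target-strand nick 18 nt 3' of the last PAM base and the
#' target-strand nick further 3' (default 23 nt), leaving a 5' overhang of
#' `targetOffset - nonTargetOffset` nt.
#'
#' @inheritParams cas9CutSite
#' @param profile A `pamSide == "five_prime"` [NucleaseProfile-class].
#' @return Named numeric vector `c(non_target = ..., target = ...)` of
#'   0-based inter-base nick coordinates on the forward strand.
#' @export
cpf1CutSites <- function(site, profile = nucleaseProfile("LbCpf1")) {
  profile <- nucleaseProfile(profile)
  if (profile@pamSide != "five_prime")
    stop(sprintf("'%s' is a 3'-PAM (Cas9-family) profile; use cas9CutSite()",
                 profile@name))
  s <- .site0(site)
  nt <- profile@nonTargetOffset
  tg <- profile@targetOffset
  if (s$strand == "-") {
    c(non_target = s$end0 - nt, target = s$end0 - tg)
  } else {
    c(non_target = s$start0 + nt, target = s$start0 + tg)
  }
}
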