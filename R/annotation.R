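# Spectrum annotation: turn spectra + PSMs into intensity vectors over the
# canonical b/y layout, apply exclusion rules, partition into datasets and
# build nonredundant precursor sets.

#' Peak-matching tolerance specification
#'
#' High-resolution (FTMS) fragment spectra are matched in parts-per-million,
#' ion-trap (ITMS) spectra in Daltons, with the widely used defaults of
#' 20 ppm and 0.5 Da respectively.
#'
#' @param mode `"ppm"` or `"dalton"`.
#' @param value Positive tolerance value.
#' @return A list of class `"tolerance_spec"`.
#' @export
tolerance_spec <- function(mode = c("ppm", "dalton"), value = NULL) {
  mode <- match.arg(mode)
  if (is.null(value)) value <- if (mode == "ppm") 20 else 0.5
  if (!is.numeric(value) || value <= 0)
    stop("tolerance value must be positive", call. = FALSE)
  structure(list(mode = mode, value = value), class = "tolerance_spec")
}

#' Default tolerance for a mass analyzer
#'
#' @param mass_analyzer `"FTMS"` or `"ITMS"`.
#' @param ftms_ppm,itms_da Configurable tolerance values.
#' @return A `"tolerance_spec"`.
#' @export
default_tolerance <- function(mass_analyzer, ftms_ppm = 20, itms_da = 0.5) {
  switch(mass_analyzer,
         FTMS = tolerance_spec("ppm", ftms_ppm),
         ITMS = tolerance_spec("dalton", itms_da),
         stop("unknown mass analyzer: ", mass_analyzer, call. = FALSE))
}

#' Match spectrum peaks to theoretical b/y fragment m/z values
#'
#' Fills the canonical-layout intensity vector of a peptide from an
#' experimental peak list. For each theoretical fragment m/z, the matching
#' peak must satisfy `|obs - theo| / theo * 1e6 <= value` (ppm mode) or
#' `|obs - theo| <= value` (dalton mode). If no peak matches, the slot is
#' zero. When several peaks fall within tolerance the closest in m/z wins;
#' an exact distance tie is broken toward the higher intensity. One peak may
#' legitimately serve two theoretical fragments (short peptides at 0.5 Da):
#' each theoretical fragment is looked up independently.
#'
#' @param spectrum A spectrum record (list with sorted `mz`, `intensity`).
#' @param pep A `"peptide"` object.
#' @param charges Fragment charge coverage, subset of `c(1, 2)`.
#' @param tol A `"tolerance_spec"`.
#' @return Canonical-layout intensity vector (attributes `pep_n`,
#'   `charges`); all-zero results are legal here, exclusion happens
#'   downstream.
#' @export
match_peaks <- function(spectrum, pep, charges = c(1L, 2L),
                        tol = tolerance_spec("ppm", 20)) {
  stopifnot(inherits(tol, "tolerance_spec"))
  frags <- enumerate_fragments(pep, charges)
  v <- .blank_vector(length(pep$residues), charges)
  mz <- spectrum$mz
  if (!length(mz)) return(v)
  if (is.unsorted(mz)) {
    ord <- order(mz)
    mz <- mz[ord]
    spectrum$intensity <- spectrum$intensity[ord]
  }
  half <- if (tol$mode == "ppm") frags$mz * tol$value * 1e-6
          else rep(tol$value, nrow(frags))
  # candidate window per theoretical m/z via binary search on the sorted list
  lo <- findInterval(frags$mz - half, mz) + 1L
  hi <- findInterval(frags$mz + half, mz)
  for (k in seq_len(nrow(frags))) {
    if (lo[k] > hi[k]) next
    idx <- lo[k]:hi[k]
    d <- abs(mz[idx] - frags$mz[k])
    best <- which(d == min(d))
    if (length(best) > 1L)
      best <- best[which.max(spectrum$intensity[idx][best])]
    v[k] <- spectrum$intensity[idx[best]]
  }
  v
}

#' Annotate PSMs against their spectra
#'
#' Joins each PSM to its spectrum by (raw file, scan) and to its acquisition
#' metadata by precursor, then extracts the experimental b/y intensity
#' vector with [match_peaks()] using the tolerance implied by the mass
#' analyzer. PSMs whose scan or precursor cannot be resolved are returned in
#' an exclusion table, not silently dropped.
#'
#' @param spectra List of spectrum records ([read_mgf()]).
#' @param psms List of PSM records ([read_psm_table()]`$psms`).
#' @param precursors Precursor metadata data.frame
#'   ([read_precursor_table()]).
#' @param charges Fragment charge coverage.
#' @param ftms_ppm,itms_da Matching tolerances.
#' @return A list with `annotated` (list of annotated PSM records: `psm`
#'   fields plus `precursor`, `nce`, `instrument`, `dissociation`,
#'   `mass_analyzer`, `pep_n`, `oxidized`, `intensities`) and `excluded`
#'   (data.frame with reasons).
#' @export
annotate_psms <- function(spectra, psms, precursors, charges = c(1L, 2L),
                          ftms_ppm = 20, itms_da = 0.5) {
  spec_key <- vapply(spectra, function(s)
    paste(s$source_file, s$scan, sep = "#"), character(1))
  out <- vector("list", length(psms))
  excl <- list()
  for (i in seq_along(psms)) {
    p <- psms[[i]]
    prec_id <- paste(peptide_string(p$peptide), p$charge, sep = "/")
    j <- match(paste(p$raw_file, p$scan, sep = "#"), spec_key)
    if (is.na(j)) {
      excl[[length(excl) + 1L]] <- data.frame(
        precursor = prec_id, scan = p$scan, reason = "scan not found",
        stringsAsFactors = FALSE)
      next
    }
    m <- match(prec_id, precursors$precursor)
    if (is.na(m)) {
      excl[[length(excl) + 1L]] <- data.frame(
        precursor = prec_id, scan = p$scan,
        reason = "precursor metadata not found", stringsAsFactors = FALSE)
      next
    }
    tol <- default_tolerance(precursors$mass_analyzer[m], ftms_ppm, itms_da)
    v <- match_peaks(spectra[[j]], p$peptide, charges, tol)
    out[[i]] <- list(
      raw_file = p$raw_file, scan = p$scan, precursor = prec_id,
      peptide = p$peptide, charge = p$charge,
      nce = precursors$nce[m], instrument = precursors$instrument[m],
      dissociation = precursors$dissociation[m],
      mass_analyzer = precursors$mass_analyzer[m],
      pep_n = length(p$peptide$residues),
      oxidized = any(p$peptide$mods$mod == "Oxidation"),
      intensities = v)
  }
  list(annotated = out[!vapply(out, is.null, logical(1))],
       excluded = if (length(excl)) do.call(rbind, excl)
                  else data.frame(precursor = character(), scan = integer(),
                                  reason = character(),
                                  stringsAsFactors = FALSE))
}

#' Filter annotated PSMs
#'
#' Applies the exclusion rules in order: (a) all configured intensities
#' zero; (b) in `charge1_only` mode, all singly-charged intensities zero;
#' (c) with the comparability filter enabled, peptide length > `max_length`
#' or precursor charge > `max_charge` (the subset every evaluated predictor
#' can process). Every exclusion carries a reason; kept + excluded always
#' partition the input.
#'
#' @param annotated List of annotated PSM records.
#' @param mode `"charge1_and_2"` or `"charge1_only"`.
#' @param comparability Apply the length/charge comparability filter
#'   (default `TRUE`).
#' @param max_length,max_charge Comparability bounds (defaults 30 and 6).
#' @return A list with `kept` and `excluded` (records with `reason` added).
#' @export
filter_psms <- function(annotated, mode = c("charge1_and_2", "charge1_only"),
                        comparability = TRUE, max_length = 30L,
                        max_charge = 6L) {
  mode <- match.arg(mode)
  kept <- list(); excluded <- list()
  for (rec in annotated) {
    reason <- NULL
    v <- rec$intensities
    if (all(v == 0)) {
      reason <- "all intensities zero"
    } else if (mode == "charge1_only" &&
               all(restrict_charge1(v, rec$pep_n) == 0)) {
      reason <- "all singly-charged intensities zero"
    } else if (comparability && rec$pep_n > max_length) {
      reason <- sprintf("peptide length %d > %d", rec$pep_n, max_length)
    } else if (comparability && rec$charge > max_charge) {
      reason <- sprintf("precursor charge %d > %d", rec$charge, max_charge)
    }
    if (is.null(reason)) kept[[length(kept) + 1L]] <- rec
    else {
      rec$reason <- reason
      excluded[[length(excluded) + 1L]] <- rec
    }
  }
  list(kept = kept, excluded = excluded)
}

#' Partition annotated PSMs into acquisition datasets
#'
#' A dataset is the set of PSMs sharing the exact
#' (NCE, dissociation, instrument, mass analyzer) combination. Datasets
#' whose nonredundant precursor count falls below `min_precursors` are
#' flagged (`too_small = TRUE`) so callers can drop sets too small for a
#' reliable comparison; they are still returned.
#'
#' @param annotated List of annotated PSM records with complete metadata.
#' @param min_precursors Minimum nonredundant precursor count (default 0 =
#'   no flagging).
#' @return A named list of datasets; each has `key` (list of the four
#'   fields), `psms`, `n_precursors` and `too_small`.
#' @export
partition_datasets <- function(annotated, min_precursors = 0L) {
  if (!length(annotated)) return(list())
  keys <- vapply(annotated, function(r) {
    for (f in c("nce", "dissociation", "instrument", "mass_analyzer"))
      if (is.null(r[[f]]) || is.na(r[[f]]))
        stop("annotated PSM lacks metadata field '", f, "'", call. = FALSE)
    paste(r$nce, r$dissociation, r$instrument, r$mass_analyzer, sep = "/")
  }, character(1))
  out <- lapply(split(annotated, keys), function(group) {
    r1 <- group[[1L]]
    nprec <- length(unique(vapply(group, `[[`, character(1), "precursor")))
    list(key = list(nce = r1$nce, dissociation = r1$dissociation,
                    instrument = r1$instrument,
                    mass_analyzer = r1$mass_analyzer),
         psms = group, n_precursors = nprec,
         too_small = nprec < min_precursors)
  })
  out[order(names(out))]
}

#' Nonredundant precursor set of a dataset
#'
#' Distinct (modified sequence, charge) precursors of a dataset with the PSM
#' multiplicity of each: a precursor matched by several spectra is counted
#' once, and its multiplicity is what downweights its PSMs when
#' distributions are built.
#'
#' @param dataset A dataset from [partition_datasets()], or a plain list of
#'   annotated PSM records.
#' @return A list with `members` (character vector of precursor ids) and
#'   `multiplicity` (named integer vector; sums to the number of PSMs).
#' @export
nonredundant_precursors <- function(dataset) {
  psms <- if (!is.null(dataset$psms)) dataset$psms else dataset
  if (!length(psms))
    return(list(members = character(), multiplicity = integer()))
  ids <- vapply(psms, `[[`, character(1), "precursor")
  tab <- table(ids)
  mult <- as.integer(tab)
  names(mult) <- names(tab)
  list(members = names(mult), multiplicity = mult)
}
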