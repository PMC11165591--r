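# Binned, precursor-weighted similarity distributions: construction,
# combination, weighted quantiles, Wasserstein distance, method ranking and
# stratified reports.

#' Construct an empty binned similarity distribution
#'
#' Bins are half-open `[k*w, (k+1)*w)` with the top edge closed, so a score
#' equal to `hi` lands in the final bin. The default range `[0, 1]` suits
#' the normalized angle; use `lo = -1` for Pearson correlations.
#'
#' @param lo,hi Score range bounds; `hi - lo` must be divisible by
#'   `bin_width` (to 1e-9).
#' @param bin_width Bin width (default 0.001, the package-wide step).
#' @return An object of class `"sim_dist"` with zero mass.
#' @export
sim_dist_empty <- function(lo = 0, hi = 1, bin_width = 0.001) {
  nb <- (hi - lo) / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("hi - lo must be divisible by bin_width", call. = FALSE)
  nb <- as.integer(round(nb))
  structure(list(lo = lo, hi = hi, bin_width = bin_width,
                 weights = numeric(nb), total_mass = 0),
            class = "sim_dist")
}

.bin_index <- function(d, scores) {
  idx <- floor((scores - d$lo) / d$bin_width) + 1L
  nb <- length(d$weights)
  idx[scores >= d$hi - 1e-12] <- nb  # top edge closed
  idx
}

#' Bin centers of a distribution
#' @param d A `"sim_dist"`.
#' @return Numeric vector of bin midpoints.
#' @export
sim_dist_centers <- function(d)
  d$lo + (seq_along(d$weights) - 0.5) * d$bin_width

#' Build a precursor-weighted similarity distribution
#'
#' Each PSM contributes weight `1 / multiplicity(precursor)` (the number of
#' PSMs of that precursor), so every precursor has equal impact on the
#' distribution and the total mass equals the number of distinct precursors
#' contributing. The literal multiplicative reading (each PSM weighted *by*
#' its precursor's PSM count) is available via
#' `weighting = "psm_count"`.
#'
#' @param scores Numeric vector of similarity scores in `[lo, hi]`.
#' @param precursor_id Character vector parallel to `scores`.
#' @param multiplicity Optional named integer vector of PSM counts per
#'   precursor; computed from `precursor_id` when `NULL` (correct when all
#'   PSMs of each precursor are scored).
#' @param lo,hi,bin_width Binning parameters, see [sim_dist_empty()].
#' @param weighting `"equal_precursor"` (default) or `"psm_count"`.
#' @return A `"sim_dist"`.
#' @export
build_distribution <- function(scores, precursor_id, multiplicity = NULL,
                               lo = 0, hi = 1, bin_width = 0.001,
                               weighting = c("equal_precursor",
                                             "psm_count")) {
  weighting <- match.arg(weighting)
  stopifnot(length(scores) == length(precursor_id))
  if (any(scores < lo - 1e-12 | scores > hi + 1e-12))
    stop("similarity score outside [", lo, ", ", hi,
         "]: upstream metric bug", call. = FALSE)
  d <- sim_dist_empty(lo, hi, bin_width)
  if (!length(scores)) return(d)
  if (is.null(multiplicity)) {
    tab <- table(precursor_id)
    multiplicity <- as.integer(tab)
    names(multiplicity) <- names(tab)
  }
  m <- multiplicity[precursor_id]
  if (anyNA(m) || any(m < 1L))
    stop("every precursor must have multiplicity >= 1", call. = FALSE)
  w <- if (weighting == "equal_precursor") 1 / m else as.numeric(m)
  idx <- .bin_index(d, scores)
  acc <- vapply(split(w, idx), sum, numeric(1))
  d$weights[as.integer(names(acc))] <- acc
  d$total_mass <- sum(d$weights)
  d
}

#' Combine similarity distributions by adding corresponding bins
#'
#' @param ... `"sim_dist"` objects (or a single list of them) sharing
#'   identical binning.
#' @return A `"sim_dist"` with per-bin sums; total mass is additive.
#' @export
combine_distributions <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && !inherits(ds[[1L]], "sim_dist")) ds <- ds[[1L]]
  stopifnot(length(ds) >= 1L)
  ref <- ds[[1L]]
  for (d in ds[-1L]) {
    if (!isTRUE(all.equal(c(d$lo, d$hi, d$bin_width),
                          c(ref$lo, ref$hi, ref$bin_width), tolerance = 0)))
      stop("cannot combine distributions with mismatched binning",
           call. = FALSE)
    ref$weights <- ref$weights + d$weights
  }
  ref$total_mass <- sum(ref$weights)
  ref
}

#' Weighted quantiles of a binned distribution
#'
#' The reported value for probability `p` is the center of the bin where the
#' cumulative (normalized) mass first reaches `p` — the crossing convention.
#' The quantization error is bounded by half a bin width, below any reported
#' precision.
#'
#' @param d A `"sim_dist"` with positive total mass.
#' @param probs Probabilities (default the report set 10/25/50/75/90%).
#' @return Named numeric vector of quantiles (names `q10`, `q25`, `median`,
#'   `q75`, `q90` for the default probs).
#' @export
dist_quantiles <- function(d, probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  stopifnot(inherits(d, "sim_dist"))
  if (d$total_mass <= 0)
    stop("cannot take quantiles of an empty distribution", call. = FALSE)
  cdf <- cumsum(d$weights) / d$total_mass
  centers <- sim_dist_centers(d)
  out <- vapply(probs, function(p) {
    centers[which(cdf >= p - 1e-12)[1L]]
  }, numeric(1))
  nm <- ifelse(probs == 0.5, "median",
               paste0("q", formatC(100 * probs, format = "fg")))
  names(out) <- nm
  out
}

#' Wasserstein (earth mover's) distance between two binned distributions
#'
#' Both distributions are normalized to unit mass; then
#' `W1 = bin_width * sum(|CDF1 - CDF2|)`. Non-negative, zero iff the
#' normalized distributions are equal; satisfies the metric axioms.
#'
#' @param d1,d2 `"sim_dist"` objects with identical binning and positive
#'   mass.
#' @return W1, a non-negative scalar.
#' @export
wasserstein_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "sim_dist"), inherits(d2, "sim_dist"))
  if (!isTRUE(all.equal(c(d1$lo, d1$hi, d1$bin_width),
                        c(d2$lo, d2$hi, d2$bin_width), tolerance = 0)))
    stop("cannot compare distributions with mismatched binning",
         call. = FALSE)
  if (d1$total_mass <= 0 || d2$total_mass <= 0)
    stop("cannot compute W1 of an empty distribution", call. = FALSE)
  cdf1 <- cumsum(d1$weights) / d1$total_mass
  cdf2 <- cumsum(d2$weights) / d2$total_mass
  d1$bin_width * sum(abs(cdf1 - cdf2))
}

#' Rank prediction methods by the medians of their distributions
#'
#' Methods are ordered by descending median (rank 1 = largest); ties are
#' broken by larger 75% quantile, then by method name, and flagged in the
#' `tied` column. When an experimental reference distribution is supplied,
#' each report row carries the W1 distance to it.
#'
#' @param method_dists Named list of `"sim_dist"` objects, one per method.
#' @param experimental Optional `"sim_dist"`, the experimental
#'   reproducibility distribution.
#' @return A data.frame (one row per method): `method`, `n_precursors`,
#'   `q10`, `q25`, `median`, `q75`, `q90`, `w1_to_experimental`, `rank`,
#'   `tied`.
#' @export
rank_methods <- function(method_dists, experimental = NULL) {
  stopifnot(length(method_dists) >= 1L, !is.null(names(method_dists)))
  rows <- lapply(names(method_dists), function(m) {
    d <- method_dists[[m]]
    q <- dist_quantiles(d)
    data.frame(method = m, n_precursors = d$total_mass,
               q10 = q[["q10"]], q25 = q[["q25"]], median = q[["median"]],
               q75 = q[["q75"]], q90 = q[["q90"]],
               w1_to_experimental = if (is.null(experimental)) NA_real_
                                    else wasserstein_distance(d, experimental),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  ord <- order(-rep$median, -rep$q75, rep$method)
  rep <- rep[ord, , drop = FALSE]
  rep$rank <- seq_len(nrow(rep))
  rep$tied <- duplicated(rep$median) | duplicated(rep$median,
                                                  fromLast = TRUE)
  rownames(rep) <- NULL
  rep
}

#' Default peptide-length intervals for stratified reports
#'
#' Six intervals spanning the comparability range 7-30:
#' 7-10, 11-14, 15-18, 19-22, 23-26, 27-30. Interval boundaries are
#' configurable wherever they are used and are always declared in the
#' report.
#'
#' @return Integer vector of interval lower bounds plus the final upper
#'   bound + 1 (breaks for `findInterval`).
#' @export
default_length_breaks <- function() c(7L, 11L, 15L, 19L, 23L, 27L, 31L)

.length_bin_label <- function(n, breaks) {
  i <- findInterval(n, breaks)
  i[n < breaks[1L]] <- 0L
  lab <- paste0(breaks[-length(breaks)], "-", breaks[-1L] - 1L)
  out <- rep(NA_character_, length(n))
  ok <- i >= 1L & i < length(breaks)
  out[ok] <- lab[i[ok]]
  out[!ok] <- ifelse(n[!ok] < breaks[1L], paste0("<", breaks[1L]),
                     paste0(">=", breaks[length(breaks)]))
  out
}

#' Stratified similarity distributions
#'
#' Splits scored PSMs into disjoint, exhaustive strata and builds a
#' distribution per stratum with the same equal-precursor weighting rule;
#' precursor multiplicities are recomputed within each stratum. Available
#' stratifiers: precursor `charge`, peptide `length_bins`, acquisition
#' `nce`, and `ptm_status` (`"modified"` iff the peptide carries methionine
#' oxidation; fixed carbamidomethylation does not count).
#'
#' @param scored A data.frame with columns `score`, `precursor`, and the
#'   metadata needed by the stratifier (`charge`, `pep_n`, `nce`,
#'   `oxidized`).
#' @param by One of `"charge"`, `"length_bins"`, `"nce"`, `"ptm_status"`.
#' @param length_breaks Interval breaks for `length_bins`.
#' @param lo,hi,bin_width Binning parameters.
#' @return Named list of `"sim_dist"` objects, one per stratum.
#' @export
stratify_scores <- function(scored, by, length_breaks = default_length_breaks(),
                            lo = 0, hi = 1, bin_width = 0.001) {
  strata <- switch(by,
    charge = paste0("z", scored$charge),
    length_bins = .length_bin_label(scored$pep_n, length_breaks),
    nce = paste0("nce", scored$nce),
    ptm_status = ifelse(scored$oxidized, "modified", "unmodified"),
    stop("unknown stratifier: ", by, call. = FALSE))
  out <- lapply(split(seq_len(nrow(scored)), strata), function(idx) {
    build_distribution(scored$score[idx], scored$precursor[idx],
                       lo = lo, hi = hi, bin_width = bin_width)
  })
  out[order(names(out))]
}
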