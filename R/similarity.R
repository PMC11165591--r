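# Per-PSM similarity metrics between predicted and experimental intensity
# vectors, plus the experimental-reproducibility reference profile.

#' Normalized spectral angle between two intensity vectors
#'
#' `alpha = 1 - 2 * theta / pi`, where `theta` is the angle between the two
#' vectors. Because fragment intensities are non-negative, `theta` lies in
#' `[0, pi/2]` and `alpha` in `[0, 1]`, with 1 meaning identical direction and
#' 0 meaning orthogonal. The arccos argument is clamped to `[-1, 1]` (dot
#' products can exceed 1 by a few ulps) and `theta` to `[0, pi/2]`.
#'
#' @param u,v Non-negative numeric vectors of equal length; neither all zero.
#' @return The normalized angle, a scalar in `[0, 1]`.
#' @export
#' @examples
#' normalized_angle(c(1, 0), c(1, 1))  # 0.5
normalized_angle <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors have different layouts (lengths ", length(u), " vs ",
         length(v), ")", call. = FALSE)
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0)
    stop("undefined similarity: all-zero intensity vector", call. = FALSE)
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  theta <- min(pi / 2, max(0, theta))
  1 - 2 * theta / pi
}

#' Pearson correlation between two intensity vectors
#'
#' Standard sample correlation over paired slots. Vectors with zero variance
#' (all slots equal) have no defined correlation and are rejected with a
#' distinct condition class `"spectrangle_zero_variance"` so callers can
#' route them to an exclusion list rather than scoring them 0.
#'
#' @param u,v Numeric vectors of equal length, each with nonzero variance.
#' @return Pearson's r in `[-1, 1]`.
#' @export
pearson_sim <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors have different layouts (lengths ", length(u), " vs ",
         length(v), ")", call. = FALSE)
  if (stats::var(u) == 0 || stats::var(v) == 0)
    stop(errorCondition("undefined correlation: zero-variance vector",
                        class = "spectrangle_zero_variance"))
  stats::cor(u, v)
}

#' Reference experimental profile of a precursor
#'
#' Element-wise mean of the L2-normalized replicate intensity vectors of one
#' precursor. Only precursors with at least two replicate PSMs are eligible;
#' the resulting profile is the comparison target when building the
#' experimental-reproducibility distribution.
#'
#' @param replicates List of >= 2 non-negative, non-zero numeric vectors of
#'   equal length.
#' @return Numeric vector, the mean of the unit-normalized replicates.
#' @export
reference_profile <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 2L)
    stop("reference profile requires >= 2 replicate spectra", call. = FALSE)
  len <- unique(vapply(replicates, length, integer(1)))
  if (length(len) != 1L)
    stop("replicate vectors have different layouts", call. = FALSE)
  normed <- lapply(replicates, function(u) {
    nu <- sqrt(sum(u * u))
    if (nu == 0)
      stop("all-zero replicate in reference profile", call. = FALSE)
    u / nu
  })
  Reduce(`+`, normed) / length(normed)
}

#' Restrict an intensity vector to its singly-charged block
#'
#' Intensity vectors covering charges 1 and 2 store the charge-1 block first
#' in the canonical layout; this returns that block (and is the identity on
#' vectors that already cover only charge 1). Needed for predictors that emit
#' singly-charged fragment intensities only.
#'
#' @param u Intensity vector with `charges` attribute (as produced by the
#'   annotation and prediction readers), or a plain numeric vector together
#'   with `pep_n`.
#' @param pep_n Peptide length, required if `u` carries no attributes.
#' @return The charge-1 block, tagged `charges = 1`.
#' @export
restrict_charge1 <- function(u, pep_n = attr(u, "pep_n")) {
  charges <- attr(u, "charges")
  if (is.null(charges)) {
    if (is.null(pep_n))
      stop("cannot infer layout: supply pep_n or a tagged vector",
           call. = FALSE)
    charges <- if (length(u) == 2L * (pep_n - 1L)) 1L else c(1L, 2L)
  }
  if (identical(as.integer(charges), 1L)) return(u)
  n1 <- length(u) / length(charges)
  out <- u[seq_len(n1)]
  attr(out, "pep_n") <- pep_n
  attr(out, "charges") <- 1L
  out
}
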