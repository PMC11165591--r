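# Monoisotopic mass arithmetic and theoretical m/z enumeration for b/y ions.

#' Monoisotopic mass constants
#'
#' Community-standard monoisotopic residue masses for the 20 canonical amino
#' acids, together with the proton and water masses and the mass deltas of the
#' two supported modifications (methionine oxidation and cysteine
#' carbamidomethylation). The table is built once at load time and treated as
#' immutable.
#'
#' @return A list with components `residues` (named numeric vector, Da),
#'   `proton` (Da), `water` (Da) and `mods` (named numeric vector of
#'   modification deltas, Da).
#' @export
#' @examples
#' mass_constants()$residues[["G"]]
mass_constants <- function() .spectrangle_masses

.spectrangle_masses <- list(
  residues = c(
    G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
  ),
  proton = 1.007276,
  water  = 18.010565,
  mods   = c(Oxidation = 15.994915, Carbamidomethyl = 57.021464)
)

.mod_targets <- c(Oxidation = "M", Carbamidomethyl = "C")

#' Construct a peptide
#'
#' A peptide is a sequence over the 20 canonical amino-acid letters plus a
#' (possibly empty) set of residue modifications. Only methionine oxidation
#' and cysteine carbamidomethylation are supported; peptides containing the
#' nonstandard residues U or O are rejected. By default carbamidomethyl is
#' applied as a fixed modification on every cysteine, mirroring common
#' database-search settings.
#'
#' @param sequence Uppercase amino-acid string, length >= 2.
#' @param mods `NULL`, or a data.frame with columns `pos` (1-based residue
#'   index) and `mod` (`"Oxidation"` or `"Carbamidomethyl"`).
#' @param fixed_carbamidomethyl Apply carbamidomethyl to every C not already
#'   modified (default `TRUE`).
#' @return An object of class `"peptide"`: list with `sequence`, `residues`
#'   (character vector), `mods` (data.frame `pos`, `mod`).
#' @export
#' @examples
#' peptide("ACDEK")
#' peptide("AMK", mods = data.frame(pos = 2, mod = "Oxidation"))
peptide <- function(sequence, mods = NULL, fixed_carbamidomethyl = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(residues)
  if (n < 2L)
    stop("peptide sequence must have length >= 2, got ", n, call. = FALSE)
  bad <- which(residues %in% c("U", "O"))
  if (length(bad))
    stop("nonstandard residue '", residues[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  unknown <- which(!residues %in% names(.spectrangle_masses$residues))
  if (length(unknown))
    stop("unknown residue letter '", residues[unknown[1L]], "' at position ",
         unknown[1L], call. = FALSE)

  if (is.null(mods)) {
    mods <- data.frame(pos = integer(), mod = character(),
                       stringsAsFactors = FALSE)
  } else {
    mods <- data.frame(pos = as.integer(mods$pos),
                       mod = as.character(mods$mod), stringsAsFactors = FALSE)
  }
  if (fixed_carbamidomethyl) {
    cys <- setdiff(which(residues == "C"), mods$pos)
    if (length(cys))
      mods <- rbind(mods, data.frame(pos = cys, mod = "Carbamidomethyl",
                                     stringsAsFactors = FALSE))
  }
  if (nrow(mods)) {
    mods <- mods[order(mods$pos), , drop = FALSE]
    rownames(mods) <- NULL
    if (anyDuplicated(mods$pos))
      stop("residue at position ", mods$pos[duplicated(mods$pos)][1L],
           " carries two modifications", call. = FALSE)
    if (any(mods$pos < 1L | mods$pos > n))
      stop("modification position out of range 1..", n, call. = FALSE)
    bad_mod <- which(!mods$mod %in% names(.mod_targets))
    if (length(bad_mod))
      stop("unsupported modification '", mods$mod[bad_mod[1L]], "'",
           call. = FALSE)
    tgt <- .mod_targets[mods$mod]
    off <- which(residues[mods$pos] != tgt)
    if (length(off))
      stop(mods$mod[off[1L]], " placed on '", residues[mods$pos[off[1L]]],
           "' at position ", mods$pos[off[1L]], " (requires ", tgt[off[1L]],
           ")", call. = FALSE)
  }
  structure(list(sequence = sequence, residues = residues, mods = mods),
            class = "peptide")
}

#' Parse a peptide string with inline modification tags
#'
#' Accepts plain uppercase sequences (`"ACDEK"`) or inline bracketed tags in
#' ProForma style (`"AM[Oxidation]K"`), where each tag modifies the residue
#' immediately preceding it.
#'
#' @param x Peptide string.
#' @param fixed_carbamidomethyl Passed to [peptide()].
#' @return A `"peptide"` object.
#' @export
parse_peptide <- function(x, fixed_carbamidomethyl = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  seq_chars <- character()
  mods <- list()
  i <- 1L
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1L]
      if (is.na(close))
        stop("unterminated modification tag in '", x, "'", call. = FALSE)
      if (!length(seq_chars))
        stop("modification tag before first residue in '", x, "'",
             call. = FALSE)
      tag <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      mods[[length(mods) + 1L]] <- data.frame(
        pos = length(seq_chars), mod = tag, stringsAsFactors = FALSE)
      i <- close + 1L
    } else {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  peptide(paste(seq_chars, collapse = ""),
          mods = if (length(mods)) do.call(rbind, mods) else NULL,
          fixed_carbamidomethyl = fixed_carbamidomethyl)
}

#' Canonical string form of a peptide
#'
#' Inverse of [parse_peptide()]: the sequence with inline `[Mod]` tags. Used
#' as the sequence half of precursor identifiers, so modified and unmodified
#' forms of the same sequence are distinct precursors.
#'
#' @param pep A `"peptide"` object.
#' @return Character scalar.
#' @export
peptide_string <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  out <- pep$residues
  if (nrow(pep$mods))
    out[pep$mods$pos] <- paste0(out[pep$mods$pos], "[", pep$mods$mod, "]")
  paste(out, collapse = "")
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", peptide_string(x), " (N = ", length(x$residues), ")\n",
      sep = "")
  invisible(x)
}

# per-residue mass including modification deltas
.residue_mass_vector <- function(pep) {
  m <- unname(.spectrangle_masses$residues[pep$residues])
  if (nrow(pep$mods))
    m[pep$mods$pos] <- m[pep$mods$pos] +
      unname(.spectrangle_masses$mods[pep$mods$mod])
  m
}

#' Monoisotopic mass of a peptide
#'
#' Sum of (modified) residue masses plus one water.
#'
#' @param pep A `"peptide"` object.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mono_mass(peptide("AG"))  # 146.06913
peptide_mono_mass <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  sum(.residue_mass_vector(pep)) + .spectrangle_masses$water
}

#' Theoretical m/z of a b or y fragment ion
#'
#' Neutral b mass is the sum of the first `ordinal` (modified) residue masses;
#' neutral y mass is the sum of the last `ordinal` residue masses plus water.
#' `m/z = (neutral + charge * proton) / charge`.
#'
#' @param pep A `"peptide"` object.
#' @param series `"b"` or `"y"`.
#' @param ordinal Fragment ordinal, 1..N-1.
#' @param charge Fragment charge (1 or 2 in all pipeline paths).
#' @return m/z in Thomson.
#' @export
#' @examples
#' fragment_mz(peptide("AG"), "b", 1, 1)  # 72.04439
fragment_mz <- function(pep, series, ordinal, charge = 1L) {
  stopifnot(inherits(pep, "peptide"), series %in% c("b", "y"),
            charge >= 1L)
  n <- length(pep$residues)
  ordinal <- as.integer(ordinal)
  if (ordinal < 1L || ordinal >= n)
    stop("fragment ordinal ", ordinal, " out of range 1..", n - 1L,
         call. = FALSE)
  rm <- .residue_mass_vector(pep)
  neutral <- if (series == "b") sum(rm[seq_len(ordinal)])
             else sum(rm[(n - ordinal + 1L):n]) + .spectrangle_masses$water
  (neutral + charge * .spectrangle_masses$proton) / charge
}

#' Enumerate the canonical fragment layout of a peptide
#'
#' The canonical layout fixes the slot order of every intensity vector in the
#' package: within each requested charge (ascending), b1..b(N-1) then
#' y1..y(N-1). The order is deterministic, so experimental and predicted
#' vectors built for the same peptide always align slot by slot.
#'
#' @param pep A `"peptide"` object.
#' @param charges Subset of `c(1, 2)`.
#' @return A data.frame with columns `series`, `ordinal`, `charge`, `mz`,
#'   one row per slot, `|charges| * 2 * (N - 1)` rows in total.
#' @export
enumerate_fragments <- function(pep, charges = c(1L, 2L)) {
  stopifnot(inherits(pep, "peptide"))
  charges <- sort(unique(as.integer(charges)))
  if (!all(charges %in% c(1L, 2L)))
    stop("fragment charges must be a subset of {1, 2}", call. = FALSE)
  n <- length(pep$residues)
  rm <- .residue_mass_vector(pep)
  b_neutral <- cumsum(rm)[seq_len(n - 1L)]
  # y_i = sum of the LAST i residue masses + water, ordinal ascending
  y_neutral <- cumsum(rev(rm))[seq_len(n - 1L)] + .spectrangle_masses$water
  out <- do.call(rbind, lapply(charges, function(z) {
    data.frame(
      series  = rep(c("b", "y"), each = n - 1L),
      ordinal = rep(seq_len(n - 1L), 2L),
      charge  = z,
      mz      = (c(b_neutral, y_neutral) + z * .spectrangle_masses$proton) / z,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Slot index of a fragment in the canonical layout
#'
#' @param n Peptide length.
#' @param series Character vector of `"b"`/`"y"`.
#' @param ordinal Integer vector of ordinals.
#' @param charge Integer vector of fragment charges.
#' @param charges Charge coverage of the layout.
#' @return Integer vector of 1-based slot indices.
#' @export
fragment_slot <- function(n, series, ordinal, charge, charges = c(1L, 2L)) {
  charges <- sort(unique(as.integer(charges)))
  block <- match(as.integer(charge), charges)
  if (anyNA(block))
    stop("fragment charge outside layout coverage", call. = FALSE)
  if (any(ordinal < 1L | ordinal >= n))
    stop("fragment ordinal out of range 1..", n - 1L, call. = FALSE)
  (block - 1L) * 2L * (n - 1L) + (series == "y") * (n - 1L) + ordinal
}

# fragment m/z values in canonical order without data.frame overhead
.fragment_mz_vector <- function(pep, charges) {
  n <- length(pep$residues)
  rm <- .residue_mass_vector(pep)
  b <- cumsum(rm)[seq_len(n - 1L)]
  y <- cumsum(rev(rm))[seq_len(n - 1L)] + .spectrangle_masses$water
  neutral <- c(b, y)
  unlist(lapply(sort(unique(as.integer(charges))), function(z)
    (neutral + z * .spectrangle_masses$proton) / z), use.names = FALSE)
}

# empty intensity vector in canonical layout, tagged with its coverage
.blank_vector <- function(n, charges) {
  charges <- sort(unique(as.integer(charges)))
  v <- numeric(length(charges) * 2L * (n - 1L))
  attr(v, "pep_n") <- n
  attr(v, "charges") <- charges
  v
}
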