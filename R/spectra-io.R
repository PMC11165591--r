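# Readers and writers for the file surface: MGF spectra, PSM tables,
# precursor tables, long-format prediction tables.
#
# All tables are UTF-8 tab-separated with a header row and '.' decimals.

#' Read an MGF (Mascot generic format) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. The scan number is taken from the
#' `SCANS=` header when present, otherwise from a `scan=<n>` token embedded
#' in `TITLE=` (both dialects occur in converter output). Blocks lacking any
#' scan number are reported and skipped.
#'
#' @param path Path to an MGF file.
#' @param source_file Label stored on each spectrum; defaults to
#'   `basename(path)` and is the join key against the PSM table's raw-file
#'   column.
#' @return A list of spectrum records, each a list with `source_file`,
#'   `scan`, `mz` and `intensity` (peaks sorted by ascending m/z). Skipped
#'   blocks are attached as attribute `"skipped"`.
#' @export
read_mgf <- function(path, source_file = basename(path)) {
  if (!file.exists(path))
    stop("cannot read MGF file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path,
         call. = FALSE)
  spectra <- vector("list", length(begins))
  skipped <- integer()
  seen_scans <- integer()
  for (k in seq_along(begins)) {
    body <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    is_header <- grepl("=", body, fixed = TRUE)
    headers <- body[is_header]
    peak_lines <- body[!is_header & nzchar(trimws(body))]
    scan <- NA_integer_
    sc <- grep("^SCANS=", headers, value = TRUE)
    if (length(sc)) {
      scan <- suppressWarnings(as.integer(sub("^SCANS=", "", sc[1L])))
    } else {
      tt <- grep("^TITLE=", headers, value = TRUE)
      if (length(tt)) {
        m <- regmatches(tt[1L], regexpr("scan=([0-9]+)", tt[1L]))
        if (length(m))
          scan <- as.integer(sub("scan=", "", m, fixed = TRUE))
      }
    }
    if (is.na(scan)) {
      warning("MGF block ", k, " in ", path,
              " has no scan number; skipped", call. = FALSE)
      skipped <- c(skipped, k)
      next
    }
    if (scan %in% seen_scans)
      stop("duplicate scan number ", scan, " in ", path, call. = FALSE)
    seen_scans <- c(seen_scans, scan)
    if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "[ \t]+")
      bad <- which(vapply(fields, function(f)
        length(f) < 2L || anyNA(suppressWarnings(as.numeric(f[1:2]))),
        logical(1)))
      if (length(bad)) {
        line_no <- begins[k] + which(!is_header &
                                       nzchar(trimws(body)))[bad[1L]]
        stop("malformed peak line ", line_no, " in ", path, ": '",
             peak_lines[bad[1L]], "'", call. = FALSE)
      }
      mz <- vapply(fields, function(f) as.numeric(f[1L]), numeric(1))
      intensity <- vapply(fields, function(f) as.numeric(f[2L]), numeric(1))
      if (any(intensity < 0))
        stop("negative intensity in scan ", scan, " of ", path,
             call. = FALSE)
      ord <- order(mz)
      mz <- mz[ord]; intensity <- intensity[ord]
    } else {
      warning("scan ", scan, " in ", path, " has no peaks", call. = FALSE)
      mz <- numeric(); intensity <- numeric()
    }
    spectra[[k]] <- list(source_file = source_file, scan = scan,
                         mz = mz, intensity = intensity)
  }
  spectra <- spectra[!vapply(spectra, is.null, logical(1))]
  attr(spectra, "skipped") <- skipped
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra List of spectrum records as returned by [read_mgf()].
#' @param path Output path.
#' @param pepmass Optional named extra headers are not supported; a
#'   `PEPMASS=0` placeholder is written when records carry no `pepmass`.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, pepmass = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s scan=%d", sp$source_file, sp$scan), con)
    writeLines(sprintf("SCANS=%d", sp$scan), con)
    pm <- if (!is.null(sp$pepmass)) sp$pepmass else 0
    writeLines(sprintf("PEPMASS=%.5f", pm), con)
    if (!is.null(sp$charge))
      writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    if (length(sp$mz))
      writeLines(sprintf("%.6f %.8g", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

# map MaxQuant-style modification tokens to internal names
.mod_aliases <- c(
  "Oxidation" = "Oxidation",
  "Oxidation (M)" = "Oxidation",
  "ox" = "Oxidation",
  "Carbamidomethyl" = "Carbamidomethyl",
  "Carbamidomethyl (C)" = "Carbamidomethyl",
  "ca" = "Carbamidomethyl"
)

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Read a PSM table
#'
#' Minimal tab-separated schema that MaxQuant's `msms.txt` satisfies after
#' column renaming: `raw_file`, `scan`, `sequence`, `charge` and optionally
#' `modifications`. The sequence may carry inline `[Oxidation]` tags;
#' alternatively the `modifications` column lists semicolon-separated
#' `position:Name` entries (e.g. `"4:Oxidation (M)"`), with `""` or
#' `"Unmodified"` meaning none. Rows with unsupported modifications or
#' nonstandard residues (U/O) are not silently dropped: they are returned in
#' a separate exclusion table with a reason per row.
#'
#' @param path Path to the TSV file.
#' @param fixed_carbamidomethyl Apply carbamidomethyl to every cysteine.
#' @return A list with `psms` (list of records: `raw_file`, `scan`,
#'   `peptide`, `charge`) and `excluded` (data.frame `row`, `sequence`,
#'   `reason`).
#' @export
read_psm_table <- function(path, fixed_carbamidomethyl = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("raw_file", "scan", "sequence", "charge"),
                   "PSM table")
  has_modcol <- "modifications" %in% names(df)
  psms <- vector("list", nrow(df))
  excl <- list()
  for (i in seq_len(nrow(df))) {
    seq_i <- df$sequence[i]
    reason <- NULL
    pep <- NULL
    mods <- NULL
    if (has_modcol) {
      spec <- trimws(df$modifications[i])
      if (nzchar(spec) && !identical(spec, "Unmodified")) {
        entries <- strsplit(spec, ";", fixed = TRUE)[[1L]]
        parts <- strsplit(trimws(entries), ":", fixed = TRUE)
        ok <- vapply(parts, length, integer(1)) == 2L
        if (!all(ok)) {
          reason <- paste0("unparseable modification spec '", spec, "'")
        } else {
          nm <- vapply(parts, `[`, character(1), 2L)
          mapped <- .mod_aliases[trimws(nm)]
          if (anyNA(mapped)) {
            reason <- "unsupported PTM"
          } else {
            mods <- data.frame(
              pos = as.integer(vapply(parts, `[`, character(1), 1L)),
              mod = unname(mapped), stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (is.null(reason)) {
      pep <- tryCatch(
        if (is.null(mods))
          parse_peptide(seq_i, fixed_carbamidomethyl = fixed_carbamidomethyl)
        else
          peptide(seq_i, mods = mods,
                  fixed_carbamidomethyl = fixed_carbamidomethyl),
        error = function(e) conditionMessage(e))
      if (is.character(pep)) {
        reason <- if (grepl("nonstandard residue", pep))
          "nonstandard residue"
        else if (grepl("unsupported modification", pep))
          "unsupported PTM"
        else pep
        pep <- NULL
      }
    }
    if (is.null(pep)) {
      excl[[length(excl) + 1L]] <- data.frame(
        row = i, sequence = seq_i, reason = reason,
        stringsAsFactors = FALSE)
    } else {
      psms[[i]] <- list(raw_file = df$raw_file[i],
                        scan = as.integer(df$scan[i]),
                        peptide = pep,
                        charge = as.integer(df$charge[i]))
    }
  }
  list(psms = psms[!vapply(psms, is.null, logical(1))],
       excluded = if (length(excl)) do.call(rbind, excl)
                  else data.frame(row = integer(), sequence = character(),
                                  reason = character(),
                                  stringsAsFactors = FALSE))
}

#' Read a precursor table
#'
#' One precursor per line with its acquisition metadata: columns `sequence`
#' (inline-tag notation), `charge`, `nce`, `instrument`, `dissociation`
#' (HCD or CID) and `mass_analyzer` (FTMS or ITMS).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the six columns plus `precursor`, the canonical
#'   `sequence/charge` identifier.
#' @export
read_precursor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("sequence", "charge", "nce", "instrument",
                         "dissociation", "mass_analyzer"), "precursor table")
  if (!all(df$dissociation %in% c("HCD", "CID")))
    stop("dissociation must be HCD or CID", call. = FALSE)
  if (!all(df$mass_analyzer %in% c("FTMS", "ITMS")))
    stop("mass_analyzer must be FTMS or ITMS", call. = FALSE)
  if (any(df$nce <= 0))
    stop("nce must be positive", call. = FALSE)
  df$charge <- as.integer(df$charge)
  df$precursor <- paste(df$sequence, df$charge, sep = "/")
  if (anyDuplicated(df$precursor))
    stop("duplicate precursor rows in ", path, call. = FALSE)
  df
}

#' Read a long-format prediction table
#'
#' Columns: `sequence` (inline-tag notation), `charge` (precursor charge),
#' `series` (b/y), `ordinal`, `fragment_charge`, `intensity`. Entries are
#' assembled into canonical-layout vectors; fragments absent from the table
#' are zero-filled. Duplicate (precursor, fragment) rows, negative
#' intensities and out-of-range ordinals are rejected.
#'
#' @param path Path to the TSV file.
#' @param method_name Label for the prediction method.
#' @param charges Charge coverage of the assembled vectors.
#' @return A list of class `"prediction_table"` with `method`, `charges` and
#'   `entries` (named list precursor id -> intensity vector).
#' @export
read_predictions <- function(path, method_name, charges = c(1L, 2L)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("sequence", "charge", "series", "ordinal",
                         "fragment_charge", "intensity"),
                   "prediction table")
  if (any(df$intensity < 0))
    stop("negative predicted intensity in ", path, call. = FALSE)
  if (!all(df$series %in% c("b", "y")))
    stop("prediction series must be b or y", call. = FALSE)
  charges <- sort(unique(as.integer(charges)))
  df$precursor <- paste(df$sequence, as.integer(df$charge), sep = "/")
  keep <- df$fragment_charge %in% charges
  df <- df[keep, , drop = FALSE]
  entries <- list()
  for (prec in unique(df$precursor)) {
    sub <- df[df$precursor == prec, , drop = FALSE]
    pep <- parse_peptide(sub$sequence[1L])
    n <- length(pep$residues)
    if (any(sub$ordinal >= n))
      stop("fragment ordinal >= peptide length for precursor ", prec,
           call. = FALSE)
    slot <- fragment_slot(n, sub$series, as.integer(sub$ordinal),
                          as.integer(sub$fragment_charge), charges)
    if (anyDuplicated(slot))
      stop("duplicate fragment row for precursor ", prec, call. = FALSE)
    v <- .blank_vector(n, charges)
    v[slot] <- sub$intensity
    entries[[prec]] <- v
  }
  structure(list(method = method_name, charges = charges, entries = entries),
            class = "prediction_table")
}

#' Write a prediction table in long format
#'
#' Serializes the entry map back to the TSV schema read by
#' [read_predictions()]; the round trip is the identity on the entry map.
#' Zero slots are omitted (the reader zero-fills them).
#'
#' @param pred A `"prediction_table"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(inherits(pred, "prediction_table"))
  rows <- lapply(names(pred$entries), function(prec) {
    v <- pred$entries[[prec]]
    n <- attr(v, "pep_n")
    lay <- data.frame(
      series  = rep(rep(c("b", "y"), each = n - 1L), length(pred$charges)),
      ordinal = rep(seq_len(n - 1L), 2L * length(pred$charges)),
      fragment_charge = rep(pred$charges, each = 2L * (n - 1L)),
      stringsAsFactors = FALSE)
    nz <- which(v > 0)
    slash <- regexpr("/[0-9]+$", prec)
    data.frame(sequence = substr(prec, 1L, slash - 1L),
               charge = as.integer(substr(prec, slash + 1L, nchar(prec))),
               lay[nz, , drop = FALSE],
               intensity = as.numeric(v[nz]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble an intensity vector from predicted (m/z, intensity) pairs
#'
#' For predictors that label output by m/z instead of ion name: each
#' predicted peak is assigned to the unique theoretical b/y fragment within
#' `tol_ppm`; theoretical positions with no assigned peak are zero. A peak
#' within tolerance of two theoretical fragments is assigned to the nearest,
#' with a warning; peaks matching nothing are dropped with a warning.
#'
#' @param mz,intensity Predicted peak list.
#' @param pep A `"peptide"` object.
#' @param charges Charge coverage of the output vector.
#' @param tol_ppm Matching tolerance in ppm (default 20).
#' @return Canonical-layout intensity vector.
#' @export
match_predictions_by_mz <- function(mz, intensity, pep,
                                    charges = c(1L, 2L), tol_ppm = 20) {
  stopifnot(length(mz) == length(intensity), tol_ppm > 0)
  frags <- enumerate_fragments(pep, charges)
  v <- .blank_vector(length(pep$residues), charges)
  if (!length(mz)) return(v)
  dropped <- 0L
  for (j in seq_along(mz)) {
    d <- abs(mz[j] - frags$mz)
    within <- which(d / frags$mz * 1e6 <= tol_ppm)
    if (!length(within)) { dropped <- dropped + 1L; next }
    if (length(within) > 1L)
      warning("predicted peak ", mz[j], " within tolerance of ",
              length(within), " theoretical fragments; assigned to nearest",
              call. = FALSE)
    v[within[which.min(d[within])]] <- intensity[j]
  }
  if (dropped)
    warning(dropped, " predicted peak(s) matched no theoretical fragment",
            call. = FALSE)
  v
}
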