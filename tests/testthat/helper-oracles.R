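# Independent oracles: every expected value asserted against the package is
# computed here by a deliberately naive, separately coded route.

# --- brute-force mass calculator (independent constants table) -----------

.oracle_res <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)
.oracle_proton <- 1.007276
.oracle_water <- 18.010565
.oracle_mod <- c(Oxidation = 15.994915, Carbamidomethyl = 57.021464)

# seq: character vector of residues; mods: named by position
oracle_residue_masses <- function(res, mod_pos = integer(),
                                  mod_name = character()) {
  m <- numeric(length(res))
  for (i in seq_along(res)) {
    m[i] <- .oracle_res[[res[i]]]
    hit <- which(mod_pos == i)
    if (length(hit)) m[i] <- m[i] + .oracle_mod[[mod_name[hit]]]
  }
  m
}

oracle_peptide_mass <- function(res, mod_pos = integer(),
                                mod_name = character()) {
  sum(oracle_residue_masses(res, mod_pos, mod_name)) + .oracle_water
}

oracle_fragment_mz <- function(res, mod_pos, mod_name, series, ordinal,
                               charge) {
  m <- oracle_residue_masses(res, mod_pos, mod_name)
  neutral <- 0
  if (series == "b") {
    for (i in 1:ordinal) neutral <- neutral + m[i]
  } else {
    for (i in (length(m) - ordinal + 1):length(m)) neutral <- neutral + m[i]
    neutral <- neutral + .oracle_water
  }
  (neutral + charge * .oracle_proton) / charge
}

# --- random peptide generator --------------------------------------------

random_test_peptide <- function(min_n = 5, max_n = 25, p_ox = 0.3) {
  n <- sample(min_n:max_n, 1)
  res <- sample(names(.oracle_res), n, replace = TRUE)
  mpos <- which(res == "M")
  ox <- mpos[runif(length(mpos)) < p_ox]
  cys <- which(res == "C")
  mod_pos <- c(ox, cys)
  mod_name <- c(rep("Oxidation", length(ox)),
                rep("Carbamidomethyl", length(cys)))
  pep <- peptide(paste(res, collapse = ""),
                 mods = if (length(ox))
                   data.frame(pos = ox, mod = "Oxidation") else NULL,
                 fixed_carbamidomethyl = TRUE)
  list(pep = pep, res = res, mod_pos = mod_pos, mod_name = mod_name)
}

# --- quadratic brute-force peak matcher ----------------------------------

# for each theoretical m/z scan ALL peaks; closest within tolerance wins,
# ties by higher intensity; no peak -> 0
oracle_match <- function(peak_mz, peak_int, theo_mz, mode, value) {
  out <- numeric(length(theo_mz))
  for (k in seq_along(theo_mz)) {
    best_d <- Inf; best_i <- NA
    for (j in seq_along(peak_mz)) {
      d <- abs(peak_mz[j] - theo_mz[k])
      ok <- if (mode == "ppm") d / theo_mz[k] * 1e6 <= value else d <= value
      if (!ok) next
      if (d < best_d || (d == best_d && !is.na(best_i) &&
                         peak_int[j] > peak_int[best_i])) {
        best_d <- d; best_i <- j
      }
    }
    if (!is.na(best_i)) out[k] <- peak_int[best_i]
  }
  out
}

# --- naive weighted histogram accumulation -------------------------------

oracle_hist <- function(scores, ids, lo, hi, bw) {
  nb <- round((hi - lo) / bw)
  counts <- table(ids)
  w <- numeric(nb)
  for (i in seq_along(scores)) {
    k <- floor((scores[i] - lo) / bw) + 1
    if (scores[i] >= hi - 1e-12) k <- nb
    w[k] <- w[k] + 1 / counts[[ids[i]]]
  }
  w
}

# --- sampling-based W1 transport oracle ----------------------------------

oracle_w1_sampling <- function(d1, d2, n = 2e5) {
  centers <- sim_dist_centers(d1)
  x1 <- sample(centers, n, replace = TRUE, prob = d1$weights)
  x2 <- sample(centers, n, replace = TRUE, prob = d2$weights)
  mean(abs(sort(x1) - sort(x2)))
}

# --- misc builders --------------------------------------------------------

make_annotated <- function(precursor = "PEPTIDEK/2", charge = 2L,
                           pep_n = 8L, nce = 27, instrument = "QE",
                           dissociation = "HCD", mass_analyzer = "FTMS",
                           oxidized = FALSE, intensities = NULL,
                           charges = c(1L, 2L), scan = 1L) {
  if (is.null(intensities)) {
    intensities <- abs(rnorm(length(charges) * 2L * (pep_n - 1L)))
  }
  list(raw_file = "x.mgf", scan = scan, precursor = precursor,
       charge = charge, nce = nce, instrument = instrument,
       dissociation = dissociation, mass_analyzer = mass_analyzer,
       pep_n = pep_n, oxidized = oxidized, intensities = intensities)
}

rand_dist <- function(nbins_used = 50, lo = 0, hi = 1, bw = 0.001) {
  d <- sim_dist_empty(lo, hi, bw)
  idx <- sample(seq_along(d$weights), nbins_used)
  d$weights[idx] <- runif(nbins_used)
  d$total_mass <- sum(d$weights)
  d
}
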