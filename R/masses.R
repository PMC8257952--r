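# Peptide monoisotopic masses and precursor m/z for verifying targeted
# (parallel reaction monitoring) peptide lists.

# Monoisotopic residue masses in Da (residue = amino acid minus water),
# standard values to 5 decimals. This table and the two physical constants
# below are the single source of truth for all mass arithmetic.
RESIDUE_MONO_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER  <- 18.010565 # monoisotopic H2O, Da
MASS_PROTON <- 1.007276  # proton, Da

# Mass deltas of the modifications used in the study's search settings.
MOD_DELTAS <- c(
  oxidation       = 15.99491, # Met oxidation (variable)
  carbamidomethyl = 57.02146  # Cys carbamidomethylation (fixed)
)

#' Construct a (possibly modified) peptide
#'
#' A peptide is a string of the twenty standard one-letter residue codes plus
#' an optional list of mass modifications. Built-in modification names are
#' `"oxidation"` (+15.99491 Da, Met) and `"carbamidomethyl"` (+57.02146 Da,
#' Cys); arbitrary deltas can be given numerically.
#'
#' @param sequence Character scalar of one-letter residue codes.
#' @param mods Optional list of modifications. Each element is either a
#'   built-in modification name, or a list with elements `delta` (Da) and
#'   optionally `name` and `position` (1-based residue index). A character
#'   vector of names is also accepted.
#' @return An object of class `peptide`.
#' @examples
#' peptide("ALAAELNQLR")
#' peptide("LHFFMPGFAPLTSR", mods = list(list(name = "oxidation",
#'   delta = 15.99491, position = 5)))
#' @export
peptide <- function(sequence, mods = list()) {
  stopifnot(is_string(sequence), nzchar(sequence))
  sequence <- toupper(sequence)
  residues <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(residues, names(RESIDUE_MONO_MASS))
  if (length(unknown) > 0) {
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "))
  }
  if (is.character(mods)) mods <- as.list(mods)
  mods <- lapply(mods, function(m) {
    if (is_string(m)) {
      if (!m %in% names(MOD_DELTAS)) {
        stop("unknown modification name: ", m)
      }
      m <- list(name = m, delta = unname(MOD_DELTAS[[m]]))
    }
    stopifnot(is.list(m), is.numeric(m$delta))
    if (!is.null(m$position)) {
      if (m$position < 1 || m$position > length(residues)) {
        stop("modification position ", m$position,
             " outside sequence of length ", length(residues))
      }
    }
    m
  })
  structure(list(sequence = sequence, mods = mods), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  modtxt <- if (length(x$mods) == 0) "" else
    paste0(" + ", paste(vapply(x$mods, function(m) {
      paste0(m$name %||% "mod",
             if (!is.null(m$position)) paste0("@", m$position) else "",
             sprintf(" (%+.5f Da)", m$delta))
    }, character(1)), collapse = ", "))
  cat("<peptide> ", x$sequence, modtxt, "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of the monoisotopic residue masses, one water (18.010565 Da) for the
#' termini, and any modification deltas.
#'
#' @param pep A [peptide()] or a bare sequence string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("G") # 75.03203
#' @export
monoisotopic_mass <- function(pep) {
  if (is.character(pep)) pep <- peptide(pep)
  stopifnot(inherits(pep, "peptide"))
  residues <- strsplit(pep$sequence, "")[[1]]
  m <- sum(RESIDUE_MONO_MASS[residues]) + MASS_WATER
  if (length(pep$mods) > 0) {
    m <- m + sum(vapply(pep$mods, function(x) x$delta, numeric(1)))
  }
  unname(m)
}

#' Precursor m/z at a given charge state
#'
#' `(M + z * 1.007276) / z` for neutral monoisotopic mass `M` and positive
#' integer charge `z`.
#'
#' @param mass Neutral monoisotopic mass in Da (or a [peptide()] / sequence,
#'   which is first passed through [monoisotopic_mass()]).
#' @param z Charge state, integer >= 1.
#' @return Precursor m/z.
#' @examples
#' precursor_mz("ALAAELNQLR", 2) # 549.817
#' @export
precursor_mz <- function(mass, z) {
  stopifnot(length(z) == 1L, is.numeric(z), z >= 1, z == round(z))
  if (is.character(mass) || inherits(mass, "peptide")) {
    mass <- monoisotopic_mass(mass)
  }
  (mass + z * MASS_PROTON) / z
}

#' The study's PRM target list
#'
#' The four GFAP / TUBB3 peptides acquired in targeted (PRM) mode, with their
#' expected precursor m/z and retention times. The LHFFMPGFAPLTSR target was
#' reported with a Met-oxidation annotation, but its printed precursor m/z
#' corresponds to the unmodified peptide (the oxidized form would be ~818.92
#' at 2+); the list therefore carries the annotation in `declared_mods` while
#' leaving `mods` empty, and [verify_targets()] flags the discrepancy.
#'
#' @return A data.frame with columns `protein`, `peptide`, `mods`,
#'   `declared_mods`, `z`, `expected_mz`, `rt_min`.
#' @export
prm_target_list <- function() {
  data.frame(
    protein = c("TUBB3", "TUBB3", "GFAP", "GFAP"),
    peptide = c("ISVYYNEASSHK", "LHFFMPGFAPLTSR", "ALAAELNQLR",
                "LEVERDNLAQDLATVR"),
    mods = c("", "", "", ""),
    declared_mods = c("", "oxidation@5", "", ""),
    z = c(3L, 2L, 2L, 3L),
    expected_mz = c(466.561, 810.921, 549.817, 614.663),
    rt_min = c(22, 76, 45, 54),
    stringsAsFactors = FALSE
  )
}

parse_mods_field <- function(s) {
  # "oxidation@5;carbamidomethyl" -> list of mod specs
  if (is.na(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, ";")[[1]], function(tok) {
    tok <- trimws(tok)
    parts <- strsplit(tok, "@")[[1]]
    name <- parts[1]
    if (!name %in% names(MOD_DELTAS)) stop("unknown modification name: ", name)
    m <- list(name = name, delta = unname(MOD_DELTAS[[name]]))
    if (length(parts) > 1) m$position <- as.integer(parts[2])
    m
  })
}

#' Verify a PRM target list against computed precursor m/z
#'
#' Recomputes each target's precursor m/z from its sequence, modifications
#' and charge, and compares with the expected value at a tolerance. Targets
#' whose `declared_mods` were not applied (because the expected m/z matches
#' the unmodified form) are flagged in the `note` column rather than
#' silently passed.
#'
#' @param targets A data.frame like [prm_target_list()] (columns `peptide`,
#'   `z`, `expected_mz`; optional `protein`, `mods`, `declared_mods`), or a
#'   path to such a CSV.
#' @param tolerance_mz Absolute m/z tolerance for a pass (> 0).
#' @return A data.frame report with `computed_mz`, `delta_mz`, `pass` and
#'   `note` columns appended.
#' @examples
#' verify_targets(prm_target_list(), tolerance_mz = 0.005)
#' @export
verify_targets <- function(targets, tolerance_mz = 0.005) {
  stopifnot(is.numeric(tolerance_mz), tolerance_mz > 0)
  if (is.character(targets)) {
    targets <- utils::read.csv(targets, stringsAsFactors = FALSE)
  }
  need <- c("peptide", "z", "expected_mz")
  missing <- setdiff(need, names(targets))
  if (length(missing) > 0) {
    stop("target list lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(targets$mods)) targets$mods <- ""
  if (is.null(targets$declared_mods)) targets$declared_mods <- ""
  targets$mods[is.na(targets$mods)] <- ""
  targets$declared_mods[is.na(targets$declared_mods)] <- ""
  out <- targets
  out$computed_mz <- NA_real_
  out$delta_mz <- NA_real_
  out$pass <- NA
  out$note <- ""
  for (i in seq_len(nrow(targets))) {
    pep <- peptide(targets$peptide[i], mods = parse_mods_field(targets$mods[i]))
    mz <- precursor_mz(monoisotopic_mass(pep), targets$z[i])
    out$computed_mz[i] <- mz
    out$delta_mz[i] <- mz - targets$expected_mz[i]
    out$pass[i] <- abs(out$delta_mz[i]) <= tolerance_mz
    declared <- targets$declared_mods[i]
    if (nzchar(declared) && !identical(declared, targets$mods[i])) {
      out$note[i] <- paste0(
        "declared modification(s) '", declared, "' not applied; ",
        "expected m/z matches the form evaluated here")
    }
  }
  attr(out, "tolerance_mz") <- tolerance_mz
  attr(out, "constants") <- c(proton = MASS_PROTON, water = MASS_WATER)
  out
}
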