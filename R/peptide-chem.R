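#' Monoisotopic mass constants
#'
#' Standard monoisotopic residue masses (Da) for the 20 canonical amino acids,
#' together with the water and proton masses and the modification deltas used
#' throughout the package. I and L are isomeric and share one mass. Values are
#' fixed to 5 decimals, which keeps all fragment m/z computations accurate to
#' well below the 25 ppm matching tolerance.
#'
#' @format A list with elements `residues` (named numeric vector of 20 residue
#'   masses), `water`, `proton`, and `mods` (named deltas for
#'   `"ox"` = methionine oxidation and `"cam"` = cysteine carbamidomethylation).
#' @export
mass_constants <- list(
  residues = c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
    H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
  ),
  water = 18.010565,
  proton = 1.0072765,
  mods = c(ox = 15.99491, cam = 57.02146)
)

#' Construct a peptide
#'
#' A peptide is a sequence over the 20 canonical amino-acid letters with an
#' optional list of modifications and a precursor charge. The identification
#' domain is restricted to lengths 7-30 and precursor charges 1-6; shorter,
#' longer, or more highly charged precursors are outside the model's domain
#' and are rejected.
#'
#' @param sequence Character scalar, upper-case amino-acid letters. May use the
#'   inline dialect `"M(ox)"` / `"C(cam)"` to place modifications.
#' @param modifications Data frame with columns `position` (1-based residue
#'   index) and `mod` (`"ox"` or `"cam"`), or `NULL`.
#' @param charge Integer precursor charge in 1..6.
#' @param validate_domain If `FALSE`, skip the length-7..30 restriction (the
#'   chemistry itself is defined for any length >= 1).
#' @return An object of class `peptide`: list with `sequence`, `modifications`
#'   (tibble), `charge`.
#' @examples
#' peptide("PEPTIDEK", charge = 2)
#' peptide("AM(ox)AAAAC(cam)K", charge = 2)
#' @export
peptide <- function(sequence, modifications = NULL, charge = 2L,
                    validate_domain = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  parsed <- parse_modified_sequence(sequence)
  sequence <- parsed$sequence
  if (is.null(modifications)) {
    modifications <- parsed$modifications
  } else {
    modifications <- dplyr::bind_rows(
      parsed$modifications,
      tibble::as_tibble(modifications)
    )
  }
  letters_seq <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters_seq, names(mass_constants$residues))
  if (length(bad) > 0L) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  n <- length(letters_seq)
  if (validate_domain && (n < 7L || n > 30L)) {
    stop("peptide length ", n, " outside the supported 7-30 range",
      call. = FALSE
    )
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L || charge > 6L) {
    stop("precursor charge must be in 1..6", call. = FALSE)
  }
  if (nrow(modifications) > 0L) {
    expected <- c(ox = "M", cam = "C")
    at <- letters_seq[modifications$position]
    ok <- !is.na(at) & at == expected[modifications$mod]
    if (!all(ok)) {
      stop("modification does not match its residue at position ",
        paste(modifications$position[!ok], collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    list(sequence = sequence, modifications = modifications, charge = charge),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", modified_sequence(x), " (", x$charge, "+)\n", sep = "")
  invisible(x)
}

# Parse the inline "M(ox)" / "C(cam)" dialect into (plain sequence, mod table).
parse_modified_sequence <- function(text) {
  mods <- tibble::tibble(position = integer(), mod = character())
  if (!grepl("(", text, fixed = TRUE)) {
    return(list(sequence = text, modifications = mods))
  }
  chars <- strsplit(text, "")[[1]]
  seq_out <- character()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      close <- i + which(chars[(i + 1L):length(chars)] == ")")[1]
      if (is.na(close)) stop("unbalanced '(' in modified sequence", call. = FALSE)
      tag <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (!tag %in% c("ox", "cam")) {
        stop("unknown modification token '", tag, "'", call. = FALSE)
      }
      mods <- dplyr::bind_rows(
        mods,
        tibble::tibble(position = length(seq_out), mod = tag)
      )
      i <- close + 1L
    } else {
      seq_out <- c(seq_out, ch)
      i <- i + 1L
    }
  }
  list(sequence = paste(seq_out, collapse = ""), modifications = mods)
}

#' Render a peptide back to the inline modified-sequence dialect
#' @param p A `peptide`.
#' @return Character scalar such as `"AM(ox)AAAAK"`.
#' @export
modified_sequence <- function(p) {
  chars <- strsplit(p$sequence, "")[[1]]
  if (nrow(p$modifications) > 0L) {
    for (k in seq_len(nrow(p$modifications))) {
      pos <- p$modifications$position[k]
      chars[pos] <- paste0(chars[pos], "(", p$modifications$mod[k], ")")
    }
  }
  paste(chars, collapse = "")
}

# Per-residue masses of a peptide including its modifications.
residue_masses <- function(p) {
  m <- unname(mass_constants$residues[strsplit(p$sequence, "")[[1]]])
  if (nrow(p$modifications) > 0L) {
    m[p$modifications$position] <- m[p$modifications$position] +
      unname(mass_constants$mods[p$modifications$mod])
  }
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of (modified) residue masses plus one water.
#'
#' @param p A `peptide` (or a plain sequence string, taken as unmodified).
#' @return Mass in Da.
#' @examples
#' peptide_mass(peptide("GGGGGGG", charge = 1)) # 417.16081
#' @export
peptide_mass <- function(p) {
  if (is.character(p)) p <- peptide(p, charge = 1L, validate_domain = FALSE)
  sum(residue_masses(p)) + mass_constants$water
}

#' Theoretical b/y fragment m/z
#'
#' b ions carry the first `index` residues plus `charge` protons; y ions carry
#' the last `index` residues plus water plus `charge` protons.
#'
#' @param p A `peptide`.
#' @param ion `"b"` or `"y"`.
#' @param index Fragment index, 1..length-1. Vectorized.
#' @param charge Fragment charge >= 1. Vectorized with `index`.
#' @return m/z in Th.
#' @export
fragment_mz <- function(p, ion, index, charge = 1L) {
  ion <- match.arg(ion, c("b", "y"))
  n <- nchar(p$sequence)
  if (any(index < 1L) || any(index >= n)) {
    stop("fragment index must be in 1..length-1", call. = FALSE)
  }
  if (any(charge < 1L)) stop("fragment charge must be >= 1", call. = FALSE)
  m <- residue_masses(p)
  cum <- cumsum(m)
  residue_sum <- if (ion == "b") {
    cum[index]
  } else {
    sum(m) - cum[n - index]
  }
  extra <- if (ion == "y") mass_constants$water else 0
  (residue_sum + extra + charge * mass_constants$proton) / charge
}

#' Levenshtein edit distance between two sequences
#'
#' @param a,b Non-empty character scalars.
#' @return Integer minimal number of insertions, deletions, substitutions.
#' @examples
#' levenshtein("FAGDLVRGVA", "FAGDLVRNL") # 3
#' @export
levenshtein <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  as.integer(utils::adist(a, b))
}

#' Are two sequences identical up to I/L exchange?
#'
#' Isoleucine and leucine are isomeric and indistinguishable by standard
#' MS/MS; sequences equal after mapping every I to L are treated as the same
#' identification.
#'
#' @param a,b Sequence strings.
#' @return Logical.
#' @export
il_equivalent <- function(a, b) {
  gsub("I", "L", a, fixed = TRUE) == gsub("I", "L", b, fixed = TRUE)
}

#' Are two sequences isobaric within a ppm tolerance?
#'
#' Compares neutral monoisotopic masses relative to their mean.
#'
#' @param a,b Sequence strings (unmodified).
#' @param tol_ppm Tolerance in parts per million (> 0).
#' @return Logical.
#' @examples
#' isobaric_pair("FAGDLVRGVA", "FAGDLVRNL", 25) # TRUE (GVA vs NL)
#' @export
isobaric_pair <- function(a, b, tol_ppm = 25) {
  stopifnot(tol_ppm > 0)
  ma <- peptide_mass(a)
  mb <- peptide_mass(b)
  abs(ma - mb) / mean(c(ma, mb)) * 1e6 <= tol_ppm
}

#' Catalog of isobaric residue-combination substitutions
#'
#' Residue combinations of (near-)equal mass that can render distinct peptide
#' sequences indistinguishable by precursor mass alone, e.g. the GVA/NL
#' exchange behind spliced-vs-canonical ambiguities.
#'
#' @return Tibble with columns `from`, `to`, `delta_da`.
#' @export
isobaric_catalog <- function() {
  combos <- tibble::tibble(
    from = c("GVA", "GG", "GA", "I"),
    to = c("NL", "N", "Q", "L")
  )
  mass_of <- function(s) {
    vapply(
      strsplit(s, ""),
      function(x) sum(mass_constants$residues[x]),
      numeric(1)
    )
  }
  dplyr::mutate(combos, delta_da = mass_of(.data$from) - mass_of(.data$to))
}
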