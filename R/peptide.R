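## Residue compositions as residues (amino acid minus one water), heavy-atom
## side chains used by the helix builder are defined in helix.R.
.residue_table <- list(
  Pro = list(code = "P", composition = c(C = 5L, H = 7L, N = 1L, O = 1L), chiral = TRUE),
  Hyp = list(code = "H", composition = c(C = 5L, H = 7L, N = 1L, O = 2L), chiral = TRUE),
  Gly = list(code = "G", composition = c(C = 2L, H = 3L, N = 1L, O = 1L), chiral = FALSE),
  Ala = list(code = "A", composition = c(C = 3L, H = 5L, N = 1L, O = 1L), chiral = TRUE)
)

.letter_to_residue <- c(P = "Pro", H = "Hyp", G = "Gly", A = "Ala")

## Monoisotopic masses (Da) of the most abundant isotopes.
.monoisotopic <- c(
  C = 12.000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221
)

#' Peptide sequence in collagen triplet notation
#'
#' Construct a peptide sequence object from residue codes. Sequences carry a
#' fixed free N-terminus (\code{H-}) and C-terminus (\code{-OH}); glycine is
#' achiral, Pro/Hyp/Ala carry L or D chirality.
#'
#' @param residues character vector of three-letter residue codes
#'   (\code{"Pro"}, \code{"Hyp"}, \code{"Gly"}, \code{"Ala"}).
#' @param chirality character vector of \code{"L"}, \code{"D"} or
#'   \code{"achiral"}; defaults to all-L with Gly achiral.
#' @return an object of class \code{peptide_sequence}: a list with
#'   \code{residues}, \code{chirality}, \code{n_terminus}, \code{c_terminus}.
#' @seealso [parse_triplet_notation()] for the \code{"(PHG)9PHA"} notation.
#' @export
peptide_sequence <- function(residues, chirality = NULL) {
  residues <- as.character(residues)
  if (length(residues) < 1L)
    stop("a peptide sequence needs at least one residue")
  bad <- setdiff(unique(residues), names(.residue_table))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  if (is.null(chirality))
    chirality <- ifelse(vapply(.residue_table[residues], `[[`, TRUE, "chiral"),
                        "L", "achiral")
  chirality <- as.character(chirality)
  stopifnot(length(chirality) == length(residues))
  chiral_flag <- vapply(.residue_table[residues], `[[`, TRUE, "chiral")
  if (any(chirality[!chiral_flag] != "achiral"))
    stop("Gly is achiral and cannot carry L/D chirality")
  if (any(!chirality[chiral_flag] %in% c("L", "D")))
    stop("chiral residues must be 'L' or 'D'")
  structure(
    list(residues = residues, chirality = chirality,
         n_terminus = "H-", c_terminus = "-OH"),
    class = "peptide_sequence"
  )
}

#' @export
print.peptide_sequence <- function(x, ...) {
  n <- length(x$residues)
  lab <- ifelse(x$chirality == "D", tolower(substr(x$residues, 1, 1)),
                substr(x$residues, 1, 1))
  cat(sprintf("peptide_sequence: %d residues\n  %s%s%s\n", n,
              x$n_terminus, paste(lab, collapse = ""), x$c_terminus))
  invisible(x)
}

#' @export
length.peptide_sequence <- function(x) length(x$residues)

#' Parse collagen triplet notation into a peptide sequence
#'
#' Parses strings such as \code{"(PHG)9PHA"} (27 + 3 = 30 residues),
#' \code{"(GHP)10A"} (31 residues) or \code{"D-(PPG)10"}. Letters map
#' P = Pro, H = Hyp, G = Gly, A = Ala. A parenthesized group followed by an
#' integer repeats that group; plain letters append single residues. A
#' leading \code{"D-"} marks every chiral residue (Pro/Hyp/Ala) as D;
#' glycine stays achiral.
#'
#' @param text notation string.
#' @return a [peptide_sequence()].
#' @examples
#' parse_triplet_notation("(PHG)9PHA")   # 30 residues
#' parse_triplet_notation("D-(PPG)10")   # all-D proline
#' @export
parse_triplet_notation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  all_d <- FALSE
  if (grepl("^D-", s)) {
    all_d <- TRUE
    s <- sub("^D-", "", s)
  }
  letters_out <- character(0)
  while (nzchar(s)) {
    m <- regmatches(s, regexec("^\\(([A-Za-z]+)\\)([0-9]+)", s))[[1]]
    if (length(m)) {
      letters_out <- c(letters_out,
                       rep(strsplit(m[2], "")[[1]], as.integer(m[3])))
      s <- substr(s, nchar(m[1]) + 1L, nchar(s))
    } else {
      m <- regmatches(s, regexec("^[A-Za-z]", s))[[1]]
      if (!length(m))
        stop("cannot parse triplet notation at: '", s, "'")
      letters_out <- c(letters_out, m[1])
      s <- substr(s, 2L, nchar(s))
    }
  }
  letters_out <- toupper(letters_out)
  bad <- setdiff(unique(letters_out), names(.letter_to_residue))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  residues <- unname(.letter_to_residue[letters_out])
  chirality <- ifelse(
    vapply(.residue_table[residues], `[[`, TRUE, "chiral"),
    if (all_d) "D" else "L", "achiral")
  peptide_sequence(residues, chirality)
}

#' Molecular formula of a peptide
#'
#' Sums residue compositions (Pro C5H7NO, Hyp C5H7NO2, Gly C2H3NO,
#' Ala C3H5NO) and adds one H2O for the free \code{H-}/\code{-OH} termini.
#' Chirality does not affect the formula.
#'
#' @param seq a [peptide_sequence()].
#' @return object of class \code{molecular_formula}: named integer vector of
#'   element counts in Hill order (C, H, then alphabetical).
#' @examples
#' sequence_to_formula(parse_triplet_notation("(PHG)9PHA"))  # C121 H174 N30 O41
#' @export
sequence_to_formula <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  counts <- c(C = 0L, H = 2L, N = 0L, O = 1L)  # start from one water
  for (r in seq$residues) {
    comp <- .residue_table[[r]]$composition
    counts[names(comp)] <- counts[names(comp)] + comp
  }
  molecular_formula(counts)
}

#' Construct a molecular formula
#'
#' @param counts named non-negative integer vector of element counts.
#' @return \code{molecular_formula} with strictly positive counts, ordered in
#'   Hill order.
#' @export
molecular_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (any(counts != round(counts)) || any(counts < 0))
    stop("element counts must be non-negative integers")
  counts <- structure(as.integer(counts), names = names(counts))
  els <- names(counts)
  rest <- sort(setdiff(els, c("C", "H")))
  order_els <- c(intersect(c("C", "H"), els), rest)
  structure(counts[order_els], class = "molecular_formula")
}

#' @export
format.molecular_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
`+.molecular_formula` <- function(e1, e2) {
  all_el <- union(names(e1), names(e2))
  out <- structure(integer(length(all_el)), names = all_el)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  molecular_formula(out)
}

#' Monoisotopic mass of a molecular formula
#'
#' Weighted sum over the most abundant isotope masses (12C = 12 exactly,
#' 1H = 1.0078250319, 14N = 14.0030740052, 16O = 15.9949146221 Da).
#'
#' @param formula a [molecular_formula()] (or named count vector).
#' @return mass in Da (double, full precision).
#' @examples
#' monoisotopic_mass(sequence_to_formula(parse_triplet_notation("(PHG)9PHA")))
#' @export
monoisotopic_mass <- function(formula) {
  counts <- unclass(formula)
  unknown <- setdiff(names(counts), names(.monoisotopic))
  if (length(unknown))
    stop("no monoisotopic mass tabulated for element(s): ",
         paste(unknown, collapse = ", "))
  sum(counts * .monoisotopic[names(counts)])
}
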