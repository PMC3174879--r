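#' Restriction enzymes with degenerate recognition sequences
#'
#' A restriction enzyme is described by its name, an IUPAC recognition
#' sequence, and the 0-based offset of the cut within that sequence on the
#' sense strand.  Only palindromic recognition sequences (equal to their own
#' IUPAC reverse complement) are supported, so that scanning the sense strand
#' finds every duplex site exactly once.
#'
#' @param name Short enzyme name, e.g. `"BstYI"`.
#' @param recognition IUPAC nucleotide string, e.g. `"RGATCY"`.
#' @param cut_offset Integer in `[0, nchar(recognition)]`: the cut falls
#'   immediately before this offset within the site (0-based).
#'
#' @return An object of class `restriction_enzyme`.
#' @examples
#' bstYI()
#' restriction_enzyme("EcoRI", "GAATTC", 1)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(as.character(recognition))
  iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  letters_seen <- strsplit(recognition, "")[[1]]
  if (length(letters_seen) == 0 || !all(letters_seen %in% iupac)) {
    stop("recognition sequence '", recognition,
         "' contains characters outside the IUPAC nucleotide alphabet",
         call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie within 0..", nchar(recognition), call. = FALSE)
  }
  if (!iupac_is_palindrome(recognition)) {
    stop("recognition sequence '", recognition, "' is not palindromic; ",
         "non-palindromic enzymes would require double-strand scanning, ",
         "which is not supported", call. = FALSE)
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(
    substr(x$recognition, 1, x$cut_offset), "/",
    substr(x$recognition, x$cut_offset + 1, nchar(x$recognition))
  )
  cat("<restriction_enzyme> ", x$name, ": ", site, "\n", sep = "")
  invisible(x)
}

#' Built-in enzyme pair used by the cDNA-AFLP protocol
#'
#' `bstYI()` cuts in the R/GATCY context and `mseI()` in the T/TAA context
#' (R = A/G, Y = C/T); these are the two enzymes of the standard protocol,
#' with BstYI providing the 5' fragment boundary and MseI the 3' one.
#'
#' @return A `restriction_enzyme`.
#' @examples
#' find_cut_positions("AAGGATCCTT", bstYI())
#' @export
bstYI <- function() restriction_enzyme("BstYI", "RGATCY", 1L)

#' @rdname bstYI
#' @export
mseI <- function() restriction_enzyme("MseI", "TTAA", 1L)

# IUPAC complement map (complement of an ambiguity code is the code matching
# the complements of its members, e.g. R <-> Y).
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

iupac_reverse_complement <- function(x) {
  paste(rev(unname(IUPAC_COMPLEMENT[strsplit(toupper(x), "")[[1]]])),
        collapse = "")
}

iupac_is_palindrome <- function(x) {
  identical(toupper(x), iupac_reverse_complement(x))
}

#' Locate restriction cut positions on a transcript
#'
#' Scans the sense strand of `sequence` for every (possibly overlapping)
#' occurrence of the enzyme's recognition sequence and returns the 0-based
#' cut positions: the cut falls immediately before the returned index.
#' Ambiguity codes in the recognition sequence are expanded; an `N` in the
#' *transcript* never matches any recognition position, so masked sequence
#' produces no cut sites.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param enzyme A [restriction_enzyme()].
#' @return Strictly increasing integer vector of 0-based cut positions.
#' @examples
#' find_cut_positions("TTAATTAA", mseI())  # c(1, 5)
#' @export
find_cut_positions <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < nchar(enzyme$recognition)) return(integer(0))
  subj <- Biostrings::DNAString(sequence)
  # fixed = "subject": ambiguity codes in the pattern are degenerate, letters
  # in the subject are literal -- so transcript N matches nothing (our
  # built-in patterns contain no N).
  hits <- Biostrings::matchPattern(enzyme$recognition, subj,
                                   fixed = "subject")
  starts <- Biostrings::start(hits)
  sort(as.integer(starts) - 1L + enzyme$cut_offset)
}
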