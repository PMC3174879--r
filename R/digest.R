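#' Selective primer specification
#'
#' A second-round cDNA-AFLP primer combination is identified by the Y-position
#' base of the BstYI primer (`C` or `T`) plus zero to two selective
#' nucleotides on each primer.  With two selective bases on each side, the
#' 2 x 16 x 16 = 512 combinations partition the amplifiable fragment pool;
#' the original screen ran a panel of 8 BstYI x 16 MseI primers.
#'
#' @param bst_variant Single base `"C"` or `"T"` (the Y of the GATCY remnant).
#' @param bst_selective 0--2 selective bases on the BstYI primer.
#' @param mse_selective 0--2 selective bases on the MseI primer.
#' @return An object of class `primer_spec`.
#' @examples
#' primer_spec("T", "CC", "TC")
#' @export
primer_spec <- function(bst_variant, bst_selective = "", mse_selective = "") {
  bst_variant <- toupper(bst_variant)
  bst_selective <- toupper(bst_selective)
  mse_selective <- toupper(mse_selective)
  if (!bst_variant %in% c("C", "T")) {
    stop("bst_variant must be 'C' or 'T'", call. = FALSE)
  }
  ok_sel <- function(x) {
    nchar(x) <= 2 &&
      (nchar(x) == 0 || all(strsplit(x, "")[[1]] %in% c("A", "C", "G", "T")))
  }
  if (!ok_sel(bst_selective) || !ok_sel(mse_selective)) {
    stop("selective nucleotides must be 0-2 bases from {A,C,G,T}",
         call. = FALSE)
  }
  structure(
    list(bst_variant = bst_variant,
         bst_selective = bst_selective,
         mse_selective = mse_selective),
    class = "primer_spec"
  )
}

#' @export
print.primer_spec <- function(x, ...) {
  cat("<primer_spec> ", primer_key(x), "\n", sep = "")
  invisible(x)
}

#' Canonical label for a primer combination
#'
#' @param primer A [primer_spec()] (or the three components separately).
#' @return A string such as `"BstYI+TCC/MseI+AG"`.
#' @export
primer_key <- function(primer) {
  paste0("BstYI+", primer$bst_variant, primer$bst_selective,
         "/MseI+", primer$mse_selective)
}

#' Predicted size model for migrated amplicons
#'
#' The amplicon carries primer tails beyond the cut-to-cut fragment: the
#' 18-nt BstYI primer overlaps GATC+Y+NN = 7 fragment bases and extends 11 nt
#' beyond the 5' cut, and the 18-nt MseI primer overlaps the remnant T
#' complement + NN = 3 bases and extends 15 nt beyond the 3' cut, so the
#' default total correction is 11 + 15 = 26 bases.  Capillary mobility and
#' dye shifts make the effective offset assay-specific, so it is
#' configurable.
#'
#' @param correction_total Non-negative integer added to the cut-to-cut
#'   length to give the predicted migrated size.
#' @return An object of class `size_model`.
#' @export
size_model <- function(correction_total = 26L) {
  correction_total <- as.integer(correction_total)
  if (is.na(correction_total) || correction_total < 0L) {
    stop("correction_total must be a non-negative integer", call. = FALSE)
  }
  structure(list(correction_total = correction_total), class = "size_model")
}

# Minimum cut-to-cut length for a reportable fragment: GATCY remnant (5) plus
# at least one internal base preceding the terminal remnant T.
MIN_FRAGMENT_LENGTH <- 6L

#' Digest a transcript in silico with the dual-enzyme cDNA-AFLP geometry
#'
#' Computes all cut positions from both enzymes, forms candidate fragments
#' from consecutive-cut intervals whose 5' boundary is a BstYI-type cut and
#' whose 3' boundary is an MseI-type cut (only such dual-enzyme fragments
#' receive both adapters and amplify), discards products shorter than 6 nt,
#' and annotates each retained fragment with its selective contexts and
#' predicted migrated size.
#'
#' @param transcript Either a nucleotide string or a one-row data frame with
#'   columns `id`, `gene_id`, `sequence` (see [read_transcripts()]).
#' @param bst,mse The 5'-side and 3'-side [restriction_enzyme()]s
#'   (defaults [bstYI()] and [mseI()]).
#' @param mode `"last"` returns only the poly-A-proximal fragment (maximal
#'   start), mimicking the fragment isolation of the wet protocol; `"all"`
#'   returns every dual-enzyme fragment ordered by start.
#' @param k5,k3 Selective-context lengths for the BstYI and MseI primers
#'   (0--2 each).
#' @param size Predicted-size model, see [size_model()].
#' @param keep_same_enzyme If `TRUE`, fragments flanked by the same enzyme at
#'   both ends are also reported (diagnostics only; they are marked with
#'   `amplifiable = FALSE` and carry no contexts).
#'
#' @return A tibble with one row per fragment: `transcript_id`, `gene_id`,
#'   `start`, `end` (0-based half-open cut-to-cut interval), `sequence`,
#'   `bst_variant`, `bst_context`, `mse_context`, `predicted_size`,
#'   `is_three_prime_most`, `amplifiable`.  Zero rows when no fragment
#'   exists.
#' @examples
#' digest_transcript("AAAAGATCTCCGGATTAAGGG", mode = "last")
#' @export
digest_transcript <- function(transcript,
                              bst = bstYI(), mse = mseI(),
                              mode = c("last", "all"),
                              k5 = 2L, k3 = 2L,
                              size = size_model(),
                              keep_same_enzyme = FALSE) {
  mode <- match.arg(mode)
  if (is.character(transcript) && length(transcript) == 1 &&
      is.null(names(transcript))) {
    transcript <- tibble::tibble(id = "transcript", gene_id = "transcript",
                                 sequence = transcript)
  }
  stopifnot(is.data.frame(transcript), nrow(transcript) == 1)
  seq <- toupper(transcript$sequence[[1]])

  cuts_b <- find_cut_positions(seq, bst)
  cuts_m <- find_cut_positions(seq, mse)
  cuts <- sort(unique(c(cuts_b, cuts_m)))
  if (length(cuts) < 2) return(empty_fragment_table())

  lo <- cuts[-length(cuts)]
  hi <- cuts[-1]
  is_bm <- (lo %in% cuts_b) & (hi %in% cuts_m)
  keep <- if (keep_same_enzyme) rep(TRUE, length(lo)) else is_bm
  keep <- keep & (hi - lo >= MIN_FRAGMENT_LENGTH)
  if (!any(keep)) return(empty_fragment_table())

  lo <- lo[keep]; hi <- hi[keep]; is_bm <- is_bm[keep]

  frag_seq <- substring(seq, lo + 1L, hi)
  out <- tibble::tibble(
    transcript_id = transcript$id[[1]],
    gene_id = transcript$gene_id[[1]],
    start = as.integer(lo),
    end = as.integer(hi),
    sequence = frag_seq,
    amplifiable = is_bm
  )

  ctx <- selective_contexts(out$sequence, k5 = k5, k3 = k3)
  out$bst_variant <- ifelse(out$amplifiable, substr(out$sequence, 5, 5),
                            NA_character_)
  out$bst_context <- ifelse(out$amplifiable, ctx$bst_context, NA_character_)
  out$mse_context <- ifelse(out$amplifiable, ctx$mse_context, NA_character_)
  out$amplifiable <- out$amplifiable & !is.na(out$bst_context)
  out$predicted_size <- out$end - out$start + size$correction_total
  out$is_three_prime_most <- out$start == max(out$start)

  if (mode == "last") {
    # poly-A-proximal dual-enzyme fragment only
    bm <- out[(out$end - out$start >= MIN_FRAGMENT_LENGTH) &
                !is.na(out$bst_variant), , drop = FALSE]
    bm <- bm[bm$start == suppressWarnings(max(bm$start)), , drop = FALSE]
    out <- bm
  }
  out[order(out$start),
      c("transcript_id", "gene_id", "start", "end", "sequence",
        "bst_variant", "bst_context", "mse_context", "predicted_size",
        "is_three_prime_most", "amplifiable")]
}

empty_fragment_table <- function() {
  tibble::tibble(
    transcript_id = character(), gene_id = character(),
    start = integer(), end = integer(), sequence = character(),
    bst_variant = character(), bst_context = character(),
    mse_context = character(), predicted_size = integer(),
    is_three_prime_most = logical(), amplifiable = logical()
  )
}

#' Selective-nucleotide contexts of a fragment
#'
#' The BstYI context is read on the sense strand immediately 3' of the GATCY
#' remnant (fragment positions 5..5+k5, 0-based).  The MseI primer anneals to
#' the opposite strand, so its context is the reverse complement of the `k3`
#' sense bases immediately preceding the terminal remnant `T`.  Fragments too
#' short for non-overlapping contexts (`length < 5 + k5 + 1 + k3`) are
#' unamplifiable for that primer set and get `NA` contexts.
#'
#' @param sequence Character vector of fragment sequences (each starting
#'   `GATC[CT]` and ending `T`).
#' @param k5,k3 Context lengths, 0--2 each.
#' @return A list with character vectors `bst_context` and `mse_context`
#'   (`NA` where unamplifiable).
#' @examples
#' selective_contexts("GATCTCCGGAT", 2, 2)  # list(bst = "CC", mse = "TC")
#' @export
selective_contexts <- function(sequence, k5 = 2L, k3 = 2L) {
  k5 <- as.integer(k5); k3 <- as.integer(k3)
  stopifnot(k5 >= 0L, k5 <= 2L, k3 >= 0L, k3 <= 2L)
  L <- nchar(sequence)
  ok <- L >= 5L + k5 + 1L + k3
  bst <- ifelse(ok, substr(sequence, 6L, 5L + k5), NA_character_)
  mse_sense <- ifelse(ok, substr(sequence, L - k3, L - 1L), NA_character_)
  mse <- ifelse(is.na(mse_sense), NA_character_,
                vapply(mse_sense, revcomp, character(1), USE.NAMES = FALSE))
  list(bst_context = bst, mse_context = mse)
}

revcomp <- function(x) {
  if (is.na(x)) return(NA_character_)
  if (nchar(x) == 0) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Does a fragment amplify with a given primer combination?
#'
#' True iff the fragment's observed Y-variant and both selective contexts
#' equal the primer's.  Together with [selective_contexts()], this models the
#' protocol's two amplification rounds as a single selectivity filter (the
#' first round's single selective base is a strict prefix of the second
#' round's pair, so the final-round primers determine the fragment set).
#'
#' @param fragment One row of a [digest_transcript()] result.
#' @param primer A [primer_spec()].
#' @return Logical scalar.
#' @export
matches_primer <- function(fragment, primer) {
  stopifnot(inherits(primer, "primer_spec"))
  if (is.na(fragment$bst_variant) || is.na(fragment$bst_context) ||
      is.na(fragment$mse_context)) {
    return(FALSE)
  }
  fragment$bst_variant == primer$bst_variant &&
    fragment$bst_context == primer$bst_selective &&
    fragment$mse_context == primer$mse_selective
}
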