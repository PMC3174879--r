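#' Build a fragment index over a transcriptome
#'
#' Digests every transcript under one digestion configuration and indexes the
#' resulting amplifiable fragments by their primer combination, so that an
#' observed TDF (primer combination + capillary size) can be resolved to the
#' gene(s) that could have produced it.
#'
#' @param transcripts Data frame with columns `id`, `gene_id`, `sequence`
#'   (see [read_transcripts()]).
#' @inheritParams digest_transcript
#' @return An object of class `fragment_index`: a tibble of fragments with a
#'   `primer_key` column, sorted by key and predicted size, with the
#'   digestion settings attached as attribute `settings`.
#' @examples
#' tx <- tibble::tibble(id = "g1.1", gene_id = "g1",
#'                      sequence = "AAAAGATCTCCGGATTAAGGG")
#' build_index(tx)
#' @export
build_index <- function(transcripts,
                        bst = bstYI(), mse = mseI(),
                        mode = c("last", "all"),
                        k5 = 2L, k3 = 2L,
                        size = size_model()) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(transcripts),
            all(c("id", "gene_id", "sequence") %in% names(transcripts)))
  if (nrow(transcripts) == 0) {
    warning("empty transcript set: returning an empty index", call. = FALSE)
    frags <- empty_fragment_table()
  } else {
    frags <- purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
      digest_transcript(transcripts[i, , drop = FALSE],
                        bst = bst, mse = mse, mode = mode,
                        k5 = k5, k3 = k3, size = size)
    })
  }
  frags <- frags[frags$amplifiable %in% TRUE, , drop = FALSE]
  frags$primer_key <- sprintf("BstYI+%s%s/MseI+%s",
                              frags$bst_variant, frags$bst_context,
                              frags$mse_context)
  frags <- frags[order(frags$primer_key, frags$predicted_size,
                       frags$gene_id, frags$transcript_id), , drop = FALSE]
  structure(
    tibble::as_tibble(frags),
    settings = list(mode = mode, k5 = k5, k3 = k3,
                    correction_total = size$correction_total,
                    bst = bst$recognition, mse = mse$recognition),
    class = c("fragment_index", class(tibble::tibble()))
  )
}

#' Identify the gene behind an observed TDF
#'
#' Looks up the TDF's primer combination in the index and keeps candidates
#' whose predicted size deviates from the observed capillary size by at most
#' `tolerance` base pairs (inclusive; sizes are fractional).  Isoforms of one
#' gene are collapsed to a single gene-level candidate carrying the minimal
#' deviation.  The match is `unique` with exactly one candidate gene,
#' `ambiguous` with two or more, `unmatched` with none; the nearest
#' out-of-tolerance candidates are reported as near misses.
#'
#' @param index A [build_index()] result.
#' @param observed_size Observed (possibly fractional) capillary size in bp.
#' @param primer A [primer_spec()] giving the TDF's primer combination.
#' @param tolerance Maximum absolute size deviation in bp (default 1.0, the
#'   stringent setting of the original screen).
#' @param tdf_id Identifier echoed into the result.
#' @param n_near Maximum number of near misses reported.
#' @return A one-row tibble: `tdf_id`, `status`, `n_genes`, `gene_ids`
#'   (comma-joined), and list-columns `matched_genes` (tibble of gene_id,
#'   predicted_size, deviation) and `near_misses`.
#' @export
match_tdf <- function(index, observed_size, primer,
                      tolerance = 1.0, tdf_id = NA_character_,
                      n_near = 3L) {
  stopifnot(inherits(index, "fragment_index"), observed_size > 0)
  key <- primer_key(primer)
  cand <- index[index$primer_key == key, , drop = FALSE]
  cand <- tibble::tibble(
    gene_id = cand$gene_id,
    transcript_id = cand$transcript_id,
    predicted_size = cand$predicted_size,
    deviation = abs(cand$predicted_size - observed_size)
  )
  inside <- cand[cand$deviation <= tolerance, , drop = FALSE]
  # collapse isoforms: one row per gene at minimal deviation
  if (nrow(inside) > 0) {
    inside <- inside |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::slice_min(.data$deviation, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$deviation, .data$gene_id)
  }
  outside <- cand[cand$deviation > tolerance, , drop = FALSE]
  outside <- outside[order(outside$deviation), , drop = FALSE]
  outside <- outside[!duplicated(outside$gene_id), , drop = FALSE]
  outside <- utils::head(outside, n_near)

  n_genes <- length(unique(inside$gene_id))
  status <- if (n_genes == 0) "unmatched" else if (n_genes == 1) "unique" else "ambiguous"
  tibble::tibble(
    tdf_id = tdf_id,
    primer_key = key,
    observed_size = observed_size,
    status = status,
    n_genes = n_genes,
    gene_ids = paste(inside$gene_id, collapse = ","),
    matched_genes = list(inside[, c("gene_id", "predicted_size", "deviation")]),
    near_misses = list(outside[, c("gene_id", "predicted_size", "deviation")])
  )
}

#' Match a table of observed TDFs
#'
#' @param index A [build_index()] result.
#' @param tdfs Data frame with columns `tdf_id`, `bst_variant`, `bst_sel`,
#'   `mse_sel`, `size` (the on-disk observed-TDF format, see
#'   [read_observed_tdfs()]).
#' @inheritParams match_tdf
#' @return A tibble with one [match_tdf()] row per input TDF.
#' @export
match_tdf_table <- function(index, tdfs, tolerance = 1.0, n_near = 3L) {
  stopifnot(all(c("tdf_id", "bst_variant", "bst_sel", "mse_sel", "size")
                %in% names(tdfs)))
  purrr::map_dfr(seq_len(nrow(tdfs)), function(i) {
    row <- tdfs[i, ]
    sel <- function(x) if (is.na(x)) "" else x
    match_tdf(index, row$size,
              primer_spec(row$bst_variant, sel(row$bst_sel), sel(row$mse_sel)),
              tolerance = tolerance, tdf_id = row$tdf_id, n_near = n_near)
  })
}

#' Derive a gene id from a transcript id
#'
#' Strips a trailing `.<number>` isoform suffix when present (the
#' locus.isoform convention of annotated transcriptomes); otherwise the
#' transcript id is its own gene id.  Supply an explicit id-to-gene map to
#' [read_transcripts()] to override.
#'
#' @param transcript_id Character vector.
#' @return Character vector of gene ids.
#' @examples
#' derive_gene_id(c("At3g09840.2", "contig77"))
#' @export
derive_gene_id <- function(transcript_id) {
  sub("\\.[0-9]+$", "", transcript_id)
}
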