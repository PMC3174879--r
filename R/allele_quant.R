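#' Maternal allele fraction from pyrosequencing signals
#'
#' Converts the two allele-specific signal intensities of a pyrosequencing
#' assay at a transcribed SNP into the percentage of transcript signal from
#' the maternal allele.
#'
#' @param maternal_signal,paternal_signal Non-negative intensities.
#' @return `100 * maternal / (maternal + paternal)`; `NA` when both signals
#'   are zero (undefined, reported as missing).
#' @examples
#' allele_fraction(3, 1)  # 75
#' @export
allele_fraction <- function(maternal_signal, paternal_signal) {
  stopifnot(all(maternal_signal >= 0), all(paternal_signal >= 0))
  total <- maternal_signal + paternal_signal
  ifelse(total > 0, 100 * maternal_signal / total, NA_real_)
}

#' Default imprinting classification thresholds
#'
#' Mean maternal percentage cutpoints: `>= binary` maternal binary,
#' `>= preferential` maternal preferential, mirrored below 50 for paternal
#' calls, biallelic in between.  The labels are interpretive; the defaults
#' reproduce the qualitative calls of the standard pyrosequencing controls
#' (a binary MEG near 95%, a preferential PEG near 20%, a biallelic gene
#' near 50%).
#'
#' @param binary,preferential Upper cutpoints (percent maternal).
#' @return Named list of thresholds.
#' @export
imprinting_thresholds <- function(binary = 90, preferential = 70) {
  stopifnot(binary > preferential, preferential > 50)
  list(binary = binary, preferential = preferential)
}

classify_maternal_mean <- function(mean_pct, thresholds) {
  dplyr::case_when(
    is.na(mean_pct) ~ NA_character_,
    mean_pct >= thresholds$binary ~ "maternal_binary",
    mean_pct >= thresholds$preferential ~ "maternal_preferential",
    mean_pct > 100 - thresholds$preferential ~ "biallelic",
    mean_pct > 100 - thresholds$binary ~ "paternal_preferential",
    TRUE ~ "paternal_binary"
  )
}

#' Summarize reciprocal allele-specific measurements per gene
#'
#' Averages the maternal percentage over the two reciprocal cross directions
#' and classifies the imprinting status from the mean.  Genes measured in
#' only one direction are flagged and left unclassified.
#'
#' @param measurements Data frame with columns `gene_id`, `cross_label`
#'   (which accession is the mother; two distinct values per gene) and
#'   `maternal_pct` (0--100).
#' @param thresholds See [imprinting_thresholds()].
#' @return A tibble `gene_id`, `n_directions`, `mean_maternal_pct`,
#'   `classification` (`NA` with a single direction), `one_directional`.
#' @examples
#' summarize_alleles(tibble::tibble(
#'   gene_id = "At4g25530", cross_label = c("Col0", "Ler0"),
#'   maternal_pct = c(92.1, 97.1)))
#' @export
summarize_alleles <- function(measurements,
                              thresholds = imprinting_thresholds()) {
  measurements <- tibble::as_tibble(measurements)
  stopifnot(all(c("gene_id", "cross_label", "maternal_pct")
                %in% names(measurements)))
  if (any(measurements$maternal_pct < 0 | measurements$maternal_pct > 100,
          na.rm = TRUE)) {
    stop("maternal_pct must lie in [0, 100]", call. = FALSE)
  }
  out <- measurements |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_directions = dplyr::n_distinct(.data$cross_label),
      mean_maternal_pct = mean(.data$maternal_pct),
      .groups = "drop"
    )
  out$one_directional <- out$n_directions < 2
  out$classification <- ifelse(
    out$one_directional, NA_character_,
    classify_maternal_mean(out$mean_maternal_pct, thresholds)
  )
  out
}
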