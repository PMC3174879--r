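#' Classify seed tissue expression records
#'
#' Partitions maternally expressed genes by their seed-tissue expression
#' pattern ahead of endosperm-enrichment ranking.  Records without a usable
#' probe are excluded; genes not called present in the seed are set aside;
#' genes whose endosperm fractions all fall below the presence threshold
#' while the seed coat is above it are seed-coat-only; of the rest, genes
#' whose best endosperm fraction does not exceed the seed coat are dropped,
#' leaving the endosperm-dominant candidates.
#'
#' @param records Data frame with columns `gene_id`, `seed_coat`, `embryo`,
#'   `peripheral_endosperm`, `micropylar_endosperm`, `chalazal_endosperm`
#'   (mean expression over replicates, all `>= 0`), optional
#'   `present_in_seed` (logical presence call, default `TRUE`) and
#'   `probe_status` (`"ok"`, `"no_probe"` or `"ambiguous_probe"`, default
#'   `"ok"`).
#' @param presence_floor Numeric floor above which a tissue counts as
#'   expressing when no array presence call is available (default 0).
#' @return The input with an added `class` column, one of
#'   `excluded_probe`, `not_seed_expressed`, `seed_coat_only`,
#'   `endosperm_le_seed_coat`, `endosperm_dominant`.
#' @export
classify_records <- function(records, presence_floor = 0) {
  records <- tibble::as_tibble(records)
  endo_cols <- c("peripheral_endosperm", "micropylar_endosperm",
                 "chalazal_endosperm")
  needed <- c("gene_id", "seed_coat", "embryo", endo_cols)
  stopifnot(all(needed %in% names(records)))
  expr_cols <- c("seed_coat", "embryo", endo_cols)
  if (any(as.matrix(records[, expr_cols]) < 0, na.rm = TRUE)) {
    stop("negative expression values in input", call. = FALSE)
  }
  if (!"present_in_seed" %in% names(records)) records$present_in_seed <- TRUE
  if (!"probe_status" %in% names(records)) records$probe_status <- "ok"

  hEF <- pmax(records$peripheral_endosperm, records$micropylar_endosperm,
              records$chalazal_endosperm)
  records$class <- dplyr::case_when(
    records$probe_status != "ok" ~ "excluded_probe",
    !records$present_in_seed ~ "not_seed_expressed",
    hEF <= presence_floor & records$seed_coat > presence_floor ~ "seed_coat_only",
    hEF <= records$seed_coat ~ "endosperm_le_seed_coat",
    TRUE ~ "endosperm_dominant"
  )
  records
}

#' Rank imprinting candidates by endosperm enrichment over the seed coat
#'
#' For each endosperm-dominant gene, the highest-expressing endosperm
#' fraction (hEF) is found among the peripheral, micropylar and chalazal
#' fractions; candidates are ranked by descending absolute difference
#' hEF - SC (seed coat), with the ratio hEF / SC reported as the
#' complementary relative-enrichment key.  The embryo column plays no role.
#'
#' @param dominant Data frame of endosperm-dominant records (see
#'   [classify_records()]; rows of other classes are rejected when a `class`
#'   column is present).
#' @return A tibble `gene_id`, `hef_fraction`, `hef`, `seed_coat`,
#'   `abs_difference`, `ratio` (`Inf` when seed coat is 0), `rank` (1..n by
#'   descending `abs_difference`).
#' @examples
#' rank_candidates(tibble::tibble(
#'   gene_id = "At3g51280", seed_coat = 143.71, embryo = 6909.54,
#'   peripheral_endosperm = 3598.61, micropylar_endosperm = 425.12,
#'   chalazal_endosperm = 170.39))
#' @export
rank_candidates <- function(dominant) {
  dominant <- tibble::as_tibble(dominant)
  if ("class" %in% names(dominant) &&
      !all(dominant$class == "endosperm_dominant")) {
    stop("rank_candidates() expects only endosperm_dominant records",
         call. = FALSE)
  }
  endo <- as.matrix(dominant[, c("peripheral_endosperm",
                                 "micropylar_endosperm",
                                 "chalazal_endosperm")])
  which_max <- max.col(endo, ties.method = "first")
  hef <- endo[cbind(seq_len(nrow(endo)), which_max)]
  out <- tibble::tibble(
    gene_id = dominant$gene_id,
    hef_fraction = c("peripheral_endosperm", "micropylar_endosperm",
                     "chalazal_endosperm")[which_max],
    hef = hef,
    seed_coat = dominant$seed_coat,
    abs_difference = hef - dominant$seed_coat,
    ratio = ifelse(dominant$seed_coat == 0, Inf, hef / dominant$seed_coat)
  )
  out <- out[order(-out$abs_difference, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
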