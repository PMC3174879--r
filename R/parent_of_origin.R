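#' Reciprocal-cross experimental design
#'
#' Builds the sample layout of a reciprocal-cross screen: for each timepoint,
#' both parental selfs (A x A, B x B) and both reciprocal F1s (A x B, B x A).
#' Sample labels are `"<mother>x<father>_<t>dap"`.
#'
#' @param accessions Character vector of two accession names.
#' @param timepoints Numeric vector of timepoints in days after pollination
#'   (default `c(3, 4, 5)`, the stages of the original screen).
#' @return A tibble with columns `sample`, `mother`, `father`, `timepoint`.
#' @examples
#' cross_design(c("Col0", "Ler0"))
#' @export
cross_design <- function(accessions, timepoints = c(3, 4, 5)) {
  stopifnot(length(accessions) == 2, !anyDuplicated(accessions),
            length(timepoints) >= 1)
  a <- accessions[1]; b <- accessions[2]
  crosses <- tibble::tibble(
    mother = c(a, b, a, b),
    father = c(a, b, b, a)
  )
  out <- tidyr::crossing(crosses, timepoint = timepoints)
  out$sample <- sprintf("%sx%s_%gdap", out$mother, out$father, out$timepoint)
  out[, c("sample", "mother", "father", "timepoint")]
}

design_accessions <- function(design) {
  sort(unique(c(design$mother, design$father)))
}

check_allele_table <- function(table, design) {
  stopifnot(is.data.frame(table),
            all(c("primer_key", "bin_center") %in% names(table)))
  missing <- setdiff(design$sample, names(table))
  if (length(missing) > 0) {
    stop("allele table is missing sample column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign capillary sizes to allele bins
#'
#' Mirrors capillary bin assignment: a size is assigned to a bin if it falls
#' within `half_width` bp of the bin center (default 0.5 bp); when several
#' bins qualify, the nearest center wins.  Bin centers are typically seeded
#' from the parental-self peak sizes.
#'
#' @param sizes Numeric vector of observed fragment sizes (bp).
#' @param centers Numeric vector of bin centers (bp).
#' @param half_width Maximum |size - center| for assignment (bp).
#' @return Integer vector: for each size, the index into `centers` of its
#'   bin, or `NA` if no center is within `half_width`.
#' @examples
#' assign_bins(c(100.3, 101.2, 150), centers = c(100, 150))
#' @export
assign_bins <- function(sizes, centers, half_width = 0.5) {
  stopifnot(half_width >= 0, length(centers) >= 1)
  vapply(sizes, function(s) {
    d <- abs(centers - s)
    i <- which.min(d)
    if (d[i] <= half_width) i else NA_integer_
  }, integer(1))
}

#' Detect TDFs polymorphic between two accessions
#'
#' A TDF (allele) is polymorphic when its fragment is present in exactly one
#' accession's self-cross, consistently across the timepoints where that self
#' was sampled -- the signature of a SNP disrupting one accession's
#' restriction site.  Alleles present in both selfs, absent everywhere, or
#' inconsistent across timepoints are not polymorphic.
#'
#' @param table Allele-call table: a data frame with key columns
#'   `primer_key`, `bin_center` and one 0/1 presence column per design
#'   sample.
#' @param design A [cross_design()] table.
#' @return The key columns plus `carrier` (the accession whose self carries
#'   the allele, `NA` if not polymorphic) and logical `polymorphic`.
#' @export
detect_polymorphic <- function(table, design) {
  check_allele_table(table, design)
  acc <- design_accessions(design)
  selfs <- design[design$mother == design$father, , drop = FALSE]
  for (a in acc) {
    if (!any(selfs$mother == a)) {
      stop("design lacks the ", a, " x ", a, " self cross", call. = FALSE)
    }
  }
  presence_in_self <- function(a) {
    cols <- selfs$sample[selfs$mother == a]
    vals <- as.matrix(table[, cols, drop = FALSE])
    list(all = rowSums(vals) == length(cols), none = rowSums(vals) == 0)
  }
  pa <- presence_in_self(acc[1])
  pb <- presence_in_self(acc[2])
  carrier <- dplyr::case_when(
    pa$all & pb$none ~ acc[1],
    pb$all & pa$none ~ acc[2],
    TRUE ~ NA_character_
  )
  out <- table[, c("primer_key", "bin_center"), drop = FALSE]
  out$carrier <- carrier
  out$polymorphic <- !is.na(carrier)
  tibble::as_tibble(out)
}

#' Call parent-of-origin expression for polymorphic TDFs
#'
#' For each polymorphic TDF, each timepoint is classified from the two
#' reciprocal F1 samples: *maternal-supporting* when the allele is present in
#' the F1 where the carrier accession is the mother and absent in the
#' reciprocal; *paternal-supporting* in the mirror case; *biallelic* when
#' present in both directions; *silent* when absent from both; timepoints
#' with any required sample missing are uninformative.  The TDF is called
#' `maternal` (resp. `paternal`) when at least `min_stages` timepoints
#' support that direction and none supports the opposite; timepoints
#' supporting both directions, or any biallelic timepoint alongside
#' sub-threshold support, yield `not_uniparental`; otherwise the evidence is
#' `insufficient_evidence`.  Non-polymorphic TDFs are passed through as
#' `not_polymorphic`.
#'
#' @inheritParams detect_polymorphic
#' @param min_stages Minimum number of supporting timepoints for a
#'   uniparental call (default 2, i.e. at least two of the stages sampled).
#' @return A tibble with one row per table row: the key columns, `carrier`,
#'   `call` in `{maternal, paternal, not_uniparental, not_polymorphic,
#'   insufficient_evidence}`, `supporting_timepoints` (comma-joined) and
#'   `n_support`.
#' @export
call_parent_of_origin <- function(table, design, min_stages = 2L) {
  check_allele_table(table, design)
  poly <- detect_polymorphic(table, design)
  acc <- design_accessions(design)
  timepoints <- sort(unique(design$timepoint))

  sample_of <- function(mother, father, tp) {
    s <- design$sample[design$mother == mother & design$father == father &
                         design$timepoint == tp]
    if (length(s) == 1) s else NA_character_
  }

  n <- nrow(table)
  call <- character(n)
  support <- character(n)
  n_support <- integer(n)

  for (i in seq_len(n)) {
    if (!poly$polymorphic[i]) {
      call[i] <- "not_polymorphic"; support[i] <- ""; n_support[i] <- 0L
      next
    }
    carrier <- poly$carrier[i]
    other <- setdiff(acc, carrier)
    m_tp <- numeric(0); p_tp <- numeric(0); n_biallelic <- 0L
    for (tp in timepoints) {
      s_mat <- sample_of(carrier, other, tp)  # carrier is mother
      s_pat <- sample_of(other, carrier, tp)  # carrier is father
      if (is.na(s_mat) || is.na(s_pat)) next  # uninformative timepoint
      in_mat <- table[[s_mat]][i] == 1
      in_pat <- table[[s_pat]][i] == 1
      if (in_mat && !in_pat) m_tp <- c(m_tp, tp)
      else if (in_pat && !in_mat) p_tp <- c(p_tp, tp)
      else if (in_mat && in_pat) n_biallelic <- n_biallelic + 1L
    }
    if (length(m_tp) > 0 && length(p_tp) > 0) {
      call[i] <- "not_uniparental"; support[i] <- ""; n_support[i] <- 0L
    } else if (length(m_tp) >= min_stages) {
      call[i] <- "maternal"
      support[i] <- paste(m_tp, collapse = ",")
      n_support[i] <- length(m_tp)
    } else if (length(p_tp) >= min_stages) {
      call[i] <- "paternal"
      support[i] <- paste(p_tp, collapse = ",")
      n_support[i] <- length(p_tp)
    } else if (n_biallelic > 0) {
      call[i] <- "not_uniparental"; support[i] <- ""; n_support[i] <- 0L
    } else {
      call[i] <- "insufficient_evidence"; support[i] <- ""; n_support[i] <- 0L
    }
  }

  out <- poly
  out$call <- call
  out$supporting_timepoints <- support
  out$n_support <- n_support
  out
}
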