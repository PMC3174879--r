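#' Intergenic neighborhood of a candidate gene
#'
#' Returns the interval spanning from the end of the nearest gene body to the
#' left of the candidate to the start of the nearest gene body to the right,
#' including the candidate's own gene body -- the region within which
#' candidate imprinting control regions are searched.  Chromosome ends (or
#' position 1) are used where no neighbor exists; a neighbor overlapping the
#' candidate truncates the region at the candidate's own boundary, with a
#' warning.
#'
#' @param gene_id Candidate gene id.
#' @param annotation Data frame of gene bodies: `gene_id`, `chrom`, `start`,
#'   `end` (1-based closed), `strand` (`"+"`/`"-"`).
#' @param chrom_lengths Optional named numeric vector of chromosome lengths;
#'   without it, a missing right neighbor extends the region to `Inf`.
#' @return A list `chrom`, `start`, `end`, `gene` (the candidate's row).
#' @examples
#' ann <- tibble::tibble(gene_id = c("l", "g", "r"), chrom = "1",
#'                       start = c(100, 1000, 3000), end = c(400, 2000, 3500),
#'                       strand = "+")
#' flank_region("g", ann)  # [400, 3000]
#' @export
flank_region <- function(gene_id, annotation, chrom_lengths = NULL) {
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand")
                %in% names(annotation)),
            all(annotation$start <= annotation$end))
  g <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1) {
    stop("gene '", gene_id, "' not found exactly once in the annotation",
         call. = FALSE)
  }
  same <- annotation[annotation$chrom == g$chrom &
                       annotation$gene_id != gene_id, , drop = FALSE]

  left <- same[same$end <= g$start, , drop = FALSE]
  right <- same[same$start >= g$end, , drop = FALSE]
  overlapping <- same[same$end > g$start & same$start < g$end, , drop = FALSE]
  if (nrow(overlapping) > 0) {
    warning("gene(s) ", paste(overlapping$gene_id, collapse = ", "),
            " overlap ", gene_id,
            "; flank region truncated at the overlap boundary",
            call. = FALSE)
  }

  start <- if (nrow(left) > 0) max(left$end) else 1
  end <- if (nrow(right) > 0) {
    min(right$start)
  } else if (!is.null(chrom_lengths) && g$chrom %in% names(chrom_lengths)) {
    unname(chrom_lengths[[g$chrom]])
  } else {
    Inf
  }
  # overlapping neighbors shrink the flank to the gene body on that side
  if (nrow(overlapping) > 0) {
    if (any(overlapping$start < g$start)) start <- g$start
    if (any(overlapping$end > g$end)) end <- g$end
  }
  list(chrom = g$chrom, start = start, end = end, gene = g)
}

#' Find differentially methylated regions between two conditions
#'
#' A cytosine is differential when the absolute difference between its two
#' percent-methylation values is at least `min_diff`.  Differential
#' cytosines are chained into a region while consecutive ones are at most
#' `max_gap` bp apart; chains with at least `min_count` differential
#' cytosines are emitted as DMRs spanning from their first to their last
#' differential cytosine.  `n_cytosines` counts *all* cytosines inside the
#' emitted interval; `n_hyper_b` counts those hypermethylated in condition B
#' (`pct_b - pct_a >= min_diff`).
#'
#' @param records Data frame of per-cytosine methylation: `chrom`, `pos`
#'   (1-based, sorted increasing within chromosome), `pct_a`, `pct_b`
#'   (percent methylation in conditions A and B, 0--100).
#' @param min_diff Minimum per-cytosine |pct_b - pct_a| in percentage points
#'   (default 20).
#' @param min_count Minimum differential cytosines per region (default 5).
#' @param max_gap Maximum distance between consecutive differential
#'   cytosines within one region, in bp (default 250).
#' @param gene Optional candidate gene (one-row annotation data frame or the
#'   `gene` element of [flank_region()]); when given, each DMR is annotated
#'   with its side and distance relative to the gene body.
#' @return A tibble of DMRs: `chrom`, `start`, `end`, `n_cytosines`,
#'   `n_differential`, `n_hyper_b`, `mean_difference` (mean of
#'   `pct_b - pct_a` over all cytosines in the interval), and when `gene` is
#'   supplied `side` (`upstream`/`downstream`/`overlapping`, per gene
#'   strand) and `distance` (bp from the gene-body boundary to the nearest
#'   DMR edge, 0 when overlapping).
#' @export
find_dmrs <- function(records, min_diff = 20, min_count = 5, max_gap = 250,
                      gene = NULL) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("chrom", "pos", "pct_a", "pct_b") %in% names(records)),
            min_diff > 0, min_count > 0, max_gap > 0)
  if (nrow(records) == 0) return(empty_dmr_table(!is.null(gene)))
  if (any(records$pct_a < 0 | records$pct_a > 100 |
            records$pct_b < 0 | records$pct_b > 100)) {
    stop("percent methylation must lie in [0, 100]", call. = FALSE)
  }
  by_chrom <- split(records, records$chrom)
  for (ch in names(by_chrom)) {
    if (is.unsorted(by_chrom[[ch]]$pos, strictly = FALSE)) {
      stop("methylation records not sorted by position on chromosome ", ch,
           call. = FALSE)
    }
  }

  out <- purrr::map_dfr(by_chrom, function(rec) {
    diff <- rec$pct_b - rec$pct_a
    is_diff <- abs(diff) >= min_diff
    if (!any(is_diff)) return(empty_dmr_table(FALSE))
    dpos <- rec$pos[is_diff]
    # chain differential cytosines while gaps stay within max_gap
    chain <- cumsum(c(1, diff(dpos) > max_gap))
    purrr::map_dfr(split(dpos, chain), function(p) {
      if (length(p) < min_count) return(empty_dmr_table(FALSE))
      inside <- rec$pos >= min(p) & rec$pos <= max(p)
      tibble::tibble(
        chrom = rec$chrom[1],
        start = min(p), end = max(p),
        n_cytosines = sum(inside),
        n_differential = length(p),
        n_hyper_b = sum(inside & diff >= min_diff),
        mean_difference = mean(diff[inside])
      )
    })
  })
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  if (!is.null(gene) && nrow(out) > 0) {
    out <- annotate_dmr_side(out, gene)
  } else if (!is.null(gene)) {
    out <- empty_dmr_table(TRUE)
  }
  out
}

empty_dmr_table <- function(with_gene = FALSE) {
  out <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    n_cytosines = integer(), n_differential = integer(),
    n_hyper_b = integer(), mean_difference = numeric()
  )
  if (with_gene) {
    out$side <- character()
    out$distance <- numeric()
  }
  out
}

annotate_dmr_side <- function(dmrs, gene) {
  if (is.list(gene) && !is.data.frame(gene) && "gene" %in% names(gene)) {
    gene <- gene$gene
  }
  gene <- tibble::as_tibble(gene)
  stopifnot(nrow(gene) == 1,
            all(c("start", "end", "strand") %in% names(gene)))
  gs <- gene$start; ge <- gene$end; plus <- gene$strand == "+"
  side <- character(nrow(dmrs))
  dist <- numeric(nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    if (dmrs$end[i] < gs) {          # left of the gene body
      side[i] <- if (plus) "upstream" else "downstream"
      dist[i] <- gs - dmrs$end[i]
    } else if (dmrs$start[i] > ge) { # right of the gene body
      side[i] <- if (plus) "downstream" else "upstream"
      dist[i] <- dmrs$start[i] - ge
    } else {
      side[i] <- "overlapping"
      dist[i] <- 0
    }
  }
  dmrs$side <- side
  dmrs$distance <- dist
  dmrs
}
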