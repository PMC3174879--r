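#' Seeded synthetic fixtures for the cDNA-AFLP pipeline
#'
#' The generators in this file build ground-truth test surfaces for every
#' analysis step without external downloads: transcriptomes with planted
#' restriction-fragment geometry and site-disrupting SNPs, reciprocal-cross
#' allele tables with known maternal genes, and methylation tracks with
#' planted DMRs.  All are deterministic under a fixed seed.
#'
#' @name synthetic-data
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Random filler over {A,C,G}: without T neither RGATCY nor TTAA can occur,
# in the filler or across any junction with the planted motifs.
site_free_filler <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G"), n, replace = TRUE), collapse = "")
}

#' Simulate a two-accession transcriptome with planted AFLP fragments
#'
#' Each gene's transcript is built as 5' filler + a single BstYI site
#' (`RGATCY`) + spacer + a single MseI site (`TTAA`) + 3' filler + poly-A
#' tail, with all filler drawn from a T-free alphabet so the planted sites
#' are the only ones; every transcript therefore carries exactly one
#' dual-enzyme fragment, which is also its poly-A-proximal one.  Accession B
#' starts as a copy of accession A; for a configured fraction of genes a SNP
#' destroys the BstYI or MseI site of the fragment, making the TDF
#' accession-A-specific (the polymorphism class the screen detects).
#'
#' @param n_genes Number of genes.
#' @param seed Random seed (fixed seed gives byte-identical output).
#' @param isoforms_per_gene Isoforms per gene; extra isoforms share the 3'
#'   end (and hence the fragment) and differ in 5' UTR length.
#' @param spacer_range Length range of the fragment interior between the two
#'   remnants (min >= 4 so two-base selective contexts never overlap).
#' @param utr5_range,utr3_range Length ranges of the flanking filler.
#' @param polya_length Poly-A tail length.
#' @param disruption_fraction Fraction of genes whose accession-B allele
#'   carries a site-disrupting SNP.
#' @param size Predicted-size model used for the truth table sizes.
#' @return A list: `accession_a` and `accession_b` (transcript tables with
#'   `id`, `gene_id`, `sequence`) and `truth` (one row per gene:
#'   planted fragment coordinates, `primer_key`, `fragment_length`,
#'   `predicted_size`, `disrupted`, `disrupted_site`).
#' @examples
#' sim <- simulate_transcriptome(n_genes = 5, seed = 1)
#' sim$truth
#' @export
simulate_transcriptome <- function(n_genes = 200, seed = 1,
                                   isoforms_per_gene = 1L,
                                   spacer_range = c(20, 180),
                                   utr5_range = c(30, 120),
                                   utr3_range = c(20, 80),
                                   polya_length = 20L,
                                   disruption_fraction = 0.5,
                                   size = size_model()) {
  stopifnot(n_genes >= 1, isoforms_per_gene >= 1,
            spacer_range[1] >= 4, spacer_range[1] <= spacer_range[2],
            disruption_fraction >= 0, disruption_fraction <= 1)
  with_seed(seed, {
    rows_a <- list(); rows_b <- list(); truth <- list()
    for (i in seq_len(n_genes)) {
      gene <- sprintf("SYN%04d", i)
      r_base <- sample(c("A", "G"), 1)
      y_base <- sample(c("C", "T"), 1)
      spacer <- site_free_filler(sample(spacer_range[1]:spacer_range[2], 1))
      utr3 <- site_free_filler(sample(utr3_range[1]:utr3_range[2], 1))
      bst_site <- paste0(r_base, "GATC", y_base)
      core <- paste0(bst_site, spacer, "TTAA", utr3,
                     strrep("A", polya_length))

      disrupted <- stats::runif(1) < disruption_fraction
      disrupted_site <- NA_character_
      core_b <- core
      if (disrupted) {
        disrupted_site <- sample(c("BstYI", "MseI"), 1)
        if (disrupted_site == "BstYI") {
          # GATC -> GGTC: removes the only GATC, creates no new site
          core_b <- sub("GATC", "GGTC", core_b)
        } else {
          # TTAA -> TCAA: removes the only TT dinucleotide
          core_b <- sub("TTAA", "TCAA", core_b)
        }
      }

      frag_len <- 6L + nchar(spacer)
      frag_seq <- paste0("GATC", y_base, spacer, "T")
      ctx <- selective_contexts(frag_seq, 2L, 2L)
      utr5_lens <- sample(utr5_range[1]:utr5_range[2], isoforms_per_gene,
                          replace = TRUE)
      for (k in seq_len(isoforms_per_gene)) {
        utr5 <- site_free_filler(utr5_lens[k])
        id <- sprintf("%s.%d", gene, k)
        rows_a[[length(rows_a) + 1]] <- tibble::tibble(
          id = id, gene_id = gene, sequence = paste0(utr5, core))
        rows_b[[length(rows_b) + 1]] <- tibble::tibble(
          id = id, gene_id = gene, sequence = paste0(utr5, core_b))
      }
      truth[[i]] <- tibble::tibble(
        gene_id = gene,
        bst_variant = y_base,
        bst_context = ctx$bst_context,
        mse_context = ctx$mse_context,
        primer_key = sprintf("BstYI+%s%s/MseI+%s", y_base,
                             ctx$bst_context, ctx$mse_context),
        fragment_length = frag_len,
        predicted_size = frag_len + size$correction_total,
        disrupted = disrupted,
        disrupted_site = disrupted_site
      )
    }
    out <- list(
      accession_a = dplyr::bind_rows(rows_a),
      accession_b = dplyr::bind_rows(rows_b),
      truth = dplyr::bind_rows(truth)
    )
    # defensive post-scan: the planted sites must be the only ones
    check <- function(tx, expect_frag) {
      for (j in seq_len(nrow(tx))) {
        f <- digest_transcript(tx[j, ], mode = "all")
        n_expected <- if (expect_frag[tx$gene_id[j]]) 1L else 0L
        if (nrow(f) != n_expected) {
          stop("internal error: post-scan found ", nrow(f),
               " fragments in ", tx$id[j], call. = FALSE)
        }
      }
    }
    expect_a <- stats::setNames(rep(TRUE, n_genes), out$truth$gene_id)
    expect_b <- stats::setNames(!out$truth$disrupted, out$truth$gene_id)
    check(out$accession_a, expect_a)
    check(out$accession_b, expect_b)
    out
  })
}

#' Simulate a reciprocal-cross allele-call table with known truth
#'
#' Converts a simulated transcriptome truth table into a presence/absence
#' allele table across both parental selfs and both reciprocal F1s at each
#' timepoint.  Polymorphic TDFs (accession-B site disrupted, carrier
#' accession A) are labelled maternal with probability `maternal_fraction`,
#' else biallelic: a maternal allele appears in an F1 only when the carrier
#' is the mother (at the first `n_maternal_timepoints` timepoints), a
#' biallelic allele appears in both F1 directions at every timepoint.
#' Non-polymorphic TDFs are present in every sample.  Optional dropout noise
#' flips present cells to absent.
#'
#' @param truth Truth table from [simulate_transcriptome()].
#' @param accessions Two accession names; the first is the fragment carrier.
#' @param timepoints Timepoints in dap.
#' @param maternal_fraction Fraction of polymorphic TDFs that are maternal.
#' @param n_maternal_timepoints Number of (leading) timepoints at which a
#'   maternal allele is actually expressed; defaults to all.
#' @param dropout Per-cell probability that a present call is lost.
#' @param seed Random seed.
#' @return A list: `table` (allele-call table for [call_parent_of_origin()]),
#'   `design` (the [cross_design()]), and `truth` (per-TDF `label` in
#'   `{maternal, biallelic, not_polymorphic}` and `carrier`).
#' @export
simulate_allele_table <- function(truth,
                                  accessions = c("AccA", "AccB"),
                                  timepoints = c(3, 4, 5),
                                  maternal_fraction = 0.5,
                                  n_maternal_timepoints = length(timepoints),
                                  dropout = 0,
                                  seed = 1) {
  stopifnot(maternal_fraction >= 0, maternal_fraction <= 1,
            n_maternal_timepoints >= 0,
            n_maternal_timepoints <= length(timepoints),
            dropout >= 0, dropout <= 1)
  design <- cross_design(accessions, timepoints)
  a <- accessions[1]; b <- accessions[2]
  with_seed(seed, {
    label <- ifelse(
      truth$disrupted,
      ifelse(stats::runif(nrow(truth)) < maternal_fraction,
             "maternal", "biallelic"),
      "not_polymorphic"
    )
    tab <- tibble::tibble(
      primer_key = truth$primer_key,
      bin_center = as.numeric(truth$predicted_size)
    )
    expressed_tps <- timepoints[seq_len(n_maternal_timepoints)]
    for (j in seq_len(nrow(design))) {
      s <- design[j, ]
      present <- vapply(seq_len(nrow(truth)), function(i) {
        switch(label[i],
          not_polymorphic = TRUE,  # both accessions yield the fragment
          biallelic = s$mother == a || s$father == a,
          maternal = s$mother == a && s$timepoint %in% expressed_tps
        )
      }, logical(1))
      if (dropout > 0) {
        present <- present & stats::runif(length(present)) >= dropout
      }
      tab[[s$sample]] <- as.integer(present)
    }
    list(
      table = tab,
      design = design,
      truth = tibble::tibble(
        primer_key = truth$primer_key,
        bin_center = as.numeric(truth$predicted_size),
        gene_id = truth$gene_id,
        label = label,
        carrier = ifelse(label == "not_polymorphic", NA_character_, a)
      )
    )
  })
}

#' Simulate a two-condition percent-methylation track with planted DMRs
#'
#' Background cytosines get condition-A methylation near `baseline` and a
#' condition-B value differing by bounded noise (strictly below any sensible
#' detection threshold); each planted DMR adds `effect` percentage points to
#' condition B over a cluster of cytosines.
#'
#' @param n_background Number of background cytosines.
#' @param region_length Track length in bp (positions drawn from
#'   `1..region_length`).
#' @param chrom Chromosome name.
#' @param baseline Background methylation percentage (condition A).
#' @param noise Half-width of the background condition difference, in
#'   percentage points.
#' @param dmrs List of planted DMRs, each a list with `start`, `width`,
#'   `n_cytosines`, `effect` (percentage points added to condition B).
#' @param seed Random seed.
#' @return A list: `records` (sorted methylation table `chrom`, `pos`,
#'   `pct_a`, `pct_b`, `planted`) and `truth` (one row per planted DMR with
#'   its realized `start`, `end`, `n_cytosines`).
#' @export
simulate_methylation <- function(n_background = 300,
                                 region_length = 20000,
                                 chrom = "1",
                                 baseline = 50,
                                 noise = 5,
                                 dmrs = list(),
                                 seed = 1) {
  stopifnot(n_background >= 0, noise >= 0,
            baseline - 10 >= 0, baseline + 10 <= 100)
  for (d in dmrs) {
    stopifnot(all(c("start", "width", "n_cytosines", "effect") %in% names(d)))
    if (d$effect <= noise) {
      warning("planted effect (", d$effect,
              ") does not exceed the noise bound (", noise,
              "): the DMR may be undetectable", call. = FALSE)
    }
  }
  with_seed(seed, {
    pos <- sort(sample.int(region_length, n_background))
    rec <- tibble::tibble(
      chrom = chrom,
      pos = pos,
      pct_a = baseline + stats::runif(n_background, -10, 10),
      planted = FALSE
    )
    rec$pct_b <- rec$pct_a + stats::runif(n_background, -noise, noise)
    truth <- list()
    for (d in dmrs) {
      p <- sort(sample(d$start:(d$start + d$width - 1), d$n_cytosines))
      a <- baseline + stats::runif(d$n_cytosines, -10, 10)
      rec <- dplyr::bind_rows(rec, tibble::tibble(
        chrom = chrom, pos = p, pct_a = a, planted = TRUE,
        pct_b = pmin(100, a + d$effect)
      ))
      truth[[length(truth) + 1]] <- tibble::tibble(
        start = min(p), end = max(p), n_cytosines = d$n_cytosines)
    }
    # on position collisions keep the planted cytosine
    rec <- rec[order(rec$pos, !rec$planted),
               c("chrom", "pos", "pct_a", "pct_b", "planted")]
    rec <- rec[!duplicated(rec$pos), , drop = FALSE]
    list(records = rec, truth = dplyr::bind_rows(truth))
  })
}
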