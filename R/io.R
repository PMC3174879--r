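#' Read a transcript set from FASTA
#'
#' Multi-record FASTA, wrapped or unwrapped lines, case-insensitive.  The
#' record id is the first whitespace-delimited token of the header; gene ids
#' are derived with [derive_gene_id()] unless an explicit map is given.
#'
#' @param path FASTA file.
#' @param gene_map Optional data frame `id`, `gene_id` overriding the
#'   suffix-stripping derivation.
#' @return A tibble `id`, `gene_id`, `sequence` (upper case).
#' @export
read_transcripts <- function(path, gene_map = NULL) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble::tibble(id = character(), gene_id = character(),
                          sequence = character()))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(set) == 0)) {
    stop("FASTA file contains empty record(s): ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  out <- tibble::tibble(
    id = ids,
    gene_id = derive_gene_id(ids),
    sequence = unname(toupper(as.character(set)))
  )
  if (!is.null(gene_map)) {
    stopifnot(all(c("id", "gene_id") %in% names(gene_map)))
    idx <- match(out$id, gene_map$id)
    out$gene_id <- ifelse(is.na(idx), out$gene_id, gene_map$gene_id[idx])
  }
  out
}

#' Write a transcript set to FASTA
#'
#' @param transcripts Tibble `id`, `sequence`.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path, width = 60L) {
  set <- Biostrings::DNAStringSet(transcripts$sequence)
  names(set) <- transcripts$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Tab-separated interchange with provenance headers
#'
#' All tabular artifacts are exchanged as UTF-8 TSV with a header row,
#' preceded by `#`-prefixed provenance comment lines echoing the parameters
#' that produced the table, so every output is self-describing.
#'
#' @param x Data frame.
#' @param path Output file.
#' @param params Named list echoed as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path, params = list()) {
  lines <- character(0)
  if (length(params) > 0) {
    lines <- sprintf("# %s=%s", names(params),
                     vapply(params, function(v) paste(format(v), collapse = ","),
                            character(1)))
  }
  writeLines(lines, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_tsv_report
#' @export
read_tsv_report <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read an observed-TDF table
#'
#' Columns: `tdf_id`, `bst_variant`, `bst_sel`, `mse_sel`, `size`.  Empty or
#' missing selective-nucleotide cells mean no selectivity on that side.
#'
#' @param path TSV file.
#' @return A tibble in the [match_tdf_table()] input format.
#' @export
read_observed_tdfs <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(
                           tdf_id = readr::col_character(),
                           bst_variant = readr::col_character(),
                           bst_sel = readr::col_character(),
                           mse_sel = readr::col_character(),
                           size = readr::col_double()
                         ))
  out$bst_sel[is.na(out$bst_sel)] <- ""
  out$mse_sel[is.na(out$mse_sel)] <- ""
  out
}

#' Read a BED-like per-cytosine methylation table
#'
#' Columns `chrom`, `pos` (1-based cytosine position), `pct_a`, `pct_b`,
#' optional `context` (CpG/CHG/CHH, pass-through metadata).
#'
#' @param path TSV file.
#' @return A tibble for [find_dmrs()].
#' @export
read_methylation <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(all(c("chrom", "pos", "pct_a", "pct_b") %in% names(out)))
  out$chrom <- as.character(out$chrom)
  out
}

#' Read gene bodies from a GFF3 subset
#'
#' Minimal GFF3 reader for `gene` features only: seqid, start, end and
#' strand are taken from the standard columns and the gene id from the `ID`
#' attribute (falling back to `Name`).  Coordinates stay 1-based closed, the
#' convention [flank_region()] expects.
#'
#' @param path GFF3 file.
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[as.character(g$type) == "gene"]
  if (length(g) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          strand = character()))
  }
  id <- g$ID
  if ("Name" %in% names(S4Vectors::mcols(g))) {
    id <- ifelse(is.na(id), g$Name, id)
  }
  tibble::tibble(
    gene_id = sub("^gene:", "", id),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = as.numeric(GenomicRanges::start(g)),
    end = as.numeric(GenomicRanges::end(g)),
    strand = as.character(GenomicRanges::strand(g))
  )
}

#' Write gene bodies as a GFF3 subset
#'
#' @param annotation Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\taflpimprint\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotation$chrom, as.integer(annotation$start),
                     as.integer(annotation$end), annotation$strand,
                     annotation$gene_id))
  writeLines(lines, path)
  invisible(path)
}
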