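#' Read a gene occupancy table
#'
#' Expected columns: `gene_id`, `chrom`, `start`, `end` (0-based half-open
#' bp), replicate log2(Dam-fusion/Dam) occupancies `occ_ctrl_rep1..k` and
#' `occ_mut_rep1..k`, per-sample `fdr`, and `n_gatc`. Extra columns are kept.
#' Common deposit-style column names (`FDR`, `gatc`/`GATC_sites`, `gene`,
#' `chr`) are normalised to this schema, so per-gene tables exported by the
#' upstream DamID gene-call scripts can be consumed directly.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_occupancy_tsv <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(tbl) <- normalise_occupancy_names(names(tbl))
  need <- c("gene_id", "fdr", "n_gatc")
  missing <- setdiff(need, names(tbl))
  if (length(missing))
    abort(paste("occupancy table lacks columns:",
                paste(missing, collapse = ", ")))
  tibble::as_tibble(tbl)
}

normalise_occupancy_names <- function(nm) {
  low <- tolower(nm)
  nm[low %in% c("gene", "gene_name", "name", "id")] <- "gene_id"
  nm[low %in% c("chr", "chromosome", "seqnames")] <- "chrom"
  nm[low == "fdr"] <- "fdr"
  nm[low %in% c("gatc", "gatc_sites", "n_gatc", "gatc.sites")] <- "n_gatc"
  nm
}

#' Write a gene occupancy table
#'
#' @param table Occupancy tibble.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene annotations as BED6
#'
#' Plain BED6: `chrom`, `start`, `end` (0-based half-open), `name`, `score`,
#' `strand`. Read returns a tibble with `name` exposed as `gene_id`.
#'
#' @param path BED file.
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`, `score`,
#'   `strand`.
#' @export
read_gene_bed <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tbl) < 4) abort("expected at least 4 BED columns")
  if (ncol(tbl) < 6) {
    if (ncol(tbl) == 4) tbl$V5 <- 0
    tbl$V6 <- "+"
  }
  names(tbl)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
  tibble::as_tibble(tbl[, 1:6])
}

#' @rdname read_gene_bed
#' @param genes Annotation tibble (`chrom`, `start`, `end`, `gene_id`,
#'   optionally `score`, `strand`).
#' @export
write_gene_bed <- function(genes, path) {
  out <- data.frame(chrom = genes$chrom, start = genes$start,
                    end = genes$end, name = genes$gene_id,
                    score = genes$score %||% 0,
                    strand = genes$strand %||% "+")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bead table
#'
#' TSV with `bead_index`, `chromosome`, `compartment` (EU|PCH) and
#' `h3k27me3` (0|1).
#'
#' @param beads Bead tibble.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_beads_tsv <- function(beads, path) {
  out <- beads
  out$h3k27me3 <- as.integer(out$h3k27me3)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_beads_tsv
#' @export
read_beads_tsv <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tbl$h3k27me3 <- as.logical(tbl$h3k27me3)
  tibble::as_tibble(tbl)
}
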