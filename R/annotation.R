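#' Construct a gene annotation
#'
#' Genes are strand-oriented half-open intervals `[tx_start, tx_end)` in
#' 0-based coordinates. The transcription start site (TSS) of a '+' gene is
#' `tx_start`; of a '-' gene, `tx_end - 1`. Genes are stored sorted by
#' `(chrom, tx_start)`.
#'
#' @param gene_id unique character ids.
#' @param chrom chromosome names.
#' @param strand `"+"` / `"-"`.
#' @param tx_start,tx_end 0-based half-open transcript bounds.
#' @param genome a [genome()].
#' @return `data.frame` of class `"annotation"` with the genome attached.
#' @export
annotation <- function(gene_id, chrom, strand, tx_start, tx_end, genome) {
  genome <- check_genome(genome)
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(tx_start >= tx_end)) {
    bad <- gene_id[tx_start >= tx_end]
    stop("tx_start >= tx_end for gene(s): ", paste(bad, collapse = ", "))
  }
  if (!all(chrom %in% names(genome)))
    stop("genes on chromosomes absent from the genome")
  if (any(tx_start < 0) || any(tx_end > unclass(genome)[chrom]))
    stop("gene interval out of chromosome bounds")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   strand = as.character(strand),
                   tx_start = as.numeric(tx_start),
                   tx_end = as.numeric(tx_end),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$tx_start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, genome = genome, class = c("annotation", "data.frame"))
}

#' Genome of an annotation
#' @param ann an [annotation()].
#' @return the attached [genome()].
#' @export
ann_genome <- function(ann) attr(ann, "genome")

#' Transcription start sites of an annotation
#'
#' @param ann an [annotation()].
#' @return numeric vector of 0-based TSS positions, named by gene id.
#' @export
tss <- function(ann) {
  setNames(ifelse(ann$strand == "+", ann$tx_start, ann$tx_end - 1),
           ann$gene_id)
}

#' @export
print.annotation <- function(x, ...) {
  cat("<annotation> ", nrow(x), " genes on ", length(ann_genome(x)),
      " chromosome(s)\n", sep = "")
  if (nrow(x) > 0) print(head(as.data.frame(x), 5))
  invisible(x)
}
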