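## Ortholog detection from pairwise homology hit tables:
## bidirectional best hits (BBH) under an e-value cutoff, and extraction
## of single-copy core ortholog groups spanning all genomes.

#' Bidirectional best hits
#'
#' A pair (a, b) is returned when b is a's best hit in b's genome and a
#' is b's best hit in a's genome, with both e-values at or below the
#' cutoff.  Best hits are resolved by highest bit score, ties by
#' lexicographically smallest subject gene id.
#'
#' @param hits data frame with columns `query_gene`, `subject_gene`,
#'   `query_genome`, `subject_genome`, `bit_score`, `evalue`
#'   (BLAST-outfmt-6-like).
#' @param evalue_cutoff maximum e-value for a hit to count.
#' @return data frame of ortholog pairs with columns `gene_a`,
#'   `genome_a`, `gene_b`, `genome_b` (each pair once, `gene_a < gene_b`).
#' @export
reciprocal_best_hits <- function(hits, evalue_cutoff = 0.001) {
  need <- c("query_gene", "subject_gene", "query_genome", "subject_genome",
            "bit_score", "evalue")
  stopifnot(all(need %in% names(hits)))
  h <- hits[hits$evalue <= evalue_cutoff &
              hits$query_genome != hits$subject_genome, , drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(gene_a = character(0), genome_a = character(0),
                      gene_b = character(0), genome_b = character(0)))
  }
  ## best hit per (query gene, subject genome): max bit score, then
  ## lexicographically smallest subject id
  h <- h[order(h$query_gene, h$subject_genome, -h$bit_score, h$subject_gene), ]
  key <- paste(h$query_gene, h$subject_genome, sep = "\r")
  best <- h[!duplicated(key), , drop = FALSE]
  fwd <- paste(best$query_gene, best$subject_gene, sep = "\r")
  rev_ <- paste(best$subject_gene, best$query_gene, sep = "\r")
  mutual <- best[fwd %in% rev_, , drop = FALSE]
  first <- mutual$query_gene < mutual$subject_gene
  out <- data.frame(gene_a = ifelse(first, mutual$query_gene, mutual$subject_gene),
                    genome_a = ifelse(first, mutual$query_genome, mutual$subject_genome),
                    gene_b = ifelse(first, mutual$subject_gene, mutual$query_gene),
                    genome_b = ifelse(first, mutual$subject_genome, mutual$query_genome),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$gene_a, out$gene_b, sep = "\r")), , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-copy core ortholog groups
#'
#' Builds a graph over genes from BBH pairs across all genome pairs and
#' keeps the connected components that contain exactly one gene from
#' every genome; all other components (missing genomes, lineage-specific
#' duplications) are discarded.
#'
#' @param bbh_pairs data frame as returned by [reciprocal_best_hits()]
#'   (pooled over all genome pairs).
#' @param genomes character vector of all genome ids that must be
#'   represented.
#' @return list of ortholog groups; each group is a named character
#'   vector mapping genome id -> gene id.
#' @export
single_copy_core <- function(bbh_pairs, genomes) {
  stopifnot(length(genomes) >= 2L)
  if (!nrow(bbh_pairs)) return(list())
  genome_of <- c(stats::setNames(bbh_pairs$genome_a, bbh_pairs$gene_a),
                 stats::setNames(bbh_pairs$genome_b, bbh_pairs$gene_b))
  genome_of <- genome_of[!duplicated(names(genome_of))]
  g <- igraph::graph_from_data_frame(
    bbh_pairs[, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  out <- list()
  for (genes in groups) {
    gs <- genome_of[genes]
    if (length(genes) == length(genomes) &&
        setequal(gs, genomes) && !anyDuplicated(gs)) {
      grp <- stats::setNames(genes, gs)[genomes]
      out[[length(out) + 1L]] <- grp
    }
  }
  ## deterministic order: by the gene id of the first genome
  if (length(out) > 1L) {
    out <- out[order(vapply(out, `[[`, character(1), 1L))]
  }
  out
}
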