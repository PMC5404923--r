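## Pathway-occurrence analysis: completeness calls per genome (a pathway
## counts as present when at least a threshold fraction of its expected
## functional roles is annotated), occurrence matrices ordered along a
## species tree, concordance between a focal gene and its dependent
## pathways, and auxotrophy prediction from minimal media.

#' Define a biosynthetic pathway
#'
#' @param name pathway name.
#' @param expected_roles functional roles expected in a complete pathway.
#' @param completeness_threshold fraction of expected roles required to
#'   call the pathway complete (inclusive); the default 0.9 tolerates
#'   one hard-to-annotate enzyme in a ten-gene pathway.
#' @param shared_roles roles counted toward this pathway although they
#'   also belong to another (e.g. a bifunctional isomerase at which two
#'   pathways converge).
#' @return a list of class `gd_pathway`.
#' @export
pathway_definition <- function(name, expected_roles,
                               completeness_threshold = 0.9,
                               shared_roles = character(0)) {
  stopifnot(length(expected_roles) >= 1L,
            completeness_threshold > 0, completeness_threshold <= 1)
  structure(list(name = name,
                 expected_roles = sort(unique(expected_roles)),
                 completeness_threshold = completeness_threshold,
                 shared_roles = sort(unique(shared_roles))),
            class = "gd_pathway")
}

#' Pathway completeness in a genome
#'
#' @param annotation a `gd_annotation`.
#' @param pathway a `gd_pathway`.
#' @return list with the `fraction` of expected roles present and the
#'   boolean `complete` (fraction >= threshold, inclusive).
#' @export
pathway_completeness <- function(annotation, pathway) {
  present <- intersect(pathway$expected_roles,
                       unique(annotation$genes$role))
  fraction <- length(present) / length(pathway$expected_roles)
  list(fraction = fraction,
       complete = fraction >= pathway$completeness_threshold - 1e-12)
}

#' Occurrence matrix of pathways and focal genes
#'
#' One column per pathway (1 when the pathway is complete in the genome)
#' and one per focal gene (1 when a gene with that role is annotated).
#' When a tree is supplied, rows follow its tip-label order, so the
#' matrix can be laid out alongside the phylogeny.
#'
#' @param annotations list of `gd_annotation`.
#' @param pathways list of `gd_pathway`.
#' @param focal_genes named character vector: column label -> functional
#'   role of the focal gene.
#' @param tree optional `phylo`; tip labels must match genome ids.
#' @return a `gd_presence` matrix (rows genomes, columns features).
#' @export
occurrence_matrix <- function(annotations, pathways,
                              focal_genes = character(0), tree = NULL) {
  genomes <- vapply(annotations, `[[`, character(1), "genome_id")
  names(annotations) <- genomes
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"))
    missing <- setdiff(tree$tip.label, genomes)
    if (length(missing)) {
      stop("tree tips without annotations: ", paste(missing, collapse = ", "))
    }
    genomes <- tree$tip.label
  }
  pnames <- vapply(pathways, `[[`, character(1), "name")
  cols <- c(pnames, names(focal_genes))
  mat <- matrix(0L, length(genomes), length(cols),
                dimnames = list(genomes, cols))
  for (g in genomes) {
    ann <- annotations[[g]]
    for (p in pathways) {
      mat[g, p$name] <- as.integer(pathway_completeness(ann, p)$complete)
    }
    roles <- unique(ann$genes$role)
    for (lab in names(focal_genes)) {
      mat[g, lab] <- as.integer(focal_genes[[lab]] %in% roles)
    }
  }
  presence_matrix(mat, "mixed")
}

#' Concordance between a focal gene and its dependent pathways
#'
#' The concordance score is the fraction of genomes where the focal
#' gene's presence matches the presence of at least one complete
#' dependent pathway (focal present <=> some pathway complete).  This
#' quantifies, per genome, whether the focal gene tracks its pathways;
#' discordant genomes are flagged.
#'
#' @param matrix a `gd_presence` from [occurrence_matrix()].
#' @param focal column name of the focal gene.
#' @param pathway_cols column names of the dependent pathways.
#' @return list with `concordance` and the named logical `discordant`
#'   per-genome flags.
#' @export
coevolution_concordance <- function(matrix, focal, pathway_cols) {
  m <- unclass(matrix)
  stopifnot(focal %in% colnames(m), all(pathway_cols %in% colnames(m)))
  focal_present <- m[, focal] == 1L
  any_pathway <- rowSums(m[, pathway_cols, drop = FALSE]) > 0L
  discordant <- focal_present != any_pathway
  list(concordance = mean(!discordant),
       discordant = stats::setNames(discordant, rownames(m)))
}

#' Predict lost biosynthetic pathways from a minimal medium
#'
#' A pathway is called lost (its end product auxotrophic) when the
#' nutrient it synthesizes appears in the model's predicted minimal
#' medium: the genome can no longer make the compound and must import
#' it.
#'
#' @param analysis a `gd_analysis` from [six_step_analysis()].
#' @param nutrient_pathway_map named character vector: nutrient id ->
#'   pathway name.
#' @return character vector of pathway names predicted auxotrophic.
#' @export
predict_auxotrophies <- function(analysis, nutrient_pathway_map) {
  nutrients <- analysis$minimal_medium$medium$nutrients
  hits <- intersect(names(nutrient_pathway_map), nutrients)
  sort(unname(nutrient_pathway_map[hits]))
}
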