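## Cross-model comparisons: reaction prevalence and presence matrices,
## lineage core models (reactions gene-associated in at least a
## threshold fraction of a lineage's models, then gapfilled), overlap
## partitions among up to four reaction sets, and containment of lineage
## cores in the cross-lineage conserved core.

#' Build a presence matrix
#'
#' @param values binary matrix (rows genomes/models, columns features).
#' @param feature_kind `"reaction"`, `"pathway"` or `"gene"`.
#' @return the matrix with class `gd_presence` and the kind attached.
#' @export
presence_matrix <- function(values, feature_kind = c("reaction", "pathway",
                                                     "gene", "mixed")) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(is.matrix(values), all(values %in% c(0L, 1L)))
  structure(values, feature_kind = feature_kind,
            class = c("gd_presence", class(values)))
}

#' Reaction prevalence across models
#'
#' @param models list of `gd_model`.
#' @param gene_associated_only count a reaction only where it carries a
#'   gene association (gapfilled occurrences are excluded); when
#'   `FALSE`, any occurrence counts.
#' @return list with the binary `matrix` (a `gd_presence`, rows =
#'   genomes) and the per-reaction `prevalence` fraction.
#' @export
reaction_prevalence <- function(models, gene_associated_only = TRUE) {
  stopifnot(length(models) >= 1L)
  sets <- lapply(models, function(m) {
    if (gene_associated_only) gene_associated_ids(m) else names(m$reactions)
  })
  genomes <- vapply(models, `[[`, character(1), "genome_id")
  features <- sort(unique(unlist(sets)))
  mat <- matrix(0L, length(models), length(features),
                dimnames = list(genomes, features))
  for (i in seq_along(sets)) mat[i, sets[[i]]] <- 1L
  list(matrix = presence_matrix(mat, "reaction"),
       prevalence = colMeans(mat))
}

## inclusive >= on a count fraction, robust to float boundaries:
## present in `count` of `n` models qualifies iff count/n >= threshold
meets_threshold <- function(count, n, threshold) {
  count >= threshold * n - 1e-9
}

#' Core metabolic model of a lineage
#'
#' The core consists of reactions gene-associated in at least
#' `threshold` of the lineage's models (the boundary is inclusive: 3 of
#' 4 models qualifies at 0.75).  The core model is then gapfilled on the
#' complete medium with the same algorithm used for genome models, so
#' the full six-step analysis can be run on it.
#'
#' @param models list of `gd_model` (at least 2).
#' @param db the `gd_universe` used to build the models.
#' @param threshold prevalence fraction required for core membership.
#' @param genome_id id given to the core model.
#' @param uptake_limit uptake cap for the gapfilling medium.
#' @return the gapfilled core `gd_model`; the `gd_gapfill` solution is
#'   attached as attribute `"gapfill"`.
#' @export
lineage_core_model <- function(models, db, threshold = 0.75,
                               genome_id = "lineage_core",
                               uptake_limit = 10) {
  stopifnot(length(models) >= 2L)
  prev <- reaction_prevalence(models, gene_associated_only = TRUE)
  n <- length(models)
  counts <- colSums(unclass(prev$matrix))
  core_ids <- names(counts)[meets_threshold(counts, n, threshold)]
  ## instantiate core reactions from the database templates; the merged
  ## gene association is the union of disjuncts seen across the lineage
  rxns <- list()
  for (rid in core_ids) {
    tmpl <- db$reactions[[rid]]
    if (is.null(tmpl)) {
      ## reaction unknown to the database: copy from the first model
      tmpl <- NULL
      for (m in models) if (rid %in% names(m$reactions)) {
        tmpl <- m$reactions[[rid]]; break
      }
    }
    gpr <- list()
    for (m in models) {
      r <- m$reactions[[rid]]
      if (!is.null(r) && is_gene_associated(r)) {
        gpr <- c(gpr, r$gene_association)
      }
    }
    tmpl$gene_association <- unique(gpr)
    tmpl$gapfilled <- FALSE
    rxns[[rid]] <- tmpl
  }
  for (nutrient in db$transportable) {
    ex <- make_exchange_reaction(nutrient)
    rxns[[ex$id]] <- ex
  }
  rxns[[db$biomass_reaction_id]] <- db$reactions[[db$biomass_reaction_id]]
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  mets <- db$metabolites[db$metabolites$id %in% used, , drop = FALSE]
  core <- stoichiometric_model(genome_id, mets, unname(rxns),
                               db$biomass_reaction_id)
  sol <- tryCatch(gapfill(core, db, uptake_limit = uptake_limit),
                  error = function(e) {
                    stop("lineage core cannot be gapfilled to growth: ",
                         conditionMessage(e), call. = FALSE)
                  })
  out <- apply_gapfill(core, db, sol)
  attr(out, "gapfill") <- sol
  out
}

#' Overlap partition of reaction sets
#'
#' Counts reactions in each of the `2^k - 1` exclusive membership
#' regions of `k` sets (2 <= k <= 4), as displayed by a Venn diagram.
#'
#' @param sets named list of 2 to 4 character vectors (e.g.
#'   gene-associated reaction ids per model), or a `gd_presence` matrix
#'   whose rows are taken as the sets.
#' @return named integer vector; region names join member set names with
#'   `"&"`.  Counts sum to the size of the union.
#' @export
overlap_partition <- function(sets) {
  if (inherits(sets, "gd_presence")) {
    m <- unclass(sets)
    sets <- lapply(rownames(m), function(g) colnames(m)[m[g, ] == 1L])
    names(sets) <- rownames(m)
  }
  k <- length(sets)
  stopifnot(k >= 2L, k <= 4L)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  out <- integer(0)
  for (size in seq_len(k)) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      pattern <- rep(FALSE, k); pattern[idx] <- TRUE
      count <- sum(apply(member, 1, function(row) all(row == pattern)))
      out[paste(names(sets)[idx], collapse = "&")] <- count
    }
  }
  out
}

#' Containment of lineage cores in the global conserved core
#'
#' For each lineage, the fraction of its core reactions that are also in
#' the conserved core across all lineages.
#'
#' @param lineage_cores named list of reaction-id sets, one per lineage.
#' @param global_core reaction-id set conserved across all models.
#' @return list with `per_lineage` fractions, their `mean`, and the
#'   `pooled` fraction (all lineage-core memberships pooled).
#' @export
core_containment <- function(lineage_cores, global_core) {
  stopifnot(length(lineage_cores) >= 1L,
            all(vapply(lineage_cores, length, integer(1)) > 0L))
  per <- vapply(lineage_cores, function(core) {
    length(intersect(core, global_core)) / length(unique(core))
  }, numeric(1))
  sizes <- vapply(lineage_cores, function(core) length(unique(core)),
                  numeric(1))
  hits <- vapply(lineage_cores, function(core) {
    length(intersect(core, global_core))
  }, numeric(1))
  list(per_lineage = per, mean = mean(per), pooled = sum(hits) / sum(sizes))
}
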