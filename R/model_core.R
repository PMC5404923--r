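## Domain types for metabolic models: metabolites, reactions with
## gene-protein-reaction (GPR) associations, stoichiometric models, the
## universal reaction database, genome annotations and growth media.
## Objects are plain lists with S3 classes, in the style of ape/vegan.

COMPARTMENTS <- c("cytosol", "extracellular")
DEFAULT_FLUX_BOUND <- 1000

#' Create a metabolite record
#'
#' @param id unique metabolite id within a model.
#' @param name human-readable name; defaults to the id.
#' @param compartment `"cytosol"` or `"extracellular"`.
#' @return a one-row data frame with columns `id`, `name`, `compartment`.
#' @export
metabolite <- function(id, name = id, compartment = "cytosol") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  compartment <- match.arg(compartment, COMPARTMENTS)
  data.frame(id = id, name = name, compartment = compartment,
             stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' Stoichiometry is a named numeric vector (names are metabolite ids,
#' negative coefficients consume, positive produce).  The gene
#' association is a disjunction of conjunctions: a list of character
#' vectors, each vector one isoenzyme (a single gene or a complex).
#' Exchange reactions follow the standard sign convention: negative flux
#' is uptake, positive flux secretion.
#'
#' @param id reaction id.
#' @param stoichiometry named numeric vector; must be nonempty.
#' @param lower_bound,upper_bound flux bounds, `lower_bound <= upper_bound`.
#' @param gene_association list of character vectors (possibly empty list).
#' @param gapfilled was this reaction added by gapfilling?  Gapfilled
#'   reactions must carry no gene association.
#' @param is_exchange exchange reaction flag.
#' @return a list of class `gd_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0,
                     upper_bound = DEFAULT_FLUX_BOUND,
                     gene_association = list(), gapfilled = FALSE,
                     is_exchange = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || length(stoichiometry) == 0L ||
      is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a nonempty named numeric vector")
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  }
  if (!is.list(gene_association) ||
      !all(vapply(gene_association, is.character, logical(1)))) {
    stop("reaction '", id, "': gene_association must be a list of character vectors")
  }
  structure(list(id = id,
                 stoichiometry = stoichiometry[order(names(stoichiometry))],
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gene_association = gene_association,
                 gapfilled = isTRUE(gapfilled),
                 is_exchange = isTRUE(is_exchange)),
            class = "gd_reaction")
}

#' Assemble a stoichiometric model
#'
#' @param genome_id genome the model was built for.
#' @param metabolites data frame with columns `id`, `name`, `compartment`
#'   (rows may come from [metabolite()]).
#' @param reactions list of [reaction()] objects.
#' @param biomass_reaction_id id of the biomass (objective) reaction.
#' @param validate check model invariants and stop on violation.
#' @return a list of class `gd_model`; metabolites and reactions are kept
#'   in canonical (lexicographic id) order.
#' @export
stoichiometric_model <- function(genome_id, metabolites, reactions,
                                 biomass_reaction_id, validate = TRUE) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "name", "compartment") %in% names(metabolites)))
  metabolites <- metabolites[order(metabolites$id),
                             c("id", "name", "compartment"), drop = FALSE]
  rownames(metabolites) <- NULL
  ids <- vapply(reactions, `[[`, character(1), "id")
  reactions <- reactions[order(ids)]
  names(reactions) <- sort(ids)
  model <- structure(list(genome_id = genome_id,
                          metabolites = metabolites,
                          reactions = reactions,
                          biomass_reaction_id = biomass_reaction_id),
                     class = "gd_model")
  if (validate) {
    v <- validate_model(model)
    if (length(v)) stop("invalid model: ", paste(v, collapse = "; "))
  }
  model
}

#' Validate a stoichiometric model
#'
#' Checks every model invariant and returns a character vector of
#' violations (empty when the model is valid): unique ids, known
#' compartments, bound ordering, nonempty stoichiometries, metabolites
#' referenced by reactions all declared, exchange reactions touching
#' exactly one extracellular metabolite, gapfilled reactions carrying no
#' gene association, and a present biomass reaction.
#'
#' @param model a `gd_model`.
#' @return character vector of violation descriptions, each naming the
#'   offending entity.
#' @export
validate_model <- function(model) {
  out <- character(0)
  met <- model$metabolites
  if (anyDuplicated(met$id)) {
    out <- c(out, paste0("duplicated metabolite id: ",
                         paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  }
  bad_comp <- setdiff(unique(met$compartment), COMPARTMENTS)
  if (length(bad_comp)) {
    out <- c(out, paste0("unknown compartment: ", paste(bad_comp, collapse = ", ")))
  }
  ids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    out <- c(out, paste0("duplicated reaction id: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound) {
      out <- c(out, paste0("reaction ", r$id, ": lower_bound > upper_bound"))
    }
    if (length(r$stoichiometry) == 0L) {
      out <- c(out, paste0("reaction ", r$id, ": empty stoichiometry"))
    }
    missing_met <- setdiff(names(r$stoichiometry), met$id)
    if (length(missing_met)) {
      out <- c(out, paste0("reaction ", r$id, ": unknown metabolite ",
                           paste(missing_met, collapse = ", ")))
    }
    if (r$gapfilled && length(r$gene_association)) {
      out <- c(out, paste0("reaction ", r$id,
                           ": gapfilled reaction has a gene association"))
    }
    if (r$is_exchange) {
      touched <- names(r$stoichiometry)
      extl <- touched[touched %in% met$id[met$compartment == "extracellular"]]
      if (length(r$stoichiometry) != 1L || length(extl) != 1L) {
        out <- c(out, paste0("reaction ", r$id,
                             ": exchange must touch exactly one extracellular metabolite"))
      }
    }
  }
  if (!model$biomass_reaction_id %in% ids) {
    out <- c(out, paste0("biomass reaction ", model$biomass_reaction_id,
                         " not present"))
  }
  out
}

#' Stoichiometric matrix of a model
#'
#' @param model a `gd_model`.
#' @return dense numeric matrix S (metabolites x reactions), rows and
#'   columns named and in canonical order.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in model$reactions) {
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  }
  S
}

#' Create a genome annotation
#'
#' @param genome_id genome id.
#' @param genes data frame with columns `gene_id` and `role` (one row per
#'   gene; gene ids unique within the genome).
#' @return a list of class `gd_annotation`.
#' @export
genome_annotation <- function(genome_id, genes) {
  stopifnot(is.data.frame(genes), all(c("gene_id", "role") %in% names(genes)))
  genes <- genes[, c("gene_id", "role"), drop = FALSE]
  if (anyDuplicated(genes$gene_id)) {
    stop("genome ", genome_id, ": duplicated gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, genes = genes),
            class = "gd_annotation")
}

#' Create a universal reaction database
#'
#' @param metabolites data frame of all metabolites usable by templates.
#' @param reactions list of template [reaction()]s (no gene associations).
#' @param role_map named list mapping functional roles to character
#'   vectors of reaction ids.
#' @param transportable character vector of extracellular metabolite ids
#'   that transporters can move into the cell (the complete medium).
#' @param biomass_reaction_id id of the biomass template reaction.
#' @return a list of class `gd_universe`.
#' @export
universal_database <- function(metabolites, reactions, role_map,
                               transportable, biomass_reaction_id) {
  ids <- vapply(reactions, `[[`, character(1), "id")
  reactions <- reactions[order(ids)]
  names(reactions) <- sort(ids)
  metabolites <- metabolites[order(metabolites$id), , drop = FALSE]
  rownames(metabolites) <- NULL
  bad <- setdiff(unlist(role_map, use.names = FALSE), names(reactions))
  if (length(bad)) {
    stop("role_map targets missing from database: ", paste(bad, collapse = ", "))
  }
  extl <- metabolites$id[metabolites$compartment == "extracellular"]
  if (length(setdiff(transportable, extl))) {
    stop("transportable metabolites must be extracellular: ",
         paste(setdiff(transportable, extl), collapse = ", "))
  }
  if (!biomass_reaction_id %in% names(reactions)) {
    stop("biomass template ", biomass_reaction_id, " missing from database")
  }
  structure(list(metabolites = metabolites,
                 reactions = reactions,
                 role_map = if (length(role_map)) {
                   role_map[order(names(role_map))]
                 } else list(),
                 transportable = sort(transportable),
                 biomass_reaction_id = biomass_reaction_id),
            class = "gd_universe")
}

#' Create a growth medium
#'
#' @param nutrients character vector of extracellular metabolite ids.
#' @param uptake_limit maximum uptake flux per nutrient (must be > 0).
#' @return a list of class `gd_medium`.
#' @export
medium <- function(nutrients = character(0), uptake_limit = 10) {
  stopifnot(uptake_limit > 0)
  structure(list(nutrients = sort(unique(as.character(nutrients))),
                 uptake_limit = as.numeric(uptake_limit)),
            class = "gd_medium")
}

#' Complete medium of a model or database
#'
#' Every transportable (exchangeable) metabolite at the given uptake limit.
#'
#' @param x a `gd_model` (nutrients are the metabolites with exchange
#'   reactions) or `gd_universe` (the transportable set).
#' @param uptake_limit maximum uptake flux per nutrient.
#' @return a `gd_medium`.
#' @export
complete_medium <- function(x, uptake_limit = 10) {
  medium(exchangeable_nutrients(x), uptake_limit)
}

exchangeable_nutrients <- function(x) {
  if (inherits(x, "gd_universe")) return(x$transportable)
  stopifnot(inherits(x, "gd_model"))
  ex <- Filter(function(r) r$is_exchange, x$reactions)
  sort(unique(vapply(ex, function(r) names(r$stoichiometry), character(1))))
}

## id of the exchange reaction for a nutrient (canonical naming)
exchange_id <- function(nutrient) paste0("EX_", nutrient)

make_exchange_reaction <- function(nutrient) {
  st <- stats::setNames(-1, nutrient)
  reaction(exchange_id(nutrient), st, lower_bound = 0,
           upper_bound = DEFAULT_FLUX_BOUND, is_exchange = TRUE)
}

#' Build a draft model from a genome annotation
#'
#' Instantiates every database reaction whose functional role occurs in
#' the annotation, filling the gene association with the annotated genes
#' (genes sharing a role become alternative isoenzymes, i.e. a
#' disjunction), then adds exchange reactions for all transportable
#' metabolites and the database biomass template.  Annotation roles
#' absent from the role map are skipped with a warning.  The result is
#' deterministic: reactions and metabolites are in canonical order.
#'
#' @param annotation a `gd_annotation`.
#' @param db a `gd_universe`.
#' @return a `gd_model`.
#' @export
build_model_from_annotation <- function(annotation, db) {
  stopifnot(inherits(annotation, "gd_annotation"), inherits(db, "gd_universe"))
  roles <- unique(annotation$genes$role)
  unknown <- setdiff(roles, names(db$role_map))
  if (length(unknown)) {
    warning("genome ", annotation$genome_id, ": roles without reactions: ",
            paste(sort(unknown), collapse = ", "))
  }
  ## reaction id -> genes catalyzing it (via any of their roles)
  rxn_genes <- list()
  for (role in intersect(roles, names(db$role_map))) {
    genes <- annotation$genes$gene_id[annotation$genes$role == role]
    for (rid in db$role_map[[role]]) {
      rxn_genes[[rid]] <- sort(unique(c(rxn_genes[[rid]], genes)))
    }
  }
  rxns <- list()
  for (rid in sort(names(rxn_genes))) {
    tmpl <- db$reactions[[rid]]
    tmpl$gene_association <- lapply(rxn_genes[[rid]], function(g) g)
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
  stoichiometric_model(annotation$genome_id, mets, unname(rxns),
                       db$biomass_reaction_id)
}

## does the reaction have a (non-gapfilled) gene association?
is_gene_associated <- function(r) length(r$gene_association) > 0L && !r$gapfilled

#' Gene-associated reactions of a model
#'
#' Ids of reactions carrying a gene association and not flagged
#' gapfilled; the currency of all comparative analyses.
#'
#' @param model a `gd_model`.
#' @return character vector of reaction ids.
#' @export
gene_associated_ids <- function(model) {
  names(Filter(is_gene_associated, model$reactions))
}

#' @export
print.gd_model <- function(x, ...) {
  ng <- length(gene_associated_ids(x))
  ngap <- sum(vapply(x$reactions, `[[`, logical(1), "gapfilled"))
  cat("Stoichiometric model of genome '", x$genome_id, "'\n", sep = "")
  cat("  ", nrow(x$metabolites), " metabolites, ", length(x$reactions),
      " reactions (", ng, " gene-associated, ", ngap, " gapfilled)\n", sep = "")
  cat("  biomass: ", x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}

#' @export
print.gd_universe <- function(x, ...) {
  cat("Universal reaction database: ", length(x$reactions), " reactions, ",
      length(x$role_map), " roles, ", length(x$transportable),
      " transportable nutrients\n", sep = "")
  invisible(x)
}

#' @export
print.gd_medium <- function(x, ...) {
  cat("Medium (uptake limit ", x$uptake_limit, "): ",
      if (length(x$nutrients)) paste(x$nutrients, collapse = ", ") else "(empty)",
      "\n", sep = "")
  invisible(x)
}
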