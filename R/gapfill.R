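## Gapfilling: add a minimum-cardinality set of universal-database
## reactions so that a draft model produces biomass on the complete
## medium.  Among cardinality-optimal solutions the algorithm prefers,
## as a second lexicographic stage, additions that let the largest
## number of gene-associated model reactions carry flux; remaining ties
## fall to the lexicographically smallest added-id set.

#' Gapfill a model against a universal database
#'
#' Stage 1 finds the minimum number of database reactions whose addition
#' restores biomass production at the growth floor (exact
#' branch-and-bound over addition indicators, one LP per probe).  Stage
#' 2 enumerates all cardinality-optimal addition sets and keeps the one
#' maximizing the count of gene-associated model reactions able to carry
#' flux (checked by flux variability on the augmented model); this
#' mirrors automated reconstruction pipelines that favor additions
#' unblocking annotated reactions.  Added reactions are flagged
#' `gapfilled` and carry no gene association.
#'
#' @param model a `gd_model` (possibly unable to grow).
#' @param db a `gd_universe` supplying candidate reactions.
#' @param uptake_limit uptake cap of the complete medium.
#' @param growth_floor biomass flux the gapfilled model must attain;
#'   default 0.1 x the maximum biomass of the fully augmented model.
#' @param max_enumerate stage-2 guard: skip the secondary objective when
#'   more than this many candidate sets would need scoring.
#' @return list of class `gd_gapfill`: `added_reaction_ids`,
#'   `objective_cost` (number added), `grows_after`, and the scored
#'   `unblocked_count` when stage 2 ran.
#' @export
gapfill <- function(model, db, uptake_limit = 10, growth_floor = NULL,
                    max_enumerate = 5000) {
  stopifnot(inherits(model, "gd_model"), inherits(db, "gd_universe"))
  candidates <- setdiff(names(db$reactions),
                        c(names(model$reactions), db$biomass_reaction_id))
  full_model <- augment_model(model, db, candidates)
  full_medium <- complete_medium(db, uptake_limit)
  vmax_full <- maximize_biomass(full_model, full_medium)
  if (vmax_full$status != "optimal" || vmax_full$objective_value <= FEAS_TOL) {
    stop("universe insufficient: no biomass even with every database reaction")
  }
  if (is.null(growth_floor)) growth_floor <- 0.1 * vmax_full$objective_value
  tol <- FEAS_TOL * max(1, growth_floor)
  feasible <- function(added) {
    m2 <- augment_model(model, db, added)
    st <- maximize_biomass(m2, full_medium)
    st$status == "optimal" && st$objective_value >= growth_floor - tol
  }
  sol <- min_feasible_subset(candidates, feasible)
  if (is.null(sol)) stop("universe insufficient for gapfilling")
  added <- sol$subset
  unblocked <- NA_integer_
  if (sol$size > 0L) {
    all_min <- enumerate_feasible_subsets(candidates, feasible, sol$size)
    if (length(all_min) > 1L && length(all_min) <= max_enumerate) {
      scores <- vapply(all_min, function(s) {
        count_unblocked(augment_model(model, db, s), full_medium, growth_floor)
      }, integer(1))
      best <- max(scores)
      added <- all_min[[which(scores == best)[1]]]   # lists are in lex order
      unblocked <- best
    } else if (length(all_min) == 1L) {
      unblocked <- count_unblocked(augment_model(model, db, added),
                                   full_medium, growth_floor)
    }
  }
  structure(list(added_reaction_ids = sort(added),
                 objective_cost = sol$size,
                 grows_after = TRUE,
                 unblocked_count = unblocked),
            class = "gd_gapfill")
}

## number of gene-associated reactions that can carry flux somewhere in
## the feasible space (biomass held at the growth floor)
count_unblocked <- function(model, medium, growth_floor) {
  ids <- gene_associated_ids(model)
  if (!length(ids)) return(0L)
  fva <- flux_variability(model, medium, growth_floor = growth_floor)
  sum(fva[ids, "max"] > 1e-6 | fva[ids, "min"] < -1e-6)
}

## add database reactions (flagged gapfilled) and their metabolites
augment_model <- function(model, db, reaction_ids) {
  if (!length(reaction_ids)) return(model)
  rxns <- model$reactions
  for (rid in reaction_ids) {
    tmpl <- db$reactions[[rid]]
    if (is.null(tmpl)) stop("reaction ", rid, " not in database")
    tmpl$gene_association <- list()
    tmpl$gapfilled <- TRUE
    rxns[[rid]] <- tmpl
  }
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  mets <- db$metabolites[db$metabolites$id %in% used, , drop = FALSE]
  extra <- setdiff(model$metabolites$id, mets$id)
  mets <- rbind(mets, model$metabolites[model$metabolites$id %in% extra, ,
                                        drop = FALSE])
  stoichiometric_model(model$genome_id, mets, unname(rxns),
                       model$biomass_reaction_id)
}

#' Apply a gapfill solution to a model
#'
#' @param model the draft `gd_model`.
#' @param db the `gd_universe` the solution was computed against.
#' @param solution a `gd_gapfill`.
#' @return the augmented `gd_model`; added reactions are flagged
#'   `gapfilled = TRUE` with empty gene associations.
#' @export
apply_gapfill <- function(model, db, solution) {
  augment_model(model, db, solution$added_reaction_ids)
}

#' Verify that a gapfill solution is minimal
#'
#' Exhaustively confirms that no strict subset of the solution restores
#' growth, and (for solutions of at most 3 reactions) that no smaller
#' database subset does either.  Refuses solutions larger than 6
#' reactions to keep the check tractable.
#'
#' @inheritParams gapfill
#' @param solution a `gd_gapfill`.
#' @return `TRUE` if the solution is minimal.
#' @export
verify_minimality <- function(model, db, solution, uptake_limit = 10,
                              growth_floor = NULL) {
  added <- solution$added_reaction_ids
  if (length(added) > 6L) {
    stop("refusing exhaustive minimality check for |solution| > 6")
  }
  full_medium <- complete_medium(db, uptake_limit)
  if (is.null(growth_floor)) {
    candidates <- setdiff(names(db$reactions),
                          c(names(model$reactions), db$biomass_reaction_id))
    vfull <- maximize_biomass(augment_model(model, db, candidates), full_medium)
    growth_floor <- 0.1 * vfull$objective_value
  }
  tol <- FEAS_TOL * max(1, growth_floor)
  grows <- function(set) {
    st <- maximize_biomass(augment_model(model, db, set), full_medium)
    st$status == "optimal" && st$objective_value >= growth_floor - tol
  }
  if (!grows(added)) return(FALSE)
  if (length(added)) {
    for (k in 0:(length(added) - 1L)) {
      subs <- if (k == 0) list(character(0)) else
        utils::combn(added, k, simplify = FALSE)
      for (s in subs) if (grows(s)) return(FALSE)
    }
  }
  if (length(added) >= 1L && length(added) <= 3L) {
    candidates <- setdiff(names(db$reactions),
                          c(names(model$reactions), db$biomass_reaction_id))
    for (k in 0:(length(added) - 1L)) {
      subs <- if (k == 0) list(character(0)) else
        utils::combn(candidates, k, simplify = FALSE)
      for (s in subs) if (grows(s)) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.gd_gapfill <- function(x, ...) {
  cat("Gapfill solution: ", x$objective_cost, " reaction(s) added",
      if (length(x$added_reaction_ids))
        paste0(" [", paste(x$added_reaction_ids, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}
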