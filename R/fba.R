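## Flux balance analysis: the six-step procedure used to characterize
## each genome's metabolism.
##   (i)   require a nonzero biomass flux (the growth floor),
##   (ii)  minimize the number of active exchanges -> minimal medium,
##   (iii) allow only the minimal exchanges to function,
##   (iv)  minimize and maximize every reaction flux (FVA),
##   (v)   maximize biomass on the minimal medium and fix it,
##   (vi)  minimize total flux (parsimonious FBA).
## Reactions are then classified from their FVA ranges: strictly signed
## ranges are essential, all-zero ranges nonfunctional, mixed functional.

FEAS_TOL <- 1e-7

flux_state <- function(fluxes, objective_value, status) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status),
            class = "gd_flux_state")
}

## lower/upper bound vectors for a model under a medium.  Exchange uptake
## (negative flux) is permitted only for medium nutrients; secretion is
## always allowed.  `fixed` is a named list of c(lb, ub) overrides.
fba_bounds <- function(model, medium, fixed = NULL) {
  rxns <- model$reactions
  lb <- vapply(rxns, `[[`, numeric(1), "lower_bound")
  ub <- vapply(rxns, `[[`, numeric(1), "upper_bound")
  for (r in rxns) {
    if (r$is_exchange) {
      nutrient <- names(r$stoichiometry)
      lb[r$id] <- if (nutrient %in% medium$nutrients) -medium$uptake_limit else 0
    }
  }
  for (id in names(fixed)) {
    if (!id %in% names(lb)) stop("fixed constraint on unknown reaction ", id)
    lb[id] <- fixed[[id]][1]; ub[id] <- fixed[[id]][2]
  }
  list(lb = lb, ub = ub)
}

## solve one FBA LP; objective is a named sparse coefficient vector
fba_lp <- function(model, medium, objective, maximize = TRUE, fixed = NULL) {
  S <- stoich_matrix(model)
  bd <- fba_bounds(model, medium, fixed)
  obj <- stats::setNames(numeric(ncol(S)), colnames(S))
  obj[names(objective)] <- objective
  res <- lp_solve(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, maximize = maximize)
  if (res$status == "optimal") {
    names(res$x) <- colnames(S)
    ## a flux pinned at the internal big bound signals a missing exchange
    ## constraint (an unbounded direction in the intended problem)
    declared_inf <- !is.finite(bd$lb) | !is.finite(bd$ub)
    if (any(declared_inf & abs(res$x) >= 0.99 * LP_BIG)) {
      stop("unbounded flux problem (missing exchange constraint?)")
    }
  }
  res
}

#' Maximize biomass flux on a medium
#'
#' @param model a `gd_model`.
#' @param medium a `gd_medium`; uptake of its nutrients is allowed up to
#'   the medium's uptake limit, all other uptake is shut.
#' @param fixed optional named list of `c(lb, ub)` flux overrides.
#' @return a `gd_flux_state` with `status` `"optimal"` or `"infeasible"`;
#'   when optimal, `fluxes` satisfy the steady-state constraint within
#'   `1e-7` and `objective_value` is the biomass flux.
#' @export
maximize_biomass <- function(model, medium, fixed = NULL) {
  res <- fba_lp(model, medium,
                stats::setNames(1, model$biomass_reaction_id),
                maximize = TRUE, fixed = fixed)
  if (res$status != "optimal") {
    return(flux_state(stats::setNames(rep(NA_real_, length(model$reactions)),
                                      names(model$reactions)),
                      NA_real_, "infeasible"))
  }
  flux_state(res$x, res$value, "optimal")
}

#' Predict the minimal medium of a model
#'
#' Finds a provably minimum-cardinality set of external nutrients whose
#' uptake permits biomass flux of at least `growth_floor`, by exact
#' branch-and-bound over binary uptake indicators with one linear
#' program per feasibility probe.  Ties among minimum-cardinality media
#' are broken toward the lexicographically smallest sorted nutrient-id
#' set, making predictions deterministic.  A greedy alternative (strip
#' nutrients from the complete medium, largest id first) is available
#' but is not guaranteed minimal.
#'
#' @param model a `gd_model`.
#' @param growth_floor minimum biomass flux that must remain attainable;
#'   default is 0.1 x the maximum biomass on the complete medium.
#' @param uptake_limit per-nutrient uptake cap.
#' @param method `"exact"` (default) or `"greedy"`.
#' @return list of class `gd_medium_prediction`: `medium`, the maximum
#'   `achieved_biomass` on it, and the `growth_floor` used.
#' @export
find_minimal_media <- function(model, growth_floor = NULL, uptake_limit = 10,
                               method = c("exact", "greedy")) {
  method <- match.arg(method)
  full <- complete_medium(model, uptake_limit)
  vmax <- maximize_biomass(model, full)
  if (vmax$status != "optimal" || vmax$objective_value <= FEAS_TOL) {
    stop("auxotrophic for biomass under complete medium (no growth); ",
         "model is a gapfilling candidate")
  }
  if (is.null(growth_floor)) growth_floor <- 0.1 * vmax$objective_value
  if (vmax$objective_value < growth_floor - FEAS_TOL) {
    stop("auxotrophic for biomass under complete medium at growth floor ",
         growth_floor)
  }
  tol <- FEAS_TOL * max(1, growth_floor)
  feasible <- function(nutrients) {
    st <- maximize_biomass(model, medium(nutrients, uptake_limit))
    st$status == "optimal" && st$objective_value >= growth_floor - tol
  }
  if (method == "greedy") {
    keep <- full$nutrients
    for (id in rev(sort(keep))) {
      trial <- setdiff(keep, id)
      if (feasible(trial)) keep <- trial
    }
    sol <- list(subset = keep, size = length(keep))
  } else {
    sol <- min_feasible_subset(full$nutrients, feasible)
  }
  med <- medium(sol$subset, uptake_limit)
  structure(list(medium = med,
                 achieved_biomass = maximize_biomass(model, med)$objective_value,
                 growth_floor = growth_floor),
            class = "gd_medium_prediction")
}

#' Flux variability analysis
#'
#' Minimizes and maximizes each reaction flux subject to steady state,
#' bounds, the medium, a biomass floor and any fixed flux intervals.
#'
#' @param model a `gd_model`.
#' @param medium a `gd_medium` (typically the predicted minimal medium).
#' @param growth_floor biomass flux required throughout; default 0.1 x
#'   the maximum biomass on `medium`.
#' @param fixed named list of `c(lb, ub)` flux intervals to impose.
#' @param biomass_at `"floor"` constrains biomass >= growth_floor during
#'   scanning (default); `"max"` pins it at its maximum instead.
#' @return numeric matrix, one row per reaction, columns `min` and `max`.
#' @export
flux_variability <- function(model, medium, growth_floor = NULL,
                             fixed = NULL, biomass_at = c("floor", "max")) {
  biomass_at <- match.arg(biomass_at)
  vmax <- maximize_biomass(model, medium, fixed = fixed)
  if (vmax$status != "optimal") stop("infeasible base problem for FVA")
  if (is.null(growth_floor)) growth_floor <- 0.1 * vmax$objective_value
  if (vmax$objective_value < growth_floor - FEAS_TOL) {
    stop("infeasible base problem for FVA: biomass floor unattainable")
  }
  bio <- model$biomass_reaction_id
  slack <- FEAS_TOL * max(1, abs(vmax$objective_value))
  fixed2 <- fixed
  fixed2[[bio]] <- if (biomass_at == "max") {
    c(vmax$objective_value - slack, model$reactions[[bio]]$upper_bound)
  } else {
    c(growth_floor - slack, model$reactions[[bio]]$upper_bound)
  }
  ids <- names(model$reactions)
  out <- matrix(NA_real_, length(ids), 2, dimnames = list(ids, c("min", "max")))
  for (id in ids) {
    for (sense in c(FALSE, TRUE)) {
      res <- fba_lp(model, medium, stats::setNames(1, id),
                    maximize = sense, fixed = fixed2)
      if (res$status != "optimal") stop("FVA subproblem infeasible for ", id)
      out[id, if (sense) "max" else "min"] <- res$value
    }
  }
  out
}

#' Classify reactions from FVA ranges
#'
#' Reactions whose attainable fluxes are strictly positive or strictly
#' negative are *essential*; reactions that can only carry zero flux are
#' *nonfunctional*; reactions with both zero and nonzero attainable flux
#' are *functional*.
#'
#' @param fva_ranges matrix from [flux_variability()].
#' @param epsilon zero-flux tolerance in model flux units.
#' @return named character vector with values `"essential"`,
#'   `"functional"` or `"nonfunctional"`.
#' @export
classify_reactions <- function(fva_ranges, epsilon = 1e-6) {
  lo <- fva_ranges[, "min"]; hi <- fva_ranges[, "max"]
  cls <- ifelse(lo > epsilon | hi < -epsilon, "essential",
                ifelse(abs(lo) <= epsilon & abs(hi) <= epsilon,
                       "nonfunctional", "functional"))
  stats::setNames(as.character(cls), rownames(fva_ranges))
}

#' Parsimonious flux distribution
#'
#' Fixes biomass at its maximum on the medium, then minimizes the sum of
#' absolute fluxes (via the standard split into forward and reverse
#' parts), yielding the simplest flux profile: futile cycles carry zero
#' flux because they add cost without enabling biomass.
#'
#' @param model a `gd_model`.
#' @param medium a `gd_medium`.
#' @return a `gd_flux_state`; `objective_value` is the (maximal) biomass
#'   flux and attribute `"total_flux"` holds the minimized sum of
#'   absolute fluxes.
#' @export
parsimonious_flux <- function(model, medium) {
  vmax <- maximize_biomass(model, medium)
  if (vmax$status != "optimal") stop("infeasible problem for parsimonious FBA")
  S <- stoich_matrix(model)
  bd <- fba_bounds(model, medium)
  bio <- model$biomass_reaction_id
  slack <- FEAS_TOL * max(1, abs(vmax$objective_value))
  bd$lb[bio] <- vmax$objective_value - slack
  bd$ub[bio] <- vmax$objective_value + slack
  ## v = p - n with p, n >= 0; min sum(p + n) = min sum(|v|)
  n <- ncol(S)
  A <- cbind(S, -S)
  lbs <- c(pmax(0, bd$lb), pmax(0, -bd$ub))
  ubs <- c(pmax(0, bd$ub), pmax(0, -bd$lb))
  res <- lp_solve(rep(1, 2 * n), A, rep(0, nrow(S)), lbs, ubs,
                  maximize = FALSE)
  if (res$status != "optimal") stop("infeasible problem for parsimonious FBA")
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- colnames(S)
  st <- flux_state(v, v[[bio]], "optimal")
  attr(st, "total_flux") <- res$value
  st
}

#' Run the full six-step analysis of a model
#'
#' Executes, in order: growth test on the complete medium, minimal-medium
#' prediction, restriction of exchanges to the minimal medium, flux
#' variability analysis, biomass maximization, and parsimonious flux
#' minimization; reactions are classified from the FVA ranges.
#'
#' @param model a `gd_model`.
#' @param uptake_limit per-nutrient uptake cap.
#' @param growth_floor_frac the growth floor as a fraction of the maximum
#'   biomass on the complete medium (the procedure only requires the
#'   floor to be nonzero; a fraction of the maximum keeps it scale-free).
#' @param epsilon zero-flux tolerance used for classification.
#' @param biomass_at biomass constraint during FVA, `"floor"` or `"max"`.
#' @return a `gd_analysis`: genome id, growth flag, minimal medium
#'   prediction, per-reaction classes, FVA ranges and the parsimonious
#'   flux state.
#' @export
six_step_analysis <- function(model, uptake_limit = 10,
                              growth_floor_frac = 0.1, epsilon = 1e-6,
                              biomass_at = c("floor", "max")) {
  biomass_at <- match.arg(biomass_at)
  step <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop("six-step analysis, step ", label, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  full <- complete_medium(model, uptake_limit)
  vmax_full <- step("(i)", maximize_biomass(model, full))
  grows <- vmax_full$status == "optimal" &&
    vmax_full$objective_value > FEAS_TOL
  floor_val <- if (grows) growth_floor_frac * vmax_full$objective_value else NA
  mm <- step("(ii)", find_minimal_media(model, growth_floor = floor_val,
                                        uptake_limit = uptake_limit))
  fva <- step("(iii-iv)",
              flux_variability(model, mm$medium, growth_floor = floor_val,
                               biomass_at = biomass_at))
  classes <- classify_reactions(fva, epsilon)
  pfba <- step("(v-vi)", parsimonious_flux(model, mm$medium))
  structure(list(genome_id = model$genome_id,
                 grows_on_complete = grows,
                 max_biomass_complete = vmax_full$objective_value,
                 growth_floor = floor_val,
                 minimal_medium = mm,
                 classes = classes,
                 fva_ranges = fva,
                 parsimonious = pfba),
            class = "gd_analysis")
}

#' @export
print.gd_analysis <- function(x, ...) {
  cat("Six-step FBA analysis of '", x$genome_id, "'\n", sep = "")
  cat("  max biomass (complete medium): ",
      format(x$max_biomass_complete, digits = 6), "\n", sep = "")
  cat("  minimal medium (", length(x$minimal_medium$medium$nutrients),
      " nutrients): ",
      paste(x$minimal_medium$medium$nutrients, collapse = ", "), "\n", sep = "")
  print(table(x$classes))
  invisible(x)
}

#' Brute-force flux optimum by vertex enumeration
#'
#' Independent reference implementation used to verify the simplex-based
#' engine: enumerates all basic solutions of the flux polytope (every
#' choice of non-fixed variables pinned at a bound, solving the reduced
#' equality system) and returns the best feasible objective.  Exponential
#' in the reaction count; intended for networks of at most ~10 reactions.
#'
#' @param model a `gd_model` (small).
#' @param medium a `gd_medium`.
#' @param objective named coefficient vector; default biomass.
#' @param maximize direction.
#' @param fixed named list of `c(lb, ub)` overrides.
#' @return list with `feasible`, `value` and the optimal `fluxes`.
#' @export
brute_force_fba <- function(model, medium, objective = NULL, maximize = TRUE,
                            fixed = NULL) {
  S <- stoich_matrix(model)
  bd <- fba_bounds(model, medium, fixed)
  if (is.null(objective)) {
    objective <- stats::setNames(1, model$biomass_reaction_id)
  }
  obj <- stats::setNames(numeric(ncol(S)), colnames(S))
  obj[names(objective)] <- objective
  res <- brute_force_lp(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, maximize)
  if (res$feasible && !is.null(res$x)) names(res$x) <- colnames(S)
  list(feasible = res$feasible, value = res$value, fluxes = res$x)
}

## vertex enumeration on min/max c'x, Ax=b, lb<=x<=ub (rank-aware)
brute_force_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  q <- qr(t(A)); rk <- q$rank
  keep <- q$pivot[seq_len(rk)]
  Ar <- A[keep, , drop = FALSE]; br <- b[keep]
  m <- nrow(Ar); n <- ncol(A)
  best <- NULL; bestv <- if (maximize) -Inf else Inf; feas <- FALSE
  combos <- if (n == m) list(integer(0)) else
    utils::combn(n, n - m, simplify = FALSE)
  for (fix in combos) {
    free <- setdiff(seq_len(n), fix)
    grid <- if (length(fix)) {
      as.matrix(expand.grid(rep(list(1:2), length(fix))))
    } else matrix(0, 1, 0)
    for (gi in seq_len(nrow(grid))) {
      xf <- ifelse(grid[gi, ] == 1, lb[fix], ub[fix])
      Af <- Ar[, free, drop = FALSE]
      if (length(free)) {
        if (qr(Af)$rank < length(free)) next
        rhs <- br - if (length(fix)) Ar[, fix, drop = FALSE] %*% xf else 0 * br
        xr <- tryCatch(solve(Af, rhs), error = function(e) NULL)
        if (is.null(xr)) next
      } else xr <- numeric(0)
      x <- numeric(n); x[fix] <- xf; x[free] <- as.numeric(xr)
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      if (max(abs(A %*% x - b)) > 1e-6) next
      feas <- TRUE
      v <- sum(obj * x)
      better <- if (maximize) v > bestv + 1e-12 else v < bestv - 1e-12
      if (better) { bestv <- v; best <- x }
    }
  }
  list(feasible = feas, value = if (feas) bestv else NA_real_, x = best)
}

#' Brute-force minimal medium by exhaustive subset search
#'
#' Reference implementation for [find_minimal_media()]: scans nutrient
#' subsets in order of increasing cardinality (lexicographic within each
#' cardinality) and returns the first subset sustaining the growth
#' floor, checked with [brute_force_fba()].  Exponential; small models
#' only.
#'
#' @inheritParams find_minimal_media
#' @return list with `nutrients` and `size`, or `NULL` when even the
#'   complete medium fails.
#' @export
brute_force_minimal_media <- function(model, growth_floor = NULL,
                                      uptake_limit = 10) {
  nutrients <- exchangeable_nutrients(model)
  full <- brute_force_fba(model, medium(nutrients, uptake_limit))
  if (!full$feasible || full$value <= FEAS_TOL) return(NULL)
  if (is.null(growth_floor)) growth_floor <- 0.1 * full$value
  ok <- function(sub) {
    r <- brute_force_fba(model, medium(sub, uptake_limit))
    r$feasible && r$value >= growth_floor - FEAS_TOL * max(1, growth_floor)
  }
  for (k in 0:length(nutrients)) {
    subs <- if (k == 0) list(character(0)) else
      utils::combn(nutrients, k, simplify = FALSE)
    for (s in subs) if (ok(s)) return(list(nutrients = s, size = k))
  }
  NULL
}
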