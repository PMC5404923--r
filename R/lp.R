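## Dense bounded-variable two-phase revised simplex.
##
## All flux-balance computations in the package reduce to linear programs
## min/max c'x subject to A x = b and lb <= x <= ub.  Problems here are
## small (tens of variables) but systematically degenerate: the right-hand
## side of every mass-balance row is zero and stoichiometric matrices are
## frequently rank-deficient.  The solver therefore keeps artificial
## variables pinned at zero through phase 2 (so redundant rows never
## require a basis repair) and falls back to Bland's rule after a run of
## degenerate pivots to guarantee termination.

LP_BIG <- 1e6

#' Solve a bounded linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A %*% x = b` and
#' `lb <= x <= ub`, using a two-phase revised simplex with bounded
#' variables.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A dense constraint matrix (`m` x `n`); rows are equalities.
#' @param b right-hand side, length `m`.
#' @param lb,ub variable bounds; infinite entries are truncated at
#'   `+-1e6`, large enough for all flux problems in this package.
#' @param maximize maximize instead of minimize.
#' @param tol pivot tolerance.
#' @param max_iter pivot budget; exceeded only on pathological inputs.
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), solution `x` and objective `value`.
#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, b, lb, ub, maximize = FALSE,
                     tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  lb <- pmax(lb, -LP_BIG); ub <- pmin(ub, LP_BIG)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
  }
  ub <- pmax(ub, lb)
  cc <- if (maximize) -obj else obj
  if (is.null(max_iter)) max_iter <- 200L * (n + m) + 2000L

  ## augmented problem: structurals then m artificials
  x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)    # nonbasic start at bound nearest 0
  r <- as.numeric(b - A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(LP_BIG, m))
  nall <- n + m
  basis <- (n + 1L):nall
  at_upper <- ifelse(abs(lb) <= abs(ub), FALSE, TRUE)  # structural nonbasic status
  status_nb <- c(at_upper, rep(FALSE, m))              # TRUE = at upper bound
  xall <- c(x0, abs(r))

  phase_cost <- c(rep(0, n), rep(1, m))
  res1 <- simplex_core(Aall, b, phase_cost, lball, uball, basis, status_nb,
                       xall, tol, max_iter)
  if (res1$status == "iterlimit") stop("LP iteration limit reached (phase 1)")
  art_sum <- sum(res1$x[(n + 1L):nall])
  if (art_sum > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
  }
  ## pin artificials at zero for phase 2 (kept in basis if a row is redundant)
  uball[(n + 1L):nall] <- 0
  x2 <- res1$x; x2[(n + 1L):nall] <- 0
  res2 <- simplex_core(Aall, b, c(cc, rep(0, m)), lball, uball,
                       res1$basis, res1$status_nb, x2, tol, max_iter)
  if (res2$status == "iterlimit") stop("LP iteration limit reached (phase 2)")
  x <- res2$x[seq_len(n)]
  val <- sum(cc * x)
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), value = NA_real_))
  }
  list(status = "optimal", x = x, value = if (maximize) -val else val)
}

## One simplex phase.  `status_nb[j]` records, for nonbasic j, whether it
## sits at its upper bound.  Returns updated basis/state and status.
simplex_core <- function(A, b, cost, lb, ub, basis, status_nb, x, tol,
                         max_iter) {
  m <- nrow(A); nall <- ncol(A)
  degen_run <- 0L
  for (it in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    ## refresh basic values from the nonbasic assignment for numerical hygiene
    nb <- setdiff(seq_len(nall), basis)
    xB <- tryCatch(solve(B, b - A[, nb, drop = FALSE] %*% x[nb]),
                   error = function(e) NULL)
    if (is.null(xB)) stop("LP basis became singular")
    x[basis] <- as.numeric(xB)

    y <- solve(t(B), cost[basis])
    d <- cost[nb] - as.numeric(crossprod(y, A[, nb, drop = FALSE]))
    free <- ub[nb] - lb[nb] > tol            # fixed variables never enter
    incr <- d < -tol & !status_nb[nb] & free
    decr <- d >  tol &  status_nb[nb] & free
    cand <- which(incr | decr)
    if (!length(cand)) {
      return(list(status = "optimal", x = x, basis = basis,
                  status_nb = status_nb))
    }
    if (degen_run > 2L * m + 20L) {
      jj <- cand[which.min(nb[cand])]        # Bland: smallest index
    } else {
      jj <- cand[which.max(abs(d[cand]))]    # Dantzig
    }
    j <- nb[jj]
    s <- if (status_nb[j]) -1 else 1         # +1 entering rises from lb
    w <- as.numeric(solve(B, A[, j]))
    delta <- -s * w                          # basic change per unit t >= 0

    tmax <- ub[j] - lb[j]                    # bound flip distance
    block <- 0L                              # 0 = bound flip
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (delta[i] < -tol) {
        lim <- (x[bi] - lb[bi]) / (-delta[i])
        if (lim < tmax - tol) { tmax <- lim; block <- i }
      } else if (delta[i] > tol) {
        lim <- (ub[bi] - x[bi]) / delta[i]
        if (lim < tmax - tol) { tmax <- lim; block <- i }
      }
    }
    if (!is.finite(tmax)) tmax <- LP_BIG * 2
    if (tmax > LP_BIG) {
      return(list(status = "unbounded", x = x, basis = basis,
                  status_nb = status_nb))
    }
    tmax <- max(tmax, 0)
    degen_run <- if (tmax <= tol) degen_run + 1L else 0L

    x[basis] <- x[basis] + delta * tmax
    x[j] <- x[j] + s * tmax
    if (block == 0L) {
      status_nb[j] <- !status_nb[j]          # flipped to its other bound
    } else {
      leave <- basis[block]
      ## leaving variable lands on whichever of its bounds blocked
      status_nb[leave] <- delta[block] > 0
      x[leave] <- if (status_nb[leave]) ub[leave] else lb[leave]
      basis[block] <- j
    }
  }
  list(status = "iterlimit", x = x, basis = basis, status_nb = status_nb)
}

#' Lexicographically smallest minimum-cardinality feasible subset
#'
#' Exact branch-and-bound over a monotone feasibility oracle: if a set is
#' feasible, every superset is feasible.  Used for minimal-medium
#' prediction and gapfilling, where feasibility is one linear program.
#' Candidates are explored in lexicographic order at increasing
#' cardinality, so the first subset found is the minimum-cardinality
#' solution with the lexicographically smallest sorted id vector.
#'
#' @param candidates character vector of selectable ids.
#' @param feasible function(character) -> logical; must be monotone.
#' @return `NULL` when even the full candidate set is infeasible,
#'   otherwise list(subset, size).
#' @keywords internal
#' @noRd
min_feasible_subset <- function(candidates, feasible) {
  cand <- sort(unique(candidates))
  n <- length(cand)
  cache <- new.env(parent = emptyenv())
  feas <- function(s) {
    key <- paste0("k:", paste(s, collapse = "\r"))
    got <- cache[[key]]
    if (is.null(got)) {
      got <- isTRUE(feasible(s))
      cache[[key]] <- got
    }
    got
  }
  if (feas(character(0))) return(list(subset = character(0), size = 0L))
  if (n == 0L || !feas(cand)) return(NULL)

  ## greedy upper bound: strip ids from the full set, largest id first
  keep <- cand
  for (id in rev(cand)) {
    trial <- setdiff(keep, id)
    if (feas(trial)) keep <- trial
  }
  k_ub <- length(keep)

  search_k <- function(chosen, start, k) {
    if (length(chosen) == k) {
      if (feas(chosen)) return(chosen) else return(NULL)
    }
    need <- k - length(chosen)
    if (start > n - need + 1L) return(NULL)
    for (i in start:(n - need + 1L)) {
      ## monotone prune: nothing drawn from cand[i:n] can help if even the
      ## whole tail is infeasible together with what is already chosen
      if (!feas(c(chosen, cand[i:n]))) return(NULL)
      res <- search_k(c(chosen, cand[i]), i + 1L, k)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  for (k in seq_len(k_ub)) {
    res <- search_k(character(0), 1L, k)
    if (!is.null(res)) return(list(subset = res, size = k))
  }
  list(subset = keep, size = k_ub)
}

## All feasible subsets of size exactly k (monotone oracle), in
## lexicographic order.  Used to enumerate cardinality-optimal gapfill
## solutions for the secondary objective.
enumerate_feasible_subsets <- function(candidates, feasible, k) {
  cand <- sort(unique(candidates))
  n <- length(cand)
  out <- list()
  rec <- function(chosen, start) {
    if (length(chosen) == k) {
      if (isTRUE(feasible(chosen))) out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    need <- k - length(chosen)
    if (start > n - need + 1L) return(invisible())
    for (i in start:(n - need + 1L)) {
      if (!isTRUE(feasible(c(chosen, cand[i:n])))) return(invisible())
      rec(c(chosen, cand[i]), i + 1L)
    }
  }
  if (k == 0L) {
    if (isTRUE(feasible(character(0)))) out[[1L]] <- character(0)
  } else if (n >= k) {
    rec(character(0), 1L)
  }
  out
}
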