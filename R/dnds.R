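## Counting estimator of nonsynonymous and synonymous substitution
## rates (dN, dS) between codon sequences, with Jukes-Cantor multiple-
## hit correction, and per-clade summaries.  Conventions: synonymous
## site fractions are counted per codon position out of the three
## possible changes, with mutations that would create a stop codon
## counted as nonsynonymous; codons differing at several positions are
## averaged over all minimal mutational pathways, discarding pathways
## that pass through a stop codon (unless every pathway does).

## precomputed per-codon synonymous site counts and per-pair averaged
## (synonymous, nonsynonymous) difference counts, built once per session
ng86_tables <- function() {
  if (!is.null(.gd$ng86)) return(.gd$ng86)
  code <- codon_tables()
  sense <- code$codons[code$aa != "*"]
  nts <- c("A", "C", "G", "T")
  syn_sites <- stats::setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    s <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(cd, pos, pos))) {
        alt <- cd
        substr(alt, pos, pos) <- nt
        if (code$aa[[alt]] != "*" && code$aa[[alt]] == code$aa[[cd]]) {
          s <- s + 1 / 3
        }
      }
    }
    syn_sites[cd] <- s
  }
  n_pairs <- length(sense)
  Sd <- matrix(0, n_pairs, n_pairs, dimnames = list(sense, sense))
  Nd <- Sd
  for (i in seq_along(sense)) {
    for (j in seq_along(sense)) {
      if (i == j) next
      d <- ng86_pair_diffs(sense[i], sense[j])
      Sd[i, j] <- d[1]; Nd[i, j] <- d[2]
    }
  }
  .gd$ng86 <- list(syn_sites = syn_sites, Sd = Sd, Nd = Nd)
  .gd$ng86
}

## average (syn, nonsyn) step counts over minimal mutational pathways
## between two sense codons; pathways through stops are discarded when
## any stop-free pathway exists
ng86_pair_diffs <- function(a, b) {
  code <- codon_tables()
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  perms <- permutations_of(pos)
  walk <- function(order) {
    cur <- a; s <- 0; n <- 0; through_stop <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (code$aa[[nxt]] == "*") through_stop <- TRUE
      if (code$aa[[nxt]] == code$aa[[cur]] && code$aa[[nxt]] != "*" &&
          code$aa[[cur]] != "*") s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n, through_stop)
  }
  res <- vapply(perms, walk, numeric(3))
  valid <- res[3, ] == 0
  if (any(valid)) res <- res[, valid, drop = FALSE]
  c(mean(res[1, ]), mean(res[2, ]))
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

## Jukes-Cantor distance; NA at or beyond saturation
jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS by the counting method
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (averaged over all minimal mutational
#' pathways per codon), applies the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)` to both proportions, and reports
#' `omega = dN / dS`.  Codon columns containing a gap or an ambiguous
#' base in either sequence are dropped pairwise.
#'
#' @param a,b codon sequences (strings, lengths equal and divisible by
#'   3), or a `gd_codon_alignment` of exactly two sequences as `a`.
#' @return list of class `gd_omega`: `dN`, `dS`, `omega` (`NA` when
#'   `dS` is 0 or a proportion is saturated), `n_pairs`, and the
#'   underlying site/difference counts.
#' @export
ng86_pairwise <- function(a, b = NULL) {
  if (inherits(a, "gd_codon_alignment")) {
    stopifnot(length(a$sequences) == 2L)
    b <- a$sequences[[2]]; a <- a$sequences[[1]]
  }
  if (nchar(a) != nchar(b)) stop("sequence length mismatch")
  ca <- split_codons(a); cb <- split_codons(b)
  tabs <- ng86_tables()
  code <- codon_tables()
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (any(ca %in% code$stops) || any(cb %in% code$stops)) {
    stop("internal stop codon in input sequence")
  }
  S <- (sum(tabs$syn_sites[ca]) + sum(tabs$syn_sites[cb])) / 2
  N <- 3 * length(ca) - S
  diff <- ca != cb
  Sd <- sum(tabs$Sd[cbind(ca[diff], cb[diff])])
  Nd <- sum(tabs$Nd[cbind(ca[diff], cb[diff])])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega, n_pairs = 1L,
                 S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, n_codons_used = length(ca)),
            class = "gd_omega")
}

#' Reference dN/dS implementation (direct enumeration)
#'
#' Recomputes the counting estimator without lookup tables, walking
#' every codon pair and every mutational pathway explicitly.  Serves as
#' an independent check of [ng86_pairwise()].
#'
#' @inheritParams ng86_pairwise
#' @return a `gd_omega`.
#' @export
ng86_reference <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequence length mismatch")
  code <- codon_tables()
  nts <- c("A", "C", "G", "T")
  ca <- split_codons(a); cb <- split_codons(b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (any(ca %in% code$stops) || any(cb %in% code$stops)) {
    stop("internal stop codon in input sequence")
  }
  count_syn <- function(cd) {
    s <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(cd, pos, pos))) {
        alt <- cd; substr(alt, pos, pos) <- nt
        if (code$aa[[alt]] != "*" && code$aa[[alt]] == code$aa[[cd]]) {
          s <- s + 1 / 3
        }
      }
    }
    s
  }
  S <- (sum(vapply(ca, count_syn, numeric(1))) +
          sum(vapply(cb, count_syn, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  ## enumerate mutational pathways recursively (independent of the
  ## table-building code used by ng86_pairwise)
  paths <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(list(c(0, 0, 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur; substr(nxt, p, p) <- substr(target, p, p)
      hit_stop <- code$aa[[nxt]] == "*"
      syn_step <- !hit_stop && code$aa[[cur]] != "*" &&
        code$aa[[nxt]] == code$aa[[cur]]
      for (tail in paths(nxt, target)) {
        out[[length(out) + 1L]] <- tail +
          c(as.numeric(syn_step), as.numeric(!syn_step), as.numeric(hit_stop))
      }
    }
    out
  }
  Sd <- 0; Nd <- 0
  for (k in seq_along(ca)) {
    if (ca[k] == cb[k]) next
    res <- do.call(rbind, paths(ca[k], cb[k]))
    ok <- res[, 3] == 0
    if (any(ok)) res <- res[ok, , drop = FALSE]
    Sd <- Sd + mean(res[, 1]); Nd <- Nd + mean(res[, 2])
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega, n_pairs = 1L,
                 S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, n_codons_used = length(ca)),
            class = "gd_omega")
}

#' Construct an omega estimate from rates
#'
#' Forms the dN/dS ratio from already-estimated substitution rates,
#' e.g. per-clade rates reported by an external analysis.
#'
#' @param dN,dS nonsynonymous and synonymous substitution rates.
#' @param n_pairs optional number of pairs behind the rates.
#' @return a `gd_omega`; `omega` is `NA` unless `dS > 0`.
#' @export
omega_estimate <- function(dN, dS, n_pairs = NA_integer_) {
  stopifnot(is.numeric(dN), is.numeric(dS), dN >= 0, dS >= 0)
  dN <- unname(dN); dS <- unname(dS)
  omega <- if (!is.na(dS) && dS > 0) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega,
                 n_pairs = as.integer(n_pairs)),
            class = "gd_omega")
}

#' Per-clade dN/dS summary
#'
#' Averages pairwise dN and dS over all within-clade sequence pairs and
#' reports their ratio.  Using the ratio of mean rates (rather than the
#' mean of ratios) keeps the estimate stable when individual pairs have
#' near-zero dS.  Pairs with a saturated (undefined) rate are dropped.
#'
#' @param alignment a `gd_codon_alignment`.
#' @param clade_leaves taxa forming the clade (at least 2 present in the
#'   alignment).
#' @return a `gd_omega` with `n_pairs` the number of usable pairs;
#'   `omega` is `NA` for clades of identical sequences (dS = 0).
#' @export
clade_omega <- function(alignment, clade_leaves) {
  stopifnot(inherits(alignment, "gd_codon_alignment"))
  leaves <- intersect(clade_leaves, names(alignment$sequences))
  if (length(leaves) < 2L) stop("clade needs at least 2 aligned taxa")
  prs <- utils::combn(sort(leaves), 2, simplify = FALSE)
  dNs <- numeric(0); dSs <- numeric(0)
  for (p in prs) {
    est <- ng86_pairwise(alignment$sequences[[p[1]]],
                         alignment$sequences[[p[2]]])
    if (!is.na(est$dN) && !is.na(est$dS)) {
      dNs <- c(dNs, est$dN); dSs <- c(dSs, est$dS)
    }
  }
  if (!length(dNs)) {
    return(structure(list(dN = NA_real_, dS = NA_real_, omega = NA_real_,
                          n_pairs = 0L),
                     class = "gd_omega"))
  }
  dN <- mean(dNs); dS <- mean(dSs)
  omega <- if (dS > 0) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega, n_pairs = length(dNs)),
            class = "gd_omega")
}

#' @export
print.gd_omega <- function(x, ...) {
  cat("dN/dS estimate: dN = ", format(x$dN, digits = 5),
      ", dS = ", format(x$dS, digits = 5),
      ", omega = ", format(x$omega, digits = 5),
      " (", x$n_pairs, " pair", if (x$n_pairs != 1) "s", ")\n", sep = "")
  invisible(x)
}
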