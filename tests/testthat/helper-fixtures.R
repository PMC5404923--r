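# Fixture networks built in code.  All are small enough for the
# brute-force vertex-enumeration and subset-search oracles.

met_e <- function(id) metabolite(id, compartment = "extracellular")

# linear chain: EX_A -> transport -> r1 -> biomass; throughput = uptake cap
chain_model <- function(genome_id = "chain") {
  stoichiometric_model(
    genome_id,
    rbind(met_e("A_e"), metabolite("A_c"), metabolite("P_c")),
    list(reaction("EX_A_e", c(A_e = -1), lower_bound = 0, is_exchange = TRUE),
         reaction("tA", c(A_e = -1, A_c = 1), gene_association = list("gT")),
         reaction("r1", c(A_c = -1, P_c = 1), gene_association = list("g1")),
         reaction("bio", c(P_c = -1))),
    "bio")
}

# two substitutable precursor routes to the same product (N1 fixture)
branched_model <- function(genome_id = "branched") {
  stoichiometric_model(
    genome_id,
    rbind(met_e("A_e"), met_e("B_e"), metabolite("A_c"), metabolite("B_c"),
          metabolite("P_c")),
    list(reaction("EX_A_e", c(A_e = -1), is_exchange = TRUE),
         reaction("EX_B_e", c(B_e = -1), is_exchange = TRUE),
         reaction("tA", c(A_e = -1, A_c = 1), gene_association = list("gTA")),
         reaction("tB", c(B_e = -1, B_c = 1), gene_association = list("gTB")),
         reaction("r1a", c(A_c = -1, P_c = 1), gene_association = list("g1a")),
         reaction("r1b", c(B_c = -1, P_c = 1), gene_association = list("g1b")),
         reaction("bio", c(P_c = -1))),
    "bio")
}

# biomass needs two precursors from two distinct nutrients
two_nutrient_model <- function() {
  stoichiometric_model(
    "two_nutrient",
    rbind(met_e("A_e"), met_e("B_e"), met_e("C_e"), metabolite("A_c"),
          metabolite("B_c"), metabolite("P1_c"), metabolite("P2_c")),
    list(reaction("EX_A_e", c(A_e = -1), is_exchange = TRUE),
         reaction("EX_B_e", c(B_e = -1), is_exchange = TRUE),
         reaction("EX_C_e", c(C_e = -1), is_exchange = TRUE),
         reaction("tA", c(A_e = -1, A_c = 1)),
         reaction("tB", c(B_e = -1, B_c = 1)),
         reaction("r1", c(A_c = -1, P1_c = 1)),
         reaction("r2", c(B_c = -1, P2_c = 1)),
         reaction("bio", c(P1_c = -1, P2_c = -1))),
    "bio")
}

# spontaneous source: biomass precursor appears without any uptake
spontaneous_model <- function() {
  stoichiometric_model(
    "spontaneous",
    rbind(met_e("A_e"), metabolite("P_c")),
    list(reaction("EX_A_e", c(A_e = -1), is_exchange = TRUE),
         reaction("src", c(P_c = 1)),
         reaction("bio", c(P_c = -1))),
    "bio")
}

# chain plus a 2-reaction futile loop off the growth path
loop_model <- function() {
  stoichiometric_model(
    "loop",
    rbind(met_e("A_e"), metabolite("A_c"), metabolite("P_c"),
          metabolite("X_c"), metabolite("Y_c")),
    list(reaction("EX_A_e", c(A_e = -1), is_exchange = TRUE),
         reaction("tA", c(A_e = -1, A_c = 1)),
         reaction("r1", c(A_c = -1, P_c = 1)),
         reaction("loop_f", c(X_c = -1, Y_c = 1),
                  lower_bound = -1000),
         reaction("loop_b", c(Y_c = -1, X_c = 1),
                  lower_bound = -1000),
         reaction("bio", c(P_c = -1))),
    "bio")
}

# small universe for gapfill tests: chain A -> M1 -> M2 -> biomass, a
# direct bypass, and a branch whose unblocking distinguishes candidates
gap_universe <- function() {
  mets <- rbind(met_e("A_e"), metabolite("A_c"), metabolite("M1_c"),
                metabolite("M2_c"), metabolite("Q_c"))
  rxns <- list(
    reaction("tA", c(A_e = -1, A_c = 1)),
    reaction("s1", c(A_c = -1, M1_c = 1)),
    reaction("s2", c(M1_c = -1, M2_c = 1)),
    reaction("alt_direct", c(A_c = -1, M2_c = 1)),
    reaction("q1", c(M1_c = -1, Q_c = 1)),
    reaction("q2", c(Q_c = -1, M2_c = 1)),
    reaction("bio", c(M2_c = -1)))
  universal_database(mets, rxns,
                     role_map = list(r_tA = "tA", r_s1 = "s1", r_s2 = "s2",
                                     r_q1 = "q1", r_q2 = "q2"),
                     transportable = "A_e",
                     biomass_reaction_id = "bio")
}

# random viable-ish network generator for the oracle battery; stays
# within 8 reactions so vertex enumeration remains exhaustive
random_network <- function(seed) {
  set.seed(seed)
  n_nut <- 2
  n_int <- sample(2:3, 1)
  nut_e <- paste0("N", seq_len(n_nut), "_e")
  int_c <- paste0("M", seq_len(n_int), "_c")
  mets <- do.call(rbind, c(lapply(nut_e, met_e), lapply(int_c, metabolite)))
  rxns <- list()
  for (i in seq_len(n_nut)) {
    rxns[[length(rxns) + 1L]] <-
      reaction(paste0("EX_", nut_e[i]), setNames(-1, nut_e[i]),
               is_exchange = TRUE)
    target <- sample(int_c, 1)
    rxns[[length(rxns) + 1L]] <-
      reaction(paste0("t", i), setNames(c(-1, 1), c(nut_e[i], target)),
               gene_association = list(paste0("gt", i)))
  }
  n_extra <- sample(1:3, 1)
  for (k in seq_len(n_extra)) {
    pair <- sample(int_c, 2)
    rev <- runif(1) < 0.3
    rxns[[length(rxns) + 1L]] <-
      reaction(paste0("r", k), setNames(c(-1, 1), pair),
               lower_bound = if (rev) -1000 else 0,
               gene_association = list(paste0("gr", k)))
  }
  bio_in <- sample(int_c, sample(1:2, 1))
  rxns[[length(rxns) + 1L]] <-
    reaction("bio", setNames(rep(-1, length(bio_in)), bio_in))
  stoichiometric_model(paste0("rand", seed), mets, rxns, "bio")
}

# oracle FVA: per-reaction min/max by vertex enumeration with the
# biomass floor imposed through a fixed interval
oracle_fva <- function(model, med, floor_val) {
  bio <- model$biomass_reaction_id
  ub_bio <- model$reactions[[bio]]$upper_bound
  fixed <- setNames(list(c(floor_val - 1e-7, ub_bio)), bio)
  ids <- names(model$reactions)
  out <- matrix(NA_real_, length(ids), 2,
                dimnames = list(ids, c("min", "max")))
  for (id in ids) {
    for (mx in c(FALSE, TRUE)) {
      r <- brute_force_fba(model, med, objective = setNames(1, id),
                           maximize = mx, fixed = fixed)
      out[id, if (mx) "max" else "min"] <- r$value
    }
  }
  out
}

# exhaustive gapfill oracle: smallest database subset restoring growth,
# lexicographically first within each cardinality
oracle_gapfill <- function(model, db, uptake_limit = 10) {
  med <- complete_medium(db, uptake_limit)
  cand <- sort(setdiff(names(db$reactions),
                       c(names(model$reactions), db$biomass_reaction_id)))
  aug <- function(set) genedecay:::augment_model(model, db, set)
  vfull <- brute_force_fba(aug(cand), med)
  if (!vfull$feasible || vfull$value <= 1e-7) return(NULL)
  floor_val <- 0.1 * vfull$value
  grows <- function(set) {
    r <- brute_force_fba(aug(set), med)
    r$feasible && r$value >= floor_val - 1e-7
  }
  for (k in 0:length(cand)) {
    subs <- if (k == 0) list(character(0)) else combn(cand, k, simplify = FALSE)
    for (s in subs) if (grows(s)) return(list(added = s, size = k))
  }
  NULL
}
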