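# The ground-truth generator: universe structure, decay dynamics,
# viability, determinism, and codon-evolution bookkeeping.

test_that("the universe has the convergent 10- and 7-role pathways", {
  ug <- generate_universe()
  expect_length(ug$pathway_roles$hisL, 10)
  expect_length(ug$pathway_roles$trpL, 7)
  ## the bifunctional role sits in both chains and maps to two reactions
  expect_true(ug$focal_role %in% ug$pathway_roles$hisL)
  expect_true(ug$focal_role %in% ug$pathway_roles$trpL)
  expect_length(ug$db$role_map[[ug$focal_role]], 2)
  ## every chain reaction is reachable through the role map
  mapped <- unlist(ug$db$role_map, use.names = FALSE)
  chain_rxns <- grep("^rx_", names(ug$db$reactions), value = TRUE)
  expect_true(all(chain_rxns %in% mapped))
  ## end products are transportable (salvage), enabling loss
  expect_true(all(paste0("sup_", ug$pathway_names, "_e") %in%
                    ug$db$transportable))
})

test_that("a minimal 2-pathway universe grows on the complete medium", {
  ug <- generate_universe(n_pathways = 2, pathway_lengths = c(10, 7))
  roles <- names(ug$db$role_map)
  m <- build_model_from_annotation(
    genome_annotation("root", data.frame(gene_id = paste0("g_", roles),
                                         role = roles)), ug$db)
  st <- maximize_biomass(m, complete_medium(ug$db))
  expect_gt(st$objective_value, 1e-6)
})

default_envs <- function(ug) {
  environments_for_loss(ug, list(LI = "trpL", LII = character(0),
                                 LIII = c("hisL", "trpL"),
                                 LIV = c("trpL", "metL")))
}

test_that("zero loss rate reproduces the root genome everywhere", {
  ug <- generate_universe()
  tree <- decay_tree(n_per_lineage = 2, seed = 3)
  sc <- simulate_decay(ug, tree, default_envs(ug), loss_rate = 0, seed = 3)
  roles_root <- sort(unique(c(names(ug$db$role_map))))
  for (g in names(sc$genomes)) {
    expect_setequal(sc$genomes[[g]]$genes$role, roles_root)
    expect_length(sc$truth[[g]]$lost_pathways, 0)
  }
})

test_that("protected pathways are never lost and every genome is viable", {
  ug <- generate_universe()
  tree <- decay_tree(n_per_lineage = 5, seed = 21)
  sc <- simulate_decay(ug, tree, default_envs(ug), loss_rate = 2, seed = 21)
  for (g in names(sc$genomes)) {
    tr <- sc$truth[[g]]
    lin <- tr$lineage
    allowed <- switch(lin, LI = "trpL", LII = character(0),
                      LIII = c("hisL", "trpL"), LIV = c("trpL", "metL"))
    expect_true(all(tr$lost_pathways %in% allowed), label = g)
    ## viability in the genome's own environment (validated on build too)
    m <- build_model_from_annotation(sc$genomes[[g]], ug$db)
    st <- maximize_biomass(m, medium(sc$environments[[lin]], 10))
    expect_gt(st$objective_value, 1e-6)
  }
  ## focal gene tracks its pathways by construction
  for (g in names(sc$genomes)) {
    tr <- sc$truth[[g]]
    both_lost <- all(c("hisL", "trpL") %in% tr$lost_pathways)
    expect_equal(tr$focal_present, !both_lost, label = g)
  }
})

test_that("per-branch loss frequency matches the closed-form probability", {
  ug <- generate_universe()
  ## many two-leaf trees with a fixed branch length; count losses of one
  ## unprotected exclusive role across replicates
  bl <- 0.5; rate <- 1.0
  p_expected <- branch_loss_probability(rate, bl)
  tree <- ape::read.tree(text = paste0(
    "(LIII_g01:", bl, ",LIII_g02:", bl, "):0;"))
  envs <- list(LIII = environments_for_loss(
    ug, list(LIII = c("hisL", "trpL")))$LIII)
  n_rep <- 150; losses <- 0; trials <- 0
  for (s in 1:n_rep) {
    sc <- simulate_decay(ug, tree, envs, loss_rate = rate, seed = s,
                         validate = FALSE)
    for (g in names(sc$genomes)) {
      trials <- trials + 1
      losses <- losses +
        !("r_hisL_01" %in% sc$genomes[[g]]$genes$role)
    }
  }
  p_hat <- losses / trials
  se <- sqrt(p_expected * (1 - p_expected) / trials)
  expect_lt(abs(p_hat - p_expected), 4 * se + 0.01)
})

test_that("planted discordances flip the focal gene where both pathways are lost", {
  ug <- generate_universe()
  tree <- decay_tree(n_per_lineage = 5, seed = 8)
  envs <- environments_for_loss(ug, list(LI = c("hisL", "trpL"),
                                         LII = c("hisL", "trpL"),
                                         LIII = c("hisL", "trpL"),
                                         LIV = c("hisL", "trpL")))
  sc <- simulate_decay(ug, tree, envs, loss_rate = 2.5, seed = 8,
                       n_discordant = 2)
  n_disc <- sum(vapply(sc$truth, `[[`, logical(1), "discordant"))
  expect_equal(n_disc, 2)
  occ <- occurrence_matrix(sc$genomes, ug$pathways,
                           focal_genes = c(priA = ug$focal_role),
                           tree = sc$tree)
  cc <- coevolution_concordance(occ, "priA", c("hisL", "trpL"))
  expect_equal(cc$concordance, (20 - 2) / 20)
  expect_setequal(names(which(cc$discordant)),
                  names(which(vapply(sc$truth, `[[`, logical(1),
                                     "discordant"))))
})

test_that("fixture emission is deterministic and round-trips", {
  ug <- generate_universe()
  tree <- decay_tree(n_per_lineage = 2, seed = 4)
  sc1 <- simulate_decay(ug, tree, default_envs(ug), loss_rate = 1, seed = 4)
  sc2 <- simulate_decay(ug, tree, default_envs(ug), loss_rate = 1, seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cs <- simulate_codon_evolution(sc1$tree, c(LI = 0.1, LII = 0.06,
                                             LIII = 0.15, LIV = 0.15),
                                 n_codons = 60, mutation_rate = 0.3,
                                 seed = 4)
  emit_fixtures(sc1, d1, codon_sim = cs)
  emit_fixtures(sc2, d2, codon_sim = cs)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  back <- read_scenario(d1)
  expect_equal(length(back$annotations), length(sc1$genomes))
  expect_setequal(back$annotations[[1]]$genes$role,
                  sc1$genomes[[back$annotations[[1]]$genome_id]]$genes$role)
  expect_setequal(names(back$db$reactions), names(ug$db$reactions))
  expect_setequal(back$tree$tip.label, sc1$tree$tip.label)
  ## re-emission of the re-read annotations is byte-identical
  d3 <- withr::local_tempdir()
  write_annotations(back$annotations, file.path(d3, "annotations.tsv"))
  expect_identical(readLines(file.path(d3, "annotations.tsv")),
                   readLines(file.path(d1, "annotations.tsv")))
})

test_that("codon evolution respects omega limits and keeps books", {
  tree <- decay_tree(c("A", "B"), n_per_lineage = 3, seed = 6,
                     bl_range = c(0.5, 1))
  ## omega 0: proteins never change
  cs0 <- simulate_codon_evolution(tree, c(A = 0, B = 0), n_codons = 80,
                                  mutation_rate = 0.4, seed = 6,
                                  base_omega = 0)
  root_prot <- genedecay:::translate_codons(
    genedecay:::split_codons(cs0$root_sequence))
  for (tx in names(cs0$alignment$sequences)) {
    prot <- genedecay:::translate_codons(
      genedecay:::split_codons(cs0$alignment$sequences[[tx]]))
    expect_equal(prot, root_prot)
  }
  expect_equal(sum(cs0$counts$nonsyn), 0)
  ## zero mutation rate: sequences identical to the root
  csq <- simulate_codon_evolution(tree, c(A = 1, B = 1), n_codons = 80,
                                  mutation_rate = 0, seed = 6)
  expect_true(all(csq$alignment$sequences == csq$root_sequence))
  ## realized nonsyn/syn acceptance ratio tracks omega
  cs1 <- simulate_codon_evolution(decay_tree("C", 20, seed = 9,
                                             bl_range = c(0.8, 1.2)),
                                  c(C = 0.5), n_codons = 300,
                                  mutation_rate = 0.3, seed = 9)
  cs2 <- simulate_codon_evolution(decay_tree("C", 20, seed = 9,
                                             bl_range = c(0.8, 1.2)),
                                  c(C = 1), n_codons = 300,
                                  mutation_rate = 0.3, seed = 9)
  r1 <- sum(cs1$counts$nonsyn) / sum(cs1$counts$syn)
  r2 <- sum(cs2$counts$nonsyn) / sum(cs2$counts$syn)
  expect_lt(r1, r2)
  expect_equal(r1 / r2, 0.5, tolerance = 0.15)
})
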