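# Pathway completeness calls, tree-ordered occurrence matrices,
# focal-gene concordance, and auxotrophy prediction against truth.

ann_with_roles <- function(id, roles) {
  roles <- unique(roles)
  genome_annotation(id, data.frame(gene_id = paste0("g_", roles),
                                   role = roles))
}

test_that("completeness fractions honor the inclusive 90% threshold", {
  ug <- generate_universe()
  his <- ug$pathways$hisL
  expect_length(his$expected_roles, 10)
  expect_length(ug$pathways$trpL$expected_roles, 7)

  ## 9 of 10 roles (one enzyme unannotated) still counts as complete
  nine <- ann_with_roles("g9", setdiff(his$expected_roles, "r_hisL_07"))
  pc <- pathway_completeness(nine, his)
  expect_equal(pc$fraction, 0.9)
  expect_true(pc$complete)

  ten <- ann_with_roles("g10", his$expected_roles)
  expect_equal(pathway_completeness(ten, his)$fraction, 1)

  ## 6 of 7 trp roles is below threshold
  trp <- ug$pathways$trpL
  six <- ann_with_roles("g6", setdiff(trp$expected_roles, "r_trpL_01"))
  pc6 <- pathway_completeness(six, trp)
  expect_equal(pc6$fraction, 6 / 7, tolerance = 1e-12)
  expect_false(pc6$complete)
})

test_that("completeness is monotone in the annotated role set", {
  ug <- generate_universe()
  his <- ug$pathways$hisL
  set.seed(9)
  for (rep in 1:10) {
    r1 <- sample(his$expected_roles, sample(0:9, 1))
    r2 <- unique(c(r1, sample(his$expected_roles, 2)))
    f1 <- pathway_completeness(ann_with_roles("a", c(r1, "pad")), his)$fraction
    f2 <- pathway_completeness(ann_with_roles("a", c(r2, "pad")), his)$fraction
    expect_gte(f2, f1)
  }
})

test_that("occurrence matrices follow tree order and record focal genes", {
  ug <- generate_universe()
  tree <- ape::read.tree(text = "((gB:1,gA:1):1,gC:1);")
  anns <- list(
    ann_with_roles("gA", c(ug$pathways$hisL$expected_roles,
                           ug$pathways$trpL$expected_roles)),
    ann_with_roles("gB", ug$pathways$hisL$expected_roles),
    ann_with_roles("gC", "r_metL_01"))
  occ <- occurrence_matrix(anns, ug$pathways[c("hisL", "trpL")],
                           focal_genes = c(priA = ug$focal_role),
                           tree = tree)
  expect_equal(rownames(occ), c("gB", "gA", "gC"))
  expect_equal(unname(occ["gA", ]), c(1L, 1L, 1L))
  expect_equal(unname(occ["gB", c("trpL", "priA")]), c(0L, 1L))
  expect_equal(unname(occ["gC", ]), c(0L, 0L, 0L))
})

test_that("concordance counts genomes where the focal gene tracks pathways", {
  m <- presence_matrix(
    matrix(c(1L, 1L, 1L,   # coupled
             0L, 0L, 0L,   # coupled (both absent)
             0L, 0L, 1L,   # focal without pathways
             1L, 0L, 0L),  # pathway without focal
           4, 3, byrow = TRUE,
           dimnames = list(paste0("g", 1:4), c("hisL", "trpL", "priA"))),
    "mixed")
  cc <- coevolution_concordance(m, "priA", c("hisL", "trpL"))
  expect_equal(cc$concordance, 0.5)
  expect_equal(unname(cc$discordant), c(FALSE, FALSE, TRUE, TRUE))
  ## perfectly coupled and perfectly anti-coupled extremes
  all1 <- presence_matrix(matrix(1L, 2, 2, dimnames = list(c("a", "b"),
                                                           c("p", "f"))),
                          "mixed")
  expect_equal(coevolution_concordance(all1, "f", "p")$concordance, 1)
  anti <- presence_matrix(matrix(c(0L, 0L, 1L, 1L), 2, 2,
                                 dimnames = list(c("a", "b"), c("p", "f"))),
                          "mixed")
  expect_equal(coevolution_concordance(anti, "f", "p")$concordance, 0)
})

test_that("auxotrophy predictions match simulated pathway loss exactly", {
  ug <- generate_universe()
  tree <- decay_tree(n_per_lineage = 3, seed = 11)
  envs <- environments_for_loss(ug, list(LI = "trpL", LII = character(0),
                                         LIII = c("hisL", "trpL"),
                                         LIV = c("trpL", "metL")))
  sc <- simulate_decay(ug, tree, envs, loss_rate = 1.5, seed = 11)
  models <- scenario_models(sc)
  for (g in names(models)) {
    a <- six_step_analysis(models[[g]])
    expect_identical(predict_auxotrophies(a, ug$nutrient_pathway_map),
                     sc$truth[[g]]$lost_pathways, label = g)
  }
  ## concordance is 1 when no discordance is planted
  occ <- occurrence_matrix(sc$genomes, ug$pathways,
                           focal_genes = c(priA = ug$focal_role),
                           tree = sc$tree)
  cc <- coevolution_concordance(occ, "priA", c("hisL", "trpL"))
  expect_equal(cc$concordance, 1)
})
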