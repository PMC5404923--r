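# The six-step flux balance procedure, checked operation by operation
# against closed-form fixtures and brute-force enumeration oracles.

test_that("biomass maximization saturates a bound-limited chain", {
  m <- chain_model()
  st <- maximize_biomass(m, medium("A_e", uptake_limit = 10))
  expect_equal(st$status, "optimal")
  expect_equal(st$objective_value, 10, tolerance = 1e-7)
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% st$fluxes)), 1e-7)
  ## empty medium shuts uptake entirely
  st0 <- maximize_biomass(m, medium(character(0)))
  expect_equal(st0$objective_value, 0, tolerance = 1e-7)
})

test_that("branched network optimum equals the enumeration oracle", {
  m <- branched_model()
  med <- complete_medium(m, uptake_limit = 10)
  st <- maximize_biomass(m, med)
  oracle <- brute_force_fba(m, med)
  expect_equal(st$objective_value, oracle$value, tolerance = 1e-6)
  expect_equal(st$objective_value, 20, tolerance = 1e-6)  # both routes add up
})

test_that("minimal media are exact, minimal and lexicographically tied", {
  ## two required nutrients
  m <- two_nutrient_model()
  mm <- find_minimal_media(m)
  expect_equal(mm$medium$nutrients, c("A_e", "B_e"))
  oracle <- brute_force_minimal_media(m)
  expect_equal(sort(oracle$nutrients), mm$medium$nutrients)
  expect_gte(mm$achieved_biomass, mm$growth_floor)

  ## substitutable routes: two singleton optima, tie broken toward A_e
  mb <- branched_model()
  mmb <- find_minimal_media(mb)
  expect_equal(mmb$medium$nutrients, "A_e")
  ob <- brute_force_minimal_media(mb)
  expect_equal(ob$size, 1L)

  ## spontaneous source needs no uptake at all
  ms <- spontaneous_model()
  expect_equal(find_minimal_media(ms)$medium$nutrients, character(0))

  ## greedy method agrees here
  expect_equal(find_minimal_media(mb, method = "greedy")$medium$nutrients,
               "A_e")
})

test_that("a model with no growth is reported as auxotrophic", {
  m <- chain_model()
  m$reactions$r1 <- NULL   # break the chain
  m <- stoichiometric_model(m$genome_id, m$metabolites,
                            unname(m$reactions), "bio")
  expect_error(find_minimal_media(m), "auxotrophic.*complete medium")
})

test_that("FVA ranges match fixtures and the enumeration oracle", {
  m <- chain_model()
  med <- medium("A_e", 10)
  ## essential chain at full throughput when biomass is fixed at max
  fva_max <- flux_variability(m, med, biomass_at = "max")
  expect_equal(unname(fva_max["r1", ]), c(10, 10), tolerance = 1e-6)

  ## under the floor, substitutable duplicates span 0..demand
  mb <- branched_model()
  mmb <- find_minimal_media(mb)
  floor_val <- mmb$growth_floor
  fva <- flux_variability(mb, mmb$medium, growth_floor = floor_val)
  expect_equal(fva["r1b", "min"], 0, tolerance = 1e-6)
  oracle <- oracle_fva(mb, mmb$medium, floor_val)
  expect_equal(unname(fva), unname(oracle), tolerance = 1e-6)

  ## blocked branch on minimal medium: identically zero
  expect_equal(unname(fva["tB", ]), c(0, 0), tolerance = 1e-6)
})

test_that("classification follows the sign structure of the ranges", {
  ranges <- rbind(a = c(10, 10), b = c(0, 0), c = c(0, 7),
                  d = c(-8, -2), e = c(-3, 4))
  colnames(ranges) <- c("min", "max")
  cls <- classify_reactions(ranges)
  expect_equal(unname(cls), c("essential", "nonfunctional", "functional",
                              "essential", "functional"))
  ## epsilon screens numerical dust
  dust <- rbind(f = c(1e-9, 1e-8))
  colnames(dust) <- c("min", "max")
  expect_equal(unname(classify_reactions(dust, epsilon = 1e-6)),
               "nonfunctional")
})

test_that("parsimonious flux removes futile loops and matches the chain", {
  ml <- loop_model()
  pf <- parsimonious_flux(ml, medium("A_e", 10))
  expect_equal(unname(pf$fluxes[c("loop_f", "loop_b")]), c(0, 0),
               tolerance = 1e-7)
  expect_equal(pf$objective_value, 10, tolerance = 1e-6)
  ## chain fluxes all equal throughput
  m <- chain_model()
  pfc <- parsimonious_flux(m, medium("A_e", 10))
  expect_equal(unname(pfc$fluxes[c("tA", "r1", "bio")]), rep(10, 3),
               tolerance = 1e-6)
  expect_equal(unname(pfc$fluxes["EX_A_e"]), -10, tolerance = 1e-6)
  ## total flux agrees with the brute-force LP bound on the branched net
  mb <- branched_model()
  pfb <- parsimonious_flux(mb, complete_medium(mb))
  expect_equal(sum(abs(pfb$fluxes)), attr(pfb, "total_flux"),
               tolerance = 1e-6)
})

test_that("six-step analysis composes the individual oracles", {
  mb <- branched_model()
  a <- six_step_analysis(mb)
  expect_true(a$grows_on_complete)
  expect_equal(a$minimal_medium$medium$nutrients, "A_e")
  expect_equal(sort(names(a$classes)), sort(names(mb$reactions)))
  expect_equal(a$parsimonious$objective_value,
               maximize_biomass(mb, a$minimal_medium$medium)$objective_value,
               tolerance = 1e-6)
  ## the nutrient kept in the minimal medium has an essential exchange
  expect_equal(unname(a$classes["EX_A_e"]), "essential")
})

test_that("genomes lacking a pathway need its product as a nutrient", {
  ug <- generate_universe()
  roles <- names(ug$db$role_map)
  ## full complement minus every exclusive trp role
  trp_only <- setdiff(roles, setdiff(ug$pathway_roles$trpL, ug$focal_role))
  ann <- genome_annotation("no_trp", data.frame(
    gene_id = paste0("g_", trp_only), role = trp_only))
  m <- build_model_from_annotation(ann, ug$db)
  a <- six_step_analysis(m)
  expect_true("sup_trpL_e" %in% a$minimal_medium$medium$nutrients)
  expect_false("sup_hisL_e" %in% a$minimal_medium$medium$nutrients)
  ## prototrophic complete genome imports precursors only
  ann_full <- genome_annotation("full", data.frame(
    gene_id = paste0("g_", roles), role = roles))
  af <- six_step_analysis(build_model_from_annotation(ann_full, ug$db))
  expect_false(any(grepl("^sup_", af$minimal_medium$medium$nutrients)))
})

test_that("enlarging the medium never decreases the biomass optimum", {
  set.seed(77)
  for (rep in 1:8) {
    m <- random_network(rep + 300)
    nuts <- genedecay:::exchangeable_nutrients(m)
    small <- medium(sample(nuts, 1))
    v1 <- maximize_biomass(m, small)$objective_value
    v2 <- maximize_biomass(m, medium(nuts))$objective_value
    expect_gte(v2 + 1e-7, v1)
  }
})
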