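# Model types, validation, GPR dialect, serialization round trips, and
# draft-model construction from annotations.

test_that("validate_model reports each invariant violation by entity", {
  m <- chain_model()
  expect_length(validate_model(m), 0)

  bad <- m
  bad$reactions$r1$lower_bound <- 5
  bad$reactions$r1$upper_bound <- 1
  v <- validate_model(bad)
  expect_length(v, 1)
  expect_match(v, "r1.*lower_bound")

  bad2 <- m
  bad2$reactions$r1$gapfilled <- TRUE      # still has genes
  expect_match(validate_model(bad2), "gapfilled")

  bad3 <- m
  bad3$reactions$r1$stoichiometry <- c(UNKNOWN_c = -1, P_c = 1)
  expect_match(validate_model(bad3), "UNKNOWN_c")

  bad4 <- m
  bad4$biomass_reaction_id <- "nope"
  expect_match(validate_model(bad4), "nope")
})

test_that("model TSV round trip is byte-identical on canonical files", {
  m <- branched_model()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, f1, "tsv")
  m2 <- read_model(f1, "tsv")
  write_model(m2, f2, "tsv")
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(m2$reactions$r1a$stoichiometry, m$reactions$r1a$stoichiometry)
  expect_equal(m2$reactions$r1a$gene_association,
               m$reactions$r1a$gene_association)
})

test_that("json and tsv emissions parse to equal models", {
  m <- branched_model()
  ft <- withr::local_tempfile(fileext = ".tsv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_model(m, ft, "tsv")
  write_model(m, fj, "json")
  mt <- read_model(ft, "tsv")
  mj <- read_model(fj, "json")
  expect_equal(mt, mj)
})

test_that("malformed inputs give errors naming the problem line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("!model\tg\tbio",
               "!met\tP_c\tP_c\tcytosol",
               "!rxn\tbio\tnot_a_number:P_c\t0\t1000\t\t0\t0"), f)
  expect_error(read_model(f, "tsv"), "line 3.*malformed")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("!model\tg\tbio",
               "!met\tP_c\tP_c\tcytosol",
               "!rxn\tr1\t-1:Q_c\t0\t1000\t\t0\t0"), f2)
  expect_error(read_model(f2, "tsv"), "Q_c")
})

test_that("GPR dialect supports disjunctions and conjunctive pairs only", {
  p <- genedecay:::parse_gpr
  expect_equal(p("gA"), list("gA"))
  expect_equal(p("gA or gB"), list("gA", "gB"))
  expect_equal(p("(gA and gB) or gC"), list(c("gA", "gB"), "gC"))
  expect_equal(p(""), list())
  expect_error(p("(gA and gB and gC)"), "unsupported")
  expect_error(p("((gA and gB))"), "unsupported")
  expect_identical(genedecay:::gpr_to_string(list(c("gA", "gB"), "gC")),
                   "(gA and gB) or gC")
})

test_that("draft models contain exactly the annotated reactions", {
  ug <- generate_universe()
  db <- ug$db
  ann <- genome_annotation("g1", data.frame(
    gene_id = c("x1", "x2"), role = c("r_hisL_01", "r_hisL_02")))
  m <- build_model_from_annotation(ann, db)
  expect_true(all(c("rx_hisL_01", "rx_hisL_02") %in% names(m$reactions)))
  expect_false("rx_trpL_01" %in% names(m$reactions))
  ## exchanges for every transportable nutrient plus biomass
  n_ex <- sum(vapply(m$reactions, `[[`, logical(1), "is_exchange"))
  expect_equal(n_ex, length(db$transportable))
  expect_true(db$biomass_reaction_id %in% names(m$reactions))
  ## empty annotation -> exchanges + biomass only
  empty <- build_model_from_annotation(
    genome_annotation("g0", data.frame(gene_id = character(0),
                                       role = character(0))), db)
  expect_equal(length(empty$reactions), length(db$transportable) + 1L)
})

test_that("genes sharing a role become a two-term disjunction", {
  ug <- generate_universe()
  ann <- genome_annotation("g2", data.frame(
    gene_id = c("xa", "xb"), role = c("r_hisL_01", "r_hisL_01")))
  m <- build_model_from_annotation(ann, ug$db)
  expect_equal(m$reactions$rx_hisL_01$gene_association, list("xa", "xb"))
})

test_that("unknown roles are skipped with a warning, not an error", {
  ug <- generate_universe()
  ann <- genome_annotation("g3", data.frame(
    gene_id = c("x1", "x2"), role = c("r_hisL_01", "r_made_up")))
  expect_warning(m <- build_model_from_annotation(ann, ug$db), "r_made_up")
  expect_true("rx_hisL_01" %in% names(m$reactions))
})

test_that("annotation construction is monotone in the gene set", {
  ug <- generate_universe()
  roles <- names(ug$db$role_map)
  set.seed(5)
  for (rep in 1:5) {
    r1 <- sample(roles, 6)
    r2 <- c(r1, sample(setdiff(roles, r1), 3))
    m1 <- build_model_from_annotation(
      genome_annotation("a", data.frame(gene_id = paste0("g", seq_along(r1)),
                                        role = r1)), ug$db)
    m2 <- build_model_from_annotation(
      genome_annotation("a", data.frame(gene_id = paste0("g", seq_along(r2)),
                                        role = r2)), ug$db)
    expect_true(all(names(m1$reactions) %in% names(m2$reactions)))
    expect_lte(length(m2$reactions),
               length(ug$db$reactions) + length(ug$db$transportable) + 1L)
  }
})
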