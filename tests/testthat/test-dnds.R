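# Codon alignments, back-translation, and the counting dN/dS estimator
# with its Jukes-Cantor correction.

random_codon_seq <- function(n, seed) {
  set.seed(seed)
  code <- genedecay:::codon_tables()
  paste(sample(setdiff(code$codons, code$stops), n, replace = TRUE),
        collapse = "")
}

test_that("back-translation places codons under residues and gaps as triplets", {
  ## gapless pair
  cds <- c(t1 = "ATGGCTAAA", t2 = "ATGGCCAAA")     # M A K / M A K
  prot <- c(t1 = "MAK", t2 = "MAK")
  al <- backtranslate_alignment(prot, cds)
  expect_equal(unname(al$sequences["t1"]), "ATGGCTAAA")

  ## a one-residue gap becomes one --- triplet; terminal stop tolerated
  prot2 <- c(t1 = "MAK", t2 = "M-K")
  cds2 <- c(t1 = "ATGGCTAAA", t2 = "ATGAAATAA")
  al2 <- backtranslate_alignment(prot2, cds2)
  expect_equal(unname(al2$sequences["t2"]), "ATG---AAA")

  ## translation mismatch names the taxon and position
  expect_error(
    backtranslate_alignment(c(t1 = "MAK", t2 = "MVK"),
                            c(t1 = "ATGGCTAAA", t2 = "ATGGCTAAA")),
    "t2.*residue 2")
})

test_that("random back-translations verify residue by residue", {
  code <- genedecay:::codon_tables()
  set.seed(33)
  for (rep in 1:5) {
    n <- 40
    cds <- vapply(1:3, function(i) random_codon_seq(n, seed = 100 * rep + i),
                  character(1))
    names(cds) <- paste0("t", 1:3)
    prot <- vapply(cds, function(s) {
      paste(genedecay:::translate_codons(genedecay:::split_codons(s)),
            collapse = "")
    }, character(1))
    ## insert aligned gap columns at random codon positions
    gap_at <- sort(sample(1:n, 4))
    prot_gapped <- vapply(names(prot), function(tx) {
      chars <- strsplit(prot[[tx]], "")[[1]]
      drop <- if (tx == "t2") gap_at else integer(0)
      out <- character(0)
      for (i in seq_len(n)) {
        out <- c(out, if (i %in% drop) "-" else chars[i])
      }
      paste(out, collapse = "")
    }, character(1))
    cds2 <- cds
    chars <- genedecay:::split_codons(cds[["t2"]])
    cds2[["t2"]] <- paste(chars[-gap_at], collapse = "")
    al <- backtranslate_alignment(prot_gapped, cds2)
    back <- genedecay:::split_codons(al$sequences[["t2"]])
    expect_equal(sum(back == "---"), 4)
    expect_equal(paste(back[back != "---"], collapse = ""), cds2[["t2"]])
  }
})

test_that("codon alignment invariants are enforced", {
  expect_error(codon_alignment(c(a = "ATGAA", b = "ATGAA")), "divisible")
  expect_error(codon_alignment(c(a = "ATGAAA", b = "ATG")), "length")
  expect_error(codon_alignment(c(a = "ATG-A-", b = "ATGAAA")),
               "codon-aligned")
  expect_error(codon_alignment(c(a = "ATGTAAAAA", b = "ATGAAAAAA")),
               "stop")
})

test_that("identical and purely synonymous pairs give the expected corner cases", {
  s <- random_codon_seq(50, seed = 1)
  est <- ng86_pairwise(s, s)
  expect_equal(est$dN, 0)
  expect_equal(est$dS, 0)
  expect_true(is.na(est$omega))

  ## synonymous-only divergence: third-position change in a 4-fold codon
  a <- paste(rep("CTT", 30), collapse = "")   # Leu
  b <- paste(rep(c("CTC", "CTT"), 15), collapse = "")
  est2 <- ng86_pairwise(a, b)
  expect_equal(est2$dN, 0)
  expect_gt(est2$dS, 0)
})

test_that("the estimator is symmetric and nonnegative", {
  for (seed in 1:5) {
    a <- random_codon_seq(60, seed = seed)
    b <- random_codon_seq(60, seed = seed + 50)
    e1 <- ng86_pairwise(a, b)
    e2 <- ng86_pairwise(b, a)
    expect_equal(e1$dN, e2$dN, tolerance = 1e-12)
    expect_equal(e1$dS, e2$dS, tolerance = 1e-12)
    if (!is.na(e1$dN)) expect_gte(e1$dN, 0)
    if (!is.na(e1$dS)) expect_gte(e1$dS, 0)
  }
})

test_that("table-driven estimates equal direct pathway enumeration to 1e-9", {
  set.seed(64)
  for (rep in 1:12) {
    tr <- decay_tree(c("X", "Y"), n_per_lineage = 1, seed = rep,
                     bl_range = c(0.5, 1.5))
    cs <- simulate_codon_evolution(tr, c(X = 0.5, Y = 0.5), n_codons = 300,
                                   mutation_rate = 0.3, seed = rep,
                                   base_omega = 0.5)
    seqs <- cs$alignment$sequences
    e1 <- ng86_pairwise(seqs[[1]], seqs[[2]])
    e2 <- ng86_reference(seqs[[1]], seqs[[2]])
    expect_equal(e1$dN, e2$dN, tolerance = 1e-9)
    expect_equal(e1$dS, e2$dS, tolerance = 1e-9)
    expect_equal(e1$Sd, e2$Sd, tolerance = 1e-9)
    expect_equal(e1$S_sites, e2$S_sites, tolerance = 1e-9)
  }
})

test_that("gap and ambiguity codons are dropped pairwise", {
  a <- "ATGCTTAAA---GGG"
  b <- "ATGCTCAAANNNGGG"
  est <- ng86_pairwise(a, b)
  expect_equal(est$n_codons_used, 4)
})

test_that("clade omega equals the pairwise estimate for two leaves", {
  a <- random_codon_seq(80, seed = 2)
  set.seed(3)
  chars <- genedecay:::split_codons(a)
  code <- genedecay:::codon_tables()
  idx <- sample(80, 15)
  chars[idx] <- sample(setdiff(code$codons, code$stops), 15, replace = TRUE)
  b <- paste(chars, collapse = "")
  al <- codon_alignment(c(x = a, y = b))
  co <- clade_omega(al, c("x", "y"))
  pw <- ng86_pairwise(a, b)
  expect_equal(co$dN, pw$dN)
  expect_equal(co$dS, pw$dS)
  expect_equal(co$n_pairs, 1L)
  ## identical sequences across a clade: undefined omega
  al2 <- codon_alignment(c(x = a, y = a, z = a))
  expect_true(is.na(clade_omega(al2, c("x", "y", "z"))$omega))
})

test_that("neutral simulation is estimated near 1 and below-1 ranks recover", {
  ## neutral: mean estimate over many pairs within [0.8, 1.2]
  tr <- decay_tree("N", n_per_lineage = 12, seed = 5, bl_range = c(0.25, 0.5))
  cs <- simulate_codon_evolution(tr, c(N = 1), n_codons = 300,
                                 mutation_rate = 0.25, seed = 5)
  prs <- combn(names(cs$alignment$sequences), 2, simplify = FALSE)
  oms <- vapply(prs, function(p) {
    ng86_pairwise(cs$alignment$sequences[[p[1]]],
                  cs$alignment$sequences[[p[2]]])$omega
  }, numeric(1))
  expect_gte(length(oms), 50)
  expect_gt(mean(oms, na.rm = TRUE), 0.8)
  expect_lt(mean(oms, na.rm = TRUE), 1.2)

  ## strong purifying selection always estimates below the neutral clade
  for (seed in 1:5) {
    tr2 <- decay_tree(c("P", "N"), n_per_lineage = 4, seed = seed,
                      bl_range = c(0.4, 0.8))
    cs2 <- simulate_codon_evolution(tr2, c(P = 0.1, N = 1), n_codons = 300,
                                    mutation_rate = 0.3, seed = seed)
    al <- cs2$alignment
    op <- clade_omega(al, grep("^P_", names(al$sequences), value = TRUE))
    on <- clade_omega(al, grep("^N_", names(al$sequences), value = TRUE))
    expect_lt(op$omega, on$omega)
  }
})
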