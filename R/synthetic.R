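## Ground-truth generator: a toy universal biochemistry with linear
## amino-acid biosynthesis pathways (two of which converge on one
## bifunctional isomerase role, mirroring histidine/tryptophan
## biosynthesis meeting at a PriA-like enzyme), progressive gene loss
## along a phylogeny conditioned on environmental nutrient supply, and
## codon evolution with clade-specific omega.  Every stage of the
## analysis pipeline can be scored against the recorded truth.

#' Generate a universal biochemistry
#'
#' Builds linear biosynthesis chains from transportable precursors to
#' amino-acid biomass precursors.  The first two pathways are the
#' convergent pair: by default 10 and 7 enzymatic roles, one of which
#' (`r_pri`, a bifunctional isomerase) catalyzes one step of each
#' chain.  Every end product is also transportable as a supplement
#' (`sup_*` nutrients), so a genome that loses a pathway can survive by
#' salvage; precursor and supplement transporters are housekeeping
#' roles that are never lost.
#'
#' @param n_pathways number of pathways (>= 2).
#' @param pathway_lengths enzymatic roles per pathway; the first two
#'   default to 10 and 7.
#' @param seed kept for interface symmetry; the universe is fully
#'   deterministic given its parameters.
#' @return list of class `gd_universe_gen` with the `db`
#'   (a `gd_universe`), `pathways` (list of `gd_pathway`), the
#'   `focal_role`, `nutrient_pathway_map` (supplement -> pathway),
#'   `pathway_roles`, and `housekeeping_roles`.
#' @export
generate_universe <- function(n_pathways = 4,
                              pathway_lengths = c(10, 7, 5, 4)[seq_len(n_pathways)],
                              seed = 1) {
  stopifnot(n_pathways >= 2, length(pathway_lengths) == n_pathways,
            all(pathway_lengths >= 2))
  pool <- c("hisL", "trpL", "metL", "serL", "thrL", "valL", "leuL", "argL",
            "lysL", "proL")
  if (n_pathways > length(pool)) stop("at most ", length(pool), " pathways")
  pw_names <- pool[seq_len(n_pathways)]
  focal_role <- "r_pri"
  pri_pos <- c(min(4L, pathway_lengths[1] - 1L), min(3L, pathway_lengths[2] - 1L))

  mets <- list(); rxns <- list(); role_map <- list()
  pathway_roles <- list(); housekeeping <- character(0)
  for (i in seq_len(n_pathways)) {
    pw <- pw_names[i]; L <- pathway_lengths[i]
    pre_e <- paste0("pre_", pw, "_e"); pre_c <- paste0("pre_", pw, "_c")
    aa_c <- paste0("aa_", pw, "_c"); sup_e <- paste0("sup_", pw, "_e")
    mets[[length(mets) + 1L]] <- metabolite(pre_e, compartment = "extracellular")
    mets[[length(mets) + 1L]] <- metabolite(pre_c)
    mets[[length(mets) + 1L]] <- metabolite(aa_c)
    mets[[length(mets) + 1L]] <- metabolite(sup_e, compartment = "extracellular")
    chain_mets <- c(pre_c,
                    if (L > 1) paste0("int_", pw, "_", seq_len(L - 1L), "_c"),
                    aa_c)
    for (k in seq_len(L - 1L)) {
      mets[[length(mets) + 1L]] <- metabolite(chain_mets[k + 1L])
    }
    roles_i <- character(L)
    for (k in seq_len(L)) {
      rid <- sprintf("rx_%s_%02d", pw, k)
      role <- if (i <= 2L && k == pri_pos[i]) focal_role
              else sprintf("r_%s_%02d", pw, k)
      roles_i[k] <- role
      st <- stats::setNames(c(-1, 1), c(chain_mets[k], chain_mets[k + 1L]))
      rxns[[rid]] <- reaction(rid, st)
      role_map[[role]] <- c(role_map[[role]], rid)
    }
    pathway_roles[[pw]] <- roles_i
    tp <- paste0("tp_", pw); ts <- paste0("ts_", pw)
    rxns[[tp]] <- reaction(tp, stats::setNames(c(-1, 1), c(pre_e, pre_c)))
    rxns[[ts]] <- reaction(ts, stats::setNames(c(-1, 1), c(sup_e, aa_c)))
    role_map[[paste0("t_pre_", pw)]] <- tp
    role_map[[paste0("t_sup_", pw)]] <- ts
    housekeeping <- c(housekeeping, paste0("t_pre_", pw), paste0("t_sup_", pw))
  }
  bio_st <- stats::setNames(rep(-1, n_pathways), paste0("aa_", pw_names, "_c"))
  rxns[["bio_biomass"]] <- reaction("bio_biomass", bio_st)
  met_df <- do.call(rbind, mets)
  met_df <- met_df[!duplicated(met_df$id), , drop = FALSE]
  transportable <- sort(c(paste0("pre_", pw_names, "_e"),
                          paste0("sup_", pw_names, "_e")))
  db <- universal_database(met_df, unname(rxns), role_map, transportable,
                           "bio_biomass")
  pathways <- list()
  for (i in seq_len(n_pathways)) {
    pw <- pw_names[i]
    pathways[[pw]] <- pathway_definition(
      pw, pathway_roles[[pw]],
      completeness_threshold = 0.9,
      shared_roles = if (i <= 2L) focal_role else character(0))
  }
  structure(list(db = db, pathways = pathways, focal_role = focal_role,
                 nutrient_pathway_map = stats::setNames(
                   pw_names, paste0("sup_", pw_names, "_e")),
                 pathway_roles = pathway_roles,
                 housekeeping_roles = sort(housekeeping),
                 pathway_names = pw_names,
                 seed = seed),
            class = "gd_universe_gen")
}

#' Random lineage-structured phylogeny
#'
#' Builds a tree of `length(lineages)` monophyletic lineage subtrees,
#' with leaves named `<lineage>_g<k>` so the lineage of every genome
#' can be read off its label.  Branch lengths are uniform draws
#' (seeded), in the same time units as the decay rate.
#'
#' @param lineages lineage labels.
#' @param n_per_lineage leaves per lineage.
#' @param seed RNG seed.
#' @param bl_range range of within-lineage branch lengths.
#' @return an `ape` `phylo` object.
#' @export
decay_tree <- function(lineages = c("LI", "LII", "LIII", "LIV"),
                       n_per_lineage = 5, seed = 1, bl_range = c(0.3, 0.8)) {
  set.seed(seed)
  bl <- function() round(stats::runif(1, bl_range[1], bl_range[2]), 4)
  subtree <- function(labels) {
    if (length(labels) == 1L) return(paste0(labels, ":", bl()))
    half <- ceiling(length(labels) / 2)
    paste0("(", subtree(labels[seq_len(half)]), ",",
           subtree(labels[-seq_len(half)]), "):", bl())
  }
  clades <- vapply(lineages, function(lin) {
    subtree(paste0(lin, "_g", sprintf("%02d", seq_len(n_per_lineage))))
  }, character(1))
  join <- clades[1]
  for (i in seq_along(clades)[-1]) {
    join <- paste0("(", join, ",", clades[i], "):0.2")
  }
  ape::read.tree(text = paste0(join, ";"))
}

lineage_of <- function(labels) sub("_.*$", "", labels)

#' Environments conditioned on pathway loss
#'
#' Every lineage environment supplies all pathway precursors; a lineage
#' additionally supplies the amino-acid supplement of each pathway it
#' is allowed to lose, which is what licenses decay of those pathways.
#'
#' @param universe_gen a `gd_universe_gen`.
#' @param lose named list: lineage -> pathway names whose products the
#'   lineage's environment supplies.
#' @return named list: lineage -> nutrient ids.
#' @export
environments_for_loss <- function(universe_gen, lose) {
  pre <- paste0("pre_", universe_gen$pathway_names, "_e")
  lapply(lose, function(pws) {
    bad <- setdiff(pws, universe_gen$pathway_names)
    if (length(bad)) stop("unknown pathway: ", paste(bad, collapse = ", "))
    sort(c(pre, paste0("sup_", pws, "_e")))
  })
}

## exponential waiting-time loss probability along a branch
#' @export
#' @rdname simulate_decay
branch_loss_probability <- function(loss_rate, branch_length) {
  1 - exp(-loss_rate * branch_length)
}

#' Simulate genome decay along a phylogeny
#'
#' Starting from a root genome carrying one gene per universal role,
#' genes are lost irreversibly along each branch with probability
#' `1 - exp(-loss_rate * branch_length)`.  A pathway is eligible for
#' loss on a branch only when its end product is supplied in the
#' environments of all lineages below that branch; pathways whose
#' product is not supplied are protected, as are transporter
#' (housekeeping) roles.  The bifunctional focal gene is removed
#' exactly when both of its dependent pathways have been broken by
#' exclusive-role losses, so focal presence tracks pathway retention by
#' construction.  Optionally, `n_discordant` leaves have the focal gene
#' re-added after the fact (where this leaves both pathways incomplete),
#' planting known discordances for the coevolution analysis.
#'
#' @param universe_gen a `gd_universe_gen`.
#' @param tree a `phylo` whose tip labels encode lineages as
#'   `<lineage>_g<k>` (see [decay_tree()]).
#' @param environments named list lineage -> nutrient ids (see
#'   [environments_for_loss()]).
#' @param loss_rate loss events per gene per unit branch length.
#' @param seed RNG seed.
#' @param n_discordant number of discordant leaves to plant.
#' @param validate check that every generated genome's model grows in
#'   its lineage environment.
#' @param uptake_limit uptake cap used for the viability check.
#' @return list of class `gd_scenario`: genomes (annotations), recorded
#'   truth per genome, tree, environments, lineage map and parameters.
#' @export
simulate_decay <- function(universe_gen, tree, environments, loss_rate = 0.5,
                           seed = 1, n_discordant = 0, validate = TRUE,
                           uptake_limit = 10) {
  stopifnot(inherits(universe_gen, "gd_universe_gen"), inherits(tree, "phylo"))
  tree <- stats::reorder(tree, "cladewise")   # edge rows in preorder
  set.seed(seed)
  lin_map <- stats::setNames(lineage_of(tree$tip.label), tree$tip.label)
  missing_env <- setdiff(unique(lin_map), names(environments))
  if (length(missing_env)) {
    stop("no environment for lineage ", paste(missing_env, collapse = ", "))
  }
  pw_names <- universe_gen$pathway_names
  focal <- universe_gen$focal_role
  exclusive_roles <- lapply(universe_gen$pathway_roles,
                            function(r) setdiff(r, focal))
  all_roles <- names(universe_gen$db$role_map)

  ## descendant leaves per node
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (k in rev(seq_len(nrow(tree$edge)))) {   # postorder accumulation
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }

  pw_broken <- function(state, pw) {
    any(!(exclusive_roles[[pw]] %in% state))
  }
  states <- vector("list", nnode)
  root <- ntip + 1L
  states[[root]] <- all_roles
  for (k in seq_len(nrow(tree$edge))) {        # preorder traversal

    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]; bl <- tree$edge.length[k]
    state <- states[[p]]
    lins <- unique(lin_map[intersect(desc[[ch]], tree$tip.label)])
    deletable_pw <- pw_names[vapply(pw_names, function(pw) {
      all(vapply(lins, function(l) {
        paste0("sup_", pw, "_e") %in% environments[[l]]
      }, logical(1)))
    }, logical(1))]
    eligible <- intersect(state, unlist(exclusive_roles[deletable_pw]))
    if (length(eligible)) {
      q <- branch_loss_probability(loss_rate, bl)
      lost <- eligible[stats::runif(length(eligible)) < q]
      state <- setdiff(state, lost)
    }
    ## the focal bifunctional gene goes when both host pathways are broken
    if (focal %in% state && pw_broken(state, pw_names[1]) &&
        pw_broken(state, pw_names[2])) {
      state <- setdiff(state, focal)
    }
    states[[ch]] <- state
  }

  genomes <- list(); truth <- list()
  for (i in seq_len(ntip)) {
    leaf <- tree$tip.label[i]
    state <- states[[i]]
    lost_pw <- pw_names[vapply(pw_names, function(pw) {
      pw_broken(state, pw) ||
        (focal %in% universe_gen$pathway_roles[[pw]] && !(focal %in% state))
    }, logical(1))]
    truth[[leaf]] <- list(lineage = unname(lin_map[leaf]),
                          lost_pathways = sort(lost_pw),
                          retained_pathways = sort(setdiff(pw_names, lost_pw)),
                          focal_present = focal %in% state,
                          discordant = FALSE)
    genomes[[leaf]] <- state
  }

  if (n_discordant > 0) {
    ## eligibility needs >= 2 exclusive losses in the longer pathway so
    ## re-adding the focal gene completes neither pathway
    eligible <- character(0)
    for (leaf in tree$tip.label) {
      state <- genomes[[leaf]]
      if (focal %in% state) next
      m1 <- sum(!(exclusive_roles[[pw_names[1]]] %in% state))
      m2 <- sum(!(exclusive_roles[[pw_names[2]]] %in% state))
      if (m1 >= 2L && m2 >= 1L) eligible <- c(eligible, leaf)
    }
    if (length(eligible) < n_discordant) {
      stop("only ", length(eligible), " genomes eligible for planted ",
           "discordance (need ", n_discordant, "); increase loss_rate or ",
           "branch lengths")
    }
    planted <- sort(sample(eligible, n_discordant))
    for (leaf in planted) {
      genomes[[leaf]] <- sort(c(genomes[[leaf]], focal))
      truth[[leaf]]$focal_present <- TRUE
      truth[[leaf]]$discordant <- TRUE
    }
  }

  annotations <- lapply(tree$tip.label, function(leaf) {
    roles <- sort(c(intersect(all_roles, genomes[[leaf]]),
                    universe_gen$housekeeping_roles))
    roles <- unique(roles)
    genome_annotation(leaf, data.frame(gene_id = paste0("g_", roles),
                                       role = roles, stringsAsFactors = FALSE))
  })
  names(annotations) <- tree$tip.label

  scenario <- structure(list(universe_gen = universe_gen, tree = tree,
                             environments = environments,
                             lineage_map = lin_map,
                             genomes = annotations, truth = truth,
                             loss_rate = loss_rate, seed = seed,
                             n_discordant = n_discordant,
                             uptake_limit = uptake_limit),
                        class = "gd_scenario")
  if (validate) {
    bad <- character(0)
    for (leaf in tree$tip.label) {
      model <- build_model_from_annotation(annotations[[leaf]],
                                           universe_gen$db)
      env_med <- medium(environments[[lin_map[[leaf]]]], uptake_limit)
      st <- maximize_biomass(model, env_med)
      if (st$status != "optimal" || st$objective_value <= FEAS_TOL) {
        bad <- c(bad, leaf)
      }
    }
    if (length(bad)) {
      stop("nonviable genomes generated (cannot grow in their environment): ",
           paste(bad, collapse = ", "))
    }
  }
  scenario
}

#' Draft models for every genome of a scenario
#'
#' @param scenario a `gd_scenario`.
#' @return named list of `gd_model`.
#' @export
scenario_models <- function(scenario) {
  lapply(scenario$genomes, build_model_from_annotation,
         db = scenario$universe_gen$db)
}

#' Simulate codon evolution with clade-specific selection
#'
#' Evolves a stop-free random root sequence along a tree.  Candidate
#' point mutations arrive as a Poisson process (`mutation_rate` per
#' nucleotide site per unit branch length); mutations creating a stop
#' codon are rejected, synonymous changes are always accepted, and
#' nonsynonymous changes are accepted with the probability `omega` of
#' the clade governing the branch (the clade of its descendant leaves
#' when unanimous, otherwise `base_omega`).  No indels are introduced,
#' so the leaf sequences are a true alignment.
#'
#' @param tree a `phylo`; tip labels `<clade>_<id>`.
#' @param clade_omegas named numeric: clade -> omega in `[0, 1]`.
#' @param n_codons sequence length in codons.
#' @param mutation_rate proposed mutations per site per unit branch
#'   length.
#' @param seed RNG seed.
#' @param base_omega omega for branches not governed by a single clade.
#' @return list of class `gd_codon_sim`: the leaf `alignment`
#'   (a `gd_codon_alignment`), per-branch accepted substitution
#'   bookkeeping (`counts`), the root sequence and parameters.
#' @export
simulate_codon_evolution <- function(tree, clade_omegas, n_codons = 300,
                                     mutation_rate = 0.3, seed = 1,
                                     base_omega = 1) {
  stopifnot(inherits(tree, "phylo"), all(clade_omegas >= 0))
  tree <- stats::reorder(tree, "cladewise")
  set.seed(seed)
  code <- codon_tables()
  sense <- setdiff(code$codons, code$stops)
  nts <- c("A", "C", "G", "T")
  root_codons <- sample(sense, n_codons, replace = TRUE)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (k in rev(seq_len(nrow(tree$edge)))) {
    desc[[tree$edge[k, 1]]] <- c(desc[[tree$edge[k, 1]]], desc[[tree$edge[k, 2]]])
  }
  clade_map <- stats::setNames(lineage_of(tree$tip.label), tree$tip.label)

  seqs <- vector("list", nnode)
  seqs[[ntip + 1L]] <- root_codons
  counts <- list()
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]; bl <- tree$edge.length[k]
    s <- seqs[[p]]
    clades <- unique(clade_map[intersect(desc[[ch]], tree$tip.label)])
    om <- if (length(clades) == 1L && clades %in% names(clade_omegas)) {
      clade_omegas[[clades]]
    } else base_omega
    n_events <- stats::rpois(1, mutation_rate * 3 * n_codons * bl)
    syn_acc <- 0L; nonsyn_acc <- 0L
    if (n_events > 0) for (ev in seq_len(n_events)) {
      site <- sample.int(3L * n_codons, 1L)
      ci <- (site - 1L) %/% 3L + 1L
      pos <- (site - 1L) %% 3L + 1L
      cur <- s[ci]
      nt <- sample(setdiff(nts, substr(cur, pos, pos)), 1L)
      alt <- cur; substr(alt, pos, pos) <- nt
      if (code$aa[[alt]] == "*") next
      if (code$aa[[alt]] == code$aa[[cur]]) {
        s[ci] <- alt; syn_acc <- syn_acc + 1L
      } else if (stats::runif(1) < om) {
        s[ci] <- alt; nonsyn_acc <- nonsyn_acc + 1L
      }
    }
    seqs[[ch]] <- s
    label <- if (ch <= ntip) tree$tip.label[ch] else paste0("node", ch)
    counts[[length(counts) + 1L]] <-
      data.frame(child = label, omega = om, branch_length = bl,
                 proposed = n_events, syn = syn_acc, nonsyn = nonsyn_acc,
                 stringsAsFactors = FALSE)
  }
  leaf_seqs <- vapply(seq_len(ntip),
                      function(i) paste(seqs[[i]], collapse = ""),
                      character(1))
  names(leaf_seqs) <- tree$tip.label
  structure(list(alignment = codon_alignment(leaf_seqs),
                 counts = do.call(rbind, counts),
                 clade_map = clade_map,
                 root_sequence = paste(root_codons, collapse = ""),
                 clade_omegas = clade_omegas,
                 mutation_rate = mutation_rate, n_codons = n_codons,
                 base_omega = base_omega, seed = seed),
            class = "gd_codon_sim")
}

#' Write scenario fixtures to a directory
#'
#' Emits, in the exact formats the analysis modules consume:
#' `annotations.tsv`, `universe.json`, `tree.nwk`, `environments.json`,
#' `pathways.json`, `truth.json`, `scenario.json` (parameters), and —
#' when a codon simulation is supplied — `cds.fasta`,
#' `alignment.fasta` and `codon_truth.json`.  Output is deterministic:
#' two runs from the same seed produce byte-identical trees.
#'
#' @param scenario a `gd_scenario`.
#' @param out_dir output directory (created if needed).
#' @param codon_sim optional `gd_codon_sim`.
#' @return invisibly, the manifest (named file paths).
#' @export
emit_fixtures <- function(scenario, out_dir, codon_sim = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_annotations(scenario$genomes, p("annotations.tsv"))
  write_universe(scenario$universe_gen$db, p("universe.json"))
  ape::write.tree(scenario$tree, p("tree.nwk"))
  jsonlite::write_json(scenario$environments, p("environments.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  jsonlite::write_json(lapply(scenario$universe_gen$pathways, unclass),
                       p("pathways.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(scenario$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  params <- list(seed = scenario$seed, loss_rate = scenario$loss_rate,
                 n_discordant = scenario$n_discordant,
                 uptake_limit = scenario$uptake_limit,
                 focal_role = scenario$universe_gen$focal_role,
                 pathway_names = scenario$universe_gen$pathway_names,
                 nutrient_pathway_map =
                   as.list(scenario$universe_gen$nutrient_pathway_map),
                 housekeeping_roles = scenario$universe_gen$housekeeping_roles,
                 lineage_map = as.list(scenario$lineage_map))
  jsonlite::write_json(params, p("scenario.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- c(annotations = "annotations.tsv", universe = "universe.json",
                tree = "tree.nwk", environments = "environments.json",
                pathways = "pathways.json", truth = "truth.json",
                scenario = "scenario.json")
  if (!is.null(codon_sim)) {
    seqs <- codon_sim$alignment$sequences
    seqinr::write.fasta(lapply(seqs, function(s) strsplit(s, "")[[1]]),
                        names = names(seqs), file.out = p("cds.fasta"),
                        nbchar = 60)
    seqinr::write.fasta(lapply(seqs, function(s) strsplit(s, "")[[1]]),
                        names = names(seqs), file.out = p("alignment.fasta"),
                        nbchar = 60)
    jsonlite::write_json(list(clade_omegas = as.list(codon_sim$clade_omegas),
                              mutation_rate = codon_sim$mutation_rate,
                              n_codons = codon_sim$n_codons,
                              counts = codon_sim$counts),
                         p("codon_truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest <- c(manifest, cds = "cds.fasta", alignment = "alignment.fasta",
                  codon_truth = "codon_truth.json")
  }
  jsonlite::write_json(as.list(manifest), p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(stats::setNames(file.path(out_dir, manifest), names(manifest)))
}

#' Read emitted scenario fixtures back
#'
#' @param dir directory written by [emit_fixtures()].
#' @return list with the re-read `annotations`, `db`, `tree`,
#'   `environments`, `truth` and `params`.
#' @export
read_scenario <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(annotations = read_annotations(p("annotations.tsv")),
       db = read_universe(p("universe.json")),
       tree = ape::read.tree(p("tree.nwk")),
       environments = lapply(jsonlite::read_json(p("environments.json")),
                             function(v) unlist(v, use.names = FALSE)),
       truth = jsonlite::read_json(p("truth.json")),
       params = jsonlite::read_json(p("scenario.json")))
}

#' @export
print.gd_scenario <- function(x, ...) {
  cat("Decay scenario: ", length(x$genomes), " genomes, ",
      length(unique(x$lineage_map)), " lineages, loss rate ", x$loss_rate,
      ", seed ", x$seed, "\n", sep = "")
  lost <- vapply(x$truth, function(t) length(t$lost_pathways), integer(1))
  cat("  pathways lost per genome: ", paste(range(lost), collapse = "-"),
      "; discordant leaves: ", sum(vapply(x$truth, `[[`, logical(1),
                                          "discordant")), "\n", sep = "")
  invisible(x)
}
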