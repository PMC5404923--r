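## End-to-end orchestration: configure, simulate a decay scenario,
## build and analyze models, compare lineages, map occurrence and
## coevolution, estimate per-clade omega, and assemble a report.  All
## stages are deterministic under the configured seed.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with validation.  Threshold
#' defaults are the standard values of this analysis: BBH e-value 0.001
#' (core orthologs) and 0.01 (permissive, lineage models), core
#' prevalence 0.75, pathway completeness 0.9, growth floor 0.1 x
#' maximum biomass, zero-flux tolerance 1e-6.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir output directory for artifacts.
#' @param n_pathways,pathway_lengths universe shape (see
#'   [generate_universe()]).
#' @param lineages,n_per_lineage,loss_rate,n_discordant decay-scenario
#'   shape (see [decay_tree()] and [simulate_decay()]).
#' @param lose named list lineage -> pathways its environment lets decay;
#'   `NULL` gives a default contrast: one protected lineage, one losing
#'   the trp-like pathway, one losing both convergent pathways, one
#'   losing the trp-like plus another pathway.
#' @param evalue_core,evalue_lineage,prevalence_threshold,completeness_threshold,growth_floor_frac,epsilon,uptake_limit
#'   analysis thresholds.
#' @param clade_omegas,n_codons,mutation_rate codon-evolution settings.
#' @return list of class `gd_config`.
#' @export
pipeline_config <- function(seed = 1,
                            out_dir = tempfile("genedecay_run_"),
                            n_pathways = 4,
                            pathway_lengths = c(10, 7, 5, 4),
                            lineages = c("LI", "LII", "LIII", "LIV"),
                            n_per_lineage = 5,
                            loss_rate = 1.2,
                            n_discordant = 0,
                            lose = NULL,
                            evalue_core = 0.001,
                            evalue_lineage = 0.01,
                            prevalence_threshold = 0.75,
                            completeness_threshold = 0.9,
                            growth_floor_frac = 0.1,
                            epsilon = 1e-6,
                            uptake_limit = 10,
                            clade_omegas = c(LI = 0.09, LII = 0.06,
                                             LIII = 0.15, LIV = 0.15),
                            n_codons = 300,
                            mutation_rate = 0.35) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x <= 0 || x > 1) {
      stop("invalid config field ", nm, ": must be in (0, 1]")
    }
  }
  chk_frac(prevalence_threshold, "prevalence_threshold")
  chk_frac(completeness_threshold, "completeness_threshold")
  chk_frac(growth_floor_frac, "growth_floor_frac")
  for (nm in c("evalue_core", "evalue_lineage", "epsilon", "uptake_limit",
               "loss_rate", "mutation_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      stop("invalid config field ", nm)
    }
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    stop("invalid config field seed: must be an integer")
  }
  if (is.null(lose)) {
    pool <- c("hisL", "trpL", "metL", "serL", "thrL", "valL", "leuL", "argL",
              "lysL", "proL")[seq_len(n_pathways)]
    third <- if (n_pathways >= 3) pool[3] else pool[1]
    base <- list(c("trpL"), character(0), c("hisL", "trpL"),
                 unique(c("trpL", third)))
    lose <- stats::setNames(rep(base, length.out = length(lineages)),
                            lineages)
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_pathways = n_pathways, pathway_lengths = pathway_lengths,
                 lineages = lineages, n_per_lineage = n_per_lineage,
                 loss_rate = loss_rate, n_discordant = n_discordant,
                 lose = lose, evalue_core = evalue_core,
                 evalue_lineage = evalue_lineage,
                 prevalence_threshold = prevalence_threshold,
                 completeness_threshold = completeness_threshold,
                 growth_floor_frac = growth_floor_frac, epsilon = epsilon,
                 uptake_limit = uptake_limit, clade_omegas = clade_omegas,
                 n_codons = n_codons, mutation_rate = mutation_rate),
            class = "gd_config")
}

#' Run the gene-loss analysis pipeline
#'
#' Stages: `simulate` (universe, tree, decay scenario, codon evolution),
#' `models` (draft model per genome), `fba` (six-step analysis per
#' genome), `core` (lineage core models, overlap partitions, conserved
#' cores), `occurrence` (pathway occurrence matrix, coevolution
#' concordance, auxotrophy predictions scored against truth), `dnds`
#' (per-clade omega), `report` (JSON + markdown summary under
#' `out_dir`).
#'
#' @param config a `gd_config` from [pipeline_config()].
#' @param stages subset of stages to run (dependencies are implied:
#'   each stage runs everything it needs).
#' @param emit write fixtures and reports to `config$out_dir`.
#' @return list of class `gd_result` with all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "models", "fba", "core",
                                    "occurrence", "dnds", "report"),
                         emit = TRUE) {
  stopifnot(inherits(config, "gd_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  res <- list(config = config)

  ## simulate
  ugen <- generate_universe(config$n_pathways, config$pathway_lengths,
                            seed = config$seed)
  tree <- decay_tree(config$lineages, config$n_per_lineage,
                     seed = config$seed)
  envs <- environments_for_loss(ugen, config$lose)
  scenario <- simulate_decay(ugen, tree, envs, loss_rate = config$loss_rate,
                             seed = config$seed,
                             n_discordant = config$n_discordant,
                             uptake_limit = config$uptake_limit)
  csim <- simulate_codon_evolution(tree, config$clade_omegas,
                                   n_codons = config$n_codons,
                                   mutation_rate = config$mutation_rate,
                                   seed = config$seed)
  res$scenario <- scenario
  res$codon_sim <- csim
  if (identical(stages, "simulate")) return(finish_pipeline(res, emit))

  models <- scenario_models(scenario)
  res$models <- models

  analyses <- lapply(models, six_step_analysis,
                     uptake_limit = config$uptake_limit,
                     growth_floor_frac = config$growth_floor_frac,
                     epsilon = config$epsilon)
  res$analyses <- analyses

  ## lineage cores, overlaps, conserved cores
  by_lineage <- split(names(models), lineage_of(names(models)))
  cores <- lapply(names(by_lineage), function(lin) {
    lineage_core_model(models[by_lineage[[lin]]], ugen$db,
                       threshold = config$prevalence_threshold,
                       genome_id = paste0("core_", lin),
                       uptake_limit = config$uptake_limit)
  })
  names(cores) <- names(by_lineage)
  core_sets <- lapply(cores, gene_associated_ids)
  all_sets <- lapply(models, gene_associated_ids)
  global_core <- Reduce(intersect, all_sets)
  res$lineage_cores <- cores
  res$core_overlap <- overlap_partition(core_sets[seq_len(min(4, length(core_sets)))])
  res$core_containment <- core_containment(core_sets, global_core)
  res$global_core <- global_core

  ## occurrence + coevolution + auxotrophies
  occ <- occurrence_matrix(scenario$genomes, ugen$pathways,
                           focal_genes = c(priA = ugen$focal_role),
                           tree = tree)
  conc <- coevolution_concordance(occ, "priA",
                                  names(ugen$pathways)[1:2])
  aux <- lapply(analyses, predict_auxotrophies,
                nutrient_pathway_map = ugen$nutrient_pathway_map)
  aux_match <- vapply(names(aux), function(g) {
    identical(aux[[g]], scenario$truth[[g]]$lost_pathways)
  }, logical(1))
  res$occurrence <- occ
  res$concordance <- conc
  res$auxotrophies <- aux
  res$auxotrophy_recovery <- mean(aux_match)

  ## per-clade omega
  clades <- unique(lineage_of(tree$tip.label))
  omegas <- lapply(clades, function(cl) {
    clade_omega(csim$alignment, tree$tip.label[lineage_of(tree$tip.label) == cl])
  })
  names(omegas) <- clades
  res$clade_omegas <- omegas

  finish_pipeline(structure(res, class = "gd_result"), emit)
}

finish_pipeline <- function(res, emit) {
  res <- structure(res, class = "gd_result")
  if (!emit) return(res)
  config <- res$config
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  emit_fixtures(res$scenario, file.path(config$out_dir, "fixtures"),
                codon_sim = res$codon_sim)
  if (!is.null(res$analyses)) {
    report <- pipeline_report(res)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report_markdown(report), file.path(config$out_dir, "report.md"))
  }
  res
}

pipeline_report <- function(res) {
  analyses <- res$analyses
  list(
    seed = res$config$seed,
    genomes = lapply(analyses, function(a) {
      list(minimal_medium = a$minimal_medium$medium$nutrients,
           n_nutrients = length(a$minimal_medium$medium$nutrients),
           max_biomass_complete = a$max_biomass_complete,
           class_counts = as.list(table(a$classes)))
    }),
    lineage_cores = lapply(res$lineage_cores, function(m) {
      list(n_reactions = length(m$reactions),
           n_gene_associated = length(gene_associated_ids(m)),
           n_gapfilled = attr(m, "gapfill")$objective_cost)
    }),
    core_overlap = as.list(res$core_overlap),
    global_core_size = length(res$global_core),
    core_containment = res$core_containment,
    occurrence = apply(unclass(res$occurrence), 1, as.list),
    concordance = res$concordance$concordance,
    auxotrophy_recovery = res$auxotrophy_recovery,
    clade_omegas = lapply(res$clade_omegas, function(o) {
      list(dN = o$dN, dS = o$dS, omega = o$omega, n_pairs = o$n_pairs)
    }))
}

report_markdown <- function(rep) {
  c("# Gene-loss pipeline report",
    "",
    paste0("Seed: ", rep$seed),
    "",
    "## Genomes",
    vapply(names(rep$genomes), function(g) {
      x <- rep$genomes[[g]]
      paste0("- ", g, ": ", x$n_nutrients, " minimal nutrients; classes ",
             paste(names(x$class_counts), unlist(x$class_counts),
                   sep = "=", collapse = ", "))
    }, character(1)),
    "",
    "## Lineage cores",
    vapply(names(rep$lineage_cores), function(l) {
      x <- rep$lineage_cores[[l]]
      paste0("- ", l, ": ", x$n_gene_associated, " gene-associated reactions, ",
             x$n_gapfilled, " gapfilled")
    }, character(1)),
    "",
    paste0("Global conserved core: ", rep$global_core_size, " reactions; ",
           "mean lineage-core containment ",
           format(rep$core_containment$mean, digits = 4)),
    "",
    paste0("Focal-gene/pathway concordance: ",
           format(rep$concordance, digits = 4),
           "; auxotrophy recovery vs truth: ",
           format(rep$auxotrophy_recovery, digits = 4)),
    "",
    "## Per-clade dN/dS",
    vapply(names(rep$clade_omegas), function(cl) {
      x <- rep$clade_omegas[[cl]]
      paste0("- ", cl, ": dN = ", format(x$dN, digits = 4), ", dS = ",
             format(x$dS, digits = 4), ", omega = ",
             format(x$omega, digits = 4), " (", x$n_pairs, " pairs)")
    }, character(1)))
}

#' @export
print.gd_result <- function(x, ...) {
  cat("Gene-loss pipeline result (seed ", x$config$seed, ")\n", sep = "")
  if (!is.null(x$analyses)) {
    cat("  genomes analyzed: ", length(x$analyses), "\n", sep = "")
    cat("  concordance: ", format(x$concordance$concordance, digits = 4),
        "; auxotrophy recovery: ",
        format(x$auxotrophy_recovery, digits = 4), "\n", sep = "")
  }
  invisible(x)
}
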