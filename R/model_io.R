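## Readers and writers.  Models travel in a line-typed TSV dialect that
## keeps fixtures hand-writable, or an equivalent JSON schema; genome
## annotations and media are plain TSV; the universal database is JSON.
##
## Model TSV dialect (tab-separated, one record per line):
##   !model <genome_id> <biomass_reaction_id>
##   !met   <id> <name> <compartment>
##   !rxn   <id> <stoichiometry> <lb> <ub> <gpr> <gapfilled> <exchange>
## Stoichiometry is "coef:met_id" terms joined by ";".  GPR strings are
## disjunctions of single genes or parenthesized conjunctive pairs, e.g.
## "gA or (gB and gC)"; deeper nesting is rejected.  Writers emit
## canonical order (lexicographic by id), so write(read(f)) is
## byte-identical to a canonical file.

gpr_to_string <- function(gpr) {
  if (!length(gpr)) return("")
  terms <- vapply(gpr, function(term) {
    if (length(term) == 1L) term
    else paste0("(", paste(term, collapse = " and "), ")")
  }, character(1))
  paste(terms, collapse = " or ")
}

parse_gpr <- function(s, where = "") {
  s <- trimws(s)
  if (!nzchar(s)) return(list())
  terms <- trimws(strsplit(s, " or ", fixed = TRUE)[[1]])
  lapply(terms, function(term) {
    if (grepl("^\\(.*\\)$", term)) {
      inner <- trimws(sub("^\\((.*)\\)$", "\\1", term))
      genes <- trimws(strsplit(inner, " and ", fixed = TRUE)[[1]])
      if (length(genes) != 2L || any(grepl("[()]", genes)) ||
          any(grepl(" ", genes))) {
        stop("unsupported gene association ", where, ": '", term,
             "' (only single genes or conjunctive pairs)")
      }
      genes
    } else {
      if (grepl("[() ]", term)) {
        stop("unsupported gene association ", where, ": '", term, "'")
      }
      term
    }
  })
}

format_num <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15),
         character(1))
}

stoich_to_string <- function(st) {
  paste(paste0(format_num(unname(st)), ":", names(st)), collapse = ";")
}

parse_stoich <- function(s, line_no) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  if (!length(parts) || !nzchar(trimws(s))) {
    stop("line ", line_no, ": empty stoichiometry")
  }
  coef <- numeric(0)
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L || is.na(suppressWarnings(as.numeric(kv[1]))) ||
        !nzchar(kv[2])) {
      stop("line ", line_no, ": malformed stoichiometry term '", p, "'")
    }
    coef[kv[2]] <- as.numeric(kv[1])
  }
  coef
}

#' Read a stoichiometric model
#'
#' @param path file path.
#' @param format `"tsv"` (line-typed dialect, see package docs) or
#'   `"json"`.
#' @return a validated `gd_model`.
#' @export
read_model <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") return(model_from_list(jsonlite::read_json(path)))
  lines <- readLines(path)
  genome_id <- NULL; biomass <- NULL
  mets <- list(); rxns <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tag <- f[1]
    if (tag == "!model") {
      if (length(f) != 3L) stop("line ", i, ": !model needs genome id and biomass id")
      genome_id <- f[2]; biomass <- f[3]
    } else if (tag == "!met") {
      if (length(f) != 4L) stop("line ", i, ": !met needs id, name, compartment")
      mets[[length(mets) + 1L]] <- metabolite(f[2], f[3], f[4])
    } else if (tag == "!rxn") {
      if (length(f) != 8L) stop("line ", i, ": !rxn needs 7 fields")
      rxns[[length(rxns) + 1L]] <- reaction(
        id = f[2],
        stoichiometry = parse_stoich(f[3], i),
        lower_bound = as.numeric(f[4]),
        upper_bound = as.numeric(f[5]),
        gene_association = parse_gpr(f[6], paste0("(line ", i, ")")),
        gapfilled = f[7] == "1",
        is_exchange = f[8] == "1")
    } else {
      stop("line ", i, ": unknown record type '", tag, "'")
    }
  }
  if (is.null(genome_id)) stop("missing !model line")
  stoichiometric_model(genome_id, do.call(rbind, mets), rxns, biomass)
}

#' Write a stoichiometric model
#'
#' Output is deterministic: metabolites and reactions sorted by id.
#'
#' @param model a valid `gd_model`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_model <- function(model, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  v <- validate_model(model)
  if (length(v)) stop("refusing to write invalid model: ", v[1])
  if (!length(model$reactions)) stop("refusing to write model with no reactions")
  if (format == "json") {
    jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  lines <- paste("!model", model$genome_id, model$biomass_reaction_id,
                 sep = "\t")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, paste("!met", m$id, m$name, m$compartment, sep = "\t"))
  }
  for (r in model$reactions) {
    lines <- c(lines, paste("!rxn", r$id, stoich_to_string(r$stoichiometry),
                            format_num(r$lower_bound), format_num(r$upper_bound),
                            gpr_to_string(r$gene_association),
                            if (r$gapfilled) "1" else "0",
                            if (r$is_exchange) "1" else "0", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

model_to_list <- function(model) {
  list(genome_id = model$genome_id,
       biomass_reaction_id = model$biomass_reaction_id,
       metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
         as.list(model$metabolites[i, c("id", "name", "compartment")])
       }),
       reactions = lapply(unname(model$reactions), reaction_to_list))
}

reaction_to_list <- function(r) {
  list(id = r$id,
       stoichiometry = as.list(r$stoichiometry),
       lower_bound = r$lower_bound, upper_bound = r$upper_bound,
       gene_association = lapply(r$gene_association, as.list),
       gapfilled = r$gapfilled, is_exchange = r$is_exchange)
}

reaction_from_list <- function(x) {
  reaction(id = x$id,
           stoichiometry = unlist(x$stoichiometry),
           lower_bound = x$lower_bound, upper_bound = x$upper_bound,
           gene_association = lapply(x$gene_association,
                                     function(t) unlist(t, use.names = FALSE)),
           gapfilled = isTRUE(x$gapfilled),
           is_exchange = isTRUE(x$is_exchange))
}

model_from_list <- function(x) {
  mets <- do.call(rbind, lapply(x$metabolites, function(m) {
    metabolite(m$id, m$name, m$compartment)
  }))
  stoichiometric_model(x$genome_id, mets,
                       lapply(x$reactions, reaction_from_list),
                       x$biomass_reaction_id)
}

#' Read genome annotations from TSV
#'
#' Expects a header line `genome_id<TAB>gene_id<TAB>role`.
#'
#' @param path TSV path.
#' @return named list of `gd_annotation`, one per genome.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("genome_id", "gene_id", "role") %in% names(tab)))
  out <- lapply(split(tab, tab$genome_id), function(d) {
    genome_annotation(d$genome_id[1],
                      data.frame(gene_id = d$gene_id, role = d$role,
                                 stringsAsFactors = FALSE))
  })
  out[sort(names(out))]
}

#' Write genome annotations to TSV
#'
#' @param annotations list of `gd_annotation`.
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    data.frame(genome_id = a$genome_id, gene_id = a$genes$gene_id,
               role = a$genes$role, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[order(vapply(annotations, `[[`, character(1),
                                          "genome_id"))])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a universal reaction database (JSON)
#'
#' @param path JSON path.
#' @return a `gd_universe`.
#' @export
read_universe <- function(path) {
  x <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(x$metabolites, function(m) {
    metabolite(m$id, m$name, m$compartment)
  }))
  universal_database(
    metabolites = mets,
    reactions = lapply(x$reactions, reaction_from_list),
    role_map = lapply(x$role_map, function(v) unlist(v, use.names = FALSE)),
    transportable = unlist(x$transportable, use.names = FALSE),
    biomass_reaction_id = x$biomass_reaction_id)
}

#' @rdname read_universe
#' @param db a `gd_universe`.
#' @export
write_universe <- function(db, path) {
  x <- list(metabolites = lapply(seq_len(nrow(db$metabolites)), function(i) {
              as.list(db$metabolites[i, c("id", "name", "compartment")])
            }),
            reactions = lapply(unname(db$reactions), reaction_to_list),
            role_map = db$role_map,
            transportable = db$transportable,
            biomass_reaction_id = db$biomass_reaction_id)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a medium as a nutrient list (TSV)
#'
#' @param path TSV path with columns `nutrient` and `uptake_limit`.
#' @return a `gd_medium`.
#' @export
read_medium <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  medium(tab$nutrient, if (nrow(tab)) tab$uptake_limit[1] else 10)
}

#' @rdname read_medium
#' @param med a `gd_medium`.
#' @export
write_medium <- function(med, path) {
  tab <- data.frame(nutrient = med$nutrients,
                    uptake_limit = rep(med$uptake_limit,
                                       length(med$nutrients)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
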