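## Codon-level utilities: genetic code tables, codon alignments, and
## back-translation of protein alignments onto coding sequences.

.gd <- new.env(parent = emptyenv())

## standard genetic code tables, built once per session from seqinr
codon_tables <- function() {
  if (!is.null(.gd$code)) return(.gd$code)
  nts <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(tolower(cd), "")[[1]])
  }, character(1))
  .gd$code <- list(codons = codons, aa = aa,
                   stops = codons[aa == "*"])
  .gd$code
}

translate_codons <- function(codons) {
  code <- codon_tables()
  unname(code$aa[codons])
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Create a codon alignment
#'
#' Validates that all sequences have equal length divisible by three,
#' that gaps occur only as whole `---` triplets, and that no sequence
#' contains an internal stop codon.
#'
#' @param sequences named character vector of aligned nucleotide
#'   sequences (gaps as `-`).
#' @return a list of class `gd_codon_alignment` with the sequences and
#'   the alignment length in codons.
#' @export
codon_alignment <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 2L,
            !is.null(names(sequences)))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("aligned sequences differ in length")
  if (lens[1] %% 3L != 0L) stop("alignment length not divisible by 3")
  code <- codon_tables()
  for (tx in names(sequences)) {
    codons <- split_codons(sequences[[tx]])
    partial_gap <- grepl("-", codons) & codons != "---"
    if (any(partial_gap)) {
      stop("taxon ", tx, ": gaps are not codon-aligned at codon ",
           which(partial_gap)[1])
    }
    stops <- codons %in% code$stops
    if (any(stops)) {
      stop("taxon ", tx, ": internal stop codon at codon ", which(stops)[1])
    }
  }
  structure(list(sequences = toupper(sequences),
                 n_codons = lens[1] %/% 3L),
            class = "gd_codon_alignment")
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Places each taxon's codons under its aligned residues; protein gaps
#' become `---` triplets.  Every coding sequence must translate exactly
#' to its ungapped protein row (a terminal stop codon is tolerated and
#' dropped).
#'
#' @param protein_alignment named character vector of aligned amino-acid
#'   sequences (gaps as `-`).
#' @param cds named character vector of in-frame nucleotide coding
#'   sequences, names matching the alignment.
#' @return a `gd_codon_alignment`.
#' @export
backtranslate_alignment <- function(protein_alignment, cds) {
  stopifnot(is.character(protein_alignment), !is.null(names(protein_alignment)))
  missing <- setdiff(names(protein_alignment), names(cds))
  if (length(missing)) {
    stop("no coding sequence for taxon ", paste(missing, collapse = ", "))
  }
  out <- character(0)
  for (tx in names(protein_alignment)) {
    prot <- toupper(protein_alignment[[tx]])
    residues <- strsplit(prot, "")[[1]]
    codons <- split_codons(cds[[tx]])
    aa <- translate_codons(codons)
    if (length(aa) && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    ungapped <- residues[residues != "-"]
    if (length(aa) != length(ungapped)) {
      stop("taxon ", tx, ": coding sequence has ", length(aa),
           " codons but the protein row has ", length(ungapped), " residues")
    }
    mismatch <- which(aa != ungapped)
    if (length(mismatch)) {
      stop("taxon ", tx, ": translation mismatch at residue ", mismatch[1],
           " (codon ", codons[mismatch[1]], " -> ", aa[mismatch[1]],
           ", protein has ", ungapped[mismatch[1]], ")")
    }
    placed <- character(length(residues))
    placed[residues == "-"] <- "---"
    placed[residues != "-"] <- codons
    out[[tx]] <- paste(placed, collapse = "")
  }
  codon_alignment(out)
}
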