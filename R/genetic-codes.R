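# Genetic-code tables and the synonymous-family structure that every
# downstream codon-usage statistic depends on.

#' All 64 codons in the DNA alphabet
#'
#' Codons are represented internally with T (DNA), matching FASTA input;
#' rendering functions may print the RNA form (U).
#'
#' @return Character vector of the 64 codons in alphabetical order.
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
}

# cache: building the family structure is cheap but called everywhere
.code_cache <- new.env(parent = emptyenv())

#' Construct a genetic code with its synonymous-family structure
#'
#' Supported tables are the NCBI translation tables used for ciliate nuclear
#' genomes: 1 (standard), 6 (ciliate/hypotrich nuclear: TAA/TAG encode Gln,
#' TGA is the only stop) and 10 (euplotid nuclear: TGA encodes Cys).
#'
#' @param table_id Integer, one of 1, 6, 10.
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `codon_to_aa` (named character over all 64 codons, `"*"` for stop),
#'   `stop_codons`, and `families`, a list of synonymous families each holding
#'   `amino_acid`, `codons` and `degeneracy`. Families partition the sense
#'   codons; degeneracy is the family size (1 to 6).
#' @examples
#' code <- genetic_code(6)
#' code$codon_to_aa[["TAA"]]  # "Q": glutamine in the ciliate nuclear code
#' @export
genetic_code <- function(table_id) {
  if (length(table_id) != 1L || !is.numeric(table_id) ||
      !table_id %in% c(1, 6, 10)) {
    stop("unsupported genetic code table '", paste(table_id, collapse = ","),
         "'; supported table ids: 1 (standard), 6 (ciliate nuclear), ",
         "10 (euplotid nuclear)", call. = FALSE)
  }
  key <- as.character(as.integer(table_id))
  if (!is.null(.code_cache[[key]])) return(.code_cache[[key]])

  codon_to_aa <- Biostrings::getGeneticCode(key)
  codon_to_aa <- codon_to_aa[all_codons()]
  stops <- names(codon_to_aa)[codon_to_aa == "*"]
  sense <- names(codon_to_aa)[codon_to_aa != "*"]
  fam_split <- split(sense, codon_to_aa[sense])
  families <- lapply(sort(names(fam_split)), function(aa) {
    cods <- sort(fam_split[[aa]])
    list(amino_acid = aa, codons = cods, degeneracy = length(cods))
  })
  code <- structure(
    list(table_id = as.integer(table_id), codon_to_aa = codon_to_aa,
         stop_codons = stops, families = families),
    class = "genetic_code")
  .code_cache[[key]] <- code
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (NCBI translation table ", x$table_id, ")\n", sep = "")
  cat("  stop codons: ", paste(x$stop_codons, collapse = ", "), "\n", sep = "")
  cat("  ", length(x$families), " synonymous families over ",
      sum(vapply(x$families, `[[`, 1L, "degeneracy")), " sense codons\n",
      sep = "")
  invisible(x)
}

#' Sense codons of a genetic code
#'
#' @param code A `genetic_code`.
#' @param min_degeneracy Keep only codons whose family has at least this many
#'   members (2 restricts to synonymously variable codons, the set over which
#'   GC3s, X3s and RSCU are defined).
#' @return Character vector of codons.
#' @export
sense_codons <- function(code, min_degeneracy = 1L) {
  fams <- code$families[vapply(code$families, `[[`, 1L, "degeneracy") >=
                          min_degeneracy]
  sort(unlist(lapply(fams, `[[`, "codons"), use.names = FALSE))
}

#' Per-codon degeneracy of a genetic code
#'
#' @param code A `genetic_code`.
#' @return Named integer vector over sense codons giving the size of each
#'   codon's synonymous family.
#' @export
codon_degeneracy <- function(code) {
  out <- unlist(lapply(code$families, function(f) {
    stats::setNames(rep.int(f$degeneracy, f$degeneracy), f$codons)
  }))
  out[sort(names(out))]
}

#' Census of synonymous families by degeneracy level
#'
#' Counts how many families sit at each degeneracy level; these counts feed
#' the class averages of Wright's ENC. For the standard code the census is
#' 2/9/1/5/3 families at degeneracy 1/2/3/4/6.
#'
#' @param code A `genetic_code`.
#' @return Named integer vector, names are degeneracy levels.
#' @export
degeneracy_classes <- function(code) {
  degs <- vapply(code$families, `[[`, 1L, "degeneracy")
  tab <- table(degs)
  stats::setNames(as.integer(tab), names(tab))
}

#' Translate an in-frame coding sequence
#'
#' @param seq A DNA string with length a multiple of 3.
#' @param code A `genetic_code`.
#' @return Single amino-acid string (`*` marks stops).
#' @export
translate_cds <- function(seq, code) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
  cods <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(code$codon_to_aa[cods], collapse = "")
}

# internal: split a sequence into in-frame codons
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# internal: reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# internal: per-sense-codon lookup table used by the statistics layer.
# One row per sense codon: amino acid, family index, degeneracy, third base,
# GC fraction of the first two bases.
codon_table <- function(code) {
  key <- paste0("tab", code$table_id)
  if (!is.null(.code_cache[[key]])) return(.code_cache[[key]])
  rows <- do.call(rbind, lapply(seq_along(code$families), function(i) {
    f <- code$families[[i]]
    data.frame(codon = f$codons, amino_acid = f$amino_acid, family = i,
               degeneracy = f$degeneracy, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$codon), , drop = FALSE]
  rownames(rows) <- rows$codon
  rows$third <- substr(rows$codon, 3L, 3L)
  b1 <- substr(rows$codon, 1L, 1L) %in% c("G", "C")
  b2 <- substr(rows$codon, 2L, 2L) %in% c("G", "C")
  rows$gc12 <- (b1 + b2) / 2
  .code_cache[[key]] <- rows
  rows
}
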