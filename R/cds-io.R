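# FASTA input/output for coding-sequence sets.
#
# A CDS set is a plain data.frame with columns `id`, `seq` (uppercase DNA)
# and `species`; every stage of the package consumes and produces this shape.

#' Read a coding-sequence FASTA file
#'
#' The first whitespace-delimited token of each header becomes the record id;
#' sequences are uppercased. Record order is preserved.
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @param species Species label attached to every record.
#' @return data.frame with columns `id`, `seq`, `species`.
#' @export
read_cds_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(data.frame(id = character(), seq = character(),
                      species = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1L],
         " does not start a record ('>') in ", path, call. = FALSE)
  }
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, seq = toupper(as.character(x)),
             species = rep(species, length(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a coding-sequence set as FASTA
#'
#' @param cds data.frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(cds$seq, cds$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
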