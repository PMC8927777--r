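# Quality filtering of coding sequences ahead of codon-usage analysis.

#' Filter a CDS set down to "perfect" coding sequences
#'
#' Keeps sequences that (i) contain no ambiguous base, (ii) have length an
#' exact multiple of 3, (iii) start with ATG, (iv) end with one of the
#' universal stop triplets TAA/TAG/TGA (the terminal-stop rule is applied with
#' this fixed set regardless of `code`, since ciliate CDS records conventionally
#' end in one of them even where the table reassigns it), (v) contain no
#' internal stop codon of `code` (or have such codons excised, see
#' `internal_stop_mode`), (vi) are strictly longer than `min_len` nucleotides
#' after any excision, and (vii) are not an exact duplicate, nor an exact
#' reverse complement, of an earlier record (first occurrence kept).
#'
#' Each rejected record gets exactly one reason, assigned in the fixed order
#' `AMBIGUOUS_BASE`, `DUPLICATE`, `REVCOMP_DUPLICATE`, `NOT_TRIPLET`,
#' `BAD_START`, `BAD_STOP`, `INTERNAL_STOP`, `TOO_SHORT`. Ambiguity is
#' checked first because a record with N cannot be assessed codon-wise;
#' duplicate removal is collection cleanup and runs on the raw sequences
#' before the structural rules (a reverse-complement copy of a valid CDS
#' would otherwise always surface as `BAD_START`, hiding its real origin).
#'
#' @param cds data.frame with columns `id`, `seq` (and optionally `species`).
#' @param code A [genetic_code()] providing the internal-stop set.
#' @param min_len Minimum length in nucleotides (strictly greater-than);
#'   must be a multiple of 3.
#' @param internal_stop_mode `"reject"` discards sequences with an internal
#'   stop codon of `code`; `"delete_codon"` excises those codons in frame and
#'   keeps the sequence, logging the event.
#' @return List with `kept` (filtered data.frame, processed sequences) and
#'   `report`, a `cds_filter_report`: `n_input`, `n_kept`, `rejections`
#'   (data.frame id/reason) and `internal_stop_deletions` (id/n_removed).
#' @examples
#' code <- genetic_code(1)
#' good <- paste0("ATG", strrep("AAA", 100), "TAA")
#' filter_cds(data.frame(id = "g1", seq = good), code)$report
#' @export
filter_cds <- function(cds, code, min_len = 300L,
                       internal_stop_mode = c("reject", "delete_codon")) {
  internal_stop_mode <- match.arg(internal_stop_mode)
  if (min_len %% 3L != 0L) {
    stop("min_len must be a multiple of 3, got ", min_len, call. = FALSE)
  }
  n_input <- nrow(cds)
  kept_idx <- integer(0)
  seen_seq <- character(0)
  seen_rc <- character(0)
  rej_id <- character(0)
  rej_reason <- character(0)
  del_id <- character(0)
  del_n <- integer(0)
  processed <- character(n_input)

  universal_stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(n_input)) {
    s <- cds$seq[i]
    reason <- NULL
    if (grepl("[^ACGT]", s)) {
      reason <- "AMBIGUOUS_BASE"
    } else if (s %in% seen_seq) {
      reason <- "DUPLICATE"
    } else if (s %in% seen_rc) {
      reason <- "REVCOMP_DUPLICATE"
    } else if (nchar(s) %% 3L != 0L || nchar(s) < 3L) {
      reason <- "NOT_TRIPLET"
    } else if (substr(s, 1L, 3L) != "ATG") {
      reason <- "BAD_START"
    } else if (!substr(s, nchar(s) - 2L, nchar(s)) %in% universal_stops) {
      reason <- "BAD_STOP"
    } else {
      cods <- split_codons(s)
      internal <- cods[-length(cods)] %in% code$stop_codons
      if (any(internal)) {
        if (internal_stop_mode == "reject") {
          reason <- "INTERNAL_STOP"
        } else {
          body <- cods[-length(cods)][!internal]
          s <- paste0(paste(body, collapse = ""), cods[length(cods)])
          del_id <- c(del_id, cds$id[i])
          del_n <- c(del_n, sum(internal))
        }
      }
      if (is.null(reason) && nchar(s) <= min_len) {
        reason <- "TOO_SHORT"
      }
    }
    if (!grepl("[^ACGT]", cds$seq[i])) {
      seen_seq <- c(seen_seq, cds$seq[i])
      seen_rc <- c(seen_rc, revcomp(cds$seq[i]))
    }
    if (is.null(reason)) {
      kept_idx <- c(kept_idx, i)
      processed[i] <- s
    } else {
      rej_id <- c(rej_id, cds$id[i])
      rej_reason <- c(rej_reason, reason)
    }
  }

  kept <- cds[kept_idx, , drop = FALSE]
  kept$seq <- processed[kept_idx]
  rownames(kept) <- NULL
  report <- structure(
    list(n_input = n_input, n_kept = length(kept_idx),
         rejections = data.frame(id = rej_id, reason = rej_reason,
                                 stringsAsFactors = FALSE),
         internal_stop_deletions = data.frame(id = del_id, n_removed = del_n,
                                              stringsAsFactors = FALSE)),
    class = "cds_filter_report")
  list(kept = kept, report = report)
}

#' @export
print.cds_filter_report <- function(x, ...) {
  cat("CDS filter report: kept ", x$n_kept, " of ", x$n_input,
      " records\n", sep = "")
  if (nrow(x$rejections)) {
    tab <- table(x$rejections$reason)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  if (nrow(x$internal_stop_deletions)) {
    cat("  internal stop codons excised from ",
        nrow(x$internal_stop_deletions), " sequence(s)\n", sep = "")
  }
  invisible(x)
}
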