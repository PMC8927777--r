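# CRISPR/Cas9 support: SpCas9 NGG PAM / guide-site scanning and
# optimal-codon-driven synonymous rewriting of a coding sequence.

#' Scan a sequence for SpCas9 guide sites (20-nt protospacer + NGG PAM)
#'
#' Reports every position where a 20-nt window is immediately followed by an
#' NGG triplet, on the + strand and, by default, on the reverse complement.
#' Overlapping sites are all reported. Windows containing an ambiguous base
#' are skipped (a message reports how many). For minus-strand sites, `start`
#' is the 0-based plus-strand position of the protospacer's leftmost base
#' while `protospacer` and `pam` are given in minus-strand orientation.
#'
#' @param seq DNA string (length >= 23 for any hit).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return data.frame with columns `start` (0-based), `strand` (`"+"`/`"-"`),
#'   `protospacer` (20 nt) and `pam` (3 nt, `[ACGT]GG`), sorted by
#'   plus-strand coordinate then strand.
#' @examples
#' scan_pam_sites("CTACATCAAGTTCATCGAAAAGG", both_strands = FALSE)
#' @export
scan_pam_sites <- function(seq, both_strands = TRUE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- data.frame(start = integer(), strand = character(),
                      protospacer = character(), pam = character(),
                      stringsAsFactors = FALSE)
  scan_one <- function(s) {
    if (L < 23L) return(list(hits = empty, skipped = 0L))
    starts <- seq_len(L - 22L)
    win <- substring(s, starts, starts + 22L)
    has_n <- grepl("[^ACGT]", win)
    pam <- substring(s, starts + 20L, starts + 22L)
    ok <- !has_n & substr(pam, 2L, 3L) == "GG"
    skipped <- sum(has_n & substr(pam, 2L, 3L) == "GG")
    list(hits = data.frame(start0 = starts[ok] - 1L,
                           protospacer = substring(s, starts, starts + 19L)[ok],
                           pam = pam[ok], stringsAsFactors = FALSE),
         skipped = skipped)
  }
  plus <- scan_one(seq)
  res <- if (nrow(plus$hits)) {
    data.frame(start = plus$hits$start0, strand = "+",
               protospacer = plus$hits$protospacer, pam = plus$hits$pam,
               stringsAsFactors = FALSE)
  } else empty
  skipped <- plus$skipped
  if (both_strands) {
    minus <- scan_one(revcomp(seq))
    skipped <- skipped + minus$skipped
    if (nrow(minus$hits)) {
      res <- rbind(res, data.frame(
        start = L - minus$hits$start0 - 20L, strand = "-",
        protospacer = minus$hits$protospacer, pam = minus$hits$pam,
        stringsAsFactors = FALSE))
    }
  }
  if (skipped > 0L) {
    message(skipped, " candidate window(s) containing ambiguous bases skipped")
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tally PAM triplets over a set of guide sites
#'
#' @param sites data.frame from [scan_pam_sites()].
#' @return Named integer vector of counts per observed PAM triplet; the sum
#'   equals the number of sites.
#' @export
classify_pams <- function(sites) {
  if (nrow(sites) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(sites$pam)
  stats::setNames(as.integer(tab), names(tab))
}

# internal: resolve an optimal-codon specification to an aa -> codon map
resolve_preference <- function(optimal, code) {
  tab <- codon_table(code)
  if (inherits(optimal, "optimal_codon_report")) {
    cods <- optimal$optimal
    if (length(cods) == 0L) return(stats::setNames(character(0), character(0)))
    delta <- optimal$delta_rscu[cods]
    aa <- tab[cods, "amino_acid"]
    # several optimal codons in one family: keep the one with largest delta
    pick <- tapply(seq_along(cods), aa, function(ix) {
      ix[order(-delta[ix], cods[ix])][1]
    })
    return(stats::setNames(cods[pick], names(pick)))
  }
  cods <- unname(unlist(optimal))
  bad <- setdiff(cods, tab$codon)
  if (length(bad)) {
    stop("not a sense codon under this code: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  aa <- tab[cods, "amino_acid"]
  if (!is.null(names(optimal)) && any(nzchar(names(optimal)))) {
    declared <- names(optimal)
    wrong <- declared != aa
    if (any(wrong)) {
      stop("codon(s) named for the wrong synonymous family: ",
           paste0(cods[wrong], " (declared ", declared[wrong], ", is ",
                  aa[wrong], ")", collapse = "; "), call. = FALSE)
    }
  }
  if (anyDuplicated(aa)) {
    stop("preference table maps more than one target codon to amino acid ",
         paste(unique(aa[duplicated(aa)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(cods, aa)
}

#' Rewrite a coding sequence with optimal codons
#'
#' Synonymously replaces every codon whose amino acid has a designated
#' optimal codon (and which is not already that codon) by the optimal one.
#' The amino-acid sequence is invariant by construction; the start codon and
#' the terminal stop codon are never edited. Applying the rewrite twice
#' equals applying it once.
#'
#' @param cds DNA string: an in-frame CDS (length a multiple of 3).
#' @param optimal Either an `optimal_codon_report` (several optimal codons in
#'   one family resolve to the one with largest delta-RSCU) or a character
#'   vector of target codons, at most one per synonymous family; if the
#'   vector is named, names must be the matching amino-acid letters.
#' @param code A [genetic_code()].
#' @return List with `seq` (rewritten CDS) and `edits`, a data.frame with
#'   `codon_index` (0-based), `old_codon`, `new_codon`, `amino_acid`, in
#'   sequence order.
#' @examples
#' out <- optimize_codons("ATGGGTTTTTAA", c(G = "GGA"), genetic_code(1))
#' out$edits  # GGT -> GGA at codon index 1
#' @export
optimize_codons <- function(cds, optimal, code) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L || nchar(cds) < 6L) {
    stop("cds must be an in-frame CDS (length a multiple of 3, >= 2 codons)",
         call. = FALSE)
  }
  pref <- resolve_preference(optimal, code)
  cods <- split_codons(cds)
  n <- length(cods)
  edits <- data.frame(codon_index = integer(), old_codon = character(),
                      new_codon = character(), amino_acid = character(),
                      stringsAsFactors = FALSE)
  if (length(pref) && n > 2L) {
    body <- seq.int(2L, n - 1L)  # never the start, never the terminal stop
    aa <- code$codon_to_aa[cods[body]]
    target <- pref[aa]
    change <- !is.na(target) & target != cods[body]
    if (any(change)) {
      idx <- body[change]
      edits <- data.frame(codon_index = idx - 1L, old_codon = cods[idx],
                          new_codon = unname(target[change]),
                          amino_acid = unname(aa[change]),
                          stringsAsFactors = FALSE)
      cods[idx] <- target[change]
    }
  }
  list(seq = paste(cods, collapse = ""), edits = edits)
}
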