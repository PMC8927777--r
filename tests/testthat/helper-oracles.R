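# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package internals: the ENC oracle walks the family
# list step by step, the PAM oracle slides a character-level window.

oracle_enc <- function(counts, code) {
  degs <- vapply(code$families, `[[`, 1L, "degeneracy")
  n1 <- sum(degs == 1L)
  n_sense <- sum(degs)
  rows <- lapply(code$families[degs >= 2L], function(f) {
    cnt <- counts[f$codons]
    n <- sum(cnt)
    if (n < 2) return(c(k = f$degeneracy, f = NA_real_))
    p <- cnt / n
    fh <- (n * sum(p^2) - 1) / (n - 1)
    if (fh <= 1e-12) fh <- NA_real_  # F <= 0 up to rounding
    c(k = f$degeneracy, f = fh)
  })
  m <- do.call(rbind, rows)
  ks <- sort(unique(m[, "k"]))
  cls <- vapply(ks, function(k) {
    v <- m[m[, "k"] == k, "f"]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 1)
  names(cls) <- ks
  if ("3" %in% names(cls) && is.na(cls[["3"]]) &&
      all(c("2", "4") %in% names(cls))) {
    cls[["3"]] <- (cls[["2"]] + cls[["4"]]) / 2
  }
  nk <- vapply(ks, function(k) sum(m[, "k"] == k), 1)
  val <- n1 + sum(nk / cls)
  if (is.na(val)) return(NA_real_)
  min(max(val, 2), n_sense)
}

oracle_pam_count <- function(seq, both_strands = TRUE) {
  strands <- if (both_strands) {
    c(seq, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))))
  } else {
    seq
  }
  hits <- 0L
  for (s in strands) {
    L <- nchar(s)
    if (L < 23L) next
    for (i in 1:(L - 22L)) {
      w <- substr(s, i, i + 22L)
      if (grepl("[^ACGT]", w)) next
      if (substr(w, 22L, 23L) == "GG") hits <- hits + 1L
    }
  }
  hits
}

# random codon-count vector for a gene: skewed synonymous usage
random_gene_counts <- function(code, n_codons = sample(50:400, 1)) {
  sense <- sense_codons(code)
  w <- stats::rexp(length(sense))
  draws <- sample(sense, n_codons, replace = TRUE, prob = w)
  cnt <- stats::setNames(numeric(64), all_codons())
  tab <- table(draws)
  cnt[names(tab)] <- as.numeric(tab)
  cnt
}

# a random valid CDS (passes filter_cds in strict mode under `code`)
random_valid_cds <- function(code, n_body = 120L) {
  sense <- sense_codons(code)
  body <- sample(sense, n_body, replace = TRUE)
  stopc <- sample(c("TAA", "TAG", "TGA")[c("TAA", "TAG", "TGA") %in%
                                           code$stop_codons], 1)
  paste0("ATG", paste(body, collapse = ""), stopc)
}

# 200-record CDS set with two planted violations of every rejection class
planted_filter_set <- function(code = genetic_code(1)) {
  set.seed(404)
  n_valid <- 184L
  seqs <- vapply(seq_len(n_valid), function(i) random_valid_cds(code), "")
  ids <- sprintf("ok%03d", seq_len(n_valid))
  bad_seq <- character(0)
  bad_id <- character(0)
  add <- function(id, s) {
    bad_id <<- c(bad_id, id)
    bad_seq <<- c(bad_seq, s)
  }
  for (j in 1:2) {
    add(paste0("short", j), paste0("ATG", strrep("AAA", 30), "TAA"))
    add(paste0("triplet", j), paste0(random_valid_cds(code), "A"))
    s <- random_valid_cds(code)
    add(paste0("start", j), paste0("TTG", substr(s, 4, nchar(s))))
    s <- random_valid_cds(code)
    add(paste0("stop", j), paste0(substr(s, 1, nchar(s) - 3), "AAA"))
    s <- random_valid_cds(code)
    add(paste0("internal", j),
        paste0(substr(s, 1, 150), "TAA", substr(s, 151, nchar(s))))
    add(paste0("dup", j), seqs[j])
    add(paste0("rcdup", j), as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqs[j + 2]))))
    s <- random_valid_cds(code)
    add(paste0("ambig", j), paste0(substr(s, 1, 50), "N",
                                   substr(s, 52, nchar(s))))
  }
  data.frame(id = c(ids, bad_id), seq = c(seqs, bad_seq),
             stringsAsFactors = FALSE)
}

# optimal-codon reports for every species of a nine-species scenario
scenario_reports <- function(sc) {
  lapply(names(sc$sets), function(sp) {
    code <- genetic_code(sc$table_ids[[sp]])
    cm <- codon_count_matrix(sc$sets[[sp]]$cds)
    prof <- composition_profiles(cm, code)
    suppressMessages(optimal_codons(
      cm, stats::setNames(prof$enc, prof$gene_id), code, species = sp))
  })
}
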