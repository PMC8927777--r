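# Per-gene codon counting and codon-usage indices: base composition, the GC
# family (GC, GC1/GC2/GC3, GC12, GC3s), third-position synonymous base
# fractions (A3s/T3s/C3s/G3s), Wright's effective number of codons (ENC) and
# its expected value under GC3 alone, and relative synonymous codon usage.

#' Count in-frame codons of a filtered CDS set
#'
#' Counts every in-frame triplet except the terminal stop codon. The start ATG
#' is counted (as Met). Sequences are assumed to have passed [filter_cds()],
#' i.e. length is a multiple of 3 and the last codon is a stop triplet.
#'
#' @param cds data.frame with columns `id` and `seq`.
#' @return Integer matrix, genes x 64 codons, rownames = gene ids.
#' @export
codon_count_matrix <- function(cds) {
  if (nrow(cds) == 0L) {
    m <- matrix(0L, 0, 64, dimnames = list(NULL, all_codons()))
    return(m)
  }
  if (any(nchar(cds$seq) %% 3L != 0L)) {
    stop("sequence length not a multiple of 3; run filter_cds() first",
         call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(cds$seq)
  m <- Biostrings::oligonucleotideFrequency(x, width = 3L, step = 3L)
  # drop the terminal codon of every gene (the stop)
  last <- substr(cds$seq, nchar(cds$seq) - 2L, nchar(cds$seq))
  m[cbind(seq_len(nrow(m)), match(last, colnames(m)))] <-
    m[cbind(seq_len(nrow(m)), match(last, colnames(m)))] - 1L
  m <- m[, all_codons(), drop = FALSE]
  rownames(m) <- cds$id
  storage.mode(m) <- "integer"
  m
}

#' Count codons of a single coding sequence
#'
#' @param cds Either a single sequence string or a one-row data.frame with
#'   `id` and `seq`.
#' @param code A [genetic_code()] (kept for interface symmetry; counting
#'   itself is code-independent once the terminal stop is removed).
#' @return Object of class `codon_counts`: list with `gene_id`, `counts`
#'   (named integer over the 64 codons) and `n_codons`.
#' @examples
#' count_codons("ATGAAATAA", genetic_code(1))$counts[c("ATG", "AAA")]
#' @export
count_codons <- function(cds, code = genetic_code(1)) {
  if (is.character(cds)) cds <- data.frame(id = "gene", seq = cds)
  m <- codon_count_matrix(cds[1, , drop = FALSE])
  structure(list(gene_id = cds$id[1], counts = m[1, ], n_codons = sum(m[1, ])),
            class = "codon_counts")
}

# internal: accept codon_counts, named vector, or 1-row slice -> named numeric
as_count_vector <- function(counts) {
  if (inherits(counts, "codon_counts")) counts <- counts$counts
  if (is.matrix(counts)) counts <- colSums(counts)
  full <- stats::setNames(numeric(64), all_codons())
  full[names(counts)] <- counts
  full
}

# internal: one-row count vectors -> matrix
as_count_matrix <- function(counts) {
  if (inherits(counts, "codon_counts")) {
    m <- matrix(counts$counts, 1, dimnames = list(counts$gene_id,
                                                  names(counts$counts)))
  } else if (is.matrix(counts)) {
    m <- counts
  } else {
    m <- matrix(as_count_vector(counts), 1,
                dimnames = list("gene", all_codons()))
  }
  m[, all_codons(), drop = FALSE]
}

#' Wright's effective number of codons (ENC) for one or many genes
#'
#' Per synonymous family with degeneracy k >= 2 and n observed codons, the
#' codon homozygosity is estimated as F = (n * sum(p_i^2) - 1) / (n - 1) with
#' p_i the within-family proportions. Families with n < 2 or F <= 0 are
#' excluded from their degeneracy-class average. ENC is the number of 1-fold
#' families plus, per degeneracy class, (number of families) / (mean F of the
#' class). A missing 3-fold class mean is imputed as the average of the 2-fold
#' and 4-fold class means; if any other class mean is missing the value is NA.
#' The result is capped between 2 and the code's sense-codon count.
#'
#' @param counts A `codon_counts`, a named count vector, or a genes x 64
#'   matrix from [codon_count_matrix()].
#' @param code A [genetic_code()].
#' @return Numeric vector of ENC values (one per gene), NA where undefined.
#' @references Wright F (1990) The 'effective number of codons' used in a
#'   gene. Gene 87:23-29.
#' @export
enc <- function(counts, code) {
  m <- as_count_matrix(counts)
  tab <- codon_table(code)
  syn <- tab[tab$degeneracy >= 2L, , drop = FALSE]
  fam_ids <- sort(unique(syn$family))
  # indicator matrix: 64 codons x families
  ind <- matrix(0, 64, length(fam_ids),
                dimnames = list(all_codons(), as.character(fam_ids)))
  ind[cbind(syn$codon, as.character(syn$family))] <- 1
  n_f <- m %*% ind                       # per-gene family totals
  s2_f <- (m * m) %*% ind                # per-gene sum of squared counts
  f_hat <- (s2_f / n_f - 1) / (n_f - 1)  # (n*sum(p^2)-1)/(n-1)
  f_hat[n_f < 2] <- NA
  f_hat[!is.na(f_hat) & f_hat <= 1e-12] <- NA  # F <= 0 up to rounding

  degs <- vapply(fam_ids, function(fi) syn$degeneracy[syn$family == fi][1], 1L)
  n1 <- sum(vapply(code$families, `[[`, 1L, "degeneracy") == 1L)
  n_sense <- sum(vapply(code$families, `[[`, 1L, "degeneracy"))
  levels_k <- sort(unique(degs))
  class_mean <- sapply(levels_k, function(k) {
    cols <- which(degs == k)
    rowMeans(f_hat[, cols, drop = FALSE], na.rm = TRUE)
  })
  class_mean <- matrix(class_mean, nrow = nrow(m),
                       dimnames = list(rownames(m), as.character(levels_k)))
  class_mean[is.nan(class_mean)] <- NA
  # impute a missing 3-fold class from the 2- and 4-fold means
  if (all(c("2", "3", "4") %in% colnames(class_mean))) {
    miss3 <- is.na(class_mean[, "3"])
    class_mean[miss3, "3"] <-
      (class_mean[miss3, "2"] + class_mean[miss3, "4"]) / 2
  }
  class_count <- stats::setNames(
    vapply(levels_k, function(k) sum(degs == k), 1L), as.character(levels_k))
  contrib <- sweep(1 / class_mean, 2, class_count[colnames(class_mean)], "*")
  out <- n1 + rowSums(contrib)
  out <- pmin(pmax(out, 2), n_sense)
  unname(out)
}

#' Expected ENC under GC3 composition alone
#'
#' The null curve for the ENC-GC3 plot: the ENC a gene would show if its
#' codon usage were shaped only by third-position GC content,
#' `2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)`.
#'
#' @param gc3 Numeric vector of GC3 fractions in \[0, 1\].
#' @return Expected ENC values.
#' @examples
#' expected_enc(0.5)  # 60.5
#' @export
expected_enc <- function(gc3) {
  if (any(is.na(gc3)) || any(gc3 < 0 | gc3 > 1)) {
    stop("gc3 must lie in [0, 1]", call. = FALSE)
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon c in a family of degeneracy k with family total N, RSCU(c) =
#' k * count(c) / N: the observed frequency relative to equal synonymous
#' usage. Families with N = 0 yield NA. One-fold families (Met, Trp in the
#' standard code) and stop codons are excluded.
#'
#' @param counts A `codon_counts`, named count vector, or count matrix
#'   (matrices are pooled by summation).
#' @param code A [genetic_code()].
#' @return data.frame with columns `codon`, `amino_acid`, `degeneracy`,
#'   `count`, `rscu`, ordered by amino acid then codon.
#' @export
rscu <- function(counts, code) {
  v <- as_count_vector(counts)
  tab <- codon_table(code)
  syn <- tab[tab$degeneracy >= 2L, , drop = FALSE]
  cnt <- v[syn$codon]
  fam_tot <- stats::ave(cnt, syn$family, FUN = sum)
  val <- ifelse(fam_tot > 0, syn$degeneracy * cnt / fam_tot, NA_real_)
  out <- data.frame(codon = syn$codon, amino_acid = syn$amino_acid,
                    degeneracy = syn$degeneracy, count = as.numeric(cnt),
                    rscu = val, stringsAsFactors = FALSE)
  out <- out[order(out$amino_acid, out$codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene composition and bias profile
#'
#' Computes, per gene: overall base fractions, overall GC, positional GC
#' (GC1/GC2/GC3 over all counted codons), GC12 = (GC1 + GC2)/2, the
#' synonymous third-position statistics GC3s and A3s/T3s/C3s/G3s (over codons
#' of families with degeneracy >= 2 only: Met, Trp and stop codons excluded),
#' and ENC. All values are fractions in \[0, 1\] except ENC; rendering as
#' percentages is left to the output layer.
#'
#' Two X3s conventions are provided. The default (`"normalized"`) divides the
#' count of synonymous-family codons ending in base X by the total number of
#' synonymous-family codons, so the four fractions sum to 1. `"codonw"`
#' follows the historical CodonW convention of per-base denominators (codons
#' of families that offer base X at the third position), in which case the
#' four values need not sum to 1.
#'
#' @param counts Genes x 64 count matrix from [codon_count_matrix()] (or a
#'   single `codon_counts` / named vector).
#' @param code A [genetic_code()].
#' @param x3s One of `"normalized"` (default) or `"codonw"`.
#' @return data.frame, one row per gene: `gene_id`, `n_codons`, `a_pct`,
#'   `c_pct`, `g_pct`, `t_pct`, `gc`, `gc1`, `gc2`, `gc3`, `gc12`, `gc3s`,
#'   `a3s`, `t3s`, `c3s`, `g3s`, `enc`. Undefined statistics (e.g. GC3s for a
#'   gene without synonymous-family codons) are NA, never zero.
#' @export
composition_profiles <- function(counts, code,
                                 x3s = c("normalized", "codonw")) {
  x3s <- match.arg(x3s)
  m <- as_count_matrix(counts)
  cods <- colnames(m)
  n <- rowSums(m)
  if (any(n < 1)) stop("every gene needs at least one counted codon",
                       call. = FALSE)
  base_mat <- vapply(c("A", "C", "G", "T"), function(b) {
    vapply(strsplit(cods, ""), function(ch) sum(ch == b), 1L)
  }, integer(64))
  overall <- (m %*% base_mat) / (3 * n)
  pos_gc <- vapply(1:3, function(p) {
    as.numeric(substr(cods, p, p) %in% c("G", "C"))
  }, numeric(64))
  gc_pos <- (m %*% pos_gc) / n

  tab <- codon_table(code)
  syn_cod <- tab$codon[tab$degeneracy >= 2L]
  third <- substr(cods, 3L, 3L)
  is_syn <- as.numeric(cods %in% syn_cod)
  syn_tot <- as.numeric(m %*% is_syn)
  gc3s_num <- as.numeric(m %*% (is_syn * (third %in% c("G", "C"))))
  gc3s <- ifelse(syn_tot > 0, gc3s_num / syn_tot, NA_real_)

  x3s_vals <- sapply(c("A", "T", "C", "G"), function(b) {
    num <- as.numeric(m %*% (is_syn * (third == b)))
    if (x3s == "normalized") {
      den <- syn_tot
    } else {
      # codons of degeneracy>=2 families offering base b at the third position
      syn_tab <- tab[tab$degeneracy >= 2L, , drop = FALSE]
      fams_with_b <- unique(syn_tab$family[syn_tab$third == b])
      elig <- as.numeric(cods %in%
                           syn_tab$codon[syn_tab$family %in% fams_with_b])
      den <- as.numeric(m %*% elig)
    }
    ifelse(den > 0, num / den, NA_real_)
  })
  x3s_vals <- matrix(x3s_vals, nrow = nrow(m),
                     dimnames = list(NULL, c("A", "T", "C", "G")))

  data.frame(
    gene_id = if (is.null(rownames(m))) paste0("g", seq_len(nrow(m)))
              else rownames(m),
    n_codons = n,
    a_pct = overall[, "A"], c_pct = overall[, "C"],
    g_pct = overall[, "G"], t_pct = overall[, "T"],
    gc = overall[, "G"] + overall[, "C"],
    gc1 = gc_pos[, 1], gc2 = gc_pos[, 2], gc3 = gc_pos[, 3],
    gc12 = (gc_pos[, 1] + gc_pos[, 2]) / 2,
    gc3s = gc3s,
    a3s = x3s_vals[, "A"], t3s = x3s_vals[, "T"],
    c3s = x3s_vals[, "C"], g3s = x3s_vals[, "G"],
    enc = enc(m, code),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Single-gene composition profile
#'
#' Convenience wrapper around [composition_profiles()].
#'
#' @inheritParams composition_profiles
#' @return One-row data.frame.
#' @export
composition_profile <- function(counts, code,
                                x3s = c("normalized", "codonw")) {
  composition_profiles(counts, code, x3s = match.arg(x3s))
}
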