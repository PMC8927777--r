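# The inferential layer: ENC-plot table, parity-rule-2 coordinates,
# neutrality regression, correlation matrix, and optimal-codon determination
# from the high- and low-bias gene deciles.

#' ENC-GC3 plot table
#'
#' For each gene, tabulates GC3, observed ENC, expected ENC under GC3 alone
#' (see [expected_enc()]) and their ratio. Genes close to the expected curve
#' (ratio near 1) are compatible with composition/mutation alone shaping
#' their codon usage; genes well below it suggest selection.
#'
#' @param profiles data.frame from [composition_profiles()].
#' @return data.frame with `gene_id`, `gc3`, `enc`, `expected_enc`,
#'   `enc_ratio`. Rows with missing ENC are dropped (count reported via
#'   message and the `n_dropped` attribute).
#' @export
enc_plot_table <- function(profiles) {
  if (nrow(profiles) == 0L) stop("profiles is empty", call. = FALSE)
  drop <- is.na(profiles$enc)
  if (any(drop)) {
    message(sum(drop), " gene(s) with undefined ENC dropped from ENC plot")
  }
  p <- profiles[!drop, , drop = FALSE]
  out <- data.frame(gene_id = p$gene_id, gc3 = p$gc3, enc = p$enc,
                    expected_enc = expected_enc(p$gc3),
                    stringsAsFactors = FALSE)
  out$enc_ratio <- out$enc / out$expected_enc
  attr(out, "n_dropped") <- sum(drop)
  rownames(out) <- NULL
  out
}

#' Parity-rule-2 coordinates
#'
#' Computes, per gene, the PR2 point x = G3/(G3 + C3), y = A3/(A3 + T3) from
#' third-position base counts. The (0.5, 0.5) centre corresponds to
#' intra-strand parity A = T and G = C at the third codon position. Stop
#' codons are excluded from the tally; `site_set = "fourfold_third"` restricts
#' to codons of fourfold-degenerate families (Sueoka's original site choice),
#' the default uses all counted third positions.
#'
#' @param counts Genes x 64 count matrix (or single-gene counts).
#' @param code A [genetic_code()].
#' @param site_set `"all_third"` or `"fourfold_third"`.
#' @return data.frame with `gene_id`, `x`, `y`; a coordinate with zero
#'   denominator is NA (gene flagged missing, not dropped).
#' @export
pr2_points <- function(counts, code,
                       site_set = c("all_third", "fourfold_third")) {
  site_set <- match.arg(site_set)
  m <- as_count_matrix(counts)
  cods <- colnames(m)
  tab <- codon_table(code)
  incl <- if (site_set == "all_third") {
    cods %in% tab$codon  # all sense codons; stops excluded
  } else {
    cods %in% tab$codon[tab$degeneracy == 4L]
  }
  third <- substr(cods, 3L, 3L)
  cnt <- sapply(c("A", "T", "G", "C"), function(b) {
    as.numeric(m %*% (incl * (third == b)))
  })
  cnt <- matrix(cnt, nrow = nrow(m), dimnames = list(NULL, c("A", "T", "G", "C")))
  x <- ifelse(cnt[, "G"] + cnt[, "C"] > 0,
              cnt[, "G"] / (cnt[, "G"] + cnt[, "C"]), NA_real_)
  y <- ifelse(cnt[, "A"] + cnt[, "T"] > 0,
              cnt[, "A"] / (cnt[, "A"] + cnt[, "T"]), NA_real_)
  data.frame(gene_id = if (is.null(rownames(m))) paste0("g", seq_len(nrow(m)))
                       else rownames(m),
             x = x, y = y, stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname pr2_points
#' @export
pr2_point <- pr2_points

#' Neutrality-plot regression of GC12 on GC3s
#'
#' Ordinary least squares of GC12 on GC3s across genes, with the Pearson
#' correlation and its two-sided p-value. A slope near 1 is read as
#' mutation-pressure dominated codon usage, a slope near 0 as
#' selection-dominated.
#'
#' @param profiles data.frame from [composition_profiles()].
#' @return Object of class `neutrality_fit`: list with `slope`, `intercept`,
#'   `pearson_r`, `p_value`, `n_genes`.
#' @export
neutrality_fit <- function(profiles) {
  ok <- stats::complete.cases(profiles[, c("gc12", "gc3s")])
  d <- profiles[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 genes with defined GC12 and GC3s",
                         call. = FALSE)
  if (stats::var(d$gc3s) == 0) {
    stop("GC3s has zero variance; neutrality fit undefined", call. = FALSE)
  }
  fit <- stats::lm(gc12 ~ gc3s, data = d)
  ct <- stats::cor.test(d$gc3s, d$gc12)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n_genes = nrow(d)),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality fit (n = %d): GC12 = %.4f * GC3s + %.4f  (r = %.3f, p = %.3g)\n",
    x$n_genes, x$slope, x$intercept, x$pearson_r, x$p_value))
  invisible(x)
}

#' Pairwise correlation matrix of composition indices
#'
#' Pearson (default) or Spearman correlations between per-gene composition
#' indices, with two-sided p-values, using pairwise-complete genes.
#'
#' @param profiles data.frame from [composition_profiles()].
#' @param variables Column names of `profiles` to correlate.
#' @param method `"pearson"` or `"spearman"`.
#' @return Object of class `cub_cor`: list with symmetric matrices `r` and
#'   `p` (diagonal r = 1, p = 0) and `method`. Pairs involving a constant
#'   variable are NA.
#' @export
correlation_matrix <- function(profiles,
                               variables = c("enc", "gc", "gc3s", "gc12",
                                             "a3s", "t3s", "c3s", "g3s"),
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  missing_vars <- setdiff(variables, names(profiles))
  if (length(missing_vars)) {
    stop("unknown profile variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(profiles) < 3L) stop("need at least 3 genes", call. = FALSE)
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- profiles[[variables[i]]]
      xj <- profiles[[variables[j]]]
      ok <- stats::complete.cases(xi, xj)
      if (sum(ok) >= 3 && stats::var(xi[ok]) > 0 && stats::var(xj[ok]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(xi[ok], xj[ok], method = method))
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, method = method), class = "cub_cor")
}

#' @export
print.cub_cor <- function(x, digits = 3, ...) {
  stars <- ifelse(is.na(x$p), "", ifelse(x$p < 0.01, "**",
                                         ifelse(x$p < 0.05, "*", "")))
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), stars),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  cat("Correlation matrix (", x$method,
      "; * p<0.05, ** p<0.01, pairwise-complete)\n", sep = "")
  print(disp, quote = FALSE)
  invisible(x)
}

#' Determine optimal codons from high- and low-bias gene deciles
#'
#' Genes are ranked by ENC ascending (low ENC = high bias; ties broken by
#' gene id, lexicographically). The first `ceiling(tail_fraction * n)` genes
#' form the high-bias set, the last as many the low-bias set. Codon counts
#' are pooled within each set, RSCU computed on the pools, and
#' delta-RSCU = RSCU(high) - RSCU(low). Codons with delta-RSCU strictly
#' greater than `threshold` are called optimal; `require_high_rscu_gt1`
#' additionally demands RSCU(high) > 1.
#'
#' @param counts Genes x 64 count matrix with gene ids as rownames.
#' @param enc_by_gene Numeric ENC vector aligned with `counts` rows (a named
#'   vector is re-ordered by rowname). Genes with undefined (NA) ENC cannot
#'   be ranked and are dropped with a message.
#' @param code A [genetic_code()].
#' @param tail_fraction Fraction of genes in each tail (default 0.10);
#'   the decile size is at least 2.
#' @param threshold delta-RSCU cutoff (default 0.08, strict inequality).
#' @param require_high_rscu_gt1 Also require RSCU > 1 in the high-bias pool.
#' @param species Optional species label stored in the report.
#' @return Object of class `optimal_codon_report`: list with `species`,
#'   `n_genes`, `decile_size`, `high_set_ids`, `low_set_ids`, `rscu_high`,
#'   `rscu_low` (data.frames from [rscu()]), `delta_rscu` (named numeric) and
#'   `optimal` (character vector of codons), plus the thresholds used.
#' @export
optimal_codons <- function(counts, enc_by_gene, code, tail_fraction = 0.10,
                           threshold = 0.08, require_high_rscu_gt1 = FALSE,
                           species = NA_character_) {
  m <- as_count_matrix(counts)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(m)))
  e <- enc_by_gene
  if (!is.null(names(e))) e <- e[ids]
  if (length(e) != nrow(m)) {
    stop("enc_by_gene must provide an ENC per gene", call. = FALSE)
  }
  if (anyNA(e)) {
    message(sum(is.na(e)), " gene(s) with undefined ENC dropped from ranking")
    keep <- !is.na(e)
    m <- m[keep, , drop = FALSE]
    ids <- ids[keep]
    e <- e[keep]
  }
  n <- nrow(m)
  if (n < 20L) {
    stop("optimal-codon determination needs at least 20 rankable genes ",
         "(each tail must hold >= 2); got ", n, call. = FALSE)
  }
  d <- max(2L, as.integer(ceiling(tail_fraction * n)))
  ord <- order(e, ids)
  if (anyDuplicated(e[ord][c(d, d + 1L)]) ||
      anyDuplicated(e[ord][c(n - d, n - d + 1L)])) {
    message("ENC tie at a decile boundary broken by gene id")
  }
  high <- ord[seq_len(d)]
  low <- ord[seq.int(n - d + 1L, n)]
  rscu_high <- rscu(colSums(m[high, , drop = FALSE]), code)
  rscu_low <- rscu(colSums(m[low, , drop = FALSE]), code)
  delta <- stats::setNames(rscu_high$rscu - rscu_low$rscu, rscu_high$codon)
  optimal <- names(delta)[!is.na(delta) & delta > threshold]
  if (require_high_rscu_gt1) {
    hi <- stats::setNames(rscu_high$rscu, rscu_high$codon)
    optimal <- optimal[hi[optimal] > 1]
  }
  structure(list(species = species, n_genes = n, decile_size = d,
                 high_set_ids = ids[high], low_set_ids = ids[low],
                 rscu_high = rscu_high, rscu_low = rscu_low,
                 delta_rscu = delta, optimal = sort(optimal),
                 threshold = threshold,
                 require_high_rscu_gt1 = require_high_rscu_gt1),
            class = "optimal_codon_report")
}

#' @export
print.optimal_codon_report <- function(x, ...) {
  cat("Optimal codon report",
      if (!is.na(x$species)) paste0(" (", x$species, ")"), "\n", sep = "")
  cat("  ", x$n_genes, " genes; high/low bias sets of ", x$decile_size,
      " genes each (ranked by ENC)\n", sep = "")
  cat("  optimal codons (delta-RSCU > ", x$threshold, "): ",
      if (length(x$optimal)) paste(x$optimal, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Optimal codons shared across species
#'
#' @param reports List of `optimal_codon_report` objects (at least 2).
#' @return Character vector: the intersection of the reports' optimal sets.
#' @export
shared_optimal_codons <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports", call. = FALSE)
  sets <- lapply(reports, function(r) {
    if (!inherits(r, "optimal_codon_report")) {
      stop("all elements must be optimal_codon_report objects", call. = FALSE)
    }
    r$optimal
  })
  sort(Reduce(intersect, sets))
}
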