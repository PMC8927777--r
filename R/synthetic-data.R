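# Synthetic CDS generator with known ground truth.
#
# Each gene draws a body length, a target synonymous third-position GC level
# (gc3) and, from it, a target GC12 through the linear neutrality coupling
# gc12 = slope * gc3 + intercept + noise. Codons are then drawn one slot at a
# time: the amino-acid family from a background distribution exponentially
# tilted to realize the gene's GC12 target, the codon within its family with
# weights proportional to a third-position base weight implied by the gc3
# target times exp(preference_strength) for designated optimal codons in
# "high-bias" genes. A start ATG and a stop codon valid under the chosen
# genetic code delimit every gene, so all output passes filter_cds() in
# strict mode by construction.

#' Configuration for the synthetic CDS generator
#'
#' @param n_genes Number of genes.
#' @param length_codons Integer (min, max): body length range in codons,
#'   drawn uniformly (start and stop codons excluded).
#' @param code Genetic-code table id (1, 6 or 10).
#' @param gc3_mean,gc3_sd Across-gene distribution (normal, clamped to
#'   \[0.02, 0.98\]) of the per-gene target GC at synonymous third positions.
#' @param neutrality_slope,neutrality_intercept,noise_sd Linear GC12-GC3
#'   coupling: `gc12_target = slope * gc3_target + intercept + N(0, noise_sd)`.
#' @param optimal_set Character vector of designated preferred codons
#'   (must be sense codons of degeneracy >= 2 families; never stops).
#' @param preference_strength Log-weight s >= 0 added to designated codons in
#'   biased genes (within-family weight multiplied by `exp(s)`).
#' @param bias_fraction Fraction of genes receiving the preference: the first
#'   `round(bias_fraction * n_genes)` genes are flagged biased.
#' @param aa_weights Optional named numeric vector of amino-acid background
#'   weights (single-letter names); default is uniform over the code's
#'   families, which keeps family sample sizes balanced.
#' @param species Species label for the emitted records.
#' @param seed Integer seed; generation is fully determined by it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 400L, length_codons = c(150L, 600L),
                       code = 6L, gc3_mean = 0.30, gc3_sd = 0.12,
                       neutrality_slope = 0.40, neutrality_intercept = 0.22,
                       noise_sd = 0.02, optimal_set = character(),
                       preference_strength = 2, bias_fraction = 0.15,
                       aa_weights = NULL, species = "synthetic", seed = 1L) {
  cd <- genetic_code(code)
  if (length(length_codons) != 2L || length_codons[1] > length_codons[2] ||
      length_codons[1] < 1L) {
    stop("length_codons must be an increasing (min, max) pair", call. = FALSE)
  }
  if (gc3_mean <= 0 || gc3_mean >= 1 || gc3_sd < 0) {
    stop("gc3_mean must lie in (0, 1) and gc3_sd must be >= 0", call. = FALSE)
  }
  if (bias_fraction < 0 || bias_fraction > 1) {
    stop("bias_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (preference_strength < 0) {
    stop("preference_strength must be >= 0", call. = FALSE)
  }
  if (length(optimal_set)) {
    if (any(optimal_set %in% cd$stop_codons)) {
      stop("optimal_set contains a stop codon of table ", cd$table_id, ": ",
           paste(intersect(optimal_set, cd$stop_codons), collapse = ", "),
           call. = FALSE)
    }
    syn <- sense_codons(cd, min_degeneracy = 2L)
    if (!all(optimal_set %in% syn)) {
      stop("optimal_set must contain sense codons of degeneracy >= 2 ",
           "families; offending: ",
           paste(setdiff(optimal_set, syn), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 length_codons = as.integer(length_codons),
                 code = cd$table_id, gc3_mean = gc3_mean, gc3_sd = gc3_sd,
                 neutrality_slope = neutrality_slope,
                 neutrality_intercept = neutrality_intercept,
                 noise_sd = noise_sd, optimal_set = optimal_set,
                 preference_strength = preference_strength,
                 bias_fraction = bias_fraction, aa_weights = aa_weights,
                 species = species, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic CDS set with ground truth
#'
#' @param config A [sim_config()].
#' @return List with `cds` (data.frame `id`/`seq`/`species`, ready for
#'   [filter_cds()] / [codon_count_matrix()]) and `truth`: a list holding
#'   `genes` (per-gene data.frame: targets, achieved GC3s/GC12, bias flag),
#'   `ledger` (named 64-codon count vector over all emitted counted codons,
#'   i.e. including the start ATG and excluding the terminal stop, matching
#'   [count_codons()]) and `config`.
#' @export
generate_cds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  code <- genetic_code(config$code)
  tab <- codon_table(code)
  fam_ids <- sort(unique(tab$family))
  fam_aa <- vapply(fam_ids, function(f) tab$amino_acid[tab$family == f][1], "")
  u_f <- if (is.null(config$aa_weights)) {
    rep(1, length(fam_ids))
  } else {
    w <- config$aa_weights[fam_aa]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) stop("aa_weights leave no family available",
                          call. = FALSE)
    as.numeric(w)
  }
  n <- config$n_genes
  s <- config$preference_strength
  n_bias <- round(config$bias_fraction * n)
  biased <- seq_len(n) <= n_bias
  lens <- if (config$length_codons[1] == config$length_codons[2]) {
    rep(config$length_codons[1], n)
  } else {
    sample(seq.int(config$length_codons[1], config$length_codons[2]), n,
           replace = TRUE)
  }
  g_target <- pmin(pmax(stats::rnorm(n, config$gc3_mean, config$gc3_sd),
                        0.02), 0.98)
  eps <- stats::rnorm(n, 0, config$noise_sd)

  is_opt <- tab$codon %in% config$optimal_set
  third <- tab$third
  fam_of <- tab$family
  gc12_cod <- tab$gc12
  ledger <- stats::setNames(numeric(64), all_codons())
  seqs <- character(n)
  t_target <- numeric(n)
  gc3s_real <- numeric(n)
  gc12_real <- numeric(n)
  deg2 <- tab$degeneracy >= 2L
  third_gc <- third %in% c("G", "C")

  for (i in seq_len(n)) {
    g <- g_target[i]
    w3 <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    wc <- unname(w3[third])
    if (biased[i] && s > 0 && any(is_opt)) wc[is_opt] <- wc[is_opt] * exp(s)
    p_in_fam <- wc / stats::ave(wc, fam_of, FUN = sum)
    e_f <- as.numeric(rowsum(p_in_fam * gc12_cod, fam_of))  # sorted by family
    lo <- min(e_f[u_f > 0]) + 1e-3
    hi <- max(e_f[u_f > 0]) - 1e-3
    t <- min(max(config$neutrality_slope * g + config$neutrality_intercept +
                   eps[i], lo), hi)
    t_target[i] <- t
    lam <- if (hi - lo < 1e-6) 0 else solve_tilt(u_f, e_f, t)
    w_fam <- u_f * exp(lam * (e_f - mean(e_f)))
    fam_draw <- sample.int(length(fam_ids), lens[i], replace = TRUE,
                           prob = w_fam)
    body <- character(lens[i])
    for (f in unique(fam_draw)) {
      slots <- which(fam_draw == f)
      members <- which(fam_of == fam_ids[f])
      body[slots] <- tab$codon[members][
        sample.int(length(members), length(slots), replace = TRUE,
                   prob = p_in_fam[members])]
    }
    counted <- c("ATG", body)
    idx <- match(counted, tab$codon)  # ATG is sense in all supported tables
    gc12_real[i] <- mean(gc12_cod[idx])
    syn_slots <- deg2[idx]
    gc3s_real[i] <- if (any(syn_slots)) mean(third_gc[idx][syn_slots])
                    else NA_real_
    add <- tabulate(match(counted, names(ledger)), 64L)
    ledger <- ledger + add
    stop_cod <- if (length(code$stop_codons) == 1L) code$stop_codons else
      code$stop_codons[sample.int(length(code$stop_codons), 1L)]
    seqs[i] <- paste0("ATG", paste(body, collapse = ""), stop_cod)
  }
  ids <- sprintf("%s_g%04d", config$species, seq_len(n))
  list(cds = data.frame(id = ids, seq = seqs,
                        species = rep(config$species, n),
                        stringsAsFactors = FALSE),
       truth = list(
         genes = data.frame(id = ids, length_codons = lens, biased = biased,
                            gc3_target = g_target, gc12_target = t_target,
                            gc3s_achieved = gc3s_real,
                            gc12_achieved = gc12_real,
                            stringsAsFactors = FALSE),
         ledger = ledger, config = config))
}

# internal: solve the exponential family tilt so that the weighted mean of
# per-family expected GC12 hits the target t
solve_tilt <- function(u, e, t) {
  f <- function(l) {
    w <- u * exp(l * (e - mean(e)))
    sum(w * e) / sum(w) - t
  }
  if (f(-60) >= 0) return(-60)
  if (f(60) <= 0) return(60)
  stats::uniroot(f, c(-60, 60), tol = 1e-8)$root
}

#' Nine-species synthetic scenario
#'
#' Builds nine CDS sets spanning an AT-rich range of synonymous GC3 levels
#' (means from 0.18 to 0.40), all sharing one designated 8-codon optimal set
#' while each species adds two private preferred codons. Eight species use
#' the ciliate nuclear code (table 6) and one the euplotid code (table 10).
#' The per-gene GC3 spread within a species is kept narrow (sd 0.015) so that
#' ENC ranking isolates the translational-preference channel; see the
#' package vignette for the reasoning.
#'
#' @param base_seed Integer; species i uses seed `base_seed + i`.
#' @param n_genes Genes per species (default 400).
#' @return List with `sets` (named list of [generate_cds()] outputs),
#'   `table_ids` (named integer vector), `shared_optimal_set` (8 codons),
#'   `private_sets` (named list of 2-codon vectors) and `base_seed`.
#' @export
nine_species_scenario <- function(base_seed, n_genes = 400L) {
  shared <- c("TTT", "TAT", "GTT", "GCA", "AGA", "AGT", "GGA", "ACT")
  pool <- c("AAT", "GAT", "CAT", "AAA", "GAA", "ATT", "ATA", "TTA", "CTT",
            "CCT", "CCA", "CAA", "TGT", "CTA", "AAG", "GAG", "CAC", "ATC")
  gc3_means <- seq(0.18, 0.40, length.out = 9)
  table_ids <- c(rep(6L, 8), 10L)
  sp <- sprintf("sp%d", 1:9)
  sets <- vector("list", 9)
  private <- vector("list", 9)
  for (i in 1:9) {
    private[[i]] <- pool[c(2 * i - 1, 2 * i)]
    cfg <- sim_config(
      n_genes = n_genes, length_codons = c(150L, 450L), code = table_ids[i],
      gc3_mean = gc3_means[i], gc3_sd = 0.015,
      neutrality_slope = 0.40, neutrality_intercept = 0.20, noise_sd = 0.02,
      optimal_set = c(shared, private[[i]]), preference_strength = 2,
      bias_fraction = 0.15, species = sp[i], seed = base_seed + i)
    sets[[i]] <- generate_cds(cfg)
  }
  names(sets) <- sp
  names(private) <- sp
  list(sets = sets, table_ids = stats::setNames(table_ids, sp),
       shared_optimal_set = shared, private_sets = private,
       base_seed = base_seed)
}
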