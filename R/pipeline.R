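# End-to-end orchestration: filter -> per-gene statistics -> ENC/PR2/
# neutrality/correlation -> RSCU and optimal codons -> cross-species
# intersection and RSCU tree, with TSV/Newick/JSON outputs.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full codon-usage-bias pipeline
#'
#' Executes every analysis stage for a set of species and writes the results
#' under `outdir`: per-species filter reports, per-gene profiles, ENC-plot,
#' PR2 and neutrality tables, correlation matrices, pooled RSCU, delta-RSCU
#' tables with optimal-codon flags, plus the cross-species shared optimal
#' set, RSCU matrix and clustering tree, and a machine-readable
#' `summary.json`. Any stage failure aborts with the stage name and leaves a
#' `FAILED` marker file next to the partial outputs.
#'
#' @param inputs Either a data.frame with columns `species`, `path` (FASTA)
#'   and `code` (table id), or a named list of entries `list(cds = <data.frame>,
#'   code = <table id>)` keyed by species label.
#' @param outdir Output directory (created if needed).
#' @param min_len,internal_stop_mode Passed to [filter_cds()].
#' @param tail_fraction,delta_threshold,require_rscu_gt1 Passed to
#'   [optimal_codons()].
#' @param pr2_sites Passed to [pr2_points()] (`"all_third"` or
#'   `"fourfold_third"`).
#' @param tree_method Passed to [build_tree()] (`"upgma"` or `"nj"`).
#' @param seed Optional integer recorded in the summary (the pipeline itself
#'   is deterministic; the seed documents upstream data generation).
#' @return The summary list, invisibly.
#' @export
run_cub_pipeline <- function(inputs, outdir, min_len = 300L,
                             internal_stop_mode = "reject",
                             tail_fraction = 0.10, delta_threshold = 0.08,
                             require_rscu_gt1 = FALSE,
                             pr2_sites = "all_third",
                             tree_method = "upgma", seed = NULL) {
  if (is.data.frame(inputs)) {
    entries <- lapply(seq_len(nrow(inputs)), function(i) {
      list(cds = read_cds_fasta(inputs$path[i], species = inputs$species[i]),
           code = inputs$code[i])
    })
    names(entries) <- inputs$species
  } else {
    entries <- inputs
  }
  if (length(entries) == 0L) stop("no inputs given", call. = FALSE)
  if (is.null(names(entries)) || anyDuplicated(names(entries))) {
    stop("inputs must be uniquely named by species", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fail_marker <- file.path(outdir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)

  stage <- function(name, species, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "; input: ", species, "; error: ",
                        conditionMessage(e)), fail_marker)
      stop("pipeline stage '", name, "' failed for input '", species, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  species_summaries <- list()
  reports <- list()
  counts_by_species <- list()
  codes_by_species <- list()
  for (sp in names(entries)) {
    cd <- entries[[sp]]$code
    code <- if (inherits(cd, "genetic_code")) cd else genetic_code(cd)
    flt <- stage("filter", sp,
                 filter_cds(entries[[sp]]$cds, code, min_len = min_len,
                            internal_stop_mode = internal_stop_mode))
    write_tsv(flt$report$rejections,
              file.path(outdir, paste0(sp, "_filter_report.tsv")))
    counts <- stage("count", sp, codon_count_matrix(flt$kept))
    prof <- stage("profile", sp, composition_profiles(counts, code))
    write_tsv(render_profile_table(prof),
              file.path(outdir, paste0(sp, "_profiles.tsv")))
    write_tsv(stage("enc_plot", sp, enc_plot_table(prof)),
              file.path(outdir, paste0(sp, "_enc_plot.tsv")))
    write_tsv(stage("pr2", sp, pr2_points(counts, code, site_set = pr2_sites)),
              file.path(outdir, paste0(sp, "_pr2.tsv")))
    nf <- stage("neutrality", sp, neutrality_fit(prof))
    write_tsv(data.frame(species = sp, slope = nf$slope,
                         intercept = nf$intercept, pearson_r = nf$pearson_r,
                         p_value = nf$p_value, n_genes = nf$n_genes),
              file.path(outdir, paste0(sp, "_neutrality.tsv")))
    cm <- stage("correlation", sp, correlation_matrix(prof))
    write_tsv(data.frame(variable = rownames(cm$r), cm$r),
              file.path(outdir, paste0(sp, "_correlation_r.tsv")))
    write_tsv(data.frame(variable = rownames(cm$p), cm$p),
              file.path(outdir, paste0(sp, "_correlation_p.tsv")))
    pooled <- rscu(counts, code)
    write_tsv(pooled, file.path(outdir, paste0(sp, "_rscu.tsv")))
    rep <- stage("optimal", sp,
                 optimal_codons(counts, stats::setNames(prof$enc,
                                                        prof$gene_id),
                                code, tail_fraction = tail_fraction,
                                threshold = delta_threshold,
                                require_high_rscu_gt1 = require_rscu_gt1,
                                species = sp))
    delta_tab <- data.frame(codon = names(rep$delta_rscu),
                            amino_acid = rep$rscu_high$amino_acid,
                            rscu_high = rep$rscu_high$rscu,
                            rscu_low = rep$rscu_low$rscu,
                            delta_rscu = unname(rep$delta_rscu),
                            optimal = names(rep$delta_rscu) %in% rep$optimal)
    write_tsv(delta_tab, file.path(outdir, paste0(sp, "_delta_rscu.tsv")))
    reports[[sp]] <- rep
    counts_by_species[[sp]] <- counts
    codes_by_species[[sp]] <- code
    species_summaries[[sp]] <- list(
      n_input = flt$report$n_input, n_kept = flt$report$n_kept,
      gc_mean = mean(prof$gc), gc12_mean = mean(prof$gc12),
      gc3s_mean = mean(prof$gc3s, na.rm = TRUE),
      enc_median = stats::median(prof$enc, na.rm = TRUE),
      neutrality_slope = nf$slope, neutrality_r = nf$pearson_r,
      optimal_codons = rep$optimal)
  }

  shared <- if (length(reports) >= 2L) shared_optimal_codons(reports)
            else character(0)
  newick <- NULL
  if (length(counts_by_species) >= 3L) {
    mat <- stage("rscu_matrix", "all",
                 pooled_rscu_matrix(counts_by_species, codes_by_species))
    write_tsv(data.frame(species = rownames(mat), mat, check.names = FALSE),
              file.path(outdir, "rscu_matrix.tsv"))
    newick <- stage("tree", "all",
                    build_tree(rscu_distance(mat), method = tree_method))
    writeLines(as.character(newick), file.path(outdir, "rscu_tree.nwk"))
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("ciliateCUB")),
    seed = seed,
    options = list(min_len = min_len, internal_stop_mode = internal_stop_mode,
                   tail_fraction = tail_fraction,
                   delta_threshold = delta_threshold,
                   require_rscu_gt1 = require_rscu_gt1,
                   pr2_sites = pr2_sites, tree_method = tree_method),
    species = species_summaries,
    shared_optimal_codons = shared,
    rscu_tree = if (is.null(newick)) NULL else as.character(newick))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}

# internal: percent-style rendering of the per-gene profile table (two
# decimals, fractions scaled to %), mirroring conventional GC tables
render_profile_table <- function(prof) {
  pct <- c("a_pct", "c_pct", "g_pct", "t_pct", "gc", "gc1", "gc2", "gc3",
           "gc12", "gc3s", "a3s", "t3s", "c3s", "g3s")
  out <- prof
  for (cn in pct) out[[cn]] <- round(100 * out[[cn]], 2)
  out$enc <- round(out$enc, 2)
  out
}
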