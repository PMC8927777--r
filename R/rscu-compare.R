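# Cross-species RSCU matrix, distances and clustering trees: the substrate
# for RSCU heatmaps and the codon-usage "phylogeny".

#' Pooled per-species RSCU matrix
#'
#' Pools codon counts within each species and computes RSCU per species. The
#' codon columns are the union over species of sense codons in families with
#' degeneracy >= 2; a codon that is a stop (or 1-fold) under one species'
#' code but synonymous under another is carried as NA for the former, e.g.
#' TAA is a Gln codon for a table-6 species but missing for a table-1 one.
#'
#' @param counts_by_species Named list of genes x 64 count matrices (or
#'   pooled named count vectors), one per species.
#' @param codes_by_species Named list (or vector) of table ids or
#'   `genetic_code` objects, aligned with `counts_by_species` by name.
#' @return Numeric matrix, species x codons, with the per-species
#'   `genetic_code` table ids in `attr(, "table_ids")`.
#' @export
pooled_rscu_matrix <- function(counts_by_species, codes_by_species) {
  sp <- names(counts_by_species)
  if (is.null(sp) || length(sp) < 2L) {
    stop("need a named list of at least 2 species", call. = FALSE)
  }
  codes <- lapply(sp, function(s) {
    cd <- if (is.list(codes_by_species)) codes_by_species[[s]]
          else codes_by_species[[s]]
    if (inherits(cd, "genetic_code")) cd else genetic_code(cd)
  })
  names(codes) <- sp
  pooled <- lapply(sp, function(s) as_count_vector(counts_by_species[[s]]))
  names(pooled) <- sp
  empty <- vapply(pooled, function(v) sum(v) == 0, TRUE)
  if (any(empty)) {
    warning("excluding species with zero counted genes: ",
            paste(sp[empty], collapse = ", "), call. = FALSE)
    sp <- sp[!empty]
    if (length(sp) < 2L) stop("fewer than 2 non-empty species", call. = FALSE)
  }
  codon_union <- sort(unique(unlist(
    lapply(sp, function(s) sense_codons(codes[[s]], min_degeneracy = 2L)))))
  out <- matrix(NA_real_, length(sp), length(codon_union),
                dimnames = list(sp, codon_union))
  for (s in sp) {
    r <- rscu(pooled[[s]], codes[[s]])
    out[s, r$codon] <- r$rscu
  }
  attr(out, "table_ids") <- stats::setNames(
    vapply(sp, function(s) codes[[s]]$table_id, 1L), sp)
  out
}

#' Distance between species RSCU profiles
#'
#' Euclidean (default) or Manhattan distance over the codon columns defined
#' in both species of a pair. To keep pairs with different numbers of shared
#' columns comparable, the summed difference is rescaled by the ratio of
#' total to shared columns before the root (the pairwise-complete rescaling
#' of [stats::dist()]).
#'
#' @param mat Species x codon matrix from [pooled_rscu_matrix()].
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return A `stats::dist` object.
#' @export
rscu_distance <- function(mat, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (nrow(mat) < 2L) stop("need at least 2 species", call. = FALSE)
  obs <- !is.na(mat)
  shared <- tcrossprod(obs * 1)
  off <- shared[upper.tri(shared)]
  if (any(off < 10)) {
    stop("some species pair shares fewer than 10 codon columns; ",
         "distances would be unstable", call. = FALSE)
  }
  stats::dist(mat, method = metric)
}

#' Cluster species by codon usage and return a Newick tree
#'
#' UPGMA (average-linkage on the given distances; ultrametric output) or
#' neighbour-joining. Labels are sorted lexicographically before clustering
#' so that tied merges resolve to the lexicographically first pair,
#' independent of input order.
#'
#' @param dist A `stats::dist` object or a symmetric matrix with zero
#'   diagonal.
#' @param method `"upgma"` (default) or `"nj"`.
#' @return Newick string with branch lengths (the `phylo` object is attached
#'   as attribute `"phylo"`).
#' @export
build_tree <- function(dist, method = c("upgma", "nj")) {
  method <- match.arg(method)
  m <- as.matrix(dist)
  if (!isSymmetric(unname(m)) || any(diag(m) != 0)) {
    stop("distance input must be symmetric with zero diagonal", call. = FALSE)
  }
  if (nrow(m) < 3L) stop("need at least 3 labels for a tree", call. = FALSE)
  o <- order(rownames(m))
  d <- stats::as.dist(m[o, o])
  phy <- if (method == "upgma") {
    ape::as.phylo(stats::hclust(d, method = "average"))
  } else {
    ape::nj(d)
  }
  nwk <- ape::write.tree(phy)
  attr(nwk, "phylo") <- phy
  nwk
}
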