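# Within-clone B cell lineage dendrograms.
#
# Per-cell feature vectors combine V/J germline identities, substitution
# counts and the combined V-J SHM rate; trees are built from Euclidean
# distances with the ward.D agglomeration criterion (the classical Ward
# update on unsquared distances, as opposed to ward.D2). Features are used
# raw by default; standardization is available via `standardize = TRUE`.

#' Per-cell lineage feature vectors for one clone
#'
#' The feature vector is `(v_identity, j_identity, v_shm, j_shm,
#' vj_shm_rate)`.
#'
#' @param shm SHM records (from [assign_germline()]) for the cells of one
#'   clone; at least 2 rows.
#' @return numeric matrix, one row per cell (rownames = cell ids).
#' @export
lineage_features <- function(shm) {
  shm <- as.data.table(shm)
  if (nrow(shm) < 2)
    stop("clone must have at least 2 cells to build lineage features")
  m <- as.matrix(shm[, .(v_identity, j_identity, v_shm, j_shm, vj_shm_rate)])
  rownames(m) <- shm$cell_id
  m
}

#' Build a Ward lineage dendrogram from feature vectors
#'
#' Computes pairwise Euclidean distances and applies agglomerative
#' clustering with the `ward.D` criterion (distances are not squared before
#' the update). Input rows are ordered by cell id so that permuting the
#' input yields an isomorphic tree. The dendrogram is serialized to Newick
#' with ultrametric branch lengths (leaf-to-node depth = merge height / 2).
#'
#' @param features numeric matrix from [lineage_features()] (>= 2 rows,
#'   finite values, rownames = cell ids).
#' @param clone_id optional clone label.
#' @param standardize z-score the feature columns first (default FALSE:
#'   counts and rates are mixed on their native scales).
#' @return object of class `lineage_tree`: list with `clone_id`, `hclust`,
#'   `phylo`, `newick`, `leaves`.
#' @export
build_tree <- function(features, clone_id = NA_character_,
                       standardize = FALSE) {
  if (!is.matrix(features) || nrow(features) < 2)
    stop("need a feature matrix with at least 2 rows")
  bad <- rownames(features)[!stats::complete.cases(features) |
                              apply(!is.finite(features), 1, any)]
  if (length(bad))
    stop("non-finite feature value(s) for cell(s): ",
         paste(bad, collapse = ", "))
  features <- features[order(rownames(features)), , drop = FALSE]
  if (standardize) {
    sds <- apply(features, 2, sd)
    sds[sds == 0] <- 1
    features <- scale(features, scale = sds)
  }
  hc <- hclust(dist(features, method = "euclidean"), method = "ward.D")
  phylo <- ape::as.phylo(hc)
  structure(list(clone_id = clone_id, hclust = hc, phylo = phylo,
                 newick = ape::write.tree(phylo),
                 leaves = hc$labels),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree>", x$clone_id, "-", length(x$leaves), "leaves\n")
  invisible(x)
}

#' Recover merge heights from a serialized lineage tree
#'
#' Parses a Newick string written by [build_tree()] and returns the merge
#' heights (node age x 2, matching `hclust$height`), sorted increasingly.
#'
#' @param newick Newick string.
#' @return numeric vector of merge heights.
#' @export
newick_heights <- function(newick) {
  tr <- ape::read.tree(text = newick)
  sort(unname(2 * ape::branching.times(tr)))
}

#' Build lineage trees for all sufficiently large clones
#'
#' @param shm SHM records.
#' @param clone_table a `clone_table` (BCR).
#' @param min_size minimum clone size (default 3).
#' @return named list of `lineage_tree` objects (clone id -> tree).
#' @export
lineage_trees <- function(shm, clone_table, min_size = 3L) {
  shm <- as.data.table(shm)
  big <- clone_table$clones[size >= min_size, clone_id]
  members <- clone_table$cells[clone_id %in% big]
  out <- list()
  for (cl in sort(unique(members$clone_id))) {
    rec <- shm[cell_id %in% members[clone_id == cl, cell_id]]
    if (nrow(rec) < 2) next
    out[[cl]] <- build_tree(lineage_features(rec), clone_id = cl)
  }
  out
}
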