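# Control-binned gene-module scoring and expanded-vs-unexpanded comparisons.
#
# The module score follows the standard single-cell convention: genes are
# binned by average expression into equal-frequency bins; each signature gene
# draws control genes from its own bin; the per-cell score is the mean
# log-normalized expression of the signature genes minus the mean over all
# control draws. Adding a constant to every gene in every cell therefore
# leaves scores unchanged.

#' Log-normalize a count matrix
#'
#' Counts are scaled per cell to `scale_factor` total and log1p-transformed.
#'
#' @param counts genes x cells sparse (dgCMatrix) or dense count matrix.
#' @param scale_factor library-size target (default 1e4).
#' @return matrix of the same shape and class family.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  if (is(counts, "CsparseMatrix")) {
    out <- counts
    out@x <- log1p(out@x / rep.int(cs, diff(out@p)) * scale_factor)
    out
  } else {
    log1p(sweep(as.matrix(counts), 2, cs, "/") * scale_factor)
  }
}

#' Control-binned gene-module score
#'
#' Genes are ranked by mean expression across cells and cut into `n_bins`
#' equal-frequency bins. For each signature gene, `n_ctrl` control genes are
#' drawn from its bin (without replacement within a draw when the bin is
#' large enough, with replacement otherwise). The per-cell score is
#' `mean(signature genes) - mean(all control draws)`.
#'
#' @param expr log-normalized genes x cells matrix with rownames.
#' @param gene_set character vector of signature genes; genes absent from
#'   `expr` are dropped with a warning; an empty (or fully absent) set is an
#'   error.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes per signature gene (default 100).
#' @param seed RNG seed for the control draws (scores are deterministic
#'   given the seed).
#' @return data.table with `cell_id` and `score`; attributes record the gene
#'   set used, `n_bins`, `n_ctrl` and `seed`.
#' @export
module_score <- function(expr, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  if (length(gene_set) == 0) stop("empty gene set")
  missing_genes <- setdiff(gene_set, rownames(expr))
  if (length(missing_genes)) {
    warning("gene(s) absent from matrix dropped: ",
            paste(missing_genes, collapse = ", "))
    gene_set <- setdiff(gene_set, missing_genes)
  }
  if (length(gene_set) == 0) stop("no signature gene present in the matrix")
  avg <- Matrix::rowMeans(expr)
  n_bins <- min(n_bins, length(avg))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
             labels = FALSE)
  names(bin) <- rownames(expr)
  ctrl <- with_local_seed(seed, function() {
    unlist(lapply(gene_set, function(g) {
      members <- rownames(expr)[bin == bin[g]]
      sample(members, n_ctrl, replace = n_ctrl > length(members))
    }))
  })
  sig_mean <- Matrix::colMeans(expr[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(expr[ctrl, , drop = FALSE])
  out <- data.table(cell_id = colnames(expr),
                    score = unname(sig_mean - ctrl_mean))
  setattr(out, "gene_set", gene_set)
  setattr(out, "n_bins", n_bins)
  setattr(out, "n_ctrl", n_ctrl)
  setattr(out, "seed", seed)
  out[]
}

#' Paired expanded-vs-unexpanded signature comparison
#'
#' For one subset, computes per donor the mean module score among expanded
#' (clone size >= 2) and unexpanded clone-assigned cells, and tests the
#' paired differences across donors with a two-sided paired t-test. Donors
#' lacking either group are excluded; with fewer than two complete pairs the
#' p-value is `NA`.
#'
#' @param scores output of [module_score()].
#' @param cells cell metadata.
#' @param clone_table a `clone_table`.
#' @param subset subset label to analyze.
#' @param tissue optional tissue restriction.
#' @return list with `per_donor` (donor means per group), `mean_diff`,
#'   `statistic`, `p`, `n_pairs`.
#' @export
expanded_vs_unexpanded <- function(scores, cells, clone_table, subset,
                                   tissue = NULL) {
  cells <- as.data.table(cells)
  want_subset <- subset
  want_tissue <- tissue
  dat <- clone_table$cells[
    cells[doublet_flag == FALSE][subset %in% want_subset],
    on = "cell_id", nomatch = NULL]
  if (!is.null(want_tissue)) dat <- dat[tissue %in% want_tissue]
  dat <- clone_table$clones[, .(clone_id, size)][dat, on = "clone_id"]
  dat <- as.data.table(scores)[dat, on = "cell_id", nomatch = NULL]
  per_donor <- dat[, .(mean_score = mean(score)),
                   by = .(donor_id, expanded = size >= 2)]
  w <- data.table::dcast(per_donor, donor_id ~ expanded,
                         value.var = "mean_score")
  setnames(w, c("TRUE", "FALSE"), c("expanded", "unexpanded"),
           skip_absent = TRUE)
  for (col in c("expanded", "unexpanded"))
    if (!col %in% names(w)) w[[col]] <- NA_real_
  w <- w[!is.na(expanded) & !is.na(unexpanded)]
  if (nrow(w) < 2) {
    return(list(per_donor = w[], mean_diff = mean(w$expanded - w$unexpanded),
                statistic = NA_real_, p = NA_real_, n_pairs = nrow(w)))
  }
  tt <- t.test(w$expanded, w$unexpanded, paired = TRUE)
  list(per_donor = w[], mean_diff = mean(w$expanded - w$unexpanded),
       statistic = unname(tt$statistic), p = tt$p.value, n_pairs = nrow(w))
}
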