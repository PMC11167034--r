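# Clonal expansion, overlap, trafficking and differential-abundance
# statistics.
#
# Repertoire overlap is quantified with the Morisita-Horn index (bounded in
# [0, 1]; the classical Morisita index can exceed 1), computed on per-clone
# cell counts per subset.

#' Morisita-Horn overlap between two clone count vectors
#'
#' `MH = 2 * sum(a_i b_i) / ((D_a + D_b) * N_a * N_b)` with
#' `D_a = sum(a_i^2) / N_a^2`, over the union of clone ids. Equals 1 iff the
#' relative abundances are identical over the union and 0 iff the clone sets
#' are disjoint.
#'
#' @param a,b named nonnegative counts (clone id -> cells).
#' @return index in \[0, 1\], or `NA_real_` when either side is empty.
#' @export
morisita_horn <- function(a, b) {
  if (length(a) == 0 || length(b) == 0 || sum(a) == 0 || sum(b) == 0)
    return(NA_real_)
  if (any(a < 0) || any(b < 0)) stop("counts must be nonnegative")
  ids <- union(names(a), names(b))
  av <- setNames(rep(0, length(ids)), ids); av[names(a)] <- av[names(a)] + a
  bv <- setNames(rep(0, length(ids)), ids); bv[names(b)] <- bv[names(b)] + b
  na <- sum(av); nb <- sum(bv)
  da <- sum(av^2) / na^2
  db <- sum(bv^2) / nb^2
  2 * sum(av * bv) / ((da + db) * na * nb)
}

#' Pairwise Morisita-Horn clonal overlap between subsets
#'
#' For each subset within a stratum (a tissue, or all tissues pooled), the
#' per-clone cell count vector is computed from clone assignments and the
#' Morisita-Horn index evaluated for every subset pair. Cell counts (not
#' clone-collapsed counts) are used; this choice is recorded in the
#' `"metadata"` attribute.
#'
#' @param clone_table a `clone_table`.
#' @param cells cell metadata.
#' @param stratum tissue label (`"SYN"`, `"PBL"`) or `NULL` for all cells.
#' @param subsets optional subset order; default: all subsets with clones.
#' @return symmetric matrix with `NA` rows/columns for subsets without
#'   clones; attribute `metadata` records the index variant and counting
#'   convention.
#' @export
overlap_matrix <- function(clone_table, cells, stratum = NULL,
                           subsets = NULL) {
  cells <- as.data.table(cells)
  dat <- clone_table$cells[cells[doublet_flag == FALSE],
                           on = "cell_id", nomatch = NULL]
  if (!is.null(stratum)) dat <- dat[tissue == stratum]
  subsets <- subsets %||% sort(unique(dat$subset))
  counts <- lapply(setNames(subsets, subsets), function(s) {
    x <- dat[subset == s, .N, by = clone_id]
    setNames(x$N, x$clone_id)
  })
  m <- matrix(NA_real_, length(subsets), length(subsets),
              dimnames = list(subsets, subsets))
  for (i in seq_along(subsets)) for (j in seq_len(i)) {
    v <- morisita_horn(counts[[i]], counts[[j]])
    m[i, j] <- v; m[j, i] <- v
  }
  attr(m, "metadata") <- list(index = "Morisita-Horn",
                              counts = "cells per clone per subset",
                              stratum = stratum %||% "all")
  m
}

#' Per-donor fraction of a subset's cells in expanded clones
#'
#' Expansion is defined as membership in a clone of two or more cells
#' (donor-wide clone size). The denominator is the subset's receptor-bearing,
#' clone-assigned cells; donors without such cells are excluded from the
#' summary.
#'
#' @param cells cell metadata.
#' @param clone_table a `clone_table`.
#' @param subset subset label.
#' @param tissue optional tissue restriction for the numerator/denominator
#'   cells (clone sizes remain donor-wide).
#' @param min_size clone size threshold defining "expanded" (default 2).
#' @return list with `per_donor` (donor_id, n, frac), `mean`, and `range`.
#' @export
expansion_fraction <- function(cells, clone_table, subset, tissue = NULL,
                               min_size = 2L) {
  cells <- as.data.table(cells)
  sizes <- clone_table$clones[, .(clone_id, size)]
  want_subset <- subset
  want_tissue <- tissue
  dat <- clone_table$cells[
    cells[doublet_flag == FALSE][subset %in% want_subset],
    on = "cell_id", nomatch = NULL]
  if (!is.null(want_tissue)) dat <- dat[tissue %in% want_tissue]
  dat <- sizes[dat, on = "clone_id"]
  per_donor <- dat[, .(n = .N, frac = mean(size >= min_size)), by = donor_id]
  list(per_donor = per_donor[],
       mean = mean(per_donor$frac),
       range = if (nrow(per_donor)) range(per_donor$frac) else c(NA, NA))
}

#' Composition of the most expanded clones within a tissue
#'
#' Ranks clones by their cell count within the stratum tissue (ties broken by
#' clone id), returns the top `n` with per-subset cell counts and a flag for
#' clones also detected in the donor's other tissue.
#'
#' @param clone_table a `clone_table`.
#' @param cells cell metadata.
#' @param n number of clones (all clones if fewer are present).
#' @param tissue stratum tissue.
#' @return list with `clones` (ranked summary) and `composition` (long
#'   clone x subset counts).
#' @export
top_clone_composition <- function(clone_table, cells, n = 50L,
                                  tissue = "SYN") {
  cells <- as.data.table(cells)
  want_tissue <- tissue
  dat <- clone_table$cells[cells[doublet_flag == FALSE],
                           on = "cell_id", nomatch = NULL]
  in_tissue <- dat[tissue %in% want_tissue]
  other <- dat[!tissue %in% want_tissue, unique(clone_id)]
  sizes <- in_tissue[, .(size = .N), by = .(clone_id, donor_id)]
  setorder(sizes, -size, clone_id)
  top <- head(sizes, n)
  top[, shared := clone_id %in% other]
  comp <- in_tissue[clone_id %in% top$clone_id,
                    .(n_cells = .N), by = .(clone_id, subset)]
  list(clones = top[], composition = comp[])
}

#' Cross-tissue clone trafficking summary
#'
#' For every clone detected in both tissues of a donor, reports per-tissue
#' sizes and per-tissue subset composition.
#'
#' @param clone_table a `clone_table`.
#' @param cells cell metadata.
#' @return list with `clones` (clone_id, donor_id, n_syn, n_pbl) and
#'   `composition` (clone x tissue x subset counts).
#' @export
trafficking_summary <- function(clone_table, cells) {
  cells <- as.data.table(cells)
  dat <- clone_table$cells[cells[doublet_flag == FALSE],
                           on = "cell_id", nomatch = NULL]
  per <- dat[, .(n_syn = sum(tissue == "SYN"), n_pbl = sum(tissue == "PBL")),
             by = .(clone_id, donor_id)]
  shared <- per[n_syn > 0 & n_pbl > 0]
  comp <- dat[clone_id %in% shared$clone_id,
              .(n_cells = .N), by = .(clone_id, tissue, subset)]
  list(clones = shared[], composition = comp[])
}

.aa_standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' CDR3 amino-acid length and net charge
#'
#' Net charge is the count of basic residues (R, K) minus acidic residues
#' (D, E). Sequences containing non-standard residues trigger a warning;
#' their charge is still computed from the standard residues present.
#'
#' @param chains chain table with `cdr3_aa`.
#' @return data.table with `cell_id`, `contig_id`, `locus`, `length`,
#'   `charge`.
#' @export
cdr3_properties <- function(chains) {
  chains <- as.data.table(chains)
  if (nrow(chains) == 0 || any(is.na(chains$cdr3_aa)) ||
      any(!nzchar(chains$cdr3_aa)))
    stop("empty CDR3 amino-acid sequence")
  ch <- strsplit(chains$cdr3_aa, "")
  nonstd <- vapply(ch, function(x) any(!x %in% .aa_standard), logical(1))
  if (any(nonstd))
    warning(sum(nonstd), " CDR3 sequence(s) contain non-standard residues; ",
            "those residues are excluded from the charge computation")
  cnt <- function(x, res) sum(x %in% res)
  chains[, .(cell_id, contig_id, locus,
             length = nchar(cdr3_aa),
             charge = vapply(ch, function(x)
               cnt(x, c("R", "K")) - cnt(x, c("D", "E")), numeric(1)))]
}

#' Per-sample composition of selected subsets
#'
#' Fraction of cells belonging to `subsets` among the cells of a compartment
#' (e.g. CD4) or lineage (T/B), per sample.
#'
#' @param cells cell metadata.
#' @param subsets character, numerator subset labels.
#' @param compartment optional compartment restriction for the denominator.
#' @param lineage optional lineage restriction for the denominator.
#' @return data.table with `sample_id`, `donor_id`, `tissue`, `n_total`,
#'   `n_subset`, `frac`.
#' @export
subset_composition <- function(cells, subsets, compartment = NULL,
                               lineage = NULL) {
  cells <- as.data.table(cells)
  want_cmp <- compartment
  want_lin <- lineage
  want_sub <- subsets
  if (!is.null(want_cmp)) cells <- cells[compartment %in% want_cmp]
  if (!is.null(want_lin)) cells <- cells[lineage %in% want_lin]
  cells[, .(n_total = .N, n_subset = sum(subset %in% want_sub),
            frac = mean(subset %in% want_sub)),
        by = .(sample_id, donor_id, tissue)]
}

#' Paired differential abundance between tissues
#'
#' For each requested subset, computes the per-donor fraction of the
#' denominator cells (lineage or compartment) in each tissue and tests the
#' paired SYN - PBL differences with a two-sided paired t-test (the default)
#' or a Wilcoxon signed-rank test. Only donors with both tissues contribute;
#' with fewer than two complete pairs the p-value is `NA`.
#'
#' @param cells cell metadata.
#' @param subsets subset label(s) to test.
#' @param denominator `"lineage"` (default) or `"compartment"`.
#' @param method `"t"` or `"wilcoxon"`.
#' @param correction `"none"` (default; raw p-values) or `"holm"`.
#' @return data.table with one row per subset: mean per-tissue fractions,
#'   mean difference, statistic, `p`, `n_pairs`; attribute `per_donor`
#'   carries the donor-level fractions.
#' @export
paired_abundance_test <- function(cells, subsets,
                                  denominator = c("lineage", "compartment"),
                                  method = c("t", "wilcoxon"),
                                  correction = c("none", "holm")) {
  denominator <- match.arg(denominator)
  method <- match.arg(method)
  correction <- match.arg(correction)
  cells <- as.data.table(cells)
  res <- list()
  donor_rows <- list()
  for (s in subsets) {
    denom_val <- unique(cells[subset == s,
                              if (denominator == "lineage") lineage
                              else compartment])
    if (length(denom_val) != 1)
      stop("subset ", s, " maps to multiple ", denominator, " values")
    den <- if (denominator == "lineage") cells[lineage == denom_val]
           else cells[compartment == denom_val]
    fr <- den[, .(frac = mean(subset == s)), by = .(donor_id, tissue)]
    w <- data.table::dcast(fr, donor_id ~ tissue, value.var = "frac")
    for (col in c("SYN", "PBL")) if (!col %in% names(w)) w[[col]] <- NA_real_
    w <- w[!is.na(SYN) & !is.na(PBL)]
    donor_rows[[s]] <- w[, .(subset = s, donor_id, SYN, PBL)]
    if (nrow(w) < 2) {
      res[[s]] <- data.table(subset = s, mean_syn = mean(w$SYN),
                             mean_pbl = mean(w$PBL),
                             mean_diff = mean(w$SYN - w$PBL),
                             statistic = NA_real_, p = NA_real_,
                             n_pairs = nrow(w))
      next
    }
    d <- w$SYN - w$PBL
    if (method == "t") {
      tt <- if (sd(d) == 0)
        list(statistic = c(t = 0), p.value = if (all(d == 0)) 1 else NA_real_)
      else t.test(w$SYN, w$PBL, paired = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(w$SYN, w$PBL, paired = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    res[[s]] <- data.table(subset = s, mean_syn = mean(w$SYN),
                           mean_pbl = mean(w$PBL), mean_diff = mean(d),
                           statistic = stat, p = p, n_pairs = nrow(w))
  }
  out <- rbindlist(res)
  if (correction == "holm") out[, p_adj := stats::p.adjust(p, "holm")]
  setattr(out, "per_donor", rbindlist(donor_rows))
  out[]
}
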