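# Cell-level QC and receptor chain filtering.
#
# Thresholds default to the study's published criteria: >= 1000 mapped reads,
# > 500 detected genes, < 20% mitochondrial reads; TCR cells keep only their
# two most expressed chains and must retain an alpha-like + beta-like pair;
# BCR chains must be high-confidence, full-length, CDR3 >= 5 aa / >= 15 nt,
# with at most two heavy and two light chains per cell.

#' Apply cell-level quality control
#'
#' Removes cells failing any of the read, gene or mitochondrial thresholds.
#' Per-sample removal counts are attached as attribute `"qc_log"`.
#'
#' @param cells cell metadata table.
#' @param min_reads minimum mapped reads (cells below are removed).
#' @param min_genes cells must have strictly more detected genes.
#' @param max_mito cells must have strictly less mitochondrial fraction.
#' @return filtered cell table with attribute `qc_log`.
#' @export
apply_cell_qc <- function(cells, min_reads = 1000, min_genes = 500,
                          max_mito = 0.20) {
  cells <- as.data.table(cells)
  keep <- cells$n_reads >= min_reads & cells$n_genes > min_genes &
    cells$pct_mito < max_mito
  log <- cells[!keep, .(removed = .N), by = sample_id][
    cells[, .(n_cells = .N), by = sample_id], on = "sample_id"]
  log[is.na(removed), removed := 0L]
  out <- cells[keep]
  setattr(out, "qc_log", log[])
  out
}

.alpha_like <- c("TRA", "TRG")
.beta_like <- c("TRB", "TRD")

#' Filter TCR chains to the top two expressed, paired chains per cell
#'
#' Within each cell, TCR chains are ranked by UMI count (ties broken by read
#' count, then contig id) and only the top two retained. Cells whose retained
#' chains cover only one locus class (alpha-like TRA/TRG or beta-like
#' TRB/TRD) - including single-chain cells - have all TCR information
#' removed. Non-TCR rows pass through untouched.
#'
#' @param chains canonical chain table.
#' @return filtered chain table.
#' @export
filter_tcr_chains <- function(chains) {
  chains <- as.data.table(chains)
  tcr <- chains[locus %in% TCR_LOCI]
  other <- chains[!locus %in% TCR_LOCI]
  if (nrow(tcr) == 0) return(chains[])
  setorder(tcr, cell_id, -umis, -reads, contig_id, na.last = TRUE)
  tcr[, chain_rank := seq_len(.N), by = cell_id]
  tcr <- tcr[chain_rank <= 2L]
  tcr[, keep_chain := any(locus %in% .alpha_like) &&
        any(locus %in% .beta_like), by = cell_id]
  tcr <- tcr[keep_chain == TRUE]
  tcr[, c("chain_rank", "keep_chain") := NULL]
  out <- rbind(tcr, other)
  setorder(out, cell_id, locus)
  out[]
}

#' Filter BCR chains
#'
#' Chain-level filters first (high-confidence, full-length, CDR3 amino-acid
#' length >= 5, CDR3 nucleotide length >= 15), then cells left with more than
#' two heavy (IGH) or more than two light (IGK+IGL) chains have all their BCR
#' information removed. Non-BCR rows pass through untouched.
#'
#' @param chains canonical chain table.
#' @param min_cdr3_aa,min_cdr3_nt minimum CDR3 lengths.
#' @return filtered chain table.
#' @export
filter_bcr_chains <- function(chains, min_cdr3_aa = 5L, min_cdr3_nt = 15L) {
  chains <- as.data.table(chains)
  bcr <- chains[locus %in% BCR_LOCI]
  other <- chains[!locus %in% BCR_LOCI]
  if (nrow(bcr) == 0) return(chains[])
  bcr <- bcr[high_confidence %in% TRUE & full_length %in% TRUE &
               !is.na(cdr3_aa) & nchar(cdr3_aa) >= min_cdr3_aa &
               !is.na(cdr3_nt) & nchar(cdr3_nt) >= min_cdr3_nt]
  if (nrow(bcr)) {
    bcr[, n_igh := sum(locus == "IGH"), by = cell_id]
    bcr[, n_light := sum(locus %in% c("IGK", "IGL")), by = cell_id]
    bcr <- bcr[n_igh <= 2L & n_light <= 2L]
    bcr[, c("n_igh", "n_light") := NULL]
  }
  out <- rbind(bcr, other)
  setorder(out, cell_id, locus)
  out[]
}

#' Update per-cell receptor presence flags from a chain table
#'
#' @param cells cell metadata table.
#' @param chains chain table (typically after QC filtering).
#' @return copy of `cells` with `has_tcr` / `has_bcr` recomputed.
#' @export
update_receptor_flags <- function(cells, chains) {
  cells <- copy(as.data.table(cells))
  cells[, has_tcr := cell_id %in% chains[locus %in% TCR_LOCI, cell_id]]
  cells[, has_bcr := cell_id %in% chains[locus %in% BCR_LOCI, cell_id]]
  cells[]
}

#' Flag cross-lineage (TCR+BCR) doublets
#'
#' Marks cells that retain at least one TCR and at least one BCR chain after
#' chain QC. Flagged cells are excluded from all downstream repertoire
#' statistics by the clonotyping and analytics functions.
#'
#' @param cells cell metadata table.
#' @param chains chain table after chain QC.
#' @return copy of `cells` with `doublet_flag` set.
#' @export
flag_cross_lineage_doublets <- function(cells, chains) {
  cells <- update_receptor_flags(cells, chains)
  cells[, doublet_flag := has_tcr & has_bcr]
  cells[]
}

#' Per-sample receptor recovery after QC
#'
#' Fraction of cells per sample with an associated TCR or BCR.
#'
#' @param cells cell metadata table with up-to-date `has_tcr` / `has_bcr`.
#' @return data.table with `sample_id`, `tissue`, `n_cells`, `frac`.
#' @export
receptor_recovery <- function(cells) {
  as.data.table(cells)[, .(n_cells = .N, frac = mean(has_tcr | has_bcr)),
                       by = .(sample_id, tissue)]
}

#' Run the full ingest stage: cell QC, chain QC, doublet flagging
#'
#' @param cells raw cell metadata.
#' @param chains raw canonical chain table.
#' @param min_reads,min_genes,max_mito cell QC thresholds
#'   (see [apply_cell_qc()]).
#' @return list with filtered `cells` (flags updated), filtered `chains`, and
#'   a `log` list of per-filter removal counts.
#' @export
ingest <- function(cells, chains, min_reads = 1000, min_genes = 500,
                   max_mito = 0.20) {
  cells_qc <- apply_cell_qc(cells, min_reads, min_genes, max_mito)
  qc_log <- attr(cells_qc, "qc_log", exact = TRUE)
  chains <- as.data.table(chains)[cell_id %in% cells_qc$cell_id]
  n0 <- nrow(chains)
  chains <- filter_tcr_chains(chains)
  n1 <- nrow(chains)
  chains <- filter_bcr_chains(chains)
  n2 <- nrow(chains)
  cells_qc <- flag_cross_lineage_doublets(cells_qc, chains)
  list(cells = cells_qc, chains = chains,
       log = list(qc = qc_log,
                  cells_removed = nrow(as.data.table(cells)) - nrow(cells_qc),
                  tcr_chains_removed = n0 - n1,
                  bcr_chains_removed = n1 - n2,
                  doublets_flagged = sum(cells_qc$doublet_flag)))
}
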