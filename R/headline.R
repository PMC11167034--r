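# Cohort-level headline statistics: the printed quantities the synthetic
# preset encodes, recomputed end-to-end through the pipeline stages.

#' Headline cohort statistics (composition, expansion, recovery, switching)
#'
#' Runs ingest (cell + chain QC, doublet flagging), TCR clonotyping and
#' switch classification on a cohort and returns the ten cohort-level summary
#' statistics the paper-default preset encodes, on the percent scale:
#'
#' * `t1`/`t2`: mean per-blood/per-synovial-sample percentage of CD4 T cells
#'   in the naive subset;
#' * `t3`: mean across donors of the per-donor percentage of synovial Tph
#'   cells in expanded (size >= 2) TCR clones;
#' * `t4`/`t5`: mean per-blood/per-synovial-sample percentage of B cells in
#'   naive subsets;
#' * `t6`/`t7`: mean per-synovial/per-blood-sample percentage of lymphocytes
#'   with a TCR or BCR after chain QC;
#' * `t8`-`t10`: pooled class-switched percentage among memory, ABC and
#'   activated B cells.
#'
#' @param cohort a `clonolink_cohort` (or a `cohort_config` to generate).
#' @return named numeric vector `t1`..`t10` (percent) with attribute `n`
#'   (named vector of the problem sizes behind each value).
#' @export
cohort_headline_stats <- function(cohort) {
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  ing <- ingest(cohort$cells, cohort$chains)
  cells <- ing$cells
  chains <- ing$chains

  naive_cd4 <- subset_composition(cells, "CD4-naive", compartment = "CD4")
  naive_b <- subset_composition(cells, c("B-naive-IgD-high",
                                         "B-naive-IgD-low"),
                                compartment = "B")
  rec <- receptor_recovery(cells)
  tcr <- call_tcr_clones(cells, chains)
  exp_tph <- expansion_fraction(cells, tcr, "CD4-Tph", tissue = "SYN")
  sw <- suppressWarnings(classify_switch(chains))
  swm <- merge(sw[!is.na(switched)],
               cells[doublet_flag == FALSE, .(cell_id, subset)],
               by = "cell_id")
  pooled_switch <- function(s) swm[subset == s, mean(switched)]

  vals <- c(
    t1 = 100 * naive_cd4[tissue == "PBL", mean(frac)],
    t2 = 100 * naive_cd4[tissue == "SYN", mean(frac)],
    t3 = 100 * exp_tph$mean,
    t4 = 100 * naive_b[tissue == "PBL", mean(frac)],
    t5 = 100 * naive_b[tissue == "SYN", mean(frac)],
    t6 = 100 * rec[tissue == "SYN", mean(frac)],
    t7 = 100 * rec[tissue == "PBL", mean(frac)],
    t8 = 100 * pooled_switch("B-memory"),
    t9 = 100 * pooled_switch("B-ABC"),
    t10 = 100 * pooled_switch("B-activated"))
  attr(vals, "n") <- c(
    t1 = naive_cd4[tissue == "PBL", sum(n_total)],
    t2 = naive_cd4[tissue == "SYN", sum(n_total)],
    t3 = nrow(exp_tph$per_donor),
    t4 = naive_b[tissue == "PBL", sum(n_total)],
    t5 = naive_b[tissue == "SYN", sum(n_total)],
    t6 = rec[tissue == "SYN", sum(n_cells)],
    t7 = rec[tissue == "PBL", sum(n_cells)],
    t8 = swm[subset == "B-memory", .N],
    t9 = swm[subset == "B-ABC", .N],
    t10 = swm[subset == "B-activated", .N])
  vals
}
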