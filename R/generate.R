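# Synthetic paired-transcriptome + receptor cohort generator.
#
# The generator emulates the statistical structure of a matched
# synovium/blood single-cell study: per-tissue subset composition, clone-size
# spectra with subset-specific expansion, per-subset SHM and isotype-switch
# probabilities, per-tissue receptor-recovery dropout, cross-tissue clone
# trafficking, planted HLA-matched viral CDR3beta sequences, and expression
# shifts in expanded cells. Every cell's ground truth (clone, germline,
# mutation positions, isotype, expansion, planted matches) is returned so
# downstream stages can be validated exactly.

# split a pool of m expanded cells into clone sizes >= 2 drawn from a
# truncated geometric law P(s) = (1-q) q^(s-2); a leftover single cell is
# absorbed into the last clone; m < 2 yields no clone (the cell reverts to
# unexpanded)
partition_clone_sizes <- function(m, q) {
  if (m < 2) return(integer(0))
  sizes <- integer(0)
  left <- m
  while (left >= 2) {
    s <- min(2L + rgeom(1L, 1 - q), left)
    sizes <- c(sizes, s)
    left <- left - s
  }
  if (left == 1L) sizes[length(sizes)] <- sizes[length(sizes)] + 1L
  sizes
}

#' Generate a synthetic paired single-cell + receptor cohort
#'
#' Produces cell metadata, receptor chains, an optional gene-count matrix,
#' the germline reference, a donor HLA table, a viral TCR reference table,
#' and full ground truth, according to a [cohort_config()]. The output is
#' fully determined by `config$seed`.
#'
#' Cells are partitioned into samples (tissue SYN for all donors, PBL only
#' for the first `n_blood_donors`); clone membership is sampled within
#' (donor, tissue, subset) from the configured expansion fractions; BCR heavy
#' chains are germline V/J segments with Bernoulli per-site substitutions
#' outside CDR3 at the subset's SHM rate (clone members share germline and
#' CDR3 but receive independent SHM draws); receptors are dropped per cell
#' with probability 1 - `recovery_prob[tissue]`; a `trafficking_frac`
#' fraction of each donor's expanded clones is seeded in both tissues; the
#' count matrix is negative-binomial with signature genes shifted by the
#' configured log fold-change in expanded cells of the target subset.
#'
#' @param config a [cohort_config()].
#' @return object of class `clonolink_cohort`: list with elements `cells`,
#'   `chains`, `counts` (dgCMatrix genes x cells, or NULL), `germline`,
#'   `hla`, `viral_ref`, `truth` (list: `clones`, `bcr`, `doublets`,
#'   `viral`, `signature_genes`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(derive_seed(config$seed, "cohort"))

  donors <- sprintf("D%02d", seq_len(config$n_donors))
  samples <- data.table(donor_id = donors, tissue = "SYN")
  if (config$n_blood_donors > 0)
    samples <- rbind(samples, data.table(
      donor_id = donors[seq_len(config$n_blood_donors)], tissue = "PBL"))
  samples[, sample_id := paste0(donor_id, "-", tissue)]

  ## ---- cell metadata ------------------------------------------------------
  cell_list <- list()
  for (i in seq_len(nrow(samples))) {
    tis <- samples$tissue[i]
    for (lin in c("T", "B")) {
      n <- if (lin == "T") config$cells_per_sample_T else config$cells_per_sample_B
      if (n == 0) next
      comp <- config$composition[[tis]][[lin]]
      if (is.null(comp) || !length(comp)) next
      cell_list[[length(cell_list) + 1L]] <- data.table(
        sample_id = samples$sample_id[i], donor_id = samples$donor_id[i],
        tissue = tis, lineage = lin,
        subset = sample(names(comp), n, replace = TRUE, prob = comp))
    }
  }
  cells <- rbindlist(cell_list)
  cells[, cell_id := sprintf("%s:C%05d", sample_id, seq_len(.N)), by = sample_id]
  cells[, compartment := unname(config$compartment[subset])]
  qc <- config$qc
  ncell <- nrow(cells)
  cells[, n_reads := pmax(100L, as.integer(round(
    rlnorm(ncell, qc$reads_meanlog, qc$reads_sdlog))))]
  cells[, n_genes := pmax(50L, as.integer(round(
    rlnorm(ncell, qc$genes_meanlog, qc$genes_sdlog))))]
  cells[, pct_mito := rbeta(ncell, qc$mito_shape1, qc$mito_shape2)]
  cells[, doublet_flag := FALSE]

  ## ---- receptor recovery and clone structure ------------------------------
  cells[, recovered := runif(ncell) < config$recovery_prob[tissue]]
  exp_frac <- setNames(config$expansion$frac, config$expansion$subset)
  size_q <- setNames(config$expansion$size_param, config$expansion$subset)
  cells[, expanded := recovered & runif(ncell) < exp_frac[subset]]

  setorder(cells, cell_id)
  cells[, clone_id := NA_character_]
  assign_list <- list()
  grp <- cells[recovered == TRUE,
               .(cell_ids = list(cell_id), exp = list(expanded)),
               by = .(donor_id, tissue, subset)]
  for (i in seq_len(nrow(grp))) {
    ids <- grp$cell_ids[[i]]
    is_exp <- grp$exp[[i]]
    exp_ids <- sample(ids[is_exp])          # random clone composition
    sizes <- partition_clone_sizes(length(exp_ids), size_q[grp$subset[i]])
    labs <- rep(NA_character_, length(ids))
    names(labs) <- ids
    if (length(sizes)) {
      cl <- rep(seq_along(sizes), sizes)
      labs[exp_ids[seq_len(sum(sizes))]] <- sprintf(
        "%s|%s|%s|c%03d", grp$donor_id[i], grp$tissue[i], grp$subset[i], cl)
    }
    sing <- ids[is.na(labs[ids])]
    labs[sing] <- paste0(grp$donor_id[i], "|s|", sing)
    assign_list[[i]] <- data.table(cell_id = names(labs), clone_id = labs)
  }
  if (length(assign_list)) {
    assign_dt <- rbindlist(assign_list)
    cells[assign_dt, clone_id := i.clone_id, on = "cell_id"]
  }
  cells[, expanded := FALSE]
  cells[!is.na(clone_id) & !grepl("|s|", clone_id, fixed = TRUE),
        expanded := TRUE]

  ## ---- cross-tissue trafficking -------------------------------------------
  # expanded clones only: a trafficked singleton would retroactively change
  # the tissue-level expansion fraction the config states
  blood_donors <- donors[seq_len(config$n_blood_donors)]
  if (config$trafficking_frac > 0 && length(blood_donors)) {
    exp_clones <- cells[expanded == TRUE & donor_id %in% blood_donors,
                        .(n = .N, tissue = tissue[1], subset = subset[1],
                          donor_id = donor_id[1]), by = clone_id]
    exp_clones <- exp_clones[runif(nrow(exp_clones)) < config$trafficking_frac]
    if (nrow(exp_clones)) {
      for (i in seq_len(nrow(exp_clones))) {
        other <- if (exp_clones$tissue[i] == "SYN") "PBL" else "SYN"
        cand <- cells[donor_id == exp_clones$donor_id[i] & tissue == other &
                        subset == exp_clones$subset[i] & recovered == TRUE &
                        expanded == FALSE, cell_id]
        if (!length(cand)) next
        take <- sample(cand, min(1L + rbinom(1L, 2L, 0.3), length(cand)))
        cells[cell_id %in% take,
              `:=`(clone_id = exp_clones$clone_id[i], expanded = TRUE)]
      }
    }
  }

  ## ---- TCR receptors -------------------------------------------------------
  chains_list <- list()
  t_cells <- cells[lineage == "T" & recovered == TRUE,
                   .(cell_id, clone_id, subset)]
  if (nrow(t_cells)) {
    t_clones <- unique(t_cells[, .(clone_id, subset)])
    ncl <- nrow(t_clones)
    trav <- germline_segments("TRA", "V")
    traj <- germline_segments("TRA", "J")
    trbv <- germline_segments("TRB", "V")
    trbj <- germline_segments("TRB", "J")
    mait_j <- c("TRAJ33", "TRAJ20", "TRAJ12")
    is_mait <- t_clones$subset == "MAIT" &
      runif(ncl) < config$mait$invariant_frac
    av <- sample(setdiff(names(trav), "TRAV1-2"), ncl, replace = TRUE)
    aj <- sample(names(traj), ncl, replace = TRUE)
    av[is_mait] <- "TRAV1-2"
    if (any(is_mait))
      aj[is_mait] <- sample(mait_j, sum(is_mait), replace = TRUE,
                            prob = c(0.6, 0.2, 0.2))
    t_clones[, `:=`(
      a_v = av, a_j = aj, a_cdr3 = random_cdr3_nt(ncl),
      b_v = sample(names(trbv), ncl, replace = TRUE),
      b_j = sample(names(trbj), ncl, replace = TRUE),
      b_cdr3 = random_cdr3_nt(ncl))]
    tc <- t_cells[t_clones, on = c("clone_id", "subset")]
    chains_list$tra <- tc[, .(
      cell_id, locus = "TRA", v_call = a_v, j_call = a_j, c_call = "TRAC",
      cdr3_nt = a_cdr3, sequence = NA_character_,
      cdr3_start = NA_integer_, cdr3_end = NA_integer_)]
    chains_list$trb <- tc[, .(
      cell_id, locus = "TRB", v_call = b_v, j_call = b_j, c_call = "TRBC1",
      cdr3_nt = b_cdr3, sequence = NA_character_,
      cdr3_start = NA_integer_, cdr3_end = NA_integer_)]
  }

  ## ---- BCR receptors (heavy with SHM, light without) -----------------------
  truth_bcr <- data.table()
  b_cells <- cells[lineage == "B" & recovered == TRUE,
                   .(cell_id, clone_id, subset)]
  if (nrow(b_cells)) {
    ighv <- germline_segments("IGH", "V")
    ighj <- germline_segments("IGH", "J")
    b_clones <- unique(b_cells[, .(clone_id, subset)])
    nbc <- nrow(b_clones)
    b_clones[, `:=`(
      h_v = sample(names(ighv), nbc, replace = TRUE),
      h_j = sample(names(ighj), nbc, replace = TRUE),
      h_cdr3 = random_cdr3_nt(nbc),
      l_locus = sample(c("IGK", "IGL"), nbc, replace = TRUE, prob = c(0.6, 0.4)))]
    lv_k <- germline_segments("IGK", "V"); lj_k <- germline_segments("IGK", "J")
    lv_l <- germline_segments("IGL", "V"); lj_l <- germline_segments("IGL", "J")
    b_clones[, l_v := ifelse(l_locus == "IGK",
                             sample(names(lv_k), nbc, replace = TRUE),
                             sample(names(lv_l), nbc, replace = TRUE))]
    b_clones[, l_j := ifelse(l_locus == "IGK",
                             sample(names(lj_k), nbc, replace = TRUE),
                             sample(names(lj_l), nbc, replace = TRUE))]
    b_clones[, l_cdr3 := random_cdr3_nt(nbc)]
    bc <- b_cells[b_clones, on = c("clone_id", "subset")]

    rate <- config$shm_rate[bc$subset]
    rate[is.na(rate)] <- 0
    vmut <- mutate_germline(unname(ighv[bc$h_v]), rate)
    jmut <- mutate_germline(unname(ighj[bc$h_j]), rate)
    v_len <- nchar(vmut$seq)
    c_len <- nchar(bc$h_cdr3)
    switched <- runif(nrow(bc)) < config$switch_prob[bc$subset]
    switched[is.na(switched)] <- FALSE
    c_call <- character(nrow(bc))
    if (any(switched))
      c_call[switched] <- sample(c("IGHG1", "IGHG2", "IGHG3", "IGHA1", "IGHA2"),
                                 sum(switched), replace = TRUE,
                                 prob = c(0.35, 0.25, 0.10, 0.20, 0.10))
    if (any(!switched))
      c_call[!switched] <- sample(c("IGHM", "IGHD"), sum(!switched),
                                  replace = TRUE, prob = c(0.9, 0.1))
    chains_list$igh <- data.table(
      cell_id = bc$cell_id, locus = "IGH", v_call = bc$h_v, j_call = bc$h_j,
      c_call = c_call, cdr3_nt = bc$h_cdr3,
      sequence = paste0(vmut$seq, bc$h_cdr3, jmut$seq),
      cdr3_start = v_len + 1L, cdr3_end = v_len + c_len)
    chains_list$light <- data.table(
      cell_id = bc$cell_id, locus = bc$l_locus, v_call = bc$l_v,
      j_call = bc$l_j, c_call = ifelse(bc$l_locus == "IGK", "IGKC", "IGLC"),
      cdr3_nt = bc$l_cdr3, sequence = NA_character_,
      cdr3_start = NA_integer_, cdr3_end = NA_integer_)
    truth_bcr <- data.table(
      cell_id = bc$cell_id, subset = bc$subset,
      v_germ = bc$h_v, j_germ = bc$h_j,
      n_v_mut = vmut$n_mut, n_j_mut = jmut$n_mut,
      v_mut_pos = vmut$pos, j_mut_pos = jmut$pos,
      isotype = isotype_of(c_call), switched = switched)
  }

  ## ---- planted cross-lineage doublets --------------------------------------
  planted_doublets <- character(0)
  n_dbl <- round(config$doublet_frac * cells[recovered == TRUE, .N])
  if (n_dbl > 0) {
    planted_doublets <- sample(cells[recovered == TRUE, cell_id], n_dbl)
    dT <- cells[cell_id %in% planted_doublets & lineage == "T", cell_id]
    dB <- cells[cell_id %in% planted_doublets & lineage == "B", cell_id]
    if (length(dT)) {   # stray BCR on a T cell
      ighv <- germline_segments("IGH", "V"); ighj <- germline_segments("IGH", "J")
      hv <- sample(names(ighv), length(dT), replace = TRUE)
      hj <- sample(names(ighj), length(dT), replace = TRUE)
      hc <- random_cdr3_nt(length(dT))
      chains_list$dblB <- data.table(
        cell_id = dT, locus = "IGH", v_call = hv, j_call = hj, c_call = "IGHM",
        cdr3_nt = hc, sequence = paste0(unname(ighv[hv]), hc, unname(ighj[hj])),
        cdr3_start = nchar(ighv[hv]) + 1L,
        cdr3_end = nchar(ighv[hv]) + nchar(hc))
    }
    if (length(dB)) {   # stray TCR pair on a B cell
      trav <- germline_segments("TRA", "V"); traj <- germline_segments("TRA", "J")
      trbv <- germline_segments("TRB", "V"); trbj <- germline_segments("TRB", "J")
      chains_list$dblT <- rbindlist(list(
        data.table(cell_id = dB, locus = "TRA",
                   v_call = sample(setdiff(names(trav), "TRAV1-2"),
                                   length(dB), replace = TRUE),
                   j_call = sample(names(traj), length(dB), replace = TRUE),
                   c_call = "TRAC", cdr3_nt = random_cdr3_nt(length(dB)),
                   sequence = NA_character_, cdr3_start = NA_integer_,
                   cdr3_end = NA_integer_),
        data.table(cell_id = dB, locus = "TRB",
                   v_call = sample(names(trbv), length(dB), replace = TRUE),
                   j_call = sample(names(trbj), length(dB), replace = TRUE),
                   c_call = "TRBC1", cdr3_nt = random_cdr3_nt(length(dB)),
                   sequence = NA_character_, cdr3_start = NA_integer_,
                   cdr3_end = NA_integer_)))
    }
  }

  chains <- if (length(chains_list)) rbindlist(chains_list) else
    data.table(cell_id = character(0), locus = character(0),
               v_call = character(0), j_call = character(0),
               c_call = character(0), cdr3_nt = character(0),
               sequence = character(0), cdr3_start = integer(0),
               cdr3_end = integer(0))
  if (nrow(chains)) {
    chains[, cdr3_aa := translate_nt(cdr3_nt)]
    chains[, umis := 1L + rpois(.N, 3)]
    chains[, reads := umis * (20L + rpois(.N, 10))]
    chains[, high_confidence := TRUE]
    chains[, full_length := TRUE]
    chains[, productive := TRUE]
    setorder(chains, cell_id, locus, -umis)
    chains[, contig_id := sprintf("%s_contig_%d", cell_id, seq_len(.N)),
           by = cell_id]
  } else {
    chains[, `:=`(cdr3_aa = character(0), umis = integer(0),
                  reads = integer(0), high_confidence = logical(0),
                  full_length = logical(0), productive = logical(0),
                  contig_id = character(0))]
  }
  setcolorder(chains, c("cell_id", "contig_id", "locus", "v_call", "j_call",
                        "c_call", "cdr3_nt", "cdr3_aa", "umis", "reads",
                        "high_confidence", "full_length", "productive",
                        "sequence", "cdr3_start", "cdr3_end"))

  cells[, has_tcr := cell_id %in% chains[locus %in% TCR_LOCI, cell_id]]
  cells[, has_bcr := cell_id %in% chains[locus %in% BCR_LOCI, cell_id]]

  ## ---- HLA table and viral reference with planted matches ------------------
  allele_pool <- c("A*01:01", "A*02:01", "A*03:01", "A*11:01", "A*24:02",
                   "B*07:02", "B*08:01", "B*15:01", "B*35:01", "B*44:02")
  hla <- rbindlist(lapply(donors, function(d) data.table(
    donor_id = d,
    allele = c(sample(allele_pool[1:5], 2), sample(allele_pool[6:10], 2)))))

  viral_ref <- data.table()
  truth_viral <- data.table()
  vp <- config$viral_plant
  if ((vp$n_reference_rows %||% 0) > 0) {
    nr <- vp$n_reference_rows
    viral_ref <- data.table(
      cdr3b_aa = translate_nt(random_cdr3_nt(nr, 36L, 48L)),
      virus = sample(c("CMV", "EBV", "FLU"), nr, replace = TRUE),
      epitope = sprintf("EP%03d", seq_len(nr)),
      mhc_allele = sample(allele_pool, nr, replace = TRUE))
    n_plant <- min(vp$n_planted_matching_clones %||% 0L, nr)
    if (n_plant > 0 && nrow(t_cells)) {
      cd8 <- cells[compartment == "CD8" & recovered == TRUE & tissue == "SYN" &
                     !(cell_id %in% planted_doublets)]
      cd8_clones <- unique(cd8$clone_id)
      n_plant <- min(n_plant, length(cd8_clones))
      pick <- sample(cd8_clones, n_plant)
      pick_dt <- unique(cells[clone_id %in% pick, .(clone_id, donor_id)])
      trb <- chains[locus == "TRB"][cells[, .(cell_id, clone_id)],
                                    on = "cell_id", nomatch = NULL]
      key <- unique(trb[clone_id %in% pick, .(clone_id, cdr3_aa)])
      pick_dt <- pick_dt[key, on = "clone_id"]
      pick_dt[, allele := vapply(donor_id, function(d)
        sample(hla[donor_id == d, allele], 1), character(1))]
      rows <- seq_len(nrow(pick_dt))
      viral_ref[rows, `:=`(cdr3b_aa = pick_dt$cdr3_aa,
                           mhc_allele = pick_dt$allele)]
      truth_viral <- pick_dt[, .(clone_id, cdr3b_aa = cdr3_aa,
                                 mhc_allele = allele, ref_row = rows)]
      truth_viral[, virus := viral_ref$virus[ref_row]]
    }
  }

  ## ---- expression ----------------------------------------------------------
  counts <- NULL
  signature_genes <- character(0)
  ex <- config$expression
  if ((ex$n_genes %||% 0) > 0) {
    ng <- ex$n_genes
    ns <- min(ex$n_signature_genes %||% 0L, ng)
    genes <- c(if (ns > 0) sprintf("SIG%03d", seq_len(ns)),
               sprintf("G%04d", seq_len(ng - ns)))
    signature_genes <- head(genes, ns)
    mu_g <- c(rlnorm(ns, log(1), 0.5), rlnorm(ng - ns, log(0.3), 1.2))
    f_c <- rlnorm(ncell, 0, 0.3)
    affected <- cells$expanded & cells$subset == (ex$target_subset %||% "")
    blocks <- split(seq_len(ncell), ceiling(seq_len(ncell) / 4000))
    parts <- lapply(blocks, function(ix) {
      mu <- outer(mu_g, f_c[ix])
      if (any(affected[ix]))
        mu[seq_len(ns), affected[ix]] <- mu[seq_len(ns), affected[ix],
                                            drop = FALSE] * exp(ex$effect)
      m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / ex$dispersion),
                  nrow = ng)
      Matrix::Matrix(m, sparse = TRUE)
    })
    counts <- do.call(cbind, parts)
    dimnames(counts) <- list(genes, cells$cell_id)
  }

  truth_clones <- cells[!is.na(clone_id),
                        .(cell_id, clone_id, expanded, tissue, subset)]
  cells_out <- cells[, .(cell_id, sample_id, donor_id, tissue, lineage,
                         compartment, subset, n_reads, n_genes, pct_mito,
                         doublet_flag, has_tcr, has_bcr)]
  structure(list(
    cells = cells_out,
    chains = chains,
    counts = counts,
    germline = germline_reference(),
    hla = hla,
    viral_ref = viral_ref,
    truth = list(clones = truth_clones, bcr = truth_bcr,
                 doublets = planted_doublets, viral = truth_viral,
                 signature_genes = signature_genes),
    config = config
  ), class = "clonolink_cohort")
}

#' @export
print.clonolink_cohort <- function(x, ...) {
  cat("<clonolink_cohort>", nrow(x$cells), "cells,", nrow(x$chains),
      "chains,", length(unique(x$cells$sample_id)), "samples\n")
  invisible(x)
}

isotype_of <- function(c_call) {
  iso <- rep("unknown", length(c_call))
  iso[grepl("^IGHM", c_call)] <- "IgM"
  iso[grepl("^IGHD", c_call)] <- "IgD"
  iso[grepl("^IGHG", c_call)] <- "IgG"
  iso[grepl("^IGHA", c_call)] <- "IgA"
  iso[grepl("^IGHE", c_call)] <- "IgE"
  iso
}

TCR_LOCI <- c("TRA", "TRB", "TRG", "TRD")
BCR_LOCI <- c("IGH", "IGK", "IGL")
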