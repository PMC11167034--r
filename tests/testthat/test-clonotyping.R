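# Clonotype calling: exact TCR keys, greedy BCR clustering vs brute-force
# oracle, size categories, MAIT flags.

simple_cells <- function(ids, donors) {
  data.table::data.table(
    cell_id = ids, sample_id = paste0(donors, "-SYN"), donor_id = donors,
    tissue = "SYN", lineage = "T", compartment = "CD4", subset = "CD4-naive",
    n_reads = 5000L, n_genes = 1000L, pct_mito = 0.05, doublet_flag = FALSE,
    has_tcr = TRUE, has_bcr = FALSE)
}

tcr_pair <- function(cell, a_cdr3, b_cdr3, a_v = "TRAV17", b_v = "TRBV9") {
  data.table::rbindlist(list(
    data.table::data.table(cell_id = cell, contig_id = paste0(cell, "_1"),
                           locus = "TRA", v_call = a_v, j_call = "TRAJ33",
                           c_call = "TRAC", cdr3_nt = a_cdr3,
                           cdr3_aa = "X", umis = 3L, reads = 90L,
                           high_confidence = TRUE, full_length = TRUE,
                           productive = TRUE, sequence = NA_character_,
                           cdr3_start = NA_integer_, cdr3_end = NA_integer_),
    data.table::data.table(cell_id = cell, contig_id = paste0(cell, "_2"),
                           locus = "TRB", v_call = b_v, j_call = "TRBJ1-1",
                           c_call = "TRBC1", cdr3_nt = b_cdr3,
                           cdr3_aa = "Y", umis = 5L, reads = 150L,
                           high_confidence = TRUE, full_length = TRUE,
                           productive = TRUE, sequence = NA_character_,
                           cdr3_start = NA_integer_, cdr3_end = NA_integer_)))
}

test_that("identical TCR keys form one clone within a donor, never across", {
  a <- strrep("TGC", 12); b <- strrep("TGA", 12)
  cells <- simple_cells(c("c1", "c2", "c3", "c4"),
                        c("D1", "D1", "D2", "D1"))
  chains <- data.table::rbindlist(list(
    tcr_pair("c1", a, b), tcr_pair("c2", a, b),   # same donor, same key
    tcr_pair("c3", a, b),                         # same key, other donor
    tcr_pair("c4", a, b, b_v = "TRBV19")))        # same CDR3, other V gene
  ct <- call_tcr_clones(cells, chains)
  cl <- merge(ct$cells, ct$clones, by = "clone_id")
  expect_identical(cl[cell_id == "c1", clone_id], cl[cell_id == "c2", clone_id])
  expect_equal(cl[cell_id == "c1", size], 2L)
  expect_identical(as.character(cl[cell_id == "c1", size_category]), "small")
  expect_false(cl[cell_id == "c3", clone_id] == cl[cell_id == "c1", clone_id])
  expect_false(cl[cell_id == "c4", clone_id] == cl[cell_id == "c1", clone_id])
})

bcr_cells <- function(ids, donors = "D1") {
  x <- simple_cells(ids, donors)
  x[, `:=`(lineage = "B", compartment = "B", subset = "B-memory",
           has_tcr = FALSE, has_bcr = TRUE)]
  x
}

igh_chain <- function(cell, cdr3) {
  data.table::data.table(
    cell_id = cell, contig_id = paste0(cell, "_1"), locus = "IGH",
    v_call = "IGHV3-23", j_call = "IGHJ4", c_call = "IGHM", cdr3_nt = cdr3,
    cdr3_aa = "CARW", umis = 4L, reads = 120L, high_confidence = TRUE,
    full_length = TRUE, productive = TRUE, sequence = NA_character_,
    cdr3_start = NA_integer_, cdr3_end = NA_integer_)
}

test_that("BCR identity thresholds behave as the worked examples state", {
  base <- strrep("ACGTA", 6)                       # 30 nt
  one <- sub("^A", "C", base)                      # 1 mismatch: 29/30
  two <- sub("^ACGTA", "CCGTC", base)              # 2 mismatches: 28/30
  expect_equal(seq_identity(base, one), 29 / 30)
  expect_equal(seq_identity(base, two), 28 / 30)
  cells <- bcr_cells(c("c1", "c2"))
  # 1 mismatch: same clone at 96.5%
  ct <- call_bcr_clones(cells, rbind(igh_chain("c1", base),
                                     igh_chain("c2", one)))
  expect_equal(nrow(ct$clones), 1)
  # 2 mismatches: distinct at 96.5%, same at 80%
  ch2 <- rbind(igh_chain("c1", base), igh_chain("c2", two))
  expect_equal(nrow(call_bcr_clones(cells, ch2)$clones), 2)
  expect_equal(nrow(call_bcr_clones(cells, ch2, threshold = 0.80)$clones), 1)
  # identical sequences cluster at any threshold
  ch3 <- rbind(igh_chain("c1", base), igh_chain("c2", base))
  expect_equal(nrow(call_bcr_clones(cells, ch3, threshold = 1)$clones), 1)
  expect_error(call_bcr_clones(cells, ch3, threshold = 1.5),
               "configuration error")
})

test_that("greedy clustering agrees with brute-force single linkage on families", {
  fam <- cdr3_family_set(60, seed = 31L)
  expect_gte(length(fam$seqs), 100)
  for (thr in c(0.965, 0.80)) {
    g <- clonolink:::greedy_cluster(fam$seqs, threshold = thr)
    bf <- brute_force_single_linkage(fam$seqs, thr)
    # greedy clusters always refine the single-linkage components
    expect_true(all(tapply(bf, g, function(x) length(unique(x))) == 1))
    # every member satisfies the identity bound against its representative
    ord <- order(-nchar(fam$seqs), -rep(1L, length(fam$seqs)), fam$seqs)
    rep_of <- integer(max(g))
    for (i in ord) if (rep_of[g[i]] == 0L) rep_of[g[i]] <- i
    for (i in seq_along(fam$seqs))
      expect_gte(seq_identity(fam$seqs[i], fam$seqs[rep_of[g[i]]]), thr)
    # where identity is transitive at the threshold, the partitions coincide
    comp_sizes <- table(bf)
    transitive <- all(vapply(names(comp_sizes), function(cmp) {
      ix <- which(bf == as.integer(cmp))
      if (length(ix) == 1) return(TRUE)
      all(combn(ix, 2, function(p)
        seq_identity(fam$seqs[p[1]], fam$seqs[p[2]]) >= thr))
    }, logical(1)))
    if (transitive) expect_equal(ari(g, bf), 1)
  }
})

test_that("lowering the threshold never increases the number of clusters", {
  fam <- cdr3_family_set(40, seed = 32L)
  n_tight <- max(clonolink:::greedy_cluster(fam$seqs, threshold = 0.965))
  n_loose <- max(clonolink:::greedy_cluster(fam$seqs, threshold = 0.80))
  expect_lte(n_loose, n_tight)
})

test_that("called BCR clones recover the generator's ground truth (ARI >= 0.95)", {
  co <- generate_cohort(tiny_config(seed = 33L, cells_per_sample_B = 300L))
  ing <- ingest(co$cells, co$chains)
  ct <- call_bcr_clones(ing$cells, ing$chains)
  m <- merge(ct$cells, co$truth$clones[, .(cell_id, clone_id)], by = "cell_id")
  expect_gte(ari(m$clone_id.x, m$clone_id.y), 0.95)
})

test_that("clone size categories use the published bins", {
  ct <- list(clones = data.table::data.table(
    clone_id = c("a", "b", "c", "d", "e"),
    size = c(1L, 3L, 10L, 50L, 150L)))
  out <- categorize_clone_sizes(ct)
  expect_identical(as.character(out$clones$size_category),
                   c("singleton", "small", "medium", "large",
                     "hyperexpanded"))
})

test_that("the invariant MAIT rearrangement is flagged correctly", {
  ch <- data.table::rbindlist(list(
    tcr_pair("m1", strrep("TGC", 12), strrep("TGA", 12), a_v = "TRAV1-2"),
    tcr_pair("m2", strrep("TGC", 12), strrep("TGA", 12), a_v = "TRAV1-2"),
    tcr_pair("m3", strrep("TGC", 12), strrep("TGA", 12), a_v = "TRAV12-1")))
  ch[cell_id == "m2" & locus == "TRA", j_call := "TRAJ42"]
  fl <- flag_invariant_mait(ch)
  expect_identical(fl[order(cell_id), invariant_mait], c(TRUE, FALSE, FALSE))
})

test_that("generator MAIT cells carry the invariant rearrangement, others do not", {
  co <- generate_cohort(tiny_config(seed = 34L))
  ing <- ingest(co$cells, co$chains)
  fl <- flag_invariant_mait(ing$chains)
  m <- merge(fl, ing$cells[, .(cell_id, subset, doublet_flag)], by = "cell_id")
  m <- m[doublet_flag == FALSE]
  expect_gte(m[subset == "MAIT", mean(invariant_mait)], 0.6)
  expect_equal(m[subset != "MAIT" & invariant_mait == TRUE, .N], 0)
})
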