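# Morisita-Horn, overlap matrices, expansion, top clones, trafficking,
# CDR3 properties, paired abundance tests.

test_that("Morisita-Horn matches closed-form values and its invariants", {
  expect_equal(morisita_horn(c(c1 = 5, c2 = 3), c(c1 = 5, c2 = 3)), 1)
  expect_equal(morisita_horn(c(c1 = 5), c(c2 = 7)), 0)
  # worked 2-clone example, computed by hand from the formula:
  # sum(ab) = 4, Na = Nb = 3, Da = Db = 5/9 -> 8/((10/9)*9) = 0.8
  expect_equal(morisita_horn(c(c1 = 2, c2 = 1), c(c1 = 1, c2 = 2)), 0.8)
  # symmetry and scale invariance
  set.seed(41)
  a <- setNames(rpois(20, 4) + 1, paste0("k", 1:20))
  b <- setNames(rpois(20, 4) + 1, paste0("k", 11:30))
  expect_equal(morisita_horn(a, b), morisita_horn(b, a))
  expect_equal(morisita_horn(a * 7, b), morisita_horn(a, b))
  # proportional abundances give exactly 1
  expect_equal(morisita_horn(a, a * 3), 1)
  # empty side is missing, not zero
  expect_true(is.na(morisita_horn(numeric(0), a)))
})

ana_cells <- function(n_per_subset, subsets, donor = "D1", tissue = "SYN") {
  ids <- paste0(donor, tissue, seq_len(sum(n_per_subset)))
  data.table::data.table(
    cell_id = ids, sample_id = paste0(donor, "-", tissue), donor_id = donor,
    tissue = tissue, lineage = "T", compartment = "CD4",
    subset = rep(subsets, n_per_subset), n_reads = 5000L, n_genes = 1000L,
    pct_mito = 0.05, doublet_flag = FALSE, has_tcr = TRUE, has_bcr = FALSE)
}

test_that("overlap matrix reflects shared and disjoint clone pools", {
  cells <- ana_cells(c(6, 6, 6), c("A", "B", "C"))
  # A and B draw from one shared pool of two clones; C is disjoint
  ct <- manual_clone_table(cells$cell_id,
                           c(rep(c("p1", "p2"), 3),
                             rep(c("p1", "p2"), 3),
                             rep(c("q1", "q2"), 3)))
  m <- overlap_matrix(ct, cells, stratum = "SYN")
  expect_equal(m["A", "B"], 1)
  expect_equal(m["A", "C"], 0)
  expect_equal(diag(m), c(A = 1, B = 1, C = 1))
  expect_true(isSymmetric(unname(m)))
})

test_that("synthetic shared-pool subsets overlap more than unrelated ones", {
  set.seed(42)
  cells <- ana_cells(c(40, 40, 40), c("Tph", "Tfh", "Other"))
  pool_shared <- paste0("s", 1:8)
  ct <- manual_clone_table(cells$cell_id, c(
    sample(pool_shared, 40, TRUE), sample(pool_shared, 40, TRUE),
    sample(paste0("u", 1:8), 40, TRUE)))
  m <- overlap_matrix(ct, cells, stratum = "SYN")
  expect_gt(m["Tph", "Tfh"], m["Tph", "Other"])
  expect_gt(m["Tph", "Tfh"], m["Tfh", "Other"])
})

test_that("expansion fraction follows its definition and the generator truth", {
  cells <- ana_cells(4, "Tph")
  # one clone of 2 + two singletons -> 0.5
  ct <- manual_clone_table(cells$cell_id, c("a", "a", "b", "c"))
  ef <- expansion_fraction(cells, ct, "Tph")
  expect_equal(ef$mean, 0.5)
  # all singletons -> 0
  ct0 <- manual_clone_table(cells$cell_id, letters[1:4])
  expect_equal(expansion_fraction(cells, ct0, "Tph")$mean, 0)
  # paper-default synthetic Tph: mean across donors near the preset 12.5%
  cfg <- paper_default_config(
    seed = 43L,
    expression = list(n_genes = 0L, n_signature_genes = 0L, effect = 0,
                      dispersion = 0.5, target_subset = NA_character_))
  co <- generate_cohort(cfg)
  ing <- ingest(co$cells, co$chains)
  ct <- call_tcr_clones(ing$cells, ing$chains)
  ef <- expansion_fraction(ing$cells, ct, "CD4-Tph", tissue = "SYN")
  expect_equal(ef$mean, 0.125, tolerance = 0.25)
  expect_true(all(ef$per_donor$frac >= 0 & ef$per_donor$frac <= 1))
})

test_that("top-clone composition ranks, truncates, and flags cross-tissue clones", {
  syn <- ana_cells(c(10), "A")
  pbl <- ana_cells(c(3), "A", tissue = "PBL")
  cells <- rbind(syn, pbl)
  ids <- c(rep("big", 4), rep("mid", 3), "s1", "s2", "s3",   # SYN
           "big", "p1", "p2")                                 # PBL
  ct <- manual_clone_table(cells$cell_id, ids)
  top <- top_clone_composition(ct, cells, n = 50, tissue = "SYN")
  expect_equal(nrow(top$clones), 5)    # fewer clones than n -> return all
  expect_identical(top$clones$clone_id[1:2], c("big", "mid"))
  expect_true(top$clones[clone_id == "big", shared])
  expect_false(top$clones[clone_id == "mid", shared])
})

test_that("trafficking summary partitions clones and matches the binomial oracle", {
  cfg0 <- tiny_config(seed = 44L, trafficking_frac = 0)
  co0 <- generate_cohort(cfg0)
  ing0 <- ingest(co0$cells, co0$chains)
  ct0 <- call_tcr_clones(ing0$cells, ing0$chains)
  tr0 <- trafficking_summary(ct0, ing0$cells)
  expect_equal(nrow(tr0$clones), 0)
  # planted trafficking: shared-clone count within 3 SE of Binomial(N, frac)
  frac <- 0.25
  cfg <- paper_default_config(
    seed = 45L, trafficking_frac = frac, doublet_frac = 0,
    expression = list(n_genes = 0L, n_signature_genes = 0L, effect = 0,
                      dispersion = 0.5, target_subset = NA_character_))
  co <- generate_cohort(cfg)
  ing <- ingest(co$cells, co$chains)
  ct <- call_tcr_clones(ing$cells, ing$chains)
  tr <- trafficking_summary(ct, ing$cells)
  truth <- co$truth$clones
  blood_donors <- sprintf("D%02d", 1:10)
  n_exp <- truth[expanded == TRUE & substr(clone_id, 1, 3) %in% blood_donors &
                   substr(clone_id, 5, 5) != "s" &
                   grepl("^D\\d+\\|(SYN|PBL)\\|(CD|MA)", clone_id),
                 data.table::uniqueN(clone_id)]
  t_shared <- nrow(tr$clones)
  se <- sqrt(n_exp * frac * (1 - frac))
  expect_lt(abs(t_shared - n_exp * frac), 4 * se)
  # the shared clones and the single-tissue clones partition all clones
  expect_true(all(tr$clones$n_syn > 0 & tr$clones$n_pbl > 0))
  per_clone <- merge(ct$cells, ing$cells[, .(cell_id, tissue)],
                     by = "cell_id")[
    , .(n_tissues = data.table::uniqueN(tissue)), by = clone_id]
  expect_setequal(per_clone[n_tissues == 2, clone_id], tr$clones$clone_id)
  expect_equal(per_clone[n_tissues == 2, .N] + per_clone[n_tissues == 1, .N],
               nrow(ct$clones))
})

test_that("CDR3 properties follow the residue-count oracle", {
  ch <- data.table::data.table(
    cell_id = c("a", "b"), contig_id = c("a1", "b1"), locus = "IGH",
    cdr3_aa = c("CARDKW", "CASSGF"))
  out <- cdr3_properties(ch)
  expect_equal(out$length, c(6L, 6L))
  expect_equal(out$charge, c(1, 0))    # (R+K) - (D) = 1; no charged residues
  expect_error(cdr3_properties(data.table::data.table(
    cell_id = "c", contig_id = "c1", locus = "IGH", cdr3_aa = "")), "empty")
  expect_warning(cdr3_properties(data.table::data.table(
    cell_id = "d", contig_id = "d1", locus = "IGH", cdr3_aa = "CARXDW")),
    "non-standard")
})

test_that("paired abundance test handles ties, requires pairs, detects enrichment", {
  # identical fractions in both tissues -> t = 0, p = 1
  mk <- function(donor) rbind(
    ana_cells(c(5, 5), c("A", "B"), donor = donor, tissue = "SYN"),
    ana_cells(c(5, 5), c("A", "B"), donor = donor, tissue = "PBL"))
  cells <- data.table::rbindlist(lapply(c("D1", "D2", "D3"), mk))
  res <- paired_abundance_test(cells, "A")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # a single complete pair -> missing p
  one <- rbind(ana_cells(5, "A", donor = "D1"),
               ana_cells(5, "A", donor = "D1", tissue = "PBL"))
  expect_true(is.na(paired_abundance_test(one, "A")$p))
  # preset SYN-enriched subset: significant in >= 80% of replicates
  hits <- 0L
  n_rep <- 15L
  for (r in seq_len(n_rep)) {
    cfg <- metadata_config(100L + r,
                           composition = paper_default_config()$composition)
    co <- generate_cohort(cfg)
    p <- paired_abundance_test(co$cells, "CD4-Tph")$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("Wilcoxon variant and Holm correction are available", {
  cfg <- metadata_config(999L, composition = paper_default_config()$composition)
  co <- generate_cohort(cfg)
  res <- paired_abundance_test(co$cells, c("CD4-naive", "CD4-Tph"),
                               method = "wilcoxon", correction = "holm")
  expect_true(all(c("p", "p_adj") %in% names(res)))
  expect_true(all(res$p_adj >= res$p))
})
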