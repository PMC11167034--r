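# Germline assignment, SHM rates, class-switch classification and the
# donor-random-effect models.

igh_with_seq <- function(cell, v_seq, cdr3, j_seq, c_call = "IGHM") {
  data.table::data.table(
    cell_id = cell, contig_id = paste0(cell, "_1"), locus = "IGH",
    v_call = "IGHV?", j_call = "IGHJ?", c_call = c_call, cdr3_nt = cdr3,
    cdr3_aa = "CARW", umis = 4L, reads = 120L, high_confidence = TRUE,
    full_length = TRUE, productive = TRUE,
    sequence = paste0(v_seq, cdr3, j_seq),
    cdr3_start = nchar(v_seq) + 1L,
    cdr3_end = nchar(v_seq) + nchar(cdr3))
}

test_that("germline assignment is exact on unmutated and planted-mutation input", {
  ref <- germline_reference("IGH")
  v <- as.character(ref[attr(ref, "region") == "V"][3])
  vname <- attr(ref, "gene")[attr(ref, "region") == "V"][3]
  j <- as.character(ref[attr(ref, "region") == "J"][2])
  jname <- attr(ref, "gene")[attr(ref, "region") == "J"][2]
  cdr3 <- strrep("TGC", 12)
  # unmutated: identity 1, zero substitutions
  rec <- assign_germline(igh_with_seq("c1", v, cdr3, j), ref)
  expect_identical(rec$v_call_assigned, vname)
  expect_identical(rec$j_call_assigned, jname)
  expect_equal(rec$v_shm, 0L)
  expect_equal(rec$v_identity, 1)
  expect_equal(rec$vj_shm_rate, 0)
  # 3 planted V substitutions + 1 J substitution
  v_mut <- v
  for (p in c(5L, 50L, 200L))
    substr(v_mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(v_mut, p, p))[1]
  j_mut <- j
  substr(j_mut, 10L, 10L) <- setdiff(c("A", "C", "G", "T"),
                                     substr(j_mut, 10L, 10L))[1]
  rec2 <- assign_germline(igh_with_seq("c2", v_mut, cdr3, j_mut), ref)
  expect_identical(rec2$v_call_assigned, vname)
  expect_equal(rec2$v_shm, 3L)
  expect_equal(rec2$j_shm, 1L)
  expect_equal(rec2$len_excl_cdr3, nchar(v) + nchar(j))
  expect_equal(rec2$vj_shm_rate, 4 / (nchar(v) + nchar(j)))
})

test_that("equidistant references resolve by name order; empty reference errors", {
  refA <- paste0(strrep("A", 30))
  refB <- paste0(strrep("A", 29), "T")   # same distance to an A(29)+G probe
  ref <- setNames(c(refA, refB, strrep("G", 20)),
                  c("IGH|VFIRST|V", "IGH|VSECOND|V", "IGH|J1|J"))
  probe <- paste0(strrep("A", 29), "G")
  rec <- assign_germline(igh_with_seq("c1", probe, strrep("TGC", 10),
                                      strrep("G", 20)), ref)
  expect_identical(rec$v_call_assigned, "VFIRST")
  expect_equal(rec$v_identity, 29 / 30)
  expect_error(assign_germline(igh_with_seq("c1", probe, strrep("TGC", 10),
                                            strrep("G", 20)),
                               ref[3]), "configuration error")
})

test_that("shm_rate follows the published formula", {
  expect_equal(shm_rate(3L, 1L, 300L), 4 / 300)
  expect_equal(shm_rate(0L, 0L, 300L), 0)
  expect_error(shm_rate(1L, 1L, 0L), "positive")
})

test_that("generator SHM is recovered per subset within 3 SE", {
  cfg <- tiny_config(seed = 51L, cells_per_sample_B = 400L, doublet_frac = 0)
  co <- generate_cohort(cfg)
  shm <- assign_germline(co$chains, co$germline)
  m <- merge(shm, co$cells[, .(cell_id, subset)], by = "cell_id")
  for (s in names(cfg$shm_rate)) {
    x <- m[subset == s, vj_shm_rate]
    if (length(x) < 100) next
    r <- cfg$shm_rate[[s]]
    se <- sqrt(r * (1 - r) / (336 * length(x)))
    expect_lt(abs(mean(x) - r), 3 * se)
  }
  # exact agreement with planted truth
  tr <- merge(shm, co$truth$bcr, by = "cell_id")
  expect_identical(tr$v_shm, tr$n_v_mut)
  expect_identical(tr$j_shm, tr$n_j_mut)
  expect_identical(tr$v_call_assigned, tr$v_germ)
})

test_that("class-switch classification follows the isotype rules", {
  mk <- function(cell, c_call) igh_with_seq(cell, strrep("A", 30),
                                            strrep("TGC", 10),
                                            strrep("G", 20), c_call = c_call)
  sw <- classify_switch(rbind(mk("a", "IGHG1"), mk("b", "IGHM"),
                              mk("c", "IGHA2"), mk("d", "IGHD")))
  expect_identical(sw[order(cell_id), switched], c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(sw[order(cell_id), isotype], c("IgG", "IgM", "IgA", "IgD"))
  expect_warning(out <- classify_switch(rbind(mk("e", NA_character_),
                                              mk("f", "IGHE"))),
                 "excluded")
  expect_true(all(is.na(out$switched)))
})

test_that("SHM mixed model recovers subset effects with the reference pinned at 0", {
  cfg <- tiny_config(seed = 52L, n_donors = 6L, n_blood_donors = 0L,
                     cells_per_sample_T = 0L, cells_per_sample_B = 400L,
                     doublet_frac = 0, trafficking_frac = 0)
  co <- generate_cohort(cfg)
  shm <- assign_germline(co$chains, co$germline)
  eff <- fit_shm_model(shm, co$cells, reference_subset = "B-naive-IgD-high")
  ref_row <- eff[level == "B-naive-IgD-high"]
  expect_equal(ref_row$estimate, 0)
  # memory > naive by construction: positive effect, CI excluding 0
  mem <- eff[level == "B-memory"]
  true_eff <- cfg$shm_rate[["B-memory"]] - cfg$shm_rate[["B-naive-IgD-high"]]
  expect_gt(mem$estimate, 0)
  expect_gt(mem$ci_lo, 0)
  expect_equal(mem$estimate, true_eff, tolerance = 0.15)
})

test_that("single-donor model falls back to fixed effects with a warning", {
  cfg <- tiny_config(seed = 53L, n_donors = 1L, n_blood_donors = 0L,
                     cells_per_sample_T = 0L, cells_per_sample_B = 300L)
  co <- generate_cohort(cfg)
  shm <- assign_germline(co$chains, co$germline)
  expect_warning(fit_shm_model(shm, co$cells, "B-naive-IgD-high"),
                 "single donor")
})

test_that("switch model: plasma log-odds largest, separation flagged for naive", {
  cfg <- tiny_config(seed = 54L, n_donors = 6L, n_blood_donors = 0L,
                     cells_per_sample_T = 0L, cells_per_sample_B = 500L,
                     doublet_frac = 0)
  co <- generate_cohort(cfg)
  sw <- classify_switch(co$chains)
  expect_warning(
    eff <- fit_switch_model(sw, co$cells, "B-naive-IgD-high"),
    "separation")   # preset naive switch probability is exactly 0
  sub_eff <- eff[term == "subset" & !level %in%
                   c("B-naive-IgD-high", "B-naive-IgD-low")]
  expect_identical(sub_eff[which.max(estimate), level], "B-plasma")
})

test_that("switch model tissue effect covers 0 when switching is tissue-independent", {
  cfg <- tiny_config(seed = 55L, n_donors = 6L, n_blood_donors = 6L,
                     cells_per_sample_T = 0L, cells_per_sample_B = 400L,
                     doublet_frac = 0,
                     switch_prob = c("B-naive-IgD-high" = 0.10,
                                     "B-naive-IgD-low" = 0.15,
                                     "B-activated" = 0.40, "B-ABC" = 0.60,
                                     "B-memory" = 0.70, "B-plasmablast" = 0.85,
                                     "B-plasma" = 0.90))
  co <- generate_cohort(cfg)
  sw <- classify_switch(co$chains)
  eff <- fit_switch_model(sw, co$cells, "B-naive-IgD-high")
  tis <- eff[term == "tissue" & level == "SYN"]
  expect_true(tis$ci_lo <= 0 && tis$ci_hi >= 0)
})

test_that("tissue-within-subset SHM model reports per-subset tissue effects", {
  cfg <- tiny_config(seed = 56L, cells_per_sample_B = 300L)
  co <- generate_cohort(cfg)
  shm <- assign_germline(co$chains, co$germline)
  eff <- fit_shm_model(shm, co$cells, "B-naive-IgD-high",
                       covariate = "tissue_within_subset")
  expect_true(all(c("subset", "level", "estimate") %in% names(eff)))
  expect_true(all(eff[level == "SYN", abs(estimate)] < 0.05))
})
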