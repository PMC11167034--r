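# HLA-restricted viral specificity matching of CD8 TCRbeta chains:
# exact CDR3beta + MHC allele identity against a reference table, and
# enrichment of interior CDR3beta k-mers (GLIPH-style, simplified: no
# local/global split, no V-gene bias correction) with a one-sided Fisher
# exact test against a background repertoire.

# two-field HLA resolution, e.g. "A*02:01:05" -> "A*02:01"
truncate_allele <- function(allele) {
  sub("^([A-Za-z0-9]+\\*\\d+:\\d+).*$", "\\1", allele)
}

#' Exact CDR3beta + HLA matching against a viral reference
#'
#' A cell matches when the CDR3 amino-acid sequence of its TRB chain equals a
#' reference row's sequence AND that row's MHC allele (truncated to two-field
#' resolution) is carried by the cell's donor. A clone matching multiple
#' epitopes keeps all matches. Cells of donors absent from the HLA table are
#' skipped with a warning.
#'
#' @param chains chain table (TRB rows are used; restrict to CD8 cells
#'   upstream if desired).
#' @param reference viral reference table with `cdr3b_aa`, `virus`,
#'   `epitope`, `mhc_allele`.
#' @param hla donor HLA table with `donor_id`, `allele`.
#' @param cells cell metadata (maps cells to donors).
#' @return data.table of match records: `cell_id`, `donor_id`, `cdr3b_aa`,
#'   `virus`, `epitope`, `mhc_allele`.
#' @export
exact_match <- function(chains, reference, hla, cells) {
  cells <- as.data.table(cells)
  hla <- as.data.table(hla)
  reference <- as.data.table(reference)
  trb <- as.data.table(chains)[locus == "TRB" & !is.na(cdr3_aa)]
  trb <- cells[, .(cell_id, donor_id)][trb, on = "cell_id", nomatch = NULL]
  missing_donor <- setdiff(unique(trb$donor_id), unique(hla$donor_id))
  if (length(missing_donor)) {
    warning("donor(s) absent from HLA table, cells skipped: ",
            paste(missing_donor, collapse = ", "))
    trb <- trb[!donor_id %in% missing_donor]
  }
  ref <- copy(reference)[, mhc_allele := truncate_allele(mhc_allele)]
  hla <- copy(hla)[, allele := truncate_allele(allele)]
  hits <- ref[trb, on = c(cdr3b_aa = "cdr3_aa"), nomatch = NULL,
              allow.cartesian = TRUE]
  hits <- hla[hits, on = c(donor_id = "donor_id", allele = "mhc_allele"),
              nomatch = NULL]
  hits[, .(cell_id, donor_id, cdr3b_aa, virus, epitope, mhc_allele = allele)]
}

# interior k-mers: trim 3 N-terminal and 2 C-terminal residues first
interior_kmers <- function(aa, k) {
  core <- substr(aa, 4L, nchar(aa) - 2L)
  lens <- nchar(core)
  out <- vector("list", length(aa))
  for (i in seq_along(aa)) {
    if (lens[i] >= k)
      out[[i]] <- unique(substring(core[i], seq_len(lens[i] - k + 1L),
                                   seq_len(lens[i] - k + 1L) + k - 1L))
    else out[[i]] <- character(0)
  }
  out
}

#' GLIPH-style CDR3beta motif enrichment with HLA filtering
#'
#' Per virus, contiguous interior k-mers (3 N-terminal and 2 C-terminal
#' residues trimmed) are enumerated from reference and sample clone CDR3beta
#' sequences; each motif is tested for enrichment of
#' (reference + sample) clones over background clones with a one-sided
#' Fisher exact test. A motif group is retained when `fisher_p < p_cut`, it
#' has at least one reference member and one sample member, and a reference
#' member's restricting allele is carried by the donor of at least one
#' member sample clone. Flags are set for member sample cells whose donor
#' carries the allele; flags are unioned over viruses.
#'
#' @param clones sample clone table: `clone_id`, `donor_id`, `cdr3_aa` (one
#'   row per clone, TRB CDR3).
#' @param clone_cells mapping `cell_id` -> `clone_id` for flag output.
#' @param reference viral reference table (`cdr3b_aa`, `virus`, `epitope`,
#'   `mhc_allele`).
#' @param background character vector of background clone CDR3beta amino-acid
#'   sequences (e.g. naive-repertoire clones); must be nonempty.
#' @param hla donor HLA table.
#' @param k motif length, 3 or 4.
#' @param p_cut Fisher p-value cutoff (default 0.01).
#' @return list with `groups` (one row per motif x virus: counts, `fisher_p`,
#'   `hla_restriction`, `retained`) and `flags` (`cell_id`,
#'   `motif_matching`).
#' @export
motif_match <- function(clones, clone_cells, reference, background, hla,
                        k = 3L, p_cut = 0.01) {
  stopifnot(k %in% c(3L, 4L))
  if (length(background) == 0)
    stop("background clone set must be nonempty")
  clones <- as.data.table(clones)
  reference <- as.data.table(reference)
  hla <- as.data.table(hla)
  hla[, allele := truncate_allele(allele)]
  donor_alleles <- split(hla$allele, hla$donor_id)
  bg_km <- interior_kmers(background, k)
  n_bg <- length(background)
  bg_count <- table(unlist(bg_km))
  sample_km <- interior_kmers(clones$cdr3_aa, k)
  groups <- list()
  flagged <- character(0)
  for (v in sort(unique(reference$virus))) {
    ref_v <- reference[virus == v]
    ref_km <- interior_kmers(ref_v$cdr3b_aa, k)
    motifs <- sort(unique(c(unlist(ref_km))))
    if (!length(motifs)) next
    n_ref <- nrow(ref_v)
    n_sample <- nrow(clones)
    n_fg <- n_ref + n_sample
    for (m in motifs) {
      ref_members <- which(vapply(ref_km, function(x) m %in% x, logical(1)))
      sam_members <- which(vapply(sample_km, function(x) m %in% x, logical(1)))
      a <- length(ref_members) + length(sam_members)
      b <- as.integer(bg_count[m]); if (is.na(b)) b <- 0L
      p <- fisher.test(matrix(c(a, n_fg - a, b, n_bg - b), nrow = 2),
                       alternative = "greater")$p.value
      ref_alleles <- truncate_allele(ref_v$mhc_allele[ref_members])
      sam_donors <- unique(clones$donor_id[sam_members])
      hla_hit <- NA_character_
      flag_donors <- character(0)
      for (d in sam_donors) {
        shared <- intersect(ref_alleles, donor_alleles[[d]] %||% character(0))
        if (length(shared)) {
          if (is.na(hla_hit)) hla_hit <- shared[1]
          flag_donors <- c(flag_donors, d)
        }
      }
      retained <- p < p_cut && length(ref_members) > 0 &&
        length(sam_members) > 0 && !is.na(hla_hit)
      groups[[length(groups) + 1L]] <- data.table(
        motif = m, virus = v, n_ref = length(ref_members),
        n_sample = length(sam_members), n_background = b,
        fisher_p = p, hla_restriction = hla_hit, retained = retained)
      if (retained) {
        member_clones <- clones$clone_id[sam_members][
          clones$donor_id[sam_members] %in% flag_donors]
        flagged <- c(flagged, member_clones)
      }
    }
  }
  groups <- if (length(groups)) rbindlist(groups) else
    data.table(motif = character(0), virus = character(0), n_ref = integer(0),
               n_sample = integer(0), n_background = integer(0),
               fisher_p = numeric(0), hla_restriction = character(0),
               retained = logical(0))
  clone_cells <- as.data.table(clone_cells)
  flags <- clone_cells[, .(cell_id,
                           motif_matching = clone_id %in% unique(flagged))]
  list(groups = groups[], flags = flags[])
}

#' Phenotype and clone-size comparison of matching vs non-matching cells
#'
#' Per tissue, compares the subset composition of flagged (viral-matching)
#' and non-matching cells with a chi-square test, and tabulates clone-size
#' category distributions side by side. Strata without both groups are
#' omitted.
#'
#' @param flags data.table `cell_id`, `motif_matching` (or any logical flag
#'   column named in `flag_col`).
#' @param cells cell metadata.
#' @param clone_table a `clone_table` (for size categories).
#' @param flag_col name of the logical column in `flags`.
#' @return list with `tests` (per-tissue chi-square), `composition` (tissue x
#'   subset x matching counts) and `size_dist` (matching x size category).
#' @export
compare_matching_phenotypes <- function(flags, cells, clone_table,
                                        flag_col = "motif_matching") {
  cells <- as.data.table(cells)
  flags <- as.data.table(flags)
  dat <- flags[, .(cell_id, matching = get(flag_col))][
    cells, on = "cell_id", nomatch = NULL]
  tests <- list()
  comp <- dat[, .(n_cells = .N), by = .(tissue, subset, matching)]
  for (tis in sort(unique(dat$tissue))) {
    dd <- dat[tissue == tis]
    if (length(unique(dd$matching)) < 2) next   # omit stratum
    tab <- table(dd$subset, dd$matching)
    p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    tests[[tis]] <- data.table(tissue = tis, p = p,
                               n_matching = sum(dd$matching),
                               n_other = sum(!dd$matching))
  }
  sizes <- clone_table$clones[, .(clone_id, size_category)]
  sz <- sizes[clone_table$cells, on = "clone_id"][
    dat[, .(cell_id, matching)], on = "cell_id", nomatch = NULL]
  size_dist <- sz[, .(n_cells = .N), by = .(matching, size_category)]
  list(tests = if (length(tests)) rbindlist(tests) else
         data.table(tissue = character(0), p = numeric(0),
                    n_matching = integer(0), n_other = integer(0)),
       composition = comp[], size_dist = size_dist[])
}
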