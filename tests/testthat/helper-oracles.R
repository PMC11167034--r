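# Shared fixtures and independent oracles for the test suite.

# small, fast cohort for unit tests; caller overrides win over the tiny
# defaults
tiny_config <- function(seed = 42L, ...) {
  defaults <- list(
    n_donors = 4L, n_blood_donors = 3L,
    cells_per_sample_T = 150L, cells_per_sample_B = 120L,
    expression = list(n_genes = 0L, n_signature_genes = 0L, effect = 0,
                      dispersion = 0.5, target_subset = NA_character_))
  args <- utils::modifyList(defaults, list(...))
  do.call(paper_default_config, c(list(seed = seed), args))
}

# metadata-only cohort (no receptors, no expression): fast for composition
# and abundance-test simulations
metadata_config <- function(seed, composition, n_donors = 10L,
                            cells_T = 200L, cells_B = 0L) {
  paper_default_config(
    seed = seed, n_donors = n_donors, n_blood_donors = n_donors,
    cells_per_sample_T = cells_T, cells_per_sample_B = cells_B,
    composition = composition,
    recovery_prob = c(SYN = 0, PBL = 0),
    trafficking_frac = 0, doublet_frac = 0,
    viral_plant = list(n_reference_rows = 0L, n_planted_matching_clones = 0L),
    expression = list(n_genes = 0L, n_signature_genes = 0L, effect = 0,
                      dispersion = 0.5, target_subset = NA_character_))
}

# clone table from explicit assignments (bypasses clonotype calling)
manual_clone_table <- function(cell_ids, clone_ids) {
  cells <- data.table::data.table(cell_id = cell_ids, clone_id = clone_ids)
  clones <- cells[, .(size = .N), by = clone_id]
  clones <- clonolink:::categorize_clone_sizes_dt(clones)
  structure(list(cells = cells, clones = clones,
                 definition = list(receptor = "TCR", threshold = "exact",
                                   partition = "donor")),
            class = "clone_table")
}

# brute-force single-linkage clustering at an identity threshold:
# all-pairs identity graph -> connected components via union-find
brute_force_single_linkage <- function(seqs, threshold,
                                       denominator = "longer") {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (seq_identity(seqs[i], seqs[j], denominator) >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  (si - e) / ((sa + sb) / 2 - e)
}

# random CDR3 set with planted families: base sequences plus near-identical
# copies (0-2 substitutions), returning sequences and true family labels
cdr3_family_set <- function(n_families, copies_max = 4L, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- character(0); fam <- integer(0)
  for (f in seq_len(n_families)) {
    len <- 3L * sample(10:20, 1)
    base <- paste(sample(bases, len, replace = TRUE), collapse = "")
    k <- sample.int(copies_max, 1)
    for (c in seq_len(k)) {
      s <- strsplit(base, "")[[1]]
      nm <- sample(0:2, 1)
      if (nm > 0) {
        pos <- sample.int(len, nm)
        for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
      }
      out <- c(out, paste(s, collapse = ""))
      fam <- c(fam, f)
    }
  }
  list(seqs = out, family = fam)
}

# hand-rolled ward.D agglomeration (Lance-Williams on unsquared distances):
# returns the multiset of merge heights and the partition (cluster leaf sets)
# after every merge
ward_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  heights <- numeric(0)
  steps <- list()
  dm <- d
  diag(dm) <- Inf
  repeat {
    if (length(active) < 2) break
    sub <- dm[active, active, drop = FALSE]
    ix <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[min(ix)]; j <- active[max(ix)]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    h <- dm[i, j]
    heights <- c(heights, h)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      dm[i, k] <- dm[k, i] <-
        ((ni + nk) * dm[i, k] + (nj + nk) * dm[j, k] - nk * h) /
        (ni + nj + nk)
    }
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    steps[[length(steps) + 1L]] <- members[[i]]
  }
  list(heights = heights, steps = steps)
}

# canonical signature of an hclust result for topology comparison:
# the sorted leaf sets created at each merge + the merge heights
hclust_signature <- function(hc) {
  n <- length(hc$height)
  members <- list()
  steps <- list()
  for (m in seq_len(n)) {
    get_m <- function(x) if (x < 0) -x else members[[x]]
    members[[m]] <- sort(c(get_m(hc$merge[m, 1]), get_m(hc$merge[m, 2])))
    steps[[m]] <- members[[m]]
  }
  list(heights = hc$height, steps = steps)
}
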