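# Germline assignment, somatic hypermutation quantification, class-switch
# classification, and donor-random-effect models of both.
#
# "Closest germline" is operationalized as maximal ungapped identity over the
# aligned (fully contained) region - substitutions only, no indel model. The
# combined V-J SHM rate divides the summed V and J substitution counts by
# the heavy-chain sequence length excluding the CDR3 region.

# best ungapped match of each observed segment against a reference set;
# ties broken by reference order. Vectorized over observations grouped by
# length; references of the observation's length take the fast equal-length
# path.
best_germline_match <- function(obs, refs) {
  n <- length(obs)
  out_call <- rep(NA_character_, n)
  out_match <- rep(NA_integer_, n)
  out_overlap <- rep(NA_integer_, n)
  out_idn <- rep(-1, n)
  ref_int <- lapply(refs, utf8ToInt)
  ref_len <- lengths(ref_int)
  for (L in unique(nchar(obs))) {
    ix <- which(nchar(obs) == L)
    if (L == 0) next
    M <- matrix(utf8ToInt(paste(obs[ix], collapse = "")), nrow = L)
    for (r in seq_along(refs)) {
      lr <- ref_len[r]
      ov <- min(L, lr)
      best_r <- rep(0L, length(ix))
      for (off in 0:abs(L - lr)) {
        m <- if (lr >= L)
          colSums(M == ref_int[[r]][off + seq_len(L)])
        else
          colSums(M[off + seq_len(lr), , drop = FALSE] == ref_int[[r]])
        best_r <- pmax(best_r, as.integer(m))
      }
      idn <- best_r / ov
      sel <- which(idn > out_idn[ix])   # strict: earlier reference wins ties
      if (length(sel)) {
        out_call[ix[sel]] <- names(refs)[r]
        out_match[ix[sel]] <- best_r[sel]
        out_overlap[ix[sel]] <- ov
        out_idn[ix[sel]] <- idn[sel]
      }
    }
  }
  data.table(call = out_call, matches = out_match, overlap = out_overlap,
             identity = out_idn,
             n_sub = out_overlap - out_match)
}

#' Assign IgH V and J germline segments and count substitutions
#'
#' For each IGH chain carrying a full sequence with CDR3 coordinates, the V
#' region (sequence before CDR3) and J region (sequence after CDR3) are
#' matched against the reference segments by maximal ungapped identity over
#' the aligned region; substitutions are counted against the best reference,
#' ties broken by reference order.
#'
#' @param chains chain table; only IGH rows with non-missing `sequence`,
#'   `cdr3_start`, `cdr3_end` are used.
#' @param reference named character vector of germline segments with names
#'   `locus|gene|region` (as from [germline_reference()] or a FASTA read via
#'   [read_fixture()]).
#' @return data.table of SHM records: `cell_id`, assigned V/J calls,
#'   `v_shm`, `j_shm`, `v_identity`, `j_identity`, `len_excl_cdr3`,
#'   `vj_shm_rate`.
#' @export
assign_germline <- function(chains, reference = germline_reference("IGH")) {
  parts <- strsplit(names(reference), "|", fixed = TRUE)
  locus_r <- vapply(parts, `[[`, character(1), 1)
  region_r <- vapply(parts, function(p) p[[length(p)]], character(1))
  gene_r <- vapply(parts, function(p)
    if (length(p) >= 3) p[[2]] else p[[1]], character(1))
  v_refs <- setNames(as.character(reference[locus_r == "IGH" & region_r == "V"]),
                     gene_r[locus_r == "IGH" & region_r == "V"])
  j_refs <- setNames(as.character(reference[locus_r == "IGH" & region_r == "J"]),
                     gene_r[locus_r == "IGH" & region_r == "J"])
  if (length(v_refs) == 0 || length(j_refs) == 0)
    stop("configuration error: reference must contain at least one IGH V ",
         "and one IGH J segment")
  ch <- as.data.table(chains)[locus == "IGH" & !is.na(sequence) &
                                !is.na(cdr3_start) & !is.na(cdr3_end)]
  if (nrow(ch) == 0)
    return(data.table(cell_id = character(0),
                      v_call_assigned = character(0),
                      j_call_assigned = character(0), v_shm = integer(0),
                      j_shm = integer(0), v_identity = numeric(0),
                      j_identity = numeric(0), len_excl_cdr3 = integer(0),
                      vj_shm_rate = numeric(0)))
  v_obs <- substr(ch$sequence, 1L, ch$cdr3_start - 1L)
  j_obs <- substr(ch$sequence, ch$cdr3_end + 1L, nchar(ch$sequence))
  vm <- best_germline_match(v_obs, v_refs)
  jm <- best_germline_match(j_obs, j_refs)
  out <- data.table(
    cell_id = ch$cell_id,
    v_call_assigned = vm$call, j_call_assigned = jm$call,
    v_shm = vm$n_sub, j_shm = jm$n_sub,
    v_identity = vm$identity, j_identity = jm$identity,
    len_excl_cdr3 = nchar(v_obs) + nchar(j_obs))
  out[, vj_shm_rate := shm_rate(v_shm, j_shm, len_excl_cdr3)]
  out[]
}

#' Combined V-J somatic hypermutation rate
#'
#' `(v_shm + j_shm) / len_excl_cdr3`: summed V and J substitution counts
#' divided by the heavy-chain sequence length excluding the CDR3 region.
#'
#' @param v_shm,j_shm substitution counts.
#' @param len_excl_cdr3 sequence length outside CDR3 (must be > 0).
#' @return mutation rate per site.
#' @export
shm_rate <- function(v_shm, j_shm, len_excl_cdr3) {
  if (any(len_excl_cdr3 <= 0))
    stop("len_excl_cdr3 must be positive")
  (v_shm + j_shm) / len_excl_cdr3
}

#' Classify class-switch state from the IgH constant gene
#'
#' IGHG*/IGHA* are class-switched, IGHM/IGHD are not. IGHE and unresolvable
#' constant calls are reported as `switched = NA` with a warning; such cells
#' are excluded from the switch models.
#'
#' @param chains chain table; IGH rows are used (highest-UMI IGH per cell).
#' @return data.table with `cell_id`, `isotype`
#'   (IgM/IgD/IgG/IgA/IgE/unknown), `switched`.
#' @export
classify_switch <- function(chains) {
  igh <- as.data.table(chains)[locus == "IGH"]
  if (nrow(igh) == 0)
    return(data.table(cell_id = character(0), isotype = character(0),
                      switched = logical(0)))
  setorder(igh, cell_id, -umis, contig_id, na.last = TRUE)
  igh <- igh[, .SD[1L], by = cell_id]
  igh[is.na(c_call), c_call := ""]
  out <- igh[, .(cell_id, isotype = isotype_of(c_call))]
  out[, switched := data.table::fcase(
    isotype %in% c("IgG", "IgA"), TRUE,
    isotype %in% c("IgM", "IgD"), FALSE,
    default = NA)]
  n_excl <- out[is.na(switched), .N]
  if (n_excl > 0)
    warning(n_excl, " cell(s) with IgE or unknown isotype are excluded from ",
            "switch models")
  out[]
}

wald_effect_table <- function(est, se, reference_level, term_levels) {
  z <- est / se
  dt <- data.table(level = term_levels, estimate = est,
                   ci_lo = est - qnorm(0.975) * se,
                   ci_hi = est + qnorm(0.975) * se,
                   p = 2 * pnorm(-abs(z)))
  rbind(data.table(level = reference_level, estimate = 0, ci_lo = NA_real_,
                   ci_hi = NA_real_, p = NA_real_), dt)
}

#' Linear mixed model of SHM rate with a donor random intercept
#'
#' Fits `vj_shm_rate ~ covariate + (1 | donor_id)` and reports per-level
#' fixed effects versus the reference subset with Wald 95% confidence
#' intervals. With a single donor the random effect is dropped (fixed-effects
#' fit, with a warning). `covariate = "tissue_within_subset"` fits a separate
#' tissue model (SYN vs the PBL reference) inside each subset.
#'
#' @param shm SHM records from [assign_germline()].
#' @param cells cell metadata (provides `donor_id`, `subset`, `tissue`).
#' @param reference_subset reference level for the subset factor.
#' @param covariate `"subset"` or `"tissue_within_subset"`.
#' @return data.table with `level` (and `subset` for the tissue model),
#'   `estimate`, `ci_lo`, `ci_hi`, `p`; the reference row has estimate 0 by
#'   the identifiability convention.
#' @export
fit_shm_model <- function(shm, cells, reference_subset,
                          covariate = c("subset", "tissue_within_subset")) {
  covariate <- match.arg(covariate)
  cells <- as.data.table(cells)
  if ("doublet_flag" %in% names(cells)) cells <- cells[doublet_flag == FALSE]
  dat <- cells[, .(cell_id, donor_id, subset, tissue)][
    as.data.table(shm), on = "cell_id", nomatch = NULL]
  if (covariate == "subset") {
    if (!reference_subset %in% dat$subset)
      stop("reference subset ", reference_subset, " not present")
    dat[, subset := stats::relevel(factor(subset), ref = reference_subset)]
    fit <- fit_lmm(vj_shm_rate ~ subset + (1 | donor_id), dat)
    fe <- fit$coef
    keep <- grepl("^subset", names(fe))
    out <- wald_effect_table(unname(fe[keep]), fit$se[keep],
                             reference_subset,
                             sub("^subset", "", names(fe)[keep]))
    return(out)
  }
  res <- lapply(sort(unique(dat$subset)), function(s) {
    dd <- dat[subset == s]
    if (length(unique(dd$tissue)) < 2) return(NULL)
    dd[, tissue := stats::relevel(factor(tissue), ref = "PBL")]
    fit <- fit_lmm(vj_shm_rate ~ tissue + (1 | donor_id), dd)
    keep <- grepl("^tissue", names(fit$coef))
    cbind(subset = s,
          wald_effect_table(unname(fit$coef[keep]), fit$se[keep], "PBL",
                            sub("^tissue", "", names(fit$coef)[keep])))
  })
  rbindlist(res)
}

fit_lmm <- function(formula, dat) {
  if (length(unique(dat$donor_id)) < 2) {
    warning("single donor: random effect dropped, fitting fixed effects only")
    f <- stats::as.formula(paste(deparse(formula[[2]]), "~",
                                 sub("\\s*\\+\\s*\\(1 \\| donor_id\\)", "",
                                     deparse(formula[[3]]))))
    m <- stats::lm(f, dat)
    return(list(coef = stats::coef(m),
                se = sqrt(diag(stats::vcov(m)))))
  }
  m <- suppressMessages(lme4::lmer(formula, dat,
                                   control = lme4::lmerControl(
                                     check.conv.singular = "ignore")))
  list(coef = lme4::fixef(m), se = sqrt(diag(as.matrix(stats::vcov(m)))))
}

#' Mixed-effect logistic model of class switching
#'
#' Fits `switched ~ subset + tissue + (1 | donor_id)` by Laplace
#' approximation and reports log-odds estimates with Wald 95% confidence
#' intervals versus the reference subset and tissue. Subsets whose outcomes
#' are all 0 or all 1 are reported with a separation warning (their Wald
#' intervals are unreliable).
#'
#' @param switch_states output of [classify_switch()]; `NA` switch states are
#'   dropped.
#' @param cells cell metadata.
#' @param reference_subset reference subset level.
#' @param reference_tissue reference tissue (default PBL).
#' @return data.table with `term`, `level`, `estimate`, `ci_lo`, `ci_hi`,
#'   `p`; attribute `separation` lists degenerate subsets.
#' @export
fit_switch_model <- function(switch_states, cells, reference_subset,
                             reference_tissue = "PBL") {
  cells <- as.data.table(cells)
  if ("doublet_flag" %in% names(cells)) cells <- cells[doublet_flag == FALSE]
  dat <- cells[, .(cell_id, donor_id, subset, tissue)][
    as.data.table(switch_states)[!is.na(switched)],
    on = "cell_id", nomatch = NULL]
  if (!reference_subset %in% dat$subset)
    stop("reference subset ", reference_subset, " not present")
  sep <- dat[, .(rate = mean(switched)), by = subset][rate %in% c(0, 1), subset]
  if (length(sep))
    warning("complete separation: subset(s) ", paste(sep, collapse = ", "),
            " have all-0 or all-1 switch outcomes; their estimates are ",
            "unreliable")
  dat[, subset := stats::relevel(factor(subset), ref = reference_subset)]
  dat[, tissue := factor(tissue)]
  if (reference_tissue %in% levels(dat$tissue))
    dat[, tissue := stats::relevel(tissue, ref = reference_tissue)]
  single_tissue <- length(levels(dat$tissue)) < 2
  form <- if (single_tissue) switched ~ subset + (1 | donor_id)
          else switched ~ subset + tissue + (1 | donor_id)
  if (length(unique(dat$donor_id)) < 2) {
    warning("single donor: random effect dropped, fitting fixed effects only")
    m <- stats::glm(if (single_tissue) switched ~ subset
                    else switched ~ subset + tissue,
                    family = stats::binomial(), data = dat)
    fe <- stats::coef(m); se <- sqrt(diag(stats::vcov(m)))
  } else {
    m <- suppressMessages(suppressWarnings(
      lme4::glmer(form, dat, family = stats::binomial(),
                  control = lme4::glmerControl(
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore"))))
    fe <- lme4::fixef(m); se <- sqrt(diag(as.matrix(stats::vcov(m))))
  }
  rows <- list()
  keep_s <- grepl("^subset", names(fe))
  rows$subset <- cbind(term = "subset",
                       wald_effect_table(unname(fe[keep_s]), se[keep_s],
                                         reference_subset,
                                         sub("^subset", "", names(fe)[keep_s])))
  keep_t <- grepl("^tissue", names(fe))
  if (any(keep_t))
    rows$tissue <- cbind(term = "tissue",
                         wald_effect_table(unname(fe[keep_t]), se[keep_t],
                                           reference_tissue,
                                           sub("^tissue", "",
                                               names(fe)[keep_t])))
  out <- rbindlist(rows)
  setattr(out, "separation", sep)
  out[]
}
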