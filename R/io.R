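# Reading and writing receptor tables, cell metadata and fixture directories.
#
# Two contig dialects are supported: the 10x `filtered_contig_annotations.csv`
# flavour and the AIRR Rearrangement TSV. Both are mapped onto one canonical
# chain table whose columns follow the ReceptorChain contract used throughout
# the package.

CANONICAL_CHAIN_COLS <- c("cell_id", "contig_id", "locus", "v_call", "j_call",
                          "c_call", "cdr3_nt", "cdr3_aa", "umis", "reads",
                          "high_confidence", "full_length", "productive",
                          "sequence", "cdr3_start", "cdr3_end")

.tenx_map <- c(cell_id = "barcode", contig_id = "contig_id", locus = "chain",
               v_call = "v_gene", j_call = "j_gene", c_call = "c_gene",
               cdr3_nt = "cdr3_nt", cdr3_aa = "cdr3", umis = "umis",
               reads = "reads", high_confidence = "high_confidence",
               full_length = "full_length", productive = "productive")
.tenx_required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
                    "umis")

.airr_map <- c(cell_id = "cell_id", contig_id = "sequence_id", locus = "locus",
               v_call = "v_call", j_call = "j_call", c_call = "c_call",
               cdr3_nt = "junction", cdr3_aa = "junction_aa",
               umis = "duplicate_count", reads = "consensus_count",
               productive = "productive", sequence = "sequence",
               cdr3_start = "cdr3_start", cdr3_end = "cdr3_end")
.airr_required <- c("cell_id", "locus", "v_call", "j_call", "junction")

#' Read receptor contigs into the canonical chain table
#'
#' Parses a 10x-style `filtered_contig_annotations.csv` or an AIRR
#' Rearrangement TSV into one chain per row with canonical column names.
#' Unknown columns are ignored; columns absent from the dialect (e.g.
#' `high_confidence` in AIRR) default to permissive values.
#'
#' @param path file path.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return data.table of receptor chains.
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- fread(path, sep = if (dialect == "tenx_csv") "," else "\t",
               colClasses = list(character = intersect(
                 c("cdr3_nt", "cdr3", "junction", "junction_aa", "sequence"),
                 names(fread(path, nrows = 0)))))
  map <- if (dialect == "tenx_csv") .tenx_map else .airr_map
  req <- if (dialect == "tenx_csv") .tenx_required else .airr_required
  missing <- setdiff(req, names(raw))
  if (length(missing))
    stop("format error: required column(s) missing from ", dialect, ": ",
         paste(missing, collapse = ", "))
  out <- data.table(row = seq_len(nrow(raw)))
  for (canon in names(map)) {
    src <- map[[canon]]
    out[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  out[, row := NULL]
  for (col in c("high_confidence", "full_length", "productive")) {
    if (!col %in% names(out) || all(is.na(out[[col]]))) {
      out[[col]] <- TRUE
    } else if (!is.logical(out[[col]])) {
      out[[col]] <- out[[col]] %in% c("true", "True", "TRUE", "T", "t")
    }
    out[[col]][is.na(out[[col]])] <- TRUE
  }
  for (col in c("umis", "reads", "cdr3_start", "cdr3_end"))
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  for (col in names(out))        # empty fields are missing values
    if (is.character(out[[col]])) out[[col]][!nzchar(out[[col]])] <- NA

  for (col in setdiff(CANONICAL_CHAIN_COLS, names(out)))
    out[[col]] <- if (col %in% c("cdr3_start", "cdr3_end")) NA_integer_
                  else NA_character_
  setcolorder(out, CANONICAL_CHAIN_COLS)
  out[]
}

#' Read a cell metadata CSV
#'
#' @param path file path to a cell metadata CSV as written by
#'   [write_fixture()].
#' @return data.table of cell records.
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fread(path)
}

#' Write a synthetic cohort to a fixture directory
#'
#' Emits every external-interface artifact for a cohort: cell metadata CSV,
#' 10x-style contig CSV, AIRR Rearrangement TSV, Matrix Market counts with
#' genes/barcodes TSVs, germline FASTA, donor HLA CSV, viral reference CSV,
#' ground-truth clone TSV and the serialized configuration. Re-reading with
#' [read_fixture()] reproduces the in-memory tables.
#'
#' @param cohort a `clonolink_cohort` (or a `cohort_config`, which is
#'   generated first).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixture <- function(cohort, dir) {
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "clonolink_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  paths <- c(
    cells = file.path(dir, "cells.csv"),
    tenx = file.path(dir, "filtered_contig_annotations.csv"),
    airr = file.path(dir, "airr_rearrangement.tsv"),
    germline = file.path(dir, "germline.fasta"),
    hla = file.path(dir, "hla.csv"),
    viral = file.path(dir, "viral_reference.csv"),
    truth = file.path(dir, "truth_clones.tsv"),
    config = file.path(dir, "config.json"))
  fwrite(cohort$cells, paths["cells"])
  ch <- cohort$chains
  tenx <- data.table(
    barcode = ch$cell_id, contig_id = ch$contig_id, chain = ch$locus,
    v_gene = ch$v_call, j_gene = ch$j_call, c_gene = ch$c_call,
    cdr3 = ch$cdr3_aa, cdr3_nt = ch$cdr3_nt, umis = ch$umis,
    reads = ch$reads, high_confidence = ch$high_confidence,
    full_length = ch$full_length, productive = ch$productive)
  fwrite(tenx, paths["tenx"])
  airr <- data.table(
    cell_id = ch$cell_id, sequence_id = ch$contig_id, locus = ch$locus,
    v_call = ch$v_call, j_call = ch$j_call, c_call = ch$c_call,
    junction = ch$cdr3_nt, junction_aa = ch$cdr3_aa,
    duplicate_count = ch$umis, consensus_count = ch$reads,
    productive = ch$productive, sequence = ch$sequence,
    cdr3_start = ch$cdr3_start, cdr3_end = ch$cdr3_end)
  fwrite(airr, paths["airr"], sep = "\t")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(as.character(cohort$germline),
                                      names(cohort$germline))),
    paths["germline"])
  fwrite(cohort$hla, paths["hla"])
  fwrite(cohort$viral_ref, paths["viral"])
  fwrite(cohort$truth$clones, paths["truth"], sep = "\t")
  writeLines(jsonlite::toJSON(unclass(cohort$config), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), paths["config"])
  if (!is.null(cohort$counts)) {
    mtx <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(cohort$counts, mtx)
    writeLines(rownames(cohort$counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(cohort$counts), file.path(dir, "barcodes.tsv"))
    paths <- c(paths, matrix = mtx,
               genes = file.path(dir, "genes.tsv"),
               barcodes = file.path(dir, "barcodes.tsv"))
  }
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `cells`, `chains` (from the AIRR table), `counts` (or
#'   NULL), `germline`, `hla`, `viral_ref`.
#' @export
read_fixture <- function(dir) {
  cells <- read_cells(file.path(dir, "cells.csv"))
  chains <- read_contigs(file.path(dir, "airr_rearrangement.tsv"), "airr_tsv")
  counts <- NULL
  if (file.exists(file.path(dir, "matrix.mtx"))) {
    counts <- Matrix::Matrix(Matrix::readMM(file.path(dir, "matrix.mtx")),
                             sparse = TRUE)
    dimnames(counts) <- list(readLines(file.path(dir, "genes.tsv")),
                             readLines(file.path(dir, "barcodes.tsv")))
  }
  germ <- Biostrings::readDNAStringSet(file.path(dir, "germline.fasta"))
  germ <- setNames(as.character(germ), names(germ))
  list(cells = cells, chains = chains, counts = counts, germline = germ,
       hla = fread(file.path(dir, "hla.csv")),
       viral_ref = fread(file.path(dir, "viral_reference.csv")))
}
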