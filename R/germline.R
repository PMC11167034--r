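# Synthetic germline mini-reference and low-level sequence machinery.
#
# The bundled reference is a stand-in for a curated V/J germline database:
# 10 V and 6 J segments per receptor class with IMGT-style names, generated
# deterministically (fixed internal seed, independent of the cohort seed) so
# the same FASTA is reproduced in every session. Segments within a class are
# mutually distant (~75% mismatches for random sequence), which makes
# nearest-germline assignment unambiguous at realistic SHM rates. Segment
# lengths are uniform within a class (V = 288 nt, J = 48 nt).

.clono_env <- new.env(parent = emptyenv())

GERMLINE_V_LEN <- 288L
GERMLINE_J_LEN <- 48L

.germline_names <- list(
  TRA = list(V = c("TRAV1-2", "TRAV8-2", "TRAV12-1", "TRAV13-1", "TRAV17",
                   "TRAV19", "TRAV21", "TRAV26-1", "TRAV29", "TRAV38-1"),
             J = c("TRAJ33", "TRAJ20", "TRAJ12", "TRAJ42", "TRAJ49", "TRAJ6")),
  TRB = list(V = c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-5", "TRBV7-9",
                   "TRBV9", "TRBV12-3", "TRBV19", "TRBV20-1", "TRBV28"),
             J = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ2-3", "TRBJ2-5",
                   "TRBJ2-7")),
  IGH = list(V = c("IGHV1-18", "IGHV1-69", "IGHV3-23", "IGHV3-30", "IGHV3-48",
                   "IGHV4-34", "IGHV4-39", "IGHV5-51", "IGHV6-1", "IGHV7-4-1"),
             J = paste0("IGHJ", 1:6)),
  IGK = list(V = c("IGKV1-5", "IGKV1-39", "IGKV2-28", "IGKV3-11", "IGKV3-15",
                   "IGKV3-20", "IGKV4-1", "IGKV1-33", "IGKV2-30", "IGKV1-12"),
             J = paste0("IGKJ", 1:5)),
  IGL = list(V = c("IGLV1-40", "IGLV1-44", "IGLV2-8", "IGLV2-14", "IGLV3-1",
                   "IGLV3-19", "IGLV3-21", "IGLV6-57", "IGLV7-43", "IGLV2-23"),
             J = paste0("IGLJ", 1:3)))

# run `fn` under a throwaway RNG stream, restoring the caller's stream
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Synthetic germline V/J mini-reference
#'
#' Returns the bundled synthetic germline reference: a named character vector
#' of nucleotide segments (10 V + 6 J per receptor class for TRA, TRB, IGH,
#' and light-chain loci), with names `<locus>|<gene>|<region>` and IMGT-style
#' gene labels. Deterministic and independent of any cohort seed.
#'
#' @param loci character, which loci to include (default all).
#' @return named character vector of DNA sequences; attributes `gene`,
#'   `locus`, `region` carry the parsed name parts.
#' @export
germline_reference <- function(loci = names(.germline_names)) {
  if (is.null(.clono_env$germline)) {
    .clono_env$germline <- with_local_seed(8675309L, function() {
      out <- character(0)
      for (loc in names(.germline_names)) {
        v <- random_dna(length(.germline_names[[loc]]$V), GERMLINE_V_LEN)
        names(v) <- paste(loc, .germline_names[[loc]]$V, "V", sep = "|")
        j <- random_dna(length(.germline_names[[loc]]$J), GERMLINE_J_LEN)
        names(j) <- paste(loc, .germline_names[[loc]]$J, "J", sep = "|")
        out <- c(out, v, j)
      }
      out
    })
  }
  ref <- .clono_env$germline
  parts <- strsplit(names(ref), "|", fixed = TRUE)
  keep <- vapply(parts, `[[`, character(1), 1) %in% loci
  ref <- ref[keep]
  parts <- parts[keep]
  attr(ref, "locus") <- vapply(parts, `[[`, character(1), 1)
  attr(ref, "gene") <- vapply(parts, `[[`, character(1), 2)
  attr(ref, "region") <- vapply(parts, `[[`, character(1), 3)
  ref
}

# named vector gene -> sequence for one locus/region
germline_segments <- function(locus, region) {
  ref <- germline_reference(locus)
  sel <- attr(ref, "region") == region
  setNames(as.character(ref[sel]), attr(ref, "gene")[sel])
}

# 61 sense codons (no TAA/TAG/TGA) for junction construction
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

# random CDR3 nucleotide sequences: length 30-60 nt in codon multiples,
# C...F anchored, stop-free
random_cdr3_nt <- function(n, min_len = 30L, max_len = 60L) {
  if (n == 0) return(character(0))
  n_codons <- sample(seq(min_len / 3L, max_len / 3L), n, replace = TRUE)
  cod <- sense_codons()
  mids <- sample(cod, sum(n_codons - 2L), replace = TRUE)
  grp <- rep.int(seq_len(n), n_codons - 2L)
  mid <- vapply(split(mids, grp), paste, character(1), collapse = "")
  paste0("TGT", mid, "TTC")
}

#' Translate DNA to amino acids
#'
#' Thin wrapper around [Biostrings::translate()] for character vectors whose
#' lengths are multiples of 3.
#'
#' @param nt character vector of DNA sequences.
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(nt) {
  if (length(nt) == 0) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE))
}

# deterministic reverse translation (first sense codon per aa, by codon order)
reverse_translate_aa <- function(aa) {
  cod <- sense_codons()
  tab <- setNames(cod, as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cod), no.init.codon = TRUE)))
  tab <- tab[!duplicated(names(tab))]
  vapply(strsplit(aa, ""), function(ch) paste(tab[ch], collapse = ""),
         character(1))
}

# Apply per-site Bernoulli substitutions (rate per cell) to germline copies.
# `germ` is a character vector of germline sequences per cell (possibly
# repeated); returns list(seq = mutated sequences, n_mut = substitution count,
# pos = list of mutated positions).
mutate_germline <- function(germ, rate) {
  n <- length(germ)
  if (n == 0) return(list(seq = character(0), n_mut = integer(0), pos = list()))
  len <- nchar(germ)
  n_mut <- rbinom(n, len, rate)
  out <- germ
  pos_list <- vector("list", n)
  todo <- which(n_mut > 0)
  if (length(todo)) {
    bases_raw <- charToRaw("ACGT")
    # alternatives[b, r]: the r-th substitute for base b (never the original)
    alternatives <- matrix(charToRaw("CAAAGGCCTTTG"), nrow = 4)
    by_germ <- split(todo, germ[todo])
    for (g in names(by_germ)) {
      ix <- by_germ[[g]]
      L <- nchar(g)
      M <- matrix(rep(charToRaw(g), length(ix)), nrow = L)
      k <- n_mut[ix]
      pos <- lapply(k, function(kk) sample.int(L, kk))
      lin <- (rep.int(seq_along(ix), k) - 1L) * L + unlist(pos)
      base_idx <- match(M[lin], bases_raw)
      r <- sample.int(3L, length(lin), replace = TRUE)
      M[lin] <- alternatives[cbind(base_idx, r)]
      all_str <- rawToChar(as.vector(M))
      out[ix] <- substring(all_str, (seq_along(ix) - 1L) * L + 1L,
                           seq_along(ix) * L)
      pos_list[ix] <- lapply(pos, sort)
    }
  }
  list(seq = out, n_mut = n_mut, pos = pos_list)
}
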