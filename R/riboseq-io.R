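#' A-site assignment for ribosome footprint reads
#'
#' Assigns the A-site codon for footprint reads of length 28, 29 or 30 nt
#' from the read length and the frame shift of the read's first
#' nucleotide relative to the closest codon start (0 in frame, +1 one
#' nucleotide before the frame, -1 one after).  The returned index is the
#' nucleotide position of the A-site codon relative to the read start:
#' length 28 maps shift +1 to codon position 15 and shift 0 to 16; length
#' 29 maps only shift 0 (to 16); length 30 maps shift 0 to 16 and shift
#' -1 to 17.  All other combinations are ambiguous and discarded (`NA`).
#'
#' @param length_nt integer vector of read lengths.
#' @param start_offset_nt integer vector of 0-based offsets of the read's
#'   first nucleotide within the ORF.
#' @return integer vector of A-site nucleotide positions within the read
#'   (`NA` where the read is discarded).
#' @export
map_read <- function(length_nt, start_offset_nt) {
  stopifnot(length(length_nt) == length(start_offset_nt))
  m <- start_offset_nt %% 3L
  shift <- ifelse(m == 0L, 0L, ifelse(m == 1L, -1L, 1L))
  out <- rep(NA_integer_, length(length_nt))
  out[length_nt == 28L & shift == 1L] <- 15L
  out[length_nt == 28L & shift == 0L] <- 16L
  out[length_nt == 29L & shift == 0L] <- 16L
  out[length_nt == 30L & shift == 0L] <- 16L
  out[length_nt == 30L & shift == -1L] <- 17L
  out
}

#' Filter genes by length and footprint coverage
#'
#' Keeps genes longer than `min_len` codons whose mean per-codon
#' footprint count exceeds `min_mean_reads`, the selection used before
#' rate inference so that the global speed normalization is not biased by
#' the 5' ramp and the steady-state estimates are well covered.
#'
#' @param profiles named list of per-codon count vectors.
#' @param min_len minimal transcript length (codons), exclusive.
#' @param min_mean_reads minimal mean count per codon, exclusive.
#' @return the filtered (named) list.
#' @export
filter_genes <- function(profiles, min_len = 200L, min_mean_reads = 10) {
  stopifnot(is.list(profiles))
  keep <- vapply(profiles, function(p)
    length(p) > min_len && mean(p) > min_mean_reads, TRUE)
  profiles[keep]
}

#' Calibrate translation efficiency against ribosome densities
#'
#' TE (footprint RPKM over mRNA RPKM) is proportional to the density of
#' detected ribosomes per transcript; the proportionality constant is
#' estimated by a through-origin least-squares fit `TE = c * density`
#' restricted to low-density genes (`density < cutoff`, in ribosomes per
#' 100 codons), where detected and total densities coincide.
#'
#' @param te numeric vector of TE values.
#' @param density numeric vector of ribosome densities (per 100 codons).
#' @param density_cutoff only genes below this density enter the fit.
#' @return a list with the constant `c`, `n_used`, and `residuals` for
#'   the fitted subset, class `te_scaling`.
#' @export
fit_te_scaling <- function(te, density, density_cutoff = 1.0) {
  stopifnot(length(te) == length(density))
  use <- is.finite(te) & is.finite(density) & density < density_cutoff
  if (sum(use) < 2L)
    stop("need at least 2 genes below the density cutoff")
  x <- density[use]; y <- te[use]
  cc <- sum(x * y) / sum(x * x)
  structure(list(c = cc, n_used = sum(use), residuals = y - cc * x,
                 density_cutoff = density_cutoff),
            class = "te_scaling")
}

#' @rdname fit_te_scaling
#' @param scaling a `te_scaling` fit (or a bare constant).
#' @export
density_from_te <- function(te, scaling) {
  cc <- if (inherits(scaling, "te_scaling")) scaling$c else scaling
  te / cc
}

#' Read coding sequences from FASTA
#'
#' Validates that each sequence has length divisible by 3, starts with
#' ATG and ends with a stop codon, and returns codon vectors.
#'
#' @param path FASTA file of coding sequences.
#' @param check validate start/stop and frame (default TRUE).
#' @return named list of character codon vectors.
#' @export
read_cds_fasta <- function(path, check = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(as.character(seqs), function(s) {
    if (nchar(s) %% 3 != 0)
      stop("CDS length not divisible by 3")
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  })
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (check) {
    for (nm in names(out)) {
      cod <- out[[nm]]
      if (cod[1L] != "ATG")
        stop("CDS ", nm, " does not start with ATG")
      if (!cod[length(cod)] %in% c("TAA", "TAG", "TGA"))
        stop("CDS ", nm, " does not end with a stop codon")
    }
  }
  out
}

#' Write coding sequences to FASTA
#'
#' @param codons_by_gene named list of codon vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(codons_by_gene, path) {
  seqs <- Biostrings::DNAStringSet(vapply(codons_by_gene, paste, "",
                                          collapse = ""))
  names(seqs) <- names(codons_by_gene)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read / write per-codon footprint profiles as TSV
#'
#' Long format with columns `gene_id`, `position`, `count`; positions
#' absent from the file are zero-filled up to the per-gene maximum
#' position (or `lengths[gene]` when given).
#'
#' @param path file path.
#' @param lengths optional named integer vector of transcript lengths.
#' @return named list of integer count vectors.
#' @export
read_profiles_tsv <- function(path, lengths = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "position", "count") %in% names(tab)))
  out <- lapply(split(tab, tab$gene_id), function(d) {
    L <- if (!is.null(lengths)) lengths[[d$gene_id[1L]]] else max(d$position)
    v <- integer(L)
    v[d$position] <- d$count
    v
  })
  out[unique(tab$gene_id)]
}

#' @rdname read_profiles_tsv
#' @param profiles named list of per-codon count vectors.
#' @export
write_profiles_tsv <- function(profiles, path) {
  df <- do.call(rbind, lapply(names(profiles), function(g)
    data.frame(gene_id = g, position = seq_along(profiles[[g]]),
               count = as.integer(profiles[[g]]))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write TE tables as TSV
#'
#' Columns `gene_id`, `te` and optionally `density` (ribosomes per 100
#' codons from polysome profiling).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_te_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "te") %in% names(tab)))
  tab
}

#' @rdname read_te_tsv
#' @param te_table data.frame with at least `gene_id` and `te`.
#' @export
write_te_tsv <- function(te_table, path) {
  write.table(te_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
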