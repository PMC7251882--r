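# Codon bookkeeping for the GY94 machinery: the 61 sense codons of the
# standard genetic code and the single-nucleotide neighbor structure.

codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  n <- length(codons)  # 61
  nts <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(codons, ""))
  # single-nucleotide neighbors: i, j, position, transition?, synonymous?
  pairs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diffpos <- which(cmat[i, ] != cmat[j, ])
    if (length(diffpos) != 1L) next
    ts <- paste0(sort(c(cmat[i, diffpos], cmat[j, diffpos])), collapse = "") %in% c("AG", "CT")
    pairs[[length(pairs) + 1L]] <- c(i, j, diffpos, ts, aa[i] == aa[j])
  }
  P <- do.call(rbind, pairs)
  codon_env$tab <- list(codons = codons, aa = aa, cmat = cmat, nts = nts,
                        nb_i = P[, 1], nb_j = P[, 2], nb_pos = P[, 3],
                        nb_ts = as.logical(P[, 4]), nb_syn = as.logical(P[, 5]))
  codon_env$tab
}

split_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  if (nchar(seq) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

translate_str <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(gsub("U", "T", toupper(cds))),
                                     if.fuzzy.codon = "X"))
}

#' Back-thread a protein alignment onto coding sequences
#'
#' Uses a protein multiple alignment as the guide for a codon-level
#' alignment of the underlying CDS: every aligned amino-acid column maps
#' to its codon triplet, and columns containing a gap in any sequence are
#' stripped, so the result is an ungapped codon alignment of length
#' divisible by 3.
#'
#' @param protein_alignment named character vector of aligned amino-acid
#'   strings (gaps as `-`), all of equal length.
#' @param cds_sequences named character vector of in-frame coding
#'   sequences; each must translate exactly to its (ungapped) protein
#'   under the standard genetic code. A trailing stop codon is tolerated
#'   and removed; internal stops are an error.
#' @return named character vector of gap-stripped codon alignments.
#' @examples
#' aln <- c(s1 = "MK-V", s2 = "MKAV")
#' cds <- c(s1 = "ATGAAAGTT", s2 = "ATGAAAGCTGTT")
#' backthread_codon_alignment(aln, cds)
#' @export
backthread_codon_alignment <- function(protein_alignment, cds_sequences) {
  nm <- names(protein_alignment)
  if (is.null(nm) || !all(nm %in% names(cds_sequences)))
    stop("protein and CDS sequences must share names")
  if (length(unique(nchar(protein_alignment))) != 1L)
    stop("aligned protein sequences differ in length")
  codons <- lapply(nm, function(s) {
    cd <- split_codons(cds_sequences[[s]])
    if (length(cd) && cd[length(cd)] %in% c("TAA", "TAG", "TGA"))
      cd <- cd[-length(cd)]
    prot <- gsub("-", "", protein_alignment[[s]])
    if (3L * nchar(prot) != 3L * length(cd))
      stop("CDS/protein length mismatch for ", s)
    tr <- translate_str(paste(cd, collapse = ""))
    if (grepl("\\*", tr)) stop("internal stop codon in CDS of ", s)
    if (tr != prot) stop("CDS does not translate to the aligned protein for ", s)
    cd
  })
  names(codons) <- nm
  ncol <- nchar(protein_alignment[[1]])
  cols <- do.call(rbind, lapply(nm, function(s) strsplit(protein_alignment[[s]], "")[[1]]))
  keep <- apply(cols != "-", 2, all)
  out <- vapply(seq_along(nm), function(i) {
    pos <- cumsum(cols[i, ] != "-")      # codon index per alignment column
    paste(codons[[i]][pos[keep]], collapse = "")
  }, character(1))
  names(out) <- nm
  out
}
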