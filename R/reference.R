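# Reference sequence handling and synonymous-site classification.
#
# All coordinates in the package are 1-based positions on a 16,569 bp
# mitochondrial reference (rCRS numbering). The genome is treated linearly;
# the control-region origin is never re-joined because the network stage
# only uses the coding region (577-16023).

#' Length of the mitochondrial reference (rCRS numbering)
#' @export
MT_LENGTH <- 16569L

#' Coding-region bounds used for network construction
#' @export
CODING_REGION <- c(577L, 16023L)

#' Read a mitochondrial reference sequence from FASTA
#'
#' Reads the first record of a FASTA file and returns it as an upper-case
#' character vector of single bases, one element per 1-based position.
#'
#' @param path path to a FASTA file.
#' @return character vector of bases (`A`/`C`/`G`/`T`/`N`).
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("reference FASTA contains no records: ", path)
  strsplit(toupper(as.character(ss[[1L]])), "", fixed = TRUE)[[1L]]
}

#' Write a reference or consensus sequence to FASTA
#'
#' @param seqs named list (or single character vector) of base vectors.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!is.list(seqs)) seqs <- list(sequence = seqs)
  ss <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Generate a synthetic mitochondrial reference sequence
#'
#' Draws a uniform random base at each of the 16,569 positions. This is a
#' synthetic stand-in with the same length and coordinate conventions as the
#' rCRS; it carries none of the real sequence. It is used by the simulator
#' and the test-suite so the pipeline can run without bundling external
#' sequence data.
#'
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return character vector of length 16,569.
#' @export
simulate_reference <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(c("A", "C", "G", "T"), MT_LENGTH, replace = TRUE)
}

#' Protein-coding gene annotation of the mitochondrial genome
#'
#' Returns the 13 protein-coding genes with their rCRS coordinates and
#' strand. Genes whose length is not a multiple of three terminate in an
#' incomplete stop codon (completed by polyadenylation in vivo); variants in
#' such trailing partial codons are classified as non-synonymous because the
#' codon cannot be translated.
#'
#' @return data.frame with columns `gene`, `start`, `end`, `strand`.
#' @export
mt_gene_annotation <- function() {
  path <- system.file("extdata", "mtdna_genes.tsv", package = "mtlineage")
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  ann
}

.MITO_CODE <- NULL

mito_code <- function() {
  if (is.null(.MITO_CODE)) {
    # vertebrate mitochondrial genetic code (NCBI translation table 2)
    utils::assignInMyNamespace(".MITO_CODE", Biostrings::getGeneticCode("2"))
  }
  .MITO_CODE
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Count synonymous substitutions in a variant set
#'
#' A substitution is synonymous when it falls inside a protein-coding gene
#' and leaves the encoded amino acid unchanged given the reference codon
#' background (vertebrate mitochondrial code). Positions outside all coding
#' genes (rRNA, tRNA, control region) are non-synonymous for the purpose of
#' the synonymous clock. At sites covered by overlapping genes the change
#' must be synonymous in every overlapping frame. Variants in an incomplete
#' terminal codon are non-synonymous.
#'
#' @param vs a [variant_set] (or data.frame with `position`, `alt`, `kind`).
#' @param ref reference base vector (length 16,569).
#' @param annotation gene table as from [mt_gene_annotation()].
#' @return integer count of synonymous substitutions.
#' @export
synonymous_count <- function(vs, ref, annotation = mt_gene_annotation()) {
  subs <- vs[vs$kind == "substitution", , drop = FALSE]
  if (nrow(subs) == 0L) return(0L)
  sum(vapply(seq_len(nrow(subs)), function(i) {
    is_synonymous(as.integer(subs$position[i]), subs$alt[i], ref, annotation)
  }, logical(1L)))
}

is_synonymous <- function(pos, alt, ref, annotation) {
  hit <- annotation[annotation$start <= pos & annotation$end >= pos, ,
                    drop = FALSE]
  if (nrow(hit) == 0L) return(FALSE)
  code <- mito_code()
  for (i in seq_len(nrow(hit))) {
    g <- hit[i, ]
    if (g$strand == "+") {
      off <- pos - g$start           # 0-based offset into the CDS
      codon_i <- off %/% 3L
      codon_start <- g$start + 3L * codon_i
      if (codon_start + 2L > g$end) return(FALSE)  # trailing partial codon
      codon <- ref[codon_start:(codon_start + 2L)]
      mut <- codon
      mut[off %% 3L + 1L] <- alt
    } else {
      off <- g$end - pos
      codon_i <- off %/% 3L
      codon_end <- g$end - 3L * codon_i
      if (codon_end - 2L < g$start) return(FALSE)
      codon <- unname(.COMPLEMENT[ref[codon_end:(codon_end - 2L)]])
      mut <- codon
      mut[off %% 3L + 1L] <- unname(.COMPLEMENT[alt])
    }
    if (anyNA(match(codon, c("A", "C", "G", "T")))) return(FALSE)
    aa_ref <- code[[paste(codon, collapse = "")]]
    aa_mut <- code[[paste(mut, collapse = "")]]
    if (is.null(aa_ref) || is.null(aa_mut) || aa_ref != aa_mut) return(FALSE)
  }
  TRUE
}
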