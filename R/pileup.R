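# Haploid consensus calling from samtools text pileups.
#
# Variant calling rule: at each site the called allele must be supported by
# at least `min_depth` reads (default 2) and by at least `min_frac` of the
# reads covering the site (default 3/4). Sites with coverage below
# `min_depth` are missing; sites where no allele reaches the fraction
# threshold look heteroplasmic/heterozygous. Both are reported as N.
# The same rule is applied to the reference allele and to indel alleles.

#' Parse a samtools text pileup
#'
#' Reads the 5/6-column samtools text pileup dialect (chrom, 1-based
#' position, reference base, depth, read bases, and optionally base
#' qualities) and returns per-site allele counts. Read-base encoding is
#' decoded: `.`/`,` are the reference base, `ACGTacgt` alternate bases,
#' `*` a deleted base (counted as the deletion allele `-`), `+nSEQ` an
#' insertion after the site (counted as allele `+SEQ` without increasing
#' site depth), `-nSEQ` an upcoming deletion (ignored; the deleted sites
#' themselves carry `*`), `^X` read starts and `$` read ends.
#'
#' @param path path to a pileup text file (or a character vector of lines
#'   via `lines=`).
#' @param lines optional character vector of pileup lines, used instead of
#'   `path`.
#' @param chrom expected chromosome name(s); lines for other chromosomes are
#'   skipped with a warning. `NULL` accepts any.
#' @return an object of class `pileup`: a list with integer vectors
#'   `position`, `depth`, character vector `ref`, and `counts`, a list of
#'   named integer allele-count vectors. `depth` equals the sum of the
#'   non-insertion allele counts at the site.
#' @export
parse_pileup <- function(path = NULL, lines = NULL, chrom = NULL) {
  if (is.null(lines)) lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(position = integer(0), ref = character(0),
                          depth = integer(0), counts = list()),
                     class = "pileup"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate space-separated pileups as well
  bad <- lengths(fields) < 5L
  if (any(bad)) {
    fields[bad] <- strsplit(lines[bad], "[ \t]+")
  }
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop("malformed pileup line ", which(nf < 5L)[1L],
         ": fewer than 5 columns")
  }
  chroms <- vapply(fields, `[[`, "", 1L)
  keep <- rep(TRUE, length(fields))
  if (!is.null(chrom)) {
    keep <- chroms %in% chrom
    if (any(!keep)) {
      warning(sum(!keep), " pileup line(s) on unexpected chromosome(s) ",
              paste(unique(chroms[!keep]), collapse = ", "), " skipped")
    }
  }
  fields <- fields[keep]
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos)) {
    stop("malformed pileup line ", which(keep)[which(is.na(pos))[1L]],
         ": non-integer position")
  }
  ref <- toupper(vapply(fields, `[[`, "", 3L))
  bases <- vapply(fields, `[[`, "", 5L)
  counts <- mapply(decode_read_bases, bases, ref,
                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  depth <- vapply(counts, function(ct) {
    sum(ct[!startsWith(names(ct), "+")])
  }, integer(1L))
  structure(list(position = pos, ref = ref, depth = depth, counts = counts),
            class = "pileup")
}

# Decode one read-base column into named allele counts.
decode_read_bases <- function(s, ref) {
  s <- gsub("\\^.", "", s)          # read-start marker + mapping quality
  s <- gsub("$", "", s, fixed = TRUE)
  ins <- character(0)
  # strip indel tokens, recording insertions
  m <- gregexpr("[+-][0-9]+", s)[[1L]]
  if (m[1L] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    keepstr <- character(0)
    cursor <- 1L
    for (i in seq_along(starts)) {
      st <- starts[i]
      tok <- substr(s, st, st + lens[i] - 1L)
      nins <- as.integer(substr(tok, 2L, lens[i]))
      seq_end <- st + lens[i] - 1L + nins
      if (seq_end > nchar(s)) stop("malformed indel token in pileup: ", s)
      if (substr(tok, 1L, 1L) == "+") {
        ins <- c(ins, toupper(substr(s, st + lens[i], seq_end)))
      }
      keepstr <- c(keepstr, substr(s, cursor, st - 1L))
      cursor <- seq_end + 1L
    }
    keepstr <- c(keepstr, substr(s, cursor, nchar(s)))
    s <- paste(keepstr, collapse = "")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  chars <- chars[!chars %in% c(">", "<")]
  alleles <- ifelse(chars %in% c(".", ","), ref, toupper(chars))
  alleles[alleles == "*"] <- "-"
  ok <- alleles %in% c("A", "C", "G", "T", "N", "-")
  if (any(!ok)) stop("unrecognized read-base symbol(s): ",
                     paste(unique(alleles[!ok]), collapse = " "))
  ct <- table(alleles)
  out <- stats::setNames(as.integer(ct), names(ct))
  if (length(ins) > 0L) {
    it <- table(paste0("+", ins))
    out <- c(out, stats::setNames(as.integer(it), names(it)))
  }
  out
}

#' Call the consensus allele at one site
#'
#' Applies the haploid calling rule: the winning allele needs support from
#' at least `min_depth` reads and at least `min_frac` of the site depth.
#' Sites below `min_depth` coverage are missing and sites where no allele
#' reaches the fraction are heterozygous-looking; both return `"N"`. The
#' reference allele is subject to the same fraction rule. Two alleles can
#' never both reach a fraction above 1/2, so no tie-break is needed for the
#' default 3/4.
#'
#' @param counts named integer vector of allele counts (`A`/`C`/`G`/`T`/`-`;
#'   `N` and insertion alleles are ignored for base calling).
#' @param depth site depth; defaults to the sum of non-insertion counts.
#' @param min_depth minimum supporting reads (default 2).
#' @param min_frac minimum supporting fraction of depth (default 3/4).
#' @return single character: the called allele or `"N"`.
#' @export
call_base <- function(counts, depth = NULL, min_depth = 2L, min_frac = 0.75) {
  if (length(counts) == 0L) return("N")
  callable <- counts[names(counts) %in% c("A", "C", "G", "T", "-")]
  if (is.null(depth)) {
    depth <- sum(counts[!startsWith(names(counts), "+")])
  }
  if (depth < min_depth || length(callable) == 0L) return("N")
  best <- which(callable == max(callable))
  if (length(best) > 1L && max(callable) / depth >= min_frac) {
    # two alleles at >= min_frac each would need fractions summing > 1
    stop("impossible tie: two alleles both reach the fraction threshold")
  }
  a <- names(callable)[best[1L]]
  if (callable[best[1L]] >= min_depth &&
      callable[best[1L]] >= min_frac * depth) a else "N"
}

#' Assemble a haploid consensus sequence from a pileup
#'
#' Every reference position receives the [call_base()] output of its pileup
#' site, or `N` when the position is absent from the pileup (uncovered).
#' Insertion alleles passing the same support rule are recorded as inserted
#' sequence after their anchor position; a winning `-` allele marks the
#' position as deleted.
#'
#' @param pu a `pileup` object from [parse_pileup()].
#' @param ref reference base vector.
#' @param sample_id sample name carried through to outputs.
#' @inheritParams call_base
#' @return object of class `consensus_seq`: list with `sample_id`, `bases`
#'   (character vector over reference coordinates, `A`/`C`/`G`/`T`/`N`/`-`),
#'   `insertions` (named list: anchor position -> inserted sequence),
#'   `n_ambiguous`, `mean_depth`.
#' @export
assemble_consensus <- function(pu, ref, sample_id = "sample",
                               min_depth = 2L, min_frac = 0.75) {
  L <- length(ref)
  if (anyDuplicated(pu$position)) {
    stop("duplicate positions in pileup: ",
         paste(utils::head(pu$position[duplicated(pu$position)], 3L),
               collapse = ", "))
  }
  if (length(pu$position) && (min(pu$position) < 1L || max(pu$position) > L)) {
    stop("pileup position outside reference length ", L)
  }
  bases <- rep("N", L)
  insertions <- list()
  for (i in seq_along(pu$position)) {
    p <- pu$position[i]
    ct <- pu$counts[[i]]
    d <- pu$depth[i]
    bases[p] <- call_base(ct, depth = d, min_depth = min_depth,
                          min_frac = min_frac)
    ins_ct <- ct[startsWith(names(ct), "+")]
    if (length(ins_ct) > 0L) {
      w <- which.max(ins_ct)
      if (ins_ct[w] >= min_depth && ins_ct[w] >= min_frac * d) {
        insertions[[as.character(p)]] <- substring(names(ins_ct)[w], 2L)
      }
    }
  }
  depth_all <- numeric(L)
  depth_all[pu$position] <- pu$depth
  structure(list(sample_id = sample_id, bases = bases,
                 insertions = insertions,
                 n_ambiguous = sum(bases == "N"),
                 mean_depth = mean(depth_all)),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat("Haploid consensus for sample", x$sample_id, "\n")
  cat("  length:", length(x$bases), " ambiguous (N):", x$n_ambiguous,
      " mean depth:", round(x$mean_depth, 1), "\n")
  if (length(x$insertions)) {
    cat("  insertions after:",
        paste(names(x$insertions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a variant set
#'
#' A variant set is one sample's differences from the reference: a
#' data.frame with columns `position` (numeric; insertions use the decimal
#' suffix convention, e.g. 309.1), `ref`, `alt`, `kind` (one of
#' `substitution`, `insertion`, `deletion`) and `name` (HVS-style label such
#' as `8701G`, `309.1C`, `249d`). Missing (N) positions are carried in the
#' `missing` attribute so the consensus can be reconstructed exactly.
#'
#' @param df variant data.frame (may omit `name`, which is derived).
#' @param sample_id sample name.
#' @param missing integer vector of N positions.
#' @export
variant_set <- function(df, sample_id = "sample", missing = integer(0)) {
  if (nrow(df) > 0L) {
    df <- df[order(df$position, df$kind, df$alt), , drop = FALSE]
    if (is.null(df$name)) df$name <- variant_name(df)
    key <- paste(df$position, df$kind, df$alt)
    if (anyDuplicated(key)) stop("duplicate variants: ",
                                 paste(df$name[duplicated(key)], collapse = ", "))
  } else {
    df <- data.frame(position = numeric(0), ref = character(0),
                     alt = character(0), kind = character(0),
                     name = character(0), stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, missing = as.integer(missing),
            class = c("variant_set", "data.frame"))
}

#' Canonical variant names
#'
#' @param df data.frame with `position`, `alt`, `kind`.
#' @return character vector of names like `8701G`, `309.1C`, `249d`.
#' @export
variant_name <- function(df) {
  ifelse(df$kind == "deletion", paste0(as.integer(df$position), "d"),
         ifelse(df$kind == "insertion",
                paste0(format(df$position, trim = TRUE), df$alt),
                paste0(as.integer(df$position), df$alt)))
}

#' Extract variants of a consensus against the reference
#'
#' N positions emit no variant (they are recorded in the `missing`
#' attribute). Insertions are named with the decimal-suffix convention
#' (`309.1C` for a C inserted after position 309, one row per inserted
#' base). Deletions are recorded per deleted position.
#'
#' @param cons a `consensus_seq`.
#' @param ref reference base vector.
#' @return a [variant_set].
#' @export
variants_vs_reference <- function(cons, ref) {
  b <- cons$bases
  sub_i <- which(b != ref & b != "N" & b != "-")
  del_i <- which(b == "-")
  rows <- list()
  if (length(sub_i)) {
    rows[[length(rows) + 1L]] <- data.frame(
      position = as.numeric(sub_i), ref = ref[sub_i], alt = b[sub_i],
      kind = "substitution", stringsAsFactors = FALSE)
  }
  if (length(del_i)) {
    rows[[length(rows) + 1L]] <- data.frame(
      position = as.numeric(del_i), ref = ref[del_i], alt = "-",
      kind = "deletion", stringsAsFactors = FALSE)
  }
  for (anchor in names(cons$insertions)) {
    seqchars <- strsplit(cons$insertions[[anchor]], "", fixed = TRUE)[[1L]]
    p <- as.integer(anchor)
    rows[[length(rows) + 1L]] <- data.frame(
      position = p + seq_along(seqchars) / 10,
      ref = "-", alt = seqchars, kind = "insertion",
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = numeric(0), ref = character(0), alt = character(0),
               kind = character(0), stringsAsFactors = FALSE)
  variant_set(df, sample_id = cons$sample_id,
              missing = which(b == "N"))
}

#' Apply a variant set to the reference
#'
#' Reconstructs the consensus a variant set was derived from: substitutions
#' and deletions replace reference bases, insertions are re-attached to
#' their anchors, and positions listed in the `missing` attribute are set
#' back to `N`. Round-trips with [variants_vs_reference()].
#'
#' @param vs a [variant_set].
#' @param ref reference base vector.
#' @return a `consensus_seq`.
#' @export
apply_variants <- function(vs, ref) {
  bases <- ref
  subs <- vs[vs$kind == "substitution", , drop = FALSE]
  bases[as.integer(subs$position)] <- subs$alt
  dels <- vs[vs$kind == "deletion", , drop = FALSE]
  bases[as.integer(dels$position)] <- "-"
  ins <- vs[vs$kind == "insertion", , drop = FALSE]
  insertions <- list()
  if (nrow(ins)) {
    anchors <- as.integer(floor(ins$position))
    for (a in unique(anchors)) {
      rows <- ins[anchors == a, , drop = FALSE]
      rows <- rows[order(rows$position), , drop = FALSE]
      insertions[[as.character(a)]] <- paste(rows$alt, collapse = "")
    }
  }
  miss <- attr(vs, "missing")
  bases[miss] <- "N"
  structure(list(sample_id = attr(vs, "sample_id"), bases = bases,
                 insertions = insertions, n_ambiguous = length(miss),
                 mean_depth = NA_real_),
            class = "consensus_seq")
}

#' Write / read variant tables
#'
#' Tab-separated mirror of the supplementary-table encoding: columns
#' `sample`, `position`, `name`, `ref`, `alt`, `kind`, plus a `missing`
#' column holding the sample's N positions as a comma list on its first row.
#'
#' @param vsets named list of [variant_set]s.
#' @param path file path.
#' @export
write_variants <- function(vsets, path) {
  rows <- lapply(vsets, function(vs) {
    sid <- attr(vs, "sample_id")
    df <- as.data.frame(vs)
    miss <- paste(attr(vs, "missing"), collapse = ",")
    if (nrow(df) == 0L) {
      df <- data.frame(position = NA_real_, ref = "", alt = "", kind = "",
                       name = "", stringsAsFactors = FALSE)
    }
    cbind(sample = sid, df,
          missing = c(miss, rep("", nrow(df) - 1L)))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants
#' @return `read_variants()` returns a named list of [variant_set]s.
#' @export
read_variants <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(missing = "character"))
  split_df <- split(df, df$sample)
  out <- lapply(split_df, function(d) {
    sid <- d$sample[1L]
    miss <- d$missing[nzchar(d$missing)]
    miss <- if (length(miss) == 0L) integer(0) else
      as.integer(strsplit(miss[1L], ",", fixed = TRUE)[[1L]])
    d <- d[!is.na(d$position), c("position", "ref", "alt", "kind", "name")]
    variant_set(d, sample_id = sid, missing = miss)
  })
  out[unique(df$sample)]
}

#' Write consensus sequences to FASTA
#'
#' Deleted positions are written as `-` so records stay aligned to
#' reference coordinates; insertions are not included in the FASTA record.
#'
#' @param conss list of `consensus_seq` objects.
#' @param path output path.
#' @export
write_consensus_fasta <- function(conss, path) {
  seqs <- lapply(conss, `[[`, "bases")
  names(seqs) <- vapply(conss, `[[`, "", "sample_id")
  write_fasta(seqs, path)
}
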