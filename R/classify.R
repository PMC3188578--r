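# Haplogroup assignment and frequency tabulation.

#' Assign a variant set to a haplogroup
#'
#' Scores every node of the definition tree as (number of cumulative
#' defining mutations matched) minus (number expected but absent) and
#' returns the best node. Positions masked as missing (N) in the sample
#' count as neither matched nor missing. Ties are broken towards the deeper
#' node, then lexicographically by name. The variant set should already be
#' filtered with [exclude_unstable_positions()]; any excluded-position
#' variants still present are ignored for scoring.
#'
#' @param vs a [variant_set].
#' @param tree a `haplo_tree` from [load_haplotree()].
#' @param exclude descriptors ignored when counting private (extra)
#'   mutations.
#' @return object of class `haplogroup_call`: list with `sample_id`,
#'   `haplogroup`, `macro`, `score`, `matched`, `missing`, `extra`
#'   (variant-name vectors) and `depth`.
#' @export
assign_haplogroup <- function(vs, tree,
                              exclude = mt_exclusions("assignment")) {
  if (nrow(tree$nodes) == 0L) stop("empty haplogroup tree")
  vs <- exclude_unstable_positions(vs, exclude)
  subs <- vs[vs$kind == "substitution", , drop = FALSE]
  sample_allele <- stats::setNames(subs$alt, as.character(as.integer(subs$position)))
  masked <- as.character(attr(vs, "missing"))
  best <- NULL
  for (i in seq_len(nrow(tree$nodes))) {
    nm <- tree$nodes$name[i]
    exp_state <- tree$expected[[nm]]
    pos <- names(exp_state)
    got <- sample_allele[pos]
    # an expected reference allele (back-mutation) is matched when the
    # sample shows the ancestral state, i.e. carries no variant there
    is_ref_exp <- if (is.null(tree$ref)) rep(FALSE, length(pos)) else
      tree$ref[as.integer(pos)] == unname(exp_state)
    matched <- ifelse(is_ref_exp, is.na(got) & !(pos %in% masked),
                      !is.na(got) & got == unname(exp_state))
    miss <- !matched & !(pos %in% masked)
    score <- sum(matched) - sum(miss)
    cand <- list(name = nm, score = score, depth = tree$nodes$depth[i],
                 matched = pos[matched], missing = pos[miss])
    if (is.null(best) ||
        score > best$score ||
        (score == best$score && cand$depth > best$depth) ||
        (score == best$score && cand$depth == best$depth &&
         cand$name < best$name)) {
      best <- cand
    }
  }
  exp_state <- tree$expected[[best$name]]
  extra <- setdiff(names(sample_allele), names(exp_state))
  structure(list(sample_id = attr(vs, "sample_id"),
                 haplogroup = best$name,
                 macro = tree$nodes$macro[tree$nodes$name == best$name],
                 score = best$score,
                 matched = best$matched, missing = best$missing,
                 extra = extra, depth = best$depth),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("%s -> %s (macro %s; %d matched, %d missing, %d private)\n",
              x$sample_id, x$haplogroup, x$macro, length(x$matched),
              length(x$missing), length(x$extra)))
  invisible(x)
}

#' Assign many samples at once
#'
#' @param vsets named list of [variant_set]s.
#' @inheritParams assign_haplogroup
#' @return data.frame with one row per sample: `sample`, `haplogroup`,
#'   `macro`, `score`, `n_matched`, `n_missing`, `n_extra`.
#' @export
assign_haplogroups <- function(vsets, tree,
                               exclude = mt_exclusions("assignment")) {
  calls <- lapply(vsets, assign_haplogroup, tree = tree, exclude = exclude)
  data.frame(sample = vapply(calls, `[[`, "", "sample_id"),
             haplogroup = vapply(calls, `[[`, "", "haplogroup"),
             macro = vapply(calls, `[[`, "", "macro"),
             score = vapply(calls, `[[`, 0, "score"),
             n_matched = vapply(calls, function(x) length(x$matched), 0L),
             n_missing = vapply(calls, function(x) length(x$missing), 0L),
             n_extra = vapply(calls, function(x) length(x$extra), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

# round half away from zero at d decimals (conventional reporting rounding)
round_half_up <- function(x, d = 1L) {
  floor(x * 10^d + 0.5) / 10^d
}

#' Macrohaplogroup composition
#'
#' Maps haplogroup labels to their macrohaplogroups through the definition
#' tree and reports percentages to one decimal. The `N` figure includes the
#' `R` clade, which is nested within N; the share of R inside N is reported
#' separately in the `R_within_N` attribute.
#'
#' @param haplogroups character vector of haplogroup labels (must be nodes
#'   of `tree`), or a data.frame from [assign_haplogroups()].
#' @param tree a `haplo_tree`.
#' @param weights optional multiplicities (e.g. counts per haplogroup).
#' @return named numeric vector of percentages by macrohaplogroup (R folded
#'   into N), summing to 100 up to rounding, with attribute `R_within_N`.
#' @export
macro_fraction <- function(haplogroups, tree, weights = NULL) {
  if (is.data.frame(haplogroups)) haplogroups <- haplogroups$haplogroup
  macro_map <- stats::setNames(tree$nodes$macro, tree$nodes$name)
  macro <- macro_map[haplogroups]
  if (anyNA(macro)) {
    stop("haplogroup(s) not in tree: ",
         paste(unique(haplogroups[is.na(macro)]), collapse = ", "))
  }
  if (is.null(weights)) weights <- rep(1, length(macro))
  tot <- sum(weights)
  r_w <- sum(weights[macro == "R"])
  macro[macro == "R"] <- "N"
  agg <- tapply(weights, macro, sum)
  out <- round_half_up(100 * as.numeric(agg) / tot)
  names(out) <- names(agg)
  attr(out, "R_within_N") <- round_half_up(100 * r_w / tot)
  out
}

#' Collapse fine haplogroup calls to reporting rows
#'
#' Applies an explicit map from fine call names to the row labels of a
#' frequency table (e.g. pooling F1a1'4 and F2 into F). Labels absent from
#' the map are kept unchanged.
#'
#' @param haplogroups character vector of fine haplogroup labels.
#' @param map named character vector, fine label -> row label.
#' @export
collapse_haplogroups <- function(haplogroups, map) {
  hit <- haplogroups %in% names(map)
  haplogroups[hit] <- unname(map[haplogroups[hit]])
  haplogroups
}

#' Haplogroup frequency table by population
#'
#' Builds the population-by-haplogroup percentage table: one row per
#' haplogroup label, one column per population plus a sample-weighted
#' `Total` column, cells as percentages rounded half-up to one decimal.
#'
#' @param haplogroups character vector of (possibly collapsed) labels, or a
#'   data.frame with columns `sample` and `haplogroup`.
#' @param populations character vector of population labels, parallel to
#'   `haplogroups` (or named by sample).
#' @return object of class `freq_table`: a numeric matrix with attribute
#'   `n` (named sample sizes, including `Total`) and `counts`.
#' @export
frequency_table <- function(haplogroups, populations) {
  if (is.data.frame(haplogroups)) {
    if (!is.null(names(populations))) {
      populations <- populations[haplogroups$sample]
    }
    haplogroups <- haplogroups$haplogroup
  }
  if (length(haplogroups) == 0L) stop("no haplogroup calls to tabulate")
  if (length(populations) != length(haplogroups)) {
    stop("populations must be parallel to haplogroup calls")
  }
  if (anyNA(populations)) stop("missing population label(s)")
  counts <- table(haplogroup = haplogroups, population = populations)
  n_pop <- colSums(counts)
  if (any(n_pop == 0L)) stop("population with zero samples: ",
                             paste(names(n_pop)[n_pop == 0L], collapse = ", "))
  counts <- cbind(counts, Total = rowSums(counts))
  n <- c(n_pop, Total = sum(n_pop))
  pct <- round_half_up(sweep(counts, 2L, n, "/") * 100)
  structure(pct, n = n, counts = counts, class = c("freq_table", "matrix"))
}

#' @export
print.freq_table <- function(x, ...) {
  n <- attr(x, "n")
  cat("Haplogroup frequencies (%)\n")
  hdr <- sprintf("%s (n=%d)", colnames(x), n)
  m <- unclass(x)
  attr(m, "n") <- NULL
  attr(m, "counts") <- NULL
  colnames(m) <- hdr
  print(m, ...)
  invisible(x)
}

#' Write a frequency table to TSV
#' @param ft a `freq_table`.
#' @param path output path.
#' @export
write_frequency_table <- function(ft, path) {
  df <- data.frame(haplogroup = rownames(ft), unclass(ft)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
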