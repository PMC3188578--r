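# Haplogroup definition trees (Phylotree-style).
#
# A tree config is a tab-separated table with one node per row: `name`,
# `parent` (`-` for the root), `mutations` (comma list) and `macro`
# (macrohaplogroup label, inherited from the parent when empty). A defining
# mutation is written as position plus derived allele (`8701G`), as a bare
# position (`8701`, derived allele resolved as the transition partner of
# the reference base), or with a trailing `!` for a back-mutation that
# reverts the position to the reference state along that branch.

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Highly recurrent positions excluded from analysis
#'
#' Descriptors of unstable sites in the control region that are excluded
#' before haplogroup assignment (`"assignment"`) or before counting
#' mutations for rho dating (`"dating"`). The two published lists name the
#' same poly-C artifact with different descriptors (`16193.1C` vs
#' `16194C`); both descriptors are excluded in both contexts by default.
#'
#' @param context `"assignment"` or `"dating"`.
#' @return character vector of descriptors.
#' @export
mt_exclusions <- function(context = c("assignment", "dating")) {
  context <- match.arg(context)
  switch(context,
    assignment = c("309.1C", "16182C", "16183C", "16193.1C", "16194C",
                   "16519"),
    dating = c("16519", "16182C", "16183C", "16194C", "16193.1C"))
}

# Parse an exclusion descriptor into matching fields.
parse_exclusion <- function(desc) {
  if (grepl("\\.", desc)) {
    pos <- as.numeric(sub("([0-9]+\\.[0-9]+).*", "\\1", desc))
    alt <- sub("[0-9]+\\.[0-9]+", "", desc)
    list(position = pos, alt = if (nzchar(alt)) alt else NA_character_,
         kind = "insertion")
  } else if (grepl("[ACGT]$", desc)) {
    list(position = as.numeric(sub("[ACGT]$", "", desc)),
         alt = sub("^[0-9]+", "", desc), kind = "substitution")
  } else {
    list(position = as.numeric(desc), alt = NA_character_,
         kind = NA_character_)
  }
}

#' Remove variants at unstable positions
#'
#' Drops variants matching the exclusion descriptors; a bare-position
#' descriptor (e.g. `16519`) matches any variant at that position, an
#' allele descriptor (`16182C`) only the named substitution, and a decimal
#' descriptor (`309.1C`) the named insertion.
#'
#' @param vs a [variant_set].
#' @param exclude descriptor vector, default the assignment list.
#' @return filtered [variant_set].
#' @export
exclude_unstable_positions <- function(vs,
                                       exclude = mt_exclusions("assignment")) {
  if (nrow(vs) == 0L || length(exclude) == 0L) return(vs)
  drop <- rep(FALSE, nrow(vs))
  for (desc in exclude) {
    p <- parse_exclusion(desc)
    hit <- abs(vs$position - p$position) < 1e-9
    if (!is.na(p$kind)) hit <- hit & vs$kind == p$kind
    if (!is.na(p$alt)) hit <- hit & vs$alt == p$alt
    drop <- drop | hit
  }
  variant_set(as.data.frame(vs)[!drop, , drop = FALSE],
              sample_id = attr(vs, "sample_id"),
              missing = attr(vs, "missing"))
}

#' Load a haplogroup definition tree
#'
#' Validates the config (single root, no cycles, parents present, unique
#' names, non-empty defining sets except at the root), resolves bare
#' defining positions against the reference, strips excluded unstable
#' positions from all defining sets, and precomputes each node's expected
#' cumulative variant state along the root-to-node path (honouring `!`
#' back-mutations, which revert a position to the reference allele).
#'
#' @param path TSV config path, or a data.frame with the same columns.
#' @param ref reference base vector; required when the config uses bare
#'   positions or back-mutations.
#' @param exclude exclusion descriptors stripped from defining sets.
#' @return object of class `haplo_tree`.
#' @export
load_haplotree <- function(path, ref = NULL,
                           exclude = mt_exclusions("assignment")) {
  df <- if (is.data.frame(path)) path else
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "",
                      colClasses = "character")
  need <- c("name", "parent", "mutations", "macro")
  if (!all(need %in% names(df))) {
    stop("haplotree config must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate node name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  root <- df$name[df$parent %in% c("-", "")]
  if (length(root) != 1L) stop("tree must have exactly one root, found ",
                               length(root))
  nonroot <- df[!(df$parent %in% c("-", "")), , drop = FALSE]
  orphan <- setdiff(nonroot$parent, df$name)
  if (length(orphan)) stop("orphan parent reference(s): ",
                           paste(orphan, collapse = ", "))
  if (any(nonroot$parent == nonroot$name)) {
    stop("node cannot be its own parent: ",
         paste(nonroot$name[nonroot$parent == nonroot$name], collapse = ", "))
  }
  parent <- stats::setNames(df$parent, df$name)
  parent[root] <- NA_character_
  # depth + cycle detection
  depth <- stats::setNames(rep(NA_integer_, nrow(df)), df$name)
  depth[root] <- 0L
  for (nm in df$name) {
    seen <- character(0)
    cur <- nm
    while (is.na(depth[cur])) {
      if (cur %in% seen) stop("cycle in haplotree involving node ", cur)
      seen <- c(seen, cur)
      cur <- parent[cur]
    }
    base <- depth[cur]
    for (i in seq_along(seen)) {
      depth[seen[length(seen) - i + 1L]] <- base + i
    }
  }
  # parse defining mutations
  excl_pos <- vapply(exclude, function(d) parse_exclusion(d)$position,
                     numeric(1L))
  muts <- lapply(seq_len(nrow(df)), function(i) {
    spec <- df$mutations[i]
    if (df$name[i] == root) {
      if (!spec %in% c("-", "")) stop("root node must have no mutations")
      return(data.frame(position = integer(0), allele = character(0),
                        back = logical(0), stringsAsFactors = FALSE))
    }
    if (spec %in% c("-", "")) {
      stop("node ", df$name[i], " has an empty defining-mutation list")
    }
    toks <- trimws(strsplit(spec, ",", fixed = TRUE)[[1L]])
    back <- grepl("!$", toks)
    toks <- sub("!$", "", toks)
    pos <- as.integer(sub("[ACGT]?$", "", toks))
    if (anyNA(pos)) stop("bad mutation token in node ", df$name[i])
    allele <- sub("^[0-9]+", "", toks)
    bare <- !nzchar(allele)
    if (any(bare | back)) {
      if (is.null(ref)) {
        stop("reference required to resolve bare positions/back-mutations")
      }
      allele[bare] <- unname(.TRANSITION[ref[pos[bare]]])
      allele[back] <- ref[pos[back]]
    }
    keep <- !(pos %in% floor(excl_pos))
    data.frame(position = pos[keep], allele = allele[keep], back = back[keep],
               stringsAsFactors = FALSE)
  })
  names(muts) <- df$name
  # macro inheritance
  macro <- stats::setNames(df$macro, df$name)
  resolve_macro <- function(nm) {
    while (!is.na(nm) && (is.na(macro[nm]) || !nzchar(macro[nm]))) {
      nm <- parent[nm]
    }
    if (is.na(nm)) NA_character_ else unname(macro[nm])
  }
  macro <- stats::setNames(vapply(df$name, resolve_macro, ""), df$name)
  # cumulative expected states; a back-mutation sets the position's
  # expected allele to the reference state (the entry is kept so scoring
  # can require the ancestral allele to be shown)
  expected <- list()
  for (nm in df$name[order(depth[df$name])]) {
    state <- if (is.na(parent[nm])) character(0) else expected[[parent[nm]]]
    m <- muts[[nm]]
    for (j in seq_len(nrow(m))) {
      state[as.character(m$position[j])] <- m$allele[j]
    }
    expected[[nm]] <- state
  }
  structure(list(nodes = data.frame(name = df$name,
                                    parent = unname(parent[df$name]),
                                    macro = unname(macro[df$name]),
                                    depth = unname(depth[df$name]),
                                    stringsAsFactors = FALSE),
                 root = root, mutations = muts, expected = expected,
                 ref = ref),
            class = "haplo_tree")
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("Haplogroup definition tree:", nrow(x$nodes), "nodes, root",
      x$root, "\n")
  cat("  macro labels:",
      paste(names(table(x$nodes$macro)), collapse = " "), "\n")
  invisible(x)
}

#' Expected variants of a haplogroup node
#'
#' The cumulative defining state along the root-to-node path, expressed as
#' a [variant_set] against the reference. When a reference is available,
#' entries whose derived allele equals the reference base are dropped (they
#' produce no observable variant).
#'
#' @param tree a `haplo_tree`.
#' @param node node name.
#' @param ref reference base vector (defaults to the tree's).
#' @return a [variant_set].
#' @export
expected_variants <- function(tree, node, ref = tree$ref) {
  state <- tree$expected[[node]]
  if (is.null(state)) stop("unknown haplogroup node: ", node)
  if (length(state) == 0L) return(variant_set(data.frame(), sample_id = node))
  pos <- as.integer(names(state))
  refb <- if (is.null(ref)) rep(NA_character_, length(pos)) else ref[pos]
  keep <- is.na(refb) | refb != unname(state)
  variant_set(data.frame(position = as.numeric(pos[keep]),
                         ref = refb[keep], alt = unname(state)[keep],
                         kind = "substitution", stringsAsFactors = FALSE),
              sample_id = node)
}
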