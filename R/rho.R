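# Rho-statistic founder age estimation with Saillard standard errors.
#
# rho is the mean number of mutations separating a designated founder
# haplotype from each sampled descendant. Over the branch decomposition of
# the genealogy, rho = (1/n) * sum_b n_b * m_b, where branch b carries m_b
# mutations and subtends n_b of the n tips, and its standard error is
# sigma_rho = sqrt( sum_b (n_b/n)^2 * m_b ). Under a molecular clock,
# E[rho] = expected substitutions accumulated since the founder, which a
# clock model inverts into years.

# Counted substitution keys ("pos:alt") of a variant set under a counting
# policy: indels never count, excluded descriptors are removed, and the
# synonymous policy keeps only amino-acid-preserving coding changes.
counted_keys <- function(vs, exclude = mt_exclusions("dating"),
                         counted = c("all", "synonymous"), ref = NULL,
                         annotation = NULL) {
  counted <- match.arg(counted)
  vs <- exclude_unstable_positions(vs, exclude)
  subs <- vs[vs$kind == "substitution", , drop = FALSE]
  if (counted == "synonymous" && nrow(subs) > 0L) {
    keep <- vapply(seq_len(nrow(subs)), function(i) {
      is_synonymous(as.integer(subs$position[i]), subs$alt[i], ref,
                    annotation)
    }, logical(1L))
    subs <- subs[keep, , drop = FALSE]
  }
  paste0(as.integer(subs$position), ":", subs$alt)
}

setsym <- function(a, b) length(setdiff(a, b)) + length(setdiff(b, a))

#' Branch genealogy of a star cluster
#'
#' Reconstructs the rooted genealogy of a detected cluster for rho dating.
#' The founder is the cluster's center node: its coding-region state comes
#' from the network, extended to the full genome by the majority state of
#' the members at non-coding positions. The topology follows the network's
#' branch structure; each sample hangs as a tip from its haplotype node.
#' Mutations are counted over complete genomes as substitutions passing the
#' counting policy (dating exclusions applied; `counted = "synonymous"`
#' restricts to synonymous changes).
#'
#' @param cluster a `star_cluster`.
#' @param mjg the `mj_graph` the cluster was detected in.
#' @param vsets named list of full-genome [variant_set]s covering all
#'   members.
#' @param counted `"all"` or `"synonymous"`.
#' @param exclude descriptors excluded from mutation counting.
#' @param region coding-region bounds used by the network.
#' @param ref reference base vector (required for `"synonymous"`).
#' @param annotation gene table (required for `"synonymous"`).
#' @return object of class `cluster_genealogy`: list with `n`, `edges`
#'   (data.frame `n_b`, `m_b`), `tip_distances` (named by sample) and
#'   `center`.
#' @export
cluster_genealogy <- function(cluster, mjg, vsets,
                              counted = c("all", "synonymous"),
                              exclude = mt_exclusions("dating"),
                              region = CODING_REGION, ref = NULL,
                              annotation = NULL) {
  counted <- match.arg(counted)
  absent <- setdiff(cluster$members, names(vsets))
  if (length(absent)) {
    stop("cluster member(s) lacking full-genome variants: ",
         paste(utils::head(absent, 3L), collapse = ", "))
  }
  sample_keys <- lapply(vsets[cluster$members], counted_keys,
                        exclude = exclude, counted = counted, ref = ref,
                        annotation = annotation)
  names(sample_keys) <- cluster$members
  # network-node coding states as counted keys
  site_names <- colnames(mjg$states)
  numeric_site <- suppressWarnings(!is.na(as.numeric(site_names)))
  excl_pos <- vapply(exclude, function(d) floor(parse_exclusion(d)$position),
                     numeric(1L))
  node_coding <- function(v) {
    st <- mjg$states[v, ]
    idx <- which(numeric_site & !is.na(st) & st != mjg$ref)
    if (length(idx) == 0L) return(character(0))
    keep <- if (counted == "synonymous") {
      vapply(idx, function(j) {
        is_synonymous(as.integer(site_names[j]), st[j], ref, annotation)
      }, logical(1L))
    } else rep(TRUE, length(idx))
    pos <- as.integer(site_names[idx])
    paste0(pos, ":", st[idx])[keep & !(pos %in% excl_pos)]
  }
  # positions represented in the network matrix; everything else (non-coding
  # sites, and coding sites monomorphic within the data set, e.g. the
  # cluster's shared defining mutations) is reconstructed from the members'
  # majority state
  matrix_pos <- as.integer(site_names[numeric_site])
  off_matrix <- function(keys) {
    pos <- as.integer(sub(":.*", "", keys))
    keys[!(pos %in% matrix_pos)]
  }
  # BFS tree over the cluster's nodes
  nodes <- cluster$member_nodes
  g <- igraph::induced_subgraph(mjg$graph, nodes)
  ctr <- cluster$center
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  order_out <- ctr
  queue <- ctr
  seen <- ctr
  adj <- stats::setNames(lapply(igraph::adjacent_vertices(g, igraph::V(g)$name),
                                function(v) v$name), igraph::V(g)$name)
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (nb in sort(setdiff(adj[[x]], seen))) {
      parent[nb] <- x
      seen <- c(seen, nb)
      order_out <- c(order_out, nb)
      queue <- c(queue, nb)
    }
  }
  if (length(order_out) != length(nodes)) {
    stop("cluster subgraph is disconnected: ",
         paste(setdiff(nodes, order_out), collapse = ", "))
  }
  samples_at <- lapply(stats::setNames(nodes, nodes), function(v) {
    samp <- mjg$samples[[v]]
    if (is.null(samp)) character(0) else intersect(samp, cluster$members)
  })
  # descendant samples at/below each node (for majority non-coding state)
  below <- samples_at
  for (v in rev(order_out)) {
    p <- parent[v]
    if (!is.na(p)) below[[p]] <- c(below[[p]], below[[v]])
  }
  majority_off_matrix <- function(samps) {
    if (length(samps) == 0L) return(character(0))
    ncl <- lapply(sample_keys[samps], off_matrix)
    tab <- table(unlist(ncl, use.names = FALSE))
    names(tab)[tab > length(samps) / 2]
  }
  node_keys <- lapply(stats::setNames(nodes, nodes), function(v) {
    union(node_coding(v), majority_off_matrix(below[[v]]))
  })
  # branch decomposition: node-node edges + per-sample tip edges
  n_tips_below <- lengths(below)
  edges <- data.frame(n_b = integer(0), m_b = integer(0))
  dist_root <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in order_out[-1L]) {
    p <- parent[v]
    m <- setsym(node_keys[[v]], node_keys[[p]])
    edges <- rbind(edges, data.frame(n_b = n_tips_below[[v]], m_b = m))
    dist_root[v] <- dist_root[p] + m
  }
  tip_distances <- numeric(0)
  for (v in nodes) {
    for (s in samples_at[[v]]) {
      m <- setsym(sample_keys[[s]], node_keys[[v]])
      edges <- rbind(edges, data.frame(n_b = 1L, m_b = m))
      tip_distances[s] <- dist_root[v] + m
    }
  }
  structure(list(n = length(cluster$members), edges = edges,
                 tip_distances = tip_distances, center = ctr),
            class = "cluster_genealogy")
}

#' Star genealogy from founder distances
#'
#' Builds the degenerate (star) branch decomposition in which every tip
#' hangs directly from the founder by its own branch.
#'
#' @param distances integer vector of per-tip mutation counts to the
#'   founder (optionally named by sample).
#' @return a `cluster_genealogy`.
#' @export
star_genealogy <- function(distances) {
  structure(list(n = length(distances),
                 edges = data.frame(n_b = rep(1L, length(distances)),
                                    m_b = as.numeric(distances)),
                 tip_distances = distances, center = "founder"),
            class = "cluster_genealogy")
}

#' Branch decomposition of a simulated genealogy
#'
#' Converts an `ape` phylo tree with known per-edge mutation counts into
#' the branch decomposition used by [rho()] and [saillard_sigma()], rooted
#' at the tree root (the founder).
#'
#' @param phy an `ape::phylo` tree.
#' @param edge_mutations integer vector of mutation counts, parallel to
#'   `phy$edge` rows.
#' @return a `cluster_genealogy`.
#' @export
as_cluster_genealogy <- function(phy, edge_mutations) {
  ntip <- length(phy$tip.label)
  stopifnot(length(edge_mutations) == nrow(phy$edge))
  # tips below each edge
  below <- integer(max(phy$edge))
  below[seq_len(ntip)] <- 1L
  ord <- rev(ape::postorder(phy))
  for (e in rev(ord)) {
    below[phy$edge[e, 1L]] <- below[phy$edge[e, 1L]] + below[phy$edge[e, 2L]]
  }
  nb <- below[phy$edge[, 2L]]
  # root-to-tip mutation sums
  depth <- numeric(max(phy$edge))
  for (e in ord) {
    depth[phy$edge[e, 2L]] <- depth[phy$edge[e, 1L]] + edge_mutations[e]
  }
  tipd <- stats::setNames(depth[seq_len(ntip)], phy$tip.label)
  structure(list(n = ntip,
                 edges = data.frame(n_b = nb,
                                    m_b = as.numeric(edge_mutations)),
                 tip_distances = tipd, center = "root"),
            class = "cluster_genealogy")
}

#' @export
print.cluster_genealogy <- function(x, ...) {
  cat("Cluster genealogy:", x$n, "tips,", nrow(x$edges), "branches, rho =",
      round(rho(x), 3), "+/-", round(saillard_sigma(x), 3), "\n")
  invisible(x)
}

#' The rho statistic
#'
#' Mean mutational distance from the founder to the tips, computed as the
#' branch sum (1/n) * sum_b n_b * m_b, which equals the direct mean of
#' root-to-tip mutation counts.
#'
#' @param g a `cluster_genealogy`.
#' @return numeric rho.
#' @export
rho <- function(g) {
  if (g$n < 1L) stop("genealogy has no tips")
  sum(g$edges$n_b * g$edges$m_b) / g$n
}

#' Saillard standard error of rho
#'
#' sigma_rho = sqrt( sum_b (n_b/n)^2 * m_b ). For a perfect star this
#' reduces to sqrt(rho / n).
#'
#' @param g a `cluster_genealogy`.
#' @return numeric standard error.
#' @export
saillard_sigma <- function(g) {
  sqrt(sum((g$edges$n_b / g$n)^2 * g$edges$m_b))
}
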