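# Star-cluster (expansion) detection on a median-joining network.

#' Detect star-like clusters
#'
#' A star cluster is a network node — observed haplotype or median vector —
#' from which at least `min_branches` branches radiate; such radiations are
#' the network signature of a rapid lineage expansion from a founder.
#' Branches are the distinct incident edges at the center (a chain passing
#' through degree-2 nodes is a single branch). Membership is collected by
#' following each branch outward: median vectors are traversed freely (they
#' carry no samples), observed haplotypes of degree at most two are
#' collected and traversal continues, and traversal stops—exclusively—at
#' another cluster center, at an observed node with more than two incident
#' edges (the start of a different radiation), or at any node bordering a
#' different center (recurrent mutations can thread median paths around a
#' center; stopping at its doorstep keeps such paths from leaking one
#' radiation's periphery into another).
#'
#' @param mjg an `mj_graph` from [median_joining()].
#' @param min_branches minimum number of radiating branches (default 5).
#' @return list of `star_cluster` objects: each a list with `center`,
#'   `n_branches`, `members` (sample ids), `member_nodes` (vertex names,
#'   center first) and `haplogroup` (`NA` until labelled).
#' @export
detect_star_clusters <- function(mjg, min_branches = 5L) {
  g <- mjg$graph
  deg <- igraph::degree(g)
  vn <- igraph::V(g)$name
  observed <- stats::setNames(igraph::V(g)$observed, vn)
  samples_of <- stats::setNames(strsplit(igraph::V(g)$samples, ",",
                                         fixed = TRUE), vn)
  centers <- vn[deg >= min_branches]
  adj <- igraph::adjacent_vertices(g, vn)
  adj <- stats::setNames(lapply(adj, function(v) v$name), vn)
  adj_centers <- lapply(adj, intersect, centers)
  clusters <- lapply(centers, function(ctr) {
    visited <- ctr
    members_nodes <- ctr
    queue <- adj[[ctr]]
    while (length(queue)) {
      x <- queue[[1L]]
      queue <- queue[-1L]
      if (x %in% visited) next
      visited <- c(visited, x)
      if (x %in% centers) next                       # another radiation
      if (observed[[x]] && deg[[x]] > 2L) next       # sub-radiation start
      if (length(setdiff(adj_centers[[x]], ctr))) next  # borders another
      members_nodes <- c(members_nodes, x)           # medians keep paths intact
      queue <- c(queue, setdiff(adj[[x]], visited))
    }
    members <- unlist(samples_of[members_nodes], use.names = FALSE)
    members <- members[nzchar(members)]
    structure(list(center = ctr,
                   n_branches = as.integer(deg[[ctr]]),
                   members = members,
                   member_nodes = members_nodes,
                   haplogroup = NA_character_),
              class = "star_cluster")
  })
  names(clusters) <- centers
  clusters
}

#' @export
print.star_cluster <- function(x, ...) {
  cat(sprintf("Star cluster at %s: %d branches, %d samples%s\n",
              x$center, x$n_branches, length(x$members),
              if (is.na(x$haplogroup)) "" else paste0(" [", x$haplogroup,
                                                      "]")))
  invisible(x)
}

#' Label clusters with the majority haplogroup of their members
#'
#' @param clusters list of `star_cluster`s.
#' @param calls data.frame from [assign_haplogroups()].
#' @return the clusters, with `haplogroup` filled in.
#' @export
label_clusters <- function(clusters, calls) {
  lapply(clusters, function(cl) {
    hg <- calls$haplogroup[match(cl$members, calls$sample)]
    hg <- hg[!is.na(hg)]
    if (length(hg)) {
      tab <- sort(table(hg), decreasing = TRUE)
      cl$haplogroup <- names(tab)[1L]
    }
    cl
  })
}

#' Write a cluster report TSV
#'
#' @param clusters list of `star_cluster`s.
#' @param path output path.
#' @export
write_clusters <- function(clusters, path) {
  df <- data.frame(center = vapply(clusters, `[[`, "", "center"),
                   haplogroup = vapply(clusters, `[[`, "", "haplogroup"),
                   n = vapply(clusters, function(x) length(x$members), 0L),
                   branches = vapply(clusters, `[[`, 0L, "n_branches"),
                   members = vapply(clusters, function(x)
                     paste(x$members, collapse = ","), ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
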