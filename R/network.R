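# Median-joining networks of coding-region haplotypes.
#
# The algorithm follows the classic median-joining construction: compute
# the minimum spanning network (union of all minimum spanning trees, within
# an epsilon weight tolerance) over the current sequence set, add
# quasi-median vectors (per-site majority consensus) for triplets of
# mutually linked nodes, and iterate to convergence; finally prune median
# vectors that do not lie on any shortest connection between observed
# haplotypes.

#' Build a haplotype matrix from variant sets
#'
#' Restricts each sample's substitutions to the coding region, expresses
#' them over the union of polymorphic positions, drops monomorphic sites
#' and collapses identical haplotypes (multiplicity and sample lists are
#' retained). Positions masked as missing (N) in a sample are `NA` for that
#' sample only. Indels are excluded by default; with
#' `include_indels = TRUE` each distinct indel becomes a binary
#' presence/absence character.
#'
#' @param vsets named list of [variant_set]s.
#' @param region inclusive position bounds, default the coding region.
#' @param include_indels include indels as binary characters.
#' @return object of class `haplotype_matrix`: list with `mat` (character
#'   matrix, haplotypes x sites), `positions`, `ref` (per-site reference
#'   allele), `samples` (list), `multiplicity`.
#' @export
build_matrix <- function(vsets, region = CODING_REGION,
                         include_indels = FALSE) {
  if (length(vsets) == 0L) stop("no variant sets supplied")
  per_sample <- lapply(vsets, function(vs) {
    keep <- vs$position >= region[1L] & vs$position <= region[2L]
    v <- as.data.frame(vs)[keep, , drop = FALSE]
    if (!include_indels) v <- v[v$kind == "substitution", , drop = FALSE]
    v
  })
  allv <- do.call(rbind, per_sample)
  # site catalogue: substitutions keyed by position, indels by name
  sub_pos <- sort(unique(as.integer(allv$position[allv$kind == "substitution"])))
  indel_names <- sort(unique(allv$name[allv$kind != "substitution"]))
  sites <- c(as.character(sub_pos), indel_names)
  if (length(sites) == 0L) {
    mat <- matrix(character(0), nrow = 1L, ncol = 0L,
                  dimnames = list("H1", NULL))
    return(structure(list(mat = mat, positions = numeric(0),
                          ref = character(0),
                          samples = list(H1 = names(vsets)),
                          multiplicity = length(vsets)),
                     class = "haplotype_matrix"))
  }
  ref_allele <- character(length(sites))
  names(ref_allele) <- sites
  ref_allele[] <- "0"                      # indel absent state
  for (v in per_sample) {
    s <- v[v$kind == "substitution", , drop = FALSE]
    ref_allele[as.character(as.integer(s$position))] <- s$ref
  }
  mat <- matrix(rep(ref_allele, each = length(vsets)),
                nrow = length(vsets), ncol = length(sites),
                dimnames = list(names(vsets), sites))
  for (i in seq_along(vsets)) {
    v <- per_sample[[i]]
    s <- v[v$kind == "substitution", , drop = FALSE]
    if (nrow(s)) mat[i, as.character(as.integer(s$position))] <- s$alt
    if (include_indels) {
      idl <- v[v$kind != "substitution", , drop = FALSE]
      if (nrow(idl)) mat[i, idl$name] <- "1"
    }
    miss <- attr(vsets[[i]], "missing")
    miss <- miss[miss >= region[1L] & miss <= region[2L]]
    hit <- as.character(miss)[as.character(miss) %in% sites]
    if (length(hit)) mat[i, hit] <- NA
  }
  # drop monomorphic sites
  poly <- apply(mat, 2L, function(col) length(unique(col[!is.na(col)])) > 1L)
  mat <- mat[, poly, drop = FALSE]
  sites <- sites[poly]
  ref_allele <- ref_allele[poly]
  # collapse identical haplotypes (including missing pattern)
  key <- apply(mat, 1L, function(r) paste(ifelse(is.na(r), "?", r),
                                          collapse = ""))
  first <- !duplicated(key)
  groups <- split(names(vsets), match(key, key[first]))
  hm_mat <- mat[first, , drop = FALSE]
  hap_ids <- paste0("H", seq_len(nrow(hm_mat)))
  rownames(hm_mat) <- hap_ids
  samples <- stats::setNames(groups[as.character(seq_len(nrow(hm_mat)))],
                             hap_ids)
  structure(list(mat = hm_mat,
                 positions = suppressWarnings(as.numeric(sites)),
                 ref = unname(ref_allele),
                 samples = samples,
                 multiplicity = lengths(samples)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("Haplotype matrix:", nrow(x$mat), "haplotypes (",
      sum(x$multiplicity), "samples ) x", ncol(x$mat),
      "polymorphic sites\n")
  invisible(x)
}

#' Pairwise haplotype distances
#'
#' Hamming distances between character-state rows. Missing entries are
#' handled by pairwise deletion: distances are computed over mutually
#' non-missing sites and rescaled to the full site count (`scale =
#' "scaled"`, the default), or all sites containing any missing entry are
#' dropped for every pair (`scale = "complete"`).
#'
#' @param mat character matrix (rows = haplotypes), `NA` = missing.
#' @param scale missing-data policy.
#' @return symmetric numeric distance matrix.
#' @export
hap_distances <- function(mat, scale = c("scaled", "complete")) {
  scale <- match.arg(scale)
  n <- nrow(mat)
  if (ncol(mat) == 0L) return(matrix(0, n, n,
                                     dimnames = list(rownames(mat),
                                                     rownames(mat))))
  if (scale == "complete") {
    keep <- !apply(mat, 2L, anyNA)
    mat <- mat[, keep, drop = FALSE]
  }
  S <- ncol(mat)
  lv <- sort(unique(as.vector(mat[!is.na(mat)])))
  M <- matrix(match(mat, lv), nrow = n)
  M[is.na(M)] <- 0L
  matches <- matrix(0, n, n)
  for (a in seq_along(lv)) {
    X <- M == a
    matches <- matches + tcrossprod(X)
  }
  comparable <- tcrossprod(M > 0L)
  d <- comparable - matches
  if (scale == "scaled" && S > 0L) {
    zero <- comparable == 0L
    d <- d * S / pmax(comparable, 1L)
    d[zero] <- S
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

# Minimum spanning network edges within epsilon tolerance.
#
# An edge (u, v) belongs to the network iff d(u, v) <= sigma(u, v) +
# epsilon, where sigma(u, v) is the smallest threshold t at which u and v
# become connected using only edges of weight <= t. At epsilon = 0 this is
# the union of all minimum spanning trees.
msn_edges <- function(D, epsilon = 0, tol = 1e-9) {
  n <- nrow(D)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  sigma <- matrix(Inf, n, n)
  comp <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  iu <- which(upper.tri(D))
  w <- D[iu]
  ord <- order(w)
  levels_w <- unique(w[ord])
  ii <- ((iu - 1L) %% n) + 1L
  jj <- ((iu - 1L) %/% n) + 1L
  for (lev in levels_w) {
    at <- which(abs(w - lev) <= tol)
    for (k in at) {
      a <- comp[ii[k]]; b <- comp[jj[k]]
      if (a != b) {
        sigma[members[[a]], members[[b]]] <- lev
        sigma[members[[b]], members[[a]]] <- lev
        members[[a]] <- c(members[[a]], members[[b]])
        comp[members[[b]]] <- a
        members[[b]] <- integer(0)
      }
    }
  }
  keep <- which(w <= sigma[cbind(ii, jj)] + epsilon + tol)
  cbind(ii[keep], jj[keep])
}

# Quasi-median(s) of three state vectors: per-site majority; sites where no
# two votes agree expand over the distinct voted states (capped).
quasi_medians <- function(a, b, c, max_tie_sites = 2L) {
  safe_eq <- function(x, y) !is.na(x) & !is.na(y) & x == y
  med <- ifelse(safe_eq(b, c), b, ifelse(safe_eq(a, b) | safe_eq(a, c), a,
                                         NA))
  resolved <- safe_eq(b, c) | safe_eq(a, b) | safe_eq(a, c)
  open <- which(!resolved)
  if (length(open)) {
    # single-vote / no-vote sites take the only vote (or stay NA)
    for (s in open) {
      votes <- unique(stats::na.omit(c(a[s], b[s], c[s])))
      if (length(votes) <= 1L) {
        med[s] <- if (length(votes)) votes else NA
        resolved[s] <- TRUE
      }
    }
    open <- which(!resolved)
  }
  if (length(open) == 0L) return(list(med))
  if (length(open) > max_tie_sites) return(list())
  choices <- lapply(open, function(s) unique(stats::na.omit(c(a[s], b[s],
                                                              c[s]))))
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(g) {
    m <- med
    m[open] <- unlist(grid[g, ])
    m
  })
}

state_key <- function(row) paste(ifelse(is.na(row), "?", row), collapse = "\r")

# distances of the rows of m1 against the rows of m2 (same columns),
# with the same pairwise-deletion rescaling as hap_distances
cross_distances <- function(m1, m2, scale = "scaled") {
  S <- ncol(m1)
  if (S == 0L) return(matrix(0, nrow(m1), nrow(m2),
                             dimnames = list(rownames(m1), rownames(m2))))
  lv <- sort(unique(c(as.vector(m1[!is.na(m1)]), as.vector(m2[!is.na(m2)]))))
  M1 <- matrix(match(m1, lv), nrow = nrow(m1)); M1[is.na(M1)] <- 0L
  M2 <- matrix(match(m2, lv), nrow = nrow(m2)); M2[is.na(M2)] <- 0L
  matches <- matrix(0, nrow(m1), nrow(m2))
  for (a in seq_along(lv)) matches <- matches + (M1 == a) %*% t(M2 == a)
  comparable <- (M1 > 0L) %*% t(M2 > 0L)
  d <- comparable - matches
  if (scale == "scaled") {
    zero <- comparable == 0L
    d <- d * S / pmax(comparable, 1L)
    d[zero] <- S
  }
  dimnames(d) <- list(rownames(m1), rownames(m2))
  d
}

# strict mismatch count between two state vectors (mutually non-missing)
mismatch2 <- function(a, b) sum(!is.na(a) & !is.na(b) & a != b)

#' Median-joining network construction
#'
#' Iterates the classic construction to convergence: link the current
#' sequence set by its minimum spanning network, delete obsolete median
#' vectors (unsampled nodes with at most two links, whose connections are
#' equally served by a direct edge), and add the quasi-medians of linked
#' triplets whose connection cost is minimal (within `epsilon`). After
#' convergence, median vectors that do not lie on any shortest connection
#' between observed haplotypes are pruned.
#'
#' @param hm a `haplotype_matrix` from [build_matrix()].
#' @param epsilon weight tolerance of the spanning network and of the
#'   median connection-cost criterion (default 0).
#' @param max_iter iteration cap; exceeding it is an error with diagnostics.
#' @param max_tie_sites cap on fully tied sites when expanding quasi-median
#'   sets for a triplet.
#' @param scale missing-data policy for distances, as in [hap_distances()].
#' @return object of class `mj_graph`: list with `graph` (an igraph whose
#'   vertices carry `observed`, `samples`, `multiplicity` attributes and
#'   whose edges carry `sites` labels and `weight` = number of labelled
#'   sites), `states` (node-by-site character matrix), `positions`, `ref`,
#'   `samples`, `multiplicity`.
#' @export
median_joining <- function(hm, epsilon = 0, max_iter = 400L,
                           max_tie_sites = 2L,
                           scale = c("scaled", "complete")) {
  scale <- match.arg(scale)
  states <- hm$mat
  if (scale == "complete") {
    states <- states[, !apply(states, 2L, anyNA), drop = FALSE]
  }
  obs_names <- rownames(hm$mat)
  keys <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(states))) {
    assign(state_key(states[i, ]), TRUE, keys)
  }
  n_median <- 0L
  dead <- new.env(parent = emptyenv())   # deleted medians never return
  D <- hap_distances(states)
  add_rows <- function(add) {
    colnames(add) <- colnames(states)
    Dn <- cross_distances(add, states)
    Dnn <- cross_distances(add, add)
    diag(Dnn) <- 0
    D <<- rbind(cbind(D, t(Dn)), cbind(Dn, Dnn))
    states <<- rbind(states, add)
  }
  drop_rows <- function(drop) {
    for (nm in drop) {
      k <- state_key(states[nm, ])
      rm(list = k, envir = keys)
      assign(k, TRUE, dead)
    }
    keep <- !rownames(states) %in% drop
    states <<- states[keep, , drop = FALSE]
    D <<- D[keep, keep, drop = FALSE]
  }
  # delete unsampled nodes with <= 2 spanning-network links until stable;
  # returns the current edge set
  prune_obsolete <- function() {
    repeat {
      E <- msn_edges(D, epsilon)
      deg <- tabulate(c(E[, 1L], E[, 2L]), nbins = nrow(states))
      drop <- rownames(states)[deg <= 2L &
                                 !rownames(states) %in% obs_names]
      if (length(drop) == 0L) return(E)
      drop_rows(drop)
    }
  }
  tri_cache <- new.env(parent = emptyenv())
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      stop("median-joining did not converge after ", max_iter,
           " iterations (", nrow(states), " nodes, ", ncol(states),
           " sites)")
    }
    E <- prune_obsolete()
    if (nrow(states) < 3L || nrow(E) == 0L) break
    adj <- vector("list", nrow(states))
    for (k in seq_len(nrow(E))) {
      adj[[E[k, 1L]]] <- c(adj[[E[k, 1L]]], E[k, 2L])
      adj[[E[k, 2L]]] <- c(adj[[E[k, 2L]]], E[k, 1L])
    }
    nms <- rownames(states)
    cand <- new.env(parent = emptyenv())   # state key -> list(state, lambda)
    for (u in seq_len(nrow(states))) {
      nb <- sort(adj[[u]])
      if (length(nb) < 2L) next
      for (vi in seq_len(length(nb) - 1L)) {
        for (wi in seq(vi + 1L, length(nb))) {
          v <- nb[vi]; w <- nb[wi]
          tkey <- paste(sort(c(nms[u], nms[v], nms[w])), collapse = "\r")
          entry <- tri_cache[[tkey]]
          if (is.null(entry)) {
            meds <- quasi_medians(states[u, ], states[v, ], states[w, ],
                                  max_tie_sites)
            entry <- lapply(meds, function(m) {
              list(key = state_key(m), state = m,
                   lambda = mismatch2(m, states[u, ]) +
                     mismatch2(m, states[v, ]) + mismatch2(m, states[w, ]))
            })
            tri_cache[[tkey]] <- entry
          }
          for (cd in entry) {
            if (exists(cd$key, envir = keys, inherits = FALSE) ||
                exists(cd$key, envir = dead, inherits = FALSE)) next
            prev <- cand[[cd$key]]
            if (is.null(prev) || prev$lambda > cd$lambda) {
              cand[[cd$key]] <- cd
            }
          }
        }
      }
    }
    ckeys <- ls(cand)
    if (length(ckeys) == 0L) break
    lams <- vapply(ckeys, function(k) cand[[k]]$lambda, 0)
    sel <- ckeys[lams <= min(lams) + epsilon + 1e-9]
    sel <- sel[order(lams[sel], sel)]
    add <- do.call(rbind, lapply(sel, function(k) cand[[k]]$state))
    rownames(add) <- paste0("mv", n_median + seq_along(sel))
    n_median <- n_median + length(sel)
    for (k in sel) assign(k, TRUE, keys)
    add_rows(add)
  }
  # prune median vectors not on any observed-observed shortest connection
  repeat {
    E <- prune_obsolete()
    med <- setdiff(rownames(states), obs_names)
    if (length(med) == 0L) break
    g <- igraph::graph_from_edgelist(
      matrix(rownames(states)[E], ncol = 2L), directed = FALSE)
    missing_v <- setdiff(rownames(states), igraph::V(g)$name)
    if (length(missing_v)) g <- igraph::add_vertices(g, length(missing_v),
                                                     name = missing_v)
    igraph::E(g)$weight <- D[cbind(E[, 1L], E[, 2L])]
    gd <- igraph::distances(g, weights = igraph::E(g)$weight)
    dobs <- gd[obs_names, obs_names, drop = FALSE]
    drop <- character(0)
    for (m in med) {
      dm <- gd[m, obs_names]
      on_path <- any(abs(outer(dm, dm, "+") - dobs) < 1e-9 & dobs > 1e-9)
      if (!on_path) drop <- c(drop, m)
    }
    if (length(drop) == 0L) break
    drop_rows(drop)
  }
  E <- msn_edges(D, epsilon)
  enames <- matrix(rownames(states)[E], ncol = 2L)
  g <- igraph::graph_from_edgelist(enames, directed = FALSE)
  missing_v <- setdiff(rownames(states), igraph::V(g)$name)
  if (length(missing_v)) g <- igraph::add_vertices(g, length(missing_v),
                                                   name = missing_v)
  vn <- igraph::V(g)$name
  obs <- vn %in% rownames(hm$mat)
  igraph::V(g)$observed <- obs
  igraph::V(g)$samples <- vapply(vn, function(v) {
    if (v %in% names(hm$samples)) paste(hm$samples[[v]], collapse = ",")
    else ""
  }, "")
  igraph::V(g)$multiplicity <- ifelse(obs,
                                      hm$multiplicity[match(vn, names(hm$multiplicity))],
                                      0L)
  sites_lab <- character(nrow(E))
  wts <- numeric(nrow(E))
  site_names <- colnames(states)
  for (k in seq_len(nrow(E))) {
    x <- states[E[k, 1L], ]; y <- states[E[k, 2L], ]
    diff <- which(!is.na(x) & !is.na(y) & x != y)
    sites_lab[k] <- paste(site_names[diff], collapse = ",")
    wts[k] <- D[E[k, 1L], E[k, 2L]]
  }
  igraph::E(g)$sites <- sites_lab
  igraph::E(g)$weight <- wts
  structure(list(graph = g, states = states, positions = hm$positions,
                 ref = hm$ref, samples = hm$samples,
                 multiplicity = hm$multiplicity, epsilon = epsilon),
            class = "mj_graph")
}

#' @export
print.mj_graph <- function(x, ...) {
  obs <- sum(igraph::V(x$graph)$observed)
  cat("Median-joining network:", igraph::vcount(x$graph), "nodes (",
      obs, "observed,", igraph::vcount(x$graph) - obs, "median ),",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Export a network to GraphML and an edge-list TSV
#'
#' @param mjg an `mj_graph`.
#' @param graphml optional GraphML output path.
#' @param edges optional TSV output path (columns node1, node2, sites).
#' @export
write_network <- function(mjg, graphml = NULL, edges = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(mjg$graph, graphml, format = "graphml")
  }
  if (!is.null(edges)) {
    el <- igraph::as_edgelist(mjg$graph)
    utils::write.table(
      data.frame(node1 = el[, 1L], node2 = el[, 2L],
                 sites = igraph::E(mjg$graph)$sites,
                 stringsAsFactors = FALSE),
      edges, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(mjg)
}
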