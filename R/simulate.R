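# Seeded synthetic-data generation: genealogies with known TMRCA, Poisson
# mutation dropping, haplotypes from a definition tree, read pileups with
# known truth, and a full synthetic study preset that exercises the whole
# pipeline (consensus -> classification -> network -> dating) end to end.

#' Simulate a genealogy with branch lengths in years
#'
#' `"star"` genealogies have every tip hanging from the root by a branch of
#' length `tmrca`. Coalescent genealogies draw standard exponential waiting
#' times (rate `choose(k,2)/ne_years` while k lineages remain) under a
#' constant size, or under exponential growth (backward-in-time size
#' `ne_years * exp(-growth_rate * t)`); when `tmrca` is also given the tree
#' is rescaled so the root sits exactly at `tmrca` years.
#'
#' @param n_tips number of sampled lineages (>= 2).
#' @param kind `"star"`, `"coalescent-constant"` or `"coalescent-growth"`.
#' @param tmrca time to the most recent common ancestor in years.
#' @param ne_years coalescent time-scale parameter (effective size times
#'   generation time), in years.
#' @param growth_rate backward decline rate per year for the growth model.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return an `ape::phylo` tree with `edge.length` in years and attribute
#'   `tmrca`.
#' @export
simulate_genealogy <- function(n_tips,
                               kind = c("star", "coalescent-constant",
                                        "coalescent-growth"),
                               tmrca = NULL, ne_years = NULL,
                               growth_rate = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (n_tips < 2L) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tips <- sprintf("t%03d", seq_len(n_tips))
  if (kind == "star") {
    if (is.null(tmrca) || tmrca <= 0) stop("star genealogy needs tmrca > 0")
    edge <- cbind(rep(n_tips + 1L, n_tips), seq_len(n_tips))
    phy <- structure(list(edge = edge,
                          edge.length = rep(tmrca, n_tips),
                          tip.label = tips, Nnode = 1L),
                     class = "phylo", order = "cladewise")
    attr(phy, "tmrca") <- tmrca
    return(phy)
  }
  if (is.null(ne_years) || ne_years <= 0) {
    stop("coalescent genealogy needs ne_years > 0")
  }
  # draw coalescent event times (years before present)
  times <- numeric(n_tips - 1L)
  t_cur <- 0
  for (k in n_tips:2L) {
    rate0 <- choose(k, 2L) / ne_years
    if (kind == "coalescent-constant" || growth_rate == 0) {
      w <- stats::rexp(1L, rate0)
    } else {
      # inhomogeneous rate rate0 * exp(growth_rate * t) backward in time
      u <- stats::rexp(1L)
      w <- log(1 + growth_rate * u / (rate0 * exp(growth_rate * t_cur))) /
        growth_rate
    }
    t_cur <- t_cur + w
    times[n_tips - k + 1L] <- t_cur
  }
  # assemble topology by random pairwise merging; internal ids descend from
  # 2n-1 so the final (root) event lands on n_tips + 1, as ape requires
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)
  age <- numeric(n_nodes)
  active <- seq_len(n_tips)
  for (i in seq_len(n_tips - 1L)) {
    node <- 2L * n_tips - i
    pick <- sample(length(active), 2L)
    parent[active[pick]] <- node
    age[node] <- times[i]
    active <- c(active[-pick], node)
  }
  child <- setdiff(seq_len(n_nodes), n_tips + 1L)
  edge <- cbind(parent[child], child)
  elen <- age[parent[child]] - age[child]
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = tips, Nnode = n_tips - 1L),
                   class = "phylo", order = "cladewise")
  phy <- ape::reorder.phylo(phy, "cladewise")
  root_age <- times[n_tips - 1L]
  if (!is.null(tmrca)) {
    phy$edge.length <- phy$edge.length * tmrca / root_age
    root_age <- tmrca
  }
  attr(phy, "tmrca") <- root_age
  phy
}

#' Drop Poisson mutations on a genealogy
#'
#' Each edge receives a Poisson number of substitutions: under a linear
#' `rate` (mutations per genome per year), with mean `rate * edge-length`;
#' under a non-linear `clock`, with mean equal to the difference of the
#' clock's expected-substitution curve at the edge's endpoint ages. Mutated
#' sites are drawn uniformly over the genome and alleles uniformly over the
#' three alternatives to the lineage's current base; sites hit more than
#' once anywhere in the tree are logged as collisions
#' (infinite-alleles-approximate model).
#'
#' @param phy an `ape::phylo` with edge lengths in years (root age =
#'   `attr(phy, "tmrca")`).
#' @param rate mutations per genome per year (linear model).
#' @param clock alternatively a `clock_model` whose expected-substitution
#'   curve sets the per-edge means.
#' @param ref reference base vector.
#' @param founder optional [variant_set] carried by the root (e.g. a
#'   haplogroup's defining mutations); tip variant sets include it.
#' @param gamma_shape optional shape of a mean-one gamma distribution of
#'   relative site rates; `NULL` (the default) mutates all sites at the
#'   same rate. Rate heterogeneity is a stress-test option only.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return list with `vsets` (named list of tip [variant_set]s),
#'   `edge_mutations` (counts parallel to `phy$edge`), and `truth` (list:
#'   `tree`, `tmrca`, `founder`, `collisions`).
#' @export
drop_mutations <- function(phy, rate = NULL, clock = NULL, ref,
                           founder = NULL, gamma_shape = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rate) && is.null(clock)) stop("need rate or clock")
  ntip <- length(phy$tip.label)
  n_nodes <- max(phy$edge)
  tmrca <- attr(phy, "tmrca")
  # node ages (years before present)
  age <- numeric(n_nodes)
  age[ntip + 1L] <- tmrca
  ord <- rev(ape::postorder(phy))
  for (e in ord) {
    age[phy$edge[e, 2L]] <- age[phy$edge[e, 1L]] - phy$edge.length[e]
  }
  means <- if (!is.null(clock)) {
    expected_substitutions(clock, age[phy$edge[, 1L]]) -
      expected_substitutions(clock, age[phy$edge[, 2L]])
  } else {
    rate * phy$edge.length
  }
  if (any(means < -1e-8)) stop("negative expected mutation count on edge")
  m_e <- stats::rpois(length(means), pmax(means, 0))
  if (sum(m_e) > length(ref)) stop("more mutations than genome sites")
  L <- length(ref)
  founder_state <- character(0)
  if (!is.null(founder) && nrow(founder) > 0L) {
    fsub <- founder[founder$kind == "substitution", , drop = FALSE]
    founder_state <- stats::setNames(fsub$alt,
                                     as.character(as.integer(fsub$position)))
  }
  site_w <- if (is.null(gamma_shape)) NULL else
    stats::rgamma(L, shape = gamma_shape, rate = gamma_shape)
  used_sites <- integer(0)
  collisions <- integer(0)
  bases <- c("A", "C", "G", "T")
  state_of <- vector("list", n_nodes)
  state_of[[ntip + 1L]] <- founder_state
  for (e in ord) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    st <- state_of[[p]]
    if (m_e[e] > 0L) {
      pos <- sample.int(L, m_e[e], replace = TRUE, prob = site_w)
      for (ps in pos) {
        if (ps %in% used_sites) collisions <- c(collisions, ps)
        used_sites <- c(used_sites, ps)
        key <- as.character(ps)
        cur <- if (key %in% names(st)) st[[key]] else ref[ps]
        alt <- sample(setdiff(bases, cur), 1L)
        if (alt == ref[ps]) st <- st[names(st) != key] else st[key] <- alt
      }
    }
    state_of[[ch]] <- st
  }
  vsets <- lapply(seq_len(ntip), function(i) {
    st <- state_of[[i]]
    if (length(st) == 0L) {
      return(variant_set(data.frame(), sample_id = phy$tip.label[i]))
    }
    pos <- as.integer(names(st))
    variant_set(data.frame(position = as.numeric(pos), ref = ref[pos],
                           alt = unname(st), kind = "substitution",
                           stringsAsFactors = FALSE),
                sample_id = phy$tip.label[i])
  })
  names(vsets) <- phy$tip.label
  list(vsets = vsets, edge_mutations = m_e,
       truth = list(tree = phy, tmrca = tmrca, founder = founder,
                    collisions = unique(collisions)))
}

#' Generate haplotypes from a haplogroup tree
#'
#' Each sample carries the cumulative defining variants of its assigned
#' node plus Poisson-distributed private substitutions at non-defining
#' positions (alleles uniform over the three alternatives to the
#' reference).
#'
#' @param tree a `haplo_tree` (loaded with a reference).
#' @param assignments named character vector, sample id -> node name.
#' @param private_rate Poisson mean of private substitutions per sample.
#' @param private_counts optional named integer vector overriding the
#'   Poisson draw for specific samples.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return list with `vsets` (named list of [variant_set]s) and `truth`
#'   (list: `assignments`, `private_positions`).
#' @export
haplotypes_from_tree <- function(tree, assignments, private_rate = 0,
                                 private_counts = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unknown <- setdiff(unique(assignments), tree$nodes$name)
  if (length(unknown)) stop("node(s) not in tree: ",
                            paste(unknown, collapse = ", "))
  ref <- tree$ref
  if (is.null(ref)) stop("tree must carry a reference")
  defining <- unique(unlist(lapply(tree$mutations, `[[`, "position")))
  free_pos <- setdiff(seq_along(ref), defining)
  bases <- c("A", "C", "G", "T")
  priv_truth <- list()
  vsets <- lapply(names(assignments), function(sid) {
    base_vs <- expected_variants(tree, assignments[[sid]])
    k <- if (!is.null(private_counts) && sid %in% names(private_counts)) {
      private_counts[[sid]]
    } else stats::rpois(1L, private_rate)
    df <- as.data.frame(base_vs)
    if (k > 0L) {
      pos <- sample(free_pos, k)
      alt <- vapply(pos, function(p) sample(setdiff(bases, ref[p]), 1L), "")
      priv_truth[[sid]] <<- pos
      df <- rbind(df[, c("position", "ref", "alt", "kind")],
                  data.frame(position = as.numeric(pos), ref = ref[pos],
                             alt = alt, kind = "substitution",
                             stringsAsFactors = FALSE))
      df$name <- NULL
    } else {
      df <- df[, c("position", "ref", "alt", "kind")]
    }
    variant_set(df, sample_id = sid)
  })
  names(vsets) <- names(assignments)
  list(vsets = vsets,
       truth = list(assignments = assignments,
                    private_positions = priv_truth))
}

#' Simulate a read pileup for a haplotype
#'
#' Per-site depth is Poisson(`depth_mean`); each read reports the true base
#' with probability `1 - error_rate` and a uniform other base otherwise.
#' Deleted positions show `*` reads, and reads supporting a true insertion
#' carry a `+nSEQ` token. Uncovered positions (depth 0) are absent from the
#' pileup, as in real samtools output.
#'
#' @param truth a `consensus_seq` or [variant_set] (applied to `ref`).
#' @param ref reference base vector.
#' @param depth_mean mean coverage.
#' @param error_rate per-read error probability (< 0.5).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param chrom chromosome label in the output.
#' @return character vector of pileup lines.
#' @export
simulate_pileup <- function(truth, ref, depth_mean = 813, error_rate = 0.005,
                            seed = NULL, chrom = "MT") {
  if (!is.null(seed)) set.seed(seed)
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (inherits(truth, "variant_set")) truth <- apply_variants(truth, ref)
  bases <- truth$bases
  L <- length(ref)
  depth <- stats::rpois(L, depth_mean)
  lines <- character(0)
  bset <- c("A", "C", "G", "T")
  for (p in which(depth > 0L)) {
    tb <- bases[p]
    d <- depth[p]
    err <- stats::runif(d) < error_rate
    if (tb == "-") {
      reads <- rep("*", d)
      reads[err] <- sample(bset, sum(err), replace = TRUE)
    } else {
      truthb <- if (tb == "N") ref[p] else tb
      reads <- rep(truthb, d)
      if (any(err)) {
        reads[err] <- vapply(which(err), function(i) {
          sample(setdiff(bset, truthb), 1L)
        }, "")
      }
      reads <- ifelse(reads == ref[p], ".", reads)
    }
    ins <- truth$insertions[[as.character(p)]]
    if (!is.null(ins)) {
      supp <- stats::runif(d) >= error_rate
      reads[supp] <- paste0(reads[supp], "+", nchar(ins), ins)
    }
    lines <- c(lines, paste(chrom, p, ref[p], d,
                            paste(reads, collapse = ""), sep = "\t"))
  }
  lines
}
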