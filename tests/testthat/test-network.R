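test_that("haplotype matrices collapse and filter by region", {
  ref <- fixture_ref()
  alt <- function(p) setdiff(c("A", "C", "G", "T"), ref[p])[1L]
  vsets <- list(a = vs_of("a", 700, alt(700), ref),
                b = vs_of("b", 700, alt(700), ref),
                c = vs_of("c", 900, alt(900), ref))
  hm <- build_matrix(vsets)
  expect_equal(nrow(hm$mat), 2L)
  expect_equal(sort(hm$multiplicity, decreasing = TRUE)[[1L]], 2L)
  expect_setequal(unlist(hm$samples), c("a", "b", "c"))

  # variants outside the coding region vanish
  hm2 <- build_matrix(list(x = vs_of("x", 16311, alt(16311), ref),
                           y = vs_of("y", integer(0), character(0), ref)))
  expect_equal(ncol(hm2$mat), 0L)
  expect_equal(nrow(hm2$mat), 1L)

  expect_error(build_matrix(list()), "no variant sets")
})

test_that("pairwise distances handle missing data by rescaling", {
  m <- rbind(a = c("A", "A", "A", "A"),
             b = c("G", "A", "A", "A"),
             c = c(NA,  "G", "A", "A"))
  D <- hap_distances(m)
  expect_equal(D["a", "b"], 1)
  # c vs a: 1 mismatch over 3 comparable sites, rescaled to 4
  expect_equal(D["a", "c"], 4 / 3)
  # complete deletion drops the NA-bearing site for every pair
  Dc <- hap_distances(m, scale = "complete")
  expect_equal(Dc["a", "c"], 1)
  expect_equal(Dc["a", "b"], 0)
})

test_that("median joining reproduces chains and quasi-medians", {
  ref <- fixture_ref()
  galt <- function(p) setdiff(c("A", "C", "G", "T"), ref[p])[1L]
  p <- c(1001, 1002, 1003)
  a <- vapply(p, galt, "")
  # chain 000 - 100 - 110: no median vectors needed
  vs <- list(h1 = vs_of("h1", integer(0), character(0), ref),
             h2 = vs_of("h2", p[1L], a[1L], ref),
             h3 = vs_of("h3", p[1:2], a[1:2], ref))
  mjg <- median_joining(build_matrix(vs))
  expect_equal(igraph::vcount(mjg$graph), 3L)
  expect_equal(igraph::ecount(mjg$graph), 2L)
  expect_false(any(!igraph::V(mjg$graph)$observed))

  # {000, 110, 011}: the per-site majority vector 010 appears as a median
  vs <- list(h1 = vs_of("h1", integer(0), character(0), ref),
             h2 = vs_of("h2", p[1:2], a[1:2], ref),
             h3 = vs_of("h3", p[2:3], a[2:3], ref))
  mjg <- median_joining(build_matrix(vs))
  med <- mjg$states[!rownames(mjg$states) %in% paste0("H", 1:3), ,
                    drop = FALSE]
  expect_equal(nrow(med), 1L)
  expect_equal(unname(med[1L, ]), c(ref[p[1L]], a[2L], ref[p[3L]]))

  # determinism: identical input gives an identical graph
  mjg2 <- median_joining(build_matrix(vs))
  expect_identical(mjg$states, mjg2$states)
  expect_identical(igraph::as_edgelist(mjg$graph),
                   igraph::as_edgelist(mjg2$graph))
})

test_that("edge labels equal the Hamming difference of their endpoints", {
  ref <- fixture_ref()
  vsets <- random_instance(10, 8, ref, seed = 17L)
  mjg <- median_joining(build_matrix(vsets))
  el <- igraph::as_edgelist(mjg$graph)
  for (k in seq_len(nrow(el))) {
    x <- mjg$states[el[k, 1L], ]
    y <- mjg$states[el[k, 2L], ]
    dh <- sum(!is.na(x) & !is.na(y) & x != y)
    lab <- igraph::E(mjg$graph)$sites[k]
    nlab <- if (nzchar(lab)) length(strsplit(lab, ",")[[1L]]) else 0L
    expect_equal(nlab, dh)
    expect_equal(igraph::E(mjg$graph)$weight[k], dh)
  }
})

test_that("the network is a spanning supergraph of a minimum spanning tree", {
  ref <- fixture_ref()
  # random (reticulate) instances: the network contains every edge of an
  # independently constructed MST over its final node set, connects all
  # observed haplotypes, and never costs more than the observed-only MST
  for (seed in c(2L, 3L, 14L, 159L)) {
    vsets <- random_instance(12, 10, ref, seed = seed)
    hm <- build_matrix(vsets)
    mjg <- median_joining(hm)
    Df <- hap_distances(mjg$states)
    mst <- kruskal_mst(Df)
    el <- igraph::as_edgelist(mjg$graph)
    ekeys <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
    ids <- rownames(mjg$states)
    mkeys <- paste(pmin(ids[mst$edges[, 1L]], ids[mst$edges[, 2L]]),
                   pmax(ids[mst$edges[, 1L]], ids[mst$edges[, 2L]]))
    expect_true(all(mkeys %in% ekeys))
    comp <- igraph::components(mjg$graph)
    expect_equal(comp$no, 1L)
    expect_lte(mst$weight, kruskal_mst(hap_distances(hm$mat))$weight)
  }

  # tree-like data (the mtDNA regime): every MST link over the observed
  # haplotypes is realised as an equal-length path through the network
  for (seed in c(5L, 11L)) {
    phy <- simulate_genealogy(12L, "coalescent-constant", ne_years = 9000,
                              seed = seed)
    sim <- drop_mutations(phy, rate = 8e-4, ref = ref, seed = seed + 50L)
    vsets <- sim$vsets[vapply(sim$vsets, nrow, 0L) >= 0L]
    hm <- build_matrix(vsets)
    mjg <- median_joining(hm)
    D <- hap_distances(hm$mat)
    mst <- kruskal_mst(D)
    gd <- igraph::distances(mjg$graph,
                            weights = igraph::E(mjg$graph)$weight)
    ids <- rownames(hm$mat)
    for (k in seq_len(nrow(mst$edges))) {
      expect_equal(unname(gd[ids[mst$edges[k, 1L]], ids[mst$edges[k, 2L]]]),
                   unname(D[mst$edges[k, 1L], mst$edges[k, 2L]]))
    }
  }
})

test_that("star clusters honour the five-branch boundary", {
  ref <- fixture_ref()
  galt <- function(p) setdiff(c("A", "C", "G", "T"), ref[p])[1L]
  star_vs <- function(n) {
    pos <- 1000 + seq_len(n)
    out <- lapply(seq_len(n), function(i)
      vs_of(paste0("t", i), pos[i], galt(pos[i]), ref))
    c(stats::setNames(out, paste0("t", seq_len(n))),
      list(ctr = vs_of("ctr", integer(0), character(0), ref)))
  }
  cl5 <- detect_star_clusters(median_joining(build_matrix(star_vs(5L))))
  expect_length(cl5, 1L)
  expect_equal(cl5[[1L]]$n_branches, 5L)
  expect_setequal(cl5[[1L]]$members, c(paste0("t", 1:5), "ctr"))
  cl4 <- detect_star_clusters(median_joining(build_matrix(star_vs(4L))))
  expect_length(cl4, 0L)
})

test_that("a simulated star embedded in background is recovered", {
  set.seed(202L)
  ref <- simulate_reference()
  tr <- load_haplotree(system.file("extdata", "haplotree_synthetic.tsv",
                                   package = "mtlineage"), ref = ref)
  clock <- default_clocks()$complete
  phy <- simulate_genealogy(40L, "star", tmrca = 15000)
  phy$tip.label <- paste0("star_", phy$tip.label)
  star <- drop_mutations(phy, clock = clock, ref = ref,
                         founder = expected_variants(tr, "N9a"))
  bg_nodes <- c("C", "Z", "M8", "U", "HV", "R9")
  bg <- list()
  for (nd in bg_nodes) {
    ids <- paste0(nd, "_", 1:4)
    cnt <- stats::setNames(c(0L, 1L + stats::rpois(3L, 1)), ids)
    bg <- c(bg, haplotypes_from_tree(tr, stats::setNames(rep(nd, 4L), ids),
                                     private_counts = cnt)$vsets)
  }
  vsets <- c(star$vsets, bg)
  mjg <- median_joining(build_matrix(vsets))
  cls <- detect_star_clusters(mjg)
  expect_length(cls, 1L)
  members <- cls[[1L]]$members
  truth <- names(star$vsets)
  correct <- length(intersect(members, truth)) /
    length(union(members, truth))
  expect_gte(correct, 0.95)
})
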