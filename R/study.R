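# A packaged synthetic study: 367 complete mtDNA genomes from four East
# Asian population samples, carrying fifteen star-like expansions with
# known founder ages, against a background of small non-expanding
# haplogroup groups. The generator draws each expansion as a star
# genealogy from its haplogroup founder with Poisson mutations under the
# complete-genome clock, so the network/dating stages can be validated
# against known truth at realistic scale.

study_fixture <- function(name) {
  system.file("extdata", name, package = "mtlineage")
}

#' Simulate the packaged synthetic study
#'
#' Generates 367 samples: fifteen star-like expansions (sizes and founder
#' ages from the packaged expansion preset) whose tips carry the founding
#' haplogroup's defining variants plus Poisson private substitutions drawn
#' under `clock`, and 22 background groups of 3-4 samples each (one sample
#' on the group's founder haplotype, the rest with one or more private
#' substitutions at non-defining positions). Population labels (CHB, CHD,
#' CHS, JPT with sizes 121/73/55/118) are assigned cyclically within
#' groups.
#'
#' @param seed integer seed controlling every random draw.
#' @param clock `clock_model` generating (and later dating) the expansion
#'   mutations.
#' @param tree_path,expansion_path,background_path fixture overrides.
#' @return list with `ref`, `tree` (a `haplo_tree`), `vsets` (367 named
#'   [variant_set]s), `populations` (named character), and `truth` (list:
#'   `expansions` data.frame with haplogroup, n, tmrca_years; `membership`
#'   named sample -> haplogroup or `NA` for background).
#' @export
simulate_study <- function(seed = 1L,
                           clock = default_clocks()$complete,
                           tree_path = study_fixture("haplotree_synthetic.tsv"),
                           expansion_path = study_fixture("expansion_preset.tsv"),
                           background_path = study_fixture("background_preset.tsv")) {
  set.seed(seed)
  ref <- simulate_reference()
  tree <- load_haplotree(tree_path, ref = ref)
  expn <- utils::read.table(expansion_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
  bg <- utils::read.table(background_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  vsets <- list()
  membership <- character(0)
  for (i in seq_len(nrow(expn))) {
    hg <- expn$haplogroup[i]
    n <- expn$n[i]
    t_years <- expn$tmrca_ky[i] * 1000
    founder <- expected_variants(tree, hg)
    phy <- simulate_genealogy(n, "star", tmrca = t_years)
    phy$tip.label <- sprintf("%s_%02d", gsub("'", "p", hg), seq_len(n))
    sim <- drop_mutations(phy, clock = clock, ref = ref, founder = founder)
    vsets <- c(vsets, sim$vsets)
    membership[names(sim$vsets)] <- hg
  }
  for (i in seq_len(nrow(bg))) {
    nd <- bg$node[i]
    sz <- bg$size[i]
    ids <- sprintf("%s_bg%02d", gsub("'", "p", nd), seq_len(sz))
    counts <- stats::setNames(c(0L, 1L + stats::rpois(sz - 1L, 1)), ids)
    hp <- haplotypes_from_tree(tree,
                               stats::setNames(rep(nd, sz), ids),
                               private_counts = counts)
    vsets <- c(vsets, hp$vsets)
    membership[ids] <- NA_character_
  }
  pops <- rep(c("CHB", "CHD", "CHS", "JPT"),
              times = c(121L, 73L, 55L, 118L))
  populations <- stats::setNames(pops[seq_along(vsets)], names(vsets))
  list(ref = ref, tree = tree, vsets = vsets, populations = populations,
       truth = list(expansions = data.frame(haplogroup = expn$haplogroup,
                                            n = expn$n,
                                            tmrca_years = expn$tmrca_ky * 1000,
                                            stringsAsFactors = FALSE),
                    membership = membership))
}

#' Run the analysis chain on a set of variant haplotypes
#'
#' Convenience wrapper over the classification, network, cluster-detection
#' and dating stages, as used on the synthetic study and by the pipeline
#' runner.
#'
#' @param vsets named list of full-genome [variant_set]s.
#' @param tree a `haplo_tree`.
#' @param ref reference base vector.
#' @param populations named population labels per sample (optional).
#' @param clocks named list of `clock_model`s.
#' @param region coding-region bounds for the network.
#' @param epsilon spanning-network tolerance.
#' @param min_branches star-cluster branch threshold.
#' @param annotation gene table for the synonymous clock.
#' @return list with `calls`, `freq` (or `NULL` without populations),
#'   `network` (`mj_graph`), `clusters` (labelled), `ages` (data.frame).
#' @export
analyze_haplotypes <- function(vsets, tree, ref, populations = NULL,
                               clocks = default_clocks(),
                               region = CODING_REGION, epsilon = 0,
                               min_branches = 5L, annotation = NULL) {
  calls <- assign_haplogroups(vsets, tree)
  freq <- if (!is.null(populations)) {
    frequency_table(calls, populations)
  }
  hm <- build_matrix(vsets, region = region)
  mjg <- median_joining(hm, epsilon = epsilon)
  clusters <- detect_star_clusters(mjg, min_branches = min_branches)
  clusters <- label_clusters(clusters, calls)
  ages <- if (length(clusters)) {
    estimate_ages(clusters, mjg, vsets, clocks = clocks, ref = ref,
                  annotation = annotation)
  } else {
    data.frame()
  }
  list(calls = calls, freq = freq, network = mjg, clusters = clusters,
       ages = ages)
}
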