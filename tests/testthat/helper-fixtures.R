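# Shared fixtures and independent oracles, built in code.

fixture_ref <- function(seed = 424242L) simulate_reference(seed)

# toy haplogroup tree with explicit alleles and one back-mutation
toy_tree_df <- function() {
  data.frame(
    name = c("root", "X", "X1", "X2", "Y"),
    parent = c("-", "root", "X", "X", "root"),
    mutations = c("-", "1000G,2000T", "3000A", "4000C,1000A!", "5000G"),
    macro = c("N", "M", "", "", "N"),
    stringsAsFactors = FALSE)
}

toy_tree <- function(ref = NULL) {
  if (is.null(ref)) {
    ref <- rep("C", 16569)
    ref[c(1000, 2000, 3000, 4000, 5000)] <- c("A", "C", "C", "T", "A")
  }
  load_haplotree(toy_tree_df(), ref = ref)
}

# variant set from position -> alt pairs against a reference
vs_of <- function(id, pos, alt, ref, missing = integer(0)) {
  if (length(pos) == 0L) {
    return(variant_set(data.frame(), sample_id = id, missing = missing))
  }
  variant_set(data.frame(position = as.numeric(pos), ref = ref[pos],
                         alt = alt, kind = "substitution",
                         stringsAsFactors = FALSE),
              sample_id = id, missing = missing)
}

# independent Kruskal MST oracle (returns edge list and total weight)
kruskal_mst <- function(D) {
  n <- nrow(D)
  comp <- seq_len(n)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  pairs <- pairs[order(D[upper.tri(D)]), , drop = FALSE]
  edges <- matrix(0L, 0L, 2L)
  for (k in seq_len(nrow(pairs))) {
    a <- comp[pairs[k, 1L]]; b <- comp[pairs[k, 2L]]
    if (a != b) {
      comp[comp == b] <- a
      edges <- rbind(edges, pairs[k, , drop = FALSE])
    }
  }
  list(edges = edges, weight = sum(D[edges]))
}

# random haplotype variant sets over binary states at given coding sites
random_instance <- function(n_hap, n_sites, ref, seed) {
  set.seed(seed)
  pos <- sort(sample(seq(600, 16000), n_sites))
  states <- matrix(sample(c(TRUE, FALSE), n_hap * n_sites, replace = TRUE),
                   n_hap, n_sites)
  states[1L, ] <- FALSE
  vsets <- lapply(seq_len(n_hap), function(i) {
    p <- pos[states[i, ]]
    vs_of(sprintf("r%02d", i), p,
          vapply(p, function(q) setdiff(c("A", "C", "G", "T"), ref[q])[1L],
                 ""), ref)
  })
  names(vsets) <- vapply(vsets, attr, "", "sample_id")
  vsets
}
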