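test_that("haplotree loading validates structure", {
  tr <- toy_tree()
  expect_s3_class(tr, "haplo_tree")
  expect_equal(nrow(tr$nodes), 5L)
  expect_equal(tr$root, "root")
  expect_equal(tr$nodes$macro[tr$nodes$name == "X1"], "M")  # inherited

  bad <- toy_tree_df(); bad$parent[2L] <- "X"   # X its own parent
  expect_error(load_haplotree(bad), "own parent")
  bad <- toy_tree_df(); bad$name[5L] <- "X"
  expect_error(load_haplotree(bad), "duplicate")
  bad <- toy_tree_df(); bad$parent[5L] <- "ZZZ"
  expect_error(load_haplotree(bad), "orphan")
  bad <- toy_tree_df(); bad$parent[2L] <- "X1"  # root -> X -> X1 -> X cycle
  expect_error(load_haplotree(bad), "cycle")
  bad <- toy_tree_df(); bad$mutations[3L] <- "-"
  expect_error(load_haplotree(bad), "empty defining")
})

test_that("unstable positions are excluded", {
  ref <- fixture_ref()
  vs <- variant_set(data.frame(
    position = c(16519, 8701, 309.1, 16182),
    ref = c(ref[16519], ref[8701], "-", ref[16182]),
    alt = c("C", "G", "C", "C"),
    kind = c("substitution", "substitution", "insertion", "substitution"),
    stringsAsFactors = FALSE), sample_id = "ex")
  out <- exclude_unstable_positions(vs)
  expect_equal(out$name, "8701G")
  # an allele descriptor only matches the named substitution
  vs2 <- vs_of("x", 16182, setdiff(c("A", "C", "G", "T"),
                                   c(ref[16182], "C"))[1L], ref)
  expect_equal(nrow(exclude_unstable_positions(vs2)), 1L)
})

test_that("assignment recovers defining nodes, ties and back-mutations", {
  tr <- toy_tree()
  ref <- tr$ref
  # exactly the cumulative defining set of X1
  vs <- vs_of("s", c(1000, 2000, 3000), c("G", "T", "A"), ref)
  call <- assign_haplogroup(vs, tr)
  expect_equal(call$haplogroup, "X1")
  expect_length(call$missing, 0L)
  expect_length(call$extra, 0L)

  # empty variant set -> root
  expect_equal(assign_haplogroup(vs_of("e", integer(0), character(0), ref),
                                 tr)$haplogroup, "root")

  # back-mutation: X2 requires 4000C and the reference state at 1000
  vs <- vs_of("b", c(2000, 4000), c("T", "C"), ref)
  expect_equal(assign_haplogroup(vs, tr)$haplogroup, "X2")
  # carrying the derived 1000G forfeits the back-mutated branch
  vs <- vs_of("b2", c(1000, 2000, 4000), c("G", "T", "C"), ref)
  expect_equal(assign_haplogroup(vs, tr)$haplogroup, "X")

  # N-masked positions count as neither matched nor missing
  vs <- vs_of("m", 2000, "T", ref, missing = 1000L)
  expect_equal(assign_haplogroup(vs, tr)$haplogroup, "X")

  # invariant to variant order and to excluded-position noise
  vs1 <- vs_of("o1", c(3000, 1000, 2000), c("A", "G", "T"), ref)
  vs2 <- vs_of("o2", c(1000, 2000, 3000, 16519), c("G", "T", "A", "C"), ref)
  expect_equal(assign_haplogroup(vs1, tr)$haplogroup,
               assign_haplogroup(vs2, tr)$haplogroup)
})

test_that("tree-generated haplotypes are assigned to their nodes", {
  ref <- fixture_ref()
  tr <- load_haplotree(system.file("extdata", "haplotree_synthetic.tsv",
                                   package = "mtlineage"), ref = ref)
  nodes <- sample(tr$nodes$name, 200, replace = TRUE)
  names(nodes) <- sprintf("g%03d", seq_along(nodes))
  hp <- haplotypes_from_tree(tr, nodes, private_rate = 3, seed = 61L)
  calls <- assign_haplogroups(hp$vsets, tr)
  hit <- mean(calls$haplogroup == nodes[calls$sample])
  expect_gte(hit, 0.99)
  # noise-free haplotypes recover the generating node with certainty
  hp0 <- haplotypes_from_tree(tr, nodes, private_rate = 0)
  calls0 <- assign_haplogroups(hp0$vsets, tr)
  expect_true(all(calls0$haplogroup == nodes[calls0$sample]))
})

test_that("macro fractions match direct counting", {
  tr <- toy_tree()
  expect_equal(unname(macro_fraction(c("X", "X1", "X2"), tr)[["M"]]), 100)
  set.seed(8)
  hg <- sample(tr$nodes$name, 500, replace = TRUE)
  mf <- macro_fraction(hg, tr)
  direct <- table(ifelse(startsWith(hg, "X"), "M", "N"))
  expect_equal(unname(mf[["M"]]), unname(round(100 * direct[["M"]] / 500, 1)))
  expect_lte(abs(sum(mf) - 100), 0.2)
  expect_error(macro_fraction("nope", tr), "not in tree")
})

test_that("frequency tables are Table-1 shaped and validated", {
  ft <- frequency_table(c("B4", "B4", "D4"), rep("POP", 3L))
  expect_equal(unname(ft["B4", "POP"]), 66.7)
  expect_equal(unname(ft["D4", "POP"]), 33.3)
  expect_equal(attr(ft, "n")[["Total"]], 3L)
  expect_error(frequency_table(character(0), character(0)), "no haplogroup")
  expect_error(frequency_table(c("A", "B"), c("P1", NA)), "population")

  # reconstructed study counts reproduce their own percentages exactly
  counts <- utils::read.table(
    system.file("extdata", "east_asian_haplogroup_counts.tsv",
                package = "mtlineage"),
    header = TRUE, sep = "\t", check.names = FALSE)
  hg <- rep(rep(counts$haplogroup, ncol(counts) - 1L),
            times = unlist(counts[, -1L]))
  pop <- rep(rep(colnames(counts)[-1L], each = nrow(counts)),
             times = unlist(counts[, -1L]))
  ft <- frequency_table(hg, pop)
  expect_equal(unname(attr(ft, "n")),
               c(121L, 73L, 55L, 118L, 367L))
  expect_equal(unname(ft["D4", "JPT"]), 33.1)
  expect_equal(unname(ft["D4", "Total"]), 19.1)
  expect_equal(unname(ft["F", "CHB"]), 17.4)
  # every population column sums to 100 within rounding tolerance
  expect_true(all(abs(colSums(ft) - 100) < 0.5))
})
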