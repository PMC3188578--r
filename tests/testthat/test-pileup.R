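test_that("pileup parsing decodes read-base strings", {
  pu <- parse_pileup(lines = "MT\t100\tG\t8\taaaaaaa.")
  expect_equal(pu$position, 100L)
  expect_equal(pu$depth, 8L)
  expect_equal(pu$counts[[1L]], c(A = 7L, G = 1L))

  expect_length(parse_pileup(lines = character(0))$position, 0L)

  # hand-decoded: "." = C ref, "+1T" insertion riding on the first read,
  # "g" = G, "," = C ref => C:2 G:1 +T:1, depth 3 (insertion not in depth)
  pu <- parse_pileup(lines = "MT\t102\tC\t3\t.+1Tg,")
  expect_equal(sort(names(pu$counts[[1L]])), c("+T", "C", "G"))
  expect_equal(pu$counts[[1L]][["+T"]], 1L)
  expect_equal(pu$counts[[1L]][["C"]], 2L)
  expect_equal(pu$depth, 3L)

  # read start/end markers and deletion stars
  pu <- parse_pileup(lines = "MT\t5\tA\t4\t^I..$*,")
  expect_equal(pu$counts[[1L]][["A"]], 3L)
  expect_equal(pu$counts[[1L]][["-"]], 1L)

  expect_error(parse_pileup(lines = "MT\t7\tA"), "line 1")
  expect_error(parse_pileup(lines = "MT\txx\tA\t1\t."), "line 1")
  expect_warning(parse_pileup(lines = c("MT\t1\tA\t1\t.",
                                        "chr1\t9\tA\t1\t."),
                              chrom = "MT"), "chr1")
})

test_that("call_base applies the 2x / three-quarters rule", {
  expect_equal(call_base(c(A = 7L, G = 1L)), "A")
  expect_equal(call_base(c(A = 1L)), "N")            # below 2x: missing
  expect_equal(call_base(c(A = 2L, G = 2L)), "N")    # heterozygous-looking
  expect_equal(call_base(c(A = 3L, G = 1L)), "A")    # exactly 3/4 accepted
  expect_equal(call_base(c(A = 5L, G = 3L)), "N")    # 5/8 < 3/4
  expect_equal(call_base(integer(0)), "N")           # zero depth
  expect_equal(call_base(c(G = 2L)), "G")            # reference-like call
  # permutation invariance of the counts map
  expect_equal(call_base(c(G = 1L, A = 7L)), call_base(c(A = 7L, G = 1L)))
  # the rule applies to deletion alleles too
  expect_equal(call_base(c(`-` = 6L, A = 1L)), "-")
})

test_that("consensus assembly and variant extraction round-trip", {
  ref <- fixture_ref()
  # no coverage anywhere -> all ambiguous
  cons0 <- assemble_consensus(parse_pileup(lines = character(0)), ref, "s0")
  expect_equal(cons0$n_ambiguous, MT_LENGTH)
  expect_true(all(cons0$bases == "N"))
  expect_equal(nrow(variants_vs_reference(cons0, ref)), 0L)

  expect_error(assemble_consensus(
    parse_pileup(lines = c("MT\t10\tA\t2\t..", "MT\t10\tA\t2\t..")),
    ref, "dup"), "duplicate")
  expect_error(assemble_consensus(
    parse_pileup(lines = "MT\t16570\tA\t2\t.."), ref, "oob"), "outside")

  # identity: sites equal to reference at 2x or more reproduce the reference
  lines <- sprintf("MT\t%d\t%s\t3\t...", 1:50, ref[1:50])
  cons <- assemble_consensus(parse_pileup(lines = lines), ref, "id")
  expect_equal(cons$bases[1:50], ref[1:50])
  expect_equal(nrow(variants_vs_reference(cons, ref)), 0L)

  # insertion naming uses the decimal suffix convention
  cons$insertions[["309"]] <- "C"
  vs <- variants_vs_reference(cons, ref)
  expect_equal(vs$name[vs$kind == "insertion"], "309.1C")

  # deletion per position, substitution naming
  cons$bases[249] <- "-"
  alt <- setdiff(c("A", "C", "G", "T"), ref[8701])[1L]
  cons$bases[8701] <- alt
  vs <- variants_vs_reference(cons, ref)
  expect_true(paste0("249d") %in% vs$name)
  expect_true(paste0("8701", alt) %in% vs$name)
})

test_that("apply_variants inverts variants_vs_reference", {
  ref <- fixture_ref()
  set.seed(99)
  for (rep in 1:8) {
    bases <- ref
    subs <- sample(MT_LENGTH, 12)
    for (p in subs) bases[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ref[p]), 1L)
    dels <- sample(setdiff(seq_len(MT_LENGTH), subs), 3)
    bases[dels] <- "-"
    nmiss <- sample(setdiff(seq_len(MT_LENGTH), c(subs, dels)), 5)
    bases[nmiss] <- "N"
    ins <- list()
    anchor <- sample(setdiff(seq_len(MT_LENGTH - 1L), c(dels, nmiss)), 2)
    for (a in anchor) ins[[as.character(a)]] <-
      paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
            collapse = "")
    cons <- structure(list(sample_id = paste0("rt", rep), bases = bases,
                           insertions = ins, n_ambiguous = length(nmiss),
                           mean_depth = NA_real_), class = "consensus_seq")
    back <- apply_variants(variants_vs_reference(cons, ref), ref)
    expect_identical(back$bases, cons$bases)
    expect_identical(back$insertions[order(names(back$insertions))],
                     cons$insertions[order(names(cons$insertions))])
  }
})

test_that("variant tables survive a write/read cycle", {
  ref <- fixture_ref()
  vsets <- list(
    a = vs_of("a", c(700, 8000), c("A", "T"), ref, missing = c(5L, 9L)),
    b = vs_of("b", integer(0), character(0), ref))
  vsets$a$alt <- vapply(seq_len(nrow(vsets$a)), function(i)
    setdiff(c("A", "C", "G", "T"), vsets$a$ref[i])[1L], "")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(vsets, path)
  back <- read_variants(path)
  expect_equal(names(back), c("a", "b"))
  expect_equal(as.data.frame(back$a)$position, c(700, 8000))
  expect_equal(attr(back$a, "missing"), c(5L, 9L))
  expect_equal(nrow(back$b), 0L)
})

test_that("simulated pileups recover the generating haplotype", {
  ref <- fixture_ref()
  alt <- function(p) setdiff(c("A", "C", "G", "T"), ref[p])[1L]
  pos <- c(1500, 4000, 9500, 16100)
  vs <- vs_of("truth", pos, vapply(pos, alt, ""), ref)
  lines <- simulate_pileup(vs, ref, depth_mean = 30, error_rate = 0.005,
                           seed = 31L)
  cons <- assemble_consensus(parse_pileup(lines = lines), ref, "truth")
  got <- variants_vs_reference(cons, ref)
  expect_equal(got$name, vs$name)
  expect_lt(cons$n_ambiguous, 5L)
})

test_that("miscall rate stays within the binomial tail bound", {
  ref <- fixture_ref()
  vs <- vs_of("clean", integer(0), character(0), ref)
  eps <- 0.1
  lines <- simulate_pileup(vs, ref, depth_mean = 10, error_rate = eps,
                           seed = 77L)
  cons <- assemble_consensus(parse_pileup(lines = lines), ref, "clean")
  called <- cons$bases != "N"
  expect_gt(sum(called), 1e4)
  miscall <- mean(cons$bases[called] != ref[called])
  # P(errors >= 3/4 of depth) mixed over the Poisson depth distribution,
  # conditioned on depth >= 2 (callable sites)
  ds <- 2:60
  tail_d <- vapply(ds, function(d)
    stats::pbinom(ceiling(0.75 * d) - 1L, d, eps, lower.tail = FALSE), 0)
  wts <- stats::dpois(ds, 10) / sum(stats::dpois(ds, 10))
  bound <- sum(wts * tail_d)
  expect_lte(miscall, 3 * bound)
})

test_that("ambiguity decreases (weakly) with coverage", {
  ref <- fixture_ref()
  vs <- vs_of("depths", integer(0), character(0), ref)
  amb <- vapply(c(1, 3, 8, 30), function(dm) {
    lines <- simulate_pileup(vs, ref, depth_mean = dm, error_rate = 0.005,
                             seed = 500L + dm)
    assemble_consensus(parse_pileup(lines = lines), ref, "d")$n_ambiguous
  }, 0)
  expect_true(all(diff(amb) <= 0))
  expect_gt(amb[1L], 1000)   # depth ~1 leaves many missing sites
  expect_lt(amb[4L], 10)
})
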