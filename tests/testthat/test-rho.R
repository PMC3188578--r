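test_that("rho equals the mean founder-to-tip distance", {
  expect_equal(rho(star_genealogy(c(1, 1, 1, 1))), 1)
  expect_equal(rho(star_genealogy(c(0, 1, 1, 2))), 1)
  # branch-sum formula agrees with the direct tip mean on random trees
  for (seed in c(5L, 21L)) {
    phy <- simulate_genealogy(12L, "coalescent-constant", ne_years = 8000,
                              seed = seed)
    sim <- drop_mutations(phy, rate = 5e-4, ref = fixture_ref(),
                          seed = seed + 1L)
    g <- as_cluster_genealogy(phy, sim$edge_mutations)
    expect_equal(rho(g), mean(g$tip_distances))
    expect_equal(sum(g$edges$n_b * g$edges$m_b), sum(g$tip_distances))
  }
})

test_that("Saillard sigma matches closed forms", {
  # star, four branches of one mutation: sigma = sqrt(4 * (1/4)^2) = 1/2
  expect_equal(saillard_sigma(star_genealogy(c(1, 1, 1, 1))), 0.5)
  # stars satisfy sigma^2 = rho / n exactly
  set.seed(40)
  for (i in 1:5) {
    d <- stats::rpois(sample(5:50, 1L), 4)
    g <- star_genealogy(d)
    expect_equal(saillard_sigma(g)^2, rho(g) / g$n)
  }
  # hand-evaluated non-star: internal branch m=2 over 2 of 3 tips, two tip
  # branches m=1, one m=0: sigma = sqrt(8/9 + 2/9)
  g <- structure(list(n = 3L,
                      edges = data.frame(n_b = c(2L, 1L, 1L, 1L),
                                         m_b = c(2, 1, 1, 0)),
                      tip_distances = c(3, 3, 0), center = "root"),
                 class = "cluster_genealogy")
  expect_equal(saillard_sigma(g), sqrt(10 / 9))
  expect_equal(rho(g), 2)
})

test_that("sigma_rho predicts the Monte-Carlo spread of rho", {
  # fixed topology; 10^4 Poisson replicates of the branch mutation counts
  phy <- simulate_genealogy(15L, "coalescent-constant", ne_years = 10000,
                            seed = 7L)
  g0 <- as_cluster_genealogy(phy, rep(0L, nrow(phy$edge)))
  nb <- g0$edges$n_b[seq_len(nrow(phy$edge))]
  lens <- phy$edge.length
  rate <- 4e-4
  set.seed(71)
  reps <- 1e4L
  m <- matrix(stats::rpois(reps * length(lens), rep(rate * lens, reps)),
              nrow = length(lens))
  n <- length(phy$tip.label)
  rhos <- colSums(m * nb) / n
  sigmas <- sqrt(colSums(m * (nb / n)^2))
  expect_lt(abs(stats::sd(rhos) / mean(sigmas) - 1), 0.05)
})

test_that("clock models convert rho to years", {
  lin <- clock_model("lin", "linear", years_per_mutation = 1000)
  est <- rho_to_time(2, 0.5, lin)
  expect_equal(est$t_years, 2000)
  expect_equal(est$sigma_t_years, 500)
  expect_equal(rho_to_time(0, 0, lin)$t_years, 0)
  # doubling the calibration doubles T and sigma exactly
  lin2 <- clock_model("lin2", "linear", years_per_mutation = 2000)
  est2 <- rho_to_time(2, 0.5, lin2)
  expect_equal(est2$t_years, 2 * est$t_years)
  expect_equal(est2$sigma_t_years, 2 * est$sigma_t_years)

  cc <- default_clocks()$complete
  est <- rho_to_time(7, 0.4, cc)
  # the inversion is consistent with the forward curve
  expect_equal(expected_substitutions(cc, est$t_years), 7, tolerance = 1e-6)
  deriv <- cc$mu_neutral + cc$mu_transient * exp(-est$t_years / cc$tau)
  expect_equal(est$sigma_t_years, 0.4 / deriv)
  expect_equal(rho_to_time(0, 0, cc)$t_years, 0)

  expect_error(rho_to_time(-1, 0, lin), "non-negative")
  expect_error(clock_model("bad", "linear"), "years_per_mutation")
  expect_error(clock_model("bad", "soares_corrected_complete",
                           mu_neutral = 1e-4), "mu_neutral")
})

test_that("rho depends on the designated founder", {
  ref <- fixture_ref()
  alt <- function(p) setdiff(c("A", "C", "G", "T"), ref[p])[1L]
  keys <- function(pos) paste0(pos, ":", vapply(pos, alt, ""))
  tips <- list(t1 = keys(c(1000)), t2 = keys(c(2000)), t3 = keys(c(3000)))
  founder_a <- character(0)           # ancestral center
  founder_b <- tips$t1                # re-anchored at a tip haplotype
  dist_to <- function(f) vapply(tips, function(k)
    length(setdiff(k, f)) + length(setdiff(f, k)), 0)
  expect_equal(rho(star_genealogy(dist_to(founder_a))), 1)
  expect_equal(rho(star_genealogy(dist_to(founder_b))), 4 / 3)
})

test_that("dating is unbiased on simulated star expansions", {
  # E[rho]/rate = TMRCA at several sample sizes (10^4 Poisson replicates)
  rate <- 1 / 1000                    # one mutation per 1000 years
  t_true <- 20000
  lam <- rate * t_true
  set.seed(90)
  for (n in c(10L, 50L, 200L)) {
    reps <- 1e4L
    rhos <- stats::rpois(reps, n * lam) / n   # sum of n iid Poissons
    bias <- abs(mean(rhos) / lam - 1)
    expect_lt(bias, 0.02)
  }
  # full estimator path: star n=50, 500 seeded replicates through
  # star_genealogy + rho_to_time under the linear clock
  lin <- clock_model("lin", "linear", years_per_mutation = 1000)
  ests <- vapply(seq_len(500L), function(i) {
    d <- stats::rpois(50L, lam)
    rho_to_time(rho(star_genealogy(d)), saillard_sigma(star_genealogy(d)),
                lin)$t_years
  }, 0)
  expect_lt(abs(mean(ests) / t_true - 1), 0.02)
})

test_that("synonymous substitutions are classified by codon translation", {
  ref <- fixture_ref()
  ann <- mt_gene_annotation()
  # force a known codon background inside ND1 (starts at 3307, frame 0):
  # CTT (Leu) at 3307..3309; third-position C-T changes stay Leu
  ref[3307:3309] <- c("C", "T", "T")
  vs_syn <- vs_of("syn", 3309, "C", ref)
  expect_equal(synonymous_count(vs_syn, ref, ann), 1L)
  # first-position change CTT -> GTT is Leu -> Val: non-synonymous
  vs_non <- vs_of("non", 3307, "G", ref)
  expect_equal(synonymous_count(vs_non, ref, ann), 0L)
  # variants outside all coding genes never count (rRNA region)
  vs_rna <- vs_of("rna", 1500, setdiff(c("A", "C", "G", "T"),
                                       ref[1500])[1L], ref)
  expect_equal(synonymous_count(vs_rna, ref, ann), 0L)
  expect_equal(synonymous_count(vs_of("none", integer(0), character(0),
                                      ref), ref, ann), 0L)
  # the minus-strand gene (ND6) translates in reverse complement: make the
  # codon on the coding strand CTT by placing AAG on the reference strand
  ref[14671:14673] <- c("A", "A", "G")   # ND6 starts at its 3' end 14673
  vs6 <- vs_of("nd6", 14671, "G", ref)   # third codon position, C->T change
  expect_equal(synonymous_count(vs6, ref, ann), 1L)
})
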