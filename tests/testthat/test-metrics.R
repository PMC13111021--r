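test_that("Shannon diversity matches analytic values and bounds", {
  expect_equal(shannon_diversity(rep(0.25, 4)), log(4))
  expect_equal(shannon_diversity(1), 0)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_error(shannon_diversity(c(0.5, 0.5, 0)), "positive")
  expect_error(shannon_diversity(c(0.5, 0.4)), "sum to 1")
  # 0 <= H <= ln S with equality at uniform
  for (seed in 1:5) {
    set.seed(seed)
    p <- rgamma(50, 1); p <- p / sum(p)
    h <- shannon_diversity(p)
    expect_gte(h, 0)
    expect_lte(h, log(50) + 1e-12)
  }
})

test_that("Pielou evenness is normalized Shannon, undefined at S = 1", {
  expect_equal(pielou_evenness(rep(1 / 7, 7)), 1)
  expect_equal(pielou_evenness(c(0.5, 0.25, 0.25)), 0.946395, tolerance = 1e-6)
  expect_true(is.na(pielou_evenness(1)))
  # invariant under permutation of clones
  set.seed(4)
  p <- rgamma(20, 1); p <- p / sum(p)
  expect_equal(pielou_evenness(p), pielou_evenness(sample(p)))
})

test_that("convergence frequency sums convergent-group mass over depth", {
  s <- make_sample(
    nt = c("TGTGCCAGCAGC", "TGCGCCAGCAGC", "TGTGCCAGCAGT"),
    v = c("TRBV5-1", "TRBV5-1", "TRBV7-2"),
    j = c("TRBJ2-7", "TRBJ2-1", "TRBJ2-7"),
    count = c(50, 20, 30)
  )
  expect_equal(convergence_frequency(s), 0.70)
  s2 <- make_sample(nt = c("TGTGCCAGCAGC", "TGTGCCAGCTTT"),
                    v = c("TRBV5-1", "TRBV5-1"),
                    j = c("TRBJ2-7", "TRBJ2-7"), count = c(5, 5))
  expect_equal(convergence_frequency(s2), 0)
})

test_that("adding a synonymous variant never decreases convergence", {
  for (seed in c(5L, 23L, 61L)) {
    s <- random_messy_sample(seed, max_clonotypes = 60L)
    before <- convergence_frequency(s)
    # plant one extra distinct encoding of an existing clonotype's CDR3aa
    cl <- s$clonotypes
    i <- which.max(cl$count)
    variants <- synonymous_variants(cl$cdr3_aa[i], 12L, seed = seed)
    new_nt <- setdiff(variants, cl$cdr3_nt)[1]
    cl2 <- rbind(cl, data.frame(cdr3_nt = new_nt, cdr3_aa = cl$cdr3_aa[i],
                                v_gene = cl$v_gene[i], j_gene = cl$j_gene[i],
                                count = 3))
    after <- convergence_frequency(repertoire_sample(cl2))
    expect_gte(after, before)
  }
})

test_that("unique clone count is the number of distinct keys", {
  s <- make_sample(nt = c("TGTGCCAGCAGC", "TGCGCCAGCAGC", "TGTGCCAGCAGT"),
                   v = rep("TRBV5-1", 3), j = rep("TRBJ2-7", 3),
                   count = c(1, 2, 3))
  expect_equal(unique_clone_count(s), 3L)
  expect_equal(unique_clone_count(repertoire_sample(s$clonotypes[0, ])), 0L)
  # agrees with an independent hash-set count on a simulated sample
  r <- sample_repertoire(300, 0.8, 5000, 0.05, seed = 8)
  key_set <- unique(paste(r$clonotypes$cdr3_nt, r$clonotypes$v_gene,
                          r$clonotypes$j_gene))
  expect_equal(unique_clone_count(r), length(key_set))
})

test_that("percent decline matches the printed worked examples", {
  expect_equal(round(percent_decline(2248, 1335)), 41)
  expect_equal(round(percent_decline(3318, 2790)), 16)
  expect_equal(percent_decline(100, 100), 0)
  expect_lt(percent_decline(100, 120), 0)
  expect_error(percent_decline(0, 10), "positive")
  expect_error(percent_decline(10, -1), "non-negative")
})

test_that("rarefaction draws exactly the target depth without replacement", {
  s <- make_sample(nt = c("TGTGCCAGCAGC", "TGCGCCAGCAGC", "TGTGCCAGCAGT"),
                   v = rep("TRBV5-1", 3), j = rep("TRBJ2-7", 3),
                   count = c(30, 50, 20))
  # exhaustive draw returns identical counts
  expect_identical(rarefy(s, 100, seed = 1)$clonotypes, s$clonotypes)
  expect_error(rarefy(s, 101, seed = 1), "exceeds")
  expect_error(rarefy(s, 0, seed = 1), "positive")
  r <- rarefy(s, 50, seed = 7)
  expect_equal(r$depth, 50)
  # each drawn count bounded by the original
  orig <- s$clonotypes$count[match(r$clonotypes$cdr3_nt, s$clonotypes$cdr3_nt)]
  expect_true(all(r$clonotypes$count <= orig))
  # deterministic given the seed, and seed handling leaves the RNG alone
  set.seed(99); before <- runif(1)
  r2 <- rarefy(s, 50, seed = 7)
  set.seed(99); after <- runif(1)
  expect_identical(r$clonotypes, r2$clonotypes)
  expect_identical(before, after)
})

test_that("rarefied counts are hypergeometric: mean and distribution checks", {
  counts <- c(5, 10, 85)
  s <- make_sample(nt = c("TGTGCCAGCAGC", "TGCGCCAGCAGC", "TGTGCCAGCAGT"),
                   v = rep("TRBV5-1", 3), j = rep("TRBJ2-7", 3),
                   count = counts)
  depth <- 40L
  n_rep <- 600L
  drawn <- matrix(0, n_rep, 3)
  for (i in seq_len(n_rep)) {
    r <- rarefy(s, depth, seed = 1000L + i)
    idx <- match(r$clonotypes$cdr3_nt, s$clonotypes$cdr3_nt)
    drawn[i, idx] <- r$clonotypes$count
    expect_equal(sum(r$clonotypes$count), depth)
  }
  # expectation: original count * depth / total, within Monte-Carlo error
  expect_equal(colMeans(drawn), counts * depth / sum(counts), tolerance = 0.02)
  # distribution of clone 1's drawn count vs the read-level oracle's exact
  # hypergeometric law (chi-square GOF, alpha = 0.01)
  k <- 0:5
  probs <- stats::dhyper(k, counts[1], sum(counts) - counts[1], depth)
  obs <- tabulate(drawn[, 1] + 1L, nbins = length(k))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs / sum(probs)))
  expect_gt(gof$p.value, 0.01)
  # the read-level shuffle-and-take oracle lives on the same support
  set.seed(42)
  oracle <- oracle_rarefy_counts(counts, depth)
  expect_equal(sum(oracle), depth)
  expect_true(all(oracle <= counts))
})

test_that("sample metrics rows and longitudinal deltas are assembled correctly", {
  r <- sample_repertoire(200, 0.8, 4000, 0.05, seed = 3)
  row <- sample_metrics(r, "P01", "T1", "DCG")
  expect_identical(names(row), c("patient_id", "timepoint", "group", "depth",
                                 "unique_clones", "shannon", "evenness",
                                 "convergence"))
  expect_equal(row$depth, 4000)
  expect_equal(row$convergence, convergence_frequency(r))
  expect_error(sample_metrics(r, "P01", "T9"), "timepoint")

  metrics <- data.frame(
    patient_id = c("A", "A", "B", "B", "C"),
    timepoint = c("T1", "T2", "T1", "T2", "T1"),
    group = c("DCG", "DCG", "PD", "PD", "DCG"),
    unique_clones = c(3000, 2500, 2000, 1200, 999)
  )
  d <- delta_metrics(metrics)
  expect_equal(nrow(d), 2L)                  # C has no T2
  expect_equal(d$delta_clones[d$patient_id == "A"], -500)
  expect_equal(d$percent_decline[d$patient_id == "B"], 40)
})
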