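test_that("synonymous variants respect codon multiplicities", {
  # methionine has a single codon: cannot produce 2 distinct encodings
  expect_error(synonymous_variants("M", 2, seed = 1), "at most 1")
  v <- synonymous_variants("CASS", 288, seed = 1)   # 2 x 4 x 6 x 6 encodings
  expect_equal(length(unique(v)), 288L)
  expect_true(all(translate_junction(v)$cdr3_aa == "CASS"))
  expect_true(all(translate_junction(v)$productive))
  expect_error(synonymous_variants("CASS", 289, seed = 1), "at most 288")
  expect_identical(synonymous_variants("CASSLGQF", 5, seed = 9),
                   synonymous_variants("CASSLGQF", 5, seed = 9))
  expect_error(synonymous_variants("CAB", 2, seed = 1), "invalid")
  expect_error(synonymous_variants("CASS", 1, seed = 1), ">= 2")
})

test_that("simulated repertoires honor their construction contract", {
  r <- sample_repertoire(300, 0.8, 6000, convergence_injection = 0.1,
                         seed = 21)
  expect_equal(r$depth, 6000)
  # every generated junction is productive and consistent with its aa
  tr <- translate_junction(r$clonotypes$cdr3_nt)
  expect_true(all(tr$productive))
  expect_identical(tr$cdr3_aa, r$clonotypes$cdr3_aa)
  # clonotype keys are distinct
  key <- paste(r$clonotypes$cdr3_nt, r$clonotypes$v_gene, r$clonotypes$j_gene)
  expect_false(anyDuplicated(key) > 0)
  # zero injection means exactly zero convergence
  r0 <- sample_repertoire(300, 0.8, 6000, 0, seed = 21)
  expect_equal(convergence_frequency(r0), 0)
  # determinism
  r2 <- sample_repertoire(300, 0.8, 6000, 0.1, seed = 21)
  expect_identical(r$clonotypes, r2$clonotypes)
  expect_error(sample_repertoire(300, 0.8, 200, 0, seed = 1), "at least")
  expect_error(sample_repertoire(300, 0.8, 6000, 1.5, seed = 1), "\\[0, 1\\]")
})

test_that("planted convergent read mass tracks the injection target", {
  realized <- vapply(1:5, function(seed) {
    convergence_frequency(
      sample_repertoire(2000, 0.8, 50000, 0.10, seed = 100 + seed)
    )
  }, numeric(1))
  expect_lt(abs(mean(realized) - 0.10), 0.02)
  # consistency: absolute error shrinks with depth for most seeds
  err <- vapply(1:5, function(seed) {
    small <- convergence_frequency(
      sample_repertoire(500, 0.8, 4000, 0.10, seed = 200 + seed))
    large <- convergence_frequency(
      sample_repertoire(500, 0.8, 40000, 0.10, seed = 200 + seed))
    c(abs(small - 0.10), abs(large - 0.10))
  }, numeric(2))
  expect_gte(sum(err[2, ] <= err[1, ]), 3L)
})

test_that("cohort bookkeeping: manifest, groups, and sample map line up", {
  cfg <- sim_config(n_dcg = 3, n_pd = 2, clones_t1 = 200, depth = 3000,
                    n_shared_dcg = 10, n_fresh_clones = 20, seed = 5)
  co <- simulate_longitudinal_cohort(cfg)
  m <- co$manifest
  expect_equal(nrow(m), 5L)
  expect_equal(sum(m$group == "DCG"), 3L)
  expect_equal(sum(m$group == "PD"), 2L)
  expect_true(all(m$response[m$group == "DCG"] %in% c("PR", "SD")))
  # every planned path resolves to a generated sample
  for (i in seq_len(nrow(m))) {
    for (tp in c("T1", "T2", "T3")) {
      if (nzchar(m[[tp]][i])) {
        key <- paste0(m$patient_id[i], "_", tp)
        expect_true(key %in% names(co$samples))
      }
    }
  }
  # T3 exists only for PD patients under the default scenario flag
  expect_true(all(!nzchar(m$T3[m$group == "DCG"])))
  expect_true(all(nzchar(m$T3[m$group == "PD"])))
  expect_true(all(m$os_days >= 0) && all(m$event %in% 0:1))
  # determinism of the whole cohort
  co2 <- simulate_longitudinal_cohort(cfg)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$samples[[1]]$clonotypes, co2$samples[[1]]$clonotypes)
})

test_that("full retention rules out clone-count decline", {
  cfg <- sim_config(n_dcg = 2, n_pd = 1, clones_t1 = 300, depth = 30000,
                    retention_dcg = 1.0, retention_sd = 0,
                    n_shared_dcg = 10, n_fresh_clones = 20, seed = 8)
  co <- simulate_longitudinal_cohort(cfg)
  for (pid in co$manifest$patient_id[co$manifest$group == "DCG"]) {
    pre <- unique_clone_count(co$samples[[paste0(pid, "_T1")]])
    post <- unique_clone_count(co$samples[[paste0(pid, "_T2")]])
    expect_lte(percent_decline(pre, post), 0)
  }
})

test_that("cohort survives a disk round trip with bit-identical metrics", {
  cfg <- sim_config(n_dcg = 2, n_pd = 2, clones_t1 = 150, depth = 2500,
                    n_shared_dcg = 8, n_fresh_clones = 15, seed = 12)
  co <- simulate_longitudinal_cohort(cfg)
  dir <- tempfile("roundtrip_")
  manifest_path <- write_cohort(co, dir)
  m <- read_cohort_manifest(manifest_path)
  expect_identical(m$patient_id, co$manifest$patient_id)
  expect_identical(m$group, co$manifest$group)
  for (key in names(co$samples)) {
    back <- read_repertoire(file.path(dir, paste0(key, ".tsv")))
    expect_identical(back$clonotypes, co$samples[[key]]$clonotypes)
    expect_identical(convergence_frequency(back),
                     convergence_frequency(co$samples[[key]]))
    freqs <- back$clonotypes$count / back$depth
    orig <- co$samples[[key]]$clonotypes$count / co$samples[[key]]$depth
    expect_identical(shannon_diversity(freqs), shannon_diversity(orig))
  }
})
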