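# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use different algorithms (all-pairs graphs, full
# enumeration, eigen-decomposition, read-level resampling) from the
# implementation paths they check.

make_sample <- function(nt, v, j, count, id = "fixture") {
  aa <- translate_junction(nt)$cdr3_aa
  repertoire_sample(
    data.frame(cdr3_nt = nt, cdr3_aa = aa, v_gene = v, j_gene = j,
               count = count, stringsAsFactors = FALSE),
    sample_id = id
  )
}

# Brute-force convergence oracle: compare every clonotype pair for V + CDR3aa
# identity with differing nucleotide sequence, take connected components of
# that graph, and sum the read mass of components containing an edge.
oracle_convergent_mass <- function(sample) {
  cl <- sample$clonotypes
  n <- nrow(cl)
  if (n == 0L) return(0)
  adj <- outer(cl$v_gene, cl$v_gene, "==") &
    outer(cl$cdr3_aa, cl$cdr3_aa, "==") &
    outer(cl$cdr3_nt, cl$cdr3_nt, "!=")
  diag(adj) <- FALSE
  if (!any(adj)) return(0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  mass <- 0
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (any(adj[idx, idx, drop = FALSE])) mass <- mass + sum(cl$count[idx])
  }
  mass / sample$depth
}

# Messy random repertoire with forced (V, aa) collisions and synonymous
# variants, for oracle-equivalence checks.
random_messy_sample <- function(seed, max_clonotypes = 200L) {
  set.seed(seed)
  aa_pool <- c("CASSF", "CASSG", "CASTF", "CAWSF", "CASRF", "CGSSF")
  variants <- lapply(seq_along(aa_pool), function(i) {
    synonymous_variants(aa_pool[i], 4L, seed = seed * 10L + i)
  })
  n <- sample(5:max_clonotypes, 1L)
  pick_aa <- sample(seq_along(aa_pool), n, replace = TRUE)
  recs <- data.frame(
    v_call = sample(c("TRBV5-1", "TRBV7-2", "TRBV20-1", "TRBV19"), n, TRUE),
    j_call = sample(c("TRBJ2-7", "TRBJ1-1"), n, TRUE),
    junction = vapply(pick_aa, function(i) sample(variants[[i]], 1L), ""),
    duplicate_count = sample(1:50, n, TRUE),
    stringsAsFactors = FALSE
  )
  repertoire_sample(collapse_clonotypes(recs), sample_id = paste0("messy", seed))
}

# Full-enumeration Mann-Whitney oracle (tie-free inputs).
oracle_wilcox_p <- function(x, y) {
  m <- length(x)
  n <- length(y)
  comb <- c(x, y)
  r <- rank(comb)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2L, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  if (u_obs > m * n / 2) {
    min(1, 2 * mean(us >= u_obs))
  } else {
    min(1, 2 * mean(us <= u_obs))
  }
}

# Full-permutation Spearman oracle computing cor() per permutation directly.
oracle_spearman_p <- function(values, timepoints) {
  rx <- rank(values)
  ry <- rank(timepoints)
  rho <- cor(rx, ry)
  n <- length(values)
  gen <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (tail in gen(v[-i])) out[[length(out) + 1L]] <- c(v[i], tail)
    }
    out
  }
  hits <- 0L
  total <- 0L
  for (p in gen(seq_len(n))) {
    total <- total + 1L
    if (abs(cor(rx[p], ry)) >= abs(rho) - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# Two-group log-rank oracle from the observed-minus-expected sums.
oracle_logrank_p <- function(times, events, groups) {
  labs <- sort(unique(groups))
  stopifnot(length(labs) == 2L)
  ts <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == labs[1L])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == labs[1L])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (o1 - e1)^2 / v
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

# Product-limit oracle computed step by step.
oracle_km_curve <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = 0, surv = 1)
  for (t in ts) {
    n <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# Eigen-decomposition PCA oracle with the same sign convention.
oracle_pca_scores <- function(m, k) {
  mc <- scale(m, center = TRUE, scale = FALSE)
  e <- eigen(stats::cov(mc), symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    i <- which.max(abs(vec[, c]))
    if (vec[i, c] < 0) vec[, c] <- -vec[, c]
  }
  mc %*% vec
}

# Read-level rarefaction oracle: expand to individual reads, shuffle, take.
oracle_rarefy_counts <- function(counts, depth) {
  reads <- rep.int(seq_along(counts), counts)
  drawn <- sample(reads, depth, replace = FALSE)
  tabulate(drawn, nbins = length(counts))
}

write_airr_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
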