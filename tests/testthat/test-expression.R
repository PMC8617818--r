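test_that("cross-mutant averaging matches a naive per-gene loop", {
  set.seed(1)
  m <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), paste0("mut", 1:6)))
  m[sample(length(m), 30)] <- NA
  m[3, ] <- NA   # an all-missing gene
  prof <- expression_profile(m)
  expect_message(rk <- average_across_mutants(prof), "all-missing")
  expect_false("g03" %in% rk$gene)
  for (i in seq_len(nrow(rk))) {
    g <- rk$gene[i]
    vals <- m[g, ][!is.na(m[g, ])]
    expect_equal(rk$mean_log2fc[i], sum(vals) / length(vals))
    expect_equal(rk$n_nonmissing[i], length(vals))
  }
  expect_equal(sort(rk$rank), seq_len(nrow(rk)))
  expect_equal(rk$mean_log2fc, sort(rk$mean_log2fc))

  ## single mutant: mean equals the column
  rk1 <- average_across_mutants(prof, mutants = "mut1")
  keep <- !is.na(m[, "mut1"])
  expect_setequal(rk1$gene, rownames(m)[keep])

  ## permutation invariance over mutant order
  prof2 <- expression_profile(m[, c(4, 2, 6, 1, 3, 5)])
  expect_message(rk2 <- average_across_mutants(prof2))
  expect_equal(rk2$mean_log2fc, rk$mean_log2fc)
  expect_equal(rk2$gene, rk$gene)

  ## plain arithmetic example
  m3 <- matrix(c(-1, -2, -3), 1, 3,
               dimnames = list("g", c("a", "b", "c")))
  expect_equal(average_across_mutants(expression_profile(m3))$mean_log2fc, -2)
})

test_that("planted repressed genes rank at the bottom and are selected", {
  prof <- simulate_expression(n_genes = 89, planted_down = 24,
                              delta_down = -1.5, noise_sd = 0.3, seed = 3)
  planted <- attr(prof, "planted_down")
  rk <- average_across_mutants(prof)
  expect_gte(sum(rk$gene[1:24] %in% planted), 23)

  cand <- select_candidates(rk, prof$pvals, alpha = 0.05, extension_n = 10)
  sig <- cand$gene[cand$tag == "significant"]
  expect_gte(sum(planted %in% sig), 23)
  expect_equal(nrow(cand), length(sig) + 10)

  cand0 <- select_candidates(rk, prof$pvals, alpha = 0.05, extension_n = 0)
  expect_true(all(cand0$tag == "significant"))

  expect_warning(big <- select_candidates(rk, prof$pvals, alpha = 0.05,
                                          extension_n = 1000),
                 "truncat")
  expect_equal(nrow(big), nrow(rk))
})

test_that("candidate selection tags 24 significant plus 10 extension genes", {
  ## clean planted signal at the study scale: exactly the planted set is
  ## significant and the list has 24 + 10 entries
  prof <- simulate_expression(n_genes = 89, planted_down = 24,
                              delta_down = -1.5, noise_sd = 0.25, seed = 8)
  rk <- average_across_mutants(prof)
  cand <- select_candidates(rk, prof$pvals, alpha = 1e-4, extension_n = 10)
  expect_equal(sum(cand$tag == "significant"), 24)
  expect_equal(nrow(cand), 34)
})

test_that("essential-gene subsetting preserves order and validates input", {
  prof <- simulate_expression(n_genes = 30, planted_down = 0, seed = 1)
  expect_equal(subset_essential(prof, prof$genes)$log2fc, prof$log2fc)
  some <- prof$genes[c(5, 1, 20)]
  sub <- subset_essential(prof, some)
  expect_equal(sub$genes, prof$genes[c(1, 5, 20)])  # original order
  expect_error(subset_essential(prof, c("nope1", "nope2")), "essential")
})

test_that("fold-change thresholding uses fold reduction, not a log2 cut", {
  rk <- data.frame(gene = c("a", "b", "c"),
                   mean_log2fc = c(-3, -2, -2.4), sd = 0, n_nonmissing = 3,
                   rank = 1:3)
  got <- threshold_repressed(rk, fold_threshold = 5)
  expect_true("a" %in% got)        # 2^3 = 8-fold >= 5
  expect_false("b" %in% got)       # 4-fold < 5
  expect_true("c" %in% got)        # 2^2.4 = 5.28-fold >= 5
  expect_error(threshold_repressed(rk, fold_threshold = 1), "fold_threshold")
})

test_that("mutant clustering matches the brute-force agglomeration oracle", {
  ## identical columns merge first at height 0
  m <- matrix(rnorm(20), 10, 2)
  m <- cbind(m, m[, 2])
  dimnames(m) <- list(paste0("g", 1:10), c("a", "b", "b2"))
  cl <- cluster_mutants(expression_profile(m))
  expect_equal(cl$hclust$height[1], 0)

  ## hand-computable 1D instance {0, 1, 10}
  m1 <- matrix(c(0, 1, 10), 1, 3, dimnames = list("g", c("x", "y", "z")))
  cl1 <- cluster_mutants(expression_profile(m1))
  expect_equal(cl1$hclust$height, c(1, 10))
  expect_equal(sort(cl1$hclust$merge[1, ]), c(-2, -1))  # {0} and {1} first

  ## random matrices vs the naive complete-linkage oracle
  for (seed in 1:5) {
    set.seed(seed)
    mm <- matrix(rnorm(8 * 5), 8, 5,
                 dimnames = list(paste0("g", 1:8), paste0("m", 1:5)))
    cl2 <- cluster_mutants(expression_profile(mm))
    expect_equal(cl2$hclust$height, brute_complete_heights(mm),
                 tolerance = 1e-9)
  }

  ## planted signatures split the mutants into two groups
  set.seed(9)
  base <- matrix(rnorm(60 * 6, 0, 0.2), 60, 6,
                 dimnames = list(paste0("g", 1:60), paste0("m", 1:6)))
  base[1:15, 1:3] <- base[1:15, 1:3] - 2
  cl3 <- cluster_mutants(expression_profile(base))
  top <- cutree(cl3$hclust, k = 2)
  expect_equal(length(unique(top[1:3])), 1)
  expect_equal(length(unique(top[4:6])), 1)
  expect_false(top[1] == top[4])

  expect_error(cluster_mutants(expression_profile(
    matrix(1:3, 3, 1, dimnames = list(letters[1:3], "only")))),
    "2 mutants")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- sprintf("u%02d", 1:20)
  query <- universe[1:5]
  res <- enrich(query, list(hit = universe[1:5], all = universe),
                universe)
  expect_equal(res$p[res$term == "hit"], 1 / choose(20, 5))
  expect_equal(res$p[res$term == "all"], 1)

  ## against subset enumeration for small universes
  for (case in list(c(N = 12, K = 4, n = 5), c(N = 10, K = 6, n = 3),
                    c(N = 15, K = 5, n = 6))) {
    N <- case["N"]; K <- case["K"]; n <- case["n"]
    uni <- sprintf("x%02d", seq_len(N))
    for (k in 1:min(K, n)) {
      q <- uni[seq_len(k)]
      if (n > k) q <- c(q, uni[(K + 1):(K + n - k)])
      r <- enrich(q, list(t = uni[seq_len(K)]), uni)
      expect_equal(r$p, enum_hyper_tail(N, K, n, k), tolerance = 1e-12,
                   info = paste(N, K, n, k))
    }
  }

  ## under-representation gives p > 0.5
  r2 <- enrich(universe[6:20], list(t = universe[1:10]), universe)
  expect_gt(r2$p, 0.5)

  ## BH keeps ordering and q in [p, 1]
  set.seed(2)
  ann <- lapply(1:8, function(i) sample(universe, 8))
  names(ann) <- paste0("t", 1:8)
  r3 <- enrich(universe[1:6], ann, universe)
  expect_true(all(r3$q >= r3$p & r3$q <= 1))
  expect_equal(order(r3$p), order(r3$q))

  expect_error(enrich(c("u01", "zzz"), list(t = universe), universe), "zzz")
})

test_that("annotation overlap counts every Venn region", {
  d <- annotation_overlap(list(A = "a", B = "b"))
  expect_equal(d$count[d$region == "A&B"], 0)
  d2 <- annotation_overlap(list(A = c("a", "b"), B = c("a", "b")))
  expect_equal(d2$count[d2$region == "A&B"], 2)
  expect_equal(sum(d2$count[d2$region != "A&B"]), 0)

  set.seed(4)
  pool <- letters[1:15]
  sets <- list(X = sample(pool, 7), Y = sample(pool, 6), Z = sample(pool, 8))
  d3 <- annotation_overlap(sets, limit = 3)
  ## enumeration oracle: classify each gene by its membership pattern
  for (i in seq_len(nrow(d3))) {
    terms_in <- strsplit(d3$region[i], "&")[[1]]
    terms_out <- setdiff(names(sets), terms_in)
    expected <- sum(vapply(unique(unlist(sets)), function(g)
      all(vapply(terms_in, function(t) g %in% sets[[t]], logical(1))) &&
        !any(vapply(terms_out, function(t) g %in% sets[[t]], logical(1))),
      logical(1)))
    expect_equal(d3$count[i], expected, info = d3$region[i])
  }
})
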