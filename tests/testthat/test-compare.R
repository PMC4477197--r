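grouped_from <- function(m, roles = NULL) {
  keys <- rownames(m)
  structure(m,
            roles = stats::setNames(roles %||% rep("neuronal", length(keys)),
                                    keys),
            sizes = stats::setNames(rep(1, length(keys)), keys),
            neuron_agg = "pair_mean", truncated_groups = character(),
            class = c("grouped_matrix", "matrix", "array"))
}

rand_grouped <- function(seed, k = 5, lambda = 1.5) {
  keys <- paste0("G", seq_len(k))
  m <- withr::with_seed(seed,
    matrix(rpois(k * k, lambda), k, k, dimnames = list(keys, keys)))
  diag(m) <- 0
  grouped_from(m)
}

test_that("alignment matches keys exactly and reports dropped groups", {
  ma <- rand_grouped(1)
  mb <- rand_grouped(2)
  pr <- align_matrices(ma, mb)
  expect_equal(pr$dropped_a, character(0))
  expect_equal(pr$dropped_b, character(0))

  keys6 <- c(rownames(mb), "INpro.left")
  mb2 <- grouped_from(matrix(1, 6, 6, dimnames = list(keys6, keys6)))
  pr2 <- align_matrices(ma, mb2)
  expect_equal(pr2$dropped_b, "INpro.left")
  expect_equal(pr2$dropped_a, character(0))
  expect_setequal(pr2$shared_keys, rownames(ma))

  # shuffled label order: alignment restores cell-wise equality
  shuf <- withr::with_seed(4, sample(nrow(mb)))
  mb_shuf <- grouped_from(unclass(mb)[shuf, shuf])
  pr3 <- align_matrices(mb, mb_shuf)
  expect_equal(unclass(pr3$m_a), unclass(pr3$m_b), ignore_attr = TRUE)

  disjoint <- grouped_from(matrix(0, 2, 2, dimnames = list(c("X", "Y"),
                                                           c("X", "Y"))))
  expect_error(align_matrices(ma, disjoint),
               class = "connstereo_comparison_error")
})

test_that("grouped correlation hits the identity and antitone limits", {
  ma <- rand_grouped(10, k = 6)
  self <- correlate_grouped(align_matrices(ma, ma), n_perm = 200, seed = 1)
  expect_equal(self$rho, 1.0)
  expect_gte(self$p_perm, 1 / 201)

  # rank reversal: strictly decreasing transform of the cells
  mb <- grouped_from(max(ma) + 1 - unclass(ma))
  rev <- correlate_grouped(align_matrices(ma, mb), n_perm = 0)
  expect_equal(rev$rho, -1.0)

  const <- grouped_from(matrix(2, 6, 6, dimnames = dimnames(ma)))
  expect_error(correlate_grouped(align_matrices(ma, const), n_perm = 0),
               class = "connstereo_degenerate_error")
})

test_that("Spearman rho equals the brute-force rank/Pearson oracle on tied data", {
  # fixed 8-cell example with heavy ties
  a <- c(0, 0, 3, 3, 3, 7, 2, 0)
  b <- c(1, 0, 4, 4, 9, 9, 0, 0)
  expect_equal(connstereo:::spearman_rho(a, b), oracle_spearman(a, b),
               tolerance = 1e-12)

  for (seed in 1:50) {
    v <- withr::with_seed(seed, {
      n <- sample(5:12, 1)
      list(x = sample(0:5, n, replace = TRUE), y = sample(0:5, n, replace = TRUE))
    })
    if (length(unique(v$x)) < 2 || length(unique(v$y)) < 2) next
    expect_equal(connstereo:::spearman_rho(v$x, v$y),
                 oracle_spearman(v$x, v$y), tolerance = 1e-12)
  }
})

test_that("permutation p respects its floor and records its seed", {
  ma <- rand_grouped(20, k = 5)
  mb <- rand_grouped(21, k = 5)
  res <- correlate_grouped(align_matrices(ma, mb), n_perm = 99, seed = 42)
  expect_gte(res$p_perm, 1 / 100)
  expect_lte(res$p_perm, 1)
  expect_equal(res$seed, 42)
  res2 <- correlate_grouped(align_matrices(ma, mb), n_perm = 99, seed = 42)
  expect_identical(res$p_perm, res2$p_perm)
})

test_that("geometric-mean combination intersects supports and bounds entries", {
  ma <- grouped_from(matrix(c(0, 2, 5, 0), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B"))))
  mb <- grouped_from(matrix(c(0, 8, 0, 0), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B"))))
  cm <- combine_geometric_mean(align_matrices(ma, mb))
  expect_equal(cm["B", "A"], 4.0)   # sqrt(2 * 8)
  expect_equal(cm["A", "B"], 0.0)   # present in one individual only

  idem <- combine_geometric_mean(align_matrices(ma, ma))
  expect_equal(unclass(idem), unclass(ma), ignore_attr = TRUE)

  for (seed in 1:40) {
    pa <- rand_grouped(seed, k = 5)
    pb <- rand_grouped(seed + 1000, k = 5)
    cm <- combine_geometric_mean(align_matrices(pa, pb))
    a <- unclass(pa); b <- unclass(pb); cc <- unclass(cm)
    expect_equal(cc > 0, a > 0 & b > 0)
    expect_true(all(cc <= pmax(a, b) + 1e-12))
    expect_true(all(cc >= pmin(a, b) - 1e-12 | cc == 0))
  }
})

test_that("rho is invariant under simultaneous relabeling of both matrices", {
  ma <- rand_grouped(30, k = 6)
  mb <- rand_grouped(31, k = 6)
  base <- correlate_grouped(align_matrices(ma, mb), n_perm = 0)$rho
  perm <- withr::with_seed(5, sample(6))
  relabel <- function(m) {
    out <- unclass(m)[perm, perm]
    dimnames(out) <- list(paste0("H", 1:6), paste0("H", 1:6))
    grouped_from(out)
  }
  again <- correlate_grouped(align_matrices(relabel(ma), relabel(mb)),
                             n_perm = 0)$rho
  expect_equal(again, base, tolerance = 1e-12)
})

test_that("per-type profiles are perfect for identical individuals and flag weak groups", {
  pair <- sample_pair(make_default_template(), noise_free(), 1, 2)
  prof <- per_type_correlations(pair$a, pair$b, n_perm = 100, seed = 3)
  defined <- !is.na(prof$pre_rho)
  expect_true(any(defined))
  expect_true(all(abs(prof$pre_rho[defined] - 1) < 1e-12))
  post_def <- !is.na(prof$post_rho)
  expect_true(all(abs(prof$post_rho[post_def] - 1) < 1e-12))
  # the weakly-wired trunk interneurons fall under the 5-synapse floor
  expect_true(prof$weakly_connected[prof$group == "INvnc.left"])
  expect_false(prof$weakly_connected[prof$group == "IN1.left"])

  # a group absent from one individual is dropped and reported
  keep <- pair$b$neurons$cell_type != "INpro"
  b2 <- connectome(pair$b$neurons[keep, ],
                   dplyr::filter(pair$b$links,
                                 !pre_id %in% pair$b$neurons$id[!keep],
                                 !post_id %in% pair$b$neurons$id[!keep]),
                   individual_id = "b2")
  prof2 <- per_type_correlations(pair$a, b2, n_perm = 0)
  expect_true(all(c("INpro.left", "INpro.right") %in% attr(prof2, "dropped_a")))
  expect_false("INpro.left" %in% prof2$group)
})

test_that("asymmetry score is zero for mirror pairs and one for orthogonal output", {
  nn <- dplyr::bind_rows(
    neurons_tbl(id = c("mn_l", "mn_r"), cell_type = "MN",
                side = c("left", "right"), func_class = "motoneuron"),
    neurons_tbl(id = c("p_l", "p_r"), cell_type = "prototroch",
                side = c("left", "right"), func_class = "effector"),
    neurons_tbl(id = c("m_l", "m_r"), cell_type = "muscle",
                side = c("left", "right"), func_class = "effector"))
  mirror_links <- tibble::tibble(
    pre_id = c("mn_l", "mn_l", "mn_r", "mn_r"),
    post_id = c("p_r", "m_r", "p_l", "m_l"),
    count = c(4L, 2L, 4L, 2L))
  x <- connectome(nn, mirror_links)
  expect_equal(asymmetry_score(x, "mn_r", "mn_l"), 0.0)

  # homolog connects nothing that mirrors the neuron's targets
  ortho_links <- tibble::tibble(pre_id = c("mn_r", "mn_l"),
                                post_id = c("mn_l", "m_r"),
                                count = c(3L, 2L))
  x2 <- connectome(nn, ortho_links)
  expect_equal(asymmetry_score(x2, "mn_r", "mn_l"), 1.0)

  # hand-computed cosine complement on a mixed fixture
  mixed <- tibble::tibble(
    pre_id = c("mn_r", "mn_r", "mn_l", "mn_l"),
    post_id = c("p_l", "mn_l", "p_r", "m_r"),
    count = c(4L, 3L, 4L, 2L))
  x3 <- connectome(nn, mixed)
  # neuron vector (mirrored space): p_l = 4, MN.left = 3
  # homolog mirrored vector: p_l = 4, m_l = 2
  expected <- 1 - (4 * 4) / (sqrt(4^2 + 3^2) * sqrt(4^2 + 2^2))
  expect_equal(asymmetry_score(x3, "mn_r", "mn_l"), expected,
               tolerance = 1e-12)

  none <- connectome(nn, NULL)
  expect_error(asymmetry_score(none, "mn_r", "mn_l"),
               class = "connstereo_degenerate_error")
  expect_error(asymmetry_score(x, "ghost", "mn_l"),
               class = "connstereo_referential_error")
})

test_that("end-to-end comparison bundles consistent components", {
  pair <- sample_pair(make_default_template(), noise_model(), 11, 22)
  cmp <- compare_connectomes(pair$a, pair$b, n_perm = 500, n_perm_type = 100,
                             seed = 5)
  expect_s3_class(cmp$global, "stereotypy_cor")
  expect_equal(dim(cmp$combined),
               rep(length(cmp$aligned$shared_keys), 2))
  expect_equal(nrow(cmp$per_type), length(cmp$aligned$shared_keys))
  g <- glance(cmp)
  expect_equal(g$estimate, cmp$global$rho)
  # deterministic given the seed
  cmp2 <- compare_connectomes(pair$a, pair$b, n_perm = 500, n_perm_type = 100,
                              seed = 5)
  expect_identical(cmp2$global$p_perm, cmp$global$p_perm)
})
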