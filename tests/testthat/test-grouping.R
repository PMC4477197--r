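test_that("full matrix reflects the edge list exactly", {
  nn <- neurons_tbl(id = c("A", "B", "C"), cell_type = "IN1",
                    side = "left", func_class = "interneuron")
  lk <- tibble::tibble(pre_id = c("A", "B"), post_id = c("B", "A"),
                       count = c(5L, 2L))
  m <- build_full_matrix(connectome(nn, lk))
  expect_equal(m["A", "B"], 5)
  expect_equal(m["B", "A"], 2)
  expect_equal(sum(m), 7)

  m0 <- build_full_matrix(connectome(nn))
  expect_true(all(m0 == 0))

  x <- random_connectome(12, seed = 3)
  expect_equal(sum(build_full_matrix(x)), sum(x$links$count))
})

test_that("grouped matrix applies the declared averaging and sum rules", {
  nn <- neurons_tbl(id = c("a1", "a2", "b1", "b2"),
                    cell_type = c("A", "A", "B", "B"), side = "left",
                    func_class = "interneuron")
  lk <- tibble::tibble(pre_id = c("a1", "a2"), post_id = c("b1", "b1"),
                       count = c(4L, 2L))
  x <- connectome(nn, lk)
  gm <- build_grouped_matrix(x)                      # pair_mean: 6 / (2*2)
  expect_equal(gm["A.left", "B.left"], 1.5)
  gp <- build_grouped_matrix(x, neuron_agg = "per_pre_mean")  # 6 / 2
  expect_equal(gp["A.left", "B.left"], 3.0)

  # two-cell group onto a singleton target: (4 + 2) / (2 * 1) = 3
  nn1 <- nn[1:3, ]
  x1 <- connectome(nn1, lk)
  expect_equal(build_grouped_matrix(x1)["A.left", "B.left"], 3.0)

  # effector targets are summed, never averaged
  nne <- neurons_tbl(id = c("mn1", "p1", "p2", "p3"),
                     cell_type = c("MN", rep("prototroch", 3)),
                     side = "left",
                     func_class = c("motoneuron", rep("effector", 3)))
  lke <- tibble::tibble(pre_id = "mn1", post_id = c("p1", "p3"),
                        count = c(3L, 5L))
  ge <- build_grouped_matrix(connectome(nne, lke))
  expect_equal(ge["MN.left", "prototroch.left"], 8)
})

test_that("singleton grouping reproduces the full matrix under any averaging", {
  x <- random_connectome(10, seed = 11)
  scheme <- type_side_scheme(x)
  singleton <- structure(
    dplyr::mutate(tibble::as_tibble(scheme), group = neuron_id),
    class = class(scheme))
  full <- unclass(build_full_matrix(x))
  class(full) <- NULL
  for (agg in c("pair_mean", "per_pre_mean")) {
    g <- build_grouped_matrix(x, singleton, neuron_agg = agg)
    expect_equal(unclass(g)[rownames(full), colnames(full)],
                 full, ignore_attr = TRUE)
  }
})

test_that("pair-mean entries recover inter-group synapse totals (conservation)", {
  for (seed in 1:25) {
    x <- random_connectome(n = 14, seed = seed, n_types = 3)
    scheme <- type_side_scheme(x)
    g <- build_grouped_matrix(x, scheme)
    sizes <- attr(g, "sizes")
    roles <- attr(g, "roles")
    recon <- unclass(g)
    for (h in colnames(recon)) {
      if (roles[h] == "neuronal") {
        recon[, h] <- recon[, h] * sizes * sizes[h]
      }
    }
    expect_equal(sum(recon), sum(x$links$count), tolerance = 1e-12)
  }
})

test_that("unassigned-neuron policies behave as declared", {
  x <- random_connectome(8, seed = 5)
  partial <- type_side_scheme(x)[-1, ]
  partial <- structure(partial, class = c("grouping_scheme", class(partial)))
  expect_error(build_grouped_matrix(x, partial),
               class = "connstereo_config_error")
  expect_s3_class(build_grouped_matrix(x, partial, unassigned = "drop"),
                  "grouped_matrix")
  gs <- build_grouped_matrix(x, partial, unassigned = "singleton")
  expect_true(x$neurons$id[1] %in% rownames(gs))
  # overlapping assignment is rejected at scheme construction
  overlap <- dplyr::bind_rows(tibble::as_tibble(type_side_scheme(x)),
                              tibble::as_tibble(type_side_scheme(x))[1, ])
  expect_error(connstereo:::new_scheme(overlap),
               class = "connstereo_config_error")
})

test_that("scheme CSV round trip preserves the grouping", {
  x <- random_connectome(10, seed = 9)
  scheme <- type_side_scheme(x)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scheme(scheme, path)
  back <- read_scheme(path, x)
  expect_equal(as.data.frame(back), as.data.frame(scheme))
})

test_that("reciprocal strength is the geometric mean and is symmetric", {
  m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- 3; m["B", "A"] <- 12
  m["A", "C"] <- 7                      # one-way: annihilated
  m["B", "C"] <- 4; m["C", "B"] <- 4    # equal counts: strength = count
  r <- reciprocal_strength_matrix(m)
  expect_equal(r["A", "B"], 6.0)
  expect_equal(r["B", "A"], 6.0)
  expect_equal(r["A", "C"], 0.0)
  expect_equal(r["B", "C"], 4.0)

  for (seed in 1:30) {
    mm <- withr::with_seed(seed,
      matrix(rpois(49, 2), 7, 7, dimnames = list(letters[1:7], letters[1:7])))
    expect_equal(reciprocal_strength_matrix(mm),
                 reciprocal_strength_matrix(t(mm)))
    expect_equal(reciprocal_strength_matrix(mm),
                 t(reciprocal_strength_matrix(mm)))
  }
})

test_that("motoneuron candidates without effector output are reclassified", {
  # 11 candidates, 5 of which never synapse onto an effector
  mn_ids <- sprintf("mn%02d", 1:11)
  nn <- dplyr::bind_rows(
    neurons_tbl(id = mn_ids, cell_type = "MN", side = "left",
                func_class = "motoneuron"),
    neurons_tbl(id = c("mus1", "in9"), cell_type = c("muscle", "INvnc"),
                side = "left", func_class = c("effector", "interneuron")))
  lk <- tibble::tibble(
    pre_id = c(mn_ids[1:6], mn_ids[7:11]),
    post_id = c(rep("mus1", 6), rep("in9", 5)),
    count = 1L)
  res <- reclassify_motoneurons(connectome(nn, lk), mn_ids)
  expect_equal(sum(res$label == "MN"), 6L)
  expect_equal(sum(res$label == "INpro_candidate"), 5L)
  expect_setequal(res$id[res$label == "INpro_candidate"], mn_ids[7:11])

  # a single synapse onto a muscle suffices to stay MN
  expect_equal(res$label[res$id == "mn01"], "MN")
  expect_error(reclassify_motoneurons(connectome(nn, lk), "ghost"),
               class = "connstereo_referential_error")
})
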