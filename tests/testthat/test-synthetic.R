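test_that("default template declares the circuit's signature motifs", {
  tpl <- make_default_template()
  expect_s3_class(tpl, "wiring_template")
  # at least one reciprocal motif, by construction the IN1 pair
  expect_gte(nrow(tpl$reciprocal_motifs), 1)
  w <- tpl$weights
  get_w <- function(p, q) {
    hit <- w$mean_weight[w$pre == p & w$post == q]
    if (length(hit)) sum(hit) else 0
  }
  expect_gt(get_w("IN1.left", "IN1.right"), 0)
  expect_gt(get_w("IN1.right", "IN1.left"), 0)
  # crosswise photoreceptor drive dominates ipsilateral for every eye
  for (eye in c("PRCa.left", "PRCa.right", "PRCp.left", "PRCp.right")) {
    side <- sub("^.*\\.", "", eye)
    contra <- if (side == "left") "IN1.right" else "IN1.left"
    ipsi <- paste0("IN1.", side)
    expect_gt(get_w(eye, contra), get_w(eye, ipsi))
  }
  # the asymmetric motoneuron motif is genuinely one-sided
  am <- tpl$asymmetric_motifs
  expect_gte(nrow(am), 1)
  expect_gt(get_w(am$pre[1], am$post[1]), 0)
  expect_equal(get_w(mirror_key(am$pre[1]), mirror_key(am$post[1])), 0)
})

test_that("template validation rejects inconsistent declarations", {
  tpl <- make_default_template()
  expect_error(
    wiring_template(dplyr::select(tpl$groups, -"group"), tpl$weights,
                    reciprocal_motifs = tibble::tibble(a = "PRCa.left",
                                                       b = "PRCa.right")),
    class = "connstereo_config_error")
  bad_w <- dplyr::mutate(tpl$weights[1, ], pre = "nosuch.left")
  expect_error(wiring_template(dplyr::select(tpl$groups, -"group"), bad_w),
               class = "connstereo_config_error")
})

test_that("sampling is deterministic given the seed and honours degenerate noise", {
  tpl <- make_default_template()
  a1 <- sample_individual(tpl, noise_model(), seed = 99)
  a2 <- sample_individual(tpl, noise_model(), seed = 99)
  expect_equal(as.data.frame(a1$neurons), as.data.frame(a2$neurons))
  expect_equal(as.data.frame(a1$links), as.data.frame(a2$links))

  empty <- sample_individual(tpl, noise_model(dropout_p = 1,
                                              fragment_rate = 0), seed = 3)
  expect_equal(nrow(empty$links), 0L)

  expect_error(sample_pair(tpl, noise_model(), 5, 5),
               class = "connstereo_config_error")
  # generation metadata records the seed
  expect_equal(a1$generation$seed, 99)
})

test_that("noise-free paired individuals are perfectly correlated", {
  pair <- sample_pair(make_default_template(), noise_free(), 1, 2)
  cmp <- correlate_grouped(
    align_matrices(build_grouped_matrix(pair$a, unassigned = "drop"),
                   build_grouped_matrix(pair$b, unassigned = "drop")),
    n_perm = 0)
  expect_equal(cmp$rho, 1.0)
})

test_that("Poisson sampling recovers template means (law of large numbers)", {
  tpl <- make_default_template()
  noise <- noise_model(dispersion = 0, dropout_p = 0, truncate_p = 0,
                       fragment_rate = 0)
  acc <- NULL
  n_rep <- 50
  for (i in seq_len(n_rep)) {
    g <- build_grouped_matrix(sample_individual(tpl, noise, seed = 7000 + i),
                              unassigned = "drop")
    acc <- if (is.null(acc)) unclass(g) else acc + unclass(g)
  }
  avg <- acc / n_rep
  one <- build_grouped_matrix(sample_individual(tpl, noise, seed = 1),
                              unassigned = "drop")
  roles <- attr(one, "roles")
  sizes <- attr(one, "sizes")
  w <- dplyr::filter(tpl$weights, roles[post] == "neuronal")
  # pair_mean of Poisson counts estimates the template weight directly; the
  # Monte-Carlo SE of each averaged entry is sqrt(w / (n_pairs * n_rep))
  n_pairs <- sizes[w$pre] * sizes[w$post]
  se <- sqrt(w$mean_weight / (n_pairs * n_rep))
  z <- (avg[cbind(w$pre, w$post)] - w$mean_weight) / se
  expect_true(all(abs(z) < 4))
  # ensemble unbiasedness within 2 Monte-Carlo SEs
  expect_lt(abs(mean(z)), 2 / sqrt(length(z)))
  # matrix-level recovery: total absolute deviation within 5% of total weight
  expect_lt(sum(abs(avg[cbind(w$pre, w$post)] - w$mean_weight)) /
              sum(w$mean_weight), 0.05)
})

test_that("moderate noise keeps paired individuals strongly correlated", {
  tpl <- make_default_template()
  noise <- noise_model(dispersion = 0.5, dropout_p = 0.05, truncate_p = 0,
                       fragment_rate = 0)
  rhos <- vapply(1:10, function(i) {
    pair <- sample_pair(tpl, noise, 100 + i, 900 + i)
    correlate_grouped(
      align_matrices(build_grouped_matrix(pair$a, unassigned = "drop"),
                     build_grouped_matrix(pair$b, unassigned = "drop")),
      n_perm = 0)$rho
  }, numeric(1))
  expect_gt(mean(rhos), 0.8)
})

test_that("fragments carry the untraceable-piece semantics", {
  x <- sample_individual(make_default_template(),
                         noise_model(fragment_rate = 50), seed = 31)
  frags <- dplyr::filter(x$neurons, status == "fragment")
  expect_gt(nrow(frags), 0)
  expect_true(all(!frags$has_soma))
  expect_true(all(is.na(frags$func_class)))
  # fragments never join the grouped analysis
  expect_false(any(grepl("^fragment", rownames(
    build_grouped_matrix(x, unassigned = "drop")))))
  # and their lengths are binnable
  fs <- classify_fragments(frags$cable_length_um)
  expect_equal(sum(fs$count), nrow(frags))
})

test_that("the asymmetric motoneuron outranks symmetric peers under Poisson sampling", {
  tpl <- make_default_template()
  noise <- noise_model(dispersion = 0, dropout_p = 0, truncate_p = 0,
                       fragment_rate = 0)
  hits <- vapply(1:30, function(i) {
    x <- sample_individual(tpl, noise, seed = 50000 + i)
    asymmetry_score(x, "MNr3_r1", "MN_l1") >
      asymmetry_score(x, "MN_r1", "MN_l1")
  }, logical(1))
  expect_true(all(hits))
})

test_that("template CSV serialisation round trips", {
  tpl <- make_default_template()
  dir <- withr::local_tempdir()
  write_template(tpl, dir)
  back <- read_template(dir)
  expect_equal(as.data.frame(back$weights), as.data.frame(tpl$weights))
  expect_equal(as.data.frame(back$groups), as.data.frame(tpl$groups))
  expect_equal(as.data.frame(back$reciprocal_motifs),
               as.data.frame(tpl$reciprocal_motifs))
})
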