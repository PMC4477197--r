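#' Ground-truth cell-type wiring template
#'
#' A wiring template is the group-level ground truth from which synthetic
#' individuals are sampled: a table of cell groups (`cell_type`, `side`,
#' `n_cells`, `func_class`) and a table of directed group-pair connections
#' with mean synapse counts per cell pair (`pre`, `post` group keys,
#' `mean_weight`). Reciprocal and left-right-asymmetric motifs are declared
#' explicitly so tests can target them.
#'
#' @param groups Tibble with columns `cell_type`, `side`, `n_cells`,
#'   `func_class`.
#' @param weights Tibble with columns `pre`, `post` (group keys) and
#'   `mean_weight` (nonnegative mean synapses per cell pair).
#' @param reciprocal_motifs Optional tibble (`a`, `b`) of group pairs wired
#'   in both directions.
#' @param asymmetric_motifs Optional tibble (`pre`, `post`) of directed
#'   group connections present on one side only (no mirrored counterpart).
#' @return A list of class `wiring_template`.
#' @export
wiring_template <- function(groups, weights, reciprocal_motifs = NULL,
                            asymmetric_motifs = NULL) {
  groups <- as_tibble(groups) |>
    mutate(group = group_key(.data$cell_type, .data$side))
  if (anyDuplicated(groups$group)) stop_config("duplicate template groups")
  if (any(groups$n_cells < 1)) stop_config("each group needs >= 1 cell")
  bad_fc <- setdiff(unique(groups$func_class), .func_classes)
  if (length(bad_fc)) {
    stop_config(paste0("unknown func_class in template: ",
                       paste(bad_fc, collapse = ", ")))
  }
  weights <- as_tibble(weights)
  unknown <- setdiff(unique(c(weights$pre, weights$post)), groups$group)
  if (length(unknown)) {
    stop_config(paste0("weight(s) reference unknown group(s): ",
                       paste(unknown, collapse = ", ")))
  }
  if (any(weights$mean_weight < 0)) stop_config("mean weights must be >= 0")
  has_edge <- function(p, q) {
    any(weights$pre == p & weights$post == q & weights$mean_weight > 0)
  }
  if (!is.null(reciprocal_motifs)) {
    ok <- purrr::map2_lgl(reciprocal_motifs$a, reciprocal_motifs$b,
                          function(a, b) has_edge(a, b) && has_edge(b, a))
    if (!all(ok)) stop_config("declared reciprocal motif lacks both directions")
  }
  if (!is.null(asymmetric_motifs)) {
    ok <- purrr::map2_lgl(asymmetric_motifs$pre, asymmetric_motifs$post,
                          function(p, q) has_edge(p, q) &&
                            !has_edge(mirror_key(p), mirror_key(q)))
    if (!all(ok)) stop_config("declared asymmetric motif is not one-sided")
  }
  structure(list(groups = groups, weights = weights,
                 reciprocal_motifs = reciprocal_motifs,
                 asymmetric_motifs = asymmetric_motifs),
            class = "wiring_template")
}

#' @export
print.wiring_template <- function(x, ...) {
  cat(sprintf("<wiring_template> %d groups (%d cells), %d directed group connections\n",
              nrow(x$groups), sum(x$groups$n_cells), nrow(x$weights)))
  invisible(x)
}

#' Default eye-circuit wiring template
#'
#' A fixed ground-truth template emulating the larval visual eye circuit's
#' feed-forward chain and its signature motifs. Photoreceptors of four eyes
#' (anterior and posterior, each side) project predominantly to the
#' *contralateral* primary interneurons (`IN1`), with a weak ipsilateral
#' branch from the posterior eyes only, so for every eye the crosswise
#' connection outweighs the ipsilateral one. The two `IN1` groups form a
#' strong reciprocal motif. `IN1` feeds trans-optic-neuropil (`INton`) and
#' intrinsic (`INint`) interneurons, which converge on Schnörkel
#' interneurons (`INsn`); each motoneuron group receives both ipsilateral
#' and contralateral `INsn` drive. Motoneurons innervate the contralateral
#' ciliary bands (prototroch, metatroch, paratrochs I-III) and longitudinal
#' muscles. One unpaired right-side motoneuron (`MNr3`) mirrors a left
#' motoneuron's effector output but additionally synapses onto
#' contralateral motoneurons — the template's left-right-asymmetric motif.
#' Projection interneurons (`INpro`) receive `INsn` input and connect
#' weakly to ventral-nerve-cord interneurons (`INvnc`), a developing trunk
#' circuit with little synaptic weight.
#'
#' @return A `wiring_template`.
#' @export
make_default_template <- function() {
  g <- function(type, n, fc) {
    tibble(cell_type = type, side = c("left", "right"), n_cells = n,
           func_class = fc)
  }
  groups <- bind_rows(
    g("PRCa", 2, "sensory"), g("PRCp", 2, "sensory"),
    g("IN1", 2, "interneuron"), g("INton", 1, "interneuron"),
    g("INint", 1, "interneuron"), g("INsn", 2, "interneuron"),
    tibble(cell_type = "MN", side = c("left", "right"), n_cells = c(3L, 2L),
           func_class = "motoneuron"),
    tibble(cell_type = "MNr3", side = "right", n_cells = 1L,
           func_class = "motoneuron"),
    g("INpro", 1, "interneuron"), g("INvnc", 1, "interneuron"),
    g("prototroch", 4, "effector"), g("metatroch", 2, "effector"),
    g("paratrochI", 2, "effector"), g("paratrochII", 2, "effector"),
    g("paratrochIII", 2, "effector"), g("muscle", 2, "effector")
  )
  w <- function(pre, post, mw) tibble(pre = pre, post = post, mean_weight = mw)
  both <- function(type_pre, type_post, mw, crossed = FALSE) {
    if (crossed) {
      bind_rows(w(group_key(type_pre, "left"), group_key(type_post, "right"), mw),
                w(group_key(type_pre, "right"), group_key(type_post, "left"), mw))
    } else {
      bind_rows(w(group_key(type_pre, "left"), group_key(type_post, "left"), mw),
                w(group_key(type_pre, "right"), group_key(type_post, "right"), mw))
    }
  }
  weights <- bind_rows(
    both("PRCa", "IN1", 6, crossed = TRUE),
    both("PRCp", "IN1", 6, crossed = TRUE),
    both("PRCp", "IN1", 1),                    # weak ipsilateral, posterior eyes
    both("IN1", "IN1", 5, crossed = TRUE),     # reciprocal IN1 motif
    both("IN1", "INton", 4), both("IN1", "INint", 4),
    both("INton", "INsn", 4), both("INint", "INsn", 4),
    both("INsn", "MN", 3), both("INsn", "MN", 3, crossed = TRUE),
    w("INsn.left", "MNr3.right", 3), w("INsn.right", "MNr3.right", 3),
    both("INsn", "INpro", 2),
    both("MN", "prototroch", 4, crossed = TRUE),
    both("MN", "metatroch", 2, crossed = TRUE),
    both("MN", "paratrochI", 2, crossed = TRUE),
    both("MN", "paratrochII", 2, crossed = TRUE),
    both("MN", "paratrochIII", 2, crossed = TRUE),
    both("MN", "muscle", 8, crossed = TRUE),
    w("MNr3.right", "prototroch.left", 4),
    w("MNr3.right", "metatroch.left", 2),
    w("MNr3.right", "paratrochI.left", 2),
    w("MNr3.right", "paratrochII.left", 2),
    w("MNr3.right", "paratrochIII.left", 2),
    w("MNr3.right", "muscle.left", 8),
    w("MNr3.right", "MN.left", 6),             # asymmetric contralateral-MN output
    both("INpro", "INvnc", 1)
  )
  wiring_template(
    groups, weights,
    reciprocal_motifs = tibble(a = "IN1.left", b = "IN1.right"),
    asymmetric_motifs = tibble(pre = "MNr3.right", post = "MN.left")
  )
}

#' Random wiring template over the default group structure
#'
#' Keeps the default template's cell groups but rewires them at random:
#' each directed group pair is connected with probability `density` and a
#' mean weight drawn uniformly from `weight_range`. The rewiring ignores
#' every biological constraint of the default template — including the rule
#' that effector cells have no output — so two such templates share no
#' structure at all beyond the group vocabulary: the null fixture for
#' correlation calibration.
#'
#' @param seed RNG seed.
#' @param density Connection probability per directed group pair.
#' @param weight_range Uniform range of mean weights.
#' @return A `wiring_template` (no declared motifs).
#' @export
random_template <- function(seed = NULL, density = 0.2,
                            weight_range = c(1, 8)) {
  groups <- make_default_template()$groups
  keys <- groups$group
  with_seed(seed, {
    pairs <- expand.grid(pre = keys, post = keys,
                         stringsAsFactors = FALSE) |>
      filter(.data$pre != .data$post)
    keep <- runif(nrow(pairs)) < density
    weights <- as_tibble(pairs[keep, , drop = FALSE]) |>
      mutate(mean_weight = runif(sum(keep), weight_range[1], weight_range[2]))
    wiring_template(select(groups, -"group"), weights)
  })
}

#' Observation-noise model for synthetic individuals
#'
#' Controls how a sampled individual deviates from the ground truth:
#' per-cell-pair synapse counts are Poisson around the template mean, with
#' a gamma-mixed (negative-binomial-like) overdispersion when
#' `dispersion > 0` (count variance `m + dispersion * m^2`); each realised
#' connection is independently unobserved with probability `dropout_p`;
#' each neuron is truncated with probability `truncate_p`, losing a
#' `truncate_frac` fraction of its outgoing links; and a Poisson number of
#' untraceable neurite fragments (mean `fragment_rate`) is added, with
#' log-normal cable lengths matched to the observed fragment-length bin
#' proportions. `deterministic = TRUE` replaces count sampling by rounding
#' the template mean — the noise-free mode in which paired individuals are
#' identical by construction.
#'
#' Defaults are the moderate-noise study conditions used throughout the
#' package's simulations: `dispersion = 0.5`, `dropout_p = 0.05`,
#' `truncate_p = 0.05`, `fragment_rate = 164` (the per-individual fragment
#' count observed in a full-body series).
#'
#' @param dispersion Overdispersion of per-cell-pair counts, `>= 0`.
#' @param dropout_p Probability a true connection goes unobserved.
#' @param truncate_p Probability a neuron is truncated.
#' @param truncate_frac Fraction of outgoing links a truncated neuron
#'   loses.
#' @param fragment_rate Expected untraceable fragments per individual.
#' @param deterministic Use rounded template means instead of sampled
#'   counts?
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(dispersion = 0.5, dropout_p = 0.05,
                        truncate_p = 0.05, truncate_frac = 0.5,
                        fragment_rate = 164, deterministic = FALSE) {
  probs <- c(dropout_p, truncate_p, truncate_frac)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must be in [0, 1]")
  if (dispersion < 0) stop_config("dispersion must be >= 0")
  if (fragment_rate < 0) stop_config("fragment_rate must be >= 0")
  structure(list(dispersion = dispersion, dropout_p = dropout_p,
                 truncate_p = truncate_p, truncate_frac = truncate_frac,
                 fragment_rate = fragment_rate,
                 deterministic = deterministic),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_free <- function() {
  noise_model(dispersion = 0, dropout_p = 0, truncate_p = 0,
              fragment_rate = 0, deterministic = TRUE)
}

# fragment cable lengths (µm): log-normal matched to the observed bin
# fractions 100/46/18 over [0,4), [4,40], (40,Inf)
rfragment_lengths <- function(n) rlnorm(n, meanlog = 0.71, sdlog = 2.42)

#' Sample one synthetic individual from a wiring template
#'
#' Instantiates the template's member neurons and draws per-cell-pair
#' synapse counts for every group-level connection under the given noise
#' model (see [noise_model()]); zero counts yield no link, autapses are
#' never generated. The draw is fully determined by `seed`; the seed and
#' noise parameters are recorded in the connectome's `generation` field.
#'
#' @param truth A `wiring_template`.
#' @param noise A `noise_model`.
#' @param seed RNG seed (required for reproducibility).
#' @param individual_id Label; default `"synth-<seed>"`.
#' @return A validated `connectome`.
#' @export
sample_individual <- function(truth, noise = noise_model(), seed,
                              individual_id = NULL) {
  stopifnot(inherits(truth, "wiring_template"), inherits(noise, "noise_model"))
  individual_id <- individual_id %||% sprintf("synth-%d", seed)
  with_seed(seed, {
    gs <- truth$groups
    member_ids <- purrr::pmap(gs, function(cell_type, side, n_cells,
                                           func_class, group) {
      sprintf("%s_%s%d", cell_type, substr(side, 1, 1), seq_len(n_cells))
    })
    names(member_ids) <- gs$group
    neurons <- purrr::pmap(gs, function(cell_type, side, n_cells,
                                        func_class, group) {
      neurons_tbl(id = sprintf("%s_%s%d", cell_type, substr(side, 1, 1),
                               seq_len(n_cells)),
                  cell_type = cell_type, side = side,
                  func_class = func_class,
                  cable_length_um = round(rlnorm(n_cells, log(120), 0.3), 1))
    }) |> bind_rows()

    links <- purrr::pmap(truth$weights, function(pre, post, mean_weight) {
      pairs <- expand.grid(pre_id = member_ids[[pre]],
                           post_id = member_ids[[post]],
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$pre_id != pairs$post_id, , drop = FALSE]
      np <- nrow(pairs)
      if (np == 0) return(NULL)
      counts <- if (noise$deterministic) {
        rep(round(mean_weight), np)
      } else if (noise$dispersion > 0) {
        lam <- rgamma(np, shape = 1 / noise$dispersion,
                      scale = mean_weight * noise$dispersion)
        rpois(np, lam)
      } else {
        rpois(np, mean_weight)
      }
      if (noise$dropout_p > 0) {
        counts[runif(np) < noise$dropout_p] <- 0L
      }
      pairs$count <- as.integer(counts)
      pairs[pairs$count > 0, , drop = FALSE]
    }) |> bind_rows()

    # truncation: distal outgoing links lost
    if (noise$truncate_p > 0 && nrow(links) > 0) {
      candidates <- neurons$id[neurons$func_class != "effector"]
      truncated <- candidates[runif(length(candidates)) < noise$truncate_p]
      if (length(truncated)) {
        neurons$status[neurons$id %in% truncated] <- "truncated"
        keep <- rep(TRUE, nrow(links))
        for (id in truncated) {
          idx <- which(links$pre_id == id)
          k <- round(noise$truncate_frac * length(idx))
          if (k > 0) keep[sample(idx, k)] <- FALSE
        }
        links <- links[keep, , drop = FALSE]
      }
    }

    n_frag <- if (noise$fragment_rate > 0) rpois(1, noise$fragment_rate) else 0L
    if (n_frag > 0) {
      neurons <- bind_rows(
        neurons,
        neurons_tbl(id = sprintf("frag_%03d", seq_len(n_frag)),
                    cell_type = "fragment", side = "unpaired",
                    func_class = NA_character_, status = "fragment",
                    cable_length_um = round(rfragment_lengths(n_frag), 2),
                    has_soma = FALSE))
    }

    x <- connectome(neurons, links, individual_id = individual_id)
    x$generation <- c(list(seed = seed), unclass(noise))
    x
  })
}

#' Sample a pair of synthetic individuals
#'
#' Two independent draws from the same ground-truth template — the
#' synthetic analogue of reconstructing the same circuit in two larvae of
#' the same age, and the end-to-end fixture for the comparison pipeline.
#'
#' @param truth A `wiring_template`.
#' @param noise A `noise_model` applied to both individuals.
#' @param seed_a,seed_b Distinct RNG seeds for the two draws.
#' @return A list with `connectome` elements `a` and `b`.
#' @export
sample_pair <- function(truth, noise = noise_model(), seed_a, seed_b) {
  if (identical(seed_a, seed_b)) {
    stop_config("seed_a and seed_b must differ: the two individuals are independent draws")
  }
  list(a = sample_individual(truth, noise, seed_a),
       b = sample_individual(truth, noise, seed_b))
}

#' Serialise / load a wiring template
#'
#' Written as two CSVs in `dir`: `groups.csv` (cell_type, side, n_cells,
#' func_class) and `weights.csv` (pre, post, mean_weight). Motif
#' declarations, when present, go to `reciprocal_motifs.csv` and
#' `asymmetric_motifs.csv`.
#'
#' @param truth A `wiring_template`.
#' @param dir Directory to write to / read from.
#' @return `write_template()`: the directory, invisibly;
#'   `read_template()`: a `wiring_template`.
#' @export
write_template <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(select(truth$groups, -"group"),
                   file.path(dir, "groups.csv"))
  readr::write_csv(truth$weights, file.path(dir, "weights.csv"))
  if (!is.null(truth$reciprocal_motifs)) {
    readr::write_csv(truth$reciprocal_motifs,
                     file.path(dir, "reciprocal_motifs.csv"))
  }
  if (!is.null(truth$asymmetric_motifs)) {
    readr::write_csv(truth$asymmetric_motifs,
                     file.path(dir, "asymmetric_motifs.csv"))
  }
  invisible(dir)
}

#' @rdname write_template
#' @export
read_template <- function(dir) {
  groups <- read_csv_checked(file.path(dir, "groups.csv"),
                             c("cell_type", "side", "n_cells", "func_class"),
                             "template group")
  weights <- read_csv_checked(file.path(dir, "weights.csv"),
                              c("pre", "post", "mean_weight"),
                              "template weight")
  rm_path <- file.path(dir, "reciprocal_motifs.csv")
  am_path <- file.path(dir, "asymmetric_motifs.csv")
  wiring_template(
    groups, weights,
    reciprocal_motifs = if (file.exists(rm_path)) {
      read_csv_checked(rm_path, c("a", "b"), "reciprocal motif")
    },
    asymmetric_motifs = if (file.exists(am_path)) {
      read_csv_checked(am_path, c("pre", "post"), "asymmetric motif")
    })
}
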