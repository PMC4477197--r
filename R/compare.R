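#' Align two grouped matrices on their shared group keys
#'
#' Restricts both matrices to the `(cell_type, side)` group keys present in
#' both individuals, in a common order, and reports the keys found in only
#' one of them (e.g. a cell type identified in only one animal) — those are
#' excluded from any correlation.
#'
#' @param m_a,m_b `grouped_matrix` objects sharing a group-key vocabulary.
#' @return A list of class `aligned_pair`: `shared_keys`, `m_a`, `m_b`
#'   (restricted and reordered), `dropped_a`, `dropped_b`.
#' @export
align_matrices <- function(m_a, m_b) {
  ka <- rownames(m_a); kb <- rownames(m_b)
  shared <- intersect(ka, kb)
  if (length(shared) == 0) {
    stop_comparison("the two matrices share no group keys")
  }
  sub <- function(m, keys) {
    out <- unclass_matrix(m)[keys, keys, drop = FALSE]
    structure(out, roles = attr(m, "roles")[keys],
              sizes = attr(m, "sizes")[keys],
              neuron_agg = attr(m, "neuron_agg"),
              truncated_groups = intersect(attr(m, "truncated_groups"), keys),
              class = c("grouped_matrix", "matrix", "array"))
  }
  structure(list(shared_keys = shared,
                 m_a = sub(m_a, shared), m_b = sub(m_b, shared),
                 dropped_a = setdiff(ka, shared),
                 dropped_b = setdiff(kb, shared)),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %d shared groups; dropped A: %d, B: %d\n",
              length(x$shared_keys), length(x$dropped_a),
              length(x$dropped_b)))
  invisible(x)
}

# Spearman rho with midrank ties: Pearson correlation of the rank vectors.
spearman_rho <- function(x, y) cor(rank(x), rank(y))

# flatten the off-diagonal cells of an aligned pair under a zero policy
aligned_cells <- function(pair, zero_policy) {
  a <- unclass_matrix(pair$m_a); b <- unclass_matrix(pair$m_b)
  off <- row(a) != col(a)
  keep <- switch(zero_policy,
    all_cells = off,
    union_support = off & (a > 0 | b > 0)
  )
  list(a = a[keep], b = b[keep])
}

#' Correlate two aligned grouped matrices
#'
#' Measures global wiring stereotypy as the Spearman rank correlation of the
#' flattened off-diagonal cells of the two aligned grouped matrices (average
#' ranks for ties). Significance comes from a permutation test: the cells of
#' one matrix are randomly permuted `n_perm` times and the two-sided p-value
#' is `(1 + #{|rho*| >= |rho|}) / (n_perm + 1)` — the add-one correction
#' makes the smallest reportable p at `n_perm = 10000` equal to about 1e-4.
#'
#' Diagonal (self-group) cells are excluded: with autapse-free data they are
#' structurally depressed. `zero_policy` chooses which cells enter: every
#' aligned cell including double zeros (`"all_cells"`, a literal matrix
#' correlation), or only cells with at least one synapse in either
#' individual (`"union_support"`, which avoids inflation by shared
#' structural zeros).
#'
#' @param pair An `aligned_pair` from [align_matrices()].
#' @param n_perm Number of permutations (default 10000; 0 skips the test and
#'   reports `p_perm = NA`).
#' @param seed RNG seed for the permutations; recorded in the result.
#' @param zero_policy `"all_cells"` (default) or `"union_support"`.
#' @return A list of class `stereotypy_cor`: `rho`, `p_perm`, `n_cells`,
#'   `n_perm`, `seed`, `zero_policy`.
#' @export
correlate_grouped <- function(pair, n_perm = 10000, seed = NULL,
                              zero_policy = c("all_cells", "union_support")) {
  zero_policy <- match.arg(zero_policy)
  cells <- aligned_cells(pair, zero_policy)
  if (length(cells$a) < 3) {
    stop_comparison("fewer than 3 matrix cells to compare")
  }
  if (length(unique(cells$a)) < 2 || length(unique(cells$b)) < 2) {
    stop_degenerate("correlation undefined: a matrix is constant over the compared cells")
  }
  ra <- rank(cells$a); rb <- rank(cells$b)
  rho <- cor(ra, rb)
  p <- NA_real_
  if (n_perm > 0) {
    p <- with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm),
                         function(i) abs(cor(ra, sample(rb))) >= abs(rho) - 1e-12,
                         logical(1)))
      (1 + hits) / (n_perm + 1)
    })
  }
  structure(list(rho = rho, p_perm = p, n_cells = length(cells$a),
                 n_perm = n_perm, seed = seed, zero_policy = zero_policy),
            class = "stereotypy_cor")
}

#' @export
print.stereotypy_cor <- function(x, ...) {
  cat(sprintf(
    "<stereotypy_cor> Spearman rho = %.3f (p_perm = %s; %d cells, %d permutations, policy %s)\n",
    x$rho, format(x$p_perm, digits = 3), x$n_cells, x$n_perm, x$zero_policy))
  invisible(x)
}

#' @method tidy stereotypy_cor
#' @export
tidy.stereotypy_cor <- function(x, ...) {
  tibble(estimate = x$rho, p.value = x$p_perm, n_cells = x$n_cells,
         n_perm = x$n_perm, zero_policy = x$zero_policy,
         seed = x$seed %||% NA_integer_)
}

#' @method glance stereotypy_cor
#' @export
glance.stereotypy_cor <- function(x, ...) tidy.stereotypy_cor(x, ...)

#' Geometric-mean combined matrix of two individuals
#'
#' Cell-wise geometric mean `sqrt(a * b)` of the two aligned grouped
#' matrices. A combined entry is nonzero only where the connection is
#' present in *both* animals, so the support of the result is exactly the
#' intersection of the two supports; each combined weight lies between the
#' two individual weights.
#'
#' @param pair An `aligned_pair`.
#' @return A `grouped_matrix` over the shared keys.
#' @export
combine_geometric_mean <- function(pair) {
  a <- unclass_matrix(pair$m_a); b <- unclass_matrix(pair$m_b)
  m <- sqrt(a * b)
  structure(m, roles = attr(pair$m_a, "roles"),
            sizes = attr(pair$m_a, "sizes"),
            neuron_agg = attr(pair$m_a, "neuron_agg"),
            truncated_groups = union(attr(pair$m_a, "truncated_groups"),
                                     attr(pair$m_b, "truncated_groups")),
            class = c("grouped_matrix", "matrix", "array"))
}

#' Per-cell-type pre- and postsynaptic correlation profiles
#'
#' For each cell-type group shared by the two individuals, correlates the
#' group's presynaptic profile (its grouped outgoing-connection vector over
#' the shared partner groups) and its postsynaptic profile (the incoming
#' vector) between individuals, with the same Spearman/permutation machinery
#' as [correlate_grouped()]. A profile constant in either individual yields
#' `NA` correlations (recorded, not an error). Groups whose members carry
#' fewer total synapses than `weak_floor` in either individual are flagged
#' `weakly_connected` — such groups are the ones expected to fail to
#' correlate; groups containing truncated members are flagged
#' `truncated_member`.
#'
#' @param conn_a,conn_b Two `connectome` objects.
#' @param scheme_a,scheme_b Grouping schemes; default [type_side_scheme()].
#' @param neuron_agg Averaging convention, see [build_grouped_matrix()].
#' @param weak_floor Minimum total (in + out) synapses per group; default 5.
#' @param n_perm Permutations per profile (default 1000).
#' @param seed RNG seed.
#' @param unassigned Policy for neurons missing from a scheme, see
#'   [build_grouped_matrix()].
#' @return A tibble with one row per shared group: `group`, `pre_rho`,
#'   `pre_p`, `post_rho`, `post_p`, `weakly_connected`, `truncated_member`,
#'   plus attributes `dropped_a`/`dropped_b` (keys compared in one
#'   individual only).
#' @export
per_type_correlations <- function(conn_a, conn_b,
                                  scheme_a = NULL, scheme_b = NULL,
                                  neuron_agg = "pair_mean", weak_floor = 5,
                                  n_perm = 1000, seed = NULL,
                                  unassigned = "drop") {
  scheme_a <- scheme_a %||% type_side_scheme(conn_a)
  scheme_b <- scheme_b %||% type_side_scheme(conn_b)
  ga <- build_grouped_matrix(conn_a, scheme_a, neuron_agg = neuron_agg,
                             unassigned = unassigned)
  gb <- build_grouped_matrix(conn_b, scheme_b, neuron_agg = neuron_agg,
                             unassigned = unassigned)
  pair <- align_matrices(ga, gb)
  keys <- pair$shared_keys
  a <- unclass_matrix(pair$m_a); b <- unclass_matrix(pair$m_b)

  group_total <- function(x, scheme, key) {
    ids <- scheme$neuron_id[scheme$group == key]
    sum(x$links$count[x$links$pre_id %in% ids | x$links$post_id %in% ids])
  }
  trunc_in <- function(x, scheme, key) {
    ids <- scheme$neuron_id[scheme$group == key]
    any(x$neurons$status[x$neurons$id %in% ids] == "truncated")
  }
  cor_one <- function(va, vb, s) {
    if (length(unique(va)) < 2 || length(unique(vb)) < 2) {
      return(c(NA_real_, NA_real_))
    }
    ra <- rank(va); rb <- rank(vb)
    rho <- cor(ra, rb)
    p <- with_seed(s, {
      hits <- sum(vapply(seq_len(n_perm),
                         function(i) abs(cor(ra, sample(rb))) >= abs(rho) - 1e-12,
                         logical(1)))
      (1 + hits) / (n_perm + 1)
    })
    c(rho, p)
  }

  rows <- purrr::imap(keys, function(key, i) {
    others <- keys != key          # own-group cell excluded, as in the global test
    sub_seed <- if (!is.null(seed)) seed + i
    pre <- cor_one(a[key, others], b[key, others], sub_seed)
    post <- cor_one(a[others, key], b[others, key],
                    if (!is.null(sub_seed)) sub_seed + length(keys))
    tibble(group = key, pre_rho = pre[1], pre_p = pre[2],
           post_rho = post[1], post_p = post[2],
           weakly_connected =
             group_total(conn_a, scheme_a, key) < weak_floor ||
             group_total(conn_b, scheme_b, key) < weak_floor,
           truncated_member =
             trunc_in(conn_a, scheme_a, key) || trunc_in(conn_b, scheme_b, key))
  })
  out <- bind_rows(rows)
  attr(out, "dropped_a") <- pair$dropped_a
  attr(out, "dropped_b") <- pair$dropped_b
  out
}

#' Left-right asymmetry score of a neuron against its bilateral homolog
#'
#' Quantifies how far a neuron's output deviates from the mirror image of
#' its homolog's output. Each neuron is represented by its partner-group
#' connection vector (summed synapses onto every group of the scheme); the
#' homolog's vector is mirrored across the midline (left and right partner
#' groups swapped) and the score is one minus the cosine similarity of the
#' two vectors. A perfectly mirror-symmetric pair scores 0; a neuron whose
#' output targets entirely different partner groups than its mirrored
#' homolog (e.g. a motoneuron uniquely synapsing onto contralateral
#' motoneurons) scores 1.
#'
#' @param x A `connectome`.
#' @param neuron_id,homolog_id Ids of the neuron and its contralateral
#'   homolog.
#' @param scheme Grouping scheme defining the partner groups; default
#'   [type_side_scheme()].
#' @return A number in `[0, 1]`.
#' @export
asymmetry_score <- function(x, neuron_id, homolog_id, scheme = NULL) {
  scheme <- scheme %||% type_side_scheme(x)
  unknown <- setdiff(c(neuron_id, homolog_id), x$neurons$id)
  if (length(unknown)) {
    stop_referential(paste0("unknown neuron id(s): ",
                            paste(unknown, collapse = ", ")))
  }
  keys <- unique(scheme$group)
  grp_of <- stats::setNames(scheme$group, scheme$neuron_id)
  out_vec <- function(id) {
    lk <- filter(x$links, .data$pre_id == id,
                 .data$post_id %in% names(grp_of))
    v <- stats::setNames(numeric(length(keys)), keys)
    if (nrow(lk) > 0) {
      s <- lk |>
        mutate(g = grp_of[.data$post_id]) |>
        group_by(.data$g) |>
        summarise(total = sum(.data$count), .groups = "drop")
      v[s$g] <- s$total
    }
    v
  }
  v <- out_vec(neuron_id)
  w <- out_vec(homolog_id)
  # mirror the homolog: its synapses onto group k count toward mirror_key(k)
  wm <- stats::setNames(numeric(length(keys)), keys)
  mk <- mirror_key(names(w))
  ok <- mk %in% keys
  wm[mk[ok]] <- wm[mk[ok]] + w[ok]
  if (sum(v) == 0 && sum(wm) == 0) {
    stop_degenerate("both connection vectors are zero; asymmetry undefined")
  }
  if (sum(v) == 0 || sum(wm) == 0) return(1)
  1 - sum(v * wm) / sqrt(sum(v^2) * sum(wm^2))
}

#' End-to-end stereotypy comparison of two connectomes
#'
#' Runs the full comparison stage: builds the grouped matrices, aligns them,
#' computes the global Spearman correlation with permutation p-value, the
#' geometric-mean combined matrix, and the per-cell-type pre/post
#' correlation profiles.
#'
#' @inheritParams per_type_correlations
#' @param n_perm Permutations for the global test (default 10000).
#' @param n_perm_type Permutations per per-type profile (default 1000).
#' @param zero_policy Cell-selection policy, see [correlate_grouped()].
#' @return A list of class `stereotypy_comparison`: `grouped_a`,
#'   `grouped_b`, `aligned`, `global` (a `stereotypy_cor`), `combined`
#'   (a `grouped_matrix`), `per_type` (tibble).
#' @export
compare_connectomes <- function(conn_a, conn_b,
                                scheme_a = NULL, scheme_b = NULL,
                                neuron_agg = "pair_mean",
                                zero_policy = "all_cells",
                                n_perm = 10000, n_perm_type = 1000,
                                weak_floor = 5, seed = NULL,
                                unassigned = "drop") {
  scheme_a <- scheme_a %||% type_side_scheme(conn_a)
  scheme_b <- scheme_b %||% type_side_scheme(conn_b)
  ga <- build_grouped_matrix(conn_a, scheme_a, neuron_agg = neuron_agg,
                             unassigned = unassigned)
  gb <- build_grouped_matrix(conn_b, scheme_b, neuron_agg = neuron_agg,
                             unassigned = unassigned)
  pair <- align_matrices(ga, gb)
  global <- correlate_grouped(pair, n_perm = n_perm, seed = seed,
                              zero_policy = zero_policy)
  per_type <- per_type_correlations(conn_a, conn_b, scheme_a, scheme_b,
                                    neuron_agg = neuron_agg,
                                    weak_floor = weak_floor,
                                    n_perm = n_perm_type,
                                    seed = if (!is.null(seed)) seed + 1L,
                                    unassigned = unassigned)
  structure(list(individuals = c(conn_a$individual_id, conn_b$individual_id),
                 grouped_a = ga, grouped_b = gb, aligned = pair,
                 global = global, combined = combine_geometric_mean(pair),
                 per_type = per_type),
            class = "stereotypy_comparison")
}

#' @export
print.stereotypy_comparison <- function(x, ...) {
  cat(sprintf("<stereotypy_comparison> %s vs %s\n",
              x$individuals[1], x$individuals[2]))
  print(x$aligned)
  print(x$global)
  n_sig <- sum(x$per_type$pre_p < 0.05 | x$per_type$post_p < 0.05,
               na.rm = TRUE)
  cat(sprintf("  per-type profiles: %d groups, %d with p < 0.05 (pre or post)\n",
              nrow(x$per_type), n_sig))
  invisible(x)
}

#' @method tidy stereotypy_comparison
#' @export
tidy.stereotypy_comparison <- function(x, ...) x$per_type

#' @method glance stereotypy_comparison
#' @export
glance.stereotypy_comparison <- function(x, ...) {
  tidy.stereotypy_cor(x$global) |>
    mutate(n_shared_groups = length(x$aligned$shared_keys),
           n_combined_connections = sum(unclass_matrix(x$combined) > 0))
}

#' Write a comparison report bundle
#'
#' Writes the grouped matrices, combined matrix and per-type profile table
#' as CSV, and a JSON summary holding the global correlation together with
#' its seed, permutation count and zero policy, plus the dropped-group
#' lists, so a re-run with the same configuration reproduces every number.
#'
#' @param x A `stereotypy_comparison`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_comparison <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(grouped_a = file.path(dir, "grouped_a.csv"),
             grouped_b = file.path(dir, "grouped_b.csv"),
             combined = file.path(dir, "combined.csv"),
             per_type = file.path(dir, "per_type.csv"),
             summary = file.path(dir, "summary.json"))
  write_matrix_csv(x$grouped_a, paths["grouped_a"])
  write_matrix_csv(x$grouped_b, paths["grouped_b"])
  write_matrix_csv(x$combined, paths["combined"])
  readr::write_csv(x$per_type, paths["per_type"])
  jsonlite::write_json(
    list(individuals = x$individuals,
         global = unclass(x$global),
         dropped_a = x$aligned$dropped_a, dropped_b = x$aligned$dropped_b),
    paths["summary"], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
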