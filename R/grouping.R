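#' Build a cell-type-by-side grouping scheme
#'
#' The stereotypy analysis aggregates single cells into groups keyed by
#' `(cell_type, side)`: connections are computed separately for cells with
#' their soma on the left or right body side, and unpaired midline cells
#' form their own stratum. Groups of effector cells (ciliary-band and muscle
#' cells) get role `"effector"`; all other groups are `"neuronal"`.
#'
#' Fragments are excluded by default: they cannot be assigned to a cell type
#' and are not part of the grouped analysis.
#'
#' @param x A `connectome` or a neuron tibble.
#' @param include_fragments Keep fragment cells (as their own
#'   `fragment.unpaired` group)? Default `FALSE`.
#' @return A tibble of class `grouping_scheme` with columns `neuron_id`,
#'   `cell_type`, `side`, `group`, `role`.
#' @export
type_side_scheme <- function(x, include_fragments = FALSE) {
  nn <- if (inherits(x, "connectome")) x$neurons else as_tibble(x)
  if (!include_fragments) nn <- filter(nn, .data$status != "fragment")
  out <- nn |>
    mutate(neuron_id = .data$id,
           group = group_key(.data$cell_type, .data$side),
           role = ifelse(!is.na(.data$func_class) &
                           .data$func_class == "effector",
                         "effector", "neuronal")) |>
    select("neuron_id", "cell_type", "side", "group", "role")
  new_scheme(out)
}

new_scheme <- function(tbl) {
  tbl <- as_tibble(tbl)
  if (anyDuplicated(tbl$neuron_id)) {
    stop_config(paste0("neuron(s) assigned to more than one group: ",
                       paste(unique(tbl$neuron_id[duplicated(tbl$neuron_id)]),
                             collapse = ", ")))
  }
  if (any(!nzchar(tbl$group) | is.na(tbl$group))) {
    stop_config("empty group key in scheme")
  }
  structure(tbl, class = c("grouping_scheme", class(tbl)))
}

#' Serialise a grouping scheme
#'
#' Written as a two-column CSV (`neuron_id,group_key`); reading requires the
#' connectome so cell types, sides and roles can be restored from the neuron
#' table.
#'
#' @param scheme A `grouping_scheme`.
#' @param path CSV path.
#' @param x The `connectome` whose neurons the scheme partitions.
#' @return The path (write) or a `grouping_scheme` (read).
#' @export
write_scheme <- function(scheme, path) {
  readr::write_csv(tibble(neuron_id = scheme$neuron_id,
                          group_key = scheme$group), path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path, x) {
  df <- read_csv_checked(path, c("neuron_id", "group_key"), "scheme")
  nn <- x$neurons
  unknown <- setdiff(df$neuron_id, nn$id)
  if (length(unknown)) {
    stop_referential(paste0("scheme references unknown neuron id(s): ",
                            paste(unknown, collapse = ", ")))
  }
  out <- df |>
    left_join(nn, by = c(neuron_id = "id")) |>
    mutate(group = .data$group_key,
           role = ifelse(!is.na(.data$func_class) &
                           .data$func_class == "effector",
                         "effector", "neuronal")) |>
    select("neuron_id", "cell_type", "side", "group", "role")
  new_scheme(out)
}

#' Full single-cell connectivity matrix
#'
#' Square synapse-count matrix over all neurons of a connectome; entry
#' `(i, j)` is the number of synapses from neuron `i` onto neuron `j`.
#'
#' @param x A `connectome`.
#' @return An integer matrix with neuron ids as dimnames, class
#'   `full_matrix`.
#' @export
build_full_matrix <- function(x) {
  ids <- x$neurons$id
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(x$links) > 0) {
    m[cbind(x$links$pre_id, x$links$post_id)] <- x$links$count
  }
  structure(m, class = c("full_matrix", class(m)))
}

#' Cell-type-grouped connectivity matrix
#'
#' Aggregates the single-cell matrix over a grouping scheme. Connections
#' onto neuronal groups use the *averaged* synapse number; connections onto
#' effector groups use the *total* synapse number (ciliary bands and muscles
#' are read out as summed drive). Two averaging conventions are offered:
#'
#' * `pair_mean` (default): the inter-group synapse total divided by the
#'   number of cell pairs `|G| * |H|` — symmetric in the two group sizes and
#'   bounded by the per-pair counts;
#' * `per_pre_mean`: divided by the presynaptic group size `|G|` only.
#'
#' @param x A `connectome`.
#' @param scheme A `grouping_scheme`; default [type_side_scheme()] of `x`.
#' @param neuron_agg Averaging convention for neuronal target groups.
#' @param unassigned Policy for neurons absent from the scheme: `"error"`
#'   (default), `"drop"` (exclude them, replicating the study-style
#'   exclusion of cells outside the circuit), or `"singleton"` (each becomes
#'   its own group).
#' @return A numeric matrix of class `grouped_matrix` with group keys as
#'   dimnames and attributes `roles` (named role per group), `sizes` (group
#'   sizes), `neuron_agg`, and `truncated_groups` (keys containing at least
#'   one truncated member, so downstream stages can flag or exclude them).
#' @export
build_grouped_matrix <- function(x, scheme = NULL,
                                 neuron_agg = c("pair_mean", "per_pre_mean"),
                                 unassigned = c("error", "drop", "singleton")) {
  neuron_agg <- match.arg(neuron_agg)
  unassigned <- match.arg(unassigned)
  scheme <- scheme %||% type_side_scheme(x)
  nn <- x$neurons
  missing_ids <- setdiff(nn$id, scheme$neuron_id)
  if (length(missing_ids)) {
    if (unassigned == "error") {
      stop_config(paste0("neuron(s) not covered by the grouping scheme: ",
                         paste(missing_ids, collapse = ", ")))
    }
    if (unassigned == "singleton") {
      extra <- nn |>
        filter(.data$id %in% missing_ids) |>
        mutate(neuron_id = .data$id, group = .data$id,
               role = ifelse(!is.na(.data$func_class) &
                               .data$func_class == "effector",
                             "effector", "neuronal")) |>
        select("neuron_id", "cell_type", "side", "group", "role")
      scheme <- new_scheme(bind_rows(as_tibble(scheme), extra))
    }
  }
  extra_sch <- setdiff(scheme$neuron_id, nn$id)
  if (length(extra_sch)) {
    stop_referential(paste0("scheme references unknown neuron id(s): ",
                            paste(extra_sch, collapse = ", ")))
  }

  keys <- unique(scheme$group)
  sizes <- table(factor(scheme$group, levels = keys))
  roles <- scheme |> distinct(.data$group, .data$role)
  if (anyDuplicated(roles$group)) {
    stop_config("groups mixing effector and neuronal members are not allowed")
  }
  role_vec <- stats::setNames(roles$role, roles$group)[keys]

  grp_of <- stats::setNames(scheme$group, scheme$neuron_id)
  lk <- x$links |>
    filter(.data$pre_id %in% scheme$neuron_id,
           .data$post_id %in% scheme$neuron_id)
  m <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
  if (nrow(lk) > 0) {
    sums <- lk |>
      mutate(g = grp_of[.data$pre_id], h = grp_of[.data$post_id]) |>
      group_by(.data$g, .data$h) |>
      summarise(total = sum(.data$count), .groups = "drop")
    m[cbind(sums$g, sums$h)] <- sums$total
  }
  size_vec <- as.numeric(sizes)
  denom <- switch(neuron_agg,
    pair_mean = outer(size_vec, size_vec),
    per_pre_mean = matrix(size_vec, length(keys), length(keys))
  )
  neuronal_cols <- role_vec[colnames(m)] == "neuronal"
  m[, neuronal_cols] <- m[, neuronal_cols] / denom[, neuronal_cols]

  trunc_ids <- nn$id[nn$status == "truncated"]
  truncated_groups <- unique(grp_of[names(grp_of) %in% trunc_ids])
  structure(m,
            roles = role_vec, sizes = stats::setNames(size_vec, keys),
            neuron_agg = neuron_agg, truncated_groups = truncated_groups,
            class = c("grouped_matrix", "matrix", "array"))
}

#' Tidy a connectivity matrix into long format
#'
#' @param x A `grouped_matrix` or `full_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `pre`, `post`, `weight` (nonzero entries
#'   only).
#' @method as_tibble grouped_matrix
#' @export
as_tibble.grouped_matrix <- function(x, ...) {
  m <- unclass_matrix(x)
  idx <- which(m != 0, arr.ind = TRUE)
  tibble(pre = rownames(m)[idx[, 1]], post = colnames(m)[idx[, 2]],
         weight = m[idx]) |>
    arrange(.data$pre, .data$post)
}

#' @method as_tibble full_matrix
#' @export
as_tibble.full_matrix <- as_tibble.grouped_matrix

unclass_matrix <- function(x) {
  attr(x, "roles") <- NULL
  attr(x, "sizes") <- NULL
  attr(x, "neuron_agg") <- NULL
  attr(x, "truncated_groups") <- NULL
  class(x) <- NULL
  x
}

#' Reciprocal connection strength between all cell pairs
#'
#' The strength of a reciprocal connection between neurons A and B is the
#' geometric mean of the synapse count from A onto B and the count from B
#' onto A: `sqrt(s_AB * s_BA)`. The result is symmetric and is zero whenever
#' either direction lacks synapses, so only genuinely reciprocal pairs score
#' above zero.
#'
#' @param full A square single-cell connectivity matrix (see
#'   [build_full_matrix()]).
#' @return A symmetric numeric matrix with the same dimnames.
#' @export
reciprocal_strength_matrix <- function(full) {
  m <- unclass_matrix(full)
  if (nrow(m) != ncol(m)) stop_validation("matrix must be square")
  sqrt(m * t(m))
}

#' Reclassify motoneuron candidates by effector output
#'
#' A candidate keeps the motoneuron label only if it forms at least one
#' synapse onto an effector cell; candidates with no effector output are
#' relabeled `INpro_candidate` (putative projection interneurons whose
#' effector connections were never observed).
#'
#' @param x A `connectome`.
#' @param candidate_ids Ids of the motoneuron candidates.
#' @return A tibble with columns `id`, `n_effector_synapses`, `label`.
#' @export
reclassify_motoneurons <- function(x, candidate_ids) {
  unknown <- setdiff(candidate_ids, x$neurons$id)
  if (length(unknown)) {
    stop_referential(paste0("unknown candidate id(s): ",
                            paste(unknown, collapse = ", ")))
  }
  eff_ids <- x$neurons$id[!is.na(x$neurons$func_class) &
                            x$neurons$func_class == "effector"]
  out_eff <- x$links |>
    filter(.data$pre_id %in% candidate_ids, .data$post_id %in% eff_ids) |>
    group_by(.data$pre_id) |>
    summarise(n_effector_synapses = sum(.data$count), .groups = "drop")
  tibble(id = candidate_ids) |>
    left_join(out_eff, by = c(id = "pre_id")) |>
    mutate(n_effector_synapses = ifelse(is.na(.data$n_effector_synapses), 0L,
                                        .data$n_effector_synapses),
           label = ifelse(.data$n_effector_synapses >= 1L, "MN",
                          "INpro_candidate"))
}
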