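#' Motoneuron-by-effector innervation table
#'
#' Summed synapse counts from each motoneuron onto every effector group of
#' the scheme (ciliary bands and muscle classes, per side). With
#' `merge_bands = TRUE` the metatroch and paratroch columns are pooled into
#' one `metatroch_paratroch.<side>` column per side — the band-merged
#' readout of trunk ciliary drive. Incompletely traced motoneurons carry a
#' `truncated` marker.
#'
#' @param x A `connectome`.
#' @param scheme A `grouping_scheme`; default [type_side_scheme()].
#' @param merge_bands Pool metatroch with paratrochs? Default `FALSE`.
#' @return A tibble of class `innervation_table`: one row per motoneuron
#'   with `mn_id`, `truncated`, and one integer column per effector group.
#' @export
innervation_summary <- function(x, scheme = NULL, merge_bands = FALSE) {
  scheme <- scheme %||% type_side_scheme(x)
  mn <- x$neurons |>
    filter(!is.na(.data$func_class), .data$func_class == "motoneuron")
  eff <- filter(as_tibble(scheme), .data$role == "effector")
  eff_groups <- unique(eff$group)
  if (merge_bands && length(eff_groups)) {
    eff <- eff |>
      mutate(group = ifelse(
        .data$cell_type %in% "metatroch" |
          grepl("^paratroch", .data$cell_type),
        group_key("metatroch_paratroch", .data$side), .data$group))
    eff_groups <- unique(eff$group)
  }
  grp_of <- stats::setNames(eff$group, eff$neuron_id)
  m <- matrix(0L, nrow(mn), length(eff_groups),
              dimnames = list(mn$id, eff_groups))
  lk <- x$links |>
    filter(.data$pre_id %in% mn$id, .data$post_id %in% eff$neuron_id)
  if (nrow(lk) > 0) {
    sums <- lk |>
      mutate(g = grp_of[.data$post_id]) |>
      group_by(.data$pre_id, .data$g) |>
      summarise(total = sum(.data$count), .groups = "drop")
    m[cbind(sums$pre_id, sums$g)] <- as.integer(sums$total)
  }
  out <- tibble(mn_id = mn$id, truncated = mn$status == "truncated") |>
    bind_cols(as_tibble(as.data.frame(m)))
  structure(out, class = c("innervation_table", class(out)))
}

#' Prototroch tier innervation totals
#'
#' The prototroch ciliary band is organised into an anterior and a
#' posterior tier; tier membership is anatomical input, not inferred. This
#' sums motoneuron synapses per tier and reports whether innervation is
#' confined to the posterior tier (`posterior_only`: anterior total zero
#' and posterior total positive; an empty innervation is not
#' posterior-only).
#'
#' @param x A `connectome`.
#' @param tier_map Tibble with columns `prototroch_id`, `tier` (values
#'   `"anterior"`/`"posterior"`), covering every prototroch cell.
#' @return A tibble with columns `tier` and `total`, plus attribute
#'   `posterior_only` (also via [posterior_only()]).
#' @export
tier_innervation <- function(x, tier_map) {
  tier_map <- as_tibble(tier_map)
  miss <- setdiff(c("prototroch_id", "tier"), names(tier_map))
  if (length(miss)) {
    stop_format(paste0("tier_map is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(tier_map$tier), c("anterior", "posterior"))
  if (length(bad)) {
    stop_config(paste0("unknown tier value(s): ", paste(bad, collapse = ", ")))
  }
  proto <- x$neurons$id[x$neurons$cell_type == "prototroch"]
  unmapped <- setdiff(proto, tier_map$prototroch_id)
  if (length(unmapped)) {
    stop_config(paste0("prototroch cell(s) missing from tier_map: ",
                       paste(unmapped, collapse = ", ")))
  }
  mn <- x$neurons$id[!is.na(x$neurons$func_class) &
                       x$neurons$func_class == "motoneuron"]
  tier_of <- stats::setNames(tier_map$tier, tier_map$prototroch_id)
  lk <- x$links |>
    filter(.data$pre_id %in% mn, .data$post_id %in% proto)
  totals <- c(anterior = 0L, posterior = 0L)
  if (nrow(lk) > 0) {
    s <- tapply(lk$count, tier_of[lk$post_id], sum)
    totals[names(s)] <- as.integer(s)
  }
  out <- tibble(tier = names(totals), total = unname(totals))
  attr(out, "posterior_only") <-
    totals["anterior"] == 0L && totals["posterior"] > 0L
  out
}

#' @rdname tier_innervation
#' @param tiers A tibble returned by [tier_innervation()].
#' @export
posterior_only <- function(tiers) {
  isTRUE(unname(attr(tiers, "posterior_only")))
}

#' Motoneuron with the most synapses onto a target cell set
#'
#' Finds the motoneuron maximising its summed synapse count onto the given
#' target cells (e.g. the trunk longitudinal muscles). Ties are broken by
#' lexicographic id for determinism; with no motoneuron-to-target synapses
#' at all, the lexicographically first motoneuron is reported with count 0.
#'
#' @param x A `connectome`.
#' @param target_ids Ids of the target cells (members of one effector
#'   group).
#' @return A one-row tibble with `mn_id` and `count`.
#' @export
max_synapses_per_mn <- function(x, target_ids) {
  mn <- sort(x$neurons$id[!is.na(x$neurons$func_class) &
                            x$neurons$func_class == "motoneuron"])
  if (length(mn) == 0) stop_degenerate("no motoneurons in the connectome")
  unknown <- setdiff(target_ids, x$neurons$id)
  if (length(unknown)) {
    stop_referential(paste0("unknown target id(s): ",
                            paste(unknown, collapse = ", ")))
  }
  totals <- stats::setNames(integer(length(mn)), mn)
  lk <- filter(x$links, .data$pre_id %in% mn, .data$post_id %in% target_ids)
  if (nrow(lk) > 0) {
    s <- tapply(lk$count, lk$pre_id, sum)
    totals[names(s)] <- as.integer(s)
  }
  best <- mn[which.max(totals)]   # mn sorted, so which.max ties go lexicographic
  tibble(mn_id = best, count = unname(totals[best]))
}
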