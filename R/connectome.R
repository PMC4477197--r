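#' Construct a neuron table
#'
#' Builds the tibble of reconstructed cells used throughout the package. Each
#' cell carries a unique `id`, a free-text `name`, a `cell_type` label (e.g.
#' `PRC`, `IN1`, `INsn`, `MN`, `prototroch`, `muscle`), a body `side`
#' (`left`, `right`, or `unpaired` for midline cells), a functional class
#' (`sensory`, `interneuron`, `motoneuron`, `effector`; `NA` only for
#' fragments, whose class cannot be assigned), a tracing `status`
#' (`complete`, `truncated`, `fragment`), an optional cable length in
#' micrometres, and a `has_soma` flag. Fragments are, by definition, traced
#' neurite pieces for which no soma was found, so `status == "fragment"` and
#' `has_soma == FALSE` must coincide.
#'
#' @param id Character vector of unique cell identifiers.
#' @param cell_type Character vector of cell-type labels.
#' @param side Character vector among `"left"`, `"right"`, `"unpaired"`.
#' @param func_class Character vector among `"sensory"`, `"interneuron"`,
#'   `"motoneuron"`, `"effector"`; `NA` allowed only for fragments.
#' @param name Free-text names; defaults to `id`.
#' @param status Tracing status; defaults to `"complete"`.
#' @param cable_length_um Nonnegative cable length in micrometres, or `NA`.
#' @param has_soma Logical; defaults to `status != "fragment"`.
#' @return A tibble with one row per cell.
#' @export
neurons_tbl <- function(id, cell_type, side, func_class,
                        name = id, status = "complete",
                        cable_length_um = NA_real_,
                        has_soma = status != "fragment") {
  tibble(
    id = as.character(id), name = as.character(name),
    cell_type = as.character(cell_type), side = as.character(side),
    func_class = as.character(func_class), status = as.character(status),
    cable_length_um = as.numeric(cable_length_um),
    has_soma = as.logical(has_soma)
  )
}

#' Assemble and validate a connectome
#'
#' A connectome bundles one individual's neuron table with its directed
#' synaptic edge list (per-pair synapse counts), optional synapse positions
#' and optional dataset metadata. Validation enforces the container's
#' invariants: unique neuron ids, known categorical values, link endpoints
#' present in the neuron table, positive integer synapse counts, no autapses
#' unless explicitly permitted, and the fragment/soma equivalence.
#'
#' Duplicate `(pre_id, post_id)` rows in `links` are summed into a single
#' link, so the total synapse count is conserved.
#'
#' @param neurons Neuron tibble as built by [neurons_tbl()].
#' @param links Tibble with columns `pre_id`, `post_id`, `count`.
#' @param positions Optional tibble with columns `pre_id`, `post_id`, `x_nm`,
#'   `y_nm`, `z_nm`, `section` (1-based section index).
#' @param metadata Optional dataset metadata list, see [dataset_metadata()].
#' @param individual_id Label for the individual (e.g. `"larva-2"`).
#' @param allow_autapses Permit self-synapses (`pre_id == post_id`)? Default
#'   `FALSE`: none are described in this circuit.
#' @return An object of class `connectome`.
#' @export
connectome <- function(neurons, links = NULL, positions = NULL,
                       metadata = NULL, individual_id = "unnamed",
                       allow_autapses = FALSE) {
  neurons <- as_tibble(neurons)
  if (is.null(links)) {
    links <- tibble(pre_id = character(), post_id = character(),
                    count = integer())
  }
  links <- as_tibble(links)
  if (nrow(links) > 0) {
    links <- links |>
      mutate(pre_id = as.character(.data$pre_id),
             post_id = as.character(.data$post_id),
             count = as.integer(.data$count)) |>
      group_by(.data$pre_id, .data$post_id) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      filter(.data$count > 0)
  }
  x <- structure(
    list(individual_id = individual_id, neurons = neurons, links = links,
         positions = if (!is.null(positions)) as_tibble(positions),
         metadata = metadata, allow_autapses = allow_autapses),
    class = "connectome"
  )
  validate_connectome(x)
}

#' Validate a connectome's invariants
#'
#' @param x A `connectome`.
#' @return `x`, invisibly returned unchanged if valid; otherwise an error of
#'   class `connstereo_validation_error`, `connstereo_referential_error` or
#'   `connstereo_format_error` describing the violation.
#' @export
validate_connectome <- function(x) {
  nn <- x$neurons
  req <- c("id", "name", "cell_type", "side", "func_class", "status",
           "cable_length_um", "has_soma")
  miss <- setdiff(req, names(nn))
  if (length(miss)) {
    stop_format(paste0("neuron table is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(nn$id)) {
    stop_validation(paste0("duplicate neuron id(s): ",
                           paste(unique(nn$id[duplicated(nn$id)]), collapse = ", ")))
  }
  bad_side <- setdiff(unique(nn$side), .sides)
  if (length(bad_side)) {
    stop_validation(paste0("unknown side value(s): ",
                           paste(bad_side, collapse = ", ")))
  }
  bad_fc <- setdiff(unique(nn$func_class[!is.na(nn$func_class)]), .func_classes)
  if (length(bad_fc)) {
    stop_validation(paste0("unknown func_class value(s): ",
                           paste(bad_fc, collapse = ", ")))
  }
  if (any(is.na(nn$func_class) & nn$status != "fragment")) {
    stop_validation("func_class may be NA only for fragments")
  }
  bad_st <- setdiff(unique(nn$status), .statuses)
  if (length(bad_st)) {
    stop_validation(paste0("unknown status value(s): ",
                           paste(bad_st, collapse = ", ")))
  }
  frag_mismatch <- xor(nn$status == "fragment", !nn$has_soma)
  if (any(frag_mismatch)) {
    stop_validation(paste0("status == 'fragment' must coincide with has_soma == FALSE for: ",
                           paste(nn$id[frag_mismatch], collapse = ", ")))
  }
  if (any(!is.na(nn$cable_length_um) & nn$cable_length_um < 0)) {
    stop_validation("cable_length_um must be nonnegative")
  }
  lk <- x$links
  miss <- setdiff(c("pre_id", "post_id", "count"), names(lk))
  if (length(miss)) {
    stop_format(paste0("edge table is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(unique(c(lk$pre_id, lk$post_id)), nn$id)
  if (length(unknown)) {
    stop_referential(paste0("edge(s) reference unknown neuron id(s): ",
                            paste(unknown, collapse = ", ")))
  }
  if (!isTRUE(x$allow_autapses) && any(lk$pre_id == lk$post_id)) {
    stop_validation(paste0("autapse(s) present but not permitted: ",
                           paste(unique(lk$pre_id[lk$pre_id == lk$post_id]),
                                 collapse = ", ")))
  }
  if (any(is.na(lk$count) | lk$count < 1)) {
    stop_validation("synapse counts must be positive integers")
  }
  ps <- x$positions
  if (!is.null(ps)) {
    miss <- setdiff(c("pre_id", "post_id", "x_nm", "y_nm", "z_nm", "section"),
                    names(ps))
    if (length(miss)) {
      stop_format(paste0("position table is missing column(s): ",
                         paste(miss, collapse = ", ")))
    }
    unknown <- setdiff(unique(c(ps$pre_id, ps$post_id)), nn$id)
    if (length(unknown)) {
      stop_referential(paste0("position(s) reference unknown neuron id(s): ",
                              paste(unknown, collapse = ", ")))
    }
    if (any(ps$section < 1)) stop_validation("section indices are 1-based")
    if (!is.null(x$metadata$n_sections) &&
        any(ps$section > x$metadata$n_sections)) {
      stop_validation("section index exceeds n_sections")
    }
    if (any(ps$x_nm < 0 | ps$y_nm < 0 | ps$z_nm < 0)) {
      stop_validation("synapse coordinates must be nonnegative")
    }
  }
  invisible(x)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s: %d cells, %d directed links, %d synapses\n",
              x$individual_id, nrow(x$neurons), nrow(x$links),
              sum(x$links$count)))
  tab <- table(x$neurons$status)
  cat("  status:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Total synapse count of a connectome
#' @param x A `connectome`.
#' @return Integer, the sum of all per-pair synapse counts.
#' @export
total_synapses <- function(x) sum(x$links$count)

#' Dataset metadata for a serial-section EM volume
#'
#' Records the sectioning parameters of an ssTEM dataset: total section
#' count, section thickness, numbers of lost and unimaged layers, and pixel
#' size. Defaults describe a full-body 40 nm series imaged at 5.7 nm/pixel.
#'
#' @param n_sections Total number of sections (> 0).
#' @param section_thickness_nm Section thickness in nm.
#' @param n_lost_layers Sections lost during processing.
#' @param n_unimaged_layers Sections never imaged.
#' @param pixel_size_nm Imaging resolution in nm/pixel.
#' @return A list of class `dataset_metadata`.
#' @export
dataset_metadata <- function(n_sections, section_thickness_nm = 40,
                             n_lost_layers = 0, n_unimaged_layers = 0,
                             pixel_size_nm = 5.7) {
  if (!is_count(n_sections)) stop_validation("n_sections must be a count")
  if (!is_count(n_lost_layers) || !is_count(n_unimaged_layers)) {
    stop_validation("layer counts must be nonnegative integers")
  }
  if (n_lost_layers + n_unimaged_layers > n_sections) {
    stop_validation("lost + unimaged layers exceed the section count")
  }
  structure(list(n_sections = n_sections,
                 section_thickness_nm = section_thickness_nm,
                 n_lost_layers = n_lost_layers,
                 n_unimaged_layers = n_unimaged_layers,
                 pixel_size_nm = pixel_size_nm),
            class = "dataset_metadata")
}

#' Percentage of sections lost from a series
#'
#' @param meta A [dataset_metadata()] object (or list with `n_lost_layers`
#'   and `n_sections`).
#' @return Percent of sections lost, reported to one decimal.
#' @export
#' @examples
#' section_loss_rate(dataset_metadata(5056, n_lost_layers = 98))
section_loss_rate <- function(meta) {
  if (is.null(meta$n_sections) || meta$n_sections == 0) {
    stop_degenerate("n_sections must be positive")
  }
  round(100 * meta$n_lost_layers / meta$n_sections, 1)
}

#' Bin untraceable fragments by cable length
#'
#' Fragments (neurite pieces without an identifiable soma) are summarised by
#' cable length into three bins: below the first threshold, between the
#' thresholds inclusive, and above the second threshold. With the default
#' thresholds of 4 and 40 micrometres the bins are `[0, 4)`, `[4, 40]` and
#' `(40, Inf)` — lengths exactly at a threshold fall in the middle bin.
#'
#' @param lengths Numeric vector of nonnegative cable lengths (µm).
#' @param edges Two increasing thresholds (µm); default `c(4, 40)`.
#' @return A tibble of class `fragment_summary` with columns `bin`, `lower`,
#'   `upper`, `count`, plus attributes `edges` and `total`.
#' @export
classify_fragments <- function(lengths, edges = c(4, 40)) {
  if (any(is.na(lengths)) || any(lengths < 0)) {
    stop_validation("fragment lengths must be nonnegative")
  }
  if (length(edges) != 2 || edges[1] >= edges[2]) {
    stop_config("edges must be two increasing thresholds")
  }
  counts <- c(sum(lengths < edges[1]),
              sum(lengths >= edges[1] & lengths <= edges[2]),
              sum(lengths > edges[2]))
  out <- tibble(
    bin = c(sprintf("<%g", edges[1]),
            sprintf("%g-%g", edges[1], edges[2]),
            sprintf(">%g", edges[2])),
    lower = c(0, edges[1], edges[2]),
    upper = c(edges[1], edges[2], Inf),
    count = as.integer(counts)
  )
  structure(out, edges = edges, total = length(lengths),
            class = c("fragment_summary", class(out)))
}

#' Instantiate a ciliary-band effector complement
#'
#' Ciliated locomotor bands (prototroch, metatroch, paratrochs) are built
#' from bilateral cell pairs plus optional unpaired midline cells. Each pair
#' contributes one left and one right cell; unpaired cells get
#' `side = "unpaired"`. All cells are effectors with complete tracing status.
#'
#' @param n_pairs Number of bilateral cell pairs.
#' @param n_unpaired Number of unpaired cells (default 0).
#' @param band Band label used as `cell_type` and id prefix.
#' @return A neuron tibble with `2 * n_pairs + n_unpaired` rows.
#' @export
#' @examples
#' nrow(instantiate_ciliary_band(11, 1, "prototroch")) # 23-cell prototroch
instantiate_ciliary_band <- function(n_pairs, n_unpaired = 0,
                                     band = "prototroch") {
  if (!is_count(n_pairs) || !is_count(n_unpaired)) {
    stop_validation("pair and unpaired counts must be nonnegative integers")
  }
  rows <- list()
  if (n_pairs > 0) {
    rows$pairs <- neurons_tbl(
      id = c(sprintf("%s_l%02d", band, seq_len(n_pairs)),
             sprintf("%s_r%02d", band, seq_len(n_pairs))),
      cell_type = band,
      side = rep(c("left", "right"), each = n_pairs),
      func_class = "effector"
    )
  }
  if (n_unpaired > 0) {
    rows$unpaired <- neurons_tbl(
      id = sprintf("%s_u%02d", band, seq_len(n_unpaired)),
      cell_type = band, side = "unpaired", func_class = "effector"
    )
  }
  if (!length(rows)) return(neurons_tbl(character(), character(),
                                        character(), character()))
  bind_rows(rows)
}
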