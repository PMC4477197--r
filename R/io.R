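read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_format(paste0(what, " file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_format(paste0(what, " table ", path, " is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  df
}

#' Read a connectome from CSV tables
#'
#' Reads one individual's neuron table and directed synapse edge list (plus
#' optional synapse-position table and dataset metadata) and returns a
#' validated [connectome()]. Duplicate `(pre_id, post_id)` edge rows are
#' summed into one link. Synapses are per-pair integer counts; polyadic
#' synapses (one presynaptic site contacting several targets) must already
#' be expanded into one row per postsynaptic partner by the data producer.
#'
#' Expected columns: neuron table
#' `id,name,cell_type,side,func_class,status,cable_length_um,has_soma`;
#' edge table `pre_id,post_id,count`; position table
#' `pre_id,post_id,x_nm,y_nm,z_nm,section`.
#'
#' @param neuron_table Path to the neuron CSV.
#' @param edge_table Path to the edge CSV.
#' @param position_table Optional path to the synapse-position CSV.
#' @param meta Optional path to a key/value metadata text file, see
#'   [read_dataset_metadata()].
#' @param individual_id Label for the individual; defaults to the neuron
#'   table's base name.
#' @param allow_autapses Permit self-synapses? Default `FALSE`.
#' @return A validated `connectome`.
#' @export
read_connectome <- function(neuron_table, edge_table, position_table = NULL,
                            meta = NULL, individual_id = NULL,
                            allow_autapses = FALSE) {
  nn <- read_csv_checked(
    neuron_table,
    c("id", "name", "cell_type", "side", "func_class", "status",
      "cable_length_um", "has_soma"),
    "neuron"
  ) |>
    mutate(id = as.character(.data$id), name = as.character(.data$name),
           has_soma = as.logical(.data$has_soma),
           func_class = as.character(.data$func_class))
  lk <- read_csv_checked(edge_table, c("pre_id", "post_id", "count"), "edge")
  ps <- if (!is.null(position_table)) {
    read_csv_checked(position_table,
                     c("pre_id", "post_id", "x_nm", "y_nm", "z_nm", "section"),
                     "position") |>
      mutate(pre_id = as.character(.data$pre_id),
             post_id = as.character(.data$post_id))
  }
  md <- if (!is.null(meta)) read_dataset_metadata(meta)
  connectome(nn, lk, positions = ps, metadata = md,
             individual_id = individual_id %||%
               sub("\\.[^.]*$", "", basename(neuron_table)),
             allow_autapses = allow_autapses)
}

#' Write a connectome to CSV tables
#'
#' Serialises a connectome into the same CSV layout [read_connectome()]
#' accepts: `neurons.csv`, `edges.csv`, and when present `positions.csv` and
#' `metadata.txt`. Reading the files back yields a field-identical
#' connectome.
#'
#' @param x A `connectome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_connectome <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(neurons = file.path(dir, "neurons.csv"),
             edges = file.path(dir, "edges.csv"))
  readr::write_csv(x$neurons, paths["neurons"])
  readr::write_csv(x$links, paths["edges"])
  if (!is.null(x$positions)) {
    paths["positions"] <- file.path(dir, "positions.csv")
    readr::write_csv(x$positions, paths["positions"])
  }
  if (!is.null(x$metadata)) {
    paths["metadata"] <- file.path(dir, "metadata.txt")
    write_dataset_metadata(x$metadata, paths["metadata"])
  }
  invisible(paths)
}

#' Read dataset metadata from a key/value text file
#'
#' The file holds one `key value` (or `key=value`, `key: value`) pair per
#' line; recognised keys are `n_sections`, `section_thickness_nm`,
#' `n_lost_layers`, `n_unimaged_layers`, `pixel_size_nm`.
#'
#' @param path Path to the metadata file.
#' @return A [dataset_metadata()] object.
#' @export
read_dataset_metadata <- function(path) {
  if (!file.exists(path)) stop_format(paste0("metadata file not found: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=:[:space:]]+")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  known <- c("n_sections", "section_thickness_nm", "n_lost_layers",
             "n_unimaged_layers", "pixel_size_nm")
  bad <- setdiff(keys, known)
  if (length(bad)) {
    stop_format(paste0("unknown metadata key(s): ", paste(bad, collapse = ", ")))
  }
  args <- as.list(vals)
  names(args) <- keys
  do.call(dataset_metadata, args)
}

write_dataset_metadata <- function(meta, path) {
  writeLines(paste(names(unclass(meta)), unlist(meta)), path)
  invisible(path)
}

#' Write / read a labeled connectivity matrix as CSV
#'
#' Full and grouped matrices serialise with row labels in the first column
#' (`row`) and one column per postsynaptic label.
#'
#' @param m A numeric matrix with dimnames (e.g. from [build_full_matrix()]
#'   or [build_grouped_matrix()]).
#' @param path Output (or input) CSV path.
#' @return `write_matrix_csv()`: the path, invisibly. `read_matrix_csv()`:
#'   the matrix with dimnames restored.
#' @export
write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m)
  df <- cbind(row = rownames(m), df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read_csv_checked(path, "row", "matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$row
  storage.mode(m) <- "double"
  m
}
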