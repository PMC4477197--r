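#' Connectivity-maturation index of a photoreceptor
#'
#' Fraction of a photoreceptor cell's outgoing synapses that target mature
#' circuit partners (by default the primary interneurons, `IN1`). A newly
#' differentiating photoreceptor with no outgoing synapses scores 0. The
#' index always lies in `[0, 1]` and equals 1 exactly when every outgoing
#' synapse targets a mature type. The definition is pluggable: pass any set
#' of cell types considered mature targets.
#'
#' @param x A `connectome`.
#' @param prc_id Photoreceptor neuron id.
#' @param mature_target_types Cell types counted as mature targets; default
#'   `"IN1"`.
#' @return A number in `[0, 1]`.
#' @export
compute_maturation_index <- function(x, prc_id,
                                     mature_target_types = "IN1") {
  if (!prc_id %in% x$neurons$id) {
    stop_referential(paste0("unknown neuron id: ", prc_id))
  }
  if (length(mature_target_types) == 0) {
    stop_config("mature_target_types must be non-empty")
  }
  out <- filter(x$links, .data$pre_id == prc_id)
  if (nrow(out) == 0 || sum(out$count) == 0) return(0)
  type_of <- stats::setNames(x$neurons$cell_type, x$neurons$id)
  mature <- sum(out$count[type_of[out$post_id] %in% mature_target_types])
  mature / sum(out$count)
}

#' Ordinary least-squares fit with confidence band
#'
#' Simple linear regression of `y` on `x` with the 95% pointwise confidence
#' band for the mean response, plus the Pearson correlation and its
#' two-sided p-value — the per-panel statistics reported for maturation
#' scatter plots.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, `x` non-constant.
#' @return A list of class `linear_fit`: `slope`, `intercept`, `pearson_r`,
#'   `p_value`, `n`, `model` (the underlying `lm`), `data`, and `ci_band`, a
#'   function mapping new x values to a tibble with columns `x`, `fit`,
#'   `lwr`, `upr`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_degenerate("need at least 3 complete observations")
  if (length(unique(x)) < 2) stop_degenerate("x is constant; design degenerate")
  df <- tibble(x = x, y = y)
  model <- lm(y ~ x, data = df)
  ct <- suppressWarnings(cor.test(x, y))
  ci_band <- function(newx) {
    pr <- predict(model, newdata = tibble(x = newx),
                  interval = "confidence", level = 0.95)
    tibble(x = newx, fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"])
  }
  structure(list(slope = unname(stats::coef(model)[2]),
                 intercept = unname(stats::coef(model)[1]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x),
                 model = model, data = df, ci_band = ci_band),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.4g + %.4g x; Pearson r = %.3f, p = %.3g, n = %d\n",
              x$intercept, x$slope, x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = c("(Intercept)", "x"),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble(r.squared = summary(x$model)$r.squared,
         pearson_r = x$pearson_r, p.value = x$p_value,
         slope = x$slope, intercept = x$intercept, n = x$n)
}

#' Read photoreceptor maturation records
#'
#' One row per photoreceptor: rhabdom volume (µm^3), axon cable length (µm)
#' and outgoing synapse count, with columns
#' `prc_id,rhabdom_volume_um3,axon_length_um,n_out_synapses` (an optional
#' `maturation_index` column is kept if present).
#'
#' @param path CSV path.
#' @return A tibble of maturation records.
#' @export
read_maturation_records <- function(path) {
  df <- read_csv_checked(path, c("prc_id", "rhabdom_volume_um3",
                                 "axon_length_um", "n_out_synapses"),
                         "maturation record")
  if (any(df$rhabdom_volume_um3 < 0, na.rm = TRUE) ||
      any(df$axon_length_um < 0, na.rm = TRUE) ||
      any(df$n_out_synapses < 0, na.rm = TRUE)) {
    stop_validation("maturation record values must be nonnegative")
  }
  df
}

#' Attach connectivity-maturation indices to maturation records
#'
#' @param records Maturation record tibble (see
#'   [read_maturation_records()]).
#' @param x A `connectome` holding the photoreceptors' outgoing synapses.
#' @param mature_target_types Passed to [compute_maturation_index()].
#' @return `records` with a `maturation_index` column added.
#' @export
add_maturation_index <- function(records, x, mature_target_types = "IN1") {
  records |>
    mutate(maturation_index = unname(vapply(
      .data$prc_id, function(id)
        compute_maturation_index(x, id, mature_target_types), numeric(1))))
}

#' Three-panel photoreceptor maturation report
#'
#' Fits the three maturation regressions: axon length against rhabdom
#' volume, outgoing synapse count against rhabdom volume, and rhabdom
#' volume against the connectivity-maturation index. Rhabdom volume indexes
#' a photoreceptor's developmental stage, so positive slopes in all three
#' panels indicate that structural and synaptic maturation advance
#' together.
#'
#' @param records Maturation record tibble; must contain a
#'   `maturation_index` column (see [add_maturation_index()]) and at least 3
#'   complete records.
#' @return A list of class `maturation_report` with `linear_fit` elements
#'   `volume_vs_axon` (x = volume, y = axon length), `volume_vs_synapses`
#'   (x = volume, y = synapse count) and `index_vs_volume` (x = index,
#'   y = volume).
#' @export
maturation_report <- function(records) {
  if (!"maturation_index" %in% names(records)) {
    stop_config("records lack a maturation_index column; see add_maturation_index()")
  }
  complete <- records |>
    filter(!is.na(.data$rhabdom_volume_um3), !is.na(.data$axon_length_um),
           !is.na(.data$n_out_synapses), !is.na(.data$maturation_index))
  if (nrow(complete) < 3) stop_degenerate("need at least 3 complete records")
  structure(list(
    volume_vs_axon = fit_linear(complete$rhabdom_volume_um3,
                                complete$axon_length_um),
    volume_vs_synapses = fit_linear(complete$rhabdom_volume_um3,
                                    complete$n_out_synapses),
    index_vs_volume = fit_linear(complete$maturation_index,
                                 complete$rhabdom_volume_um3)
  ), class = "maturation_report")
}

#' @export
print.maturation_report <- function(x, ...) {
  cat("<maturation_report>\n")
  for (nm in names(unclass(x))) {
    cat(" ", nm, ": ", sep = "")
    print(x[[nm]])
  }
  invisible(x)
}

#' @method tidy maturation_report
#' @export
tidy.maturation_report <- function(x, ...) {
  purrr::imap(unclass(x), function(fit, nm) {
    glance.linear_fit(fit) |> mutate(panel = nm, .before = 1)
  }) |> bind_rows()
}

#' Simulate photoreceptor maturation records
#'
#' Draws rhabdom volumes uniformly over a developmental range and generates
#' axon length, synapse count and maturation index as linear responses with
#' Gaussian noise — the fixture for parameter-recovery checks of
#' [maturation_report()].
#'
#' @param n Number of photoreceptors (default 12, a typical four-eye
#'   complement).
#' @param volume_range Rhabdom volume range in µm^3 (default 0.5-8).
#' @param axon_slope,axon_intercept Axon length response (µm per µm^3).
#' @param syn_slope,syn_intercept Synapse-count response.
#' @param index_slope,index_intercept Maturation-index response (clamped to
#'   `[0, 1]`).
#' @param noise_sd Relative noise standard deviation (default 0.15).
#' @param seed RNG seed.
#' @return A maturation record tibble with a `maturation_index` column.
#' @export
simulate_maturation_records <- function(n = 12, volume_range = c(0.5, 8),
                                        axon_slope = 6, axon_intercept = 10,
                                        syn_slope = 2.5, syn_intercept = 0,
                                        index_slope = 0.1,
                                        index_intercept = 0.1,
                                        noise_sd = 0.15, seed = NULL) {
  with_seed(seed, {
    vol <- runif(n, volume_range[1], volume_range[2])
    axon <- pmax(0, axon_intercept + axon_slope * vol +
                   stats::rnorm(n, 0, noise_sd * axon_slope * diff(volume_range) / 2))
    syn <- pmax(0, round(syn_intercept + syn_slope * vol +
                           stats::rnorm(n, 0, noise_sd * syn_slope * diff(volume_range) / 2)))
    idx <- pmin(1, pmax(0, index_intercept + index_slope * vol +
                          stats::rnorm(n, 0, noise_sd * index_slope * diff(volume_range) / 2)))
    tibble(prc_id = sprintf("PRC_%02d", seq_len(n)),
           rhabdom_volume_um3 = vol, axon_length_um = axon,
           n_out_synapses = as.integer(syn), maturation_index = idx)
  })
}
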