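#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols rename distinct pull n
#' @importFrom stats cor rpois rgamma rlnorm runif lm predict cor.test
#' @importFrom utils modifyList
NULL

# error helpers: every user-facing failure carries a condition class so
# callers (and the CLI) can react without parsing messages
stop_format <- function(msg) abort(msg, class = "connstereo_format_error")
stop_referential <- function(msg) abort(msg, class = "connstereo_referential_error")
stop_validation <- function(msg) abort(msg, class = "connstereo_validation_error")
stop_config <- function(msg) abort(msg, class = "connstereo_config_error")
stop_degenerate <- function(msg) abort(msg, class = "connstereo_degenerate_error")
stop_comparison <- function(msg) abort(msg, class = "connstereo_comparison_error")

.sides <- c("left", "right", "unpaired")
.func_classes <- c("sensory", "interneuron", "motoneuron", "effector")
.statuses <- c("complete", "truncated", "fragment")

#' Compose a cell-type/side group key
#'
#' Group keys are `"<cell_type>.<side>"` strings; the side stratum is part of
#' the key because connections are aggregated separately for cells with their
#' soma on the left or right body side (unpaired midline cells form their own
#' stratum).
#'
#' @param cell_type Character vector of cell-type labels.
#' @param side Character vector among `"left"`, `"right"`, `"unpaired"`.
#' @return Character vector of group keys.
#' @export
group_key <- function(cell_type, side) paste(cell_type, side, sep = ".")

#' Mirror a group key across the body midline
#'
#' Swaps the left/right side stratum of a group key; unpaired keys map to
#' themselves. Used when scoring left-right asymmetry of bilateral homologs.
#'
#' @param key Character vector of group keys as produced by [group_key()].
#' @return Character vector of mirrored keys.
#' @export
mirror_key <- function(key) {
  out <- sub("\\.left$", ".__L__", key)
  out <- sub("\\.right$", ".left", out)
  sub("\\.__L__$", ".right", out)
}

# run code with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
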