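#' Species configuration
#'
#' A species configuration names the feeding instars (ordered larval stages
#' that contribute measurably to defoliation), the maximum instar count, and
#' the approximate digestibility (AD) used to convert frass to ingested
#' biomass. First instars eat a negligible amount of foliage, so feeding
#' normally starts at L2.
#'
#' @param species_name Species label, e.g. `"Choristoneura pinus"`.
#' @param feeding_instars Character vector of ordered instar labels
#'   (e.g. `c("L2", ..., "L7")`). Must be non-empty with no duplicates.
#' @param approximate_digestibility Proportion of ingested foliage retained by
#'   the larva (not excreted as frass), in `[0, 1)`.
#' @param max_instars Maximum number of instars for the species; defaults to
#'   the number of feeding instars plus one (the non-feeding L1).
#' @param notes Free-text notes.
#'
#' @return An object of class `species_config`.
#' @examples
#' species_config("Toyworm", c("L2", "L3", "L4"), 0.3)
#' @export
species_config <- function(species_name, feeding_instars,
                           approximate_digestibility,
                           max_instars = length(feeding_instars) + 1L,
                           notes = "") {
  if (length(feeding_instars) == 0)
    abort_parameter("`feeding_instars` must be non-empty.")
  if (anyDuplicated(feeding_instars))
    abort_parameter("`feeding_instars` must be distinct ordered labels.")
  ad <- approximate_digestibility
  if (!is.numeric(ad) || length(ad) != 1 || is.na(ad) || ad < 0 || ad >= 1)
    abort_parameter("`approximate_digestibility` must be a single value in [0, 1).")
  if (max_instars < length(feeding_instars))
    abort_parameter("`max_instars` must be at least the number of feeding instars.")
  structure(
    list(
      species_name = species_name,
      feeding_instars = as.character(feeding_instars),
      max_instars = as.integer(max_instars),
      approximate_digestibility = ad,
      notes = notes
    ),
    class = "species_config"
  )
}

#' @export
print.species_config <- function(x, ...) {
  cat("<species_config> ", x$species_name, "\n", sep = "")
  cat("  feeding instars: ", paste(x$feeding_instars, collapse = ", "), "\n", sep = "")
  cat("  max instars: ", x$max_instars, "\n", sep = "")
  cat("  approximate digestibility (AD): ", x$approximate_digestibility, "\n", sep = "")
  invisible(x)
}

#' Read a species configuration from a YAML file
#'
#' @param path Path to a YAML file with keys `species_name`, `feeding_instars`,
#'   `approximate_digestibility`, and optionally `max_instars` and `notes`.
#' @return A [species_config()] object.
#' @export
read_species_config <- function(path) {
  if (!file.exists(path)) abort_format(paste0("Species config not found: ", path))
  raw <- yaml::read_yaml(path)
  need <- c("species_name", "feeding_instars", "approximate_digestibility")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    abort_format(paste0("Species config missing field(s): ",
                        paste(missing, collapse = ", ")))
  species_config(
    species_name = raw$species_name,
    feeding_instars = unlist(raw$feeding_instars),
    approximate_digestibility = raw$approximate_digestibility,
    max_instars = raw$max_instars %||% (length(unlist(raw$feeding_instars)) + 1L),
    notes = raw$notes %||% ""
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Built-in species configurations
#'
#' Jack pine budworm (*Choristoneura pinus*): up to seven instars, feeding
#' instars L2-L7, approximate digestibility 0.30 (estimated from the
#' closely related spruce budworm). Spongy moth (*Lymantria dispar dispar*):
#' five (male) to six (female) instars, feeding instars L2-L6, approximate
#' digestibility 0.35. Both ship as editable YAML under
#' `system.file("extdata/species", package = "phenofrass")`.
#'
#' @return A [species_config()] object.
#' @examples
#' cpinus_config()
#' @export
cpinus_config <- function() {
  read_species_config(system.file("extdata/species/cpinus.yml",
                                  package = "phenofrass", mustWork = TRUE))
}

#' @rdname cpinus_config
#' @export
ldispar_config <- function() {
  read_species_config(system.file("extdata/species/ldispar.yml",
                                  package = "phenofrass", mustWork = TRUE))
}

#' Field-calibrated instar weights for the two reference defoliators
#'
#' Per-instar seasonal consumption weights for *C. pinus* and
#' *L. dispar dispar* calibrated against field-collected frass deposition in
#' Wisconsin and Maryland outbreak plots. Weights sum to one within each
#' species and show the characteristic negative skew: consumption peaks at
#' the second-to-last instar.
#'
#' @return A tibble with columns `species`, `instar`, `weight`.
#' @examples
#' calibrated_weights()
#' @export
calibrated_weights <- function() {
  path <- system.file("extdata/calibrated_weights.csv",
                      package = "phenofrass", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Percent share of seasonal consumption per instar
#'
#' Converts a weight vector (or the per-species rows of a weight table) into
#' percent shares of total seasonal consumption, e.g. to report how much of a
#' season's feeding the late instars account for.
#'
#' @param weights A data frame with columns `instar` and `weight` (extra
#'   columns such as `species` are preserved as grouping), or a named numeric
#'   vector of weights.
#' @return A tibble with a `share_pct` column; shares sum to 100 within each
#'   species group.
#' @examples
#' weight_shares(calibrated_weights())
#' @export
weight_shares <- function(weights) {
  if (is.numeric(weights)) {
    weights <- tibble(instar = names(weights), weight = as.numeric(weights))
  }
  if (!all(c("instar", "weight") %in% names(weights)))
    abort_parameter("`weights` needs columns `instar` and `weight`.")
  grp <- intersect("species", names(weights))
  weights |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(share_pct = 100 * .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
}
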