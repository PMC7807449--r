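new_composition <- function(name, entries) {
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  if (any(entries < 0)) {
    stop("composition fractions must be non-negative", call. = FALSE)
  }
  tot <- sum(entries)
  if (abs(tot - 100) > 0.5) {
    stop(
      sprintf("composition fractions sum to %.3f; expected 100 within 0.5", tot),
      call. = FALSE
    )
  }
  out <- lipid_species(names(entries))
  out <- dplyr::mutate(out, fraction = unname(entries), .after = "species")
  attr(out, "composition_name") <- name
  class(out) <- c("ple_composition", class(out))
  out
}

#' Load a membrane composition
#'
#' Returns one of the four preset PLE model compositions (`"Avanti"`, the
#' 14-species natural-extract mimic, or the three-species `"SimplePOM"`,
#' `"SimplePVM"`, `"SimplePVJ"` reductions), or reads a composition from a
#' YAML config file with a top-level `composition:` map of species code to
#' mole-percent.
#'
#' The Avanti preset keeps its fractions exactly as listed by the extract
#' vendor (they sum to 99.8); fraction-returning computations renormalise
#' internally.
#'
#' @param name_or_config A preset name or a path to a YAML config file.
#' @return A composition tibble (class `ple_composition`) with columns
#'   `species`, `fraction` (mole percent), `headgroup`, `tails` (list),
#'   `tails_per_lipid`, `charge`.
#' @examples
#' load_composition("SimplePOM")
#' nrow(load_composition("Avanti")) # 14 lipid species
#' @export
load_composition <- function(name_or_config) {
  stopifnot(is.character(name_or_config), length(name_or_config) == 1L)
  if (name_or_config %in% names(composition_presets)) {
    return(new_composition(name_or_config, composition_presets[[name_or_config]]))
  }
  if (file.exists(name_or_config)) {
    cfg <- yaml::read_yaml(name_or_config)
    entries <- cfg$composition %||% cfg
    entries <- unlist(entries)
    return(new_composition(
      cfg$name %||% basename(name_or_config),
      entries
    ))
  }
  stop(
    "unknown composition preset '", name_or_config, "' (and no such file); ",
    "presets are: ", paste(names(composition_presets), collapse = ", "),
    call. = FALSE
  )
}

#' Tail-type fractions of a composition
#'
#' Percentage of each acyl tail code among all tails of the membrane,
#' weighting each cardiolipin by its four tails and each PE/PG by two.
#' Fractions are renormalised over the listed species, so a composition
#' whose printed mole fractions sum to 99.8 still yields tail percentages
#' summing to 100.
#'
#' @param comp A composition from [load_composition()].
#' @return A tibble with columns `tail` and `percent`, sorted by
#'   decreasing `percent`.
#' @examples
#' tail_fractions(load_composition("Avanti")) # P = 37.4% and friends
#' @export
tail_fractions <- function(comp) {
  stopifnot(inherits(comp, "ple_composition"))
  if (nrow(comp) == 0L) stop("empty composition", call. = FALSE)
  comp |>
    dplyr::mutate(tail = .data$tails) |>
    tidyr::unnest_longer("tail") |>
    dplyr::count(.data$tail, wt = .data$fraction, name = "weight") |>
    dplyr::mutate(percent = 100 * .data$weight / sum(.data$weight)) |>
    dplyr::select("tail", "percent") |>
    dplyr::arrange(dplyr::desc(.data$percent))
}

#' Headgroup-class fractions of a composition
#'
#' Mole percent of lipids in each headgroup class (PE, PG, CL), renormalised
#' over the listed species.
#'
#' @inheritParams tail_fractions
#' @return A tibble with columns `headgroup` and `percent`.
#' @examples
#' headgroup_fractions(load_composition("SimplePOM")) # 72 / 23 / 5
#' @export
headgroup_fractions <- function(comp) {
  stopifnot(inherits(comp, "ple_composition"))
  if (nrow(comp) == 0L) stop("empty composition", call. = FALSE)
  comp |>
    dplyr::count(.data$headgroup, wt = .data$fraction, name = "weight") |>
    dplyr::mutate(percent = 100 * .data$weight / sum(.data$weight)) |>
    dplyr::select("headgroup", "percent") |>
    dplyr::arrange(dplyr::desc(.data$percent))
}

#' Integer per-leaflet lipid counts for a composition
#'
#' Converts mole fractions into integer lipid counts per leaflet by the
#' largest-remainder method. Both leaflets of a PLE model carry exactly the
#' same lipids, so one count vector serves both. Ties in the remainder are
#' broken by descending fraction and then by species name.
#'
#' @inheritParams tail_fractions
#' @param n_per_leaflet Number of lipids in one leaflet.
#' @return A tibble with columns `species`, `count`; counts sum to
#'   `n_per_leaflet`.
#' @examples
#' realize_counts(load_composition("SimplePOM"), 100)
#' @export
realize_counts <- function(comp, n_per_leaflet) {
  stopifnot(inherits(comp, "ple_composition"))
  if (!is.numeric(n_per_leaflet) || length(n_per_leaflet) != 1L ||
    n_per_leaflet < 0 || n_per_leaflet != round(n_per_leaflet)) {
    stop("n_per_leaflet must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n_per_leaflet)
  quota <- comp$fraction / sum(comp$fraction) * n
  base <- floor(quota)
  short <- n - sum(base)
  ord <- order(-(quota - base), -comp$fraction, comp$species)
  extra <- integer(nrow(comp))
  if (short > 0) extra[ord[seq_len(short)]] <- 1L
  tibble::tibble(species = comp$species, count = as.integer(base) + extra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
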