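#' Acyl tail chemistry registry
#'
#' The single-letter tail codes used by the *E. coli* polar lipid extract
#' (PLE) membrane models. Each code identifies a tail by carbon count and by
#' the type and position of its structural feature: a cis double bond or a
#' cyclopropane ring (the enzymatic cyclopropanation product of the former).
#'
#' @return A tibble with columns `code`, `carbons`, `feature`
#'   (`"saturated"`, `"cis-double-bond"` or `"cyclopropane"`) and
#'   `feature_position` (`"9,10"`, `"11,12"` or `NA`).
#' @examples
#' tail_registry()
#' @export
tail_registry <- function() {
  tibble::tibble(
    code = c("P", "O", "V", "Y", "M", "N", "J"),
    carbons = c(16L, 18L, 18L, 16L, 17L, 19L, 17L),
    feature = c(
      "saturated", "cis-double-bond", "cis-double-bond", "cis-double-bond",
      "cyclopropane", "cyclopropane", "cyclopropane"
    ),
    feature_position = c(NA, "9,10", "11,12", "9,10", "9,10", "11,12", "11,12")
  )
}

headgroup_charge <- c(PE = 0L, PG = -1L, CL = -2L)

# Species name convention: tail letters followed by the headgroup class,
# e.g. POPE = tails P,O on a PE; MPPO-CL = tails M,P,P,O on a cardiolipin.
parse_species_name <- function(name) {
  is_cl <- grepl("-CL$", name)
  head <- ifelse(is_cl, "CL", substr(name, nchar(name) - 1L, nchar(name)))
  tailpart <- ifelse(is_cl, sub("-CL$", "", name), substr(name, 1L, nchar(name) - 2L))
  tails <- strsplit(tailpart, "")
  valid <- head %in% c("PE", "PG", "CL") &
    purrr::map2_lgl(tails, is_cl, function(tl, cl) {
      length(tl) == (if (cl) 4L else 2L) && all(tl %in% tail_registry()$code)
    })
  if (!all(valid)) {
    stop("unparseable lipid species name(s): ",
      paste(name[!valid], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    species = name,
    headgroup = head,
    tails = tails,
    tails_per_lipid = ifelse(is_cl, 4L, 2L),
    charge = unname(headgroup_charge[head])
  )
}

#' Lipid species descriptors
#'
#' Expands short species codes (tail letters + headgroup, `-CL` suffix for
#' cardiolipins) into full descriptors: headgroup class, ordered tail codes,
#' tails per lipid (2 for PE/PG, 4 for CL) and net charge in elementary
#' charges (PE 0, PG -1, CL -2; each cardiolipin phosphate carries a single
#' negative charge).
#'
#' @param name Character vector of species codes, e.g. `"POPE"`, `"MPPO-CL"`.
#' @return A tibble with one row per species; `tails` is a list column of
#'   single-letter tail codes.
#' @examples
#' lipid_species(c("POPE", "MMPG", "MPPO-CL"))
#' @export
lipid_species <- function(name) {
  parse_species_name(name)
}

# Table 1 of the model set: the four preset membrane compositions.
composition_presets <- list(
  SimplePOM = c("MPPO-CL" = 5, "MMPG" = 23, "POPE" = 72),
  SimplePVJ = c("JPPV-CL" = 5, "JJPG" = 23, "PVPE" = 72),
  SimplePVM = c("MPPV-CL" = 5, "MMPG" = 23, "PVPE" = 72),
  Avanti = c(
    "YPMN-CL" = 1.0, "YPMV-CL" = 1.0, "MPPV-CL" = 2.1, "MPPM-CL" = 0.5,
    "PMPG" = 12.4, "PNPG" = 2.1, "YVPG" = 1.0, "PVPG" = 4.1, "PYPG" = 2.1,
    "YVPE" = 14.5, "PMPE" = 17.6, "PNPE" = 5.7, "MVPE" = 8.8, "PVPE" = 26.9
  )
)
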