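#' Filter docking results to valid interactions
#'
#' Keeps docking records whose binding affinity is strictly below the cutoff
#' (more negative = stronger binding; the default keeps affinities
#' < -8 kcal/mol). Duplicate (compound, protein) pairs -- re-runs of the same
#' docking -- are collapsed keeping the best (minimum) affinity.
#'
#' @param docking Data frame with columns `compound`, `protein`,
#'   `affinity_kcal_mol` (names configurable).
#' @param affinity_cutoff Strict upper bound on affinity, kcal/mol.
#' @param col_compound,col_protein,col_affinity Column names.
#' @return Tibble of valid interactions, one row per (compound, protein).
#' @export
filter_valid_interactions <- function(docking, affinity_cutoff = -8,
                                      col_compound = "compound",
                                      col_protein = "protein",
                                      col_affinity = "affinity_kcal_mol") {
  missing <- setdiff(c(col_compound, col_protein, col_affinity), names(docking))
  if (length(missing) > 0) {
    abort(paste0("docking table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tibble(
    compound = as.character(docking[[col_compound]]),
    protein = canonicalize_protein(docking[[col_protein]]),
    affinity_kcal_mol = docking[[col_affinity]]
  ) |>
    dplyr::filter(.data$affinity_kcal_mol < affinity_cutoff)
  if (nrow(tbl) == 0) return(tbl)
  tbl |>
    dplyr::summarise(
      affinity_kcal_mol = min(.data$affinity_kcal_mol),
      .by = c("compound", "protein")
    )
}

#' Per-protein docking summary
#'
#' Counts, for each protein, the number of valid interactions and the number
#' of distinct interacting compounds. After per-pair deduplication (see
#' [filter_valid_interactions()]) the two counts coincide.
#'
#' @param valid Tibble of cutoff-filtered docking records.
#' @return Tibble with columns `protein`, `n_interactions`, `n_compounds`.
#' @export
docking_summary <- function(valid) {
  valid |>
    dplyr::summarise(
      n_interactions = dplyr::n(),
      n_compounds = dplyr::n_distinct(.data$compound),
      .by = "protein"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_interactions))
}

#' Select dockable proteins (DPs)
#'
#' A dockable protein has strictly more than `min_interactions` valid
#' docking interactions (default > 10).
#'
#' @param valid Tibble of cutoff-filtered docking records, from
#'   [filter_valid_interactions()].
#' @param min_interactions Strict lower bound on the valid-interaction count.
#' @return An `evidence_set` with provenance `"DP"`; the per-protein summary
#'   is attached as attribute `"summary"`.
#' @export
select_dockable_proteins <- function(valid, min_interactions = 10) {
  summ <- docking_summary(valid)
  members <- summ$protein[summ$n_interactions > min_interactions]
  out <- evidence_set(
    members, provenance = "DP", name = "dockable proteins",
    params = sprintf("affinity-filtered interactions > %d", min_interactions)
  )
  attr(out, "summary") <- summ
  out
}

#' Select core proteins
#'
#' A core protein docks strictly more than `min_compounds` distinct
#' compounds at valid affinity (default > 50).
#'
#' @inheritParams select_dockable_proteins
#' @param min_compounds Strict lower bound on the distinct-compound count.
#' @return An `evidence_set` with provenance `"DP"` (core proteins are a
#'   subset of dockable proteins at the default thresholds), name
#'   `"core proteins"`.
#' @export
select_core_proteins <- function(valid, min_compounds = 50) {
  summ <- docking_summary(valid)
  members <- summ$protein[summ$n_compounds > min_compounds]
  out <- evidence_set(
    members, provenance = "DP", name = "core proteins",
    params = sprintf("distinct docked compounds > %d", min_compounds)
  )
  attr(out, "summary") <- summ
  out
}
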