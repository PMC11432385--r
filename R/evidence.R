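#' Construct an evidence set
#'
#' An evidence set is a named set of protein identifiers with a provenance
#' tag: `NP` (network-pharmacology predicted targets), `DP` (dockable
#' proteins), `DEG` (differentially expressed genes) or `IP` (integrated
#' DP + DEG list).
#'
#' @param members Character vector of protein identifiers.
#' @param provenance One of `"NP"`, `"DP"`, `"DEG"`, `"IP"`.
#' @param name Display name.
#' @param params Free-text description of the filters that produced the set.
#' @return An object of class `evidence_set`.
#' @export
evidence_set <- function(members, provenance = c("NP", "DP", "DEG", "IP"),
                         name = provenance, params = "") {
  provenance <- match.arg(provenance)
  structure(
    list(
      name = name,
      provenance = provenance,
      members = unique(canonicalize_protein(members)),
      params = params
    ),
    class = "evidence_set"
  )
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("<evidence_set '%s' [%s]> %d proteins\n",
              x$name, x$provenance, length(x$members)))
  invisible(x)
}

#' @export
tidy.evidence_set <- function(x, ...) {
  tibble(protein = x$members, evidence = x$name, provenance = x$provenance)
}

#' Select network-pharmacology targets from a compound-target table
#'
#' Keeps compound-target predictions with score at or above the cutoff
#' ("10 or higher" on the BATMAN-TCM score scale) and returns the distinct
#' target proteins as an `NP` evidence set. The number of valid
#' compound-target interactions is attached as attribute
#' `"n_valid_interactions"`.
#'
#' @param targets Data frame with columns `compound`, `target`, `score`
#'   (names configurable via `col_*`).
#' @param score_cutoff Minimum prediction score (inclusive); default 10.
#' @param col_compound,col_target,col_score Column names.
#' @return An `evidence_set` with provenance `"NP"`.
#' @export
parse_np_targets <- function(targets, score_cutoff = 10,
                             col_compound = "compound", col_target = "target",
                             col_score = "score") {
  missing <- setdiff(c(col_compound, col_target, col_score), names(targets))
  if (length(missing) > 0) {
    abort(paste0("compound-target table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(targets) == 0) abort("compound-target table is empty")
  tbl <- tibble(
    compound = as.character(targets[[col_compound]]),
    target = canonicalize_protein(targets[[col_target]]),
    score = targets[[col_score]]
  )
  valid <- dplyr::filter(tbl, .data$score >= score_cutoff)
  if (nrow(valid) == 0) {
    warn("no compound-target interactions at or above the score cutoff")
  }
  out <- evidence_set(
    unique(valid$target), provenance = "NP",
    name = "NP targets",
    params = sprintf("prediction score >= %s", format(score_cutoff))
  )
  attr(out, "n_valid_interactions") <- nrow(valid)
  out
}

#' Project an evidence set onto a network
#'
#' Intersects the evidence members with the network node set. Unmapped
#' identifiers are retained on the result for the run log.
#'
#' @param evidence An `evidence_set` (or bare character vector).
#' @param network A `protein_network`.
#' @return An object of class `projection` with `mapped`, `unmapped` and
#'   counts.
#' @export
project_evidence <- function(evidence, network) {
  stopifnot(inherits(network, "protein_network"))
  if (network_size(network) == 0) abort("cannot project onto an empty network")
  if (is.character(evidence)) {
    evidence <- evidence_set(evidence, provenance = "NP", name = "ad hoc")
  }
  stopifnot(inherits(evidence, "evidence_set"))
  nodes <- network_nodes(network)
  mapped <- intersect(evidence$members, nodes)
  unmapped <- setdiff(evidence$members, nodes)
  structure(
    list(
      evidence = evidence,
      network_ref = network$label,
      mapped = mapped,
      unmapped = unmapped,
      unmapped_count = length(unmapped)
    ),
    class = "projection"
  )
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("<projection '%s' onto '%s'> %d mapped, %d unmapped\n",
              x$evidence$name, x$network_ref, length(x$mapped),
              x$unmapped_count))
  invisible(x)
}

#' @export
tidy.projection <- function(x, ...) {
  tibble(
    protein = c(x$mapped, x$unmapped),
    evidence = x$evidence$name,
    network = x$network_ref,
    mapped = rep(c(TRUE, FALSE), c(length(x$mapped), length(x$unmapped)))
  )
}

#' Hit ratio of a projection against a network or its hub set
#'
#' Against a whole network, the hit ratio is the number of mapped evidence
#' proteins over the network size; against a hub set it is the number of
#' mapped hub members over the hub-set size. The reported percentage is
#' rounded half-up to two decimals (80 of 1040 nodes prints as "7.69%");
#' the raw ratio keeps full precision.
#'
#' @param projection A `projection`.
#' @param against A `protein_network` or a `hub_set`.
#' @return A one-row tibble of class `hit_result` with columns `analysis`,
#'   `network`, `denominator_kind`, `n_hit`, `denominator`, `ratio`,
#'   `percent`.
#' @export
hit_ratio <- function(projection, against) {
  stopifnot(inherits(projection, "projection"))
  if (inherits(against, "protein_network")) {
    denom_ids <- network_nodes(against)
    kind <- "whole_network"
    net <- against$label
  } else if (inherits(against, "hub_set")) {
    denom_ids <- against$members
    kind <- "hub_set"
    net <- against$network_ref
  } else {
    abort("`against` must be a protein_network or a hub_set")
  }
  if (length(denom_ids) == 0) abort("hit_ratio denominator set is empty")
  n_hit <- length(intersect(projection$mapped, denom_ids))
  ratio <- n_hit / length(denom_ids)
  out <- tibble(
    analysis = projection$evidence$provenance,
    network = net,
    denominator_kind = kind,
    n_hit = as.integer(n_hit),
    denominator = length(denom_ids),
    ratio = ratio,
    percent = format_percent(ratio)
  )
  class(out) <- c("hit_result", class(out))
  out
}

#' Integrate dockable proteins and DEGs into one evidence set
#'
#' Unions a `DP` and a `DEG` evidence set into the integrated protein list
#' (`IP`). The overlap is retained (attribute `"overlap"`) for three-way
#' node colouring: DP-only, DEG-only, both.
#'
#' @param dps `evidence_set` with provenance `"DP"`.
#' @param degs `evidence_set` with provenance `"DEG"`.
#' @return An `evidence_set` with provenance `"IP"`.
#' @export
integrate_sets <- function(dps, degs) {
  stopifnot(inherits(dps, "evidence_set"), inherits(degs, "evidence_set"))
  if (dps$provenance != "DP") abort("`dps` must have provenance 'DP'")
  if (degs$provenance != "DEG") abort("`degs` must have provenance 'DEG'")
  out <- evidence_set(
    union(dps$members, degs$members), provenance = "IP",
    name = "integrated DP+DEG",
    params = paste0("union of [", dps$params, "] and [", degs$params, "]")
  )
  attr(out, "overlap") <- intersect(dps$members, degs$members)
  attr(out, "dp_only") <- setdiff(dps$members, degs$members)
  attr(out, "deg_only") <- setdiff(degs$members, dps$members)
  out
}
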