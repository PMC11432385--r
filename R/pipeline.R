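#' Default analysis parameters
#'
#' All thresholds of the analysis in one place: STRING score
#' cutoff 700, minimum retained component 10 nodes, top-20% degree hubs,
#' prediction-score cutoff 10, docking validity cutoff -8 kcal/mol, > 10
#' interactions for dockable proteins, > 50 compounds for core proteins,
#' |log2FC| > log2(1.5) with adjusted p < 0.05 for DEGs, and 100,000
#' permutations.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
default_params <- function(...) {
  params <- list(
    score_cutoff = 700,
    min_component_size = 10,
    hub_fraction = 0.2,
    np_score_cutoff = 10,
    affinity_cutoff = -8,
    dp_min_interactions = 10,
    core_min_compounds = 50,
    lfc_cutoff = log2(1.5),
    alpha = 0.05,
    n_permutations = 100000
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(params))
  if (length(bad) > 0) {
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  }
  params[names(dots)] <- dots
  params
}

#' Read a run configuration from YAML
#'
#' Flat YAML with an `organs` map (per organ: `proteins`, `interactions`,
#' `np_targets`, `docking`, `de` file paths), optional `params` overrides
#' of [default_params()], a `seed` and an `out_dir`. Paths are resolved
#' relative to the YAML file.
#'
#' @param path Path to the YAML configuration.
#' @return List with `organs` (list of `organ_bundle`s), `params`, `seed`,
#'   `out_dir`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$organs) || length(cfg$organs) < 2) {
    abort("config must define at least two organs")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  organs <- purrr::imap(cfg$organs, function(o, name) {
    need <- c("proteins", "interactions", "np_targets", "docking", "de")
    miss <- setdiff(need, names(o))
    if (length(miss) > 0) {
      abort(sprintf("organ '%s' is missing input(s): %s", name,
                    paste(miss, collapse = ", ")))
    }
    ints <- readr::read_delim(resolve(o$interactions), show_col_types = FALSE,
                              progress = FALSE)
    structure(
      list(
        label = name,
        proteins = load_protein_list(resolve(o$proteins), quiet = TRUE),
        interactions = tibble(a = ints[[1]], b = ints[[2]],
                              score = ints[["combined_score"]] %||% ints[[3]]),
        np_targets = readr::read_csv(resolve(o$np_targets),
                                     show_col_types = FALSE, progress = FALSE),
        docking = readr::read_csv(resolve(o$docking),
                                  show_col_types = FALSE, progress = FALSE),
        de = readr::read_csv(resolve(o$de), show_col_types = FALSE,
                             progress = FALSE)
      ),
      class = "organ_bundle"
    )
  })
  list(
    organs = organs,
    params = do.call(default_params, cfg$params %||% list()),
    seed = cfg$seed %||% 1L,
    out_dir = cfg$out_dir
  )
}

analyse_organ <- function(bundle, params, seed) {
  label <- bundle$label
  net <- build_network(bundle$proteins, bundle$interactions,
                       score_cutoff = params$score_cutoff,
                       min_component_size = params$min_component_size,
                       label = label)
  if (network_size(net) == 0) {
    abort(sprintf("stage build_network: organ '%s' network is empty", label))
  }
  hubs <- select_hubs(net, hub_fraction = params$hub_fraction)

  np <- parse_np_targets(bundle$np_targets,
                         score_cutoff = params$np_score_cutoff)
  valid <- filter_valid_interactions(bundle$docking,
                                     affinity_cutoff = params$affinity_cutoff)
  dp <- select_dockable_proteins(valid,
                                 min_interactions = params$dp_min_interactions)
  core <- select_core_proteins(valid,
                               min_compounds = params$core_min_compounds)
  degs <- select_degs(bundle$de, lfc_cutoff = params$lfc_cutoff,
                      alpha = params$alpha)
  ip <- integrate_sets(dp, degs$evidence)

  evs <- list(NP = np, DP = dp, DEG = degs$evidence, IP = ip)
  projections <- purrr::map(evs, project_evidence, network = net)
  whole <- purrr::map(projections, hit_ratio, against = net)
  hub_hits <- purrr::map(projections, hit_ratio, against = hubs)
  perms <- purrr::imap(projections, function(pr, nm) {
    if (length(pr$mapped) == 0) return(NULL)
    permutation_pvalue(net, hubs, pr,
                       n_permutations = params$n_permutations,
                       seed = seed + match(nm, names(evs)))
  })
  span <- if (length(projections$IP$mapped) > 0) {
    walks_to_full_span(net, projections$IP)
  }
  list(network = net, hubs = hubs, evidence = evs, core = core,
       degs = degs, projections = projections, whole = whole,
       hub_hits = hub_hits, perms = perms, spanning = span)
}

#' Run the full organ-dominance pipeline
#'
#' For every organ bundle: builds the pruned network, selects hubs, derives
#' the NP / DP / DEG / IP evidence sets, projects each onto the network,
#' computes whole-network and hub hit ratios, permutation p-values, and the
#' spanning analysis seeded by the integrated (IP) projection. Organs are
#' then compared on four criteria -- lower IP permutation p, higher IP hub
#' hit ratio, higher shell-1 spanning rate, fewer walks to full span -- and
#' the dominance verdict is the simple majority, each criterion reported
#' individually.
#'
#' @param bundles Named list of `organ_bundle`s (at least two), from
#'   [simulate_bundle()], [read_bundle()] or assembled by hand.
#' @param params Analysis parameters, see [default_params()].
#' @param seed Integer seed driving all permutation tests.
#' @param out_dir Optional directory; when given, every artifact (network
#'   exports, hit tables, permutation JSON, shell tables, report) is
#'   written there.
#' @return An object of class `comparison_report`.
#' @export
run_pipeline <- function(bundles, params = default_params(), seed = 1,
                         out_dir = NULL) {
  if (length(bundles) < 2) abort("run_pipeline needs at least two organs")
  labels <- purrr::map_chr(bundles, "label")
  names(bundles) <- labels
  # organs share the seed stream so identical inputs give identical results
  results <- purrr::imap(bundles, function(b, nm) {
    tryCatch(
      analyse_organ(b, params, seed = seed),
      error = function(e) {
        abort(sprintf("organ '%s': %s", nm, conditionMessage(e)))
      }
    )
  })

  whole_tbl <- purrr::map_dfr(results, function(r) {
    dplyr::bind_rows(r$whole)
  })
  hub_tbl <- purrr::map_dfr(results, function(r) {
    tbl <- dplyr::bind_rows(r$hub_hits)
    tbl$degree_threshold <- r$hubs$degree_threshold
    tbl$p_value <- purrr::map_dbl(r$perms[tbl$analysis], function(p) {
      if (is.null(p)) NA_real_ else p$p_value
    })
    tbl$p_display <- purrr::map_chr(r$perms[tbl$analysis], function(p) {
      if (is.null(p)) NA_character_ else p$p_display
    })
    tbl
  })
  span_tbl <- purrr::map_dfr(results, function(r) {
    if (is.null(r$spanning)) return(tibble())
    glance(r$spanning)
  })

  verdict <- dominance_verdict(results)
  report <- structure(
    list(
      whole = whole_tbl,
      hub = hub_tbl,
      spanning = span_tbl,
      verdict = verdict,
      params = params,
      seed = seed,
      organs = results
    ),
    class = "comparison_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Majority vote over the four narrative dominance criteria, computed on the
# integrated (IP) evidence. Ties on a criterion contribute no vote.
dominance_verdict <- function(results) {
  labels <- names(results)
  val <- function(f) purrr::map_dbl(results, f)
  criteria <- tibble(
    criterion = c("lower IP permutation p", "higher IP hub hit ratio",
                  "higher shell-1 spanning rate", "fewer walks to full span"),
    value = list(
      val(function(r) if (is.null(r$perms$IP)) NA_real_ else r$perms$IP$p_value),
      val(function(r) r$hub_hits$IP$ratio),
      val(function(r) {
        if (is.null(r$spanning)) NA_real_ else
          r$spanning$shells$rate[r$spanning$shells$walk == 1]
      }),
      val(function(r) if (is.null(r$spanning)) NA_real_ else
        r$spanning$walks_to_full)
    ),
    direction = c("min", "max", "max", "min")
  )
  criteria$winner <- purrr::map2_chr(criteria$value, criteria$direction,
    function(v, d) {
      if (all(is.na(v))) return(NA_character_)
      best <- if (d == "min") min(v, na.rm = TRUE) else max(v, na.rm = TRUE)
      w <- labels[!is.na(v) & v == best]
      if (length(w) == 1) w else "tie"
    })
  votes <- table(factor(criteria$winner[criteria$winner %in% labels],
                        levels = labels))
  top <- names(votes)[votes == max(votes)]
  dominant <- if (max(votes) == 0 || length(top) > 1) "tie" else top
  list(dominant = dominant, votes = as.list(votes),
       criteria = criteria[, c("criterion", "direction", "winner", "value")])
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== Organ-dominance comparison ==\n\nWhole-network hit ratios:\n")
  print(as.data.frame(x$whole[, c("analysis", "network", "denominator",
                                  "n_hit", "percent")]), row.names = FALSE)
  cat("\nHub hit ratios and permutation p:\n")
  print(as.data.frame(x$hub[, c("analysis", "network", "denominator",
                                "degree_threshold", "n_hit", "percent",
                                "p_display")]), row.names = FALSE)
  if (nrow(x$spanning) > 0) {
    cat("\nSpanning (IP seeds):\n")
    print(as.data.frame(x$spanning), row.names = FALSE)
  }
  cat(sprintf("\nDominant organ: %s\n", x$verdict$dominant))
  for (i in seq_len(nrow(x$verdict$criteria))) {
    cat(sprintf("  - %s: %s\n", x$verdict$criteria$criterion[i],
                x$verdict$criteria$winner[i]))
  }
  invisible(x)
}

#' @export
tidy.comparison_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$whole, degree_threshold = NA_integer_,
                  p_value = NA_real_, p_display = NA_character_),
    x$hub
  )
}

#' @export
glance.comparison_report <- function(x, ...) {
  tibble(
    n_organs = length(x$organs),
    dominant = x$verdict$dominant,
    seed = x$seed,
    n_permutations = x$params$n_permutations
  )
}

#' Write all report artifacts to a directory
#'
#' Emits, per organ, the network views (GraphML, SIF, node attributes), the
#' permutation results as JSON and the shell table as TSV; plus the
#' whole-network and hub hit-ratio TSVs and the full
#' report (verdict included) as JSON. Every number in the report is
#' recomputable from these files alone.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$whole, file.path(dir, "whole_network_hits.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$hub, file.path(dir, "hub_hits.tsv"),
                   progress = FALSE)
  if (nrow(report$spanning) > 0) {
    readr::write_tsv(report$spanning, file.path(dir, "spanning_summary.tsv"),
                     progress = FALSE)
  }
  for (nm in names(report$organs)) {
    r <- report$organs[[nm]]
    export_network_views(r$network, r$hubs, r$projections,
                         spanning = r$spanning,
                         dir = file.path(dir, nm))
    perms <- purrr::compact(r$perms)
    jsonlite::write_json(
      purrr::map(perms, function(p) tidy(p)),
      file.path(dir, nm, "permutation_results.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    if (!is.null(r$spanning)) {
      readr::write_tsv(r$spanning$shells,
                       file.path(dir, nm, "spanning_shells.tsv"),
                       progress = FALSE)
    }
  }
  jsonlite::write_json(
    list(
      dominant = report$verdict$dominant,
      votes = report$verdict$votes,
      criteria = purrr::pmap(report$verdict$criteria,
        function(criterion, direction, winner, value) {
          list(criterion = criterion, direction = direction,
               winner = winner, value = as.list(value))
        }),
      seed = report$seed,
      params = report$params
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
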