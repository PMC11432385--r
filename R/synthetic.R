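#' Synthetic study configuration
#'
#' Bundles every knob of the synthetic-data generators in one validated
#' list, mirroring the shape of a real study: an organ protein list with a
#' STRING-like interaction table, a compound-target prediction table, a
#' docking score table with planted strong binders, and a DESeq2-style
#' differential-expression table with planted up/down genes.
#'
#' Networks are grown by preferential attachment so the degree distribution
#' is heavy-tailed like a protein-protein interaction network -- hub
#' enrichment is only meaningful when a degree hierarchy exists. Evidence
#' sets are planted with a tunable `hub_bias`: the probability that each
#' planted protein is drawn from the hub set rather than elsewhere
#' (`hub_bias = 0` samples uniformly from all nodes, matching the
#' permutation null exactly).
#'
#' @param n_proteins Number of organ proteins (network nodes before pruning
#'   decoy cliques are added).
#' @param attachment_edges Edges added per node during preferential
#'   attachment (controls density).
#' @param score_range Integer (low, high) range of interaction scores.
#' @param below_cutoff_frac Fraction of edges forced below `score_cutoff`
#'   to exercise the edge filter.
#' @param score_cutoff Score threshold the downstream builder will use.
#' @param decoy_clique_sizes Integer vector of small disjoint clique sizes
#'   (< 10) appended to exercise component pruning.
#' @param n_compounds Compounds in the docking and target tables.
#' @param planted_dp Number of proteins planted as dockable (strong
#'   binders).
#' @param dp_compounds Strong-affinity compounds per planted protein (must
#'   exceed the DP `min_interactions` rule to be recoverable).
#' @param affinity_null_mean,affinity_null_sd Null docking affinity
#'   distribution, kcal/mol.
#' @param affinity_planted_mean,affinity_planted_sd Planted strong-binder
#'   affinity distribution, kcal/mol.
#' @param n_genes Genes in the DE table (network proteins padded with null
#'   genes).
#' @param planted_up,planted_down Planted DEG counts.
#' @param planted_lfc_mean,planted_lfc_sd Planted |log2FC| distribution
#'   (truncated above `lfc_cutoff`).
#' @param lfc_cutoff DEG fold-change threshold the table is built against.
#' @param planted_p Deterministic raw p-value given to planted DEGs; chosen
#'   far below the post-adjustment threshold so recovery is exact.
#' @param evidence_size Planted NP evidence-set size.
#' @param hub_bias Probability a planted evidence protein is drawn from the
#'   hub set, in `[0, 1]`.
#' @param n_decoys Evidence identifiers not present on the network.
#' @param seed Integer seed; every generator is a pure function of the
#'   configuration including this seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 300, attachment_edges = 2,
                             score_range = c(400L, 1000L),
                             below_cutoff_frac = 0.3, score_cutoff = 700,
                             decoy_clique_sizes = integer(0),
                             n_compounds = 60, planted_dp = 7,
                             dp_compounds = 15,
                             affinity_null_mean = -6, affinity_null_sd = 0.5,
                             affinity_planted_mean = -9.5,
                             affinity_planted_sd = 0.4,
                             n_genes = 2000, planted_up = 40,
                             planted_down = 25, planted_lfc_mean = 1.5,
                             planted_lfc_sd = 0.5, lfc_cutoff = log2(1.5),
                             planted_p = 1e-8, evidence_size = 50,
                             hub_bias = 0, n_decoys = 0, seed = 1) {
  cfg <- list(
    n_proteins = n_proteins, attachment_edges = attachment_edges,
    score_range = as.integer(score_range),
    below_cutoff_frac = below_cutoff_frac, score_cutoff = score_cutoff,
    decoy_clique_sizes = as.integer(decoy_clique_sizes),
    n_compounds = n_compounds, planted_dp = planted_dp,
    dp_compounds = dp_compounds,
    affinity_null_mean = affinity_null_mean,
    affinity_null_sd = affinity_null_sd,
    affinity_planted_mean = affinity_planted_mean,
    affinity_planted_sd = affinity_planted_sd,
    n_genes = n_genes, planted_up = planted_up, planted_down = planted_down,
    planted_lfc_mean = planted_lfc_mean, planted_lfc_sd = planted_lfc_sd,
    lfc_cutoff = lfc_cutoff, planted_p = planted_p,
    evidence_size = evidence_size, hub_bias = hub_bias,
    n_decoys = n_decoys, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_proteins >= cfg$attachment_edges + 1,
    length(cfg$score_range) == 2, cfg$score_range[1] <= cfg$score_range[2],
    cfg$below_cutoff_frac >= 0, cfg$below_cutoff_frac <= 1,
    all(cfg$decoy_clique_sizes >= 2),
    cfg$planted_dp <= cfg$n_proteins,
    cfg$affinity_null_sd > 0, cfg$affinity_planted_sd > 0,
    cfg$planted_up + cfg$planted_down <= cfg$n_genes,
    cfg$planted_lfc_sd > 0,
    cfg$hub_bias >= 0, cfg$hub_bias <= 1
  )
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic organ protein list and interaction table
#'
#' Grows an undirected preferential-attachment graph over
#' `cfg$n_proteins` symbols, draws integer edge scores uniformly from
#' `cfg$score_range` with a configurable fraction forced below the score
#' cutoff, and optionally appends small disjoint decoy cliques (high-score
#' edges, size < 10) that the component-pruning rule should remove.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `proteins` (character), `interactions` (tibble `a`,
#'   `b`, `score`) and `truth` (edges at/above cutoff, clique node ids).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    g <- igraph::sample_pa(cfg$n_proteins, power = 1,
                           m = cfg$attachment_edges, directed = FALSE)
    igraph::V(g)$name <- sprintf("P%04d", seq_len(cfg$n_proteins))
    el <- igraph::as_data_frame(g, what = "edges")
    ne <- nrow(el)
    lo <- cfg$score_range[1]
    hi <- cfg$score_range[2]
    cut <- cfg$score_cutoff
    below <- runif(ne) < cfg$below_cutoff_frac
    score <- integer(ne)
    # forced-below edges take scores in [lo, cut); the rest in [cut, hi]
    score[below] <- sample(seq(lo, cut - 1), sum(below), replace = TRUE)
    score[!below] <- sample(seq(cut, hi), sum(!below), replace = TRUE)
    ints <- tibble(a = el$from, b = el$to, score = score)
    proteins <- igraph::V(g)$name
    clique_nodes <- character(0)
    for (i in seq_along(cfg$decoy_clique_sizes)) {
      s <- cfg$decoy_clique_sizes[i]
      ids <- sprintf("D%02d_%02d", i, seq_len(s))
      pairs <- utils::combn(ids, 2)
      ints <- dplyr::bind_rows(ints, tibble(
        a = pairs[1, ], b = pairs[2, ],
        score = sample(seq(cut, hi), ncol(pairs), replace = TRUE)
      ))
      proteins <- c(proteins, ids)
      clique_nodes <- c(clique_nodes, ids)
    }
    list(
      proteins = proteins,
      interactions = ints,
      truth = list(
        n_edges_above_cutoff = sum(ints$score >= cut),
        n_edges_below_cutoff = sum(ints$score < cut),
        clique_nodes = clique_nodes,
        main_nodes = igraph::V(g)$name
      )
    )
  })
}

# Draw `size` node ids: each with probability hub_bias from the hub set,
# otherwise from the non-hubs; hub_bias = 0 degenerates to a uniform draw
# from ALL nodes so the null case matches the permutation null exactly.
draw_biased_nodes <- function(nodes, hub_members, size, hub_bias) {
  stopifnot(size <= length(nodes))
  if (hub_bias == 0) return(sample(nodes, size))
  hubs <- intersect(nodes, hub_members)
  rest <- setdiff(nodes, hub_members)
  n_hub <- rbinom(1, size, hub_bias)
  n_hub <- min(n_hub, length(hubs))
  n_rest <- min(size - n_hub, length(rest))
  n_hub <- size - n_rest  # top up from hubs if the non-hub pool ran short
  c(sample(hubs, n_hub), sample(rest, n_rest))
}

#' Generate a planted evidence set on a synthetic network
#'
#' Each member is drawn from the hub set with probability `hub_bias`,
#' otherwise uniformly from the non-hubs, without replacement
#' (`hub_bias = 0` draws uniformly from all nodes). Optional decoy
#' identifiers absent from the network exercise the unmapped-count
#' bookkeeping.
#'
#' @param network A `protein_network`.
#' @param hubs The network's `hub_set`.
#' @param evidence_size Number of planted on-network members.
#' @param hub_bias Hub-draw probability in `[0, 1]`.
#' @param n_decoys Off-network identifiers appended.
#' @param provenance Provenance tag for the resulting set.
#' @param seed Integer seed.
#' @return An `evidence_set` with attribute `"truth"` (planted hub and
#'   non-hub members, decoys).
#' @export
generate_evidence <- function(network, hubs, evidence_size = 50,
                              hub_bias = 0, n_decoys = 0,
                              provenance = "NP", seed = 1) {
  stopifnot(inherits(network, "protein_network"), inherits(hubs, "hub_set"))
  nodes <- network_nodes(network)
  stopifnot(evidence_size <= length(nodes))
  withr::with_seed(seed, {
    members <- draw_biased_nodes(nodes, hubs$members, evidence_size, hub_bias)
    decoys <- if (n_decoys > 0) sprintf("X%04d", seq_len(n_decoys)) else character(0)
    out <- evidence_set(
      c(members, decoys), provenance = provenance,
      name = sprintf("synthetic %s (hub_bias=%.2f)", provenance, hub_bias),
      params = sprintf("planted size %d + %d decoys", evidence_size, n_decoys)
    )
    attr(out, "truth") <- list(
      planted = members,
      planted_hubs = intersect(members, hubs$members),
      decoys = decoys
    )
    out
  })
}

#' Generate a synthetic compound-target prediction table
#'
#' Planted targets receive 1-4 compound interactions with prediction scores
#' at or above the cutoff; a background of sub-cutoff rows over other
#' proteins exercises the score filter.
#'
#' @param targets Character vector of planted target proteins.
#' @param other_proteins Pool of non-target proteins for sub-cutoff noise.
#' @param n_compounds Compound pool size.
#' @param score_cutoff Cutoff the table is built against (default 10).
#' @param n_noise Sub-cutoff rows to add.
#' @param seed Integer seed.
#' @return Tibble with columns `compound`, `target`, `score`.
#' @export
generate_np_table <- function(targets, other_proteins, n_compounds = 60,
                              score_cutoff = 10, n_noise = 200, seed = 1) {
  compounds <- sprintf("C%03d", seq_len(n_compounds))
  withr::with_seed(seed, {
    planted <- purrr::map_dfr(targets, function(t) {
      k <- sample(1:4, 1)
      tibble(compound = sample(compounds, k),
             target = t,
             score = round(runif(k, score_cutoff, score_cutoff + 30), 2))
    })
    noise_pool <- if (length(other_proteins) > 0) other_proteins else targets
    noise <- tibble(
      compound = sample(compounds, n_noise, replace = TRUE),
      target = sample(noise_pool, n_noise, replace = TRUE),
      score = round(runif(n_noise, 0, score_cutoff - 0.01), 2)
    )
    dplyr::bind_rows(planted, noise)
  })
}

#' Generate a synthetic docking score table
#'
#' Emits the full compound-by-protein affinity grid. Null pairs draw from
#' `Normal(affinity_null_mean, affinity_null_sd)` (default mean -6 kcal/mol,
#' essentially never below the -8 validity cutoff); each planted protein
#' gets `dp_compounds` compounds redrawn from the strong-binder distribution
#' (default mean -9.5), so the dockable-protein rule (> 10 valid
#' interactions) recovers the planted set.
#'
#' @param cfg A [synthetic_config()].
#' @param proteins Protein pool to dock against.
#' @param planted Planted dockable proteins; defaults to the first
#'   `cfg$planted_dp` of a random draw from `proteins`.
#' @return List with `table` (tibble `compound`, `protein`,
#'   `affinity_kcal_mol`) and `truth` (planted proteins, sub-cutoff pair
#'   count).
#' @export
generate_docking_table <- function(cfg, proteins, planted = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  compounds <- sprintf("C%03d", seq_len(cfg$n_compounds))
  withr::with_seed(cfg$seed + 1L, {
    if (is.null(planted)) {
      planted <- sample(proteins, cfg$planted_dp)
    }
    stopifnot(all(planted %in% proteins),
              cfg$dp_compounds <= cfg$n_compounds)
    grid <- tidyr::expand_grid(compound = compounds, protein = proteins)
    grid$affinity_kcal_mol <- round(
      rnorm(nrow(grid), cfg$affinity_null_mean, cfg$affinity_null_sd), 3)
    for (p in planted) {
      strong <- sample(compounds, cfg$dp_compounds)
      sel <- grid$protein == p & grid$compound %in% strong
      grid$affinity_kcal_mol[sel] <- round(
        rnorm(sum(sel), cfg$affinity_planted_mean, cfg$affinity_planted_sd), 3)
    }
    list(
      table = grid,
      truth = list(
        planted = planted,
        n_below_cutoff = sum(grid$affinity_kcal_mol < -8)
      )
    )
  })
}

#' Generate a synthetic differential-expression table
#'
#' Null genes draw `log2FoldChange ~ Normal(0, 0.2)` and uniform p-values;
#' planted genes draw `|log2FoldChange|` from a normal truncated above the
#' fold-change cutoff and receive a deterministic raw p-value far below the
#' post-adjustment threshold, so DEG selection recovers the planted sets
#' exactly. The emitted table carries DESeq2-dialect columns (`gene`,
#' `log2FoldChange`, `pvalue`, `padj`) with `padj` the Benjamini-Hochberg
#' adjustment of `pvalue`.
#'
#' @param cfg A [synthetic_config()].
#' @param gene_pool Optional gene universe; padded with `G`-prefixed null
#'   genes up to `cfg$n_genes`.
#' @param planted_up,planted_down Optional explicit planted gene sets;
#'   defaults to random draws of `cfg$planted_up` / `cfg$planted_down` from
#'   the pool.
#' @return List with `table` (tibble) and `truth` (`up`, `down`).
#' @export
generate_de_table <- function(cfg, gene_pool = NULL, planted_up = NULL,
                              planted_down = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed + 2L, {
    pool <- gene_pool %||% character(0)
    if (length(pool) < cfg$n_genes) {
      pool <- c(pool, sprintf("G%05d", seq_len(cfg$n_genes - length(pool))))
    }
    pool <- pool[seq_len(cfg$n_genes)]
    if (is.null(planted_up) && is.null(planted_down)) {
      pick <- sample(pool, cfg$planted_up + cfg$planted_down)
      planted_up <- head(pick, cfg$planted_up)
      planted_down <- setdiff(pick, planted_up)
    }
    planted_up <- planted_up %||% character(0)
    planted_down <- planted_down %||% character(0)
    stopifnot(all(c(planted_up, planted_down) %in% pool),
              length(intersect(planted_up, planted_down)) == 0)
    lfc <- rnorm(length(pool), 0, 0.2)
    pval <- runif(length(pool))
    names(lfc) <- names(pval) <- pool
    # truncated-above-cutoff |log2FC| via inverse-CDF sampling
    draw_lfc <- function(k) {
      lo <- pnorm(cfg$lfc_cutoff, cfg$planted_lfc_mean, cfg$planted_lfc_sd)
      qnorm(runif(k, lo, 1), cfg$planted_lfc_mean, cfg$planted_lfc_sd)
    }
    lfc[planted_up] <- draw_lfc(length(planted_up))
    lfc[planted_down] <- -draw_lfc(length(planted_down))
    pval[c(planted_up, planted_down)] <- cfg$planted_p
    tbl <- tibble(
      gene = pool,
      log2FoldChange = unname(lfc),
      pvalue = unname(pval),
      padj = p.adjust(unname(pval), method = "BH")
    )
    list(table = tbl, truth = list(up = planted_up, down = planted_down))
  })
}

#' Simulate a complete input bundle for one organ
#'
#' Generates every pipeline input with shared ground truth: the organ
#' protein list and interaction table, a compound-target prediction table
#' whose planted targets are drawn with the configured hub bias, a docking
#' table whose planted dockable proteins are hub-biased the same way, and a
#' DE table whose planted DEGs are hub-biased network proteins. The same
#' `hub_bias` therefore shifts all three evidence channels toward (or away
#' from) the organ's hubs.
#'
#' @param cfg A [synthetic_config()].
#' @param label Organ label for the bundle.
#' @return A list of class `organ_bundle` with elements `proteins`,
#'   `interactions`, `np_targets`, `docking`, `de`, `label`, `truth`.
#' @export
simulate_bundle <- function(cfg, label = "organ") {
  stopifnot(inherits(cfg, "synthetic_config"))
  net_raw <- generate_network(cfg)
  net <- build_network(net_raw$proteins, net_raw$interactions,
                       score_cutoff = cfg$score_cutoff,
                       min_component_size = 10, label = label)
  hubs <- select_hubs(net)
  np_ev <- generate_evidence(net, hubs, cfg$evidence_size, cfg$hub_bias,
                             n_decoys = cfg$n_decoys, provenance = "NP",
                             seed = cfg$seed + 3L)
  np_tbl <- generate_np_table(
    np_ev$members,
    setdiff(network_nodes(net), np_ev$members),
    n_compounds = cfg$n_compounds, seed = cfg$seed + 4L
  )
  dp_planted <- withr::with_seed(cfg$seed + 5L, {
    draw_biased_nodes(network_nodes(net), hubs$members, cfg$planted_dp,
                      cfg$hub_bias)
  })
  dock <- generate_docking_table(cfg, network_nodes(net), planted = dp_planted)
  deg_planted <- withr::with_seed(cfg$seed + 6L, {
    draw_biased_nodes(network_nodes(net), hubs$members,
                      cfg$planted_up + cfg$planted_down, cfg$hub_bias)
  })
  de <- generate_de_table(
    cfg, gene_pool = network_nodes(net),
    planted_up = head(deg_planted, cfg$planted_up),
    planted_down = deg_planted[seq_len(cfg$planted_down) + cfg$planted_up]
  )
  structure(
    list(
      label = label,
      proteins = net_raw$proteins,
      interactions = net_raw$interactions,
      np_targets = np_tbl,
      docking = dock$table,
      de = de$table,
      config = cfg,
      truth = list(
        network = net_raw$truth,
        np = attr(np_ev, "truth"),
        dp = dock$truth,
        deg = de$truth
      )
    ),
    class = "organ_bundle"
  )
}

#' Write an organ bundle to a directory as plain-text tables
#'
#' Emits the file dialects the readers consume: a headerless protein list,
#' a STRING-links-style interaction TSV, compound-target / docking / DE
#' CSVs, and the ground truth as JSON.
#'
#' @param bundle An `organ_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "organ_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    proteins = file.path(dir, "proteins.txt"),
    interactions = file.path(dir, "interactions.tsv"),
    np_targets = file.path(dir, "np_targets.csv"),
    docking = file.path(dir, "docking.csv"),
    de = file.path(dir, "de_results.csv"),
    truth = file.path(dir, "truth.json")
  )
  writeLines(bundle$proteins, paths["proteins"])
  readr::write_tsv(
    dplyr::rename(bundle$interactions, protein1 = "a", protein2 = "b",
                  combined_score = "score"),
    paths["interactions"], progress = FALSE
  )
  readr::write_csv(bundle$np_targets, paths["np_targets"], progress = FALSE)
  readr::write_csv(bundle$docking, paths["docking"], progress = FALSE)
  readr::write_csv(bundle$de, paths["de"], progress = FALSE)
  jsonlite::write_json(bundle$truth, paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}

#' Read an organ bundle back from a directory
#'
#' Inverse of [write_bundle()]: loads the raw tables (no filtering applied)
#' so the bundle round-trips losslessly through the standard readers.
#'
#' @param dir Directory written by [write_bundle()].
#' @param label Organ label.
#' @return An `organ_bundle` (without ground truth unless `truth.json`
#'   exists).
#' @export
read_bundle <- function(dir, label = basename(dir)) {
  ints <- readr::read_tsv(file.path(dir, "interactions.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  truth_path <- file.path(dir, "truth.json")
  structure(
    list(
      label = label,
      proteins = load_protein_list(file.path(dir, "proteins.txt"), quiet = TRUE),
      interactions = tibble(a = ints$protein1, b = ints$protein2,
                            score = ints$combined_score),
      np_targets = readr::read_csv(file.path(dir, "np_targets.csv"),
                                   show_col_types = FALSE, progress = FALSE),
      docking = readr::read_csv(file.path(dir, "docking.csv"),
                                show_col_types = FALSE, progress = FALSE),
      de = readr::read_csv(file.path(dir, "de_results.csv"),
                           show_col_types = FALSE, progress = FALSE),
      truth = if (file.exists(truth_path)) jsonlite::read_json(truth_path)
    ),
    class = "organ_bundle"
  )
}
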