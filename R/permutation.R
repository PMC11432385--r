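#' Permutation test for hub enrichment of a projected evidence set
#'
#' For each permutation, a node set of the same size as the mapped evidence
#' is drawn uniformly without replacement from the network's nodes and its
#' hub-hit count recorded. The p-value is the rank-based tail
#' `#(permutation count >= observed) / n_permutations` (with `tail = "gt"`
#' the strict form is used instead). Because the sample size is fixed, the
#' hub-hit count, the hit ratio over the sample and the hit ratio over the
#' hub set are rank-equivalent statistics; the count is used to avoid float
#' comparison. When no permutation reaches the observed count the display
#' form is `"<1/N"` (e.g. `"<0.00001"` at 100,000 permutations); the
#' add-one estimate `(b + 1) / (N + 1)` is always reported alongside as
#' `p_plus_one`.
#'
#' @param network A `protein_network`.
#' @param hubs The network's `hub_set`.
#' @param projection A `projection` of the evidence onto the same network.
#' @param n_permutations Number of resamples; default 100000.
#' @param seed Integer seed for reproducibility (the caller's RNG state is
#'   left untouched).
#' @param tail `"geq"` (default) counts permutations with count >= observed;
#'   `"gt"` counts strict exceedances.
#' @return An object of class `permutation_result`.
#' @export
permutation_pvalue <- function(network, hubs, projection,
                               n_permutations = 100000, seed = NULL,
                               tail = c("geq", "gt")) {
  tail <- match.arg(tail)
  stopifnot(inherits(network, "protein_network"),
            inherits(hubs, "hub_set"),
            inherits(projection, "projection"))
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  if (!identical(hubs$network_ref, network$label) ||
      !identical(projection$network_ref, network$label)) {
    abort("hubs and projection must refer to the same network")
  }
  nodes <- network_nodes(network)
  n <- length(nodes)
  m <- length(projection$mapped)
  if (m < 1) abort("projection has no mapped nodes to resample")
  if (m > n) abort("sample size exceeds network node count")
  observed <- length(intersect(projection$mapped, hubs$members))
  is_hub <- nodes %in% hubs$members

  draw <- function() {
    counts <- integer(n_permutations)
    for (i in seq_len(n_permutations)) {
      counts[i] <- sum(is_hub[sample.int(n, m)])
    }
    counts
  }
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  b <- if (tail == "geq") sum(counts >= observed) else sum(counts > observed)
  p <- b / n_permutations
  p_display <- if (b == 0) {
    paste0("<", format(1 / n_permutations, scientific = FALSE))
  } else {
    format(p, scientific = FALSE)
  }
  structure(
    list(
      network_ref = network$label,
      evidence_name = projection$evidence$name,
      observed_hub_hits = as.integer(observed),
      sample_size = as.integer(m),
      n_hubs = length(hubs$members),
      n_nodes = n,
      n_permutations = as.integer(n_permutations),
      n_at_least = as.integer(b),
      p_value = p,
      p_plus_one = (b + 1) / (n_permutations + 1),
      p_display = p_display,
      tail = tail,
      seed = seed,
      null_counts = counts
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result '%s' on '%s'> %d/%d hub hits in %d sampled; p %s (%d permutations)\n",
    x$evidence_name, x$network_ref, x$observed_hub_hits, x$n_hubs,
    x$sample_size, x$p_display, x$n_permutations
  ))
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(
    network = x$network_ref,
    evidence = x$evidence_name,
    observed_hub_hits = x$observed_hub_hits,
    sample_size = x$sample_size,
    n_hubs = x$n_hubs,
    n_permutations = x$n_permutations,
    n_at_least = x$n_at_least,
    p_value = x$p_value,
    p_plus_one = x$p_plus_one,
    p_display = x$p_display
  )
}

#' @export
glance.permutation_result <- function(x, ...) tidy(x)

#' Exact hypergeometric tail probability
#'
#' Closed-form counterpart of the permutation null: the probability that a
#' uniform without-replacement sample of `sample_size` nodes from a network
#' of `n_nodes` containing `n_hubs` hubs contains at least `observed` hubs.
#' Used as an independent oracle for [permutation_pvalue()]; the permutation
#' sampler remains the primary method.
#'
#' @param n_nodes Network size.
#' @param n_hubs Number of hub nodes.
#' @param sample_size Evidence sample size.
#' @param observed Observed hub-hit count.
#' @return `P(X >= observed)` for `X ~ Hypergeometric(n_hubs, n_nodes - n_hubs,
#'   sample_size)`.
#' @export
exact_pvalue <- function(n_nodes, n_hubs, sample_size, observed) {
  if (observed < 0 || n_hubs > n_nodes || sample_size > n_nodes ||
      observed > min(n_hubs, sample_size)) {
    abort("inconsistent counts for hypergeometric tail")
  }
  phyper(observed - 1, n_hubs, n_nodes - n_hubs, sample_size,
         lower.tail = FALSE)
}

#' @describeIn autoplot.spanning_result Null hub-hit distribution with the
#'   observed count marked.
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble(count = object$null_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar(fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_hub_hits,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "hub hits per permutation",
      y = "permutations",
      title = sprintf("%s on %s: observed %d hub hits, p %s",
                      object$evidence_name, object$network_ref,
                      object$observed_hub_hits, object$p_display)
    ) +
    ggplot2::theme_minimal()
}
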