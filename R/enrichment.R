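# Permutation enrichment of divergent pairs, the hybrid-gene computation and
# grouped external-binding comparisons.

#' Permutation test for divergent-pair enrichment in a gene group
#'
#' Counts the pairs with both members inside `group`, then builds a null
#' distribution by drawing `length(group)` genes uniformly without
#' replacement from the universe `n_samples` times and counting pairs in each
#' draw. Both an enrichment p (null >= observed) and a depletion p (null <=
#' observed) are reported under the add-one convention
#' `p = (#{null as-or-more extreme} + 1) / (n_samples + 1)`, which keeps the
#' empirical p strictly positive.
#'
#' @param pairs a [DivergentPairSet-class]; its universe defines the sampling
#'   frame.
#' @param group character vector of gene ids, a subset of the universe.
#' @param n_samples number of random resamples (default 10000).
#' @param seed optional integer seed for reproducible resampling.
#' @return a [PermutationResult-class].
#' @export
pairPermutationTest <- function(pairs, group, n_samples = 10000L,
                                seed = NULL) {
  stopifnot(is(pairs, "DivergentPairSet"))
  universe <- pairUniverse(pairs)
  group <- unique(group)
  if (!all(group %in% universe))
    stop("group contains genes outside the pair universe")
  if (length(group) > length(universe))
    stop("group larger than universe")
  pt <- pairTable(pairs)
  i1 <- match(pt$gene1, universe)
  i2 <- match(pt$gene2, universe)
  N <- length(universe); g <- length(group)
  in_group <- universe %in% group
  observed <- sum(in_group[i1] & in_group[i2])
  if (!is.null(seed)) set.seed(as.integer(seed))
  null_counts <- integer(n_samples)
  member <- logical(N)
  for (b in seq_len(n_samples)) {
    idx <- sample.int(N, g)
    member[] <- FALSE
    member[idx] <- TRUE
    null_counts[b] <- sum(member[i1] & member[i2])
  }
  new("PermutationResult", observed = as.integer(observed),
      null_counts = null_counts,
      p_enrich = (sum(null_counts >= observed) + 1) / (n_samples + 1),
      p_deplete = (sum(null_counts <= observed) + 1) / (n_samples + 1),
      n_samples = as.integer(n_samples),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Exact pair-count distribution by exhaustive subset enumeration
#'
#' Enumerates every size-`g` subset of the universe and returns the exact
#' probability that the number of pairs fully inside a random subset is at
#' least (or at most) the observed count. Intended as an oracle for
#' [pairPermutationTest()] on small universes.
#'
#' @param pairs a [DivergentPairSet-class] with a universe of at most ~15
#'   genes.
#' @param group gene ids (only its size matters for the null).
#' @return list with `observed`, `p_enrich`, `p_deplete`, `null_mean`.
#' @export
exactPairEnrichment <- function(pairs, group) {
  universe <- pairUniverse(pairs)
  N <- length(universe)
  if (N > 20) stop("exhaustive enumeration limited to universes of <= 20")
  pt <- pairTable(pairs)
  i1 <- match(pt$gene1, universe); i2 <- match(pt$gene2, universe)
  g <- length(unique(group))
  in_group <- universe %in% group
  observed <- sum(in_group[i1] & in_group[i2])
  subsets <- utils::combn(N, g)
  cnt <- apply(subsets, 2, function(idx) {
    member <- logical(N); member[idx] <- TRUE
    sum(member[i1] & member[i2])
  })
  list(observed = observed,
       p_enrich = mean(cnt >= observed),
       p_deplete = mean(cnt <= observed),
       null_mean = mean(cnt))
}

#' Elongation-factor level on Pol2 at a reporter gene (hybrid construct)
#'
#' Given factor-IP, Pol2-IP and no-tag signals at control genes (where all
#' strains are expected to agree) and at one test gene, computes per-strain
#' scaling factors as the mean over control genes of reference/strain signal
#' ratios, applies them, and evaluates
#' `(factor - notag) / (pol2 - notag)` at the test gene.
#'
#' @param controls data.frame of control-gene signals, one row per control
#'   gene, with one numeric column per strain (e.g. `paf1`, `rpb3`, `notag`).
#' @param test named numeric vector (or one-row data.frame) of test-gene
#'   signals with the same names.
#' @param test_col,pol2_col,bg_col column names of the factor-IP, Pol2-IP and
#'   no-tag strains (defaults `"paf1"`, `"rpb3"`, `"notag"`).
#' @param reference strain used as scaling reference (default: the Pol2
#'   strain).
#' @return list with `level` (NA with a warning when the scaled Pol2 minus
#'   background is not positive) and `scalings` (named vector).
#' @examples
#' controls <- data.frame(paf1 = 1, rpb3 = 2, notag = 2)
#' hybridGeneLevel(controls, c(paf1 = 3, rpb3 = 2, notag = 1))$level  # 5
#' @export
hybridGeneLevel <- function(controls, test, test_col = "paf1",
                            pol2_col = "rpb3", bg_col = "notag",
                            reference = pol2_col) {
  cols <- c(test_col, pol2_col, bg_col)
  if (!all(cols %in% names(controls)))
    stop("controls must have columns ", paste(cols, collapse = ", "))
  test <- unlist(test[cols])
  if (nrow(controls) < 1) stop("at least one control gene is required")
  if (any(controls[cols] <= 0))
    stop("control-gene signals must be positive to determine scalings")
  scalings <- vapply(cols, function(f)
    mean(controls[[reference]] / controls[[f]]), numeric(1))
  scaled <- scalings * test
  denom <- scaled[pol2_col] - scaled[bg_col]
  if (denom <= 0) {
    warning("scaled Pol2 signal does not exceed background at the test ",
            "gene; level undefined")
    return(list(level = NA_real_, scalings = scalings))
  }
  list(level = unname((scaled[test_col] - scaled[bg_col]) / denom),
       scalings = scalings)
}

#' Compare per-gene binding densities between occupancy classes
#'
#' Group means with standard errors for `enriched`, `depleted` and `ns`
#' genes, plus one-sided Welch t tests of enriched-vs-ns (alternative:
#' greater) and depleted-vs-ns (alternative: less). Used for externally
#' measured RNA-binding densities (e.g. crosslinking counts per nucleotide,
#' normalized for transcript level upstream).
#'
#' @param density numeric per-gene binding density.
#' @param groups character/factor of the same length with values
#'   `"enriched"`, `"depleted"`, `"ns"`.
#' @return list with `summary` (data.frame: group, n, mean, sem) and `tests`
#'   (data.frame: comparison, alternative, t, df, p; a comparison is NA when
#'   a group has fewer than 2 values).
#' @export
groupBindingCompare <- function(density, groups) {
  groups <- as.character(groups)
  stopifnot(length(density) == length(groups))
  keep <- !is.na(density) & groups %in% c("enriched", "depleted", "ns")
  density <- density[keep]; groups <- groups[keep]
  lv <- c("enriched", "depleted", "ns")
  summ <- do.call(rbind, lapply(lv, function(g) {
    x <- density[groups == g]
    data.frame(group = g, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_)
  }))
  welch <- function(a, b, alternative) {
    x <- density[groups == a]; y <- density[groups == b]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(comparison = paste0(a, "_vs_", b),
                        alternative = alternative, t = NA_real_,
                        df = NA_real_, p = NA_real_))
    ht <- stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
    data.frame(comparison = paste0(a, "_vs_", b), alternative = alternative,
               t = unname(ht$statistic), df = unname(ht$parameter),
               p = unname(ht$p.value))
  }
  list(summary = summ,
       tests = rbind(welch("enriched", "ns", "greater"),
                     welch("depleted", "ns", "less")))
}

#' Cluster-membership percentages for gene groups
#'
#' Joins gene groups against published cluster memberships and reports, per
#' group and cluster, the percentage of the group's genes in that cluster
#' (no statistical claim).
#'
#' @param groups named list of gene-id vectors.
#' @param clusters data.frame with columns `gene_id` and `cluster`.
#' @return data.frame: `group`, `cluster`, `n`, `percent`.
#' @export
clusterMembership <- function(groups, clusters) {
  out <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    cl <- clusters$cluster[match(ids, clusters$gene_id)]
    cl <- cl[!is.na(cl)]
    if (!length(cl)) next
    tab <- table(cl)
    out[[g]] <- data.frame(group = g, cluster = names(tab),
                           n = as.integer(tab),
                           percent = 100 * as.integer(tab) / length(cl))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
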