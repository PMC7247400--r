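# Overrepresentation analysis of DDRG groups against user-supplied gene-set
# collections (GMT format).

#' Read a gene-set collection in GMT format
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#'
#' @param path path to the .gmt file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Build a validated gene-set collection against a universe
#'
#' Set members outside the universe are removed; sets left empty are
#' dropped.
#'
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all testable gene ids (typically the
#'   genes that entered the fitting stage).
#' @return list with elements \code{sets} and \code{universe}.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets),
            length(universe) > 0)
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L) stop("no gene set overlaps the universe")
  list(sets = sets, universe = universe)
}

#' Hypergeometric overrepresentation test
#'
#' One-sided hypergeometric tail probability of the observed overlap per
#' set, with Benjamini-Hochberg adjustment across sets.
#'
#' @param query character vector of gene ids (must lie in the universe).
#' @param collection a [gene_set_collection()].
#' @param alpha significance cut on the adjusted p-value (default 0.05).
#' @return data.frame with one row per set: \code{set}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{universe_size}, \code{pval},
#'   \code{adj_pval}, \code{significant}.
#' @export
overrepresentation <- function(query, collection, alpha = 0.05) {
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("empty query gene list")
  extra <- setdiff(query, collection$universe)
  if (length(extra) > 0L) {
    stop("query genes outside the universe: ", extra[1L],
         if (length(extra) > 1L) paste0(" (and ", length(extra) - 1L, " more)"))
  }
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    m <- length(s)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = m, query_size = n,
               universe_size = N, pval = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_pval <- stats::p.adjust(out$pval, method = "BH")
  out$significant <- out$adj_pval < alpha
  out[order(out$pval), ]
}

#' Overrepresentation per POD-label group
#'
#' Runs [overrepresentation()] on each group of DDR genes sharing a joint
#' POD label.
#'
#' @param results results data.frame of a [run_ddr()] object.
#' @param collection a [gene_set_collection()].
#' @param alpha adjusted-p cut (default 0.05).
#' @return named list of enrichment tables, one per joint label.
#' @export
enrich_by_label <- function(results, collection, alpha = 0.05) {
  groups <- split(results$gene_id, results$joint_label)
  groups <- lapply(groups, intersect, collection$universe)
  groups <- groups[lengths(groups) > 0L]
  lapply(groups, overrepresentation, collection = collection, alpha = alpha)
}
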