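# Hypergeometric over-representation of gene sets in communities.
#
# Community membership is an unranked gene list, so enrichment is
# over-representation analysis: the upper-tail hypergeometric probability
# of observing at least k genes of a set of size K inside a query of size
# n drawn from a universe of N genes, followed by Benjamini-Hochberg
# false-discovery-rate adjustment across sets within each query.

#' Construct a gene-set collection
#'
#' @param sets Named list; each element a list with `description` and
#'   `genes` (character). Duplicate members within a set are dropped.
#' @return List of class `gene_set_collection` with elements `sets` and
#'   `universe` (union of all members).
#' @export
gene_set_collection <- function(sets) {
  if (length(sets) && is.null(names(sets))) {
    stop_input("gene sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    stop_input("duplicated gene-set name: ",
               names(sets)[duplicated(names(sets))][1L])
  }
  sets <- lapply(sets, function(s) {
    list(description = as.character(s$description %||% ""),
         genes = unique(as.character(s$genes)))
  })
  structure(list(sets = sets,
                 universe = sort(unique(unlist(lapply(sets, `[[`, "genes"),
                                               use.names = FALSE)))),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then member genes, all
#' tab-separated (the MSigDB exchange format).
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_input("GMT parse error at line ", i,
                 ": need name, description and >=1 member")
    }
    sets[[fields[1L]]] <- list(description = fields[2L],
                               genes = fields[-(1:2)])
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` marked genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are marked.
#'
#' @param k Observed overlap.
#' @param n Query (draw) size.
#' @param K Gene-set size within the universe.
#' @param N Universe size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_test <- function(k, n, K, N) {
  if (!all(vapply(list(k, n, K, N), is_count, logical(1L)))) {
    stop_input("k, n, K, N must be non-negative counts")
  }
  if (k > min(n, K) || n > N || K > N) {
    stop_input("inconsistent counts: need k <= min(n, K) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; q-values are monotone along
#' the sorted p-values and never below their p-value.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop_input("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation of gene sets in communities
#'
#' Tests every community with at least `min_size` members against every
#' set in the collection. The universe is the intersection of `universe`
#' (by default the collection's own universe) with the collection
#' universe; community and set memberships are intersected with it before
#' testing. BH adjustment is applied per community across sets.
#'
#' @param partition A community partition from [louvain()].
#' @param collection A [gene_set_collection()].
#' @param universe Optional character vector of genes defining the
#'   analysis namespace (typically all annotated genes).
#' @param min_size Minimum community size to test (default 50, the
#'   conventional cutoff for community-level enrichment).
#' @return Data frame with columns `community`, `set`, `k`, `n`, `K`,
#'   `N`, `p_value`, `q_value`, ordered by community then p-value.
#' @export
enrich_communities <- function(partition, collection, universe = NULL,
                               min_size = 50L) {
  if (!inherits(partition, "community_partition")) {
    stop_input("`partition` must come from louvain()")
  }
  if (!inherits(collection, "gene_set_collection")) {
    stop_input("`collection` must be a gene_set_collection")
  }
  if (!length(collection$sets)) stop_input("empty gene-set collection")
  U <- if (is.null(universe)) collection$universe else
    intersect(as.character(universe), collection$universe)
  if (!length(U)) {
    stop_input("universe does not intersect the gene-set collection")
  }
  N <- length(U)
  comm_sizes <- table(partition$assignment)
  big <- names(comm_sizes)[comm_sizes >= min_size]
  out <- list()
  for (cid in big) {
    members <- intersect(names(partition$assignment)[
      partition$assignment == as.integer(cid)], U)
    n <- length(members)
    if (n == 0L) next
    rows <- lapply(names(collection$sets), function(nm) {
      set_genes <- intersect(collection$sets[[nm]]$genes, U)
      K <- length(set_genes)
      if (K == 0L) return(NULL)
      k <- length(intersect(members, set_genes))
      data.frame(community = as.integer(cid), set = nm, k = k, n = n,
                 K = K, N = N,
                 p_value = hypergeometric_test(k, n, K, N),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) next
    tab$q_value <- bh_adjust(tab$p_value)
    out[[cid]] <- tab[order(tab$p_value, tab$set), , drop = FALSE]
  }
  if (!length(out)) {
    warning("no community reaches min_size = ", min_size)
    return(data.frame(community = integer(), set = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
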