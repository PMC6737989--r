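#' Build a Pearson-thresholded co-expression graph
#'
#' Undirected graph over features; an edge is present when the Pearson
#' correlation between the two features' expression profiles is at least
#' `r_min` (default 0.90). Zero-variance features cannot carry a defined
#' correlation and are excluded with a message.
#'
#' @param expr `normalized_matrix` or matrix (features x samples, >= 3
#'   samples), pre-filtered to expressed features.
#' @param r_min correlation threshold (inclusive `>=`).
#' @return an object of class `coexpression_graph`: list with `nodes`
#'   (character), `edges` (data.frame `a`, `b`, `r`), `r_min`.
#' @export
build_correlation_graph <- function(expr, r_min = 0.90) {
  v <- expr_values(expr)
  if (ncol(v) < 3L) {
    stop("correlation graph needs >= 3 samples", call. = FALSE)
  }
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    message("excluding ", sum(sds == 0), " zero-variance feature(s)")
    v <- v[sds > 0, , drop = FALSE]
  }
  nodes <- rownames(v)
  r <- stats::cor(t(v))
  idx <- which(upper.tri(r) & r >= r_min, arr.ind = TRUE)
  edges <- data.frame(a = nodes[idx[, 1L]], b = nodes[idx[, 2L]],
                      r = r[idx], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, r_min = r_min),
            class = "coexpression_graph")
}

#' Markov clustering (MCL) of a co-expression graph
#'
#' Standard MCL: a column-stochastic transition matrix with unit self-loops
#' is alternately expanded (matrix power) and inflated (elementwise power
#' followed by column renormalization), with small entries pruned, until the
#' maximum column change falls below `tol`. Clusters are read off as the
#' connected components of the attractor structure. Edges enter unweighted
#' (weight 1) after thresholding unless `use_weights` is set.
#'
#' @param graph a `coexpression_graph`.
#' @param inflation inflation exponent (default 2.2).
#' @param expansion expansion power (default 2).
#' @param prune_below entries below this value are set to zero each
#'   iteration.
#' @param max_iter iteration cap; non-convergence returns the current
#'   clustering with a warning and `converged = FALSE`.
#' @param tol convergence tolerance on the max absolute matrix change.
#' @param use_weights use edge correlations as weights instead of 1.
#' @return an object of class `cluster_set`: list with `clusters` (list of
#'   character vectors, size >= 2, ordered by decreasing size), `singletons`
#'   (character), `labels` (NULL until [label_clusters()]), `inflation`,
#'   `converged`, `iterations`.
#' @export
mcl_cluster <- function(graph, inflation = 2.2, expansion = 2L,
                        prune_below = 1e-5, max_iter = 200L, tol = 1e-6,
                        use_weights = FALSE) {
  stopifnot(inherits(graph, "coexpression_graph"))
  nodes <- sort(graph$nodes)   # canonical order: row-order invariance
  n <- length(nodes)
  if (n == 0L) stop("empty graph", call. = FALSE)
  linked <- unique(c(graph$edges$a, graph$edges$b))
  isolated <- setdiff(nodes, linked)
  active <- sort(intersect(nodes, linked))
  clusters <- list()
  converged <- TRUE
  iter <- 0L
  if (length(active) > 0L) {
    m <- length(active)
    A <- matrix(0, m, m, dimnames = list(active, active))
    w <- if (use_weights) graph$edges$r else rep(1, nrow(graph$edges))
    A[cbind(match(graph$edges$a, active), match(graph$edges$b, active))] <- w
    A[cbind(match(graph$edges$b, active), match(graph$edges$a, active))] <- w
    diag(A) <- 1
    M <- sweep(A, 2L, colSums(A), "/")
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      prev <- M
      for (k in seq_len(expansion - 1L)) M <- M %*% prev  # matrix power
      M <- M^inflation
      M[M < prune_below] <- 0
      cs <- colSums(M)
      cs[cs == 0] <- 1
      M <- sweep(M, 2L, cs, "/")
      if (max(abs(M - prev)) < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warning("MCL did not converge within ", max_iter, " iterations",
              call. = FALSE)
    }
    # clusters = connected components of the limit matrix support
    sup <- which(M > 0, arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = active[sup[, 1L]], to = active[sup[, 2L]]),
      directed = FALSE,
      vertices = data.frame(name = active)
    )
    comp <- igraph::components(g)
    clusters <- split(active, comp$membership[active])
  }
  sizes <- vapply(clusters, length, integer(1L))
  singles <- unlist(clusters[sizes == 1L], use.names = FALSE)
  clusters <- clusters[sizes >= 2L]
  clusters <- lapply(clusters, sort)
  ord <- order(-vapply(clusters, length, integer(1L)),
               vapply(clusters, `[`, character(1L), 1L))
  clusters <- unname(clusters[ord])
  structure(list(clusters = clusters,
                 singletons = sort(c(isolated, singles)),
                 labels = NULL, inflation = inflation,
                 converged = converged, iterations = iter),
            class = "cluster_set")
}

#' Label clusters by their dominant tissue
#'
#' Each cluster is labeled with the tissue (sample column) whose mean
#' expression over the cluster members is maximal. Exact ties are broken
#' towards the lexicographically first tissue name, with a warning.
#'
#' @param clusters a `cluster_set`.
#' @param expr expression matrix covering every clustered node.
#' @return the `cluster_set` with `labels` filled (character vector
#'   parallel to `clusters`).
#' @export
label_clusters <- function(clusters, expr) {
  stopifnot(inherits(clusters, "cluster_set"))
  v <- expr_values(expr)
  labs <- vapply(clusters$clusters, function(members) {
    missing <- setdiff(members, rownames(v))
    if (length(missing) > 0L) {
      stop("no expression profile for clustered node(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    mu <- colMeans(v[members, , drop = FALSE])
    top <- names(mu)[mu == max(mu)]
    if (length(top) > 1L) {
      warning("tie between tissues ", paste(top, collapse = ", "),
              "; using ", min(top), call. = FALSE)
    }
    min(top)
  }, character(1L))
  clusters$labels <- labs
  clusters
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters (inflation %.2f), %d singletons%s\n",
              length(x$clusters), x$inflation, length(x$singletons),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
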